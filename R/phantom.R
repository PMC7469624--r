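#' Synthetic kidney/tumor phantom specification
#'
#' Parameters of the digital phantom used to exercise and validate the whole
#' mold pipeline without patient data: an ellipsoidal kidney, a spherical
#' (optionally lobulated) tumor bulging from its surface, a perinephric fat
#' shell of direction-dependent thickness with a designated thin point over
#' the tumor (the tumor contact point) and a second thin point over the
#' kidney, and a hemispherical hilar notch on the medial surface.
#'
#' Defaults approximate an adult kidney (10 x 5.6 x 4.4 cm) carrying a large
#' 4.2-cm-diameter lower-pole tumor, with fat 4-12 mm thick away from the
#' contact points.
#'
#' @param kidney_semiaxes_mm ellipsoid semi-axes (long axis first).
#' @param tumor_radius_mm tumor radius.
#' @param tumor_direction unit-ish direction from the kidney center to the
#'   tumor; the tumor center sits on the kidney surface along it.
#' @param fat_range_mm min/max ambient fat thickness.
#' @param fat_min_mm fat thickness at the tumor contact point.
#' @param kidney_contact_mm fat thickness at the kidney contact point.
#' @param kidney_contact_direction direction of the kidney contact point.
#' @param hilum_notch_mm diameter of the hemispherical hilar notch on the
#'   medial (-y) kidney surface.
#' @param lobulation_amp amplitude of a low-order spherical-harmonic
#'   perturbation of the tumor radius (0 = perfect sphere).
#' @param spacing_mm lattice spacing of the anatomy volumes.
#' @param map_spacing_mm lattice spacing of the multiparametric maps
#'   (functional MRI maps are coarser than anatomy; 2 mm gives roughly
#'   5,000 tumor voxels at the default tumor size).
#' @param habitat_layout a [default_habitat_layout()]-style layout.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(kidney_semiaxes_mm = c(50, 28, 22),
                         tumor_radius_mm = 21,
                         tumor_direction = c(-0.55, -0.60, -0.58),
                         fat_range_mm = c(4, 12),
                         fat_min_mm = 1,
                         kidney_contact_mm = 3,
                         kidney_contact_direction = c(0, 0.35, 0.94),
                         hilum_notch_mm = 10,
                         lobulation_amp = 0,
                         spacing_mm = 1,
                         map_spacing_mm = 2,
                         habitat_layout = default_habitat_layout()) {
  stopifnot(length(kidney_semiaxes_mm) == 3, all(kidney_semiaxes_mm > 0),
            tumor_radius_mm > 0, all(fat_range_mm > 0),
            fat_range_mm[1] <= fat_range_mm[2], fat_min_mm > 0,
            spacing_mm > 0, map_spacing_mm > 0, lobulation_amp >= 0)
  structure(list(kidney_semiaxes_mm = kidney_semiaxes_mm,
                 tumor_radius_mm = tumor_radius_mm,
                 tumor_direction = unitv(tumor_direction, "tumor direction"),
                 fat_range_mm = fat_range_mm, fat_min_mm = fat_min_mm,
                 kidney_contact_mm = kidney_contact_mm,
                 kidney_contact_direction =
                   unitv(kidney_contact_direction, "kidney contact direction"),
                 hilum_notch_mm = hilum_notch_mm,
                 lobulation_amp = lobulation_amp,
                 spacing_mm = spacing_mm, map_spacing_mm = map_spacing_mm,
                 habitat_layout = habitat_layout),
            class = "phantom_spec")
}

# ellipsoid radius along a unit direction
ellipsoid_radius <- function(semi, u) {
  1 / sqrt(sum((u / semi)^2))
}

# low-order (l = 2) real spherical-harmonic perturbation of a unit direction
# field; coefficients drawn once from the rng
sh2_field <- function(coef, ux, uy, uz) {
  coef[1] * (ux^2 - uy^2) + coef[2] * (3 * uz^2 - 1) / 2 +
    coef[3] * ux * uy + coef[4] * ux * uz + coef[5] * uy * uz
}

#' Generate the phantom anatomy
#'
#' Builds the kidney, tumor and fat masks, the landmark set and an analytic
#' ground-truth record on a lattice of `spec$spacing_mm`. The same seed
#' reproduces bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the lobulation coefficients.
#' @return list with `study` (an [mri_study()]), and `truth` (analytic
#'   parameters: centers, radii, landmark coordinates, seed).
#' @export
make_anatomy <- function(spec = phantom_spec(), seed = 7) {
  semi <- spec$kidney_semiaxes_mm
  u_t <- spec$tumor_direction
  r_t <- spec$tumor_radius_mm
  c_t <- u_t * ellipsoid_radius(semi, u_t) # tumor center on the kidney surface

  # consistency: the tumor must bulge from the surface, not drown in the core
  apex <- c_t + r_t * u_t
  if (sum((apex / semi)^2) <= 1) {
    stop("inconsistent phantom spec: tumor lies inside the kidney core")
  }
  inner <- c_t - r_t * u_t
  if (sum((inner / semi)^2) >= 1) {
    stop("inconsistent phantom spec: tumor does not intersect the kidney")
  }

  set.seed(seed)
  sh_coef <- if (spec$lobulation_amp > 0) {
    rnorm(5, 0, spec$lobulation_amp)
  } else {
    rep(0, 5)
  }

  sp <- spec$spacing_mm
  fat_hi <- spec$fat_range_mm[2]
  pad <- fat_hi + 5
  lim <- rbind(-semi - pad, semi + pad)
  lim[1, ] <- pmin(lim[1, ], c_t - r_t - pad)
  lim[2, ] <- pmax(lim[2, ], c_t + r_t + pad)
  xs <- seq(floor(lim[1, 1]), ceiling(lim[2, 1]), by = sp)
  ys <- seq(floor(lim[1, 2]), ceiling(lim[2, 2]), by = sp)
  zs <- seq(floor(lim[1, 3]), ceiling(lim[2, 3]), by = sp)
  d <- c(length(xs), length(ys), length(zs))
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  kidney <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
  # hilar notch: hemisphere removed at the medial surface point
  hil <- c(0, -semi[2], 0)
  notch_r <- spec$hilum_notch_mm / 2
  kidney <- kidney &
    ((X - hil[1])^2 + (Y - hil[2])^2 + (Z - hil[3])^2 > notch_r^2)

  DX <- X - c_t[1]; DY <- Y - c_t[2]; DZ <- Z - c_t[3]
  RT <- sqrt(DX^2 + DY^2 + DZ^2)
  if (spec$lobulation_amp > 0) {
    eps <- 1e-9
    r_loc <- r_t * (1 + sh2_field(sh_coef, DX / (RT + eps), DY / (RT + eps),
                                  DZ / (RT + eps)))
    tumor <- RT <= r_loc
  } else {
    tumor <- RT <= r_t
  }

  # the tumor replaces kidney parenchyma: tissue masks are disjoint
  kidney <- kidney & !tumor
  organ <- kidney | tumor
  Dorg <- distance_transform(organ, rep(sp, 3))

  # direction-dependent fat thickness with sharp minima at the contact points
  Rc <- sqrt(X^2 + Y^2 + Z^2) + 1e-9
  ux <- X / Rc; uy <- Y / Rc; uz <- Z / Rc
  d_thick <- unitv(-u_t) # thickest fat opposite the tumor
  cos_thick <- ux * d_thick[1] + uy * d_thick[2] + uz * d_thick[3]
  base_th <- spec$fat_range_mm[1] +
    diff(spec$fat_range_mm) * (1 + cos_thick) / 2
  g_t <- pmax(0, ux * u_t[1] + uy * u_t[2] + uz * u_t[3])^16
  u_k <- spec$kidney_contact_direction
  g_k <- pmax(0, ux * u_k[1] + uy * u_k[2] + uz * u_k[3])^16
  th <- base_th - (base_th - spec$fat_min_mm) * g_t -
    (base_th - spec$kidney_contact_mm) * g_k
  fat <- !organ & Dorg <= th

  affine <- diag(c(sp, sp, sp, 1))
  affine[1:3, 4] <- c(xs[1], ys[1], zs[1])
  seg <- segmentation_set(list(tumor = tumor, kidney = kidney, fat = fat),
                          affine)

  tc <- c_t + u_t * (if (spec$lobulation_amp > 0) {
    r_t * (1 + sh2_field(sh_coef, u_t[1], u_t[2], u_t[3]))
  } else r_t)
  kc <- u_k * ellipsoid_radius(semi, u_k)
  lms <- landmark_set(list(
    upper_pole = c(semi[1], 0, 0),
    lower_pole = c(-semi[1], 0, 0),
    hilum = hil,
    tumor_contact = tc,
    kidney_contact = kc))

  truth <- list(kidney_semiaxes = semi, tumor_center = c_t,
                tumor_radius = r_t, tumor_direction = u_t,
                sh_coef = sh_coef, hilum = hil,
                tumor_contact = tc, kidney_contact = kc,
                fat_min_mm = spec$fat_min_mm,
                fat_range_mm = spec$fat_range_mm,
                spacing_mm = sp, seed = seed)
  list(study = mri_study(seg, lms), truth = truth, spec = spec)
}

#' Default three-habitat layout for the phantom tumor
#'
#' Mimics the qualitative pattern reported for renal tumors: habitat 1 is a
#' necrotic core (poorly perfused: low Ktrans and f, high D0, T1w-hypo- and
#' T2w-hyperintense), habitat 2 is a well-perfused rim on the kidney side
#' (highest Ktrans), habitat 3 is the remaining rim with the lowest
#' diffusivity and highest R2*. Adjacent region means are separated by at
#' least 4 SD in every channel.
#'
#' @param separation_sd mean separation between adjacent regions in SD units.
#' @return a `habitat_layout`: list of regions (`name`, `type`, `params`) and
#'   a `channels` list with a 3 x 7 `means` matrix and per-channel `sds`.
#' @export
default_habitat_layout <- function(separation_sd = 4) {
  sds <- c(T1w = 25, T2w = 20, T1 = 60, Ktrans = 0.02, D0 = 0.1,
           f = 0.02, R2star = 3)
  # per-channel region means in units of sd: rows = regions
  steps <- rbind(
    necrotic_core = c(T1w = 0, T2w = 8, T1 = 8, Ktrans = 0, D0 = 8,
                      f = 0, R2star = 0),
    perikidney_rim = c(T1w = 4, T2w = 4, T1 = 4, Ktrans = 8, D0 = 4,
                       f = 8, R2star = 4),
    outer_rim = c(T1w = 8, T2w = 0, T1 = 0, Ktrans = 4, D0 = 0,
                  f = 4, R2star = 8))
  base <- c(T1w = 250, T2w = 320, T1 = 1720, Ktrans = 0.05, D0 = 1.6,
            f = 0.08, R2star = 14)
  means <- sweep(steps * (separation_sd / 4), 2, sds, `*`)
  means <- sweep(means, 2, base, `+`)
  structure(list(
    regions = list(
      list(name = "necrotic_core", type = "core", radius_frac = 0.5),
      list(name = "perikidney_rim", type = "hemisphere"),
      list(name = "outer_rim", type = "rest")),
    channels = list(means = means, sds = sds)),
    class = "habitat_layout")
}

#' Generate co-registered multiparametric maps with known habitats
#'
#' Draws the 7 channels (T1w, T2w, T1 map, Ktrans, IVIM D0 and f, R2*) per
#' voxel from the habitat layout's per-region normal distributions, on a map
#' lattice of `spec$map_spacing_mm`, and returns the ground-truth labels.
#'
#' @param anatomy result of [make_anatomy()].
#' @param layout a habitat layout (default from the phantom spec).
#' @param seed integer seed; the same seed reproduces a bit-identical stack.
#' @return list with `stack` (a [parameter_stack()]) and `truth_labels`
#'   (integer vector over the tumor voxels, in mask order).
#' @export
make_parameter_maps <- function(anatomy, layout = NULL, seed = 7) {
  spec <- anatomy$spec
  if (is.null(layout)) layout <- spec$habitat_layout
  tr <- anatomy$truth
  sp <- spec$map_spacing_mm
  r_t <- tr$tumor_radius
  c_t <- tr$tumor_center
  pad <- 4
  xs <- seq(floor(c_t[1] - r_t - pad), ceiling(c_t[1] + r_t + pad), by = sp)
  ys <- seq(floor(c_t[2] - r_t - pad), ceiling(c_t[2] + r_t + pad), by = sp)
  zs <- seq(floor(c_t[3] - r_t - pad), ceiling(c_t[3] + r_t + pad), by = sp)
  d <- c(length(xs), length(ys), length(zs))
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  DX <- X - c_t[1]; DY <- Y - c_t[2]; DZ <- Z - c_t[3]
  RT <- sqrt(DX^2 + DY^2 + DZ^2)
  if (any(tr$sh_coef != 0)) {
    eps <- 1e-9
    r_loc <- r_t * (1 + sh2_field(tr$sh_coef, DX / (RT + eps),
                                  DY / (RT + eps), DZ / (RT + eps)))
    tumor <- RT <= r_loc
  } else {
    tumor <- RT <= r_t
  }
  idx <- which(tumor)
  n <- length(idx)
  if (n == 0) stop("map lattice does not intersect the tumor")

  labels <- assign_habitat_regions(layout,
                                   cbind(DX[idx], DY[idx], DZ[idx]),
                                   RT[idx], r_t, tr$tumor_direction)

  set.seed(seed)
  means <- layout$channels$means
  sds <- layout$channels$sds
  channels <- lapply(MP_CHANNELS, function(ch) {
    arr <- array(NA_real_, d)
    arr[idx] <- rnorm(n, mean = means[labels, ch], sd = sds[ch])
    arr
  })
  names(channels) <- MP_CHANNELS

  affine <- diag(c(sp, sp, sp, 1))
  affine[1:3, 4] <- c(xs[1], ys[1], zs[1])
  stack <- parameter_stack(channels, tumor, affine)
  list(stack = stack, truth_labels = labels)
}

# map tumor voxels (offsets from the tumor center) to layout regions;
# explicit regions must not overlap, and a "rest" region absorbs whatever
# they leave unclaimed (gaps without one raise an error)
assign_habitat_regions <- function(layout, offsets, radii, r_t, u_t) {
  n <- nrow(offsets)
  types <- vapply(layout$regions, `[[`, "", "type")
  if (sum(types == "rest") > 1) stop("at most one 'rest' region is allowed")
  assigned <- matrix(FALSE, n, length(layout$regions))
  for (i in seq_along(layout$regions)) {
    reg <- layout$regions[[i]]
    assigned[, i] <- switch(
      reg$type,
      core = radii <= reg$radius_frac * r_t,
      hemisphere = radii > core_radius(layout, r_t) &
        (offsets %*% (-u_t)) > 0,
      rest = FALSE,
      ball = rowSums(sweep(offsets, 2, reg$center)^2) <= reg$radius^2,
      stop("unknown habitat region type: ", reg$type))
  }
  hits <- rowSums(assigned)
  if (any(hits > 1)) stop("overlapping habitat layout regions")
  if (any(hits == 0)) {
    if (!any(types == "rest")) {
      stop("habitat layout does not cover the tumor mask")
    }
    assigned[hits == 0, which(types == "rest")] <- TRUE
  }
  max.col(assigned, ties.method = "first")
}

core_radius <- function(layout, r_t) {
  for (reg in layout$regions) {
    if (reg$type == "core") return(reg$radius_frac * r_t)
  }
  0
}

#' Write phantom volumes, landmarks and ground truth to a directory
#'
#' Emits `segmentation.nii.gz` (labels 1=tumor, 2=kidney, 3=fat),
#' `landmarks.json`, `truth.json`, per-channel map NIfTIs under `maps/` and
#' `maps/tumor_mask.nii.gz`.
#'
#' @param anatomy result of [make_anatomy()].
#' @param maps optional result of [make_parameter_maps()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(anatomy, maps = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segmentation_set(anatomy$study$seg,
                         file.path(dir, "segmentation.nii.gz"),
                         role_map = c(tumor = 1, kidney = 2, fat = 3))
  write_landmarks(anatomy$study$landmarks, file.path(dir, "landmarks.json"))
  jsonlite::write_json(anatomy$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  if (!is.null(maps)) {
    mdir <- file.path(dir, "maps")
    dir.create(mdir, showWarnings = FALSE)
    st <- maps$stack
    for (ch in names(st$channels)) {
      vol <- image_volume(replace_na(st$channels[[ch]]), st$affine)
      write_image_volume(vol, file.path(mdir, paste0(ch, ".nii.gz")))
    }
    write_image_volume(image_volume(st$tumor_mask * 1L, st$affine),
                       file.path(mdir, "tumor_mask.nii.gz"),
                       datatype = "int16")
  }
  invisible(dir)
}

replace_na <- function(arr, value = 0) {
  arr[is.na(arr)] <- value
  arr
}
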