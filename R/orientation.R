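#' Centroid of a binary mask in world coordinates
#'
#' Arithmetic mean of the world coordinates of all member voxel centers.
#'
#' @param mask logical 3-D array.
#' @param affine 4x4 voxel(0-based)-to-world affine.
#' @return world-mm point (length 3).
#' @export
mask_centroid <- function(mask, affine = diag(4)) {
  idx <- which(mask)
  if (length(idx) == 0) stop("cannot take the centroid of an empty mask")
  d <- dim(mask)
  z <- idx - 1
  ijk <- cbind(z %% d[1], (z %/% d[1]) %% d[2], z %/% (d[1] * d[2]))
  apply_affine(affine, colMeans(ijk))
}

#' Sectioning frame from kidney poles and tumor centroid
#'
#' Builds the orthonormal mold coordinate frame. The knife-plane normal (the
#' slice-stacking direction) follows the pathology protocol: in `transverse`
#' mode it is the kidney long axis (lower to upper pole), so cuts are
#' perpendicular to it; in `longitudinal` mode it is perpendicular to the
#' plane spanned by the long axis and the tumor centroid, so cuts are
#' parallel to that plane and the central cut contains both poles and the
#' centroid. `up` (out of the mold base) and `lateral` complete a
#' right-handed triad (`normal x lateral = up`) and are later refined by
#' [base_roll()].
#'
#' @param landmarks a [landmark_set()].
#' @param tumor_centroid world-mm tumor centroid, see [mask_centroid()].
#' @param mode `"transverse"` or `"longitudinal"`.
#' @return a `sectioning_frame`: `normal`, `up`, `lateral`, `origin`, `mode`.
#' @export
sectioning_frame <- function(landmarks, tumor_centroid,
                             mode = c("transverse", "longitudinal")) {
  mode <- match.arg(mode)
  up_p <- landmarks$points["upper_pole", ]
  lo_p <- landmarks$points["lower_pole", ]
  a <- unitv(up_p - lo_p, "pole axis")
  h <- tumor_centroid - lo_p
  if (mode == "transverse") {
    normal <- a
    # any direction perpendicular to the axis; prefer the centroid offset
    perp <- h - sum(h * a) * a
    if (sqrt(sum(perp^2)) < 1e-6) {
      # centroid on the axis: fall back to the world axis least aligned
      e <- diag(3)[, which.min(abs(a))]
      perp <- e - sum(e * a) * a
    }
    up <- unitv(perp, "frame up")
  } else {
    nrm <- cross3(a, h)
    if (sqrt(sum(nrm^2)) < 1e-6 * sqrt(sum(h^2))) {
      stop("tumor centroid is collinear with the pole axis; ",
           "longitudinal plane undefined - consider transverse mode")
    }
    normal <- unitv(nrm, "frame normal")
    up <- cross3(normal, a)
  }
  lateral <- cross3(up, normal) # then normal x lateral = up
  structure(list(normal = normal, up = unitv(up), lateral = unitv(lateral),
                 origin = tumor_centroid, mode = mode, roll_deg = 0),
            class = "sectioning_frame")
}

#' @method print sectioning_frame
#' @export
print.sectioning_frame <- function(x, ...) {
  cat(sprintf("sectioning_frame (%s): normal [%s], up [%s], roll %.0f deg\n",
              x$mode, paste(signif(x$normal, 3), collapse = ", "),
              paste(signif(x$up, 3), collapse = ", "), x$roll_deg))
  invisible(x)
}

#' World point to frame (s, l, u) coordinates
#'
#' `s` runs along the slice normal, `l` along `lateral`, `u` along `up`,
#' with the frame origin (tumor centroid) at zero.
#'
#' @param frame a [sectioning_frame()].
#' @param p world point (length 3) or `n x 3` matrix.
#' @return coordinates in the frame, same shape as `p`.
#' @export
frame_coords <- function(frame, p) {
  B <- rbind(frame$normal, frame$lateral, frame$up)
  if (is.matrix(p)) {
    out <- sweep(p, 2, frame$origin) %*% t(B)
    colnames(out) <- c("s", "l", "u")
    out
  } else {
    stats::setNames(as.numeric(B %*% (p - frame$origin)), c("s", "l", "u"))
  }
}

#' Roll the frame about the slice normal to seat the anchors at the base
#'
#' The hilum and the tumor contact point must end up at the bottom of the
#' mold, where 2-cm holes let the pathologist see and feel them. The roll
#' angle about `normal` is chosen on a uniform grid (default 1 degree) to
#' minimize the summed height of the two landmarks above the lowest point of
#' the specimen outline along `-up`; ties pick the smallest absolute angle.
#'
#' @param frame a [sectioning_frame()].
#' @param hilum,tumor_contact world-mm landmark points.
#' @param outline logical outline mask.
#' @param affine the outline's voxel-to-world affine.
#' @param step_deg grid resolution in degrees.
#' @return the rolled `sectioning_frame` (with `roll_deg` and `roll_objective`
#'   recorded).
#' @export
base_roll <- function(frame, hilum, tumor_contact, outline, affine = diag(4),
                      step_deg = 1) {
  # the lowest-point reference must not inherit the lattice anisotropy of
  # the voxelization (a raw voxel-center support function is up to half a
  # voxel smaller along oblique directions, which biases the optimum), so
  # the support is evaluated on sub-voxel vertices of the lightly smoothed
  # outline surface
  pts <- outline_support_points(outline, affine)

  # project everything onto the (lateral, up) plane
  q_l <- as.numeric(sweep(pts, 2, frame$origin) %*% frame$lateral)
  q_u <- as.numeric(sweep(pts, 2, frame$origin) %*% frame$up)
  lm <- rbind(hilum, tumor_contact)
  p_l <- as.numeric(sweep(lm, 2, frame$origin) %*% frame$lateral)
  p_u <- as.numeric(sweep(lm, 2, frame$origin) %*% frame$up)

  if (all(sqrt(p_l^2 + p_u^2) < 1e-6)) {
    warning("anchor landmarks lie on the rotation axis; roll left at 0")
    return(frame)
  }

  ang <- seq(0, 360 - step_deg, by = step_deg)
  rad <- ang * pi / 180
  # height along the rolled up axis: u(theta) = cos(t)*up + sin(t)*lateral
  obj <- vapply(seq_along(rad), function(i) {
    ct <- cos(rad[i]); st <- sin(rad[i])
    hts <- ct * p_u + st * p_l
    low <- min(ct * q_u + st * q_l)
    sum(hts - low)
  }, 0)
  best <- which(obj <= min(obj) + 1e-9)
  wrapped <- ifelse(ang[best] > 180, ang[best] - 360, ang[best])
  pick <- best[order(abs(wrapped), wrapped)][1]
  theta <- rad[pick]

  new_up <- cos(theta) * frame$up + sin(theta) * frame$lateral
  new_lat <- cross3(new_up, frame$normal)
  out <- frame
  out$up <- unitv(new_up)
  out$lateral <- unitv(new_lat)
  out$roll_deg <- ang[pick]
  out$roll_objective <- obj[pick]
  out
}

# sub-voxel surface points of a mask: vertices of the iso-surface of the
# mask smoothed by one voxel (falls back to the binary surface if smoothing
# would annihilate a thin structure); world coordinates
outline_support_points <- function(outline, affine = diag(4)) {
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  field <- gaussian_smooth(outline, min(sp), sp)
  if (max(field) < 0.5) field <- outline * 1.0
  surf <- extract_surface(field, c(1, 1, 1), 0.5, origin = c(0, 0, 0))
  apply_affine(affine, surf$vertices)
}

#' Resample a study into the mold frame
#'
#' Rotates all masks (nearest-neighbour) and parameter maps (trilinear) onto
#' an axis-aligned isotropic lattice whose axes are (`normal`, `lateral`,
#' `up`), and expresses the landmarks in frame coordinates exactly. Per-mask
#' volume must survive within 5% (nearest-neighbour at equal or finer
#' spacing); a mask that vanishes raises an error.
#'
#' @param study an [mri_study()].
#' @param frame a [sectioning_frame()].
#' @param spacing_mm isotropic target spacing in mm (default 1).
#' @param pad_mm padding around the outline bounding box in mm.
#' @return a `resampled_study`: `seg`, `landmarks`, `landmarks_frame`, `maps`,
#'   `frame`, `spacing`, `s`, `l`, `u` (frame-coordinate vectors of the
#'   lattice planes) and `volume_ratio` per mask.
#' @export
resample_to_frame <- function(study, frame, spacing_mm = 1, pad_mm = 2) {
  stopifnot(spacing_mm > 0)
  seg <- study$seg
  # frame-coordinate bounding box of the outline via its voxel bbox corners
  idx <- which(seg$outline)
  d <- dim(seg$outline)
  z <- idx - 1
  ijk <- cbind(z %% d[1], (z %/% d[1]) %% d[2], z %/% (d[1] * d[2]))
  rng <- apply(ijk, 2, range)
  corners <- as.matrix(expand.grid(rng[, 1], rng[, 2], rng[, 3]))
  fc <- frame_coords(frame, apply_affine(seg$affine, corners))
  # pad in whole voxels so an axis-aligned frame keeps the source lattice
  # phase (voxel centers map onto voxel centers, no rounding ties)
  pad <- ceiling((pad_mm + max(seg$spacing) / 2) / spacing_mm) * spacing_mm
  qmin <- apply(fc, 2, min) - pad
  qmax <- apply(fc, 2, max) + pad
  nd <- pmax(2L, as.integer(ceiling((qmax - qmin) / spacing_mm)) + 1L)

  B <- cbind(frame$normal, frame$lateral, frame$up)
  A_tgt <- diag(4)
  A_tgt[1:3, 1:3] <- B * spacing_mm
  A_tgt[1:3, 4] <- frame$origin + as.numeric(B %*% qmin)

  # source continuous indices of all target voxel centers
  grid <- as.matrix(expand.grid(0:(nd[1] - 1), 0:(nd[2] - 1), 0:(nd[3] - 1)))
  world <- apply_affine(A_tgt, grid)
  src <- apply_affine(solve(seg$affine), world)

  masks <- lapply(seg$masks, function(m) resample_nn_mask(m, src, nd))
  vol_ratio <- vapply(names(masks), function(r) {
    sum(masks[[r]]) * spacing_mm^3 /
      (sum(seg$masks[[r]]) * prod(seg$spacing))
  }, 0)
  gone <- names(masks)[vapply(masks, function(m) !any(m), TRUE)]
  if (length(gone) > 0) {
    stop("mask(s) vanished at spacing ", spacing_mm, " mm: ",
         paste(gone, collapse = ", "))
  }
  new_seg <- segmentation_set(masks, A_tgt)

  maps <- NULL
  if (!is.null(study$maps)) {
    maps <- lapply(study$maps, function(v) {
      srcm <- apply_affine(solve(v$affine), world)
      image_volume(resample_trilinear(v$voxels, srcm, nd), A_tgt)
    })
  }

  lmf <- frame_coords(frame, study$landmarks$points)
  structure(list(seg = new_seg, landmarks = study$landmarks,
                 landmarks_frame = lmf, maps = maps, frame = frame,
                 spacing = spacing_mm,
                 s = qmin[1] + spacing_mm * (0:(nd[1] - 1)),
                 l = qmin[2] + spacing_mm * (0:(nd[2] - 1)),
                 u = qmin[3] + spacing_mm * (0:(nd[3] - 1)),
                 volume_ratio = vol_ratio),
            class = "resampled_study")
}

resample_nn_mask <- function(mask, src_idx, out_dim) {
  d <- dim(mask)
  i <- round(src_idx[, 1]) + 1
  j <- round(src_idx[, 2]) + 1
  k <- round(src_idx[, 3]) + 1
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- logical(nrow(src_idx))
  out[ok] <- mask[cbind(i[ok], j[ok], k[ok])]
  array(out, out_dim)
}

resample_trilinear <- function(arr, src_idx, out_dim) {
  d <- dim(arr)
  x <- src_idx[, 1]; y <- src_idx[, 2]; z <- src_idx[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- rep(NA_real_, nrow(src_idx))
  ok <- x0 >= 0 & x0 <= d[1] - 2 & y0 >= 0 & y0 <= d[2] - 2 &
    z0 >= 0 & z0 <= d[3] - 2
  g <- function(dx, dy, dz) {
    arr[cbind(x0[ok] + 1 + dx, y0[ok] + 1 + dy, z0[ok] + 1 + dz)]
  }
  out[ok] <-
    g(0, 0, 0) * (1 - fx[ok]) * (1 - fy[ok]) * (1 - fz[ok]) +
    g(1, 0, 0) * fx[ok] * (1 - fy[ok]) * (1 - fz[ok]) +
    g(0, 1, 0) * (1 - fx[ok]) * fy[ok] * (1 - fz[ok]) +
    g(0, 0, 1) * (1 - fx[ok]) * (1 - fy[ok]) * fz[ok] +
    g(1, 1, 0) * fx[ok] * fy[ok] * (1 - fz[ok]) +
    g(1, 0, 1) * fx[ok] * (1 - fy[ok]) * fz[ok] +
    g(0, 1, 1) * (1 - fx[ok]) * fy[ok] * fz[ok] +
    g(1, 1, 1) * fx[ok] * fy[ok] * fz[ok]
  array(out, out_dim)
}
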