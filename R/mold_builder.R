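#' Mold design parameters
#'
#' Geometric constants of the printed block. Defaults: 10 mm lateral walls and
#' base, 2 mm knife slots bridged by 5 mm of uncut material at the bottom,
#' 2-cm landmark holes (the anchor holes the pathologist sees and feels
#' through the base), a 15 mm guide comb and 5 mm interslot spacing unless
#' the imaging slice spacing is supplied.
#'
#' @param block_margin_mm lateral wall width around the specimen footprint.
#' @param base_thickness_mm cavity floor to block bottom.
#' @param slot_width_mm knife slot width.
#' @param slot_bridge_mm uncut material left below each slot; must be smaller
#'   than `base_thickness_mm`.
#' @param hole_diameter_mm diameter of the two landmark holes (20 mm).
#' @param guide_depth_mm how far the guide comb extends on the +lateral side.
#' @param slice_spacing_mm interslot spacing; match the imaging slices of
#'   interest.
#' @return a `mold_spec` list.
#' @export
mold_spec <- function(block_margin_mm = 10, base_thickness_mm = 10,
                      slot_width_mm = 2, slot_bridge_mm = 5,
                      hole_diameter_mm = 20, guide_depth_mm = 15,
                      slice_spacing_mm = 5) {
  spec <- list(block_margin_mm = block_margin_mm,
               base_thickness_mm = base_thickness_mm,
               slot_width_mm = slot_width_mm,
               slot_bridge_mm = slot_bridge_mm,
               hole_diameter_mm = hole_diameter_mm,
               guide_depth_mm = guide_depth_mm,
               slice_spacing_mm = slice_spacing_mm)
  if (any(unlist(spec) <= 0)) stop("all mold_spec fields must be positive")
  if (slot_bridge_mm >= base_thickness_mm) {
    stop("slot_bridge_mm must be smaller than base_thickness_mm")
  }
  structure(spec, class = "mold_spec")
}

#' Read a mold_spec from a YAML config
#' @param yaml_path YAML file whose keys match the [mold_spec()] arguments
#'   (unknown keys rejected; missing keys keep their defaults).
#' @return a [mold_spec()].
#' @export
read_mold_spec <- function(yaml_path) {
  y <- yaml::read_yaml(yaml_path)
  if (!is.null(y$mold)) y <- y$mold
  known <- names(formals(mold_spec))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown mold_spec field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(mold_spec, y)
}

#' Gaussian surface smoothing of the outline mask
#'
#' Blurs the binary outline with an isotropic Gaussian of the stated sigma and
#' re-thresholds at the iso level, removing voxelization steps before the
#' surface is extracted. For structures whose minimal feature size is at
#' least 4 sigma the enclosed volume changes by well under 10%.
#'
#' @param outline logical 3-D mask.
#' @param sigma_mm Gaussian sigma in mm (0 = no smoothing).
#' @param spacing voxel spacing per axis in mm.
#' @param iso_level threshold in (0, 1); 0.5 preserves volume to first order.
#' @return list with `field` (the blurred scalar field) and `mask`
#'   (`field >= iso_level`).
#' @export
smooth_outline <- function(outline, sigma_mm = 2, spacing = c(1, 1, 1),
                           iso_level = 0.5) {
  stopifnot(sigma_mm >= 0, iso_level > 0, iso_level < 1)
  field <- gaussian_smooth(outline, sigma_mm, spacing)
  mask <- field >= iso_level
  if (!any(mask)) {
    stop("smoothing annihilated the outline; use a smaller sigma_mm")
  }
  list(field = field, mask = mask)
}

#' Extract a triangle mesh iso-surface from a voxel field
#'
#' Marching-tetrahedra surface at the given iso level on the voxel lattice.
#' The result is closed, manifold and consistently outward-oriented (outward
#' from the region with values above the level). For a binary mask use
#' `iso_level = 0.5`; note that with midpoint interpolation an isolated
#' single voxel yields a rhombic solid of half the voxel volume, while blobs
#' a few voxels across converge to the voxel volume within a few percent.
#'
#' @param field numeric or logical 3-D array.
#' @param spacing voxel spacing per axis in mm.
#' @param iso_level iso value; must lie inside the field's range.
#' @param origin world position of voxel (0,0,0), default `c(0,0,0)`.
#' @return a [triangle_mesh()].
#' @export
extract_surface <- function(field, spacing = c(1, 1, 1), iso_level = 0.5,
                            origin = c(0, 0, 0)) {
  arr <- field * 1.0
  if (!(max(arr) > iso_level && min(arr) <= iso_level)) {
    stop("iso level ", iso_level, " is not crossed by the field")
  }
  res <- .mt_isosurface(as.numeric(arr), as.integer(dim(arr)),
                        as.numeric(spacing[1:3]), as.numeric(origin[1:3]),
                        as.numeric(iso_level))
  if (nrow(res$faces) == 0) stop("empty iso-surface")
  triangle_mesh(res$vertices, res$faces)
}

#' Simplify a mesh for printing
#'
#' Face reduction by quadric edge collapse, optional Laplacian smoothing and
#' Taubin lambda/mu smoothing, in that order. Decimation refuses collapses
#' that would pinch the surface or flip normals, so watertightness is
#' preserved; if the face target cannot be reached safely the result keeps
#' more faces and a warning is raised.
#'
#' @param mesh a [triangle_mesh()].
#' @param target_faces face budget after decimation (>= 4).
#' @param laplacian_iters plain Laplacian iterations (shrinks; default 0).
#' @param taubin_lambda,taubin_mu,taubin_iters Taubin parameters; the scheme
#'   requires `taubin_mu < -taubin_lambda < 0`.
#' @return a simplified `triangle_mesh`.
#' @export
simplify_mesh <- function(mesh, target_faces = 20000, laplacian_iters = 0,
                          taubin_lambda = 0.5, taubin_mu = -0.53,
                          taubin_iters = 10) {
  stopifnot(target_faces >= 4)
  out <- mesh
  if (nrow(out$faces) > target_faces) {
    res <- .qem_decimate(out$vertices, out$faces, as.integer(target_faces))
    cand <- triangle_mesh(res$vertices, res$faces)
    if (!mesh_is_watertight(cand)) {
      # retry with a looser budget before giving up
      res <- .qem_decimate(out$vertices, out$faces,
                           as.integer(ceiling(target_faces * 2)))
      cand <- triangle_mesh(res$vertices, res$faces)
      if (!mesh_is_watertight(cand)) {
        stop("decimation broke manifoldness even at twice the face target")
      }
      warning("face target relaxed to preserve manifoldness: ",
              nrow(cand$faces), " faces")
    }
    if (nrow(cand$faces) > target_faces) {
      warning("decimation stopped at ", nrow(cand$faces),
              " faces (safe collapses exhausted)")
    }
    out <- cand
  }
  if (laplacian_iters > 0) out <- laplacian_smooth(out, 0.5, laplacian_iters)
  if (taubin_iters > 0) {
    out <- taubin_smooth(out, taubin_lambda, taubin_mu, taubin_iters)
  }
  out
}

#' Plan the knife-plane positions along the slice normal
#'
#' Planes sit at `alignment_offset_mm + k * slice_spacing_mm`, covering the
#' tumor extent along the normal plus one margin plane on each side, and are
#' labelled 1..N from the lower end. This registers every interslot space to
#' an imaging slice location.
#'
#' @param tumor_mask tumor mask on the frame lattice.
#' @param s_coords frame s-coordinate (mm) of each lattice plane along axis 1.
#' @param slice_spacing_mm spacing between planes in mm.
#' @param alignment_offset_mm phase of the plane grid in mm (0 puts a plane
#'   at s = 0, the tumor centroid).
#' @return a `slice_plan`: `positions` (mm, strictly increasing), `labels`,
#'   `spacing`, `offset`.
#' @export
build_slice_plan <- function(tumor_mask, s_coords, slice_spacing_mm,
                             alignment_offset_mm = 0) {
  stopifnot(slice_spacing_mm > 0)
  present <- which(apply(tumor_mask, 1, any))
  if (length(present) == 0) stop("tumor mask is empty on the frame lattice")
  smin <- s_coords[min(present)]
  smax <- s_coords[max(present)]
  if (smax - smin < slice_spacing_mm) {
    warning("tumor extent (", round(smax - smin, 1),
            " mm) is smaller than the slice spacing; single central plane")
    pos <- alignment_offset_mm +
      round(((smin + smax) / 2 - alignment_offset_mm) / slice_spacing_mm) *
      slice_spacing_mm
  } else {
    k <- seq(ceiling((smin - alignment_offset_mm) / slice_spacing_mm),
             floor((smax - alignment_offset_mm) / slice_spacing_mm))
    k <- c(min(k) - 1, k, max(k) + 1) # one margin plane each side
    pos <- alignment_offset_mm + k * slice_spacing_mm
  }
  structure(list(positions = pos, labels = seq_along(pos),
                 spacing = slice_spacing_mm, offset = alignment_offset_mm),
            class = "slice_plan")
}

#' Carve the printable mold from the reoriented outline
#'
#' Voxel-space constructive geometry in the mold frame:
#' \enumerate{
#'   \item block: the outline footprint dilated laterally by
#'     `block_margin_mm`, extruded from the block bottom to
#'     `base_thickness_mm` + outline height; the +lateral side is flattened
#'     and extended by `guide_depth_mm` to form the guide comb;
#'   \item cavity: for every (s, l) column that meets the outline, all
#'     material from the outline's lowest surface upward is removed
#'     (vertical-shadow carving), which makes the cavity open-top and
#'     overhang-free so a rigid specimen can be lowered in;
#'   \item slots: every plan plane removes `|s - s_k| <= slot_width/2` from
#'     the top down to `slot_bridge_mm` above the bottom, across block and
#'     comb alike;
#'   \item holes: two vertical cylinders of `hole_diameter_mm` through the
#'     base at the (s, l) of the hilum and tumor contact point;
#'   \item tick marks: guide tooth k carries k small notches on its top outer
#'     edge as a slice-numbering surrogate.
#' }
#'
#' @param study a `resampled_study` from [resample_to_frame()].
#' @param spec a [mold_spec()].
#' @param plan a [build_slice_plan()] result.
#' @param outline_mask optional replacement outline on the study lattice
#'   (e.g. the Gaussian-smoothed outline); defaults to the study's outline.
#' @return a `mold_model`: `occupancy` (final), `occupancy_noslot` (before
#'   slots/holes; used for cross-section validation), lattice coordinate
#'   vectors `s`, `l`, `u` (u measured from the block bottom), `mesh`
#'   (`NULL` until [mold_mesh()] is applied), `slice_plan`, `spec`,
#'   `hole_centers`, `footprint`, and bookkeeping for QC.
#' @export
carve_mold <- function(study, spec, plan, outline_mask = NULL) {
  sp <- study$spacing
  outline <- if (is.null(outline_mask)) study$seg$outline else outline_mask
  if (!any(outline)) stop("outline mask is empty")
  d <- dim(outline)

  margin_vox <- ceiling(spec$block_margin_mm / sp)
  guide_vox <- ceiling(spec$guide_depth_mm / sp)

  # trim the study lattice to the outline bounding box, then embed in the
  # block grid with margins
  occ_any_s <- which(apply(outline, 1, any))
  occ_any_l <- which(apply(outline, 2, any))
  occ_any_u <- which(apply(outline, 3, any))
  s_keep <- seq(min(occ_any_s), max(occ_any_s))
  l_keep <- seq(min(occ_any_l), max(occ_any_l))
  u_keep <- seq(min(occ_any_u), max(occ_any_u))
  outline <- outline[s_keep, l_keep, u_keep, drop = FALSE]
  d <- dim(outline)

  ns <- d[1] + 2 * margin_vox
  nl <- d[2] + 2 * margin_vox + guide_vox
  base_vox <- round(spec$base_thickness_mm / sp)
  nu <- base_vox + d[3] + 1
  s_mold <- study$s[s_keep[1]] + sp * ((0:(ns - 1)) - margin_vox)
  l_mold <- study$l[l_keep[1]] + sp * ((0:(nl - 1)) - margin_vox)
  u_mold <- sp * (0:(nu - 1)) # 0 at block bottom
  u_frame_of_mold <- u_mold - spec$base_thickness_mm + study$u[u_keep[1]]

  # footprint of the specimen in mold-grid (s, l) indices
  fp <- matrix(FALSE, ns, nl)
  fp_any <- apply(outline, c(1, 2), any)
  fp[margin_vox + seq_len(d[1]), margin_vox + seq_len(d[2])] <- fp_any

  # block footprint: dilate laterally, then flatten the +l side up to the
  # comb so the guides attach to a planar wall
  dil <- distance_transform(fp, c(sp, sp)) <= spec$block_margin_mm
  lmax_blk <- max(which(apply(dil, 2, any)))
  s_rows <- which(apply(dil, 1, any))
  block2d <- dil
  for (s in s_rows) {
    lmax_s <- max(which(dil[s, ]))
    block2d[s, lmax_s:min(lmax_blk + guide_vox, nl)] <- TRUE
  }

  # outline's lowest surface per column, shifted so its global minimum sits
  # base_thickness above the block bottom
  floor_u <- matrix(NA_integer_, ns, nl)
  first_u <- column_extrema(outline)$first
  floor_u[margin_vox + seq_len(d[1]), margin_vox + seq_len(d[2])] <-
    first_u + base_vox # outline u index 1 -> mold u index base_vox + 1
  if (any(floor_u[!is.na(floor_u)] > nu)) {
    stop("internal error: cavity deeper than block")
  }

  # assemble occupancy: block material below the cavity floor (or full
  # height off the specimen footprint)
  uidx <- array(rep(seq_len(nu), each = ns * nl), c(ns, nl, nu))
  colfloor <- array(rep(floor_u, nu), c(ns, nl, nu))
  inblock <- array(rep(block2d, nu), c(ns, nl, nu))
  occ <- inblock & (is.na(colfloor) | uidx < colfloor)

  occ_noslot <- occ

  # landmark holes at the hilum and tumor contact point
  lmf <- study$landmarks_frame
  holes <- lmf[c("hilum", "tumor_contact"), c("s", "l"), drop = FALSE]
  wall_guard <- block2d & (distance_transform(!block2d, c(sp, sp)) > 0) &
    (distance_transform(!dil, c(sp, sp)) <= 2) # within 2 mm of the outer wall
  hole2d <- matrix(FALSE, ns, nl)
  for (h in seq_len(nrow(holes))) {
    ds <- s_mold - holes[h, "s"]
    dl <- l_mold - holes[h, "l"]
    disc <- outer(ds^2, dl^2, `+`) <= (spec$hole_diameter_mm / 2)^2
    if (any(disc & wall_guard)) {
      stop("landmark hole '", rownames(holes)[h],
           "' would breach a lateral wall of the mold")
    }
    hole2d <- hole2d | disc
  }
  occ <- occ & !array(rep(hole2d, nu), c(ns, nl, nu))
  occ_noslot_holes <- occ_noslot # kept without holes for floor extraction

  # knife slots, registered to the plan planes
  bridge_vox <- ceiling(spec$slot_bridge_mm / sp)
  slot_rows <- integer(0)
  for (s_k in plan$positions) {
    rows <- which(abs(s_mold - s_k) <= spec$slot_width_mm / 2 + 1e-9)
    slot_rows <- union(slot_rows, rows)
    if (length(rows) > 0) {
      occ[rows, , (bridge_vox + 1):nu] <- FALSE
    }
  }

  # tick-mark notches: k notches on the top outer edge of guide tooth k
  notch_vox <- max(1L, round(2 / sp))
  l_notch <- (nl - notch_vox + 1):nl
  u_notch <- (nu - notch_vox + 1):nu
  pos <- plan$positions
  teeth <- cbind(pos[-length(pos)], pos[-1]) # tooth k between slots k, k+1
  if (length(pos) == 1) teeth <- matrix(numeric(0), 0, 2)
  for (k in seq_len(nrow(teeth))) {
    width <- teeth[k, 2] - teeth[k, 1] - spec$slot_width_mm
    n_notch <- min(k, max(1, floor(width / (2 * notch_vox * sp))))
    at <- teeth[k, 1] + (teeth[k, 2] - teeth[k, 1]) *
      (seq_len(n_notch)) / (n_notch + 1)
    for (s_n in at) {
      rows <- which(abs(s_mold - s_n) <= (notch_vox * sp) / 2)
      occ[rows, l_notch, u_notch] <- FALSE
    }
  }

  structure(list(occupancy = occ, occupancy_noslot = occ_noslot_holes,
                 hole_mask2d = hole2d, footprint = fp, block2d = block2d,
                 s = s_mold, l = l_mold, u = u_mold,
                 u_frame = u_frame_of_mold, spacing = sp,
                 slice_plan = plan, spec = spec,
                 hole_centers = holes,
                 base_vox = base_vox, bridge_vox = bridge_vox,
                 mesh = NULL),
            class = "mold_model")
}

#' @method print mold_model
#' @export
print.mold_model <- function(x, ...) {
  cat(sprintf(paste0("mold_model: %s voxels at %.2g mm, %d slots, ",
                     "%d landmark holes%s\n"),
              paste(dim(x$occupancy), collapse = "x"), x$spacing,
              length(x$slice_plan$positions), nrow(x$hole_centers),
              if (is.null(x$mesh)) "" else
                sprintf(", mesh %d faces", nrow(x$mesh$faces))))
  invisible(x)
}

#' Extract and simplify the printable mesh of a mold
#'
#' Iso-surfaces the mold occupancy grid and applies [simplify_mesh()]
#' (decimation to `target_faces` followed by Taubin smoothing). The binary
#' occupancy is first blurred very slightly (default half a voxel), which
#' rounds single-voxel staircase steps and removes the degenerate
#' corner-touching lattice configurations that would otherwise pinch the
#' surface into a non-manifold edge; the 0.5 iso level keeps the carved
#' dimensions to within a fraction of a voxel.
#'
#' @param mold a `mold_model` from [carve_mold()].
#' @param target_faces face budget (default 20000).
#' @param taubin_iters Taubin smoothing iterations. The default is 2: the
#'   surface is already smooth after the occupancy blur, and longer
#'   uniform-weight Taubin runs round the mold's many concave features
#'   (cavity, slots, holes) outward, inflating the enclosed volume beyond
#'   the 5%-of-occupancy invariant.
#' @param presmooth_vox Gaussian sigma applied to the occupancy before
#'   iso-surfacing, in voxels (default 0.5; 0 disables).
#' @return the `mold_model` with its `mesh` field set (vertices in mold-frame
#'   mm: s, l, u-from-block-bottom).
#' @export
mold_mesh <- function(mold, target_faces = 20000, taubin_iters = 2,
                      presmooth_vox = 0.5) {
  sp <- mold$spacing
  # pad so the surface closes at the grid boundary
  d <- dim(mold$occupancy)
  padded <- array(0, d + 4)
  padded[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- mold$occupancy
  if (presmooth_vox > 0) {
    padded <- gaussian_smooth(padded, presmooth_vox * sp, rep(sp, 3))
  }
  mesh <- extract_surface(padded, rep(sp, 3), 0.5,
                          origin = c(mold$s[1], mold$l[1], mold$u[1]) - 2 * sp)
  mold$mesh <- simplify_mesh(mesh, target_faces = target_faces,
                             taubin_iters = taubin_iters)
  mold
}

#' End-to-end mold generation pipeline
#'
#' Runs the full chain on a study: tumor centroid, sectioning frame, base
#' roll, resampling to the mold frame, Gaussian outline smoothing, slice
#' plan, voxel carving and mesh extraction.
#'
#' @param study an [mri_study()].
#' @param mode `"transverse"` or `"longitudinal"` sectioning.
#' @param spec a [mold_spec()].
#' @param sigma_mm Gaussian surface smoothing sigma (default 2 mm).
#' @param spacing_mm mold-frame lattice spacing (default 1 mm).
#' @param alignment_offset_mm slice-plan phase; `NULL` anchors the plan to
#'   the source imaging lattice (nearest source slice center to the tumor
#'   centroid), 0 puts a plane through the centroid.
#' @param target_faces,taubin_iters mesh simplification, see [mold_mesh()].
#' @param landmark_tol_mm tolerance for [check_landmarks_in_outline()].
#' @return list with `mold` (mold_model incl. mesh), `frame`, `resampled`
#'   (the resampled study), and `plan`.
#' @export
build_mold <- function(study, mode = c("transverse", "longitudinal"),
                       spec = mold_spec(), sigma_mm = 2, spacing_mm = 1,
                       alignment_offset_mm = NULL, target_faces = 20000,
                       taubin_iters = 2, landmark_tol_mm = 5) {
  mode <- match.arg(mode)
  check_landmarks_in_outline(study$landmarks, study$seg, landmark_tol_mm)
  centroid <- mask_centroid(study$seg$masks$tumor, study$seg$affine)
  frame <- sectioning_frame(study$landmarks, centroid, mode)
  frame <- base_roll(frame, study$landmarks$points["hilum", ],
                     study$landmarks$points["tumor_contact", ],
                     study$seg$outline, study$seg$affine)
  rs <- resample_to_frame(study, frame, spacing_mm = spacing_mm)
  sm <- smooth_outline(rs$seg$outline, sigma_mm, rep(spacing_mm, 3))
  if (is.null(alignment_offset_mm)) {
    alignment_offset_mm <- imaging_aligned_offset(study, frame,
                                                  spec$slice_spacing_mm)
  }
  plan <- build_slice_plan(rs$seg$masks$tumor, rs$s, spec$slice_spacing_mm,
                           alignment_offset_mm)
  mold <- carve_mold(rs, spec, plan, outline_mask = sm$mask)
  mold <- mold_mesh(mold, target_faces = target_faces,
                    taubin_iters = taubin_iters)
  list(mold = mold, frame = frame, resampled = rs, plan = plan)
}

# phase of the slice plan so that plan planes coincide with source imaging
# slice centers projected on the frame normal (the source axis most aligned
# with the normal defines the slice stack)
imaging_aligned_offset <- function(study, frame, slice_spacing_mm) {
  A <- study$seg$affine
  align <- abs(as.numeric(frame$normal %*% A[1:3, 1:3])) /
    sqrt(colSums(A[1:3, 1:3]^2))
  j <- which.max(align)
  centroid_s <- 0 # frame origin is the tumor centroid
  # s-coordinates of source plane centers along axis j
  n_j <- dim(study$seg$outline)[j]
  k <- 0:(n_j - 1)
  base <- as.numeric(frame$normal %*% (A[1:3, 4] - frame$origin))
  step <- as.numeric(frame$normal %*% A[1:3, j])
  s_planes <- base + k * step
  s_planes[which.min(abs(s_planes - centroid_s))]
}

#' Serialize a mold design report as JSON
#'
#' Writes the sectioning frame (direction cosines, origin, mode, roll), the
#' slice plan, hole centers, spec and QC metrics to a JSON file.
#'
#' @param build result of [build_mold()].
#' @param path output JSON path.
#' @param qc optional result of [mold_qc()] to embed.
#' @return `path`, invisibly.
#' @export
write_mold_report <- function(build, path, qc = NULL) {
  frame <- build$frame
  rep <- list(
    frame = list(normal = frame$normal, lateral = frame$lateral,
                 up = frame$up, origin = frame$origin, mode = frame$mode,
                 roll_deg = frame$roll_deg),
    slice_plan = list(positions_mm = build$plan$positions,
                      labels = build$plan$labels,
                      spacing_mm = build$plan$spacing,
                      offset_mm = build$plan$offset),
    hole_centers_frame_mm = as.data.frame(build$mold$hole_centers),
    spec = unclass(build$mold$spec))
  if (!is.null(qc)) rep$qc <- unclass(qc)
  jsonlite::write_json(rep, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
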