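#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A| + |B|)` between two binary regions on the same lattice;
#' 1 means perfect agreement, 0 disjoint regions.
#'
#' @param A,B logical arrays/vectors of identical shape.
#' @return numeric in `[0, 1]`.
#' @export
dice <- function(A, B) {
  if (!identical(dim(A), dim(B)) || length(A) != length(B)) {
    stop("dice requires two regions on the same lattice")
  }
  a <- sum(A); b <- sum(B)
  if (a + b == 0) stop("Dice is undefined for two empty regions")
  2 * sum(A & B) / (a + b)
}

#' Per-plane cross-sections of specimen and mold cavity
#'
#' For every knife plane of the slice plan, pairs the tissue cross-sections
#' (per role, on the mold-frame lattice) with the cross-section of the
#' specimen as seated in the mold: the region bounded below by the carved
#' cavity floor (the mold material surface, taken from the occupancy before
#' slots are cut; over the landmark holes, where the specimen is
#' unsupported, by the specimen's own lower surface) and above by the
#' specimen's upper surface. This is the geometric analogue of comparing a
#' photographed tissue section against the imaging contour, and the per-role
#' Dice of each section against it quantifies the coregistration accuracy of
#' the design.
#'
#' @param mold a `mold_model` from [carve_mold()].
#' @param study the `resampled_study` the mold was carved from.
#' @param plan a slice plan (defaults to the mold's).
#' @return list of per-plane records: `position`, `label`, `sections` (named
#'   list of logical matrices per role plus `outline` and `cavity`), `dice`
#'   (named vector: role section vs cavity section), `area_mm2`.
#' @export
slot_cross_sections <- function(mold, study, plan = mold$slice_plan) {
  sp <- mold$spacing
  out <- list()
  for (pi in seq_along(plan$positions)) {
    s_k <- plan$positions[pi]
    i_mold <- which.min(abs(mold$s - s_k))
    if (abs(mold$s[i_mold] - s_k) > sp) {
      warning("plane ", s_k, " mm lies outside the mold grid; skipped")
      next
    }
    # mold-grid cross-section at the plane: material & floor
    occ2d <- mold$occupancy_noslot[i_mold, , ] # l x u, pre-slot material
    nl <- length(mold$l); nu <- length(mold$u)
    lastmat <- rep(0L, nl)
    has <- which(rowSums(occ2d) > 0)
    lastmat[has] <- max.col(occ2d[has, , drop = FALSE], ties.method = "last")
    floor_idx <- lastmat + 1L # first empty voxel above the material column

    # specimen sections on the study lattice mapped into mold (l, u) indices
    i_study <- which.min(abs(study$s - s_k))
    roles <- names(study$seg$masks)
    l_off <- round((study$l[1] - mold$l[1]) / sp)
    u_off <- round((study$u[1] - mold$u_frame[1]) / sp)
    put <- function(m) {
      sec <- matrix(FALSE, nl, nu)
      src <- which(m, arr.ind = TRUE)
      if (nrow(src) > 0) {
        li <- src[, 1] + l_off
        ui <- src[, 2] + u_off
        ok <- li >= 1 & li <= nl & ui >= 1 & ui <= nu
        sec[cbind(li[ok], ui[ok])] <- TRUE
      }
      sec
    }
    secs <- lapply(roles, function(r) put(study$seg$masks[[r]][i_study, , ]))
    names(secs) <- roles
    outline_sec <- put(study$seg$outline[i_study, , ])

    # seated-specimen region: cavity floor up to the specimen top
    top <- rep(0L, nl)
    bot <- rep(NA_integer_, nl)
    haso <- which(rowSums(outline_sec) > 0)
    if (length(haso) > 0) {
      top[haso] <- max.col(outline_sec[haso, , drop = FALSE],
                           ties.method = "last")
      bot[haso] <- max.col(outline_sec[haso, , drop = FALSE],
                           ties.method = "first")
    }
    hole <- mold$hole_mask2d[i_mold, ]
    lower <- ifelse(hole & !is.na(bot), bot, floor_idx)
    ui_mat <- matrix(rep(seq_len(nu), each = nl), nl, nu)
    cavity_sec <- ui_mat >= lower & ui_mat <= rep(top, nu) & top > 0
    cavity_sec <- cavity_sec & matrix(rep(top > 0, nu), nl, nu)

    dsc <- vapply(c(secs, list(outline = outline_sec)), function(sec) {
      if (!any(sec) && !any(cavity_sec)) return(NA_real_)
      if (!any(sec)) return(NA_real_)
      dice(sec, sec & cavity_sec)
    }, 0)
    out[[length(out) + 1]] <- list(
      position = s_k, label = plan$labels[pi],
      sections = c(secs, list(outline = outline_sec, cavity = cavity_sec)),
      dice = dsc,
      dice_outline_cavity = if (any(outline_sec) || any(cavity_sec)) {
        if (any(outline_sec) && any(cavity_sec)) {
          dice(outline_sec, cavity_sec)
        } else NA_real_
      } else NA_real_,
      area_mm2 = c(outline = sum(outline_sec) * sp^2,
                   cavity = sum(cavity_sec) * sp^2))
  }
  out
}

#' Quality control of a carved mold
#'
#' Checks the mesh (watertight, manifold, outward volume), the insertability
#' invariant (in every vertical column of the occupancy grid, material is a
#' contiguous stack from the bottom: nothing overhangs the cavity), the
#' landmark hole placement and opening diameter, and the interslot spacing
#' against the requested slice spacing.
#'
#' @param mold a `mold_model` (run [mold_mesh()] first for mesh checks).
#' @return a `mold_qc` list of flags and measured errors.
#' @export
mold_qc <- function(mold) {
  occ <- mold$occupancy
  d <- dim(occ)
  sp <- mold$spacing

  insertable <- check_insertable(occ)

  # landmark holes measured on the bottom slice (slots and cavity never
  # reach it, so its only openings inside the block are the two holes)
  bottom <- occ[, , 1]
  opening <- mold$block2d & !bottom
  lab <- label_components(opening)
  n_holes <- max(lab)
  hole_stats <- lapply(seq_len(n_holes), function(h) {
    ij <- which(lab == h, arr.ind = TRUE)
    ctr <- c(s = mean(mold$s[ij[, 1]]), l = mean(mold$l[ij[, 2]]))
    list(center = ctr, area_mm2 = nrow(ij) * sp^2,
         diameter_mm = 2 * sqrt(nrow(ij) * sp^2 / pi))
  })
  hole_err <- rep(NA_real_, nrow(mold$hole_centers))
  names(hole_err) <- rownames(mold$hole_centers)
  for (h in seq_len(nrow(mold$hole_centers))) {
    want <- as.numeric(mold$hole_centers[h, c("s", "l")])
    if (n_holes > 0) {
      errs <- vapply(hole_stats, function(st) {
        sqrt(sum((st$center - want)^2))
      }, 0)
      hole_err[h] <- min(errs)
    }
  }

  # interslot spacing measured from full-width empty rows at the block top
  top <- occ[, , d[3]]
  block_rows <- which(rowSums(mold$block2d) > 0)
  slot_row <- vapply(block_rows, function(s) {
    cols <- mold$block2d[s, ]
    !any(top[s, cols])
  }, TRUE)
  runs <- rle(slot_row)
  centers <- numeric(0)
  at <- cumsum(runs$lengths)
  for (ri in which(runs$values)) {
    rows <- block_rows[(at[ri] - runs$lengths[ri] + 1):at[ri]]
    centers <- c(centers, mean(mold$s[rows]))
  }
  want <- mold$slice_plan$positions
  slot_err <- if (length(centers) == length(want)) {
    max(abs(sort(centers) - sort(want)))
  } else {
    NA_real_
  }
  spacing_err <- if (length(centers) >= 2) {
    max(abs(diff(sort(centers)) - mold$slice_plan$spacing))
  } else {
    NA_real_
  }

  mesh_ok <- !is.null(mold$mesh)
  res <- list(
    watertight = mesh_ok && mesh_is_watertight(mold$mesh),
    manifold = mesh_ok && mesh_is_watertight(mold$mesh),
    outward_oriented = mesh_ok && mesh_volume(mold$mesh) > 0,
    insertable = insertable,
    mesh_volume_mm3 = if (mesh_ok) mesh_volume(mold$mesh) else NA_real_,
    occupancy_volume_mm3 = sum(occ) * sp^3,
    n_holes_found = n_holes,
    hole_diameters_mm = vapply(hole_stats, `[[`, 0, "diameter_mm"),
    hole_center_error_mm = hole_err,
    n_slots_found = length(centers),
    slot_center_error_mm = slot_err,
    interslot_spacing_error_mm = spacing_err)
  class(res) <- "mold_qc"
  res
}

#' @method print mold_qc
#' @export
print.mold_qc <- function(x, ...) {
  cat(sprintf(paste0("mold_qc: watertight=%s insertable=%s holes=%d ",
                     "(diam %s mm) slots=%d (spacing err %.3g mm)\n"),
              x$watertight, x$insertable, x$n_holes_found,
              paste(signif(x$hole_diameters_mm, 3), collapse = "/"),
              x$n_slots_found, x$interslot_spacing_error_mm))
  invisible(x)
}

#' Insertability of the mold cavity
#'
#' TRUE when every empty voxel has only empty voxels above it in its column
#' (equivalently: material is a contiguous stack from the block bottom), so
#' a rigid specimen can be lowered vertically into the cavity.
#'
#' @param occ logical occupancy array (s, l, u with u up).
#' @return logical scalar.
#' @export
check_insertable <- function(occ) {
  d <- dim(occ)
  m <- matrix(aperm(occ, c(3, 1, 2)), nrow = d[3]) # u runs down each column
  # material after the first empty voxel in a column is an overhang
  first_empty <- max.col(t(!m), ties.method = "first")
  all_mat <- colSums(m) == d[3]
  last_mat <- rep(0L, ncol(m))
  hasmat <- colSums(m) > 0
  last_mat[hasmat] <- max.col(t(m)[hasmat, , drop = FALSE],
                              ties.method = "last")
  all(all_mat | last_mat < first_empty)
}

#' Full validation report for a mold build
#'
#' Combines [mold_qc()] with the per-slot Dice of [slot_cross_sections()]
#' into one JSON-serializable record (the per-slice validation table).
#'
#' @param build result of [build_mold()].
#' @return a `validation_report` list.
#' @export
validation_report <- function(build) {
  qc <- mold_qc(build$mold)
  xs <- slot_cross_sections(build$mold, build$resampled)
  per_slot <- lapply(xs, function(x) {
    c(list(label = x$label, position_mm = x$position),
      as.list(x$dice),
      list(outline_vs_cavity = x$dice_outline_cavity,
           outline_area_mm2 = unname(x$area_mm2["outline"]),
           cavity_area_mm2 = unname(x$area_mm2["cavity"])))
  })
  structure(list(qc = qc, per_slot = per_slot,
                 frame = list(mode = build$frame$mode,
                              roll_deg = build$frame$roll_deg)),
            class = "validation_report")
}

#' Write a validation report as JSON
#' @param report a [validation_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(path)
}
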