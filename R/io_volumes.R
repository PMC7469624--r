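#' Image volume container
#'
#' A 3-D scalar lattice with a world-coordinate affine. World coordinates are
#' mm in the NIfTI RAS+ frame (volumes are canonically reoriented on load);
#' voxel indices are 0-based with positions at voxel centers, matching the
#' iso-surfacing convention used by the mold builder.
#'
#' @param voxels 3-D array.
#' @param affine 4x4 matrix mapping 0-based voxel index to world mm.
#' @return an `image_volume` object with fields `voxels`, `affine`, `spacing`.
#' @export
image_volume <- function(voxels, affine = diag(4)) {
  stopifnot(length(dim(voxels)) == 3, all(dim(affine) == c(4, 4)))
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  structure(list(voxels = voxels, affine = affine, spacing = spacing),
            class = "image_volume")
}

#' @method print image_volume
#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume: %s voxels, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Read a NIfTI volume as an image_volume
#'
#' Loads with RNifti, reorients to canonical RAS+ and returns the array plus
#' its 0-based voxel-to-world affine.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @return an [image_volume()].
#' @export
read_image_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(img), "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  vox <- as.array(img)
  if (length(dim(vox)) == 2) dim(vox) <- c(dim(vox), 1L)
  image_volume(vox, aff)
}

#' Write an image_volume to NIfTI
#'
#' @param vol an [image_volume()].
#' @param path output path (`.nii` / `.nii.gz`).
#' @param datatype NIfTI datatype string, e.g. `"int16"` or `"double"`.
#' @return `path`, invisibly.
#' @export
write_image_volume <- function(vol, path, datatype = "auto") {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Convert between world mm and continuous voxel indices
#'
#' Indices are 0-based and continuous (voxel centers at integers). The
#' round trip `world -> voxel -> world` is exact to numerical precision.
#'
#' @param vol an [image_volume()] (or any list with an `affine` field).
#' @param p numeric vector of length 3 or an `n x 3` matrix of points.
#' @return same shape as `p`.
#' @export
world_to_voxel <- function(vol, p) {
  inv <- solve(vol$affine)
  apply_affine(inv, p)
}

#' @rdname world_to_voxel
#' @param idx 0-based continuous voxel indices (vector or `n x 3` matrix).
#' @export
voxel_to_world <- function(vol, idx) {
  apply_affine(vol$affine, idx)
}

apply_affine <- function(A, p) {
  if (is.matrix(p)) {
    out <- cbind(p, 1) %*% t(A)
    out[, 1:3, drop = FALSE]
  } else {
    as.numeric(A %*% c(p, 1))[1:3]
  }
}

#' Segmentation set: named binary masks on a shared lattice
#'
#' Holds the per-role tissue masks (tumor, kidney, fat, optional pelvis) plus
#' their voxelwise union, the specimen outline that defines the mold cavity.
#'
#' @param masks named list of logical arrays on one lattice. A `tumor` mask is
#'   required and must be non-empty.
#' @param affine shared 4x4 voxel-to-world affine.
#' @return a `segmentation_set` with fields `masks`, `outline`, `affine`,
#'   `spacing`.
#' @export
segmentation_set <- function(masks, affine = diag(4)) {
  if (!"tumor" %in% names(masks)) stop("tumor mask required")
  unknown <- setdiff(names(masks), SEG_ROLES)
  if (length(unknown) > 0) {
    stop("unknown mask roles: ", paste(unknown, collapse = ", "))
  }
  dims <- lapply(masks, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("all masks must share one lattice")
  }
  masks <- lapply(masks, function(m) array(as.logical(m), dim(m)))
  if (!any(masks$tumor)) stop("tumor mask required (empty tumor mask)")
  outline <- Reduce(`|`, masks)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(masks = masks, outline = outline, affine = affine,
                 spacing = spacing),
            class = "segmentation_set")
}

#' @method print segmentation_set
#' @export
print.segmentation_set <- function(x, ...) {
  cat("segmentation_set:",
      paste(sprintf("%s (%d vox)", names(x$masks),
                    vapply(x$masks, sum, 0)), collapse = ", "),
      sprintf("; outline %d vox\n", sum(x$outline)))
  invisible(x)
}

#' Read a label volume into a segmentation set
#'
#' The label volume is an integer NIfTI image; `role_map` assigns label values
#' to tissue roles, e.g. `list(tumor = 1, kidney = 2, fat = 3)`.
#'
#' @param label_volume_path NIfTI path.
#' @param role_map named list/vector mapping role name to label value.
#' @return a [segmentation_set()].
#' @export
read_segmentation_set <- function(label_volume_path, role_map) {
  vol <- read_image_volume(label_volume_path)
  vox <- vol$voxels
  if (any(abs(vox - round(vox)) > 1e-6)) {
    stop("label volume must contain integer voxel values")
  }
  vox <- round(vox)
  role_map <- unlist(role_map)
  if (!"tumor" %in% names(role_map)) stop("tumor mask required")
  present <- setdiff(unique(as.vector(vox)), 0)
  unknown <- setdiff(present, role_map)
  if (length(unknown) > 0) {
    stop("label volume contains values not in role_map: ",
         paste(unknown, collapse = ", "))
  }
  masks <- lapply(role_map, function(v) vox == v)
  masks <- masks[vapply(masks, any, TRUE) | names(masks) == "tumor"]
  segmentation_set(masks, vol$affine)
}

#' Write a segmentation set as one integer label volume
#'
#' Overlapping roles are resolved by precedence tumor > kidney > fat > pelvis,
#' so the tumor boundary is always preserved exactly.
#'
#' @param seg a [segmentation_set()].
#' @param path output NIfTI path.
#' @param role_map named vector of label values; defaults to 1..n in
#'   precedence order of the roles present.
#' @return the role map used, invisibly.
#' @export
write_segmentation_set <- function(seg, path, role_map = NULL) {
  roles <- intersect(SEG_ROLES, names(seg$masks))
  if (is.null(role_map)) role_map <- stats::setNames(seq_along(roles), roles)
  lab <- array(0L, dim(seg$outline))
  for (r in rev(roles)) lab[seg$masks[[r]]] <- as.integer(role_map[[r]])
  vol <- image_volume(lab, seg$affine)
  write_image_volume(vol, path, datatype = "int16")
  invisible(role_map)
}

#' Landmark set: named anatomic points in world mm
#'
#' At least the four roles `upper_pole`, `lower_pole`, `hilum` and
#' `tumor_contact` are needed to orient a specimen inside the mold; the
#' kidney contact point is optional and kept for reporting.
#'
#' @param points named list (or `n x 3` matrix with rownames) of world-mm
#'   coordinates.
#' @return a `landmark_set`; `points` is an `n x 3` matrix with role rownames.
#' @export
landmark_set <- function(points) {
  if (is.list(points)) {
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
  }
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("landmarks must be x,y,z triples in mm")
  roles <- rownames(points)
  missing <- setdiff(LM_REQUIRED, roles)
  if (length(missing) > 0) {
    stop("missing required landmark role(s): ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(roles, LM_ROLES)
  if (length(unknown) > 0) {
    stop("unknown landmark role(s): ", paste(unknown, collapse = ", "))
  }
  if (sqrt(sum((points["upper_pole", ] - points["lower_pole", ])^2)) < 1e-9) {
    stop("upper_pole and lower_pole must be distinct points")
  }
  structure(list(points = points), class = "landmark_set")
}

#' @method print landmark_set
#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", paste(rownames(x$points), collapse = ", "), "\n")
  invisible(x)
}

#' Read landmarks from a JSON sidecar
#'
#' The sidecar maps role names to `[x, y, z]` mm triples, e.g.
#' `{"upper_pole": [1.5, -20, 88], ...}`.
#'
#' @param json_path path to the JSON file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(json_path) {
  pts <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  landmark_set(pts)
}

#' Write landmarks to a JSON sidecar
#' @param landmarks a [landmark_set()].
#' @param json_path output path.
#' @return `json_path`, invisibly.
#' @export
write_landmarks <- function(landmarks, json_path) {
  pts <- lapply(seq_len(nrow(landmarks$points)),
                function(i) as.numeric(landmarks$points[i, ]))
  names(pts) <- rownames(landmarks$points)
  jsonlite::write_json(pts, json_path, digits = NA, auto_unbox = FALSE)
  invisible(json_path)
}

#' Check that landmarks lie on or near the specimen outline
#'
#' Every landmark must fall inside the outline mask dilated by `tol_mm`; a
#' landmark floating in air almost certainly indicates a frame mismatch
#' between the label volume and the sidecar.
#'
#' @param landmarks a [landmark_set()].
#' @param seg a [segmentation_set()].
#' @param tol_mm dilation tolerance in mm (default 5).
#' @return `TRUE` invisibly, or an error naming the offending landmark.
#' @export
check_landmarks_in_outline <- function(landmarks, seg, tol_mm = 5) {
  d <- distance_transform(seg$outline, seg$spacing)
  idx <- round(world_to_voxel(seg, landmarks$points)) + 1
  dims <- dim(seg$outline)
  for (i in seq_len(nrow(idx))) {
    v <- idx[i, ]
    inside <- all(v >= 1) && all(v <= dims) && d[v[1], v[2], v[3]] <= tol_mm
    if (!inside) {
      stop("landmark '", rownames(landmarks$points)[i],
           "' lies more than ", tol_mm, " mm outside the specimen outline")
    }
  }
  invisible(TRUE)
}

#' Read a role map from a YAML config
#'
#' @param yaml_path YAML file with a `roles:` mapping of role name to label
#'   value (or a flat mapping).
#' @return named list of label values.
#' @export
read_role_map <- function(yaml_path) {
  y <- yaml::read_yaml(yaml_path)
  if (!is.null(y$roles)) y <- y$roles
  y
}

#' Bundle a segmentation set, landmarks and optional parameter maps
#'
#' @param seg a [segmentation_set()].
#' @param landmarks a [landmark_set()].
#' @param maps optional named list of [image_volume()] parameter maps
#'   co-registered with the segmentation lattice.
#' @return an `mri_study` object.
#' @export
mri_study <- function(seg, landmarks, maps = NULL) {
  stopifnot(inherits(seg, "segmentation_set"), inherits(landmarks, "landmark_set"))
  structure(list(seg = seg, landmarks = landmarks, maps = maps),
            class = "mri_study")
}
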