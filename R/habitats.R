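#' Multiparametric parameter stack
#'
#' The 7 co-registered MRI channels (T1-weighted, T2-weighted, T1 map, DCE
#' Ktrans, IVIM D0 and perfusion fraction f, R2*) on one lattice, plus the
#' tumor mask over which habitats are defined.
#'
#' @param channels named list of 3-D arrays; names must be the 7 channels
#'   T1w, T2w, T1, Ktrans, D0, f, R2star.
#' @param tumor_mask logical array on the same lattice; non-empty.
#' @param affine shared 4x4 voxel-to-world affine.
#' @param units named character vector of per-channel units.
#' @return a `parameter_stack`.
#' @export
parameter_stack <- function(channels, tumor_mask, affine = diag(4),
                            units = MP_UNITS) {
  if (!setequal(names(channels), MP_CHANNELS)) {
    stop("channels must be exactly: ", paste(MP_CHANNELS, collapse = ", "))
  }
  channels <- channels[MP_CHANNELS]
  dims <- unique(vapply(channels, function(x) paste(dim(x), collapse = "x"), ""))
  if (length(dims) != 1 ||
      !identical(paste(dim(tumor_mask), collapse = "x"), dims)) {
    stop("all channels and the tumor mask must share one lattice")
  }
  tumor_mask <- array(as.logical(tumor_mask), dim(tumor_mask))
  if (!any(tumor_mask)) stop("tumor mask is empty")
  structure(list(channels = channels, tumor_mask = tumor_mask,
                 affine = affine, units = units),
            class = "parameter_stack")
}

#' @method print parameter_stack
#' @export
print.parameter_stack <- function(x, ...) {
  cat(sprintf("parameter_stack: %d channels on %s lattice, %d tumor voxels\n",
              length(x$channels), paste(dim(x$tumor_mask), collapse = "x"),
              sum(x$tumor_mask)))
  invisible(x)
}

#' Read a parameter stack from a directory of NIfTI maps
#'
#' Expects one NIfTI per channel (named `<channel>.nii.gz`) plus the tumor
#' mask volume.
#'
#' @param dir directory containing the per-channel volumes.
#' @param tumor_mask_path NIfTI tumor mask (default `tumor_mask.nii.gz` in
#'   `dir`).
#' @return a [parameter_stack()].
#' @export
read_parameter_stack <- function(dir,
                                 tumor_mask_path = file.path(dir, "tumor_mask.nii.gz")) {
  channels <- lapply(MP_CHANNELS, function(ch) {
    p <- file.path(dir, paste0(ch, ".nii.gz"))
    if (!file.exists(p)) p <- file.path(dir, paste0(ch, ".nii"))
    read_image_volume(p)
  })
  names(channels) <- MP_CHANNELS
  mask_vol <- read_image_volume(tumor_mask_path)
  parameter_stack(lapply(channels, `[[`, "voxels"),
                  mask_vol$voxels > 0.5, channels[[1]]$affine)
}

#' Per-voxel feature table for habitat clustering
#'
#' One row per tumor voxel, one column per channel, z-scored (population SD)
#' per channel within the tumor mask so that channels with incommensurate
#' units contribute comparably. Voxels with any non-finite channel value are
#' dropped with a message; a zero-variance channel stays an all-zero column
#' with a warning.
#'
#' @param stack a [parameter_stack()].
#' @return list with `features` (matrix), `voxels` (lattice indices of the
#'   rows), `center`/`scale` per channel, `dropped` (count).
#' @export
build_feature_table <- function(stack) {
  idx <- which(stack$tumor_mask)
  raw <- vapply(stack$channels, function(ch) ch[idx], numeric(length(idx)))
  finite <- rowSums(!is.finite(raw)) == 0
  dropped <- sum(!finite)
  if (dropped > 0) {
    message(dropped, " tumor voxel(s) with non-finite channel values dropped")
    raw <- raw[finite, , drop = FALSE]
    idx <- idx[finite]
  }
  if (nrow(raw) == 0) stop("no finite tumor voxels")
  ctr <- colMeans(raw)
  n <- nrow(raw)
  scl <- sqrt(colMeans(sweep(raw, 2, ctr)^2)) # population SD
  zerovar <- scl < 1e-12
  if (any(zerovar)) {
    warning("zero-variance channel(s) left at zero: ",
            paste(colnames(raw)[zerovar], collapse = ", "))
    scl[zerovar] <- 1
  }
  feats <- sweep(sweep(raw, 2, ctr), 2, scl, `/`)
  feats[, zerovar] <- 0
  list(features = feats, voxels = idx, center = ctr, scale = scl,
       dropped = dropped)
}

# k-means++ seeding
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      tot <- sum(d2)
      i <- if (tot <= 0) sample.int(n, 1) else {
        sample.int(n, 1, prob = d2 / tot)
      }
      centers[j, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Cluster tumor voxels into spatial habitats by k-means
#'
#' k-means with k-means++ initialization and `n_init` restarts (best inertia
#' kept). Habitat labels are renumbered by decreasing habitat size, so the
#' labelling is deterministic for a fixed seed.
#'
#' @param features feature matrix (or result of [build_feature_table()]).
#' @param k number of habitats (>= 1, <= number of rows).
#' @param seed integer seed controlling all restarts.
#' @param n_init number of k-means++ restarts.
#' @return a `habitat_map`: `labels` (per feature row), `k`, `centers` (in
#'   feature space, by final label), `inertia`, `sizes`, `seed`, and the
#'   `voxels` row indices when a feature-table result was supplied.
#' @export
cluster_habitats <- function(features, k, seed = 1, n_init = 10) {
  voxels <- NULL
  if (is.list(features) && !is.null(features$features)) {
    voxels <- features$voxels
    features <- features$features
  }
  X <- as.matrix(features)
  stopifnot(k >= 1)
  if (k > nrow(X)) stop("k exceeds the number of tumor voxels")
  set.seed(seed)
  best <- NULL
  for (rep in seq_len(n_init)) {
    ctr <- kmeanspp_centers(X, k)
    km <- suppressWarnings(
      stats::kmeans(X, centers = ctr, iter.max = 200, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  ord <- order(-tabulate(best$cluster, k), seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[best$cluster]
  structure(list(labels = labels, k = k,
                 centers = best$centers[ord, , drop = FALSE],
                 inertia = best$tot.withinss,
                 sizes = tabulate(labels, k),
                 seed = seed, n_init = n_init, voxels = voxels),
            class = "habitat_map")
}

#' @method print habitat_map
#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("habitat_map: k=%d, sizes %s, inertia %.1f\n",
              x$k, paste(x$sizes, collapse = "/"), x$inertia))
  invisible(x)
}

#' Select the number of habitats by mean silhouette
#'
#' Clusters at every k in `k_range` and returns the k maximizing the mean
#' silhouette width (ties resolved toward the smaller k). When even the best
#' silhouette is below `structure_threshold` the result is flagged as having
#' no habitat structure.
#'
#' @param features feature matrix or [build_feature_table()] result.
#' @param k_range candidate cluster counts (default 2:6).
#' @param seed integer seed.
#' @param n_init k-means restarts per k.
#' @param structure_threshold mean-silhouette floor below which the
#'   `no_structure` flag is raised (default 0.25).
#' @return list with `k` (chosen), `silhouette` (named vector over k_range),
#'   `no_structure` flag and the per-k `maps`.
#' @export
select_k <- function(features, k_range = 2:6, seed = 1, n_init = 10,
                     structure_threshold = 0.25) {
  if (is.list(features) && !is.null(features$features)) {
    features <- features$features
  }
  X <- as.matrix(features)
  if (nrow(X) < 3) stop("too few voxels to select a cluster count")
  if (min(k_range) < 2 || max(k_range) > nrow(X) - 1) {
    stop("k_range must lie within [2, rows - 1]")
  }
  if (all(apply(X, 2, function(col) max(col) - min(col) < 1e-12))) {
    stop("degenerate features: all voxels identical")
  }
  D <- stats::dist(X)
  sil <- numeric(length(k_range))
  maps <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    maps[[i]] <- cluster_habitats(X, k_range[i], seed = seed, n_init = n_init)
    s <- cluster::silhouette(maps[[i]]$labels, D)
    sil[i] <- mean(s[, "sil_width"])
  }
  names(sil) <- k_range
  k <- k_range[which.max(sil)] # which.max takes the first (smallest k) on ties
  list(k = k, silhouette = sil, no_structure = max(sil) < structure_threshold,
       maps = maps)
}

#' Per-habitat channel profiles (median and IQR)
#'
#' Summaries are computed on the raw (unnormalized) channel values, so they
#' read in physical units.
#'
#' @param stack a [parameter_stack()].
#' @param map a [cluster_habitats()] result whose rows correspond to the
#'   stack's feature table (use the same stack).
#' @return data frame with habitat, channel, n, median, q25, q75, iqr, unit.
#' @export
habitat_profiles <- function(stack, map) {
  ft <- build_feature_table(stack)
  if (length(map$labels) != nrow(ft$features)) {
    stop("habitat map does not match the stack's tumor voxels")
  }
  raw <- vapply(stack$channels, function(ch) ch[ft$voxels],
                numeric(length(ft$voxels)))
  rows <- list()
  for (h in seq_len(map$k)) {
    sel <- map$labels == h
    for (ch in colnames(raw)) {
      v <- raw[sel, ch]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        habitat = h, channel = ch, n = sum(sel),
        median = q[2], q25 = q[1], q75 = q[3], iqr = q[3] - q[1],
        unit = unname(stack$units[ch]))
    }
  }
  do.call(rbind, rows)
}

#' Habitat labels as an integer volume on the stack lattice
#'
#' @param map a [cluster_habitats()] result carrying `voxels` (cluster on a
#'   [build_feature_table()] result to get them).
#' @param stack the [parameter_stack()] the features came from.
#' @return integer array; 0 outside the tumor mask.
#' @export
habitat_label_volume <- function(map, stack) {
  if (is.null(map$voxels)) {
    stop("habitat map carries no voxel indices; cluster a feature table")
  }
  lab <- array(0L, dim(stack$tumor_mask))
  lab[map$voxels] <- map$labels
  lab
}
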