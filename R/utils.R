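#' Euclidean distance transform of a binary volume
#'
#' Exact distance (in mm) from every voxel to the nearest `TRUE` voxel,
#' honouring anisotropic spacing. Computed with the separable lower-envelope
#' algorithm over squared distances, so it is exact on the lattice.
#'
#' @param mask logical array (2-D or 3-D).
#' @param spacing numeric voxel size per axis in mm.
#' @return numeric array of distances in mm (`Inf` if `mask` is all-`FALSE`).
#' @export
distance_transform <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be an array")
  if (length(d) == 2) {
    d <- c(d, 1L)
    spacing <- c(spacing[1:2], 1)
  }
  stopifnot(length(spacing) >= 3, all(spacing[1:3] > 0))
  out <- .edt3d(as.logical(mask), as.integer(d), as.numeric(spacing[1:3]))
  array(out, dim(mask))
}

#' Separable Gaussian smoothing of a 3-D scalar field
#'
#' Convolves with a truncated Gaussian (radius 3 sigma) independently along
#' each axis; the field is treated as zero outside the array, which is the
#' natural convention for binary occupancy fields embedded with background 0.
#'
#' @param field numeric (or logical) 3-D array.
#' @param sigma_mm Gaussian standard deviation in mm; 0 returns the input.
#' @param spacing voxel size per axis in mm.
#' @return numeric array of the same dimension.
#' @export
gaussian_smooth <- function(field, sigma_mm, spacing = c(1, 1, 1)) {
  stopifnot(sigma_mm >= 0)
  arr <- field * 1.0
  if (sigma_mm == 0) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    s_vox <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * s_vox))
    kv <- exp(-0.5 * ((-r:r) / s_vox)^2)
    kv <- kv / sum(kv)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- kv[o + r + 1]
    }
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = n)
    m <- K %*% m
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  arr
}

#' Connected components of a binary array
#'
#' Labels 6-connected (face-adjacent) components of a 2-D or 3-D logical
#' array with a vectorised breadth-first search.
#'
#' @param mask logical array.
#' @return integer array; 0 is background, components are numbered from 1 in
#'   decreasing size order.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) d <- c(d, 1L)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  lab <- integer(length(mask))
  remaining <- as.logical(mask)
  remaining[is.na(remaining)] <- FALSE
  cur <- 0L
  todo <- which(remaining)
  while (length(todo) > 0) {
    cur <- cur + 1L
    frontier <- todo[1]
    remaining[frontier] <- FALSE
    while (length(frontier) > 0) {
      lab[frontier] <- cur
      z <- frontier - 1L
      i <- z %% nx
      j <- (z %/% nx) %% ny
      k <- z %/% (nx * ny)
      nb <- c(frontier[i > 0L] - 1L, frontier[i < nx - 1L] + 1L,
              frontier[j > 0L] - nx, frontier[j < ny - 1L] + nx,
              frontier[k > 0L] - nx * ny, frontier[k < nz - 1L] + nx * ny)
      nb <- unique(nb[remaining[nb]])
      remaining[nb] <- FALSE
      frontier <- nb
    }
    todo <- todo[remaining[todo]]
  }
  # renumber by decreasing size for determinism
  if (cur > 1L) {
    sizes <- tabulate(lab, cur)
    ord <- order(-sizes)
    remap <- integer(cur)
    remap[ord] <- seq_len(cur)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  array(lab, dim(mask))
}

# unit-normalize a vector, erroring on degenerate input
unitv <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop(what, " has zero length")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# first/last TRUE index along the 3rd axis for every (i,j) column;
# returns a list of two matrices (NA where the column is empty)
column_extrema <- function(mask) {
  d <- dim(mask)
  m <- matrix(aperm(mask, c(3, 1, 2)), nrow = d[3])
  any_col <- colSums(m) > 0
  first <- rep(NA_integer_, ncol(m))
  last <- rep(NA_integer_, ncol(m))
  tm <- t(m)
  first[any_col] <- max.col(tm, ties.method = "first")[any_col]
  last[any_col] <- max.col(tm, ties.method = "last")[any_col]
  list(first = matrix(first, d[1], d[2]),
       last = matrix(last, d[1], d[2]),
       any = matrix(any_col, d[1], d[2]))
}
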