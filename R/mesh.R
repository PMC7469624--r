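#' Triangle mesh container
#'
#' A minimal indexed triangle mesh in mm: an `n x 3` vertex matrix and an
#' `m x 3` integer face matrix (1-based, counter-clockwise when viewed from
#' outside).
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0) {
    stopifnot(min(faces) >= 1, max(faces) <= nrow(vertices))
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @method print triangle_mesh
#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, volume %.1f mm^3%s\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x),
              if (mesh_is_watertight(x)) ", watertight" else ", NOT watertight"))
  invisible(x)
}

#' Signed enclosed volume of a triangle mesh
#'
#' Divergence-theorem volume; positive for a closed, outward-oriented surface.
#'
#' @param mesh a [triangle_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0) return(0)
  v0 <- V[F[, 1], , drop = FALSE]
  v1 <- V[F[, 2], , drop = FALSE]
  v2 <- V[F[, 3], , drop = FALSE]
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  sum(rowSums(v0 * cr)) / 6
}

#' Total surface area of a triangle mesh
#' @param mesh a [triangle_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0) return(0)
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

mesh_edge_keys <- function(faces) {
  ed <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  list(directed = ed,
       undirected = pmin(ed[, 1], ed[, 2]) * (2^31) + pmax(ed[, 1], ed[, 2]))
}

#' Watertightness and orientation check
#'
#' A mesh is watertight-manifold here when every undirected edge is shared by
#' exactly two faces and the two faces traverse it in opposite directions
#' (consistent orientation, no boundary, no fins).
#'
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
mesh_is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  ek <- mesh_edge_keys(mesh$faces)
  if (anyDuplicated(paste(ek$directed[, 1], ek$directed[, 2]))) return(FALSE)
  all(tabulate(factor(ek$undirected)) == 2L)
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a [triangle_mesh()].
#' @return integer; 2 for a genus-0 closed surface.
#' @export
mesh_euler <- function(mesh) {
  ek <- mesh_edge_keys(mesh$faces)
  ne <- length(unique(ek$undirected))
  nv <- length(unique(as.vector(mesh$faces)))
  nv - ne + nrow(mesh$faces)
}

mesh_adjacency <- function(mesh) {
  F <- mesh$faces
  ed <- unique(rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)]))
  n <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = ed[, 1], j = ed[, 2], x = 1, dims = c(n, n))
}

# one uniform-weight Laplacian displacement step: p <- p + w * (mean(nb) - p)
laplacian_step <- function(V, A, deg, w) {
  V + w * (as.matrix(A %*% V) / deg - V)
}

#' Uniform-weight Laplacian mesh smoothing
#'
#' Repeatedly moves each vertex toward the mean of its neighbours. Smooths but
#' also shrinks closed surfaces; see [taubin_smooth()] for the
#' shrink-compensated variant.
#'
#' @param mesh a [triangle_mesh()].
#' @param lambda step size in (0, 1].
#' @param iterations number of passes.
#' @return smoothed `triangle_mesh`.
#' @export
laplacian_smooth <- function(mesh, lambda = 0.5, iterations = 10) {
  if (iterations == 0) return(mesh)
  A <- mesh_adjacency(mesh)
  deg <- pmax(Matrix::rowSums(A), 1)
  V <- mesh$vertices
  for (i in seq_len(iterations)) V <- laplacian_step(V, A, deg, lambda)
  triangle_mesh(V, mesh$faces)
}

#' Taubin lambda/mu mesh smoothing
#'
#' Alternates a positive Laplacian step (`lambda`) with a negative one (`mu`),
#' which acts as a low-pass filter on the surface and largely cancels the
#' volume shrinkage of plain Laplacian smoothing. Requires
#' `mu < -lambda < 0`.
#'
#' @param mesh a [triangle_mesh()].
#' @param lambda positive step size.
#' @param mu negative step size with `|mu| > lambda`.
#' @param iterations number of lambda+mu pairs.
#' @return smoothed `triangle_mesh`.
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, mu = -0.53, iterations = 10) {
  if (iterations == 0) return(mesh)
  if (!(mu < -lambda && lambda > 0)) {
    stop("Taubin scheme requires mu < -lambda < 0")
  }
  A <- mesh_adjacency(mesh)
  deg <- pmax(Matrix::rowSums(A), 1)
  V <- mesh$vertices
  for (i in seq_len(iterations)) {
    V <- laplacian_step(V, A, deg, lambda)
    V <- laplacian_step(V, A, deg, mu)
  }
  triangle_mesh(V, mesh$faces)
}

#' Distance from points to a triangle mesh surface
#'
#' Exact point-to-triangle distances computed by brute force over all faces;
#' intended for QC and for Hausdorff-style mesh comparisons at modest sizes.
#'
#' @param points numeric matrix, one row per query point (mm).
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of unsigned distances in mm.
#' @export
point_mesh_distance <- function(points, mesh) {
  P <- as.matrix(points)
  if (ncol(P) != 3) P <- matrix(P, ncol = 3)
  V <- mesh$vertices; F <- mesh$faces
  best <- rep(Inf, nrow(P))
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; cc <- V[F[f, 3], ]
    ab <- b - a; ac <- cc - a
    d1 <- sweep(P, 2, a)
    # project into the triangle plane using barycentric clamping
    dAB <- d1 %*% ab; dAC <- d1 %*% ac
    abab <- sum(ab^2); acac <- sum(ac^2); abac <- sum(ab * ac)
    det <- abab * acac - abac^2
    u <- (acac * dAB - abac * dAC) / det
    v <- (abab * dAC - abac * dAB) / det
    u <- pmin(pmax(u, 0), 1)
    v <- pmin(pmax(v, 0), 1)
    over <- (u + v) > 1
    if (any(over)) {
      s <- (u[over] + v[over])
      u[over] <- u[over] / s
      v[over] <- v[over] / s
    }
    # clamped barycentric point is not the exact closest point on edges, so
    # refine by also testing the three edges explicitly
    q <- outer(as.vector(u), ab) + outer(as.vector(v), ac)
    d2 <- rowSums((d1 - q)^2)
    for (e in list(list(a, ab), list(a, ac), list(b, cc - b))) {
      pe <- sweep(P, 2, e[[1]])
      t <- pmin(pmax((pe %*% e[[2]]) / sum(e[[2]]^2), 0), 1)
      d2e <- rowSums((pe - outer(as.vector(t), e[[2]]))^2)
      d2 <- pmin(d2, d2e)
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Export a triangle mesh as STL
#'
#' Writes binary (default) or ASCII STL in mm. The mesh must be watertight;
#' export of an open or inconsistently oriented mesh is refused so that a
#' defective mold cannot silently reach a printer.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"binary"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
export_stl <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  if (!mesh_is_watertight(mesh)) {
    stop("mesh is not watertight; run mold_qc() on the model for details")
  }
  V <- mesh$vertices; F <- mesh$faces
  v0 <- V[F[, 1], , drop = FALSE]
  v1 <- V[F[, 2], , drop = FALSE]
  v2 <- V[F[, 3], , drop = FALSE]
  e1 <- v1 - v0; e2 <- v2 - v0
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n <- n / ifelse(len > 0, len, 1)
  nf <- nrow(F)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # 50 bytes per facet: 12 little-endian float32 + 2 attribute bytes
    fl <- writeBin(as.numeric(t(cbind(n, v0, v1, v2))), raw(),
                   size = 4, endian = "little")
    block <- matrix(as.raw(0), 50, nf)
    block[1:48, ] <- matrix(fl, 48, nf)
    writeBin(as.vector(block), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mold", con)
    tri <- sprintf(paste0(
      " facet normal %.9e %.9e %.9e\n  outer loop\n",
      "   vertex %.9e %.9e %.9e\n   vertex %.9e %.9e %.9e\n",
      "   vertex %.9e %.9e %.9e\n  endloop\n endfacet"),
      n[, 1], n[, 2], n[, 3],
      v0[, 1], v0[, 2], v0[, 3],
      v1[, 1], v1[, 2], v1[, 3],
      v2[, 1], v2[, 2], v2[, 3])
    writeLines(tri, con)
    writeLines("endsolid mold", con)
  }
  invisible(path)
}

#' Import an STL file as a triangle mesh
#'
#' Reads binary or ASCII STL (auto-detected) and welds identical vertices so
#' topological checks are meaningful after a round trip.
#'
#' @param path STL file path.
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path) {
  head_bytes <- readBin(path, raw(), n = 6)
  is_ascii <- identical(rawToChar(head_bytes[1:5]), "solid") &&
    !is_binary_stl(path)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, raw(), n = 80)
    nf <- readBin(con, integer(), size = 4, endian = "little")
    xyz <- matrix(NA_real_, nf * 3, 3)
    for (f in seq_len(nf)) {
      vals <- readBin(con, numeric(), n = 12, size = 4, endian = "little")
      readBin(con, integer(), n = 1, size = 2, endian = "little")
      xyz[(3 * f - 2):(3 * f), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  uid <- !duplicated(key)
  vid <- match(key, key[uid])
  V <- xyz[uid, , drop = FALSE]
  Fm <- matrix(vid, ncol = 3, byrow = TRUE)
  triangle_mesh(V, Fm)
}

is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, raw(), n = 80)
  nf <- readBin(con, integer(), size = 4, endian = "little")
  identical(sz, 84 + 50 * as.numeric(nf))
}
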