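#' @useDynLib ventricle3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rnorm runif median mad pt p.adjust coef complete.cases
#' @importFrom utils head tail write.csv read.csv read.table write.table
#' @importFrom methods as
NULL

#' Volume image in world (RAS) millimetre coordinates
#'
#' A 3D scalar grid plus a 4x4 voxel-to-world affine following the NIfTI
#' convention (0-based voxel indices).
#'
#' @param data 3D numeric or logical array.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @return An object of class `tv_volume` with fields `data`, `affine`,
#'   `voxel_size`.
#' @export
volume_image <- function(data, affine = diag(4)) {
  stopifnot(length(dim(data)) == 3L)
  affine <- as.matrix(affine)
  stopifnot(nrow(affine) == 4L, ncol(affine) == 4L)
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes must be positive")
  structure(list(data = data, affine = affine, voxel_size = vs),
            class = "tv_volume")
}

#' Binary mask volume
#'
#' A [volume_image()] whose data is restricted to \{0, 1\} and contains at
#' least one foreground voxel.
#'
#' @param data 3D array coercible to logical.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @return An object of class `tv_mask` (inherits `tv_volume`).
#' @export
binary_mask <- function(data, affine = diag(4)) {
  d <- data
  if (!is.logical(d)) {
    u <- unique(as.vector(d))
    if (!all(u %in% c(0, 1))) stop("mask data must be binary (0/1)")
    d <- array(as.logical(d), dim(d))
  }
  if (!any(d)) stop("mask has no foreground voxels")
  v <- volume_image(d, affine)
  class(v) <- c("tv_mask", class(v))
  v
}

#' Oriented midplane (center + unit normal, world mm)
#'
#' @param center numeric length-3 point on the plane (mm).
#' @param normal numeric length-3 normal; normalised on construction.
#' @return An object of class `tv_midplane`.
#' @export
midplane <- function(center = c(0, 0, 0), normal = c(1, 0, 0)) {
  center <- as.numeric(center)
  normal <- as.numeric(normal)
  stopifnot(length(center) == 3L, length(normal) == 3L)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("normal must be non-zero")
  structure(list(center = center, normal = normal / nn),
            class = "tv_midplane")
}

#' Triangle mesh with fixed connectivity
#'
#' Vertices are world coordinates in mm; faces are 1-based vertex index
#' triples, consistently oriented with outward normals. Connectivity is never
#' changed by any deformation in this package, so vertex correspondence is
#' carried through the whole pipeline.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix (1-based).
#' @return An object of class `tv_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3L)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("faces index vertices out of range")
  structure(list(vertices = vertices, faces = faces), class = "tv_mesh")
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation numeric length-3 (mm).
#' @return An object of class `tv_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(nrow(rotation) == 3L, ncol(rotation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "tv_rigid")
}

#' Apply a rigid transform to points
#' @param xfm a [rigid_transform()].
#' @param points k x 3 matrix (or length-3 vector) of mm coordinates.
#' @return transformed points, k x 3.
#' @export
apply_transform <- function(xfm, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  sweep(p %*% t(xfm$rotation), 2, xfm$translation, "+")
}

#' Invert a rigid transform
#' @param xfm a [rigid_transform()].
#' @return the inverse `tv_rigid`.
#' @export
invert_transform <- function(xfm) {
  rt <- t(xfm$rotation)
  rigid_transform(rt, -as.numeric(rt %*% xfm$translation))
}

#' Compose rigid transforms (apply `b` first, then `a`)
#' @param a,b rigid transforms.
#' @return `tv_rigid` equal to a o b.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

# ---- voxel <-> world helpers (0-based voxel indices) ----

voxel_to_world <- function(vol, ijk) {
  ijk <- if (is.null(dim(ijk))) matrix(ijk, ncol = 3) else as.matrix(ijk)
  h <- cbind(ijk, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

world_to_voxel <- function(vol, xyz) {
  xyz <- if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else as.matrix(xyz)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE]
}

# world coordinates of all voxel centres (in array order)
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  voxel_to_world(vol, ijk)
}

#' @export
print.tv_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.tv_mesh <- function(x, ...) {
  cat(sprintf("<tv_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
print.tv_midplane <- function(x, ...) {
  cat(sprintf("<tv_midplane> center (%s) mm, normal (%s)\n",
              paste(signif(x$center, 4), collapse = ", "),
              paste(signif(x$normal, 4), collapse = ", ")))
  invisible(x)
}

#' Per-vertex outward unit normals (area-weighted average of face normals)
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(V), 3)
  for (c in 1:3) {
    agg <- rowsum(fn, F[, c])
    idx <- as.integer(rownames(agg))
    n[idx, ] <- n[idx, ] + agg
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

#' Enclosed volume of a closed oriented mesh (divergence theorem)
#' @param mesh a closed [triangle_mesh()].
#' @return volume in mm^3 (positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}
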