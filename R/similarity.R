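#' Dice coefficient of two binary masks
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return 2|A intersect B| / (|A| + |B|).
#' @export
dice_coefficient <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$data)
  nb <- sum(b$data)
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(a$data & b$data) / (na + nb)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$affine - b$affine)) > 1e-6)
    stop("masks are not on the same grid")
  invisible(TRUE)
}

#' Symmetric mean and Hausdorff surface distances
#'
#' Each argument may be a point matrix (k x 3) or a [triangle_mesh()];
#' distances from the other object's points to a mesh are point-to-triangle
#' (nearest point anywhere on the surface), not point-to-vertex. Distances
#' between two point sets are nearest-point.
#'
#' @param a,b point matrices or meshes.
#' @return list with `mean_distance` (symmetric mean, mm) and `hausdorff`
#'   (symmetric Hausdorff, mm).
#' @export
surface_distances <- function(a, b) {
  pts <- function(x) if (inherits(x, "tv_mesh")) x$vertices else as.matrix(x)
  if (!nrow(pts(a)) || !nrow(pts(b))) stop("empty point set")
  d_to <- function(from, to) {
    p <- pts(from)
    if (inherits(to, "tv_mesh"))
      .cpp_point_mesh_dist(p, to$vertices, to$faces - 1L)
    else
      RANN::nn2(pts(to), p, k = 1)$nn.dists[, 1]
  }
  dab <- d_to(a, b)
  dba <- d_to(b, a)
  list(mean_distance = (mean(dab) + mean(dba)) / 2,
       hausdorff = max(max(dab), max(dba)))
}

#' Relative volume difference and volume overlap error
#'
#' RVD = (|A| - |B|) / |B| x 100 (signed, percent); VOE =
#' (1 - |A intersect B| / |A union B|) x 100. The absolute volume
#' difference in cubic mm is reported alongside, since both readings of a
#' "volume difference" are in common use.
#'
#' @param a,b [binary_mask()] objects on the same grid; `b` is the
#'   reference.
#' @return list with `rvd_percent`, `voe_percent`,
#'   `volume_difference_mm3`.
#' @export
volume_metrics <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$data)
  nb <- sum(b$data)
  if (nb == 0) stop("reference mask is empty")
  inter <- sum(a$data & b$data)
  uni <- na + nb - inter
  if (uni == 0) stop("both masks are empty")
  list(rvd_percent = (na - nb) / nb * 100,
       voe_percent = (1 - inter / uni) * 100,
       volume_difference_mm3 = (na - nb) * prod(b$voxel_size))
}

#' Bland-Altman agreement analysis
#'
#' @param x,y paired per-subject measurements (length >= 3).
#' @return list with `bias` (mean of x - y), `loa` (bias +/- 1.96 sd),
#'   `sd`, and the paired `means`/`differences` for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       sd = s, means = (x + y) / 2, differences = d)
}

#' Full similarity report between a fitted mesh and its source mask
#'
#' Voxelizes the mesh on the mask grid for the volumetric metrics and
#' measures the surface distances against the mask's voxel boundary mesh
#' (the exposed voxel faces), mirroring the standard validation protocol of
#' comparing an individualized model with the voxel mesh generated from its
#' binary mask.
#'
#' @param mesh fitted [triangle_mesh()].
#' @param mask source [binary_mask()].
#' @return list with `dice`, `mean_distance`, `hausdorff`, `rvd_percent`,
#'   `voe_percent`, `volume_difference_mm3`, `mesh_volume_mm3`,
#'   `mask_volume_mm3`.
#' @export
compare_fit <- function(mesh, mask) {
  vox <- voxelize_mesh(mesh, mask)
  dc <- dice_coefficient(vox, mask)
  vm <- volume_metrics(vox, mask)
  sdists <- surface_distances(mesh, mask_boundary_mesh(mask))
  list(dice = dc, mean_distance = sdists$mean_distance,
       hausdorff = sdists$hausdorff, rvd_percent = vm$rvd_percent,
       voe_percent = vm$voe_percent,
       volume_difference_mm3 = vm$volume_difference_mm3,
       mesh_volume_mm3 = sum(vox$data) * prod(mask$voxel_size),
       mask_volume_mm3 = sum(mask$data) * prod(mask$voxel_size))
}
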