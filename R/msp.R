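#' Midsagittal plane from a native-to-standard rigid transform
#'
#' In standard space the midsagittal plane is fixed: normal (1, 0, 0) through
#' the origin. The subject's plane in native space is that plane mapped
#' through the inverse of the native-to-standard rigid registration.
#'
#' @param native_to_standard a [rigid_transform()] (native mm to standard mm).
#' @return a [midplane()] in native space.
#' @export
plane_from_transform <- function(native_to_standard) {
  stopifnot(inherits(native_to_standard, "tv_rigid"))
  inv <- invert_transform(native_to_standard)
  center <- drop(apply_transform(inv, c(0, 0, 0)))
  normal <- drop(inv$rotation %*% c(1, 0, 0))
  midplane(center, normal)
}

#' Map a midplane through a rigid transform
#' @param plane a [midplane()].
#' @param xfm a [rigid_transform()].
#' @return the transformed [midplane()].
#' @export
transform_plane <- function(plane, xfm) {
  midplane(drop(apply_transform(xfm, plane$center)),
           drop(xfm$rotation %*% plane$normal))
}

#' Dice overlap of a mask with its own reflection across a plane
#'
#' Reflection symmetry score used both as the objective of
#' [estimate_msp_by_symmetry()] and as a QC measure of a supplied plane.
#' The reflected foreground is compared voxel-wise after nearest-neighbour
#' resampling onto the mask grid.
#'
#' @param mask a [binary_mask()].
#' @param plane a [midplane()].
#' @return Dice coefficient in \[0, 1\].
#' @export
reflection_dice <- function(mask, plane) {
  fg <- which(mask$data)
  idx <- which(mask$data, arr.ind = TRUE) - 1L
  w <- voxel_to_world(mask, idx)
  wr <- reflect_across_plane(w, plane)
  ijk <- round(world_to_voxel(mask, wr))
  d <- dim(mask$data)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
    ijk[, 3] >= 0 & ijk[, 3] < d[3]
  hit <- logical(nrow(ijk))
  hit[ok] <- mask$data[ijk[ok, , drop = FALSE] + 1L]
  2 * sum(hit) / (2 * length(fg))
}

#' Estimate the midsagittal plane by reflection symmetry
#'
#' Searches for the plane of best reflection symmetry: a coarse
#' deterministic grid over normal tilt and offset around an initial plane,
#' followed by local refinement by repeated grid shrinking. The objective
#' is the mean squared signed distance from the reflected boundary-voxel
#' cloud to the mask surface (sub-voxel, via the signed distance field),
#' which stays sharp where the voxel-wise Dice overlap plateaus; the
#' attained symmetry Dice is attached as a QC score. Intended for
#' near-midline structures when no registration to standard space is
#' available.
#'
#' @param mask a [binary_mask()].
#' @param init initial [midplane()]; default: normal (1,0,0) through the
#'   foreground centroid.
#' @param max_tilt_deg search bound on normal tilt (degrees).
#' @param max_offset_mm search bound on plane offset along its normal (mm).
#' @param coarse_step_deg,coarse_step_mm coarse grid resolution.
#' @param refine_levels number of grid-shrinking refinement passes.
#' @return a [midplane()] with attribute `symmetry_dice`.
#' @export
estimate_msp_by_symmetry <- function(mask, init = NULL, max_tilt_deg = 15,
                                     max_offset_mm = 10,
                                     coarse_step_deg = 1,
                                     coarse_step_mm = 0.5,
                                     refine_levels = 3) {
  stopifnot(inherits(mask, "tv_mask"))
  idx <- which(mask$data, arr.ind = TRUE) - 1L
  w <- voxel_to_world(mask, idx)
  if (nrow(w) >= 4) {
    sv <- svd(sweep(w, 2, colMeans(w)))
    if (sv$d[3] < 1e-9 * sv$d[1] || sv$d[2] < 1e-9 * sv$d[1])
      stop("degenerate mask: foreground is planar or linear")
  }
  if (is.null(init)) init <- midplane(colMeans(w), c(1, 0, 0))
  n0 <- init$normal
  # two in-plane axes to tilt about
  e1 <- pick_orthogonal(n0)
  e2 <- cross3v(n0, e1)
  sdf <- signed_distance_field(mask)
  # sample points that lie on the mask surface itself (voxel-face corners),
  # where the SDF of a symmetric mask vanishes after reflection
  cloud <- mask_boundary_mesh(mask)$vertices
  score <- function(a, b, off) {
    n <- rotate_about(rotate_about(n0, e1, a), e2, b)
    refl <- reflect_across_plane(cloud, midplane(init$center + off * n0, n))
    -mean(interp_volume(sdf, refl)^2)
  }
  best <- c(a = 0, b = 0, off = 0)
  step_deg <- coarse_step_deg
  step_mm <- coarse_step_mm
  span_deg <- max_tilt_deg
  span_mm <- max_offset_mm
  for (lev in seq_len(refine_levels + 1)) {
    as <- best["a"] + seq(-span_deg, span_deg, by = step_deg) * pi / 180
    bs <- best["b"] + seq(-span_deg, span_deg, by = step_deg) * pi / 180
    offs <- best["off"] + seq(-span_mm, span_mm, by = step_mm)
    # search axes alternately (full 3D grid is needless at this smoothness)
    sc <- vapply(offs, function(o) score(best["a"], best["b"], o), 0)
    best["off"] <- offs[which.max(sc)]
    sc <- vapply(as, function(a) score(a, best["b"], best["off"]), 0)
    best["a"] <- as[which.max(sc)]
    sc <- vapply(bs, function(b) score(best["a"], b, best["off"]), 0)
    best["b"] <- bs[which.max(sc)]
    span_deg <- 2 * step_deg
    span_mm <- 2 * step_mm
    step_deg <- step_deg / 4
    step_mm <- step_mm / 4
  }
  n <- rotate_about(rotate_about(n0, e1, best["a"]), e2, best["b"])
  pl <- midplane(init$center + best["off"] * n0, n)
  attr(pl, "symmetry_dice") <- reflection_dice(mask, pl)
  pl
}

# first level searches in degrees already converted; helpers below

cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

pick_orthogonal <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- cross3v(n, ref)
  v / sqrt(sum(v^2))
}

# Rodrigues rotation of vector v about unit axis k by angle (radians)
rotate_about <- function(v, k, angle) {
  v * cos(angle) + cross3v(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}

# rotation matrix about unit axis by angle
rotation_about_axis <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# minimal rotation taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  v <- cross3v(a, b)
  s <- sqrt(sum(v^2))
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate pi about any orthogonal axis
    return(rotation_about_axis(pick_orthogonal(a), pi))
  }
  rotation_about_axis(v / s, atan2(s, cth))
}
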