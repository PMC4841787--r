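#' Reflect points across a plane
#'
#' Mirror image of each point across an oriented plane; an isometric
#' involution (reflecting twice returns the input).
#'
#' @param points k x 3 matrix (or length-3 vector) of mm coordinates.
#' @param plane a [midplane()].
#' @return k x 3 matrix of reflected points.
#' @export
reflect_across_plane <- function(points, plane) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  d <- plane_signed_distance(p, plane)
  p - 2 * outer(d, plane$normal)
}

#' Signed distance of points to a plane
#'
#' Positive on the side the normal points to.
#'
#' @inheritParams reflect_across_plane
#' @return numeric vector of signed distances (mm).
#' @export
plane_signed_distance <- function(points, plane) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  drop(sweep(p, 2, plane$center) %*% plane$normal)
}

#' Signed Euclidean distance field of a binary mask
#'
#' Exact Euclidean distance transform (voxel centre to voxel centre, mm),
#' computed on the mask and its complement and combined with the
#' negative-inside convention: foreground voxels carry minus the distance to
#' the nearest background centre, background voxels plus the distance to the
#' nearest foreground centre. Under trilinear interpolation the zero level
#' then falls on the voxel faces between inside and outside centres.
#'
#' @param mask a [binary_mask()].
#' @return a [volume_image()] of signed distances (mm) on the mask grid.
#' @export
signed_distance_field <- function(mask) {
  stopifnot(inherits(mask, "tv_mask"))
  d <- dim(mask$data)
  fg <- as.vector(mask$data)
  if (!any(fg)) stop("empty mask")
  vs <- mask$voxel_size
  if (all(fg)) {
    # no background anywhere: inside distance is unbounded; cap at grid scale
    sdf <- array(-max(d * vs), d)
    return(volume_image(sdf, mask$affine))
  }
  d_out <- sqrt(.cpp_edt_sq(fg, as.integer(d), vs))        # dist to foreground
  d_in <- sqrt(.cpp_edt_sq(!fg, as.integer(d), vs))        # dist to background
  sdf <- ifelse(fg, -d_in, d_out)
  volume_image(array(sdf, d), mask$affine)
}

#' Interpolate a volume at world-space points
#'
#' @param vol a [volume_image()].
#' @param points k x 3 world coordinates (mm).
#' @param method "linear" (trilinear) or "nearest". Points outside the grid
#'   are clamped to the border.
#' @return numeric vector of sampled values.
#' @export
interp_volume <- function(vol, points, method = c("linear", "nearest")) {
  method <- match.arg(method)
  ijk <- world_to_voxel(vol, points)
  .cpp_interp3(as.numeric(vol$data), as.integer(dim(vol$data)), ijk,
               method == "nearest")
}

#' Voxelize a closed mesh onto a reference grid
#'
#' A voxel is foreground iff its centre lies inside the surface, decided by
#' parity of ray crossings along the grid x axis (rays jittered off lattice
#' lines so hits on shared triangle edges cannot double count).
#'
#' @param mesh a closed, consistently oriented [triangle_mesh()].
#' @param reference a [volume_image()] or [binary_mask()] supplying the grid.
#' @return a [binary_mask()] on the reference grid.
#' @export
voxelize_mesh <- function(mesh, reference) {
  check_closed_mesh(mesh)
  d <- dim(reference$data)
  Vv <- world_to_voxel(reference, mesh$vertices)
  inside <- .cpp_voxelize_parity(Vv, mesh$faces - 1L, as.integer(d))
  arr <- array(inside, d)
  if (!any(arr)) {
    # mesh entirely outside the grid (or thinner than a voxel everywhere)
    return(structure(volume_image(array(FALSE, d), reference$affine),
                     class = c("tv_mask", "tv_volume")))
  }
  binary_mask(arr, reference$affine)
}

# error with the open edges named if the mesh is not closed
check_closed_mesh <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  open <- names(tab)[tab != 2]
  if (length(open))
    stop("mesh is not closed: ", length(open), " boundary edge(s), e.g. ",
         paste(head(open, 3), collapse = "; "))
  invisible(TRUE)
}

#' World-space centres of boundary voxels
#'
#' Boundary voxels are foreground voxels with at least one background
#' 6-neighbour (faces of the grid count as background).
#'
#' @param mask a [binary_mask()].
#' @return k x 3 matrix of world coordinates (mm).
#' @export
extract_voxel_point_cloud <- function(mask) {
  stopifnot(inherits(mask, "tv_mask"))
  b <- boundary_voxels(mask$data)
  idx <- which(b, arr.ind = TRUE) - 1L
  voxel_to_world(mask, idx)
}

boundary_voxels <- function(arr) {
  d <- dim(arr)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  core <- function(di, dj, dk)
    pad[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj, (2:(d[3] + 1)) + dk]
  all_nb <- core(1, 0, 0) & core(-1, 0, 0) & core(0, 1, 0) &
    core(0, -1, 0) & core(0, 0, 1) & core(0, 0, -1)
  arr & !all_nb
}

#' Quad boundary surface of a binary mask as a triangle mesh
#'
#' The closed surface made of exposed voxel faces, each split into two
#' triangles, with outward orientation. Used for topology checks (Euler
#' characteristic) and mask-derived surface geometry; it is exact for the
#' voxel solid, not a smooth isosurface.
#'
#' @param mask a [binary_mask()].
#' @return a [triangle_mesh()] whose `vertices` are voxel-corner points in mm.
#' @export
mask_boundary_mesh <- function(mask) {
  stopifnot(inherits(mask, "tv_mask"))
  arr <- mask$data
  d <- dim(arr)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  idx <- which(arr, arr.ind = TRUE)  # 1-based
  # face offsets: for each axis and direction, the 4 corner offsets (voxel
  # corner coordinates relative to the voxel centre, in voxel units),
  # ordered counter-clockwise seen from outside
  corner_sets <- list(
    `+1` = rbind(c(.5, -.5, -.5), c(.5, .5, -.5), c(.5, .5, .5), c(.5, -.5, .5)),
    `-1` = rbind(c(-.5, -.5, -.5), c(-.5, -.5, .5), c(-.5, .5, .5), c(-.5, .5, -.5)),
    `+2` = rbind(c(-.5, .5, -.5), c(-.5, .5, .5), c(.5, .5, .5), c(.5, .5, -.5)),
    `-2` = rbind(c(-.5, -.5, -.5), c(.5, -.5, -.5), c(.5, -.5, .5), c(-.5, -.5, .5)),
    `+3` = rbind(c(-.5, -.5, .5), c(.5, -.5, .5), c(.5, .5, .5), c(-.5, .5, .5)),
    `-3` = rbind(c(-.5, -.5, -.5), c(-.5, .5, -.5), c(.5, .5, -.5), c(.5, -.5, -.5)))
  shifts <- list(`+1` = c(1, 0, 0), `-1` = c(-1, 0, 0), `+2` = c(0, 1, 0),
                 `-2` = c(0, -1, 0), `+3` = c(0, 0, 1), `-3` = c(0, 0, -1))
  corner_blocks <- list()
  face_blocks <- list()
  offset <- 0L
  for (nm in names(shifts)) {
    s <- shifts[[nm]]
    nb <- pad[cbind(idx[, 1] + 1L + s[1], idx[, 2] + 1L + s[2],
                    idx[, 3] + 1L + s[3])]
    exposed <- idx[!nb, , drop = FALSE]
    n <- nrow(exposed)
    if (!n) next
    ctr <- exposed - 1L  # 0-based voxel centres
    cs <- corner_sets[[nm]]
    corner_blocks[[length(corner_blocks) + 1L]] <-
      rbind(sweep(ctr, 2, cs[1, ], "+"), sweep(ctr, 2, cs[2, ], "+"),
            sweep(ctr, 2, cs[3, ], "+"), sweep(ctr, 2, cs[4, ], "+"))
    i1 <- offset + seq_len(n)
    i2 <- i1 + n
    i3 <- i2 + n
    i4 <- i3 + n
    face_blocks[[length(face_blocks) + 1L]] <-
      rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
    offset <- offset + 4L * n
  }
  if (!length(corner_blocks)) stop("mask has no boundary faces")
  corner_mat <- do.call(rbind, corner_blocks)
  face_idx <- do.call(rbind, face_blocks)
  # merge duplicate corner vertices
  key <- paste(corner_mat[, 1] * 2, corner_mat[, 2] * 2, corner_mat[, 3] * 2)
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  Vijk <- corner_mat[uniq, , drop = FALSE]
  Fm <- matrix(map[face_idx], ncol = 3)
  Vw <- voxel_to_world(mask, Vijk)
  triangle_mesh(Vw, Fm)
}

#' Euler characteristic of a triangle mesh
#'
#' V - E + F; 2 for a genus-0 closed surface, 0 for genus 1.
#'
#' @param mesh a [triangle_mesh()].
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nrow(mesh$vertices) - length(unique(key)) + nrow(F)
}
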