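#' Pool masks into a left-right symmetric mean shape
#'
#' Each mask is rigidly moved so its midsagittal plane coincides with the
#' standard plane x = 0 (minimal rotation of the plane normal onto (1,0,0),
#' plane centre to the origin, then in-plane centring on the foreground
#' centroid), resampled onto a common isotropic grid (nearest neighbour),
#' pooled with its own x-flip, converted to signed distance fields, averaged,
#' and thresholded at zero. The result is symmetric about x = 0 by
#' construction (each subject enters together with its mirror image, and the
#' averaged field is explicitly symmetrized against floating-point drift).
#'
#' @param masks list of [binary_mask()].
#' @param planes list of [midplane()], one per mask.
#' @param spacing isotropic grid spacing of the mean shape (mm).
#' @param margin_mm margin around the pooled shapes (mm).
#' @return a [binary_mask()] on a grid symmetric about x = 0.
#' @export
build_symmetric_shape <- function(masks, planes, spacing = 0.7,
                                  margin_mm = 4) {
  if (length(masks) < 1) stop("need at least one mask")
  if (length(masks) != length(planes))
    stop("masks and planes differ in length (", length(masks), " vs ",
         length(planes), ")")
  xfms <- vector("list", length(masks))
  ranges <- matrix(0, 0, 3)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    pl <- planes[[i]]
    R <- rotation_between(pl$normal, c(1, 0, 0))
    idx <- which(m$data, arr.ind = TRUE) - 1L
    w <- voxel_to_world(m, idx)
    q <- sweep(w, 2, pl$center) %*% t(R)
    ctr <- c(0, mean(q[, 2]), mean(q[, 3]))
    xfms[[i]] <- rigid_transform(R, -as.numeric(R %*% pl$center) - ctr)
    ranges <- rbind(ranges, apply_transform(xfms[[i]], w))
  }
  ext <- apply(abs(ranges), 2, max) + margin_mm
  nhalf <- ceiling(ext / spacing)
  nx <- 2L * nhalf[1] + 1L
  ny <- 2L * nhalf[2] + 1L
  nz <- 2L * nhalf[3] + 1L
  origin <- -c(nhalf[1], nhalf[2], nhalf[3]) * spacing
  affine <- rbind(cbind(diag(rep(spacing, 3)), origin), c(0, 0, 0, 1))
  grid <- volume_image(array(0, c(nx, ny, nz)), affine)
  centres <- grid_world_coords(grid)
  acc <- array(0, c(nx, ny, nz))
  for (i in seq_along(masks)) {
    native <- apply_transform(invert_transform(xfms[[i]]), centres)
    vals <- interp_volume(masks[[i]], native, method = "nearest")
    res <- array(vals > 0.5, c(nx, ny, nz))
    if (!any(res)) stop("subject ", i, " resampled to an empty mask")
    sdf <- signed_distance_field(binary_mask(res, affine))$data
    acc <- acc + sdf + sdf[nx:1, , ]  # subject plus its x-flip
  }
  acc <- (acc + acc[nx:1, , ]) / 2  # exact symmetry against summation order
  mean_mask <- acc < 0
  if (!any(mean_mask)) stop("mean shape is empty")
  binary_mask(mean_mask, affine)
}

# Mirror-symmetric UV-sphere scaffold. Poles sit on the +/- y axis (in the
# plane x = 0) and the meridian count is a multiple of 4, so two whole
# meridians lie exactly in the midplane (midline vertices) and every other
# vertex has a strict mirror partner. Quad diagonals are chosen by side so
# the triangulated surface itself - not only the vertex set - is exactly
# mirror symmetric.
symmetric_sphere_mesh <- function(target_vertices, center = c(0, 0, 0),
                                  radii = c(1, 1, 1)) {
  stopifnot(target_vertices >= 20)
  n_lon <- max(8L, as.integer(4 * round(sqrt(2 * target_vertices) / 4)))
  n_rows <- max(3L, as.integer(round((target_vertices - 2) / n_lon)))
  n_lat <- n_rows + 1L  # latitude band count
  phi <- 2 * pi * (0:(n_lon - 1)) / n_lon  # around the y axis, from +x
  theta <- pi * (1:n_rows) / n_lat         # from the +y pole
  nv <- n_rows * n_lon + 2L
  V <- matrix(0, nv, 3)
  V[1, ] <- c(0, 1, 0)
  V[nv, ] <- c(0, -1, 0)
  vid <- function(row, j) 1L + (row - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  for (r in seq_len(n_rows))
    V[1L + (r - 1L) * n_lon + seq_len(n_lon), ] <-
      cbind(sin(theta[r]) * cos(phi), cos(theta[r]),
            sin(theta[r]) * sin(phi))
  # mirror pairing: meridian j pairs with (n_lon/2 - j) mod n_lon (0-based);
  # meridians n_lon/4 and 3 n_lon/4 are self-paired (x = 0)
  pairing <- integer(nv)
  pairing[1] <- 1L
  pairing[nv] <- nv
  for (r in seq_len(n_rows)) {
    j0 <- 0:(n_lon - 1)
    pj <- as.integer((n_lon / 2 - j0) %% n_lon)
    pairing[1L + (r - 1L) * n_lon + j0 + 1L] <- 1L + (r - 1L) * n_lon + pj + 1L
  }
  # snap exact mirror symmetry
  canon <- which(V[, 1] > 1e-9 & pairing != seq_len(nv))
  V[pairing[canon], ] <- cbind(-V[canon, 1], V[canon, 2], V[canon, 3])
  V[pairing == seq_len(nv), 1] <- 0
  # faces; quad strip j gets its diagonal by side so reflection maps the
  # triangulation onto itself (strip j mirrors onto strip n_lon/2 - 1 - j,
  # which is always a different strip)
  faces <- list()
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1L]] <- c(1L, vid(1, j), vid(1, j + 1))
  strip_right <- cos(phi + pi / n_lon) > 0  # strip centre on the x > 0 side
  for (r in seq_len(n_rows - 1L)) {
    for (j in seq_len(n_lon)) {
      a <- vid(r, j); b <- vid(r, j + 1)
      c2 <- vid(r + 1, j); d <- vid(r + 1, j + 1)
      if (strip_right[j]) {
        faces[[length(faces) + 1L]] <- c(a, c2, d)
        faces[[length(faces) + 1L]] <- c(a, d, b)
      } else {
        faces[[length(faces) + 1L]] <- c(b, a, c2)
        faces[[length(faces) + 1L]] <- c(b, c2, d)
      }
    }
  }
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1L]] <- c(nv, vid(n_rows, j + 1), vid(n_rows, j))
  Vs <- sweep(sweep(V, 2, radii, "*"), 2, center, "+")
  Fm <- do.call(rbind, faces)
  mesh <- triangle_mesh(Vs, Fm)
  if (mesh_volume(mesh) < 0) mesh$faces <- Fm[, c(1, 3, 2)]
  attr(mesh, "mirror_pairing") <- pairing
  mesh
}

# restore exact mirror symmetry of a mesh with a known vertex pairing,
# averaging each pair without bias; midline (self-paired) vertices are
# projected onto the plane x = 0
enforce_mirror_symmetry <- function(V, pairing) {
  canon <- which(seq_along(pairing) < pairing)  # one member per pair
  pr <- pairing[canon]
  avg <- (V[canon, , drop = FALSE] +
            cbind(-V[pr, 1], V[pr, 2], V[pr, 3])) / 2
  V[canon, ] <- avg
  V[pr, ] <- cbind(-avg[, 1], avg[, 2], avg[, 3])
  V[pairing == seq_along(pairing), 1] <- 0
  V
}

#' Build the symmetric template model
#'
#' Wraps an exactly mirror-symmetric sphere scaffold onto the symmetric mean
#' mask by progressive Laplacian deformation (the package's own fitting
#' machinery, without midplane constraints), re-imposing exact mirror
#' symmetry through the known vertex pairing after every iteration. The
#' result is a genus-0 template whose left and right halves correspond
#' vertex-by-vertex, with the midplane fixed at x = 0.
#'
#' @param mean_mask a symmetric [binary_mask()] from
#'   [build_symmetric_shape()].
#' @param target_vertices requested vertex count (attained within about 10%).
#' @param wall_angle_deg lateral-wall labelling threshold passed to
#'   [label_lateral_walls()].
#' @param symmetry_tol minimum Dice between the mask and its x-flip.
#' @return an object of class `tv_template`: `mesh`, `midplane`,
#'   `side_label` (left/right/midline), `wall_label` (logical),
#'   `mirror_pairing` (index vector).
#' @export
build_template <- function(mean_mask, target_vertices = 2500,
                           wall_angle_deg = 45, symmetry_tol = 0.99) {
  stopifnot(inherits(mean_mask, "tv_mask"))
  d <- dim(mean_mask$data)
  flip <- binary_mask(mean_mask$data[d[1]:1, , ], mean_mask$affine)
  sym_dice <- dice_coefficient(mean_mask, flip)
  if (sym_dice < symmetry_tol)
    stop("mean mask is not symmetric about x = 0 (flip Dice ",
         signif(sym_dice, 4), " < ", symmetry_tol, ")")
  idx <- which(mean_mask$data, arr.ind = TRUE) - 1L
  w <- voxel_to_world(mean_mask, idx)
  ctr <- c(0, mean(w[, 2]), mean(w[, 3]))
  radii <- pmax(apply(abs(sweep(w, 2, ctr)), 2, max) * 1.15, 2)
  scaffold <- symmetric_sphere_mesh(target_vertices, ctr, radii)
  pairing <- attr(scaffold, "mirror_pairing")
  plane <- midplane(c(0, 0, 0), c(1, 0, 0))
  sdf <- signed_distance_field(mean_mask)
  params <- deformation_params(search_range = max(radii) + 2)
  mesh <- scaffold
  for (stage in seq_along(params$stage_n_rings)) {
    W <- neighborhood_matrix(mesh, params$stage_n_rings[stage])
    for (it in seq_len(params$stage_iterations[stage])) {
      vold <- mesh$vertices
      st <- compute_boundary_targets(mesh, sdf, params)
      ref <- laplacian_coordinates(mesh, W)
      mesh <- deform_step(mesh, st, ref, W)
      mesh$vertices <- enforce_mirror_symmetry(mesh$vertices, pairing)
      if (mean(sqrt(rowSums((mesh$vertices - vold)^2))) <
          params$convergence_tol) break
    }
  }
  tpl <- structure(list(mesh = mesh, midplane = plane,
                        side_label = ifelse(pairing == seq_along(pairing),
                                            "midline",
                                            ifelse(mesh$vertices[, 1] > 0,
                                                   "right", "left")),
                        wall_label = rep(FALSE, nrow(mesh$vertices)),
                        mirror_pairing = pairing),
                   class = "tv_template")
  label_lateral_walls(tpl, wall_angle_deg)
}

#' Label the lateral-wall vertices of a template
#'
#' A vertex belongs to a lateral wall when its outward normal is within
#' `angle_threshold` of the midplane normal (either side); labels are
#' symmetrized through the mirror pairing.
#'
#' @param template a `tv_template`.
#' @param angle_threshold degrees; 90 labels every vertex.
#' @return the template with `wall_label` replaced.
#' @export
label_lateral_walls <- function(template, angle_threshold = 45) {
  n <- vertex_normals(template$mesh)
  a <- abs(drop(n %*% template$midplane$normal))
  wall <- a >= cos(angle_threshold * pi / 180) - 1e-12
  wall <- wall | wall[template$mirror_pairing]
  template$wall_label <- wall
  template
}

#' @export
print.tv_template <- function(x, ...) {
  cat(sprintf(paste0("<tv_template> %d vertices (%d left / %d right / %d",
                     " midline), %d wall-labelled\n"),
              nrow(x$mesh$vertices), sum(x$side_label == "left"),
              sum(x$side_label == "right"), sum(x$side_label == "midline"),
              sum(x$wall_label)))
  invisible(x)
}

#' Residual of the template's mirror symmetry
#'
#' Maximum distance (mm) between each vertex reflected across the midplane
#' and its paired partner; 0 for an exactly symmetric template.
#'
#' @param template a `tv_template`.
#' @return numeric scalar (mm).
#' @export
template_symmetry_residual <- function(template) {
  V <- template$mesh$vertices
  refl <- reflect_across_plane(V, template$midplane)
  max(sqrt(rowSums((refl - V[template$mirror_pairing, , drop = FALSE])^2)))
}

#' Serialize a template to a directory (PLY + JSON sidecar)
#' @param template a `tv_template`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_template <- function(template, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(template$mesh, file.path(dir, "template.ply"))
  meta <- list(midplane = list(center = template$midplane$center,
                               normal = template$midplane$normal),
               side_label = template$side_label,
               wall_label = template$wall_label,
               mirror_pairing = template$mirror_pairing)
  jsonlite::write_json(meta, file.path(dir, "template.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a template written by [write_template()]
#' @param dir template directory.
#' @return a `tv_template`.
#' @export
read_template <- function(dir) {
  mesh <- read_ply(file.path(dir, "template.ply"))
  meta <- jsonlite::read_json(file.path(dir, "template.json"),
                              simplifyVector = TRUE)
  structure(list(mesh = mesh,
                 midplane = midplane(meta$midplane$center,
                                     meta$midplane$normal),
                 side_label = meta$side_label,
                 wall_label = meta$wall_label,
                 mirror_pairing = as.integer(meta$mirror_pairing)),
            class = "tv_template")
}
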