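#' Normalise a fitted mesh to the template frame
#'
#' Brings an individual fitted mesh into the template's coordinate frame for
#' shape comparison: optional rigid mapping of the subject midplane onto the
#' template midplane, isotropic rescaling by a head-size factor about the
#' midplane-projected centroid, then a 3-degree-of-freedom Procrustes
#' alignment (rotation about the midplane normal, in-plane translation)
#' minimising the summed squared distances to the template vertices. The
#' restriction keeps the midplane correspondence intact, so left/right
#' comparisons remain meaningful.
#'
#' @param fitted a [triangle_mesh()] in vertex correspondence with
#'   `template` (e.g. from [fit_template()]).
#' @param template the `tv_template`.
#' @param scale_factor isotropic scale divisor; use
#'   `(icv_subject / icv_reference)^(1/3)` for head-size correction, or 1.
#' @param msp the subject [midplane()] if `fitted` is still in native space;
#'   `NULL` when `fitted` already lives in the template frame.
#' @return the normalised [triangle_mesh()].
#' @export
normalize_to_template <- function(fitted, template, scale_factor = 1,
                                  msp = NULL) {
  if (scale_factor <= 0) stop("scale_factor must be positive")
  stopifnot(nrow(fitted$vertices) == nrow(template$mesh$vertices))
  V <- fitted$vertices
  if (!is.null(msp)) {
    R <- rotation_between(msp$normal, template$midplane$normal)
    V <- sweep(sweep(V, 2, msp$center) %*% t(R), 2,
               template$midplane$center, "+")
  }
  # isotropic rescale about the midplane-projected centroid
  ctr <- colMeans(V)
  ctr <- ctr - sum((ctr - template$midplane$center) *
                     template$midplane$normal) * template$midplane$normal
  V <- sweep(sweep(V, 2, ctr) / scale_factor, 2, ctr, "+")
  # closed-form 1-DOF rotation + 2-DOF in-plane translation Procrustes
  nrm <- template$midplane$normal
  c0 <- template$midplane$center
  e1 <- pick_orthogonal(nrm)
  e2 <- cross3v(nrm, e1)
  Tv <- template$mesh$vertices
  pxi <- sweep(V, 2, c0) %*% cbind(e1, e2)
  qxi <- sweep(Tv, 2, c0) %*% cbind(e1, e2)
  pm <- colMeans(pxi)
  qm <- colMeans(qxi)
  px <- sweep(pxi, 2, pm)
  qx <- sweep(qxi, 2, qm)
  th <- atan2(sum(px[, 1] * qx[, 2] - px[, 2] * qx[, 1]),
              sum(px[, 1] * qx[, 1] + px[, 2] * qx[, 2]))
  R <- rotation_about_axis(nrm, th)
  Vr <- sweep(sweep(V, 2, c0) %*% t(R), 2, c0, "+")
  off <- qm - colMeans(sweep(Vr, 2, c0) %*% cbind(e1, e2))
  Vr <- sweep(Vr, 2, off[1] * e1 + off[2] * e2, "+")
  out <- fitted
  out$vertices <- Vr
  attr(out, "procrustes_rotation_deg") <- th * 180 / pi
  out
}

#' Vertex-wise signed deformity against the template
#'
#' Displacement of each corresponding vertex projected onto the template's
#' outward vertex normal: positive values are local enlargement (outward),
#' negative values local contraction.
#'
#' @param normalized a mesh from [normalize_to_template()].
#' @param template the `tv_template`.
#' @return numeric vector of signed deformities (mm).
#' @export
vertex_deformity <- function(normalized, template) {
  stopifnot(nrow(normalized$vertices) == nrow(template$mesh$vertices))
  n <- vertex_normals(template$mesh)
  rowSums((normalized$vertices - template$mesh$vertices) * n)
}

#' Width map of a mesh over its midplane
#'
#' Samples the midplane on a regular 0.5 mm grid (in the plane's two
#' in-plane axes) and casts a line through each sample point along the
#' plane normal. The left (negative side) and right (positive side)
#' half-widths are the distances to the farthest surface crossing on each
#' side, bounding the lumen; points whose line misses a side are flagged
#' invalid. The first in-plane axis follows the world y direction
#' (anteroposterior), the second completes the right-handed frame.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param msp the [midplane()].
#' @param spacing grid spacing in the plane (mm).
#' @return an object of class `tv_widthmap`: data.frame with in-plane
#'   coordinates `a` (anteroposterior), `b`, world `x/y/z`, `lw`, `rw`,
#'   `valid`; attributes `plane`, `axes`, `spacing`.
#' @export
compute_width_map <- function(mesh, msp, spacing = 0.5) {
  nrm <- msp$normal
  e1 <- pick_orthogonal(nrm)
  e2 <- cross3v(nrm, e1)
  # favour the world-y direction as the anteroposterior in-plane axis
  ydir <- c(0, 1, 0) - sum(c(0, 1, 0) * nrm) * nrm
  if (sqrt(sum(ydir^2)) > 1e-6) {
    e1 <- ydir / sqrt(sum(ydir^2))
    e2 <- cross3v(nrm, e1)
  }
  Vc <- sweep(mesh$vertices, 2, msp$center)
  a_rng <- range(Vc %*% e1)
  b_rng <- range(Vc %*% e2)
  a <- seq(floor(a_rng[1] / spacing) * spacing,
           ceiling(a_rng[2] / spacing) * spacing, by = spacing)
  b <- seq(floor(b_rng[1] / spacing) * spacing,
           ceiling(b_rng[2] / spacing) * spacing, by = spacing)
  gr <- expand.grid(a = a, b = b)
  origins <- sweep(outer(gr$a, e1) + outer(gr$b, e2), 2, msp$center, "+")
  hits <- .cpp_line_mesh_hits(origins, nrm, mesh$vertices, mesh$faces - 1L)
  lw <- rw <- rep(NA_real_, nrow(gr))
  valid <- logical(nrow(gr))
  for (i in seq_along(hits)) {
    t <- hits[[i]]
    if (!length(t)) next
    t <- t[c(TRUE, diff(t) > 1e-9)]  # dedupe shared-edge double hits
    neg <- t[t < 0]
    pos <- t[t > 0]
    if (length(neg) && length(pos)) {
      lw[i] <- -min(neg)  # farthest crossing on the negative (left) side
      rw[i] <- max(pos)
      valid[i] <- TRUE
    }
  }
  out <- cbind(gr, as.data.frame(origins))
  names(out) <- c("a", "b", "x", "y", "z")
  out$lw <- lw
  out$rw <- rw
  out$valid <- valid
  structure(out, class = c("tv_widthmap", "data.frame"), plane = msp,
            axes = list(e1 = e1, e2 = e2), spacing = spacing)
}

#' Third-ventricle width and asymmetry at each midplane sample point
#'
#' Width is the sum of the two half-widths; asymmetry is the absolute
#' half-width difference normalised by the maximum width over the map, so
#' it always lies in \[0, 1\].
#'
#' @param width_map a `tv_widthmap` from [compute_width_map()].
#' @return list with per-point `tvw` and `tva` (NA at invalid points) and
#'   `max_tvw`.
#' @export
tvw_tva <- function(width_map) {
  if (!any(width_map$valid)) stop("width map has no valid sample points")
  tvw <- width_map$lw + width_map$rw
  mx <- max(tvw, na.rm = TRUE)
  tva <- abs(width_map$lw - width_map$rw) / mx
  list(tvw = tvw, tva = tva, max_tvw = mx)
}

#' Regional maximum widths along the anteroposterior axis
#'
#' Splits the valid in-plane samples at a fraction of the anteroposterior
#' extent; the anterior (larger `a`) and posterior maxima of the width, and
#' the average width over all valid points, are the scalar width measures.
#'
#' @param width_map a `tv_widthmap`.
#' @param region_split split fraction along the anteroposterior axis,
#'   in (0, 1).
#' @return list with `anterior_tvw`, `posterior_tvw`, `average_tvw`
#'   (NA with a warning for an empty sub-region).
#' @export
regional_widths <- function(width_map, region_split = 0.5) {
  stopifnot(region_split > 0, region_split < 1)
  wt <- tvw_tva(width_map)
  ok <- width_map$valid
  a <- width_map$a[ok]
  tvw <- wt$tvw[ok]
  cut <- min(a) + region_split * (max(a) - min(a))
  ant <- tvw[a >= cut]
  post <- tvw[a < cut]
  res <- list(
    anterior_tvw = if (length(ant)) max(ant) else NA_real_,
    posterior_tvw = if (length(post)) max(post) else NA_real_,
    average_tvw = mean(tvw))
  if (!length(ant) || !length(post))
    warning("empty anterior or posterior sub-region")
  res
}

#' All model-based shape measures for one subject
#'
#' Convenience wrapper: normalises the fitted mesh, computes the vertex-wise
#' deformity, the width map over the template midplane, the width/asymmetry
#' maps and the regional width summaries, plus the ventricular volume from
#' the binary mask (voxel count times voxel volume).
#'
#' @param fitted a fitted [triangle_mesh()] in native space.
#' @param template the `tv_template`.
#' @param mask the subject [binary_mask()].
#' @param msp the subject [midplane()].
#' @param scale_factor head-size scale divisor (see
#'   [normalize_to_template()]).
#' @param region_split see [regional_widths()].
#' @return an object of class `tv_measures`: list with `deformity`,
#'   `width_map`, `tvw`, `tva`, `max_tva`, `mean_tva`, `anterior_tvw`,
#'   `posterior_tvw`, `average_tvw`, `volume_mm3`, `normalized` (mesh).
#' @export
shape_measures <- function(fitted, template, mask, msp, scale_factor = 1,
                           region_split = 0.5) {
  normalized <- normalize_to_template(fitted, template, scale_factor, msp)
  deform <- vertex_deformity(normalized, template)
  wm <- compute_width_map(normalized, template$midplane)
  wt <- tvw_tva(wm)
  reg <- regional_widths(wm, region_split)
  structure(list(deformity = deform, width_map = wm, tvw = wt$tvw,
                 tva = wt$tva, max_tva = max(wt$tva, na.rm = TRUE),
                 mean_tva = mean(wt$tva, na.rm = TRUE),
                 anterior_tvw = reg$anterior_tvw,
                 posterior_tvw = reg$posterior_tvw,
                 average_tvw = reg$average_tvw,
                 volume_mm3 = sum(mask$data) * prod(mask$voxel_size),
                 normalized = normalized),
            class = "tv_measures")
}
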