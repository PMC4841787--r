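test_that("normalisation recovers rotation and scale exactly", {
  tpl <- fx_template()
  # identity: the template itself maps to itself
  out <- normalize_to_template(tpl$mesh, tpl, 1)
  expect_lt(max(abs(out$vertices - tpl$mesh$vertices)), 1e-9)

  # pure in-plane rotation: closed-form recovery to 0.01 degree
  rot <- tpl$mesh
  rot$vertices <- rot$vertices %*% t(rotation_about_x(7))
  out2 <- normalize_to_template(rot, tpl, 1)
  expect_equal(abs(attr(out2, "procrustes_rotation_deg")), 7,
               tolerance = 0.01 / 7)
  expect_lt(max(abs(out2$vertices - tpl$mesh$vertices)), 1e-6)

  # isotropic scale is inverted exactly
  sc <- tpl$mesh
  ctr <- colMeans(sc$vertices)
  ctr[1] <- 0
  sc$vertices <- sweep(sweep(sc$vertices, 2, ctr) * 1.1, 2, ctr, "+")
  out3 <- normalize_to_template(sc, tpl, 1.1)
  expect_lt(max(abs(out3$vertices - tpl$mesh$vertices)), 1e-6)

  expect_error(normalize_to_template(tpl$mesh, tpl, -1), "positive")
})

test_that("vertex deformity is the normal-projected displacement", {
  tpl <- fx_template()
  expect_equal(vertex_deformity(tpl$mesh, tpl),
               rep(0, nrow(tpl$mesh$vertices)))
  # inflate 1 mm along the template normals
  n <- vertex_normals(tpl$mesh)
  infl <- tpl$mesh
  infl$vertices <- infl$vertices + n
  expect_equal(vertex_deformity(infl, tpl),
               rep(1, nrow(n)), tolerance = 1e-9)
  # tangential displacement projects to zero
  tang <- tpl$mesh
  t1 <- cbind(-n[, 2], n[, 1], 0)
  t1 <- t1 / pmax(sqrt(rowSums(t1^2)), 1e-6)
  tang$vertices <- tang$vertices + 0.5 * t1
  expect_lt(max(abs(vertex_deformity(tang, tpl))), 1e-9)
})

test_that("width maps reproduce analytic box and sphere widths", {
  # box of half-widths 2 mm each side of the plane
  bx <- box_mesh(-2, 2, -8, 8, -6, 6)
  wm <- compute_width_map(bx, midplane())
  interior <- wm$valid & abs(wm$a) < 7 & abs(wm$b) < 5
  expect_true(any(interior))
  expect_equal(wm$lw[interior], rep(2, sum(interior)))
  expect_equal(wm$rw[interior], rep(2, sum(interior)))
  expect_equal(attr(wm, "spacing"), 0.5)
  # grid points outside the silhouette are invalid
  expect_true(all(!wm$valid[abs(wm$a) > 8.6 | abs(wm$b) > 6.6]))

  # sphere of radius 8: chord half-width sqrt(r^2 - rho^2)
  sp <- fx_sphere()
  sp8 <- sp
  sp8$vertices <- sp$vertices * 8
  wm2 <- compute_width_map(sp8, midplane())
  ok <- wm2$valid
  rho <- sqrt(wm2$a[ok]^2 + wm2$b[ok]^2)
  pred <- sqrt(pmax(0, 64 - rho^2))
  expect_lt(max(abs(wm2$lw[ok] - pred)[rho < 7]), 0.1)
  expect_lt(max(abs(wm2$rw[ok] - pred)[rho < 7]), 0.1)
})

test_that("width map of the symmetric template is symmetric", {
  tpl <- fx_template()
  wm <- compute_width_map(tpl$mesh, tpl$midplane)
  expect_lte(max(abs(wm$lw - wm$rw), na.rm = TRUE), 0.05)
})

test_that("TVW and TVA implement their defining formulas", {
  wm <- structure(data.frame(a = c(0, 1, 2), b = 0, x = 0, y = 0, z = 0,
                             lw = c(2, 5, 5), rw = c(3, 5, 0),
                             valid = c(TRUE, TRUE, TRUE)),
                  class = c("tv_widthmap", "data.frame"))
  wt <- tvw_tva(wm)
  expect_equal(wt$max_tvw, 10)
  expect_equal(wt$tvw, c(5, 10, 5))
  expect_equal(wt$tva, c(0.1, 0, 0.5))  # |LW-RW| / max TVW
  # bound attained when one side vanishes at the maximum-width point
  wm2 <- wm
  wm2$lw <- c(5, 2, 1)
  wm2$rw <- c(0, 2, 1)
  expect_equal(tvw_tva(wm2)$tva[1], 1)
  # TVA lies in [0, 1] for arbitrary non-negative half-widths
  set.seed(41)
  wm3 <- wm
  for (k in 1:20) {
    wm3$lw <- runif(3, 0, 10)
    wm3$rw <- runif(3, 0, 10)
    tva <- tvw_tva(wm3)$tva
    expect_true(all(tva >= 0 & tva <= 1))
  }
  wm$valid[] <- FALSE
  expect_error(tvw_tva(wm), "valid")
})

test_that("regional widths split along the anteroposterior axis", {
  # uniform slab: every region sees the same width
  bx <- box_mesh(-2, 2, -8, 8, -6, 6)
  wm <- compute_width_map(bx, midplane())
  reg <- regional_widths(wm)
  expect_equal(reg$anterior_tvw, 4)
  expect_equal(reg$posterior_tvw, 4)
  expect_equal(reg$average_tvw, 4)

  # wedge widening anteriorly from 1 to 5 mm total width: prism mesh
  # with width w(y) = 3 + y/5 for y in [-10, 10]
  yv <- c(-10, 10)
  wv <- (3 + yv / 5) / 2
  V <- rbind(c(-wv[1], yv[1], -6), c(wv[1], yv[1], -6),
             c(-wv[1], yv[1], 6), c(wv[1], yv[1], 6),
             c(-wv[2], yv[2], -6), c(wv[2], yv[2], -6),
             c(-wv[2], yv[2], 6), c(wv[2], yv[2], 6))
  Fm <- rbind(c(1, 2, 4), c(1, 4, 3), c(5, 8, 6), c(5, 7, 8),
              c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),
              c(1, 3, 7), c(1, 7, 5), c(2, 6, 8), c(2, 8, 4))
  wedge <- triangle_mesh(V, Fm)
  if (mesh_volume(wedge) < 0) wedge$faces <- wedge$faces[, c(1, 3, 2)]
  wmw <- compute_width_map(wedge, midplane())
  regw <- regional_widths(wmw)
  expect_equal(regw$anterior_tvw, 5, tolerance = 0.05)
  expect_lte(regw$posterior_tvw, 4.05)

  # a single valid point determines all three summaries
  wm1 <- structure(data.frame(a = 0.4, b = 0, x = 0, y = 0, z = 0,
                              lw = 1.5, rw = 2, valid = TRUE),
                   class = c("tv_widthmap", "data.frame"))
  expect_warning(r1 <- regional_widths(wm1), "empty")
  expect_equal(r1$average_tvw, 3.5)
  expect_equal(max(r1$anterior_tvw, r1$posterior_tvw, na.rm = TRUE), 3.5)
})

test_that("deformity is mirror-consistent for symmetric individuals", {
  tpl <- fx_template()
  # an exactly symmetric synthetic individual: symmetric normal inflation
  n <- vertex_normals(tpl$mesh)
  bump <- 0.8 * exp(-rowSums(tpl$mesh$vertices[, 2:3]^2) / 40)
  indiv <- tpl$mesh
  indiv$vertices <- indiv$vertices + bump * n
  indiv$vertices <- ventricle3d:::enforce_mirror_symmetry(
    indiv$vertices, tpl$mirror_pairing)
  d <- vertex_deformity(normalize_to_template(indiv, tpl, 1), tpl)
  expect_lt(max(abs(d - d[tpl$mirror_pairing])), 1e-6)
})

test_that("full-pipeline width recovery is within one voxel", {
  tpl <- fx_template()
  ph <- make_phantom(phantom_spec(half_width_left = 2.6,
                                  half_width_right = 2.6, seed = 61))
  fit <- suppressWarnings(fit_template(tpl, ph$mask, ph$plane))
  ms <- shape_measures(fit, tpl, ph$mask, ph$plane)
  true_max <- max(ph$truth$lw + ph$truth$rw, na.rm = TRUE)
  measured_max <- max(ms$tvw, na.rm = TRUE)
  expect_lt(abs(measured_max - true_max), 1.0)
  # symmetric phantom: asymmetry index stays near zero
  expect_lt(ms$max_tva, 0.05)
  expect_true(all(ms$tva >= 0 & ms$tva <= 1, na.rm = TRUE))
})
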