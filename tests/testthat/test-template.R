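test_that("symmetric mean shape is symmetric and idempotent-ish", {
  phs <- fx_small_cohort()
  masks <- lapply(phs, `[[`, "mask")
  planes <- lapply(phs, `[[`, "plane")

  mm <- build_symmetric_shape(masks, planes)
  d <- dim(mm$data)
  flip <- binary_mask(mm$data[d[1]:1, , ], mm$affine)
  expect_gte(dice_coefficient(mm, flip), 0.995)

  # a single already-symmetric mask is close to a fixed point
  sym <- make_phantom(phantom_spec(seed = 55))  # no roughness, equal sides
  mm1 <- build_symmetric_shape(list(sym$mask), list(sym$plane))
  # compare volumes and resampled overlap on the output grid
  ctr <- ventricle3d:::grid_world_coords(mm1)
  orig <- array(interp_volume(ventricle3d:::mask_as_volume(sym$mask), ctr,
                              method = "nearest") > 0.5, dim(mm1$data))
  expect_gte(dice_coefficient(binary_mask(orig, mm1$affine), mm1), 0.97)

  # flip-invariance: pre-mirrored masks give the same mean shape up to
  # nearest-neighbour rounding ties at resampling boundaries
  dm <- lapply(masks, function(m) {
    dd <- dim(m$data)
    binary_mask(m$data[dd[1]:1, , ], m$affine)
  })
  mm2 <- build_symmetric_shape(dm, planes)
  expect_gte(dice_coefficient(mm2, mm), 0.995)

  expect_error(build_symmetric_shape(masks, planes[1:2]), "length")
})

test_that("mean of two off-centre spheres is centred on the plane", {
  # one subject whose shape is a sphere at +a, its flip pools a sphere at -a
  a <- 3
  grid <- volume_image(array(0, c(31, 25, 25)),
                       rbind(cbind(diag(c(1, 1, 1)), c(-15, -12, -12)),
                             c(0, 0, 0, 1)))
  ctr <- ventricle3d:::grid_world_coords(grid)
  sph <- function(c0) array(sqrt(rowSums(sweep(ctr, 2, c0)^2)) < 6,
                            dim(grid$data))
  mk <- binary_mask(sph(c(a, 0, 0)), grid$affine)
  mm <- build_symmetric_shape(list(mk), list(midplane()))
  idx <- which(mm$data, arr.ind = TRUE) - 1L
  w <- ventricle3d:::voxel_to_world(mm, idx)
  expect_lt(abs(mean(w[, 1])), 0.05)
  expect_lt(abs(mean(w[, 2])), 0.2)
})

test_that("template construction yields an exactly symmetric genus-0 mesh", {
  tpl <- fx_template()
  expect_lte(template_symmetry_residual(tpl), 1e-6)
  expect_equal(euler_characteristic(tpl$mesh), 2)
  expect_equal(nrow(tpl$mesh$vertices), 1500, tolerance = 0.1)
  # pairing is an involution consistent with the side labels
  p <- tpl$mirror_pairing
  expect_identical(p[p], seq_along(p))
  expect_true(all(tpl$side_label[p][tpl$side_label == "left"] == "right"))
  expect_true(all(abs(tpl$mesh$vertices[tpl$side_label == "midline", 1])
                  < 1e-12))
  # wall labels symmetric under the pairing
  expect_identical(tpl$wall_label, tpl$wall_label[p])
  # asymmetric mean masks are rejected
  ph <- fx_small_cohort()[[1]]
  shifted <- binary_mask(ph$mask$data, ph$mask$affine +
                           matrix(c(rep(0, 3), 4, rep(0, 12)), 4, 4))
  expect_error(build_template(shifted), "not symmetric")
})

test_that("template recovers a sphere with sub-voxel radius error", {
  grid <- volume_image(array(0, c(31, 31, 31)),
                       rbind(cbind(diag(c(1, 1, 1)), c(-15, -15, -15)),
                             c(0, 0, 0, 1)))
  ctr <- ventricle3d:::grid_world_coords(grid)
  mk <- binary_mask(array(sqrt(rowSums(ctr^2)) < 9.2, dim(grid$data)),
                    grid$affine)
  tpl <- build_template(mk, target_vertices = 2000)
  expect_equal(nrow(tpl$mesh$vertices), 2000, tolerance = 0.1)
  r <- sqrt(rowSums(sweep(tpl$mesh$vertices, 2,
                          colMeans(tpl$mesh$vertices))^2))
  expect_lt(abs(mean(r) - 9.2), 1)
  expect_lte(template_symmetry_residual(tpl), 1e-6)
})

test_that("lateral-wall labelling follows the normal-alignment criterion", {
  sp <- fx_sphere()
  tpl <- structure(list(
    mesh = sp, midplane = midplane(),
    side_label = ifelse(sp$vertices[, 1] > 1e-9, "right",
                        ifelse(sp$vertices[, 1] < -1e-9, "left", "midline")),
    wall_label = rep(FALSE, nrow(sp$vertices)),
    mirror_pairing = attr(sp, "mirror_pairing")), class = "tv_template")
  lab <- label_lateral_walls(tpl, 45)
  # area fraction of the two 45-degree caps of a sphere: 2 * (1 - cos45)/2
  V <- sp$vertices
  Fm <- sp$faces
  e1 <- V[Fm[, 2], ] - V[Fm[, 1], ]
  e2 <- V[Fm[, 3], ] - V[Fm[, 1], ]
  fa <- 0.5 * sqrt(rowSums(cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2))
  va <- numeric(nrow(V))
  for (cc in 1:3) {
    agg <- rowsum(fa / 3, Fm[, cc])
    va[as.integer(rownames(agg))] <- va[as.integer(rownames(agg))] + agg
  }
  frac <- sum(va[lab$wall_label]) / sum(va)
  expect_equal(frac, 1 - cos(45 * pi / 180), tolerance = 0.02)
  # threshold 90 labels everything
  expect_true(all(label_lateral_walls(tpl, 90)$wall_label))
  # thin slab: both large faces labelled, the rim not
  slab <- box_mesh(-1, 1, -10, 10, -8, 8)
  tps <- structure(list(
    mesh = slab, midplane = midplane(),
    side_label = ifelse(slab$vertices[, 1] > 0, "right", "left"),
    wall_label = rep(FALSE, 8), mirror_pairing = c(5:8, 1:4)),
    class = "tv_template")
  lab2 <- label_lateral_walls(tps, 45)
  n <- vertex_normals(slab)
  expect_true(all(lab2$wall_label[abs(n[, 1]) > 0.8]))
})
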