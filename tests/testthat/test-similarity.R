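test_that("Dice coefficient matches its formula and is symmetric", {
  aff <- diag(4)
  a <- array(FALSE, c(10, 2, 1))
  a[1:5, 1, 1] <- TRUE
  a[1:5, 2, 1] <- TRUE          # |A| = 10
  b <- array(FALSE, c(10, 2, 1))
  b[3:7, 1, 1] <- TRUE
  b[3:7, 2, 1] <- TRUE          # |B| = 10, overlap 6
  ma <- binary_mask(a, aff)
  mb <- binary_mask(b, aff)
  expect_equal(dice_coefficient(ma, mb), 2 * 6 / 20)
  expect_equal(dice_coefficient(ma, mb), dice_coefficient(mb, ma))
  expect_equal(dice_coefficient(ma, ma), 1)
  # disjoint masks
  c0 <- array(FALSE, c(10, 2, 1))
  c0[8:10, , 1] <- TRUE
  expect_equal(dice_coefficient(ma, binary_mask(c0, aff)), 0)
  expect_error(dice_coefficient(ma, binary_mask(c0, diag(4) * 2)), "grid")
})

test_that("surface distances agree with O(n^2) brute force", {
  expect_equal(surface_distances(matrix(c(0, 0, 0), 1),
                                 matrix(c(3, 0, 0), 1)),
               list(mean_distance = 3, hausdorff = 3))
  p <- matrix(c(0, 0, 0), 1)
  expect_equal(surface_distances(p, p),
               list(mean_distance = 0, hausdorff = 0))
  set.seed(51)
  A <- matrix(rnorm(300), ncol = 3)
  B <- matrix(rnorm(300), ncol = 3)
  got <- surface_distances(A, B)
  dm <- as.matrix(dist(rbind(A, B)))[1:100, 101:200]
  md <- (mean(apply(dm, 1, min)) + mean(apply(dm, 2, min))) / 2
  hd <- max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
  expect_equal(got$mean_distance, md, tolerance = 1e-12)
  expect_equal(got$hausdorff, hd, tolerance = 1e-12)
  # Hd >= Md >= 0 on random pairs
  expect_gte(got$hausdorff, got$mean_distance)
  expect_gte(got$mean_distance, 0)
})

test_that("point-to-mesh distance is point-to-triangle, not point-to-vertex", {
  bx <- box_mesh(-1, 1, -1, 1, -1, 1)
  # a point facing the centre of the +x face: distance 1 to the surface,
  # but > 1.9 to the nearest vertex
  p <- matrix(c(2, 0, 0), 1)
  got <- surface_distances(p, bx)
  # the p -> mesh direction must be the face distance
  expect_equal(min(ventricle3d:::.cpp_point_mesh_dist(
    p, bx$vertices, bx$faces - 1L)), 1)
  expect_gt(min(sqrt(rowSums(sweep(bx$vertices, 2, p)^2))), 1.7)
})

test_that("volume metrics follow their conventions and the VOE identity", {
  aff <- diag(4)
  mk <- function(n, from = 1) {
    a <- array(FALSE, c(20, 3, 3))
    a[from:(from + n - 1), 2, 2] <- TRUE
    binary_mask(a, aff)
  }
  a <- mk(9)          # |A| = 9
  b <- mk(10)         # |B| = 10, overlap 9
  vm <- volume_metrics(a, b)
  expect_equal(vm$rvd_percent, -10)
  expect_equal(vm$voe_percent, 10)
  expect_equal(vm$volume_difference_mm3, -1)
  expect_equal(volume_metrics(a, a),
               list(rvd_percent = 0, voe_percent = 0,
                    volume_difference_mm3 = 0))
  # VOE = (1 - Dc / (2 - Dc)) * 100 on arbitrary pairs
  set.seed(52)
  for (k in 1:10) {
    x <- binary_mask(array(runif(60) < 0.5, c(20, 3, 1)) |
                       array(c(TRUE, rep(FALSE, 59)), c(20, 3, 1)), aff)
    y <- binary_mask(array(runif(60) < 0.5, c(20, 3, 1)) |
                       array(c(TRUE, rep(FALSE, 59)), c(20, 3, 1)), aff)
    dc <- dice_coefficient(x, y)
    expect_equal(volume_metrics(x, y)$voe_percent,
                 (1 - dc / (2 - dc)) * 100, tolerance = 1e-12)
  }
})

test_that("Bland-Altman bias and limits of agreement", {
  x <- c(1, 2, 3, 4)
  expect_equal(bland_altman(x, x)$bias, 0)
  expect_equal(unname(bland_altman(x, x)$loa), c(0, 0))
  ba <- bland_altman(x, x - 2)
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd, 0)
  # Monte Carlo: differences N(1, 0.5^2)
  set.seed(53)
  y0 <- rnorm(1e4, 50, 5)
  ba2 <- bland_altman(y0 + rnorm(1e4, 1, 0.5), y0)
  expect_equal(ba2$bias, 1, tolerance = 0.02)
  expect_equal(unname(ba2$loa["upper"] - ba2$loa["lower"]),
               2 * 1.96 * 0.5, tolerance = 0.05)
  expect_error(bland_altman(1:3, 1:4), "length")
  expect_error(bland_altman(1:2, 1:2), "3")
})

test_that("mesh and its own voxelization agree above the discretisation floor", {
  tpl <- fx_template()
  ph <- fx_small_cohort()[[1]]
  mk <- voxelize_mesh(tpl$mesh, ph$mask)  # 1.0 x 1.0 x 1.3 mm grid
  r <- compare_fit(tpl$mesh, mk)
  expect_gte(r$dice, 0.95)
  expect_lte(r$mean_distance, 0.3)
})
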