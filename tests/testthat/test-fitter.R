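test_that("extended Laplacian equals the BFS-neighbourhood centroid rule", {
  tpl <- fx_template()
  mesh <- tpl$mesh
  # brute-force BFS oracle
  brute <- function(mesh, n_ring) {
    nv <- nrow(mesh$vertices)
    Fm <- mesh$faces
    adj <- vector("list", nv)
    for (r in seq_len(nrow(Fm))) {
      tr <- Fm[r, ]
      adj[[tr[1]]] <- c(adj[[tr[1]]], tr[2:3])
      adj[[tr[2]]] <- c(adj[[tr[2]]], tr[c(1, 3)])
      adj[[tr[3]]] <- c(adj[[tr[3]]], tr[1:2])
    }
    adj <- lapply(adj, unique)
    out <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      seen <- i
      frontier <- i
      for (k in seq_len(n_ring)) {
        frontier <- setdiff(unique(unlist(adj[frontier])), seen)
        seen <- c(seen, frontier)
      }
      nb <- setdiff(seen, i)
      out[i, ] <- mesh$vertices[i, ] - colMeans(mesh$vertices[nb, ,
                                                              drop = FALSE])
    }
    out
  }
  L2 <- extended_laplacian(mesh, 2)
  expect_equal(L2, brute(mesh, 2), tolerance = 1e-12)
  # n_ring = 1 is the standard umbrella operator
  expect_equal(extended_laplacian(mesh, 1), brute(mesh, 1),
               tolerance = 1e-12)
  # a vertex at the centroid of its neighbourhood has zero Laplacian
  W <- neighborhood_matrix(mesh, 1)
  m2 <- mesh
  m2$vertices[10, ] <- as.matrix(W %*% m2$vertices)[10, ]
  expect_lt(max(abs(extended_laplacian(m2, 1)[10, ])), 1e-12)
})

test_that("deform_step solves the stacked least-squares system exactly", {
  sp <- ventricle3d:::symmetric_sphere_mesh(50)
  nv <- nrow(sp$vertices)
  W <- neighborhood_matrix(sp, 1)
  set.seed(31)
  state <- list(targets = sp$vertices + matrix(rnorm(nv * 3, sd = 0.3),
                                               nv, 3),
                alpha = runif(nv, 0.2, 1))
  ref <- ventricle3d:::laplacian_coordinates(sp, W)
  out <- deform_step(sp, state, ref, W)
  # dense least-squares oracle: rows alpha*(M v - Lref) and (v - b)
  M <- diag(nv) - as.matrix(W)
  A <- rbind(state$alpha * M, diag(nv))
  for (d in 1:3) {
    b <- c(state$alpha * ref[, d], state$targets[, d])
    expect_equal(out$vertices[, d], qr.solve(A, b), tolerance = 1e-8)
  }

  # zero force: identity is the optimum
  st0 <- list(targets = sp$vertices, alpha = rep(0.7, nv))
  expect_lt(max(abs(deform_step(sp, st0, ref, W)$vertices - sp$vertices)),
            1e-9)

  # uniform translation targets: exact equivariance
  t0 <- c(1.5, -2, 0.5)
  stt <- list(targets = sweep(sp$vertices, 2, t0, "+"),
              alpha = state$alpha)
  expect_lt(max(abs(deform_step(sp, stt, ref, W)$vertices -
                      sweep(sp$vertices, 2, t0, "+"))), 1e-9)
})

test_that("boundary targets march to the nearest SDF zero crossing", {
  # half-space mask: boundary plane at x = 5.5 (face between centres 5 and 6)
  arr <- array(FALSE, c(12, 9, 9))
  arr[1:6, , ] <- TRUE
  mk <- binary_mask(arr)
  sdf <- signed_distance_field(mk)
  # a box with prescribed +x marching directions: the right face sits 2 mm
  # inside the boundary, the left face 3 mm
  patch <- box_mesh(2.5, 3.5, 2, 6, 2, 6)
  nrm <- matrix(rep(c(1, 0, 0), each = 8), 8, 3)
  st <- compute_boundary_targets(patch, sdf, deformation_params(),
                                 normals = nrm)
  d <- sqrt(rowSums((st$targets - patch$vertices)^2))
  right <- patch$vertices[, 1] > 3
  expect_true(all(abs(d[right] - 2) < 0.2))
  expect_true(all(abs(d[!right] - 3) < 0.2))
  # rigidity falls linearly with the force magnitude
  p <- deformation_params()
  expect_equal(st$alpha,
               pmin(pmax(p$alpha_max - (p$alpha_max - p$alpha_min) *
                           st$force / p$search_range, p$alpha_min),
                    p$alpha_max))

  # a vertex already on the boundary receives (almost) no force
  onb <- box_mesh(4.5, 5.5, 3, 5, 3, 5)  # right face exactly at x = 5.5
  nrm2 <- matrix(rep(c(1, 0, 0), each = 8), 8, 3)
  st2 <- compute_boundary_targets(onb, sdf, deformation_params(),
                                  normals = nrm2)
  expect_lt(max(st2$force[onb$vertices[, 1] > 5]), 0.05)

  # no boundary within search range: zero force
  far <- box_mesh(30, 31, 3, 5, 3, 5)
  stf <- compute_boundary_targets(far, sdf,
                                  deformation_params(search_range = 4))
  expect_equal(stf$targets, far$vertices)
  expect_equal(stf$force, rep(0, 8))
})

test_that("midplane constraints: active attraction and passive clamp", {
  tpl <- fx_template()
  msp <- midplane()
  ph <- fx_small_cohort()[[4]]  # IA phantom
  p <- deformation_params()
  thr <- p$ia_threshold_factor * sqrt(sum(ph$mask$voxel_size^2))
  expect_equal(p$ia_threshold_factor * sqrt(sum(c(1, 1, 1.3)^2)),
               2 * sqrt(1 + 1 + 1.69))  # 3.8419 mm for this voxel size

  # construct a state where one wall vertex faces an empty gap inside the
  # IA hole and another has foreground in between
  mesh <- tpl$mesh
  wall <- which(tpl$wall_label & tpl$side_label == "right")
  # vertex closest to the IA hole centre (y, z) = (0, 0)
  vhole <- wall[which.min(rowSums(mesh$vertices[wall, 2:3]^2))]
  mesh$vertices[vhole, 1] <- 1  # 1 mm from the plane, inside the hole
  st <- compute_boundary_targets(mesh, signed_distance_field(ph$mask), p)
  st2 <- apply_midplane_constraints(mesh, st, tpl, msp, ph$mask, p)
  expect_true(st2$active_ia[vhole])
  expect_equal(st2$targets[vhole, ], c(0, mesh$vertices[vhole, 2:3]))

  # far-side vertices (gap > threshold) keep their boundary targets
  vfar <- wall[which.max(abs(mesh$vertices[wall, 1]))]
  if (abs(mesh$vertices[vfar, 1]) > thr)
    expect_false(st2$active_ia[vfar])

  # passive clamp projects a crossing wall vertex back onto the plane
  mesh2 <- tpl$mesh
  mesh2$vertices[vhole, 1] <- -0.3  # right-wall vertex on the left side
  clamped <- clamp_to_plane(mesh2, tpl, msp)
  expect_equal(clamped$vertices[vhole, 1], 0)
  expect_equal(clamped$vertices[vhole, 2:3], mesh2$vertices[vhole, 2:3])
})

test_that("3-DOF initialisation recovers injected in-plane transforms", {
  tpl <- fx_template()
  ph <- fx_small_cohort()[[1]]
  # self-alignment: voxelized template at its own pose
  mk <- voxelize_mesh(tpl$mesh, ph$mask)
  est <- initialize_alignment(tpl, mk, tpl$midplane)
  # pose search quantises the angle in 0.25-degree steps, so self-alignment
  # can legitimately tie at the half-degree mark
  expect_lte(abs(angle_about_x_deg(est$rotation)), 0.5)
  expect_lte(max(abs(est$translation)), 0.5)

  # injected 10 degrees about the plane normal + (2, -1) mm in plane
  xf <- rigid_transform(rotation_about_x(10), c(0, 2, -1))
  moved <- tpl$mesh
  moved$vertices <- apply_transform(xf, moved$vertices)
  mk2 <- voxelize_mesh(moved, ph$mask)
  est2 <- initialize_alignment(tpl, mk2, tpl$midplane)
  expect_lt(abs(angle_about_x_deg(est2$rotation) - 10), 1)
  expect_lt(max(abs(est2$translation - c(0, 2, -1))), 0.5)

  # centre of mass of the aligned template stays on the MSP
  com <- colMeans(apply_transform(est2, tpl$mesh$vertices))
  expect_lt(abs(com[1]), 1e-6)
})

test_that("full fit restores the target with correspondence intact", {
  tpl <- fx_template()
  ph <- fx_small_cohort()[[1]]
  # self-fit: mask is the voxelized template
  mk <- voxelize_mesh(tpl$mesh, ph$mask)
  fit <- suppressWarnings(fit_template(tpl, mk, tpl$midplane))
  sd <- surface_distances(fit, mask_boundary_mesh(mk))
  expect_lte(sd$mean_distance, 0.3)
  expect_identical(fit$faces, tpl$mesh$faces)
  expect_equal(nrow(fit$vertices), nrow(tpl$mesh$vertices))

  # zero iterations returns the rigidly aligned template
  fit0 <- fit_template(tpl, mk, tpl$midplane,
                       deformation_params(max_iterations = 0))
  xfm <- attr(fit0, "transform")
  expect_equal(fit0$vertices, apply_transform(xfm, tpl$mesh$vertices))

  # monotone fitting: final distance not worse than after rigid alignment
  for (ph2 in fx_small_cohort()[2:3]) {
    f <- suppressWarnings(fit_template(tpl, ph2$mask, ph2$plane))
    f0 <- fit_template(tpl, ph2$mask, ph2$plane,
                       deformation_params(max_iterations = 0))
    bm <- mask_boundary_mesh(ph2$mask)
    expect_lte(surface_distances(f, bm)$mean_distance,
               surface_distances(f0, bm)$mean_distance)
  }
})

test_that("fit is equivariant under in-plane rigid motion of the subject", {
  tpl <- fx_template()
  ph <- fx_small_cohort()[[2]]
  fit1 <- suppressWarnings(fit_template(tpl, ph$mask, ph$plane))
  xf <- rigid_transform(rotation_about_x(8), c(0, 1.5, -1))
  aff <- ph$mask$affine
  aff[1:3, ] <- xf$rotation %*% aff[1:3, ]
  aff[1:3, 4] <- aff[1:3, 4] + xf$translation
  mask2 <- binary_mask(ph$mask$data, aff)
  msp2 <- transform_plane(ph$plane, xf)
  fit2 <- suppressWarnings(fit_template(tpl, mask2, msp2))
  moved <- apply_transform(xf, fit1$vertices)
  expect_lt(sqrt(mean(rowSums((fit2$vertices - moved)^2))), 0.5)
})

test_that("boundary roughness perturbs the fit by less than a voxel", {
  tpl <- fx_template()
  base <- make_phantom(phantom_spec(seed = 77))
  rough <- make_phantom(phantom_spec(seed = 77, roughness_amplitude = 0.5))
  f1 <- suppressWarnings(fit_template(tpl, base$mask, base$plane))
  f2 <- suppressWarnings(fit_template(tpl, rough$mask, rough$plane))
  rms <- sqrt(mean(rowSums((f1$vertices - f2$vertices)^2)))
  expect_lt(rms, 1)
})
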