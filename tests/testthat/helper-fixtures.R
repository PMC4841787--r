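# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

# small phantom cohort (two plain, one asymmetric, one with an IA hole)
fx_small_cohort <- function() memo("small_cohort", function() {
  specs <- list(
    phantom_spec(half_width_left = 2.2, half_width_right = 2.2,
                 roughness_amplitude = 0.3, seed = 101),
    phantom_spec(half_width_left = 2.8, half_width_right = 2.8,
                 length = 27, roughness_amplitude = 0.3, seed = 102),
    phantom_spec(half_width_left = 3.0, half_width_right = 2.2,
                 roughness_amplitude = 0.3, seed = 103),
    phantom_spec(half_width_left = 2.5, half_width_right = 2.5,
                 ia_radius = 2, roughness_amplitude = 0.3, seed = 104))
  lapply(specs, make_phantom)
})

# template built from the small cohort
fx_template <- function() memo("template", function() {
  phs <- fx_small_cohort()
  mean_mask <- build_symmetric_shape(lapply(phs, `[[`, "mask"),
                                     lapply(phs, `[[`, "plane"))
  build_template(mean_mask, target_vertices = 1500)
})

# fit of the template to the IA phantom (shared by constraint tests)
fx_ia_fit <- function() memo("ia_fit", function() {
  phs <- fx_small_cohort()
  suppressWarnings(fit_template(fx_template(), phs[[4]]$mask,
                                phs[[4]]$plane))
})

# unit sphere mesh (fine) and a small voxelization reference grid
fx_sphere <- function() memo("sphere", function()
  ventricle3d:::symmetric_sphere_mesh(3000))

fx_sphere_grid <- function() memo("sphere_grid", function() {
  nv <- 2 * ceiling(1.5 / 0.2) + 1
  # generic origin offset keeps lattice points off the exact sphere surface
  orig <- rep(-(nv - 1) / 2 * 0.2, 3) + c(0.013, 0.007, -0.011)
  volume_image(array(0, rep(nv, 3)),
               rbind(cbind(diag(rep(0.2, 3)), orig), c(0, 0, 0, 1)))
})

# 20-phantom accuracy cohort (study conditions of the synthetic analog of
# the reconstruction-accuracy experiment), template, fits, and metrics;
# expensive, built once and shared by the acceptance tests
fx_accuracy_experiment <- function() memo("accuracy", function() {
  cohort <- make_cohort(20, seed = 42)
  masks <- lapply(cohort$phantoms, `[[`, "mask")
  planes <- lapply(cohort$phantoms, `[[`, "plane")
  template <- build_template(build_symmetric_shape(masks, planes), 2500)
  fits <- vector("list", 20)
  metrics <- vector("list", 20)
  for (i in seq_len(20)) {
    fits[[i]] <- suppressWarnings(
      fit_template(template, masks[[i]], planes[[i]]))
    metrics[[i]] <- compare_fit(fits[[i]], masks[[i]])
  }
  list(cohort = cohort, template = template, fits = fits,
       metrics = do.call(rbind, lapply(metrics, as.data.frame)))
})

# an explicit closed box mesh: [x0,x1] x [y0,y1] x [z0,z1]
box_mesh <- function(x0, x1, y0, y1, z0, z1) {
  V <- as.matrix(expand.grid(x = c(x0, x1), y = c(y0, y1), z = c(z0, z1)))
  # faces of the cube (vertex order gives outward normals)
  Fm <- rbind(c(1, 3, 7), c(1, 7, 5),   # x = x0
              c(2, 8, 4), c(2, 6, 8),   # x = x1
              c(1, 5, 6), c(1, 6, 2),   # y = y0
              c(3, 4, 8), c(3, 8, 7),   # y = y1
              c(1, 2, 4), c(1, 4, 3),   # z = z0
              c(5, 7, 8), c(5, 8, 6))   # z = z1
  m <- triangle_mesh(V, Fm)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

rotation_about_x <- function(deg)
  ventricle3d:::rotation_about_axis(c(1, 0, 0), deg * pi / 180)

angle_about_x_deg <- function(R) atan2(R[3, 2], R[2, 2]) * 180 / pi
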