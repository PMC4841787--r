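#' Specification of a synthetic third-ventricle phantom
#'
#' The phantom is a thin, near-midline slab straddling a known midplane:
#' left and right lumen walls at analytic half-widths that taper to zero at
#' an elliptical rim, optionally bent, with band-limited random boundary
#' roughness and an optional through-hole where an inter-thalamic adhesion
#' (IA) crosses the cavity. All downstream ground truth (true plane, true
#' half-width maps, true volume) derives from the same analytic surfaces.
#'
#' @param half_width_left,half_width_right peak lumen half-widths (mm).
#' @param length anteroposterior extent (mm, y axis).
#' @param height dorsoventral extent (mm, z axis).
#' @param bend common x-offset amplitude of both walls toward the ends of
#'   the y axis (mm); 0 keeps the slab mirror-symmetric about the midplane.
#' @param roughness_amplitude standard deviation of the boundary
#'   perturbation field (mm).
#' @param roughness_wavelength shortest wavelength of the perturbation
#'   field (mm); the field is sampled on a grid of this spacing and
#'   interpolated, so finer detail is absent by construction.
#' @param ia_radius radius of the IA through-hole (mm); 0 for none.
#' @param ia_center length-2 (y, z) centre of the IA on the midplane (mm).
#' @param voxel_size length-3 voxel dimensions (mm).
#' @param plane_offset x position of the true midplane (mm).
#' @param margin_voxels grid margin around the phantom (voxels).
#' @param seed integer seed for the roughness field.
#' @return an object of class `tv_phantom_spec`.
#' @export
phantom_spec <- function(half_width_left = 2.5, half_width_right = 2.5,
                         length = 25, height = 20, bend = 0,
                         roughness_amplitude = 0, roughness_wavelength = 3,
                         ia_radius = 0, ia_center = c(0, 0),
                         voxel_size = c(1, 1, 1.3), plane_offset = 0,
                         margin_voxels = 3, seed = 1L) {
  stopifnot(half_width_left > 0, half_width_right > 0, length > 0,
            height > 0, roughness_amplitude >= 0, ia_radius >= 0,
            all(voxel_size > 0), margin_voxels >= 2)
  spec <- structure(as.list(environment()), class = "tv_phantom_spec")
  if (ia_radius > 0) {
    rim <- footprint_rho(ia_center[1] + c(-1, 1, 0, 0) * ia_radius,
                         ia_center[2] + c(0, 0, -1, 1) * ia_radius,
                         length, height)
    if (any(rim >= 1))
      stop("IA cylinder exceeds the slab extent")
  }
  spec
}

# elliptical footprint coordinate: 1 at the rim
footprint_rho <- function(y, z, length, height) {
  sqrt((2 * y / length)^2 + (2 * z / height)^2)
}

# tapering profile: ~1 over the plateau, 0 at the rim
footprint_profile <- function(rho) {
  pmax(0, 1 - rho^4)
}

# band-limited Gaussian field over (y, z): white noise on a coarse grid at
# the cutoff wavelength, bilinearly interpolated
smooth_field <- function(y, z, amplitude, wavelength, ylim, zlim) {
  if (amplitude == 0) return(rep(0, base::length(y)))
  gy <- seq(ylim[1] - wavelength, ylim[2] + wavelength, by = wavelength)
  gz <- seq(zlim[1] - wavelength, zlim[2] + wavelength, by = wavelength)
  vals <- matrix(rnorm(base::length(gy) * base::length(gz), sd = amplitude),
                 base::length(gy), base::length(gz))
  fy <- pmin(pmax((y - gy[1]) / wavelength, 0), base::length(gy) - 1.0001)
  fz <- pmin(pmax((z - gz[1]) / wavelength, 0), base::length(gz) - 1.0001)
  i0 <- floor(fy); j0 <- floor(fz)
  ty <- fy - i0; tz <- fz - j0
  i0 <- i0 + 1; j0 <- j0 + 1
  vals[cbind(i0, j0)] * (1 - ty) * (1 - tz) +
    vals[cbind(i0 + 1, j0)] * ty * (1 - tz) +
    vals[cbind(i0, j0 + 1)] * (1 - ty) * tz +
    vals[cbind(i0 + 1, j0 + 1)] * ty * tz
}

# run expr with a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  expr
}

#' Generate a synthetic phantom mask with ground truth
#'
#' Voxelizes the analytic slab of a [phantom_spec()] by the voxel-centre
#' rule and returns the mask, the true midplane, and a ground-truth record:
#' analytic half-width maps on a 0.5 mm reference grid, the true volume, and
#' the wall-position functions themselves.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `mask` ([binary_mask()]), `plane`
#'   ([midplane()]), and `truth` (list: `lw`, `rw`, `grid_y`, `grid_z`,
#'   `volume`, `spec`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "tv_phantom_spec"))
  vs <- spec$voxel_size
  # roughness fields are frozen once per phantom (functions of (y, z))
  ylim <- c(-1, 1) * spec$length / 2
  zlim <- c(-1, 1) * spec$height / 2
  fields <- with_seed(spec$seed, {
    # realise both wall fields on a fixed fine lattice so any caller
    # evaluating them later sees identical surfaces
    gy <- seq(ylim[1], ylim[2], by = 0.25)
    gz <- seq(zlim[1], zlim[2], by = 0.25)
    pts <- expand.grid(y = gy, z = gz)
    fl <- smooth_field(pts$y, pts$z, spec$roughness_amplitude,
                       spec$roughness_wavelength, ylim, zlim)
    fr <- smooth_field(pts$y, pts$z, spec$roughness_amplitude,
                       spec$roughness_wavelength, ylim, zlim)
    list(gy = gy, gz = gz,
         fl = matrix(fl, length(gy), length(gz)),
         fr = matrix(fr, length(gy), length(gz)))
  })
  lookup <- function(m, y, z) {
    fy <- pmin(pmax((y - fields$gy[1]) / 0.25, 0), length(fields$gy) - 1.0001)
    fz <- pmin(pmax((z - fields$gz[1]) / 0.25, 0), length(fields$gz) - 1.0001)
    i0 <- floor(fy); j0 <- floor(fz); ty <- fy - i0; tz <- fz - j0
    i0 <- i0 + 1; j0 <- j0 + 1
    m[cbind(i0, j0)] * (1 - ty) * (1 - tz) + m[cbind(i0 + 1, j0)] * ty * (1 - tz) +
      m[cbind(i0, j0 + 1)] * (1 - ty) * tz + m[cbind(i0 + 1, j0 + 1)] * ty * tz
  }
  # analytic wall x-positions (left wall < plane < right wall)
  walls <- function(y, z) {
    rho <- footprint_rho(y, z, spec$length, spec$height)
    g <- footprint_profile(rho)
    cbend <- spec$bend * (2 * y / spec$length)^2
    xl <- spec$plane_offset + cbend - (spec$half_width_left + lookup(fields$fl, y, z)) * g
    xr <- spec$plane_offset + cbend + (spec$half_width_right + lookup(fields$fr, y, z)) * g
    inside_fp <- g > 0
    if (spec$ia_radius > 0) {
      hole <- (y - spec$ia_center[1])^2 + (z - spec$ia_center[2])^2 <
        spec$ia_radius^2
      inside_fp <- inside_fp & !hole
    }
    list(xl = xl, xr = xr, inside = inside_fp)
  }
  # grid: centred on the phantom with margin
  xext <- max(spec$half_width_left, spec$half_width_right) +
    abs(spec$bend) + 3 * spec$roughness_amplitude
  half_extent <- c(xext, spec$length / 2, spec$height / 2)
  n <- 2 * (ceiling(half_extent / vs) + spec$margin_voxels) + 1
  origin <- -((n - 1) / 2) * vs + c(spec$plane_offset, 0, 0)
  affine <- rbind(cbind(diag(vs), origin), c(0, 0, 0, 1))
  cx <- origin[1] + (0:(n[1] - 1)) * vs[1]
  cy <- origin[2] + (0:(n[2] - 1)) * vs[2]
  cz <- origin[3] + (0:(n[3] - 1)) * vs[3]
  yz <- expand.grid(y = cy, z = cz)
  wl <- walls(yz$y, yz$z)
  arr <- array(FALSE, n)
  for (i in seq_len(n[1])) {
    inside <- wl$inside & cx[i] > wl$xl & cx[i] < wl$xr
    arr[i, , ] <- matrix(inside, n[2], n[3])
  }
  if (!any(arr)) stop("phantom produced an empty mask; check dimensions")
  mask <- binary_mask(arr, affine)
  # ground truth on a 0.5 mm reference grid (analytic, pre-voxelization)
  gy <- seq(ylim[1], ylim[2], by = 0.5)
  gz <- seq(zlim[1], zlim[2], by = 0.5)
  gyz <- expand.grid(y = gy, z = gz)
  gw <- walls(gyz$y, gyz$z)
  lw <- pmax(0, spec$plane_offset - gw$xl)
  rw <- pmax(0, gw$xr - spec$plane_offset)
  lw[!gw$inside] <- NA_real_
  rw[!gw$inside] <- NA_real_
  # true volume by fine 2D integration of the width
  fy <- seq(ylim[1], ylim[2], by = 0.125)
  fz <- seq(zlim[1], zlim[2], by = 0.125)
  fyz <- expand.grid(y = fy, z = fz)
  fw <- walls(fyz$y, fyz$z)
  vol <- sum(pmax(0, fw$xr - fw$xl)[fw$inside]) * 0.125^2
  list(mask = mask,
       plane = midplane(c(spec$plane_offset, 0, 0), c(1, 0, 0)),
       truth = list(lw = matrix(lw, length(gy), length(gz)),
                    rw = matrix(rw, length(gy), length(gz)),
                    grid_y = gy, grid_z = gz, volume = vol, spec = spec,
                    walls = walls))
}

#' Simulate a phantom cohort with covariates
#'
#' Draws phantom parameters uniformly from the stated ranges, assigns an IA
#' through-hole to a fixed fraction of subjects, and generates a covariate
#' table (group, age, head size, brain tissue volume, cognition score) with
#' known injected effects so that downstream regression recovery can be
#' checked against ground truth. Fully reproducible from the seed.
#'
#' @param n number of phantoms (>= 2).
#' @param seed integer seed.
#' @param ranges named list of `c(lo, hi)` ranges for `half_width` (per-side
#'   base, mm), `asymmetry` (left minus right half-width, mm), `length`,
#'   `height` (mm).
#' @param roughness_amplitude boundary roughness (mm) applied to every
#'   phantom.
#' @param ia_fraction fraction of subjects given an IA hole (the last
#'   `round(n * ia_fraction)` subjects).
#' @param ia_radius IA hole radius (mm) for those subjects.
#' @param group_width_effect additional total width (mm) given to group 1
#'   subjects, split equally between the two sides.
#' @param voxel_size voxel dimensions (mm).
#' @return list with `phantoms` (list of [make_phantom()] results),
#'   `covariates` (data.frame: subject_id, group, gender, age_days, icv,
#'   btv, fi), and `truth` (per-subject true volume/width summaries).
#' @export
make_cohort <- function(n, seed = 42L,
                        ranges = list(half_width = c(1.6, 3.2),
                                      asymmetry = c(-0.8, 0.8),
                                      length = c(22, 28),
                                      height = c(16, 20)),
                        roughness_amplitude = 0.5,
                        ia_fraction = 0.5, ia_radius = 2,
                        group_width_effect = 0,
                        voxel_size = c(1, 1, 1.3)) {
  stopifnot(n >= 2)
  for (r in ranges) stopifnot(length(r) == 2, r[2] >= r[1])
  draws <- with_seed(seed, {
    list(hw = runif(n, ranges$half_width[1], ranges$half_width[2]),
         asym = runif(n, ranges$asymmetry[1], ranges$asymmetry[2]),
         len = runif(n, ranges$length[1], ranges$length[2]),
         hgt = runif(n, ranges$height[1], ranges$height[2]),
         group = rep_len(c(0L, 1L), n),
         age = runif(n, 70 * 365.25, 75 * 365.25),
         icv = rnorm(n, 1.45e6, 8e4),
         fi = rnorm(n),
         btv_noise = rnorm(n, 0, 2e4),
         seeds = sample.int(1e6, n))
  })
  n_ia <- round(n * ia_fraction)
  has_ia <- seq_len(n) > (n - n_ia)
  phantoms <- vector("list", n)
  truth <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                      half_width_left = NA_real_,
                      half_width_right = NA_real_, has_ia = has_ia,
                      true_volume = NA_real_, true_max_tvw = NA_real_)
  for (i in seq_len(n)) {
    extra <- if (draws$group[i] == 1L) group_width_effect / 2 else 0
    hwl <- pmax(0.8, draws$hw[i] + draws$asym[i] / 2 + extra)
    hwr <- pmax(0.8, draws$hw[i] - draws$asym[i] / 2 + extra)
    sp <- phantom_spec(half_width_left = hwl, half_width_right = hwr,
                       length = draws$len[i], height = draws$hgt[i],
                       roughness_amplitude = roughness_amplitude,
                       ia_radius = if (has_ia[i]) ia_radius else 0,
                       voxel_size = voxel_size, seed = draws$seeds[i])
    phantoms[[i]] <- make_phantom(sp)
    truth$half_width_left[i] <- hwl
    truth$half_width_right[i] <- hwr
    truth$true_volume[i] <- phantoms[[i]]$truth$volume
    tw <- phantoms[[i]]$truth$lw + phantoms[[i]]$truth$rw
    truth$true_max_tvw[i] <- max(tw, na.rm = TRUE)
  }
  covariates <- data.frame(
    subject_id = truth$subject_id,
    group = draws$group,
    gender = draws$group,  # group doubles as the gender covariate (0/1)
    age_days = draws$age,
    icv = draws$icv,
    btv = 0.78 * draws$icv - 120 * truth$true_volume + draws$btv_noise,
    fi = draws$fi)
  list(phantoms = phantoms, covariates = covariates, truth = truth)
}
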