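#' Parameters of the progressive Laplacian deformation
#'
#' The deformation runs in stages from large to small scale: the Laplacian
#' neighbourhood order starts wide (stiff, smooth propagation of boundary
#' forces) and narrows so late iterations capture local detail. Per-vertex
#' rigidity is set dynamically each iteration: vertices pulled hard by the
#' boundary force lose rigidity (down to `alpha_min`) so the force
#' propagates to their neighbours, quiet vertices keep `alpha_max`.
#'
#' @param stage_n_rings neighbourhood orders of the successive stages.
#' @param stage_iterations iteration cap per stage (total additionally
#'   capped by `max_iterations`).
#' @param alpha_min,alpha_max rigidity bounds, in (0, 1].
#' @param max_iterations overall iteration cap.
#' @param convergence_tol mean vertex displacement (mm) below which a stage
#'   stops.
#' @param ia_threshold_factor the active midplane constraint fires within
#'   this multiple of the voxel diagonal of the target mask (default 2).
#' @param search_range boundary search distance along the vertex normal (mm).
#' @param search_step sampling step of the boundary search and of the
#'   empty-gap test (mm).
#' @return an object of class `tv_deform_params`.
#' @export
deformation_params <- function(stage_n_rings = c(3L, 2L, 1L),
                               stage_iterations = c(20L, 20L, 40L),
                               alpha_min = 0.15, alpha_max = 1,
                               max_iterations = 100L,
                               convergence_tol = 0.01,
                               ia_threshold_factor = 2,
                               search_range = 10, search_step = 0.25) {
  stopifnot(all(stage_n_rings >= 1), length(stage_iterations) ==
              length(stage_n_rings), alpha_min > 0, alpha_max <= 1,
            alpha_min <= alpha_max, ia_threshold_factor > 0,
            search_range > 0, search_step > 0)
  structure(list(stage_n_rings = as.integer(stage_n_rings),
                 stage_iterations = as.integer(stage_iterations),
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 ia_threshold_factor = ia_threshold_factor,
                 search_range = search_range, search_step = search_step),
            class = "tv_deform_params")
}

#' Row-normalised N-ring neighbourhood matrix
#'
#' Sparse matrix W with `W[i, j] = 1/|N(i)|` for every vertex j within graph
#' distance `n_ring` of i (excluding i itself); (I - W) V gives the extended
#' Laplacian coordinates.
#'
#' @param mesh a [triangle_mesh()].
#' @param n_ring neighbourhood order (>= 1).
#' @return a `dgCMatrix`.
#' @export
neighborhood_matrix <- function(mesh, n_ring = 1L) {
  stopifnot(n_ring >= 1)
  nv <- nrow(mesh$vertices)
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nv, nv))
  A <- A > 0
  if (any(Matrix::rowSums(A) == 0)) stop("mesh has isolated vertices")
  R <- A
  if (n_ring > 1) {
    for (k in 2:n_ring) R <- (R %*% A) > 0 | R
  }
  Matrix::diag(R) <- FALSE
  R <- methods::as(R, "dMatrix")
  W <- R / Matrix::rowSums(R)
  methods::as(W, "CsparseMatrix")
}

#' Extended Laplacian coordinates
#'
#' Deviation of each vertex from the centroid of its N-ring neighbourhood
#' (uniform weights).
#'
#' @param mesh a [triangle_mesh()].
#' @param n_ring neighbourhood order.
#' @return n x 3 matrix of Laplacian coordinates.
#' @export
extended_laplacian <- function(mesh, n_ring = 1L) {
  laplacian_coordinates(mesh, neighborhood_matrix(mesh, n_ring))
}

laplacian_coordinates <- function(mesh, W) {
  mesh$vertices - as.matrix(W %*% mesh$vertices)
}

#' Boundary targets and dynamic rigidity for one deformation iteration
#'
#' For each vertex, marches along its (outward and inward) normal within
#' `search_range`, locates the nearest sign change of the mask's signed
#' distance field (sub-voxel position by linear interpolation), and sets the
#' target position there; vertices with no boundary in range keep their
#' position (zero force). Rigidity falls linearly with the force magnitude,
#' from `alpha_max` at zero force to `alpha_min` at `search_range`.
#'
#' @param mesh current [triangle_mesh()].
#' @param sdf signed distance field of the target mask
#'   ([signed_distance_field()]).
#' @param params a [deformation_params()].
#' @param normals optional precomputed vertex normals.
#' @return deformation state: list with `targets` (n x 3), `alpha` (n),
#'   `force` (n, mm), `active_ia` (logical n).
#' @export
compute_boundary_targets <- function(mesh, sdf, params = deformation_params(),
                                     normals = NULL) {
  V <- mesh$vertices
  n <- if (is.null(normals)) vertex_normals(mesh) else normals
  if (any(rowSums(n^2) < 1e-12)) stop("zero vertex normal encountered")
  nv <- nrow(V)
  ts <- seq(-params$search_range, params$search_range,
            by = params$search_step)
  nt <- length(ts)
  pts <- V[rep(seq_len(nv), times = nt), ] +
    n[rep(seq_len(nv), times = nt), ] * rep(ts, each = nv)
  vals <- matrix(interp_volume(sdf, pts), nv, nt)
  sgn <- vals < 0
  cross <- sgn[, -nt, drop = FALSE] != sgn[, -1, drop = FALSE]
  mid <- (ts[-nt] + ts[-1]) / 2
  # nearest crossing interval to t = 0
  ord <- order(abs(mid))
  tbest <- rep(NA_real_, nv)
  for (ci in ord) {
    hit <- is.na(tbest) & cross[, ci]
    if (!any(hit)) next
    v0 <- vals[hit, ci]
    v1 <- vals[hit, ci + 1]
    tbest[hit] <- ts[ci] + (0 - v0) / (v1 - v0) * params$search_step
  }
  force <- abs(tbest)
  tbest[is.na(tbest)] <- 0
  force[is.na(force)] <- 0
  targets <- V + n * tbest
  alpha <- pmin(pmax(params$alpha_max - (params$alpha_max - params$alpha_min) *
                       force / params$search_range, params$alpha_min),
                params$alpha_max)
  list(targets = targets, alpha = alpha, force = force,
       active_ia = rep(FALSE, nv), normals = n)
}

#' Apply the midplane constraints for the inter-thalamic adhesion
#'
#' Active constraint: a lateral-wall vertex whose gap to the midplane (on
#' its own side) contains no mask foreground and is narrower than
#' `ia_threshold_factor` voxel diagonals has its target replaced by its
#' perpendicular projection onto the plane, driving the left and right
#' walls into contact where the adhesion passes through. The passive
#' clamp (wall vertices may not cross the plane) is applied separately
#' after each solve by [clamp_to_plane()].
#'
#' @param mesh current [triangle_mesh()].
#' @param state deformation state from [compute_boundary_targets()].
#' @param template the `tv_template` (supplies wall labels and sides).
#' @param msp the subject's [midplane()].
#' @param mask the target [binary_mask()].
#' @param params a [deformation_params()].
#' @return the updated state with `active_ia` flagged.
#' @export
apply_midplane_constraints <- function(mesh, state, template, msp, mask,
                                       params = deformation_params()) {
  V <- mesh$vertices
  d <- plane_signed_distance(V, msp)
  side <- template_side_sign(template)
  thr <- params$ia_threshold_factor * sqrt(sum(mask$voxel_size^2))
  cand <- which(template$wall_label & side != 0 & abs(d) < thr)
  if (!length(cand)) return(state)
  # empty-gap test: sample the segment from the vertex to its foot on the
  # plane; active when no foreground voxel is met
  nstep <- max(2L, ceiling(thr / params$search_step))
  u <- seq(0, 1, length.out = nstep + 1L)
  seg <- V[rep(cand, times = length(u)), ] -
    outer(rep(d[cand], times = length(u)) * rep(u, each = length(cand)),
          msp$normal)
  inside <- matrix(interp_volume(mask_as_volume(mask), seg,
                                 method = "nearest") > 0.5,
                   length(cand), length(u))
  empty <- !apply(inside, 1, any)
  act <- cand[empty]
  if (length(act)) {
    state$targets[act, ] <- V[act, , drop = FALSE] -
      outer(d[act], msp$normal)
    state$force[act] <- abs(d[act])
    # the contact force must dominate local shape preservation so the
    # walls actually meet on the plane: minimum rigidity
    state$alpha[act] <- params$alpha_min
    state$active_ia[act] <- TRUE
  }
  state
}

mask_as_volume <- function(mask) {
  volume_image(array(as.numeric(mask$data), dim(mask$data)), mask$affine)
}

# +1 for right-labelled vertices, -1 for left, 0 for midline
template_side_sign <- function(template) {
  ifelse(template$side_label == "right", 1,
         ifelse(template$side_label == "left", -1, 0))
}

#' Clamp wall vertices that crossed the midplane (passive constraint)
#'
#' Any lateral-wall vertex lying on the wrong side of the plane is replaced
#' by its perpendicular projection onto the plane, so left and right walls
#' may touch but never interpenetrate.
#'
#' @param mesh a [triangle_mesh()] in vertex correspondence with `template`.
#' @param template the `tv_template`.
#' @param msp the subject's [midplane()].
#' @return the clamped mesh.
#' @export
clamp_to_plane <- function(mesh, template, msp) {
  V <- mesh$vertices
  d <- plane_signed_distance(V, msp)
  side <- template_side_sign(template)
  bad <- template$wall_label & side != 0 & (d * side) < 0
  if (any(bad))
    V[bad, ] <- V[bad, , drop = FALSE] - outer(d[bad], msp$normal)
  mesh$vertices <- V
  mesh
}

#' One linear solve of the Laplacian deformation energy
#'
#' Minimises the sum of the rigidity-weighted Laplacian preservation term
#' and the positional term: rows alpha_i ((I - W) v' - L_ref)_i and rows
#' (v'_i - b_i), solved in closed form through the sparse normal equations
#' (one symmetric positive-definite factorisation, three right-hand sides).
#' Connectivity is untouched and the solve is deterministic.
#'
#' @param mesh current [triangle_mesh()].
#' @param state deformation state (targets `b`, rigidity `alpha`).
#' @param reference_laplacians n x 3 Laplacian coordinates to preserve.
#' @param W neighbourhood matrix matching `reference_laplacians`
#'   ([neighborhood_matrix()]).
#' @return the deformed [triangle_mesh()].
#' @export
deform_step <- function(mesh, state, reference_laplacians, W) {
  nv <- nrow(mesh$vertices)
  if (all(state$alpha == 0) && all(state$targets == mesh$vertices))
    stop("singular system: all rigidities zero and no positional targets")
  M <- Matrix::Diagonal(nv) - W
  D2 <- Matrix::Diagonal(nv, state$alpha^2)
  S <- Matrix::forceSymmetric(Matrix::t(M) %*% D2 %*% M +
                                Matrix::Diagonal(nv))
  rhs <- as.matrix(Matrix::t(M) %*% (D2 %*% reference_laplacians)) +
    state$targets
  Vnew <- as.matrix(Matrix::solve(S, rhs))
  dimnames(Vnew) <- NULL
  mesh$vertices <- Vnew
  mesh
}

#' Rigid 3-DOF initialisation of the template on a subject mask
#'
#' Step 1 moves the template so its midplane coincides with the subject's
#' midsagittal plane (minimal rotation of normal onto normal, centre onto
#' centre). Step 2 refines with an iterative-closest-point registration
#' restricted to the three in-plane degrees of freedom (rotation about the
#' plane normal, translation within the plane). Correspondences are the
#' closest points on the mask's implicit surface, obtained by projecting
#' each template vertex along the gradient of the signed distance field
#' (sub-voxel accurate, so the angular minimum is not blurred by voxel
#' discretisation); a coarse deterministic scan over the rotation angle
#' seeds the iteration in the correct basin. The restriction keeps the
#' template midplane on the MSP and the model's centre of mass on the
#' plane.
#'
#' @param template a `tv_template`.
#' @param mask the subject [binary_mask()].
#' @param msp the subject [midplane()].
#' @param max_icp_iterations iteration cap of the ICP refinement.
#' @param scan_deg coarse scan bound on the in-plane rotation (degrees).
#' @param sdf optional precomputed [signed_distance_field()] of `mask`.
#' @param refine_voxel polish the pose by coordinate descent on the count
#'   of mismatching voxels between the voxelized template and the mask,
#'   which localises the pose below the resolution of the distance-based
#'   objective.
#' @return a [rigid_transform()] mapping template space to native space,
#'   with attribute `icp_cost` (final mean squared surface distance).
#' @export
initialize_alignment <- function(template, mask, msp,
                                 max_icp_iterations = 50L, scan_deg = 15,
                                 sdf = NULL, refine_voxel = TRUE) {
  R1 <- rotation_between(template$midplane$normal, msp$normal)
  t1 <- msp$center - as.numeric(R1 %*% template$midplane$center)
  step1 <- rigid_transform(R1, t1)
  if (is.null(sdf)) sdf <- signed_distance_field(mask)
  P0 <- apply_transform(step1, template$mesh$vertices)
  nrm <- msp$normal
  e1 <- pick_orthogonal(nrm)
  e2 <- cross3v(nrm, e1)
  c0 <- msp$center
  place <- function(theta, u) {
    R <- rotation_about_axis(nrm, theta)
    sweep(sweep(P0, 2, c0) %*% t(R), 2,
          c0 + u[1] * e1 + u[2] * e2, "+")
  }
  cost <- function(theta, u) mean(interp_volume(sdf, place(theta, u))^2)
  # closest point on the implicit mask surface for each query point
  project_to_surface <- function(P) {
    s <- interp_volume(sdf, P)
    h <- 0.5
    g <- cbind(
      interp_volume(sdf, sweep(P, 2, c(h, 0, 0), "+")) -
        interp_volume(sdf, sweep(P, 2, c(-h, 0, 0), "+")),
      interp_volume(sdf, sweep(P, 2, c(0, h, 0), "+")) -
        interp_volume(sdf, sweep(P, 2, c(0, -h, 0), "+")),
      interp_volume(sdf, sweep(P, 2, c(0, 0, h), "+")) -
        interp_volume(sdf, sweep(P, 2, c(0, 0, -h), "+"))) / (2 * h)
    gn <- sqrt(rowSums(g^2))
    gn[gn < 1e-6] <- 1
    P - (s / gn) * g
  }
  # in-plane centroid of the mask foreground, for the scan translation
  idx <- which(mask$data, arr.ind = TRUE) - 1L
  fg <- voxel_to_world(mask, idx)
  fgm <- colMeans(sweep(fg, 2, c0) %*% cbind(e1, e2))
  # coarse scan over the rotation angle (centroid-matched translation)
  thetas <- seq(-scan_deg, scan_deg, by = 2) * pi / 180
  best <- Inf
  theta <- 0
  u <- c(0, 0)
  for (th in thetas) {
    pu <- fgm - colMeans(sweep(place(th, c(0, 0)), 2, c0) %*% cbind(e1, e2))
    cc <- cost(th, pu)
    if (cc < best) {
      best <- cc
      theta <- th
      u <- pu
    }
  }
  step1_cost <- cost(0, c(0, 0))
  prev_cost <- cost(theta, u)
  fails <- 0L
  for (it in seq_len(max_icp_iterations)) {
    P <- place(theta, u)
    Q <- project_to_surface(P)
    # closed-form 3-DOF update: 2D rigid Procrustes in the plane basis
    pxi <- sweep(P, 2, c0) %*% cbind(e1, e2)
    qxi <- sweep(Q, 2, c0) %*% cbind(e1, e2)
    pm <- colMeans(pxi)
    qm <- colMeans(qxi)
    px <- sweep(pxi, 2, pm)
    qx <- sweep(qxi, 2, qm)
    dth <- atan2(sum(px[, 1] * qx[, 2] - px[, 2] * qx[, 1]),
                 sum(px[, 1] * qx[, 1] + px[, 2] * qx[, 2]))
    theta_new <- theta + dth
    # in-plane offset that matches the in-plane centroids after rotation
    Pn <- place(theta_new, c(0, 0))
    u_new <- qm - colMeans(sweep(Pn, 2, c0) %*% cbind(e1, e2))
    cnew <- cost(theta_new, u_new)
    if (cnew >= prev_cost - 1e-12) {
      fails <- fails + 1L
      if (it <= 3L && fails == it && prev_cost > step1_cost) {
        # genuinely failing (still worse than the plane-matching pose)
        if (it == 3L) {
          warning("ICP failed to reduce cost in 3 successive iterations; ",
                  "returning the plane-matching transform")
          attr(step1, "icp_cost") <- step1_cost
          return(step1)
        }
        theta <- theta_new
        u <- u_new
        prev_cost <- cnew
        next
      }
      break
    }
    improve <- prev_cost - cnew
    theta <- theta_new
    u <- u_new
    prev_cost <- cnew
    if (improve < 1e-10) break
  }
  if (refine_voxel) {
    # discrete polish in the voxel domain: the number of mismatching voxels
    # between the voxelized template and the mask is sharpest exactly at
    # the true pose, where the distance-based objective is blurred by the
    # staircase of the binary boundary
    vox_cost <- function(theta, u) {
      m <- triangle_mesh(place(theta, u), template$mesh$faces)
      sum(xor(.cpp_voxelize_parity(world_to_voxel(mask, m$vertices),
                                   m$faces - 1L, dim(mask$data)),
              as.vector(mask$data)))
    }
    cur <- vox_cost(theta, u)
    for (pass in 1:2) {
      for (dth in seq(-1.5, 1.5, by = 0.25) * pi / 180) {
        cc <- vox_cost(theta + dth, u)
        if (cc < cur) {
          cur <- cc
          theta <- theta + dth
        }
      }
      for (ax in 1:2) {
        for (dv in seq(-0.4, 0.4, by = 0.1)) {
          u2 <- u
          u2[ax] <- u2[ax] + dv
          cc <- vox_cost(theta, u2)
          if (cc < cur) {
            cur <- cc
            u <- u2
          }
        }
      }
    }
  }
  R <- rotation_about_axis(nrm, theta)
  tr <- c0 + u[1] * e1 + u[2] * e2 - as.numeric(R %*% c0)
  out <- compose_transforms(rigid_transform(R, tr), step1)
  attr(out, "icp_cost") <- prev_cost
  out
}

#' Fit the symmetric template to an individual mask
#'
#' Full individual shape modelling: rigid 3-DOF initialisation, then
#' progressive Laplacian deformation (stages of decreasing neighbourhood
#' order), each iteration recomputing normals, boundary targets, the active
#' midplane constraint in the adhesion region, solving the sparse linear
#' system, and clamping wall vertices that crossed the plane. Vertex count
#' and connectivity are those of the template throughout, so the result is
#' in dense correspondence with it.
#'
#' @param template a `tv_template`.
#' @param mask the subject [binary_mask()].
#' @param msp the subject [midplane()].
#' @param params a [deformation_params()].
#' @return the fitted [triangle_mesh()] with attributes `transform` (the
#'   rigid initialisation), `active_ia` (final active-constraint flags),
#'   `residuals` (per-iteration mean displacement), `converged`.
#' @export
fit_template <- function(template, mask, msp, params = deformation_params()) {
  sdf <- signed_distance_field(mask)
  xfm <- initialize_alignment(template, mask, msp, sdf = sdf)
  mesh <- template$mesh
  mesh$vertices <- apply_transform(xfm, mesh$vertices)
  if (params$max_iterations < 1L) {
    attr(mesh, "transform") <- xfm
    attr(mesh, "active_ia") <- rep(FALSE, nrow(mesh$vertices))
    attr(mesh, "residuals") <- numeric(0)
    attr(mesh, "converged") <- NA
    return(mesh)
  }
  residuals <- numeric(0)
  total <- 0L
  state <- NULL
  for (stage in seq_along(params$stage_n_rings)) {
    W <- neighborhood_matrix(mesh, params$stage_n_rings[stage])
    for (it in seq_len(params$stage_iterations[stage])) {
      if (total >= params$max_iterations) break
      total <- total + 1L
      vold <- mesh$vertices
      state <- compute_boundary_targets(mesh, sdf, params)
      state <- apply_midplane_constraints(mesh, state, template, msp, mask,
                                          params)
      ref <- laplacian_coordinates(mesh, W)
      mesh <- deform_step(mesh, state, ref, W)
      mesh <- clamp_to_plane(mesh, template, msp)
      disp <- mean(sqrt(rowSums((mesh$vertices - vold)^2)))
      residuals <- c(residuals, disp)
      if (disp < params$convergence_tol) break
    }
  }
  converged <- length(residuals) > 0 &&
    tail(residuals, 1) < params$convergence_tol
  if (!converged)
    warning("deformation did not converge in ", total,
            " iterations (final mean displacement ",
            signif(tail(residuals, 1), 3), " mm)")
  mesh <- clamp_to_plane(mesh, template, msp)
  attr(mesh, "transform") <- xfm
  attr(mesh, "active_ia") <- if (is.null(state)) logical(nrow(mesh$vertices))
                             else state$active_ia
  attr(mesh, "residuals") <- residuals
  attr(mesh, "converged") <- converged
  mesh
}
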