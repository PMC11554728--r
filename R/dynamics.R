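## Time integration: symplectic Euler with damped rotational gradient flow,
## catheter-insertion boundary conditions, two-phase wall geometry,
## sequential multi-coil chains and inextensibility diagnostics.

#' Simulation configuration
#'
#' Numerical and insertion parameters.  Anything left NULL is derived at
#' run time from the coil being simulated: the time step as the largest
#' power-of-two fraction of a second below the stability bound of the
#' stiffest mode (the axial penalty,
#' \eqn{0.5\sqrt{m\bar\ell/\alpha_{abs}}}, or the shortest discrete bending
#' wave), the translational damping near critical for the slowest bending
#' mode, and the rotational damping small enough that the edge-angle flow
#' is quasi-static yet stable.
#'
#' @param dt time step (s) or NULL for automatic
#' @param v_push insertion speed (mm/s)
#' @param post_swap_fraction extra fraction of the insertion steps run with
#'   the full vessel geometry after insertion completes
#' @param gravity acceleration vector (mm/s^2)
#' @param seed integer seed controlling all randomness of a scenario
#' @param record_every record a trajectory sample every k steps (NULL:
#'   about 250 samples)
#' @param eta_x translational damping (mN s/mm) or NULL
#' @param eta_phi rotational damping (mN mm s) or NULL
#' @param friction a \code{\link{friction_params}} object
#' @param literal_wall use the projection-only wall narrow phase (the
#'   paper-faithful rule) instead of closest-feature contact
#' @return object of class \code{simulation_config}
#' @export
simulation_config <- function(dt = NULL, v_push = 20, post_swap_fraction = 0.10,
                              gravity = c(0, 0, 0), seed = 1L,
                              record_every = NULL, eta_x = NULL, eta_phi = NULL,
                              friction = friction_params(),
                              literal_wall = FALSE) {
  stopifnot(is.null(dt) || dt > 0, post_swap_fraction >= 0)
  structure(list(dt = dt, v_push = v_push,
                 post_swap_fraction = post_swap_fraction,
                 gravity = as.double(gravity), seed = as.integer(seed),
                 record_every = record_every, eta_x = eta_x, eta_phi = eta_phi,
                 friction = friction, literal_wall = isTRUE(literal_wall)),
            class = "simulation_config")
}

# Node masses: uniform lumping (M = m I), one segment's stock-wire mass per
# node.
node_masses <- function(natural, spec) {
  len <- natural$rest_edge_lengths
  rep(spec$mass_per_length * mean(len), length(len) + 1L)
}

# Derived numerical parameters for a chain.
resolve_numerics <- function(config, pa, masses, D3ref) {
  el <- pa$elbar[pa$virt == 0L]
  lmin <- min(el)
  dt <- config$dt
  if (is.null(dt)) {
    # stability: the stiffest of the axial penalty mode and the discrete
    # zigzag bending mode (per-node stiffness 16 b / lbar^3, stability
    # window 0.5 sqrt(m lbar^3 / b)) must stay inside the explicit window
    ax <- 0.5 * sqrt(min(masses) * lmin / max(pa$alpha))
    bend <- 0.4 * sqrt(min(masses) * lmin^3 / max(pa$b))
    bound <- min(ax, bend)
    dt <- 2^floor(log2(bound))
  }
  eta_x <- config$eta_x
  if (is.null(eta_x)) {
    # near-critical damping of the slowest bending mode (wavelength of
    # order the imprint loop)
    q <- 2 * pi / (pi * D3ref)
    m <- stats::median(masses)
    k <- max(pa$b) * q^4 * lmin
    eta_x <- 2 * m * sqrt(k / m)
  }
  eta_phi <- config$eta_phi
  if (is.null(eta_phi)) {
    kphi <- 2 * max(pa$beta) / lmin +
      max(pa$b) * (max(abs(pa$kbar)) + 0.5)^2 / lmin
    eta_phi <- 8 * dt * kphi
  }
  list(dt = dt, eta_x = eta_x, eta_phi = eta_phi)
}

#' Advance a rod state by one time step
#'
#' One symplectic Euler step: velocities are updated first from the elastic
#' gradient, external forces and viscous damping; positions then advance
#' with the new velocities; edge angles follow the damped gradient flow
#' (rotational inertia is zero by model choice); finally the Bishop frames
#' are re-propagated with the material directors preserved.
#'
#' @param state a \code{rod_state}
#' @param natural a \code{coil_natural_shape}
#' @param spec a \code{coil_spec}
#' @param f_ext external nodal forces (N x 3, mN), e.g. from
#'   \code{\link{assemble_external_forces}}
#' @param config a \code{simulation_config}; \code{dt}, \code{eta_x},
#'   \code{eta_phi} are resolved if NULL
#' @return the advanced \code{rod_state}
#' @export
rod_step <- function(state, natural, spec, f_ext = NULL, config = simulation_config()) {
  pa <- rod_param_arrays(natural, spec)
  m <- node_masses(natural, spec)
  num <- resolve_numerics(config, pa, m, spec$D3)
  N <- nrow(state$x)
  if (is.null(f_ext)) f_ext <- matrix(0, N, 3)
  g <- grad_energy(state, natural, spec)
  acc <- (-g$grad_x + f_ext - num$eta_x * state$vel) / m
  gvec <- matrix(config$gravity, N, 3, byrow = TRUE)
  vel_new <- state$vel + num$dt * (acc + gvec)
  x_new <- state$x + num$dt * vel_new
  phi_new <- state$phi - num$dt / num$eta_phi * g$grad_phi
  # frames: time transport to the new tangents, then Bishop re-propagation
  # with the holonomy folded back into phi
  tr <- cpp_transport_frames(state$x, x_new, state$u, state$v)
  bi <- cpp_propagate_bishop(x_new, tr$U[1, ])
  tt <- diff(x_new); tt <- tt / sqrt(rowSums(tt^2))
  corr <- vapply(seq_len(N - 1L), function(j) {
    a <- bi$U[j, ]; b <- tr$U[j, ]; tj <- tt[j, ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
    atan2(sum(cr * tj), sum(a * b))
  }, numeric(1))
  state$x <- x_new
  state$vel <- vel_new
  state$phi <- wrap_angle(phi_new + corr)
  state$u <- bi$U
  state$v <- bi$V
  state
}

## ---- multi-coil chain assembly (internal) --------------------------------

# coils: list of list(spec = coil_spec, shape = shape_program or
# coil_natural_shape).  Returns concatenated arrays plus bookkeeping.
build_chain <- function(coils) {
  specs <- lapply(coils, `[[`, "spec")
  nats <- lapply(coils, function(cl) {
    if (inherits(cl$shape, "coil_natural_shape")) cl$shape
    else natural_shape(cl$shape, cl$spec)
  })
  nnodes <- vapply(nats, function(n) nrow(n$natural_vertices), integer(1))
  N <- sum(nnodes)
  elbar <- numeric(0); vor <- numeric(0); kbar <- NULL
  alpha <- numeric(0); b <- numeric(0); beta <- numeric(0)
  virt <- integer(0); mass <- numeric(0)
  coil_id <- integer(0)
  for (k in seq_along(coils)) {
    pa <- rod_param_arrays(nats[[k]], specs[[k]])
    mk <- node_masses(nats[[k]], specs[[k]])
    if (k > 1L) {
      # virtual connector edge between consecutive coils
      elbar <- c(elbar, mean(pa$elbar))
      alpha <- c(alpha, 0)
      virt <- c(virt, 1L)
    }
    elbar <- c(elbar, pa$elbar)
    vor <- c(vor, pa$vor)
    kbar <- rbind(kbar, pa$kbar)
    alpha <- c(alpha, pa$alpha)
    b <- c(b, pa$b)
    beta <- c(beta, pa$beta)
    virt <- c(virt, pa$virt)
    mass <- c(mass, mk)
    coil_id <- c(coil_id, rep(k, nnodes[k]))
  }
  list(N = N, specs = specs, naturals = nats, n_nodes = nnodes,
       elbar = elbar, vor = vor, kbar = kbar, alpha = alpha, b = b,
       beta = beta, virt = as.integer(virt), mass = mass, coil_id = coil_id,
       D2 = max(vapply(specs, `[[`, numeric(1), "D2")),
       arc = c(0, cumsum(elbar)))
}

mesh_or_empty <- function(mesh) {
  if (is.null(mesh)) list(v = matrix(0, 0, 3), f = matrix(0L, 0, 3))
  else list(v = mesh$vertices, f = mesh$faces - 1L)
}

#' Low-level rod simulation without insertion
#'
#' Integrates a free (or clamped) rod for a fixed number of steps,
#' optionally against wall meshes and gravity.  Used for free-space
#' relaxation, gravity validation and energy-decay studies; the deployment
#' pipeline proper is \code{\link{run_deployment}}.
#'
#' @param state initial \code{rod_state}
#' @param natural a \code{coil_natural_shape}
#' @param spec a \code{coil_spec}
#' @param config a \code{simulation_config}
#' @param n_steps number of time steps
#' @param wall optional \code{surface_mesh} obstacle
#' @param clamp integer node indices held fixed (e.g. a cantilever root)
#' @param contact enable self- and wall-contact forces.  Contact detection
#'   treats every non-adjacent edge pair as a potential collision, which
#'   presumes edges no shorter than the coil diameter D2; disable it for
#'   beam-theory studies on finer discretizations.
#' @return a \code{coil_deployment}-like object (no insertion bookkeeping)
#' @export
simulate_rod <- function(state, natural, spec, config = simulation_config(),
                         n_steps, wall = NULL, clamp = integer(0),
                         contact = TRUE) {
  chain <- build_chain(list(list(spec = spec, shape = natural)))
  num <- resolve_numerics(config, chain, chain$mass, spec$D3)
  N <- chain$N
  clampv <- integer(N); clampv[clamp] <- 1L
  rodl <- list(x = state$x, u = state$u, v = state$v, vel = state$vel,
               phi = state$phi, rest_edge_lengths = chain$elbar,
               voronoi = chain$vor, kbar = chain$kbar, alpha = chain$alpha,
               b = chain$b, beta = chain$beta,
               virtual_edge = chain$virt, mass = chain$mass,
               clamp = clampv, arc = chain$arc)
  wm <- mesh_or_empty(wall)
  walls <- list(dome_vertices = wm$v, dome_faces = wm$f,
                vessel_vertices = wm$v, vessel_faces = wm$f)
  cp <- resolve_contact_params(config$friction, spec, mean(chain$elbar))
  cfg <- list(dt = num$dt, v_push = 0, n_insert = n_steps, n_post = 0,
              record_every = record_stride(config, n_steps),
              eta_x = num$eta_x, eta_phi = num$eta_phi,
              gravity = config$gravity, s_head = 0, contact = isTRUE(contact))
  res <- cpp_run_deployment(rodl, list(active = FALSE), walls, cp,
                            config$literal_wall, cfg)
  as_deployment(res, chain, state, config, num, domain = NULL,
                n_insert = n_steps, n_post = 0)
}

record_stride <- function(config, n_total) {
  if (!is.null(config$record_every)) return(config$record_every)
  max(1, floor(n_total / 250))
}

#' Deploy one or more coils into an aneurysm
#'
#' Full insertion pipeline: the coil chain starts inside the micro-catheter
#' and is pushed out at constant speed; nodes inside the catheter are
#' kinematic (velocity along the local spline tangent), released nodes obey
#' the damped rod dynamics with octree contact against the neck-cut dome,
#' the catheter tube and the coil itself.  After the last node is released,
#' an additional \code{post_swap_fraction} of the insertion steps is run
#' with the full vessel geometry (catheter retracted).  Multiple coils are
#' inserted sequentially; consecutive coils are linked by virtual edges
#' excluded from both elasticity and contact.
#'
#' @param domain an \code{aneurysm_domain} (with a catheter; otherwise a
#'   \code{\link{default_catheter}} is attached)
#' @param coils a single \code{list(spec=, shape=)} pair or a list of them,
#'   in insertion order
#' @param config a \code{simulation_config}
#' @return object of class \code{coil_deployment}: final state, stretch
#'   statistics, recorded series, trajectory samples and contact
#'   diagnostics
#' @export
run_deployment <- function(domain, coils, config = simulation_config()) {
  stopifnot(inherits(domain, "aneurysm_domain"))
  if (!is.null(coils$spec)) coils <- list(coils)
  chain <- build_chain(coils)
  cath <- domain$catheter
  if (is.null(cath)) cath <- default_catheter(domain)
  num <- resolve_numerics(config, chain, chain$mass,
                          max(vapply(chain$specs, `[[`, numeric(1), "D3")))
  N <- chain$N
  elb <- mean(chain$elbar[chain$virt == 0L])
  s_head0 <- cath$arc_length - elb     # tip node one edge inside the tip
  push_arc <- chain$arc[N] + elb       # arc to push until the last node exits
  n_insert <- ceiling(push_arc / (config$v_push * num$dt))
  n_post <- ceiling(config$post_swap_fraction * n_insert)

  # initial condition: chain parked along the catheter (and its backward
  # extension), twist-free Bishop frames
  x0 <- t(vapply(seq_len(N), function(i) {
    cath_point(cath, s_head0 - chain$arc[i])
  }, numeric(3)))
  st0 <- rod_state(x0)
  vel0 <- t(vapply(seq_len(N), function(i) {
    config$v_push * cath_tangent(cath, s_head0 - chain$arc[i])
  }, numeric(3)))
  st0$vel <- vel0

  rodl <- list(x = st0$x, u = st0$u, v = st0$v, vel = st0$vel, phi = st0$phi,
               rest_edge_lengths = chain$elbar, voronoi = chain$vor,
               kbar = chain$kbar, alpha = chain$alpha, b = chain$b,
               beta = chain$beta, virtual_edge = chain$virt,
               mass = chain$mass, clamp = integer(N), arc = chain$arc)
  cathl <- list(active = TRUE, points = cath$arc_points,
                tangents = cath$arc_tangents, ds = cath$ds,
                arc_length = cath$arc_length,
                tube_vertices = cath$tube_vertices,
                tube_faces = cath$tube_faces - 1L)
  walls <- list(dome_vertices = domain$dome_mesh$vertices,
                dome_faces = domain$dome_mesh$faces - 1L,
                vessel_vertices = domain$vessel_mesh$vertices,
                vessel_faces = domain$vessel_mesh$faces - 1L)
  spec_ref <- chain$specs[[1]]
  cp <- resolve_contact_params(config$friction, spec_ref, elb)
  cfg <- list(dt = num$dt, v_push = config$v_push, n_insert = n_insert,
              n_post = n_post,
              record_every = record_stride(config, n_insert + n_post),
              eta_x = num$eta_x, eta_phi = num$eta_phi,
              gravity = config$gravity, s_head = s_head0)
  res <- cpp_run_deployment(rodl, cathl, walls, cp, config$literal_wall, cfg)
  if (res$aborted_at >= 0)
    stop(sprintf("simulation became unstable (non-finite force) at step %d",
                 as.integer(res$aborted_at)))
  as_deployment(res, chain, st0, config, num, domain, n_insert, n_post)
}

cath_point <- function(cath, s) {
  if (s <= 0) return(cath$arc_points[1, ] + s * cath$arc_tangents[1, ])
  if (s >= cath$arc_length)
    return(cath$tip + (s - cath$arc_length) * cath$tip_tangent)
  k <- s / cath$ds
  i <- min(nrow(cath$arc_points) - 1L, floor(k) + 1L)
  f <- k - (i - 1L)
  (1 - f) * cath$arc_points[i, ] + f * cath$arc_points[i + 1L, ]
}

cath_tangent <- function(cath, s) {
  if (s <= 0) return(cath$arc_tangents[1, ])
  if (s >= cath$arc_length) return(cath$tip_tangent)
  k <- s / cath$ds
  i <- min(nrow(cath$arc_tangents) - 1L, floor(k) + 1L)
  f <- k - (i - 1L)
  tv <- (1 - f) * cath$arc_tangents[i, ] + f * cath$arc_tangents[i + 1L, ]
  tv / sqrt(sum(tv^2))
}

as_deployment <- function(res, chain, st0, config, num, domain, n_insert, n_post) {
  N <- chain$N
  final <- structure(list(x = res$x, phi = res$phi, u = res$u, v = res$v,
                          vel = res$vel, release_step = res$release_step),
                     class = "rod_state")
  structure(list(state = final, chain = chain, domain = domain,
                 config = config, numerics = num,
                 n_insert = n_insert, n_post = n_post,
                 series = res$series, trajectory = res$trajectory,
                 trajectory_steps = res$trajectory_steps,
                 release_step = res$release_step,
                 stretch_sum = res$stretch_sum,
                 stretch_sumsq = res$stretch_sumsq,
                 stretch_count = res$stretch_count,
                 max_friction_ratio = res$max_friction_ratio,
                 max_pair_asymmetry = res$max_pair_asymmetry,
                 max_penetration = res$max_penetration),
            class = "coil_deployment")
}

#' @export
print.coil_deployment <- function(x, ...) {
  ss <- compute_stretch_stats(x)
  cat(sprintf("<coil_deployment> %d nodes, %d + %d steps (dt = %.3g s)\n",
              nrow(x$state$x), x$n_insert, x$n_post, x$numerics$dt))
  cat(sprintf("  mean stretch %.3f %%, total extension %.4f %%, max |penetration| %.4f mm\n",
              100 * ss$mean_stretch, 100 * ss$total_extension, x$max_penetration))
  invisible(x)
}

#' Inextensibility diagnostics of a deployment
#'
#' Per-edge relative stretch statistics accumulated from each edge's
#' release step onward:
#' time-averaged relative stretch per edge, its time standard deviation,
#' their averages over the coil length, and the total relative extension of
#' the whole coil at the final step (all as fractions; multiply by 100 for
#' percent).
#'
#' @param deployment a \code{coil_deployment}
#' @return object of class \code{stretch_stats}
#' @export
compute_stretch_stats <- function(deployment) {
  chain <- deployment$chain
  real <- chain$virt == 0L
  cnt <- deployment$stretch_count
  used <- real & cnt > 0
  if (!any(used)) warning("no edge was ever released; stretch statistics are empty")
  mean_e <- deployment$stretch_sum[used] / cnt[used]
  var_e <- pmax(0, deployment$stretch_sumsq[used] / cnt[used] - mean_e^2)
  len_fin <- edge_lengths(deployment$state)
  L <- sum(chain$elbar[real])
  dL <- abs(L - sum(len_fin[real])) / L
  structure(list(per_edge = data.frame(edge = which(used),
                                       mean = mean_e, sd = sqrt(var_e),
                                       n = cnt[used]),
                 mean_stretch = mean(mean_e),
                 sd_stretch = mean(sqrt(var_e)),
                 total_extension = dL),
            class = "stretch_stats")
}

#' @export
print.stretch_stats <- function(x, ...) {
  cat(sprintf("<stretch_stats> mean %.3f %%, sd %.3f %%, total extension %.4f %%\n",
              100 * x$mean_stretch, 100 * x$sd_stretch, 100 * x$total_extension))
  invisible(x)
}

#' Stretch statistics from a recorded edge-length history
#'
#' Same aggregation as \code{\link{compute_stretch_stats}} but computed
#' from an explicit matrix of edge lengths over time; used to cross-check
#' the accumulator path and for synthetic histories.
#'
#' @param edge_len T x (N-1) matrix of edge lengths per recorded step
#' @param rest_len rest edge lengths (N-1)
#' @param release_row first row index (1-based) at which each edge counts
#' @param L nominal coil length; default \code{sum(rest_len)}
#' @return a \code{stretch_stats}
#' @export
stretch_stats_from_lengths <- function(edge_len, rest_len, release_row = NULL, L = NULL) {
  edge_len <- as.matrix(edge_len)
  ne <- ncol(edge_len)
  if (is.null(release_row)) release_row <- rep(1L, ne)
  if (is.null(L)) L <- sum(rest_len)
  mean_e <- sd_e <- rep(NA_real_, ne)
  for (j in seq_len(ne)) {
    r <- release_row[j]
    if (r > nrow(edge_len)) next
    s <- abs(edge_len[r:nrow(edge_len), j] / rest_len[j] - 1)
    mean_e[j] <- mean(s)
    sd_e[j] <- sqrt(mean((s - mean_e[j])^2))
  }
  ok <- !is.na(mean_e)
  if (!all(ok)) warning("some edges were never released and are excluded")
  dL <- abs(L - sum(edge_len[nrow(edge_len), ])) / L
  structure(list(per_edge = data.frame(edge = which(ok), mean = mean_e[ok],
                                       sd = sd_e[ok]),
                 mean_stretch = mean(mean_e[ok]),
                 sd_stretch = mean(sd_e[ok]),
                 total_extension = dL),
            class = "stretch_stats")
}

#' Apply the catheter-insertion boundary condition to a rod state
#'
#' Nodes whose pushed arc coordinate is still short of the catheter tip are
#' kinematic: their velocity is set to the insertion speed along the local
#' catheter tangent (their rotational degrees of freedom stay free).  Nodes
#' beyond the tip evolve freely; the time step at which a node first exits
#' is recorded in \code{release_step}.  This is the standalone form of the
#' rule applied inside \code{\link{run_deployment}}; membership is tracked
#' by pushed arc length, never by geometric containment.
#'
#' @param state a \code{rod_state}
#' @param catheter a \code{catheter_spline}
#' @param config a \code{simulation_config} (uses \code{v_push} and
#'   \code{dt}; \code{dt} must be set explicitly here)
#' @param step_index current time-step index n (0-based)
#' @param arc rest arc coordinate of each node from the leading tip;
#'   default cumulative current edge lengths
#' @param s_head0 arc position of node 1 at step 0; default one mean edge
#'   short of the catheter tip
#' @return the state with kinematic velocities imposed and
#'   \code{release_step} updated
#' @export
apply_insertion_bc <- function(state, catheter, config, step_index,
                               arc = NULL, s_head0 = NULL) {
  if (is.null(config$dt)) stop("config$dt must be set for the standalone insertion rule")
  N <- nrow(state$x)
  if (is.null(arc)) arc <- c(0, cumsum(edge_lengths(state)))
  if (is.null(s_head0)) s_head0 <- catheter$arc_length - mean(edge_lengths(state))
  shead <- s_head0 + config$v_push * config$dt * step_index
  for (i in seq_len(N)) {
    s_i <- shead - arc[i]
    if (s_i < catheter$arc_length) {
      state$vel[i, ] <- config$v_push * cath_tangent(catheter, s_i)
    } else if (state$release_step[i] < 0L) {
      state$release_step[i] <- as.integer(step_index)
    }
  }
  state
}
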