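## Reproducible scenario running: YAML configs with explicit units in the
## key names, subcommands, manifests.  All randomness of a scenario flows
## from its single seed through named substreams.

#' Read a scenario description
#'
#' A scenario is a YAML file (or an equivalent named list) with blocks
#' \code{geometry} (either \code{mesh_*} paths or \code{synthetic}
#' parameters), \code{coils} (a list of coil blocks with diameters in mm,
#' modulus in GPa and either an explicit \code{length_mm} or a
#' \code{packing_density}), optional \code{catheter}, \code{simulation}
#' and \code{occlusion} blocks, and a top-level \code{seed}.
#'
#' @param source path to a YAML file or a named list
#' @return object of class \code{coil_scenario}
#' @export
read_scenario <- function(source) {
  sc <- if (is.character(source)) yaml::read_yaml(source) else source
  if (is.null(sc$seed)) sc$seed <- 1L
  structure(sc, class = "coil_scenario")
}

scenario_domain <- function(sc) {
  seed_geom <- sc$seed * 1000L + 1L
  g <- sc$geometry
  if (!is.null(g$mesh_dome)) {
    if (!file.exists(g$mesh_dome)) stop("mesh file not found: ", g$mesh_dome)
    dome <- load_mesh(g$mesh_dome)
    vessel <- if (!is.null(g$mesh_vessel)) load_mesh(g$mesh_vessel) else dome
    np <- list(point = as.double(g$neck_point_mm), normal = as.double(g$neck_normal))
    domain <- aneurysm_domain(dome, vessel, np, g$neck_radius_mm)
  } else {
    s <- g$synthetic
    if (is.null(s)) s <- list()
    domain <- make_synthetic_aneurysm(
      dome_radius = s$dome_radius_mm %||% 2.5,
      neck_radius = s$neck_radius_mm %||% 1,
      resolution = s$resolution %||% 40,
      seed = seed_geom,
      bump_amplitude = s$bump_amplitude %||% 0)
  }
  cb <- sc$catheter
  cath <- if (!is.null(cb$control_points_mm)) {
    catheter_spline(matrix(unlist(cb$control_points_mm), 3, 3, byrow = TRUE),
                    radius = cb$radius_mm %||% 0.35)
  } else default_catheter(domain)
  if (!is.null(cb$tip_perturbation_mm) && cb$tip_perturbation_mm > 0)
    cath <- perturb_catheter_tip(cath, cb$tip_perturbation_mm,
                                 seed = sc$seed * 1000L + 2L)
  domain$catheter <- cath
  domain
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_coils <- function(sc, domain) {
  lapply(sc$coils, function(cb) {
    D2 <- cb$D2_mm %||% 0.305
    L <- cb$length_mm %||% coil_length_for_pd(domain, D2, cb$packing_density %||% 0.15)
    spec <- coil_spec(D1 = cb$D1_mm %||% 0.05, D2 = D2, D3 = cb$D3_mm %||% 2,
                      length = L,
                      E_w = (cb$E_w_GPa %||% 168) * 1e9,
                      mu_w = cb$mu_w %||% 0.38,
                      pitch = cb$pitch %||% 1.1,
                      alpha = cb$alpha %||% 0.1)
    nn <- cb$n_nodes %||% max(30L, round(L / (cb$edge_length_mm %||% 0.45)))
    shape <- shape_program(cb$shape %||% "helix", D3 = spec$D3, length = L,
                           n_nodes = nn)
    list(spec = spec, shape = shape)
  })
}

scenario_config <- function(sc) {
  sb <- sc$simulation %||% list()
  simulation_config(dt = sb$dt_s, v_push = sb$v_push_mm_s %||% 20,
                    post_swap_fraction = sb$post_swap_fraction %||% 0.10,
                    gravity = sb$gravity_mm_s2 %||% c(0, 0, 0),
                    seed = sc$seed,
                    literal_wall = isTRUE(sb$literal_wall))
}

scenario_manifest <- function(sc, out_dir) {
  canon <- jsonlite::toJSON(unclass(sc), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(canon, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(config_md5 = h, seed = sc$seed,
       package = "coildeploy",
       version = as.character(utils::packageVersion("coildeploy")))
}

#' Run a full simulation scenario
#'
#' Deploys the scenario's coils, computes stretch diagnostics and the
#' occlusion report, and (optionally) writes trajectory, series, voxel
#' field, report and manifest files.
#'
#' @param scenario path to a scenario YAML or a \code{coil_scenario}
#' @param out_dir output directory; NULL skips file output
#' @return list with the deployment, stretch stats, occlusion report and
#'   manifest
#' @export
cmd_simulate <- function(scenario, out_dir = NULL) {
  sc <- read_scenario(scenario)
  domain <- scenario_domain(sc)
  coils <- scenario_coils(sc, domain)
  config <- scenario_config(sc)
  dep <- run_deployment(domain, coils, config)
  ss <- compute_stretch_stats(dep)
  ob <- sc$occlusion %||% list()
  rep <- occlusion_report(dep, N_V = ob$N_V %||% 70)
  manifest <- scenario_manifest(sc, out_dir)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_series_csv(dep, file.path(out_dir, "series.csv"))
    write_trajectory_vtk(dep, file.path(out_dir, "trajectory"))
    write_vtk_structured_points(rep$voxel_field, file.path(out_dir, "voxels.vtk"))
    jsonlite::write_json(
      list(class = rep$class,
           packing_density = list(core = rep$pd_core, boundary = rep$pd_boundary,
                                  sphere = rep$pd_sphere, total = rep$pd_total),
           volume_fractions = list(BA = rep$psi_BA, CA = rep$psi_CA,
                                   AA = rep$psi_AA, SS = rep$psi_SS),
           neck_sphere = rep$partition$sphere_def,
           stretch = list(mean_percent = 100 * ss$mean_stretch,
                          sd_percent = 100 * ss$sd_stretch,
                          total_extension_percent = 100 * ss$total_extension)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(deployment = dep, stretch = ss, report = rep,
                 manifest = manifest))
}

#' Run a scaled-down parameter sweep from a scenario
#'
#' @param scenario path or \code{coil_scenario}
#' @param variable "E_w", "D2" or "D3"
#' @param interval length-2 range (GPa for E_w, mm otherwise)
#' @param n_samples number of deployments
#' @param out_dir optional output directory (CSV of bins + samples)
#' @param n_bins,min_per_bin binning protocol
#' @return a \code{sweep_result}
#' @export
cmd_sweep <- function(scenario, variable, interval, n_samples, out_dir = NULL,
                      n_bins = 5, min_per_bin = 30) {
  sc <- read_scenario(scenario)
  domain <- scenario_domain(sc)
  config <- scenario_config(sc)
  base <- sc$coils[[1]]
  runner <- function(value, seed) {
    cb <- base
    if (variable == "E_w") cb$E_w_GPa <- value
    if (variable == "D2") cb$D2_mm <- value
    if (variable == "D3") cb$D3_mm <- value
    sc2 <- sc; sc2$coils <- list(cb)
    coils <- scenario_coils(sc2, domain)
    cfg <- config
    cfg$seed <- as.integer(seed %% .Machine$integer.max)
    dep <- run_deployment(domain, coils, cfg)
    rep <- occlusion_report(dep, N_V = (sc$occlusion %||% list())$N_V %||% 70)
    rep
  }
  iv <- if (variable == "E_w") interval else interval
  sw <- parameter_sweep(variable, iv, n_samples, runner, n_bins = n_bins,
                        min_per_bin = min_per_bin, seed = sc$seed, domain = domain)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sw$bins, file.path(out_dir, "sweep_bins.csv"), row.names = FALSE)
    utils::write.csv(sw$samples, file.path(out_dir, "sweep_samples.csv"), row.names = FALSE)
  }
  sw
}

#' Generate and save a synthetic aneurysm geometry
#'
#' @param out_dir output directory (dome.stl, vessel.stl, geometry.json)
#' @param ... passed to \code{\link{make_synthetic_aneurysm}}
#' @return the \code{aneurysm_domain}, invisibly
#' @export
cmd_make_geometry <- function(out_dir, ...) {
  domain <- make_synthetic_aneurysm(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_mesh(domain$dome_mesh, file.path(out_dir, "dome.stl"))
  save_mesh(domain$vessel_mesh, file.path(out_dir, "vessel.stl"))
  jsonlite::write_json(list(V_A_mm3 = domain$V_A,
                            neck_radius_mm = domain$neck_radius,
                            neck_point_mm = domain$neck_plane$point,
                            neck_normal = domain$neck_plane$normal),
                       file.path(out_dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(domain)
}

#' Classify a stored voxel field
#'
#' @param voxel_base base path of a \code{\link{write_voxel_dump}} pair
#' @param dome_mesh path to the dome mesh
#' @param neck_point,neck_normal,neck_radius neck description
#' @return an \code{occlusion_report}-like list with the class label
#' @export
cmd_classify <- function(voxel_base, dome_mesh, neck_point, neck_normal, neck_radius) {
  hdr <- jsonlite::read_json(paste0(voxel_base, ".json"), simplifyVector = TRUE)
  vals <- as.numeric(readLines(paste0(voxel_base, ".txt")))
  vf <- voxel_field(vals, hdr$origin, hdr$a, hdr$N_V)
  dome <- load_mesh(dome_mesh)
  domain <- aneurysm_domain(dome, dome,
                            list(point = neck_point, normal = neck_normal),
                            neck_radius)
  part <- partition_regions(domain, vf)
  fr <- volume_fractions(vf, part)
  cls <- classify_rroc(fr$pd_core, fr$pd_boundary, fr$pd_sphere)
  c(fr, list(class = cls))
}

#' Run the built-in property suite
#'
#' Quick self-checks of the core numerics: gradient vs finite differences,
#' octree vs brute-force collision detection, zero twist of propagated
#' Bishop frames, capsule voxel volume, the classifier truth table and the
#' stiffness-ratio identity.  Prints a pass/fail table.
#'
#' @param seed integer seed
#' @return data frame of check results, invisibly
#' @export
cmd_validate <- function(seed = 1L) {
  checks <- list()
  add <- function(name, ok) checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = ok)

  # gradient vs central finite differences on a random rod
  ok <- with_seed(seed, {
    errs <- vapply(1:5, function(k) {
      r <- random_test_rod(8L)
      max_grad_fd_error(r$state, r$natural, r$spec)
    }, numeric(1))
    all(errs < 1e-5)
  })
  add("gradient matches finite differences (rel 1e-5)", ok)

  # octree candidates vs brute force
  ok <- with_seed(seed + 1L, {
    all(vapply(1:10, function(k) {
      X <- matrix(cumsum(rnorm(3 * 60, sd = 0.4)), ncol = 3)
      st <- rod_state(X)
      spec <- coil_spec(0.05, 0.305, 2, length = 10)
      got <- candidate_pairs_coil(st, spec, rest_len = 0.5)
      want <- brute_candidate_pairs(X, 0.5, spec$D2)
      setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
    }, logical(1)))
  })
  add("octree candidates equal brute force", ok)

  # Bishop frames are twist free
  ok <- with_seed(seed + 2L, {
    th <- seq(0, 6 * pi, length.out = 50)
    st <- rod_state(cbind(cos(th), sin(th), 0.2 * th))
    all(abs(vapply(2:(length(th) - 1L), function(j) measure_twist(st, j),
                   numeric(1))) < 1e-10)
  })
  add("propagated Bishop frame has zero twist", ok)

  # capsule voxel volume
  ok <- {
    vf <- voxelize_coil(rbind(c(-1, 0, 0), c(1, 0, 0)), D2 = 0.4,
                        cube = list(origin = c(-2, -2, -2), a = 4), N_V = 160)
    vol <- sum(vf$values) * vf$h^3
    exact <- pi * 0.2^2 * 2 + 4 / 3 * pi * 0.2^3
    abs(vol - exact) / exact < 0.05
  }
  add("capsule voxel volume within 5%", ok)

  # classifier truth table
  ok <- {
    lab <- function(co, bo, sp) classify_rroc(co, bo, sp)
    all(lab(.25, .19, .19) == "I", lab(.25, .19, .10) == "II",
        lab(.10, .19, .19) == "IIIa", lab(.10, .19, .10) == "IIIa",
        lab(.25, .10, .19) == "IIIb", lab(.25, .10, .10) == "IIIb",
        lab(.10, .10, .19) == "Fail", lab(.10, .10, .10) == "Fail")
  }
  add("classifier truth table", ok)

  # stiffness ratio identity
  ok <- {
    st <- stiffness_from_microstructure(0.05, 0.305, 168e9, 0.38, 1.1)
    abs(st$beta / st$b - (2 + 0.38) / 2) < 1e-12
  }
  add("beta/b = (2 + mu)/2", ok)

  out <- do.call(rbind, checks)
  status <- ifelse(out$pass, "PASS", "FAIL")
  cat(sprintf("%-50s %s\n", out$check, status), sep = "")
  invisible(out)
}

## internal helpers shared with the test suite --------------------------------

random_test_rod <- function(N) {
  base <- cbind(seq(0, 1, length.out = N), 0, 0) +
    matrix(rnorm(3 * N, sd = 0.08), ncol = 3)
  nat_base <- cbind(seq(0, 1, length.out = N), 0, 0) +
    matrix(rnorm(3 * N, sd = 0.05), ncol = 3)
  natural <- natural_shape_from_vertices(nat_base)
  spec <- coil_spec(0.05, 0.305, 2, length = sum(natural$rest_edge_lengths))
  state <- rod_state(base, edge_angles = runif(N - 1, -0.5, 0.5))
  list(state = state, natural = natural, spec = spec)
}

# Finite-difference check of the analytic gradient; returns the max
# relative error over all position and angle components.
max_grad_fd_error <- function(state, natural, spec, h = 1e-7) {
  g <- grad_energy(state, natural, spec)
  scale <- max(abs(g$grad_x), abs(g$grad_phi), 1e-8)
  energy_at <- function(x) {
    fr <- cpp_transport_frames(state$x, x, state$u, state$v)
    st2 <- state; st2$x <- x; st2$u <- fr$U; st2$v <- fr$V
    total_energy(st2, natural, spec)
  }
  N <- nrow(state$x)
  hh <- h * max(1, max(abs(state$x)))
  errx <- 0
  for (i in seq_len(N)) for (d in 1:3) {
    xp <- state$x; xp[i, d] <- xp[i, d] + hh
    xm <- state$x; xm[i, d] <- xm[i, d] - hh
    fd <- (energy_at(xp) - energy_at(xm)) / (2 * hh)
    errx <- max(errx, abs(fd - g$grad_x[i, d]) / scale)
  }
  errp <- 0
  for (j in seq_len(N - 1L)) {
    pp <- state$phi; pp[j] <- pp[j] + h
    pm <- state$phi; pm[j] <- pm[j] - h
    stp <- state; stp$phi <- pp
    stm <- state; stm$phi <- pm
    fd <- (total_energy(stp, natural, spec) - total_energy(stm, natural, spec)) / (2 * h)
    errp <- max(errp, abs(fd - g$grad_phi[j]) / scale)
  }
  max(errx, errp)
}

# O(N^2) reference implementation of the broad-phase condition.
brute_candidate_pairs <- function(X, rest_len, D2) {
  ne <- nrow(X) - 1L
  ctr <- (X[-1, , drop = FALSE] + X[-nrow(X), , drop = FALSE]) / 2
  bound <- sqrt((rest_len / 2)^2 + D2^2)
  out <- NULL
  for (i in seq_len(ne - 2L)) {
    d <- sqrt(rowSums((ctr[(i + 2L):ne, , drop = FALSE] -
                         matrix(ctr[i, ], ne - i - 1L, 3, byrow = TRUE))^2))
    j <- which(d <= bound)
    if (length(j)) out <- rbind(out, cbind(i, (i + 1L) + j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}
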