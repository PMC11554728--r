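# Time integration, insertion boundary conditions and stretch diagnostics.

test_that("free flight advances positions by dt * v with the new velocity", {
  nat <- natural_shape_from_vertices(cbind(seq(0, 10, length.out = 21), 0, 0))
  spec <- coil_spec(0.05, 0.305, 2, length = 10)
  st <- rod_state(nat$natural_vertices)
  st$vel <- matrix(rep(c(1, 2, 3), each = 21), 21, 3)
  cfg <- simulation_config(dt = 1e-4, eta_x = 0, eta_phi = 1)
  st2 <- rod_step(st, nat, spec, config = cfg)
  expect_equal(st2$x, st$x + 1e-4 * st$vel, tolerance = 1e-12)
  expect_equal(st2$vel, st$vel, tolerance = 1e-12)
})

test_that("viscous damping contracts velocities by exactly (1 - dt eta / m)", {
  nat <- natural_shape_from_vertices(cbind(seq(0, 10, length.out = 21), 0, 0))
  spec <- coil_spec(0.05, 0.305, 2, length = 10)
  m <- coildeploy:::node_masses(nat, spec)[10]
  dt <- 1e-6
  eta <- 0.004 * m / dt
  st <- rod_state(nat$natural_vertices)
  st$vel <- matrix(rnorm(63), 21, 3)
  st2 <- rod_step(st, nat, spec,
                  config = simulation_config(dt = dt, eta_x = eta, eta_phi = 1))
  expect_equal(st2$vel, (1 - 0.004) * st$vel, tolerance = 1e-12)
})

test_that("relative twist decays geometrically under the angle gradient flow", {
  # two-edge rod, pure twist tau = phi2 - phi1; both angles are free, so
  # tau' = tau (1 - 2 dt beta / (eta_phi lbar)) per step (closed form)
  nat <- natural_shape_from_vertices(cbind(0:2, 0, 0))
  spec <- coil_spec(0.05, 0.305, 2, length = 2)
  dt <- 1e-6; eta_phi <- 5e-4
  fac <- 1 - 2 * dt * spec$beta / (eta_phi * 1)
  st <- rod_state(cbind(0:2, 0, 0), edge_angles = c(0, 0.3))
  cfg <- simulation_config(dt = dt, eta_x = 0, eta_phi = eta_phi)
  for (k in 1:3) {
    st <- rod_step(st, nat, spec, config = cfg)
    expect_equal(measure_twist(st, 2), 0.3 * fac^k, tolerance = 1e-10)
  }
})

test_that("strain + kinetic energy is non-increasing for a damped free rod", {
  # smooth transverse perturbation of a straight rod (no self-contact, so
  # the only forces are elastic and viscous)
  spec <- coil_spec(0.05, 0.305, 2, length = 12)
  xs <- seq(0, 12, length.out = 28)
  hel <- natural_shape_from_vertices(cbind(xs, 0, 0))
  st <- rod_state(cbind(xs, 0.4 * sin(pi * xs / 12), 0.2 * sin(2 * pi * xs / 12)))
  dep <- simulate_rod(st, hel, spec, simulation_config(record_every = 500),
                      n_steps = 20000)
  s <- dep$series
  etot <- s$axial_energy + s$bending_energy + s$twist_energy + s$kinetic_energy
  expect_true(all(diff(etot) <= 1e-9 * etot[1]))
})

test_that("a cantilever under gravity reaches the Euler-Bernoulli tip deflection", {
  spec <- coil_spec(0.05, 0.305, 2, length = 10)
  N <- 61
  nat <- natural_shape_from_vertices(cbind(seq(0, 10, length.out = N), 0, 0))
  st <- rod_state(nat$natural_vertices)
  g <- 500   # mm/s^2, keeps the deflection in the small-deflection regime
  # near-critical damping for the slowest cantilever mode (the default is
  # tuned to coil-loop wavelengths and overdamps a free beam); self-contact
  # is off: the detection rule treats any non-adjacent edge pair as a
  # potential collision, which presumes edges no shorter than D2
  dep <- simulate_rod(st, nat, spec,
                      simulation_config(gravity = c(0, 0, -g), record_every = 50000,
                                        eta_x = 1e-5),
                      n_steps = 250000, clamp = c(1, 2), contact = FALSE)
  w <- spec$mass_per_length * g               # load per unit length (mN/mm)
  # with uniform nodal lumping and the two-node clamp, the discrete beam
  # converges to the closed form evaluated at the full length
  L <- 10
  delta <- w * L^4 / (8 * spec$b)
  tip <- dep$state$x[N, 3] - dep$state$x[2, 3]
  expect_lt(abs(delta) / L, 0.02)              # small-deflection regime
  expect_equal(-tip, delta, tolerance = 0.05)
})

test_that("insertion releases nodes in order at the pushed-arc rate", {
  res <- small_simulation()
  dep <- res$deployment
  rel <- dep$release_step
  expect_true(all(diff(rel) >= 0))             # tip first, tail last
  expect_true(all(rel >= 0))                   # everyone released
  # release spacing ~ rest edge length / (v dt)
  expected_gap <- mean(dep$chain$elbar) / (dep$config$v_push * dep$numerics$dt)
  gaps <- diff(rel)
  expect_equal(mean(gaps), expected_gap, tolerance = 0.05)
  # inserted arc length grows at v_push within one edge length
  s <- dep$series
  sel <- s$inserted_length > 0 & s$step < dep$n_insert
  pred <- dep$config$v_push * s$time[sel] - (dep$config$v_push * s$time[sel])[1] +
    s$inserted_length[sel][1]
  expect_lt(max(abs(s$inserted_length[sel] - pred)), mean(dep$chain$elbar) + 1e-9)
})

test_that("deployments are deterministic for identical seeds and configs", {
  a <- small_simulation()
  b <- cmd_simulate(small_scenario())
  expect_identical(a$deployment$state$x, b$deployment$state$x)
  expect_identical(a$deployment$series$max_stretch, b$deployment$series$max_stretch)
  expect_identical(a$report$class, b$report$class)
})

test_that("stretch statistics aggregate the recorded history exactly", {
  # perfectly inextensible history
  el <- matrix(1, 5, 4)
  ss <- stretch_stats_from_lengths(el, rest_len = rep(1, 4))
  expect_equal(ss$mean_stretch, 0)
  expect_equal(ss$sd_stretch, 0)
  expect_equal(ss$total_extension, 0)

  # constant 1% stretch everywhere
  ss2 <- stretch_stats_from_lengths(matrix(1.01, 5, 4), rest_len = rep(1, 4))
  expect_equal(ss2$mean_stretch, 0.01, tolerance = 1e-12)
  expect_equal(ss2$sd_stretch, 0)
  expect_equal(ss2$total_extension, 0.01, tolerance = 1e-12)

  # two-step history with stretches {0%, 2%}: mean 1%, variance 1e-4
  el3 <- rbind(rep(1, 3), rep(1.02, 3))
  ss3 <- stretch_stats_from_lengths(el3, rest_len = rep(1, 3))
  expect_equal(ss3$mean_stretch, 0.01, tolerance = 1e-12)
  expect_equal(ss3$per_edge$sd[1]^2, 1e-4, tolerance = 1e-12)

  # release masking: edges count only from their release row
  el4 <- rbind(c(2, 1), c(1.5, 1), c(1, 1))
  ss4 <- stretch_stats_from_lengths(el4, rest_len = c(1, 1),
                                    release_row = c(3L, 1L))
  expect_equal(ss4$per_edge$mean[1], 0)
})

test_that("an unreleased edge is excluded with a warning", {
  el <- matrix(1.01, 3, 2)
  expect_warning(
    ss <- stretch_stats_from_lengths(el, rest_len = c(1, 1),
                                     release_row = c(1L, 10L)),
    "never released")
  expect_equal(nrow(ss$per_edge), 1L)
})

test_that("multi-coil chains assemble virtual edges excluded from elasticity", {
  spec <- coil_spec(0.05, 0.305, 2, length = 5)
  sh <- shape_program("straight", D3 = 2, length = 5, n_nodes = 6)
  chain <- coildeploy:::build_chain(list(list(spec = spec, shape = sh),
                                         list(spec = spec, shape = sh)))
  expect_equal(chain$N, 12L)
  expect_equal(sum(chain$virt), 1L)
  expect_equal(which(chain$virt == 1L), 6L)
  expect_equal(chain$alpha[6], 0)
  # arc coordinates keep spacing across the connector
  expect_equal(length(chain$arc), 12L)
  expect_true(all(diff(chain$arc) > 0))
})

test_that("the insertion rule sets kinematic velocities and release bookkeeping", {
  P <- rbind(c(0, 0, -8), c(0, 0, -3), c(0, 0, 2))   # straight catheter up +z
  cath <- catheter_spline(P)
  st <- rod_state(cbind(0, 0, seq(-7, -3, length.out = 9)))
  cfg <- simulation_config(dt = 1e-3, v_push = 5)
  # all nodes inside: every velocity equals v_push along the tangent (+z)
  st2 <- apply_insertion_bc(st, cath, cfg, step_index = 0,
                            arc = seq(0, 4, by = 0.5), s_head0 = 2)
  expect_equal(st2$vel, matrix(rep(c(0, 0, 5), each = 9), 9, 3), tolerance = 1e-9)
  expect_true(all(st2$release_step == -1L))
  # push far enough that the two leading nodes exit: they are released at
  # the current step and their velocities are no longer prescribed
  n_exit <- ceiling((cath$arc_length - 2 + 0.5 + 1e-9) / (5 * 1e-3))
  st3 <- apply_insertion_bc(st, cath, cfg, step_index = n_exit,
                            arc = seq(0, 4, by = 0.5), s_head0 = 2)
  expect_equal(st3$release_step[1:2], rep(as.integer(n_exit), 2))
  expect_true(all(st3$release_step[3:9] == -1L))
  expect_equal(st3$vel[3, ], c(0, 0, 5), tolerance = 1e-9)
})
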