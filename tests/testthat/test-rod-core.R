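# Discrete rod geometry and elasticity kernels.

test_that("curvature binormal matches closed forms and errors on kinks", {
  expect_equal(curvature_binormal(c(1, 0, 0), c(1, 0, 0)), c(0, 0, 0))
  expect_equal(curvature_binormal(c(1, 0, 0), c(0, 1, 0)), c(0, 0, 2))
  expect_error(curvature_binormal(c(1, 0, 0), c(-1, 0, 0)), "degenerate")
})

test_that("polygon-on-circle curvature converges to 1/R", {
  R <- 1.7
  for (n in c(8, 32, 128)) {
    th <- 2 * pi * (0:2) / n
    tgs <- cbind(-sin(th + pi / n), cos(th + pi / n), 0)   # edge tangents
    kb <- curvature_binormal(tgs[1, ], tgs[2, ])
    lbar <- 2 * R * sin(pi / n)
    expect_equal(sqrt(sum(kb^2)) / lbar, 1 / R,
                 tolerance = (pi / n)^2)
  }
})

test_that("discrete curvatures behave under frames and planar arcs", {
  # straight rod: zero curvature for any edge angles
  st <- rod_state(cbind(0:3, 0, 0), edge_angles = c(0.3, -0.7, 1.1))
  expect_equal(discrete_curvatures(st, 2), c(0, 0))

  # planar arc with D2 aligned to the arc binormal: kappa2 = 0, kappa1 = |kb|
  # (seed U radially in-plane, so V = t x U is the +/- z binormal = D2)
  th <- seq(0, pi / 2, length.out = 6)
  st2 <- rod_state(cbind(cos(th), sin(th), 0), u0 = c(1, 0, 0))
  tt <- diff(st2$x); tt <- tt / sqrt(rowSums(tt^2))
  kb <- curvature_binormal(tt[2, ], tt[3, ])
  k <- discrete_curvatures(st2, 3)
  expect_equal(k[2], 0, tolerance = 1e-12)
  expect_equal(abs(k[1]), sqrt(sum(kb^2)), tolerance = 1e-12)

  # rotating all material frames by theta rotates (k1, k2), preserving norm
  set.seed(7)
  st3 <- rod_state(random_curve(8))
  k0 <- discrete_curvatures(st3, 4)
  for (theta in seq(0.2, 2 * pi, length.out = 9)) {
    st4 <- st3
    st4$phi <- st3$phi + theta
    k1 <- discrete_curvatures(st4, 4)
    Rm <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    expect_equal(k1, as.numeric(Rm %*% k0), tolerance = 1e-10)
    expect_equal(sqrt(sum(k1^2)), sqrt(sum(k0^2)), tolerance = 1e-10)
  }
})

test_that("Rodrigues rotation maps tangents and preserves norms", {
  expect_equal(rodrigues_rotation(c(1, 0, 0), c(1, 0, 0)), diag(3))
  R90 <- rodrigues_rotation(c(1, 0, 0), c(0, 1, 0))
  # axis-angle construction about +z
  expect_equal(R90, matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
               tolerance = 1e-12)
  set.seed(11)
  for (k in 1:100) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    R <- rodrigues_rotation(a, b)
    expect_equal(as.numeric(R %*% a), b, tolerance = 1e-10)
    v <- rnorm(3)
    expect_equal(sqrt(sum((R %*% v)^2)), sqrt(sum(v^2)), tolerance = 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
})

test_that("Bishop propagation is orthonormal, twist-free and holonomy-free on planar loops", {
  set.seed(3)
  for (k in 1:10) {
    st <- rod_state(random_curve(30))
    tt <- diff(st$x); tt <- tt / sqrt(rowSums(tt^2))
    # right-handed orthonormal triads
    expect_lt(max(abs(rowSums(st$u * st$v))), 1e-10)
    expect_lt(max(abs(rowSums(st$u * tt))), 1e-10)
    expect_lt(max(abs(rowSums(st$u^2) - 1)), 1e-10)
    w <- vapply(2:29, function(j) measure_twist(st, j), numeric(1))
    expect_lt(max(abs(w)), 1e-10)
  }
  # straight rod: all triads identical
  st <- rod_state(cbind(0:5, 0, 0))
  expect_equal(st$u, matrix(st$u[1, ], 5, 3, byrow = TRUE))
  # closed planar square: transported frame returns to the start
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
              c(1, 0, 0))
  stsq <- rod_state(sq)
  expect_equal(stsq$u[5, ], stsq$u[1, ], tolerance = 1e-12)
})

test_that("measured twist is the wrapped angle increment", {
  st <- rod_state(random_curve(6), edge_angles = rep(0.4, 5))
  expect_equal(vapply(2:5, function(j) measure_twist(st, j), numeric(1)),
               rep(0, 4), tolerance = 1e-12)
  st2 <- rod_state(cbind(0:2, 0, 0), edge_angles = c(0, pi / 4))
  expect_equal(measure_twist(st2, 2), pi / 4)
})

cross_v <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

test_that("a frame pointing at the helix axis has constant twist per edge", {
  r <- 1; cpit <- 0.15
  n_per_turn <- 24
  th <- seq(0, 4 * pi, by = 2 * pi / n_per_turn)
  X <- cbind(r * cos(th), r * sin(th), cpit * th)
  st <- rod_state(X)
  N <- nrow(X)
  # build the axis-pointing material frame: D1 = projection of (-x, -y, 0)
  tt <- diff(X); tt <- tt / sqrt(rowSums(tt^2))
  phi <- numeric(N - 1)
  for (j in seq_len(N - 1)) {
    mid <- (X[j, ] + X[j + 1, ]) / 2
    d1 <- c(-mid[1], -mid[2], 0)
    d1 <- d1 - sum(d1 * tt[j, ]) * tt[j, ]
    d1 <- d1 / sqrt(sum(d1^2))
    phi[j] <- atan2(sum(cross_v(st$u[j, ], d1) * tt[j, ]), sum(st$u[j, ] * d1))
  }
  st$phi <- phi
  tw <- vapply(2:(N - 1), function(j) measure_twist(st, j), numeric(1))
  expect_lt(diff(range(tw)), 1e-6)
  # the axis-pointing frame is the Frenet frame, whose twist rate is the
  # geometric torsion c/(r^2 + c^2); per edge that is
  # 2 pi sin(pitch angle) / (edges per turn)
  expect_equal(mean(tw), 2 * pi * cpit / sqrt(r^2 + cpit^2) / n_per_turn,
               tolerance = 0.01)
})

test_that("total energy matches hand-evaluated components", {
  nat <- natural_shape_from_vertices(cbind(0:2, 0, 0))
  spec <- coil_spec(0.05, 0.305, 2, length = 2)

  # at the natural shape with zero angles the energy vanishes
  st <- rod_state(nat$natural_vertices)
  expect_equal(total_energy(st, nat, spec), 0)

  # pure twist: E = beta * theta^2 / (2 lbar)
  theta <- 0.37
  st2 <- rod_state(cbind(0:2, 0, 0), edge_angles = c(0, theta))
  E <- total_energy(st2, nat, spec, parts = TRUE)
  expect_equal(as.numeric(E), spec$beta * theta^2 / 2)
  expect_equal(unname(attr(E, "parts")["twist"]), as.numeric(E))

  # uniform stretch by (1 + s): E = sum alpha s^2 |ebar| / 2
  s <- 0.013
  st3 <- rod_state(cbind((0:2) * (1 + s), 0, 0))
  expect_equal(total_energy(st3, nat, spec),
               2 * spec$alpha_abs * s^2 / 2, tolerance = 1e-12)
})

test_that("energy is invariant under rigid-body motion", {
  set.seed(19)
  for (k in 1:5) {
    r <- coildeploy:::random_test_rod(9L)
    E0 <- total_energy(r$state, r$natural, r$spec)
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    R <- rodrigues_rotation(a, b)
    shift <- rnorm(3, sd = 5)
    st2 <- r$state
    st2$x <- r$state$x %*% t(R) + matrix(shift, nrow(r$state$x), 3, byrow = TRUE)
    st2$u <- r$state$u %*% t(R)
    st2$v <- r$state$v %*% t(R)
    E1 <- total_energy(st2, r$natural, r$spec)
    expect_equal(E1, E0, tolerance = 1e-8)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(23)
  errs <- vapply(1:5, function(k) {
    r <- coildeploy:::random_test_rod(sample(5:12, 1))
    coildeploy:::max_grad_fd_error(r$state, r$natural, r$spec)
  }, numeric(1))
  expect_lt(max(errs), 1e-5)
  # twist-only perturbation: grad_phi follows the telescoping beta*tau/lbar
  nat <- natural_shape_from_vertices(cbind(0:3, 0, 0))
  spec <- coil_spec(0.05, 0.305, 2, length = 3)
  st <- rod_state(cbind(0:3, 0, 0), edge_angles = c(0, 0.2, 0.5))
  g <- grad_energy(st, nat, spec)
  tau <- c(0.2, 0.3)   # at interior nodes 2, 3
  expect_equal(g$grad_phi,
               c(-spec$beta * tau[1], spec$beta * tau[1] - spec$beta * tau[2],
                 spec$beta * tau[2]),
               tolerance = 1e-12)
  expect_equal(g$grad_x, matrix(0, 4, 3), tolerance = 1e-12)
})

test_that("stiffness constants follow the torsion-spring formulas", {
  st <- stiffness_from_microstructure(0.05, 0.305, 168e9, 0.38, 1.1)
  # single-formula hand evaluation:
  # b = 168000 * 0.05^4 * 0.055 / (32 * 2.38 * 0.305) N mm^2
  expect_equal(st$b, 0.05775 / 23.2288, tolerance = 1e-10)
  expect_equal(st$beta, 0.05775 / 19.52, tolerance = 1e-10)
  expect_equal(st$beta / st$b, (2 + 0.38) / 2, tolerance = 1e-12)
  st0 <- stiffness_from_microstructure(0.05, 0.305, 168e9, 0, 1.1)
  expect_equal(st0$beta / st0$b, 1, tolerance = 1e-12)
  expect_error(stiffness_from_microstructure(-1, 0.3, 1e9, 0.3), "positive")
  expect_error(stiffness_from_microstructure(0.05, 0.3, 1e9, 0.3, p = 0.9), "pitch")
})

test_that("coil_spec validates diameters and derives masses", {
  expect_error(coil_spec(0.4, 0.305, 2, length = 10), "D1 < D2 < D3")
  sp <- coil_spec(0.05, 0.305, 2, length = 10)
  # platinum wire: rho * A * (pi D2 / p_c) per coil length
  expect_equal(sp$mass_per_length,
               2.145e-5 * pi * 0.05^2 / 4 * pi * 0.305 / 0.055,
               tolerance = 1e-12)
})
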