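# Collision detection and contact/friction forces.

test_that("segment minimum distance matches closed forms", {
  r <- min_distance_segments(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0.3), c(1, 0, 0.3))
  expect_equal(r$distance, 0.3)
  r2 <- min_distance_segments(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0))
  expect_equal(r2$distance, 0)
  expect_error(min_distance_segments(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "zero-length")
})

test_that("segment distance agrees with a dense-sampling oracle", {
  set.seed(31)
  for (k in 1:20) {
    p1 <- rnorm(3); q1 <- rnorm(3); p2 <- rnorm(3); q2 <- rnorm(3)
    d <- min_distance_segments(p1, q1, p2, q2)$distance
    ds <- sampling_seg_dist(p1, q1, p2, q2)
    expect_lt(abs(d - ds), 1e-3)
    expect_lte(d, ds + 1e-12)   # exact minimum can only be smaller
  }
})

test_that("octree candidates equal the brute-force broad phase", {
  set.seed(41)
  spec <- coil_spec(0.05, 0.305, 2, length = 10)
  for (k in 1:15) {
    X <- random_tangle(80)
    st <- rod_state(X)
    got <- candidate_pairs_coil(st, spec, rest_len = 0.35)
    want <- oracle_candidate_pairs(X, 0.35, spec$D2)
    expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
    # adjacent edges never appear
    if (nrow(got)) expect_true(all(got[, 2] - got[, 1] > 1))
  }
})

test_that("narrow-phase coil collisions match brute force with overlap D2 - d", {
  set.seed(43)
  spec <- coil_spec(0.05, 0.305, 2, length = 10)
  for (k in 1:8) {
    X <- random_tangle(60, step = 0.3)
    st <- rod_state(X)
    got <- detect_coil_collisions(st, spec, rest_len = 0.3)
    want <- oracle_detect_coil(X, spec$D2, rest_len = 0.3)
    nwant <- if (is.null(want)) 0L else nrow(want)
    expect_equal(nrow(got), nwant)
    if (nwant) {
      got <- got[order(got$i, got$j), ]
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(got$i, want[, 1])
      expect_equal(got$j, want[, 2])
      expect_equal(got$distance, want[, 3], tolerance = 1e-9)
      expect_equal(got$overlap, spec$D2 - want[, 3], tolerance = 1e-9)
    }
  }
})

test_that("boundary cases of coil collision detection", {
  spec <- coil_spec(0.05, 0.305, 2, length = 10)
  # two parallel segments (edges 1 and 5) at distance exactly D2
  st <- rod_state(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(2.2, 1, 1),
                        c(0, 0, spec$D2), c(1, 0, spec$D2)))
  got <- detect_coil_collisions(st, spec, rest_len = 1)
  hit <- got[got$i == 1 & got$j == 5, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$overlap, 0, tolerance = 1e-12)
  # at 1.01 * D2: no contact
  st2 <- rod_state(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(2.2, 1, 1),
                         c(0, 0, 1.01 * spec$D2), c(1, 0, 1.01 * spec$D2)))
  got2 <- detect_coil_collisions(st2, spec, rest_len = 1)
  expect_equal(nrow(got2[got2$i == 1 & got2$j == 5, ]), 0L)
})

test_that("wall narrow phase handles faces, features and the literal rule", {
  spec <- coil_spec(0.05, 0.305, 2, length = 10)
  big <- surface_mesh(rbind(c(-5, -5, 0), c(5, -5, 0), c(0, 5, 0)),
                      matrix(c(1, 2, 3), 1))
  # node above the interior at height D2/4: contact with penetration D2/4
  got <- detect_wall_collisions(matrix(c(0, 0, spec$D2 / 4), 1), big, spec)
  top <- got[got$triangle == 1, ]
  expect_equal(nrow(top), 1L)
  expect_equal(top$penetration, spec$D2 / 4, tolerance = 1e-12)
  expect_equal(c(top$nx, top$ny, top$nz), c(0, 0, 1), tolerance = 1e-12)

  # node beyond the outer edge: projection falls outside every face ->
  # no contact in literal mode, closest-feature contact otherwise
  p <- matrix(c(0, 5 + 0.1, 0), 1)
  expect_equal(nrow(detect_wall_collisions(p, big, spec, literal = TRUE)), 0L)
  rob <- detect_wall_collisions(p, big, spec, literal = FALSE)
  expect_gt(nrow(rob), 0L)
  expect_equal(min(rob$distance), 0.1, tolerance = 1e-12)
})

test_that("wall distances on a spherical shell match the analytic radius", {
  domain <- make_synthetic_aneurysm(dome_radius = 2, neck_radius = 0.2,
                                    resolution = 48)
  spec <- coil_spec(0.05, 0.305, 2, length = 10)
  # node inside the sphere at radius 2 - 0.1: distance to wall ~ 0.1
  p <- matrix(c(0, 0, 1.9), 1)
  got <- detect_wall_collisions(p, domain$dome_mesh, spec)
  expect_gt(nrow(got), 0L)
  expect_equal(min(got$distance), 0.1, tolerance = 0.02)
})

test_that("contact force formulas follow their closed forms", {
  prm <- friction_params(k_sc = 100, gamma_sc = 2, k_w = 80, gamma_w = 1)
  d <- c(0.2, 0, 0)

  # Heaviside: no force without overlap
  z <- coil_coil_normal_force(-0.01, d, c(0, 0, 0), c(0, 0, 0), prm)
  expect_equal(z$force_i, c(0, 0, 0))

  # static overlap: magnitude k eps |d| along d
  f <- coil_coil_normal_force(0.05, d, c(0, 0, 0), c(0, 0, 0), prm)
  expect_equal(sqrt(sum(f$force_i^2)), 100 * 0.05 * 0.2, tolerance = 1e-12)
  expect_equal(f$force_i / sqrt(sum(f$force_i^2)), -d / 0.2, tolerance = 1e-12)
  expect_equal(f$force_j, -f$force_i)

  # head-on approach increases repulsion (dissipation opposes closing)
  fa <- coil_coil_normal_force(0.05, d, c(1, 0, 0), c(-1, 0, 0), prm)
  expect_gt(sqrt(sum(fa$force_i^2)), sqrt(sum(f$force_i^2)))
  expect_lt(sum(fa$force_i * d), 0)   # pushes i away from j

  # wall reaction cancels a pure normal push and adds the penalty
  n <- c(0, 0, 1)
  fw <- wall_normal_force(0.02, n, f_node = c(0, 0, -3), v = c(0, 0, 0), prm)
  expect_equal(fw, c(0, 0, 3 + 80 * 0.02), tolerance = 1e-12)
  # tangential-only load: reaction reduces to penalty + damping
  fw2 <- wall_normal_force(0.02, n, f_node = c(5, 0, 0), v = c(0, 0, -0.5), prm)
  expect_equal(fw2, c(0, 0, 80 * 0.02 + 1 * 0.5), tolerance = 1e-12)
  expect_equal(wall_normal_force(-0.01, n, c(0, 0, -3), c(0, 0, 0), prm),
               c(0, 0, 0))
})

test_that("friction obeys the Coulomb model and its caps", {
  prm <- friction_params(k_sc = 100, gamma_sc = 0, k_w = 80, gamma_w = 0)
  d <- c(0.3, 0, 0)
  # no relative tangential velocity: no coil-coil friction
  expect_equal(coil_coil_friction(2, c(0.5, 0, 0), d, prm), c(0, 0, 0))
  # magnitude mu |F_perp|, direction opposing v_par
  set.seed(53)
  for (k in 1:25) {
    v <- rnorm(3)
    fr <- coil_coil_friction(2, v, d, prm)
    vpar <- v - sum(v * d) / sum(d^2) * d
    if (sqrt(sum(vpar^2)) > 1e-12) {
      expect_equal(sqrt(sum(fr^2)), 0.4 * 2, tolerance = 1e-12)
      expect_lte(sum(fr * vpar), 0)
    }
  }
  n <- c(0, 0, 1)
  # stick: small tangential force is cancelled exactly
  fs <- wall_friction(n, f_node = c(0.1, 0, -1), v = c(0, 0, 0), prm)
  expect_equal(fs, c(-0.1, 0, 0), tolerance = 1e-12)
  # stick: large tangential force capped at mu_stick |F_perp|
  fb <- wall_friction(n, f_node = c(10, 0, -1), v = c(0, 0, 0), prm)
  expect_equal(sqrt(sum(fb^2)), 0.6 * 1, tolerance = 1e-12)
  # slip: mu_slip |F_perp| opposing motion
  fk <- wall_friction(n, f_node = c(10, 0, -1), v = c(0.5, 0, 0), prm)
  expect_equal(fk, c(-0.4 * 1, 0, 0), tolerance = 1e-12)
})

test_that("assembled coil-coil forces conserve momentum and match the formulas", {
  spec <- coil_spec(0.05, 0.305, 2, length = 4)
  prm <- friction_params(k_sc = 50, gamma_sc = 0.3, k_w = 40, gamma_w = 0.2)
  # two crossing strands of one chain in contact at mid-span
  X <- rbind(c(-1, 0, 0), c(1, 0, 0), c(3, 3, 3),
             c(0, -1, 0.2), c(0, 1, 0.2))
  st <- rod_state(X)
  st$vel <- matrix(rnorm(15, sd = 2), 5, 3)
  nat <- natural_shape_from_vertices(X)
  out <- assemble_external_forces(st, nat, spec, params = prm)
  # only the pair (edge 1, edge 4) can touch; forces sum to zero
  expect_equal(out$n_coil_contacts, 1L)
  expect_equal(colSums(out$force), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(out$max_pair_asymmetry, 0)

  # compare against the standalone formulas with barycentric distribution
  sd1 <- min_distance_segments(X[1, ], X[2, ], X[4, ], X[5, ])
  eps <- spec$D2 - sd1$distance
  vi <- (1 - sd1$s) * st$vel[1, ] + sd1$s * st$vel[2, ]
  vj <- (1 - sd1$t) * st$vel[4, ] + sd1$t * st$vel[5, ]
  nf <- coil_coil_normal_force(eps, sd1$vector, vi, vj, prm)
  ff <- coil_coil_friction(nf$magnitude, vi - vj, sd1$vector, prm)
  expect_equal(out$force[1, ], (1 - sd1$s) * (nf$force_i + ff), tolerance = 1e-9)
  expect_equal(out$force[2, ], sd1$s * (nf$force_i + ff), tolerance = 1e-9)
  expect_equal(out$force[4, ], -(1 - sd1$t) * (nf$force_i + ff), tolerance = 1e-9)

  # far from everything: all zeros
  Xf <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4, 0, 0))
  stf <- rod_state(Xf)
  outf <- assemble_external_forces(stf, natural_shape_from_vertices(Xf), spec,
                                   params = prm)
  expect_equal(outf$force, matrix(0, 5, 3))
})

test_that("friction parameters validate and resolve defaults", {
  expect_error(friction_params(mu_slip_cw = 0.5, mu_stick_cw = 0.3), "stick")
  spec <- coil_spec(0.05, 0.305, 2, length = 10)
  cp <- coildeploy:::resolve_contact_params(friction_params(), spec, 0.45)
  expect_length(cp, 9L)
  expect_true(all(cp[1:4] > 0))
  expect_equal(cp[9], spec$D2)
})
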