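# Voxelization, SDF partitioning, volume fractions, classifier, ensembles.

sphere_domain <- function(R = 2.5, res = 48) {
  make_synthetic_aneurysm(dome_radius = R, neck_radius = 0.1 * R,
                          resolution = res)
}

test_that("signed distances follow the analytic sphere and face distances", {
  d <- sphere_domain(R = 2)
  pts <- rbind(c(0, 0, 0), c(0, 0, 1), c(1.5, 0, 0), c(0, 3, 0), c(0, 0, 2))
  s <- mesh_sdf(d$dome_mesh, pts)
  expect_equal(s[1], -2, tolerance = 0.02)
  expect_equal(s[2], 1 - 2, tolerance = 0.02)
  expect_equal(s[3], 1.5 - 2, tolerance = 0.02)
  expect_equal(s[4], 3 - 2, tolerance = 0.02)
  expect_lt(abs(s[5]), 0.02)   # on the surface

  # deep interior of a convex mesh: |sdf| equals the nearest-face distance
  cube_v <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  cube_f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
                  c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
                  c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- surface_mesh(cube_v, cube_f)
  q <- c(0.3, -0.2, 0.1)
  sd <- mesh_sdf(cube, matrix(q, 1))
  # brute force over faces: for the axis-aligned cube the distance is
  # 1 - max|coordinate|
  expect_equal(sd, -(1 - max(abs(q))), tolerance = 1e-9)
})

test_that("capsule voxelization converges to the analytic swept volume", {
  cube <- list(origin = c(-2, -2, -2), a = 4)
  seg <- rbind(c(-1, 0, 0), c(1, 0, 0))
  exact <- pi * 0.2^2 * 2 + 4 / 3 * pi * 0.2^3
  err <- sapply(c(50, 100, 200), function(nv) {
    vf <- voxelize_coil(seg, D2 = 0.4, cube = cube, N_V = nv)
    abs(sum(vf$values) * vf$h^3 - exact) / exact
  })
  expect_lt(err[3], 0.03)
  # refinement: error roughly halves when N_V doubles
  expect_lt(err[2], 0.75 * err[1])
  expect_lt(err[3], 0.75 * err[2])

  # empty polyline -> empty field; centerline outside the cube -> error
  vf0 <- voxelize_coil(matrix(numeric(0), 0, 3), D2 = 0.4, cube = cube)
  expect_equal(sum(vf0$values), 0)
  expect_error(voxelize_coil(rbind(c(0, 0, 0), c(9, 0, 0)), D2 = 0.4, cube = cube),
               "cube")
})

test_that("equal-volume partition recovers the analytic core radius of a ball", {
  d <- sphere_domain(R = 2.5)
  vf <- voxelize_coil(matrix(numeric(0), 0, 3), D2 = 0.3,
                      cube = bounding_cube_of(d), N_V = 96)
  part <- partition_regions(d, vf)
  expect_lt(abs(part$V_C - part$V_B), 0.005 * part$V_A)
  r_core <- 2.5 + part$iso            # iso is negative
  expect_equal(r_core, 2.5 / 2^(1 / 3), tolerance = 0.02)
  # refinement: iso converges
  isos <- sapply(c(40, 64, 96), function(nv) {
    vfk <- voxelize_coil(matrix(numeric(0), 0, 3), D2 = 0.3,
                         cube = bounding_cube_of(d), N_V = nv)
    partition_regions(d, vfk)$iso
  })
  expect_lt(abs(isos[3] - (-2.5 * (1 - 2^(-1 / 3)))),
            abs(isos[1] - (-2.5 * (1 - 2^(-1 / 3)))) + 0.01)
})

test_that("volume fractions are additive and normalized as defined", {
  d <- sphere_domain(R = 2)
  vf <- voxelize_coil(matrix(numeric(0), 0, 3), D2 = 0.3,
                      cube = bounding_cube_of(d), N_V = 48)
  part <- partition_regions(d, vf)

  # psi = 0 everywhere
  fr0 <- volume_fractions(vf, part)
  expect_equal(unlist(fr0), c(psi_BA = 0, psi_CA = 0, psi_AA = 0, psi_SS = 0,
                              pd_core = 0, pd_boundary = 0, pd_sphere = 0,
                              pd_total = 0))

  # psi = 1 on the aneurysm interior
  vf1 <- vf; vf1$values[part$interior] <- 1
  fr1 <- volume_fractions(vf1, part)
  expect_equal(fr1$psi_AA, 1, tolerance = 1e-9)
  expect_equal(fr1$psi_BA, 0.5, tolerance = 0.005)
  expect_equal(fr1$psi_CA, 0.5, tolerance = 0.005)
  expect_equal(fr1$psi_SS, 1, tolerance = 1e-9)

  # additivity on random fields
  set.seed(61)
  for (k in 1:5) {
    vfr <- vf; vfr$values <- runif(length(vf$values))
    fr <- volume_fractions(vfr, part)
    expect_equal(fr$psi_BA + fr$psi_CA, fr$psi_AA, tolerance = 1e-12)
  }
})

test_that("the classifier reproduces the full threshold truth table", {
  lab <- function(co, bo, sp) classify_rroc(co, bo, sp)
  # all eight threshold-side combinations
  expect_equal(lab(0.25, 0.19, 0.19), "I")
  expect_equal(lab(0.25, 0.19, 0.10), "II")
  expect_equal(lab(0.10, 0.19, 0.19), "IIIa")
  expect_equal(lab(0.10, 0.19, 0.10), "IIIa")
  expect_equal(lab(0.25, 0.10, 0.19), "IIIb")
  expect_equal(lab(0.25, 0.10, 0.10), "IIIb")
  expect_equal(lab(0.10, 0.10, 0.19), "Fail")
  expect_equal(lab(0.10, 0.10, 0.10), "Fail")
  # thresholds are boundary-inclusive ("reaches ... and above")
  expect_equal(lab(0.20, 0.18, 0.18), "I")
  expect_equal(lab(0.20 - 1e-9, 0.18, 0.18), "IIIa")
  expect_equal(lab(0.20, 0.18 - 1e-9, 0.18), "IIIb")
  expect_equal(lab(0.20, 0.18, 0.18 - 1e-9), "II")
  # total on [0,1]^3
  set.seed(67)
  g <- matrix(runif(300), ncol = 3)
  labs <- mapply(lab, g[, 1], g[, 2], g[, 3])
  expect_true(all(labs %in% c("I", "II", "IIIa", "IIIb", "Fail")))
})

test_that("ensemble statistics match hand arithmetic and a brute-force recomputation", {
  cube <- list(origin = c(0, 0, 0), a = 1)
  mk <- function(vals) voxel_field(vals, cube$origin, cube$a, 4)
  z <- mk(rep(0, 64)); o <- mk(rep(1, 64))
  es <- ensemble_stats(list(z, o))
  expect_equal(es$mean$values, rep(0.5, 64))
  expect_equal(es$variance$values, rep(0.25, 64))
  expect_equal(ensemble_stats(list(o, o))$variance$values, rep(0, 64))

  # region-integrated mean and deviation vs direct summation
  set.seed(71)
  flds <- lapply(1:5, function(k) mk(runif(64)))
  part <- list(core = rep(c(TRUE, FALSE), 32), boundary = rep(c(FALSE, TRUE), 32),
               interior = rep(TRUE, 64), sphere = c(rep(TRUE, 16), rep(FALSE, 48)),
               V_C = 32 * (1 / 4)^3, V_B = 32 * (1 / 4)^3, V_A = 64 * (1 / 4)^3,
               V_S = 16 * (1 / 4)^3, voxel_volume = (1 / 4)^3)
  es2 <- ensemble_stats(flds, part = part)
  vol <- (1 / 4)^3
  M <- vapply(flds, `[[`, numeric(64), "values")
  mu <- rowMeans(M)
  for (rn in c("core", "sphere")) {
    mask <- part[[rn]]
    psiV <- sum(mu[mask]) * vol
    dev <- sqrt(mean(vapply(1:5, function(i) (sum((mu - M[, i])[mask]) * vol)^2,
                            numeric(1))))
    row <- es2$regions[es2$regions$region == rn, ]
    expect_equal(row$psi_V, psiV, tolerance = 1e-12)
    expect_equal(row$psi_sigma_V, dev, tolerance = 1e-12)
  }
  # mismatched grids are rejected
  expect_error(ensemble_stats(list(z, voxel_field(rep(0, 27), c(0, 0, 0), 1, 3))),
               "same grid")
})

test_that("parameter sweep recovers a linear response exactly and reproducibly", {
  lin <- function(value, seed) {
    list(psi_BA = 0.1 + 0.02 * value, psi_CA = 0.3 - 0.01 * value,
         psi_AA = 0.4 + 0.01 * value, psi_SS = 0.05 * value)
  }
  expect_warning(
    sw <- parameter_sweep("D3", c(2, 8), 40, lin, n_bins = 5, min_per_bin = 30,
                          seed = 9),
    "fewer than")
  for (b in seq_len(5)) {
    sel <- sw$samples$value >= sw$bins$center[b] - 0.6 - 1e-9 &
      sw$samples$value <= sw$bins$center[b] + 0.6 + 1e-9
    expect_equal(sw$bins$psi_SS_mean[b], 0.05 * mean(sw$samples$value[sel]),
                 tolerance = 1e-9)
  }
  suppressWarnings({
    sw2 <- parameter_sweep("D3", c(2, 8), 40, lin, n_bins = 5, seed = 9)
  })
  expect_identical(sw$bins, sw2$bins)
  # empty sweep
  sw0 <- parameter_sweep("D3", c(2, 8), 0, lin, seed = 9)
  expect_equal(nrow(sw0$bins), 0L)
})
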