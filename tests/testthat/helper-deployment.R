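# Shared deployment fixtures.  The reference scenario (synthetic dome,
# helix coil to 15% packing density) is expensive, so runs are memoized and
# reused across test files within one session.

.dep_cache <- new.env(parent = emptyenv())

reference_domain <- function() {
  if (is.null(.dep_cache$domain)) {
    d <- make_synthetic_aneurysm(dome_radius = 2.5, neck_radius = 1,
                                 seed = 11, bump_amplitude = 0.04)
    d$catheter <- default_catheter(d)
    .dep_cache$domain <- d
  }
  .dep_cache$domain
}

# Reference deployment at a given axial penalty weight.
reference_deployment <- function(alpha = 0.1) {
  key <- sprintf("dep_%g", alpha)
  if (is.null(.dep_cache[[key]])) {
    domain <- reference_domain()
    L <- coil_length_for_pd(domain, 0.305, 0.15)
    spec <- coil_spec(D1 = 0.05, D2 = 0.305, D3 = 2, length = L, alpha = alpha)
    shape <- shape_program("helix", D3 = 2, length = L, n_nodes = 300)
    .dep_cache[[key]] <- run_deployment(domain, list(spec = spec, shape = shape),
                                        simulation_config(seed = 1))
  }
  .dep_cache[[key]]
}

# Small, fast scenario for pipeline smoke tests (~15 s).
small_scenario <- function(seed = 3) {
  list(seed = seed,
       geometry = list(synthetic = list(dome_radius_mm = 1.3,
                                        neck_radius_mm = 0.6,
                                        resolution = 28)),
       coils = list(list(shape = "helix", D1_mm = 0.05, D2_mm = 0.305,
                         D3_mm = 1.2, packing_density = 0.08,
                         n_nodes = 40, alpha = 0.1)))
}

small_simulation <- function() {
  if (is.null(.dep_cache$small)) {
    .dep_cache$small <- cmd_simulate(small_scenario())
  }
  .dep_cache$small
}
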