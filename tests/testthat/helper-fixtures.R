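# Shared fixtures and memoised expensive objects for the test suite.

# a well-behaved reference parameter set used across files
ref_params <- function(...) {
  args <- modifyList(
    list(l_ro = 14, l_ri = 7, l_a = pi / 3, l_p = 2, l_h = 10,
         r_r = 12, b_ro = 13, b_ri = 8, b_a = pi / 3, b_p = 2, b_h = 5),
    list(...))
  do.call(leaflet_params, args)
}

# draw a random valid leaflet parameter set (seeded by the caller)
random_params <- function() {
  l_ro <- runif(1, 12, 16)
  l_h <- runif(1, 8, 12)
  b_h <- l_h * runif(1, 0.35, 0.65)
  l_a <- runif(1, 45, 75) * pi / 180
  leaflet_params(
    l_ro = l_ro,
    l_ri = l_ro * runif(1, 0.15, 0.6),
    l_a = l_a,
    l_p = runif(1, 1.5, 6),
    l_h = l_h,
    r_r = runif(1, 10, 14),
    b_ro = l_ro * runif(1, 0.85, 0.97),
    b_ri = l_ro * runif(1, 0.25, 0.6),
    b_a = l_a + runif(1, -0.05, 0.05),
    b_p = runif(1, 1.5, 6),
    b_h = b_h)
}

symmetric_valve <- function(p = ref_params()) {
  assemble_valve(list(p,
                      modifyList(p, list(theta = 2 * pi / 3)),
                      modifyList(p, list(theta = 4 * pi / 3))))
}

# memoised expensive objects (built once per test run)
.cache <- new.env(parent = emptyenv())
memo <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

# the desk-scale simulation of one named fixture (criteria 5/6 cohorts)
fixture_run <- function(name, seed = 42) {
  memo(paste0("run_", name, "_", seed), function() {
    leaflets <- generate_fixture(name, seed = seed)
    valve <- suppressWarnings(assemble_valve(leaflets))
    mesh <- generate_cylinder_mesh(
      cylinder_spec_for_valve(valve, h_fine = 1.5, h_coarse = 2.25))
    gam <- build_gamma(mesh, valve)
    st <- run_simulation(mesh, gam, inflow_spec(), solver_config(dt = 0.01),
                         fluid_properties(),
                         z_up = -valve$max_l_h, z_down = 3 * valve$max_l_h)
    list(valve = valve, mesh = mesh, gamma = gam, state = st,
         peak_v = max(st$series$v_max), peak_dp = max(st$series$dP))
  })
}

# small straight-tube mesh for solver verification tests
tube_mesh <- function() {
  memo("tube", function() {
    generate_cylinder_mesh(cylinder_spec(radius = 5, z_min = -5, z_max = 15,
                                         h_fine = 1, h_coarse = 1,
                                         refine_zmin = -1, refine_zmax = 1))
  })
}
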