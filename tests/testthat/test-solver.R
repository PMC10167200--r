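# Penalized Navier-Stokes solver: verification problems and diagnostics.

test_that("inlet profile is no-slip at the rim and zero at t = 0", {
  spec <- inflow_spec()
  props <- fluid_properties()
  R <- 14
  rim <- cbind(R * cos(seq(0, 2 * pi, 0.5)), R * sin(seq(0, 2 * pi, 0.5)), -20)
  expect_lt(max(abs(inlet_profile(rim, 0.1, spec, props, R))), 1e-12)
  centre <- matrix(c(0, 0, -20), 1)
  expect_true(all(inlet_profile(centre, 0, spec, props, R)[, 3] == 0))
  # peak centre velocity at t = T/2 realizes the Reynolds target
  u_peak <- unname(inlet_profile(centre, spec$T / 2, spec, props, R)[1, 3])
  Re <- props$rho * u_peak * 2 * R * 1e-3 / props$mu
  expect_equal(Re, spec$Re_max, tolerance = 1e-12)
})

test_that("instantaneous inlet flow rate matches the analytic integral", {
  spec <- inflow_spec(Re_max = 600)
  props <- fluid_properties()
  R <- 10
  # integrate U (1 - (r/R)^2) env(t) over the disk: U env pi R^2 / 2
  t <- 0.07
  U <- inlet_peak_velocity(spec, props, R)
  env <- sin(pi * t / spec$T)
  rr <- seq(0, R, length.out = 4000)
  num <- sum(inlet_profile(cbind(rr, 0, 0), t, spec, props, R)[, 3] *
               2 * pi * rr * 1e-3 * (rr[2] - rr[1]) * 1e-3)
  expect_equal(num, U * env * pi * (R * 1e-3)^2 / 2, tolerance = 1e-4)
})

test_that("rest state is preserved exactly", {
  mesh <- tube_mesh()
  st <- run_simulation(mesh, NULL,
                       inflow_spec(T = 1, T_end = 0.1, Re_max = 1e-9,
                                   envelope = "constant"),
                       solver_config(dt = 0.05), fluid_properties(),
                       z_up = 2, z_down = 12)
  expect_lt(max(abs(st$u)), 1e-10)
  expect_lt(max(abs(st$p)), 1e-8)
})

test_that("steady low-Re flow recovers the Poiseuille pressure drop", {
  mesh <- tube_mesh()
  props <- fluid_properties()
  inflow <- inflow_spec(T = 1, T_end = 1, Re_max = 30, envelope = "constant")
  st <- run_simulation(mesh, NULL, inflow, solver_config(dt = 0.05), props,
                       z_up = 2, z_down = 12)
  U <- inlet_peak_velocity(inflow, props, mesh$spec$radius)
  dp_exact <- 4 * props$mu * 10e-3 * U / (5e-3)^2 / 133.322
  expect_equal(tail(st$series$dP, 1), dp_exact, tolerance = 0.1)
  # discrete mass balance at every recorded step
  bal <- abs(st$series$flux_in - st$series$flux_out) /
    pmax(st$series$flux_in, 1e-30)
  expect_lt(max(bal), 0.01)
  # the velocity field is essentially the exact parabolic profile
  expect_equal(max(st$series$v_max), U, tolerance = 0.05)
})

test_that("one step is taken when T_end equals dt", {
  mesh <- tube_mesh()
  st <- run_simulation(mesh, NULL,
                       inflow_spec(T = 0.4, T_end = 0.05, Re_max = 50),
                       solver_config(dt = 0.05), fluid_properties(),
                       z_up = 2, z_down = 12)
  expect_identical(nrow(st$series), 1L)
  expect_equal(st$t, 0.05)
})

test_that("a penalized slab blocks pressure-driven flow", {
  mesh <- tube_mesh()
  props <- fluid_properties()
  # slab spanning the cross-section at z in [4, 6]
  gam_vals <- ifelse(mesh$nodes[, 3] >= 4 & mesh$nodes[, 3] <= 6, 1e8, 0)
  gam <- structure(list(values = gam_vals, epsilon_used = 1,
                        support_count = sum(gam_vals > 0), C = 1e8),
                   class = "gamma_field")
  p_drive <- 20  # Pa
  inflow <- inflow_spec(T = 1, T_end = 0.5, Re_max = 1, envelope = "constant",
                        type = "pressure", p_in = p_drive)
  st <- run_simulation(mesh, gam, inflow, solver_config(dt = 0.1), props,
                       z_up = 2, z_down = 12)
  # reference: peak Poiseuille velocity the same head drives in the open tube
  R <- 5e-3; L <- 20e-3
  U_ref <- p_drive * R^2 / (4 * props$mu * L)
  mean_u <- mean(sqrt(rowSums(st$u[gam_vals > 0, ]^2)))
  expect_lt(mean_u, 1e-3 * U_ref)
  # the open tube under the same drive really does flow
  st_open <- run_simulation(mesh, NULL, inflow, solver_config(dt = 0.1),
                            props, z_up = 2, z_down = 12)
  expect_gt(max(st_open$series$v_max), 0.1 * U_ref)
})

test_that("gamma = NULL and an explicit zero field give identical runs", {
  mesh <- tube_mesh()
  zero_gam <- structure(list(values = numeric(nrow(mesh$nodes)),
                             epsilon_used = 1, support_count = 0L, C = 1e8),
                        class = "gamma_field")
  inflow <- inflow_spec(T = 0.4, T_end = 0.1, Re_max = 100)
  a <- run_simulation(mesh, NULL, inflow, solver_config(dt = 0.05),
                      fluid_properties(), z_up = 2, z_down = 12)
  b <- run_simulation(mesh, zero_gam, inflow, solver_config(dt = 0.05),
                      fluid_properties(), z_up = 2, z_down = 12)
  expect_identical(a$u, b$u)
  expect_identical(a$p, b$p)
})

test_that("plane-averaged pressure drop is exact for linear fields", {
  mesh <- tube_mesh()
  a <- 1234.5
  st <- list(p = a * mesh$nodes[, 3] * 1e0)  # p = a * z (z in mm)
  got <- compute_pressure_drop(st, mesh, 3.3, 11.7)
  expect_equal(got, a * (3.3 - 11.7) / 133.322, tolerance = 1e-10)
  # spatially uniform pressure: zero drop
  st0 <- list(p = rep(77, nrow(mesh$nodes)))
  expect_equal(compute_pressure_drop(st0, mesh, 2, 12), 0)
  expect_error(compute_pressure_drop(st, mesh, -100, 5), "outside")
})

test_that("bernoulli comparison recovers an exact quadratic", {
  v <- c(0.8, 1.4, 2.1, 3.0, 3.8)
  bc <- bernoulli_compare(v, 4 * v^2)
  expect_equal(unname(bc$coefficients["a"]), 4, tolerance = 1e-9)
  expect_equal(unname(bc$coefficients["b"]), 0, tolerance = 1e-9)
  expect_equal(unname(bc$coefficients["c"]), 0, tolerance = 1e-9)
  expect_equal(bc$ratio, rep(4, 5))
  # single point: no fit, ratio still reported
  one <- bernoulli_compare(2, 20)
  expect_true(all(is.na(one$coefficients)))
  expect_equal(one$ratio, 5)
  expect_error(bernoulli_compare(c(1, 1, 1), c(4, 4, 4)), "degenerate")
})
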