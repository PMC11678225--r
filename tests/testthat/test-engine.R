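test_that("engine reproduces the one-compartment closed form within 0.5%", {
  ind <- onecomp_individual(volume_ml_kg = 3000, clearance_ml_min_kg = 33.8,
                            body_weight = 10.5)
  reg <- dose_regimen(5, 60, 0.13, 180)
  grid <- default_grid(reg, 12)
  prof <- simulate_profile(ind, reg, grid = grid)
  # same zero-order inputs fed to the analytic superposition solution
  inf <- tibble::tibble(start_min = c(0, 1),
                        rate_mg_min = c(5 * 10.5 / 1, 0.13 * 10.5),
                        duration_min = c(1, 180))
  cf <- closed_form_onecomp(0, 3000 * 10.5, 33.8 * 10.5, grid, infusions = inf)
  rel <- abs(prof$conc_ug_ml - cf$conc_ug_ml) / pmax(cf$conc_ug_ml, 1e-9)
  expect_lt(max(rel[-1]), 0.005)
  # and the AUC-infinity identity dose/CL
  long <- simulate_profile(ind, dose_regimen(5, 60),
                           grid = default_grid(dose_regimen(5, 60), 24, 2))
  expect_rel_equal(auc(long), 5 * 1000 / 60 / 33.8, 0.005)
})

test_that("closed-form one-compartment limits are exact", {
  # D/V at t = 0 and the steady-state infusion plateau R/CL
  p0 <- closed_form_onecomp(100, 10000, 1000, times_h = 0)
  expect_equal(p0$conc_ug_ml, 10)
  inf <- tibble::tibble(start_min = 0, rate_mg_min = 0.13 * 10, duration_min = 1e6)
  pss <- closed_form_onecomp(0, 33800, 338, times_h = 100, infusions = inf)
  expect_equal(pss$conc_ug_ml, 0.13 * 10 / 338 * 1000, tolerance = 1e-6)
  # 0.13 mg/kg/min against 33.8 mL/min/kg sits inside the 2.5-4.7 window
  css <- 0.13 / 33.8 * 1e3
  expect_gt(css, 2.5); expect_lt(css, 4.7)
  expect_equal(css, 3.846, tolerance = 1e-3)
})

test_that("zero dose gives an identically zero profile", {
  prof <- simulate_profile(test_reference_dog(), dose_regimen(0, 60), horizon_h = 2)
  expect_true(all(prof$conc_ug_ml == 0))
})

test_that("mass balance closes to well under 0.1% of the administered dose", {
  reg <- standard_maintenance_regimen()
  prof <- simulate_profile(test_reference_dog(), reg, horizon_h = 12,
                           keep_balance = TRUE)
  bal <- attr(prof, "balance")
  total <- max(bal$administered_mg)
  gap <- abs(bal$administered_mg - bal$in_body_mg - bal$eliminated_mg)
  expect_lt(max(gap) / total, 1e-3)
  expect_lt(max(gap) / total, 1e-9) # exact propagation: machine-level closure
})

test_that("profiles are dose-proportional and obey superposition", {
  dog <- test_reference_dog()
  grid <- default_grid(standard_maintenance_regimen(), 8)
  p1 <- simulate_profile(dog, dose_regimen(5, 60, 0.13, 180), grid = grid)
  p2 <- simulate_profile(dog, dose_regimen(10, 60, 0.26, 180), grid = grid)
  expect_equal(p2$conc_ug_ml, 2 * p1$conc_ug_ml, tolerance = 1e-9)

  pb <- simulate_profile(dog, dose_regimen(5, 60), grid = grid)
  pi <- simulate_profile(dog, dose_regimen(0, 60, 0.13, 180), grid = grid)
  expect_equal(pb$conc_ug_ml + pi$conc_ug_ml, p1$conc_ug_ml, tolerance = 1e-9)
})

test_that("halving the output step changes AUC0-12h by less than 0.1%", {
  dog <- test_reference_dog()
  reg <- standard_maintenance_regimen()
  g1 <- default_grid(reg, 12, washout_step_min = 2)
  g2 <- sort(unique(c(g1, g1[-1] - diff(g1) / 2)))
  a1 <- auc(simulate_profile(dog, reg, grid = g1), 0, 12)
  a2 <- auc(simulate_profile(dog, reg, grid = g2), 0, 12)
  expect_lt(abs(a1 / a2 - 1), 1e-3)
})

test_that("matrix-exponential propagation agrees with an ODE solver", {
  skip_if_not_installed("deSolve")
  dog <- make_individual(test_model(), 17.9)
  reg <- dose_regimen(7, 60, 0.47, 360)
  sys <- canipbpk:::build_system(dog)
  times_min <- c(0, 1, 30, 120, 360, 720, 1440)
  phases <- canipbpk:::regimen_phases(reg, 17.9, max(times_min))
  rhs <- canipbpk:::system_rhs(sys, phases)
  y0 <- rep(0, length(sys$state_names) + 1)
  ode <- deSolve::lsoda(y0, times_min, rhs, NULL, rtol = 1e-9, atol = 1e-10)
  conc_ode <- ode[, 1 + sys$idx_obs] / (sys$v_obs * sys$bp) * 1000
  prof <- simulate_profile(dog, reg, grid = times_min / 60)
  expect_equal(prof$conc_ug_ml[-1], unname(conc_ode[-1]), tolerance = 1e-5)
})

test_that("realized clearance from the liver relation matches the AUC route", {
  sys <- canipbpk:::build_system(test_reference_dog())
  expect_rel_equal(canipbpk:::realized_clearance_system(sys),
                   test_model()$cl_healthy_ml_min_kg * 10.5, 1e-9)
})

test_that("degenerate dosing inputs are rejected", {
  expect_error(dose_regimen(5, 0), ">= 1 second")
  expect_error(dose_regimen(-1, 60), ">= 0")
  expect_error(simulate_profile(test_reference_dog(), dose_regimen(5, 60),
                                grid = c(0, 1, 1, 2)), "increasing")
})
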