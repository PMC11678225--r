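test_that("noiseless unperturbed datasets equal the underlying simulation", {
  model <- test_model()
  st <- study_table()[study_table()$study_id == "nolan_reid_1993", ]
  obs <- make_virtual_study(model, st, residual_cv = 0, seed = 1)
  expect_equal(obs$conc_obs_ug_ml, obs$conc_true_ug_ml)
  ind <- make_individual(model, st$body_weight_kg)
  reg <- study_regimen(st)
  grid <- sort(unique(c(default_grid(reg, 24), obs$time_h)))
  prof <- simulate_profile(ind, reg, grid = grid)
  expect_equal(obs$conc_true_ug_ml,
               stats::approx(prof$time_h, prof$conc_ug_ml, xout = obs$time_h)$y,
               tolerance = 1e-9)
})

test_that("synthetic datasets are reproducible from their seed", {
  model <- test_model()
  st <- study_table()[4, ]
  a <- make_virtual_study(model, st, residual_cv = 0.15, seed = 99)
  b <- make_virtual_study(model, st, residual_cv = 0.15, seed = 99)
  expect_identical(a, b)
  c <- make_virtual_study(model, st, residual_cv = 0.15, seed = 100)
  expect_false(identical(a$conc_obs_ug_ml, c$conc_obs_ug_ml))
})

test_that("NCA on noiseless synthetic data recovers perturbed clearances within 2%", {
  model <- test_model()
  # a small dog leaves headroom under the hepatic flow limit for the 2x arm
  st <- study_table()[study_table()$study_id == "luiz_2012", ]
  dose <- total_dose_mg_kg(study_regimen(st))
  for (mult in c(0.5, 1, 2)) {
    obs <- make_virtual_study(model, st, perturbation = c(clearance = mult),
                              residual_cv = 0, seed = 5,
                              sampling_times_h = default_sampling_times(48))
    prof <- dplyr::rename(obs[, c("time_h", "conc_obs_ug_ml")],
                          conc_ug_ml = conc_obs_ug_ml)
    prof <- dplyr::bind_rows(tibble::tibble(time_h = 0, conc_ug_ml = 0), prof)
    est <- nca_clearance(prof, dose)
    expect_rel_equal(est, mult * model$cl_healthy_ml_min_kg, 0.02)
  }
})

test_that("noisy replicates still recover a 1.25x clearance within 5%", {
  model <- test_model()
  st <- study_table()[study_table()$study_id == "nolan_reid_1993", ]
  dose <- total_dose_mg_kg(study_regimen(st))
  obs <- make_virtual_study(model, st, perturbation = c(clearance = 1.25),
                            residual_cv = 0.1, seed = 17, n_replicates = 8,
                            sampling_times_h = default_sampling_times(48))
  ests <- vapply(split(obs, obs$replicate), function(d) {
    prof <- tibble::tibble(time_h = c(0, d$time_h),
                           conc_ug_ml = c(0, d$conc_obs_ug_ml))
    nca_clearance(prof, dose)
  }, numeric(1))
  expect_rel_equal(mean(ests), 1.25 * model$cl_healthy_ml_min_kg, 0.05)
})

test_that("virtual studies built on every design are self-consistent", {
  model <- test_model()
  st <- study_table()
  pred <- obs <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    d <- make_virtual_study(model, st[i, ], residual_cv = 0, seed = i,
                            sampling_times_h = default_sampling_times(24))
    prof <- tibble::tibble(time_h = c(0, d$time_h),
                           conc_ug_ml = c(0, d$conc_obs_ug_ml))
    obs[i] <- auc(prof)
    sim <- simulate_profile(make_individual(model, st$body_weight_kg[i]),
                            study_regimen(st[i, ]),
                            grid = default_grid(study_regimen(st[i, ]), 24, 2))
    pred[i] <- auc(sim, 0, 24)
  }
  # the residual fold error measures the clinical sampling-schedule
  # discretization (sparse samples around the bolus peak), not noise
  expect_equal(gmfe(pred, obs, absolute = TRUE), 1, tolerance = 0.1)
})

test_that("fixture writer reproduces the shipped inputs", {
  dir <- withr::local_tempdir()
  paths <- make_fixture_tables(dir)
  st <- study_table(paths[["studies"]])
  expect_equal(st, study_table())
  drug <- drug_parameters(paths[["drug"]])
  expect_equal(unclass(drug), unclass(drug_parameters()))
  w <- yaml::read_yaml(paths[["window"]])
  expect_equal(w$recovery_threshold, 2.15)
  zoran <- st[st$study_id == "zoran_1993", ]
  expect_equal(zoran$bolus_mg_kg, 5)
  expect_equal(zoran$body_weight_kg, 32.7)
  expect_equal(zoran$role, "validation")
})

test_that("invalid sampling schedules are rejected", {
  model <- test_model()
  st <- study_table()[1, ]
  expect_error(make_virtual_study(model, st, sampling_times_h = c(1, 0.5)),
               "increasing")
})
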