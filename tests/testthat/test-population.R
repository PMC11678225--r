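test_that("populations are bit-identical under a fixed seed", {
  model <- test_model()
  cfg <- population_config(n = 50, seed = 123)
  p1 <- generate_population(cfg, model)
  p2 <- generate_population(cfg, model)
  expect_identical(p1, p2)
  p3 <- generate_population(population_config(n = 50, seed = 124), model)
  expect_false(identical(p1$bw_kg, p3$bw_kg))
})

test_that("zero variability returns the reference individual at the drawn weight", {
  model <- test_model()
  cfg <- population_config(n = 1, seed = 9, variability = c(clearance = 0))
  pop <- generate_population(cfg, model)
  expect_equal(pop$cl_multiplier, 1)
  expect_equal(pop$muscle_multiplier, 1)
  expect_equal(pop$fat_multiplier, 1)
  expect_equal(pop$cl_realized_ml_min_kg, model$cl_healthy_ml_min_kg)
})

test_that("body weights stay inside the design bounds and average to 10.5 kg", {
  model <- test_model()
  pop <- generate_population(population_config(n = 10000, seed = 11), model)
  expect_true(all(pop$bw_kg >= 7.5 & pop$bw_kg <= 13.5))
  # uniform(7.5, 13.5): mean 10.5, sd 6/sqrt(12); allow 3 standard errors
  se <- (13.5 - 7.5) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(pop$bw_kg) - 10.5), 3 * se)
  # multiplicative perturbations are mean-one
  expect_lt(abs(mean(pop$cl_multiplier) - 1), 0.01)
})

test_that("identical subjects produce identical profiles and match single runs", {
  model <- test_model()
  pop <- generate_population(
    population_config(n = 3, bw_min = 10.49999, bw_max = 10.50001,
                      variability = c(clearance = 0), seed = 2), model)
  reg <- standard_maintenance_regimen()
  grid <- default_grid(reg, 4)
  profs <- simulate_population(pop, model, reg, grid = grid)
  wide <- tidyr::pivot_wider(profs, names_from = "subject_id",
                             values_from = "conc_ug_ml")
  expect_equal(wide$dog_0001, wide$dog_0002, tolerance = 1e-6)
  single <- simulate_profile(make_individual(model, pop$bw_kg[1]), reg, grid = grid)
  expect_equal(auc(dplyr::rename(dplyr::filter(profs, subject_id == "dog_0001"),
                                 conc_ug_ml = conc_ug_ml), 0, 3),
               auc(single, 0, 3), tolerance = 1e-5)
})

test_that("population summary matches a brute-force sort at every time point", {
  model <- test_model()
  pop <- generate_population(population_config(n = 21, seed = 5), model)
  reg <- dose_regimen(5, 60)
  grid <- default_grid(reg, 2)
  profs <- simulate_population(pop, model, reg, grid = grid)
  s <- summarize_profiles(profs)
  # brute force: sort concentrations per time point
  brute <- vapply(split(profs$conc_ug_ml, profs$time_h), function(x) {
    sort(x)[(length(x) + 1) / 2]
  }, numeric(1))
  expect_equal(s$central, unname(brute[order(as.numeric(names(brute)))]))
  expect_true(all(s$lower <= s$central & s$central <= s$upper))
})

test_that("degenerate and invalid summaries behave as specified", {
  one <- tibble::tibble(subject_id = "a", time_h = 0:3,
                        conc_ug_ml = c(1, 2, 3, 4))
  s <- summarize_profiles(one)
  expect_equal(s$central, c(1, 2, 3, 4))
  three <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 2),
    time_h = rep(0:1, 3),
    conc_ug_ml = rep(c(1, 2, 3), each = 2)
  )
  expect_equal(summarize_profiles(three)$central, c(2, 2))
  ragged <- three[-1, ]
  expect_error(summarize_profiles(ragged), "common grid")
  expect_error(summarize_profiles(three[0, ]), "no profiles")
})

test_that("geometric summaries bracket the geometric mean", {
  profs <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2),
    time_h = rep(0:1, 2),
    conc_ug_ml = c(1, 1, 4, 4)
  )
  s <- summarize_profiles(profs, type = "geometric")
  expect_equal(s$central, c(2, 2))
  expect_true(all(s$lower < s$central & s$central < s$upper))
})

test_that("invalid population configurations are rejected", {
  expect_error(population_config(n = 0), "n >= 1")
  expect_error(population_config(bw_min = 10, bw_max = 10), "bw_min < bw_max")
  expect_error(population_config(variability = c(clearance = -0.1)))
})

test_that("profiles round-trip through the CSV exchange format", {
  prof <- simulate_profile(test_reference_dog(), dose_regimen(5, 60),
                           grid = c(0, 0.5, 1, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(prof, path)
  back <- read_profiles(path)
  expect_equal(back$conc_ug_ml, prof$conc_ug_ml, tolerance = 1e-9)
  expect_equal(unique(back$subject_id), "subject_1")
  long <- tibble::tibble(subject_id = rep(c("a", "b"), each = 2),
                         time_h = rep(0:1, 2), conc_ug_ml = c(1, 2, 3, 4))
  write_profiles(long, path)
  expect_equal(read_profiles(path)$conc_ug_ml, long$conc_ug_ml)
})
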