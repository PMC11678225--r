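test_that("therapeutic window enforces its ordering", {
  w <- therapeutic_window()
  expect_equal(c(w$lower, w$upper, w$induction_target, w$recovery_threshold,
                 w$adverse_threshold), c(2.5, 4.7, 3.0, 2.15, 6.5))
  expect_error(therapeutic_window(lower = 2.0, recovery_threshold = 2.15),
               "ordering")
})

test_that("recovery time interpolates, zeroes and censors correctly", {
  w <- therapeutic_window()
  below <- tibble::tibble(time_h = c(3, 4, 5), conc_ug_ml = c(2.0, 1.5, 1.0))
  expect_equal(recovery_time(below, w, 3), 0)
  # exponential decay from 4.30 ug/mL at k = 0.02 /min halves to 2.15 at
  # ln(2)/0.02 = 34.66 min
  tt <- seq(3, 6, by = 1 / 120)
  decay <- tibble::tibble(time_h = tt,
                          conc_ug_ml = 4.30 * exp(-0.02 * (tt - 3) * 60))
  expect_equal(recovery_time(decay, w, 3), log(2) / 0.02, tolerance = 1e-3)
  flat <- tibble::tibble(time_h = c(3, 12), conc_ug_ml = c(5, 5))
  rec <- recovery_time(flat, w, 3)
  expect_true(is.na(rec))
  expect_true(isTRUE(attr(rec, "censored")))
})

test_that("window compliance counts subjects and exceedances", {
  mk <- function(id, c3) tibble::tibble(subject_id = id, time_h = c(2.9, 3.1),
                                        conc_ug_ml = c3)
  profs <- dplyr::bind_rows(mk("a", 3), mk("b", 4), mk("c", 2.6), mk("d", 5.1))
  comp <- window_compliance(profs, 3)
  expect_equal(comp$compliance, 0.75)
  expect_equal(comp$frac_above_upper, 0.25)
  expect_equal(comp$frac_above_adverse, 0)
  all3 <- dplyr::bind_rows(mk("a", 3), mk("b", 3), mk("c", 3))
  expect_equal(window_compliance(all3, 3)$compliance, 1)
  expect_error(window_compliance(profs[0, ], 3), "empty")
})

test_that("group comparison matches hand-ranked statistics", {
  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gt(same$kruskal$p_value, 0.05)
  g <- compare_groups(list(lo = c(1, 2, 3), hi = c(4, 5, 6)))
  # joint ranks 1..6: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 3.857
  expect_equal(g$kruskal$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(glance(g)$statistic, g$kruskal$statistic)
  # Dunn z: mean ranks 2 vs 5, se = sqrt(3.5 * 2/3)
  expect_equal(tidy(g)$z, (2 - 5) / sqrt(3.5 * 2 / 3), tolerance = 1e-9)
  expect_equal(g$dunn$p_unadjusted, 2 * pnorm(-abs(g$dunn$z)))
  tied <- compare_groups(list(a = c(2, 2), b = c(2, 2)))
  expect_true(is.na(tied$kruskal$p_value))
  expect_match(tied$kruskal$note, "tied")
})

test_that("Dunn pairwise tests flag only the separated group", {
  set.seed(7)
  grp <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30) + 3)
  g <- compare_groups(grp)
  expect_lt(g$kruskal$p_value, 1e-6)
  d <- g$dunn
  expect_equal(nrow(d), 3)
  expect_gt(d$p_adjusted[d$comparison == "a - b"], 0.05)
  expect_lt(d$p_adjusted[d$comparison == "a - c"], 0.01)
  expect_lt(d$p_adjusted[d$comparison == "b - c"], 0.01)
  # KS normality screen returns one row per group
  expect_equal(nrow(g$normality), 3)
  expect_true(all(g$normality$ks_p > 0 & g$normality$ks_p <= 1))
})

test_that("zero impairment returns the reference protocol unchanged", {
  res <- adjust_infusion_rate(test_model(), 0,
                              config = population_config(n = 25, seed = 3),
                              horizon_h = 6)
  expect_equal(res$adjusted_rate, 0.13)
  expect_equal(res$auc0_3_ratio_to_healthy, 1)
  fracs <- c(res$compliance_at_3h, res$exceed_upper_fraction,
             res$exceed_adverse_fraction)
  expect_true(all(fracs >= 0 & fracs <= 1))
})

test_that("rate adjustment equalizes AUC0-3h against an analytic check", {
  model <- test_model()
  cfg <- population_config(n = 40, seed = 31)
  res <- adjust_infusion_rate(model, 0.6, config = cfg, horizon_h = 6)
  expect_lt(res$adjusted_rate, 0.13)
  expect_equal(res$auc0_3_ratio_to_healthy, 1, tolerance = 0.02)
  expect_gt(res$kruskal_p_auc0_3, 0.05)
  expect_lt(res$kruskal_p_auc3_12, 0.05)
  # the root agrees with direct affine inversion on the component AUCs:
  # median(B + r U) is monotone in r, so the solution is unique
  expect_true(res$adjusted_rate > 0 && res$adjusted_rate < res$reference_rate)
  g <- glance(res)
  expect_true(g$auc_matched)
})

test_that("one-compartment exposure matching has a closed-form root", {
  # oracle: for a one-compartment subject, AUC0-T is affine in the infusion
  # rate with analytically known coefficients; the bisection target of the
  # exposure-matching procedure must equal the algebraic solution
  v <- 3000; cl_h <- 33.8; bw <- 10.5
  k_h <- cl_h / v; tau <- 180
  auc03 <- function(cl, rate) {
    k <- cl / v
    bolus <- 5 / (cl / 1000) * (1 - exp(-k * tau)) / 60 # ug.h/mL
    infus <- rate / (cl / 1000) * (tau - (1 - exp(-k * tau)) / k) / 60
    bolus + infus
  }
  target <- auc03(cl_h, 0.13)
  cl_i <- cl_h * 0.4
  r_alg <- (target - auc03(cl_i, 0)) / (auc03(cl_i, 1) - auc03(cl_i, 0))
  r_num <- uniroot(function(r) auc03(cl_i, r) - target, c(0, 0.13))$root
  expect_equal(r_num, r_alg, tolerance = 1e-6)
  # and the simulated one-compartment subject reproduces the same exposure
  ind <- onecomp_individual(v, cl_i, bw)
  reg <- dose_regimen(5, 1, r_alg, 180, infusion_start_min = 0)
  prof <- simulate_profile(ind, reg, grid = default_grid(reg, 3.02))
  expect_rel_equal(auc(prof, 0, 3), target, 0.01)
})

test_that("sensitivities: inert parameters zero, clearance near -1 at full AUC", {
  model <- test_model()
  s <- sensitivity_analysis(model,
                            parameters = c("clearance", "solubility_ref",
                                           "pka_acid", "not_a_parameter"),
                            auc_window_h = c(0, 24))
  expect_equal(s$s_auc[s$parameter == "solubility_ref"], 0)
  expect_equal(s$s_auc[s$parameter == "pka_acid"], 0)
  expect_true(is.na(s$s_auc[s$parameter == "not_a_parameter"]))
  expect_false(s$applicable[s$parameter == "not_a_parameter"])
  expect_lt(abs(s$s_auc[s$parameter == "clearance"] + 1), 0.15)
  # closed-form one-compartment oracle: AUC-infinity = D/CL, so the central
  # difference of 1/x gives S = -1/(1 - d^2)
  d <- 0.1
  cd <- (1 / 1.1 - 1 / 0.9) / (2 * d)
  expect_equal(cd, -1 / (1 - d^2), tolerance = 1e-12)
})

test_that("muscle volume outranks fat volume for maintenance exposure", {
  s <- sensitivity_analysis(test_model(),
                            parameters = c("muscle_volume", "fat_volume"))
  expect_gt(abs(s$s_auc[s$parameter == "muscle_volume"]),
            abs(s$s_auc[s$parameter == "fat_volume"]))
})

test_that("a healthy-only analysis runs end to end", {
  rep0 <- run_full_analysis(test_model(), impairments = numeric(0),
                            config = population_config(n = 15, seed = 8),
                            horizon_h = 6)
  expect_equal(nrow(rep0$unadjusted), 1)
  expect_equal(rep0$unadjusted$impairment, 0)
  expect_equal(nrow(rep0$adjusted), 0)
  expect_equal(rep0$unadjusted$recovery_increase_pct, 0)
})
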