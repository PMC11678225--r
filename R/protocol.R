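#' Propofol therapeutic window for canine anesthesia
#'
#' Plasma-concentration reference values: the 2.5-4.7 ug/mL maintenance
#' window, the 3.0 ug/mL induction target, the 2.15 ug/mL recovery
#' threshold, and the 6.5 ug/mL adverse-effect ceiling.
#'
#' @param lower,upper Maintenance window bounds, ug/mL.
#' @param induction_target Induction target, ug/mL.
#' @param recovery_threshold Anesthetic-recovery threshold, ug/mL.
#' @param adverse_threshold Adverse-effect ceiling, ug/mL.
#' @return A list of class `"therapeutic_window"`.
#' @export
therapeutic_window <- function(lower = 2.5, upper = 4.7, induction_target = 3.0,
                               recovery_threshold = 2.15, adverse_threshold = 6.5) {
  if (!(recovery_threshold < lower && lower < induction_target &&
        induction_target < upper && upper < adverse_threshold)) {
    stop("window ordering violated: need recovery < lower < induction < upper < adverse")
  }
  w <- list(lower = lower, upper = upper, induction_target = induction_target,
            recovery_threshold = recovery_threshold,
            adverse_threshold = adverse_threshold)
  class(w) <- "therapeutic_window"
  w
}

#' Anesthesia recovery time of a concentration profile
#'
#' Time, in minutes after `from_time_h`, at which the concentration first
#' falls to or below the recovery threshold, with linear interpolation
#' between grid points. A profile already at or below the threshold at
#' `from_time_h` recovers in 0 min; a profile that never crosses within the
#' grid is censored and reported as `NA` (with attribute `censored`).
#'
#' @param profile Tibble with `time_h`, `conc_ug_ml` (a subject profile or
#'   a population median renamed accordingly).
#' @param window A `"therapeutic_window"`.
#' @param from_time_h Reference time (typically the end of the maintenance
#'   infusion), hours.
#' @return Recovery time in minutes (`NA` if censored).
#' @export
#' @examples
#' p <- tibble::tibble(time_h = c(3, 4), conc_ug_ml = c(4.3, 4.3 / 2))
#' recovery_time(p, from_time_h = 3) # crosses 2.15 at 60 min
recovery_time <- function(profile, window = therapeutic_window(), from_time_h = 3) {
  thr <- window$recovery_threshold
  seg <- profile[profile$time_h >= from_time_h - 1e-12, ]
  if (nrow(seg) < 2) stop("profile must extend beyond `from_time_h`")
  cc <- seg$conc_ug_ml
  tt <- seg$time_h
  if (cc[1] <= thr) return(0)
  below <- which(cc <= thr)
  if (length(below) == 0) {
    out <- NA_real_
    attr(out, "censored") <- TRUE
    return(out)
  }
  j <- below[1]
  # linear interpolation inside the bracketing interval
  t_cross <- tt[j - 1] + (tt[j] - tt[j - 1]) * (cc[j - 1] - thr) / (cc[j - 1] - cc[j])
  unname((t_cross - from_time_h) * 60)
}

#' Therapeutic-window compliance of a population at a time point
#'
#' Fraction of subjects whose plasma concentration at `at_time_h` lies
#' inside the maintenance window, together with the fractions above the
#' upper bound and above the adverse-effect ceiling.
#'
#' @param profiles Long tibble (`subject_id`, `time_h`, `conc_ug_ml`).
#' @param at_time_h Evaluation time, hours.
#' @param window A `"therapeutic_window"`.
#' @return One-row tibble: `n`, `compliance`, `frac_above_upper`,
#'   `frac_above_adverse`.
#' @export
window_compliance <- function(profiles, at_time_h = 3, window = therapeutic_window()) {
  if (nrow(profiles) == 0) stop("empty profile set")
  conc <- profiles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      c_at = stats::approx(.data$time_h, .data$conc_ug_ml, xout = at_time_h)$y,
      .groups = "drop"
    )
  if (anyNA(conc$c_at)) stop("profiles are not defined at the requested time")
  tibble::tibble(
    n = nrow(conc),
    compliance = mean(conc$c_at >= window$lower & conc$c_at <= window$upper),
    frac_above_upper = mean(conc$c_at > window$upper),
    frac_above_adverse = mean(conc$c_at > window$adverse_threshold)
  )
}

#' Exposure-matched infusion-rate adjustment for hepatic impairment
#'
#' Finds the maintenance infusion rate for an impaired population that
#' equalizes the median AUC from bolus start to the end of the 3-h infusion
#' (AUC0-3h) with the healthy reference population dosed at the reference
#' rate, keeping the induction bolus fixed. Because the model is linear,
#' each subject's AUC0-3h is affine in the infusion rate; the root is found
#' by bounded scalar root-finding on the median over precomputed bolus-only
#' and unit-rate infusion responses. The adjusted regimen is then simulated
#' in full and the result annotated with compliance, exceedance fractions,
#' the median recovery time, and Kruskal-Wallis checks of AUC0-3h (should
#' not differ from healthy) and AUC3-12h (expected to differ, since
#' elimination remains impaired).
#'
#' @param model A calibrated `"pbpk_model"`.
#' @param impairment Fractional clearance reduction in `[0, 1)`.
#' @param config Population configuration shared by all arms; each
#'   impairment arm is drawn with seed `config$seed + round(100*impairment)`
#'   so arms are independent but reproducible.
#' @param reference Reference regimen (healthy protocol).
#' @param window Therapeutic window.
#' @param tolerance Relative tolerance on the median-AUC match.
#' @param horizon_h Simulation horizon, hours.
#' @return A list of class `"adjustment_result"`; see [tidy.adjustment_result()].
#' @export
adjust_infusion_rate <- function(model, impairment,
                                 config = population_config(),
                                 reference = standard_maintenance_regimen(),
                                 window = therapeutic_window(),
                                 tolerance = 0.02,
                                 horizon_h = 12) {
  check_impairment(impairment)
  if (nrow(reference$segments) != 1) {
    stop("the reference regimen must have exactly one maintenance segment")
  }
  ref_rate <- reference$segments$rate_mg_kg_min[1]
  inf_start <- reference$segments$start_min[1]
  inf_dur <- reference$segments$duration_min[1]
  inf_end_h <- (inf_start + inf_dur) / 60
  grid <- default_grid(reference, horizon_h)

  healthy_pop <- generate_population(config, model, impairment = 0)
  healthy_mat <- population_profile_matrix(healthy_pop, model, reference, grid)
  target <- stats::median(auc_rows(healthy_mat, grid, 0, inf_end_h))

  if (impairment == 0) {
    adj_rate <- ref_rate
    arm_pop <- healthy_pop
    bolus_mat <- NULL
    unit_mat <- NULL
    arm_mat <- healthy_mat
  } else {
    arm_cfg <- config
    arm_cfg$seed <- config$seed + as.integer(round(100 * impairment))
    arm_pop <- generate_population(arm_cfg, model, impairment = impairment)
    bolus_only <- dose_regimen(reference$bolus_mg_kg, reference$bolus_s)
    unit_inf <- dose_regimen(0, reference$bolus_s, 1, inf_dur,
                             infusion_start_min = inf_start)
    bolus_mat <- population_profile_matrix(arm_pop, model, bolus_only, grid)
    unit_mat <- population_profile_matrix(arm_pop, model, unit_inf, grid)
    auc_b <- auc_rows(bolus_mat, grid, 0, inf_end_h)
    auc_u <- auc_rows(unit_mat, grid, 0, inf_end_h)
    f <- function(r) stats::median(auc_b + r * auc_u) - target
    if (f(ref_rate) < 0) {
      stop("reference rate does not bracket the exposure target; increase the bracket")
    }
    root <- stats::uniroot(f, c(0, ref_rate), tol = tolerance * ref_rate / 100)
    adj_rate <- root$root
    arm_mat <- bolus_mat + adj_rate * unit_mat
    attr(arm_mat, "grid_h") <- grid
  }

  arm_auc03 <- auc_rows(arm_mat, grid, 0, inf_end_h)
  rel_gap <- stats::median(arm_auc03) / target - 1
  if (abs(rel_gap) > tolerance) {
    stop(sprintf("AUC0-%.0fh matching failed: residual %.3f exceeds tolerance %.3f",
                 inf_end_h, rel_gap, tolerance))
  }
  healthy_auc03 <- auc_rows(healthy_mat, grid, 0, inf_end_h)
  healthy_auc312 <- auc_rows(healthy_mat, grid, inf_end_h, horizon_h)
  arm_auc312 <- auc_rows(arm_mat, grid, inf_end_h, horizon_h)

  arm_long <- matrix_to_long(arm_mat, arm_pop$subject_id, grid)
  comp <- window_compliance(arm_long, at_time_h = inf_end_h, window = window)
  med_profile <- tibble::tibble(
    time_h = grid,
    conc_ug_ml = apply(arm_mat, 2, stats::median)
  )
  rec <- recovery_time(med_profile, window, from_time_h = inf_end_h)

  kw03 <- stats::kruskal.test(list(healthy = healthy_auc03, arm = arm_auc03))
  kw312 <- stats::kruskal.test(list(healthy = healthy_auc312, arm = arm_auc312))

  res <- list(
    impairment = impairment,
    adjusted_rate = adj_rate,
    reference_rate = ref_rate,
    auc0_3_ratio_to_healthy = stats::median(arm_auc03) / stats::median(healthy_auc03),
    compliance_at_3h = comp$compliance,
    exceed_upper_fraction = comp$frac_above_upper,
    exceed_adverse_fraction = comp$frac_above_adverse,
    recovery_time_median = rec,
    kruskal_p_auc0_3 = kw03$p.value,
    kruskal_p_auc3_12 = kw312$p.value,
    extrapolated = impairment > 0 & impairment < 0.4,
    median_profile = med_profile,
    arm_auc0_3 = arm_auc03,
    healthy_auc0_3 = healthy_auc03,
    arm_auc3_12 = arm_auc312,
    healthy_auc3_12 = healthy_auc312
  )
  class(res) <- "adjustment_result"
  res
}

# trapezoid AUC of every row of a subjects-by-times matrix
auc_rows <- function(mat, grid, t0, t1) {
  apply(mat, 1, function(cc) {
    auc(tibble::tibble(time_h = grid, conc_ug_ml = cc), t0, t1)
  })
}

matrix_to_long <- function(mat, subject_ids, grid) {
  tibble::tibble(
    subject_id = rep(subject_ids, each = length(grid)),
    time_h = rep(grid, times = length(subject_ids)),
    conc_ug_ml = as.numeric(t(mat))
  )
}

#' @export
print.adjustment_result <- function(x, ...) {
  cat(sprintf("<adjustment_result> impairment %.0f%%: rate %.4f mg/kg/min (ref %.3f)%s\n",
              100 * x$impairment, x$adjusted_rate, x$reference_rate,
              if (isTRUE(x$extrapolated)) " [extrapolated level]" else ""))
  cat(sprintf("  AUC0-3h ratio to healthy %.3f, compliance %.3f, >upper %.3f, >adverse %.3f\n",
              x$auc0_3_ratio_to_healthy, x$compliance_at_3h,
              x$exceed_upper_fraction, x$exceed_adverse_fraction))
  cat(sprintf("  median recovery %.1f min; KW p: AUC0-3h %.3g, AUC3-12h %.3g\n",
              x$recovery_time_median, x$kruskal_p_auc0_3, x$kruskal_p_auc3_12))
  invisible(x)
}

#' Nonparametric group comparison of per-subject exposures
#'
#' Kolmogorov-Smirnov normality screen per group, Kruskal-Wallis omnibus
#' test, and pairwise Dunn tests on the ranks with a multiplicity
#' correction. Implemented on the standard rank statistics (the Dunn z uses
#' the tie-corrected Kruskal-Wallis variance).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param p_adjust Multiplicity correction for the Dunn tests, see
#'   [stats::p.adjust()].
#' @return A list of class `"group_comparison"` with `normality`,
#'   `kruskal`, `dunn` tibbles.
#' @export
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))
compare_groups <- function(groups, p_adjust = "holm") {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("group_", seq_along(groups))
  normality <- purrr::imap(groups, function(x, nm) {
    if (stats::sd(x) == 0) {
      return(tibble::tibble(group = nm, n = length(x), ks_p = NA_real_,
                            note = "degenerate (all values tied)"))
    }
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    tibble::tibble(group = nm, n = length(x), ks_p = ks$p.value, note = NA_character_)
  }) |> dplyr::bind_rows()

  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  if (stats::sd(values) == 0) {
    kr <- tibble::tibble(statistic = NA_real_, df = length(groups) - 1, p_value = NA_real_,
                         note = "all values tied across groups; tests undefined")
    dunn <- tibble::tibble(comparison = character(), z = numeric(),
                           p_unadjusted = numeric(), p_adjusted = numeric())
  } else {
    kw <- stats::kruskal.test(values, g)
    kr <- tibble::tibble(statistic = unname(kw$statistic), df = unname(kw$parameter),
                         p_value = kw$p.value, note = NA_character_)
    dunn <- dunn_test(values, g, p_adjust)
  }
  out <- list(normality = normality, kruskal = kr, dunn = dunn)
  class(out) <- "group_comparison"
  out
}

# Pairwise Dunn z-tests on joint ranks with tie correction.
dunn_test <- function(values, g, p_adjust = "holm") {
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(g)
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[p[1]] + 1 / n_g[p[2]]))
    z <- (mean_r[p[1]] - mean_r[p[2]]) / se
    tibble::tibble(comparison = paste(p, collapse = " - "),
                   z = unname(z),
                   p_unadjusted = 2 * stats::pnorm(-abs(unname(z))))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_unadjusted, method = p_adjust)
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat(sprintf("  Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value))
  if (nrow(x$dunn)) {
    cat("  Dunn pairwise (adjusted p):\n")
    for (i in seq_len(nrow(x$dunn))) {
      cat(sprintf("    %s: z = %.3f, p = %.4g\n",
                  x$dunn$comparison[i], x$dunn$z[i], x$dunn$p_adjusted[i]))
    }
  }
  invisible(x)
}
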