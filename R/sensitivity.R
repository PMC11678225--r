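#' Local sensitivity analysis of exposure to model parameters
#'
#' Normalized local sensitivities
#' \eqn{S = (\Delta AUC / AUC) / (\Delta p / p)} computed by central
#' differences on the reference dog under a regimen, for the AUC over
#' `auc_window_h` and for the peak plasma concentration. A value of
#' +1 means a 10% increase in the parameter raises the metric by 10%.
#' The default AUC window is the 3-h maintenance period (the exposure
#' metric the dose-adjustment procedure matches); use `c(0, 24)` for a
#' near-total-exposure sensitivity, where clearance approaches -1 and
#' volume sensitivities vanish.
#'
#' Supported parameter names: `clearance` (realized plasma clearance),
#' `cardiac_output`, `<organ>_volume` (e.g. `muscle_volume`, `fat_volume`),
#' `logp`, `fu_plasma`, `bp_ratio`, `kp_scale`, plus the inert
#' physicochemical inputs `solubility_ref` and `pka_acid` (carried by the
#' parameter file but not used by the flow-limited model; their sensitivity
#' is identically 0). Unknown names are reported as not applicable
#' (`NA`), not as zero.
#'
#' @param model A calibrated `"pbpk_model"`.
#' @param parameters Character vector of parameter names.
#' @param relative_delta Relative perturbation for the central difference.
#' @param regimen Dose regimen (standard maintenance protocol by default).
#' @param body_weight Reference subject weight, kg.
#' @param horizon_h Simulation horizon, hours.
#' @param auc_window_h Two-element vector, AUC integration window in hours.
#' @return A tibble with `parameter`, `s_auc`, `s_cmax`, `applicable`.
#' @export
#' @examples
#' model <- calibrate_model()
#' sensitivity_analysis(model, c("clearance", "muscle_volume", "fat_volume"))
sensitivity_analysis <- function(model,
                                 parameters = c("clearance", "muscle_volume",
                                                "fat_volume", "cardiac_output",
                                                "bp_ratio", "fu_plasma", "logp",
                                                "solubility_ref"),
                                 relative_delta = 0.1,
                                 regimen = standard_maintenance_regimen(),
                                 body_weight = 10.5,
                                 horizon_h = 12,
                                 auc_window_h = c(0, 3)) {
  stopifnot(relative_delta > 0, length(auc_window_h) == 2)
  horizon_h <- max(horizon_h, auc_window_h[2])
  grid <- default_grid(regimen, horizon_h)
  metrics <- function(m, cl_scale = 1, vol_scales = NULL, co_scale = 1) {
    tpl <- m$template
    if (co_scale != 1) {
      tpl$cardiac_output_ml_min_per_kg075 <- tpl$cardiac_output_ml_min_per_kg075 * co_scale
      m$template <- tpl
    }
    ind <- make_individual(m, body_weight, cl_multiplier = cl_scale)
    if (!is.null(vol_scales)) {
      org <- ind$physiology$organs
      for (nm in names(vol_scales)) {
        if (!nm %in% org$name) return(NULL)
        org$volume_ml[org$name == nm] <- org$volume_ml[org$name == nm] * vol_scales[[nm]]
      }
      ind$physiology$organs <- org
      # organ volumes do not change realized clearance; re-solve the hepatic
      # coefficient in case hepatic flow bookkeeping changed
      ind <- set_realized_clearance(ind, ind$cl_realized_ml_min_kg)
    }
    prof <- simulate_profile(ind, regimen, grid = grid)
    c(auc = auc(prof, auc_window_h[1], auc_window_h[2]),
      cmax = max(prof$conc_ug_ml))
  }
  base <- metrics(model)
  one <- function(par) {
    d <- relative_delta
    eval_at <- function(scale) {
      m <- model
      switch(
        par,
        clearance = metrics(m, cl_scale = scale),
        cardiac_output = metrics(m, co_scale = scale),
        logp = { m$drug$logp <- m$drug$logp * scale; metrics(m) },
        fu_plasma = { m$drug$fu_plasma <- m$drug$fu_plasma * scale; metrics(m) },
        bp_ratio = { m$drug$bp_ratio <- m$drug$bp_ratio * scale; metrics(m) },
        kp_scale = { m$drug$kp_scale <- m$drug$kp_scale * scale; metrics(m) },
        solubility_ref = { m$drug$solubility_ref <- m$drug$solubility_ref * scale; metrics(m) },
        pka_acid = { m$drug$pka_acid <- m$drug$pka_acid * scale; metrics(m) },
        {
          if (grepl("_volume$", par)) {
            organ <- sub("_volume$", "", par)
            vs <- stats::setNames(list(scale), organ)
            metrics(m, vol_scales = vs)
          } else {
            NULL
          }
        }
      )
    }
    up <- eval_at(1 + d)
    dn <- eval_at(1 - d)
    if (is.null(up) || is.null(dn)) {
      return(tibble::tibble(parameter = par, s_auc = NA_real_, s_cmax = NA_real_,
                            applicable = FALSE))
    }
    tibble::tibble(
      parameter = par,
      s_auc = (up[["auc"]] - dn[["auc"]]) / base[["auc"]] / (2 * d),
      s_cmax = (up[["cmax"]] - dn[["cmax"]]) / base[["cmax"]] / (2 * d),
      applicable = TRUE
    )
  }
  dplyr::bind_rows(purrr::map(parameters, one))
}

#' Run the complete impairment analysis
#'
#' End-to-end orchestration: reproduces the predicted/observed exposure
#' table, simulates the unadjusted standard regimen across the healthy and
#' impaired arms (population medians and recovery times), adjusts the
#' infusion rate per impairment level, and collects compliance and group
#' statistics. Every stage is seeded through `config`.
#'
#' @param model A calibrated `"pbpk_model"`.
#' @param impairments Impairment levels (fractions) to analyse in addition
#'   to the healthy arm.
#' @param config Population configuration shared across arms.
#' @param reference Reference regimen.
#' @param window Therapeutic window.
#' @param horizon_h Simulation horizon, hours.
#' @return A list of class `"impairment_report"`: `pred_obs` (tibble),
#'   `unadjusted` (per-arm medians and recovery, tibble), `adjusted`
#'   (tibble of [adjust_infusion_rate()] summaries), `adjustments` (the
#'   full result objects) and `compliance_healthy` (one-row tibble).
#' @export
run_full_analysis <- function(model,
                              impairments = c(0.2, 0.4, 0.6, 0.8),
                              config = population_config(),
                              reference = standard_maintenance_regimen(),
                              window = therapeutic_window(),
                              horizon_h = 12) {
  stopifnot(all(impairments >= 0 & impairments < 1))
  inf_end_h <- (reference$segments$start_min[1] + reference$segments$duration_min[1]) / 60
  grid <- default_grid(reference, horizon_h)
  pred_obs <- pred_obs_table(model)

  arms <- c(0, sort(unique(impairments[impairments > 0])))
  unadj <- purrr::map(arms, function(hi) {
    cfg <- config
    cfg$seed <- config$seed + as.integer(round(100 * hi))
    pop <- generate_population(cfg, model, impairment = hi)
    mat <- population_profile_matrix(pop, model, reference, grid)
    med <- tibble::tibble(time_h = grid, conc_ug_ml = apply(mat, 2, stats::median))
    long <- matrix_to_long(mat, pop$subject_id, grid)
    comp <- window_compliance(long, at_time_h = inf_end_h, window = window)
    tibble::tibble(
      impairment = hi,
      median_c_end_ug_ml = med$conc_ug_ml[which.min(abs(grid - inf_end_h))],
      recovery_min = recovery_time(med, window, from_time_h = inf_end_h),
      compliance = comp$compliance,
      frac_above_upper = comp$frac_above_upper,
      frac_above_adverse = comp$frac_above_adverse,
      median_profile = list(med)
    )
  }) |> dplyr::bind_rows()
  healthy_recovery <- unadj$recovery_min[unadj$impairment == 0]
  unadj$recovery_increase_pct <- 100 * (unadj$recovery_min / healthy_recovery - 1)

  adjustments <- purrr::map(arms[arms > 0], function(hi) {
    adjust_infusion_rate(model, hi, config = config, reference = reference,
                         window = window, horizon_h = horizon_h)
  })
  names(adjustments) <- sprintf("HI%02.0f", 100 * arms[arms > 0])
  adjusted <- dplyr::bind_rows(purrr::map(adjustments, tidy_adjustment_row))

  report <- list(
    pred_obs = pred_obs,
    unadjusted = unadj,
    adjusted = adjusted,
    adjustments = adjustments,
    compliance_healthy = unadj[unadj$impairment == 0,
                               c("compliance", "frac_above_upper", "frac_above_adverse")],
    reference = reference,
    window = window,
    config = config
  )
  class(report) <- "impairment_report"
  report
}

tidy_adjustment_row <- function(a) {
  tibble::tibble(
    impairment = a$impairment,
    adjusted_rate = a$adjusted_rate,
    reference_rate = a$reference_rate,
    auc0_3_ratio_to_healthy = a$auc0_3_ratio_to_healthy,
    compliance_at_3h = a$compliance_at_3h,
    exceed_upper_fraction = a$exceed_upper_fraction,
    exceed_adverse_fraction = a$exceed_adverse_fraction,
    recovery_time_median = a$recovery_time_median,
    kruskal_p_auc0_3 = a$kruskal_p_auc0_3,
    kruskal_p_auc3_12 = a$kruskal_p_auc3_12,
    extrapolated = a$extrapolated
  )
}

#' @export
print.impairment_report <- function(x, ...) {
  cat("<impairment_report>\n")
  cat("  unadjusted arms:\n")
  print(x$unadjusted[, c("impairment", "median_c_end_ug_ml", "recovery_min",
                         "recovery_increase_pct", "compliance")])
  cat("  adjusted protocols:\n")
  print(x$adjusted[, c("impairment", "adjusted_rate", "auc0_3_ratio_to_healthy",
                       "recovery_time_median")])
  invisible(x)
}
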