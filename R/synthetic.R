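#' Generate a pseudo-observed study dataset
#'
#' Emulates a digitized literature concentration-time dataset for a study
#' design: the design is simulated with optionally perturbed parameters,
#' sampled on a clinical schedule, and overlaid with multiplicative
#' log-normal residual noise (the standard error model for concentration
#' assays). The generating truth is attached so parameter-recovery tests
#' can close the loop. Everything is reproducible from `seed`.
#'
#' @param model A calibrated `"pbpk_model"`.
#' @param study One row of [study_table()] giving the design (regimen and
#'   body weight).
#' @param perturbation Named multipliers applied to the generating subject;
#'   recognised names: `clearance`, `muscle_volume`, `fat_volume`.
#' @param residual_cv Proportional log-normal residual CV (>= 0).
#' @param sampling_times_h Sampling schedule, hours, strictly increasing.
#'   The default mimics a dense clinical schedule: every 2 min for the
#'   first 30 min, every 15 min to 8 h, then hourly to 24 h.
#' @param n_replicates Number of replicate animals (residual noise is drawn
#'   independently per replicate).
#' @param seed Integer seed.
#' @return A tibble with `replicate`, `time_h`, `conc_obs_ug_ml`,
#'   `conc_true_ug_ml`; attribute `"truth"` records the design, the
#'   perturbation and the generating subject's realized clearance.
#' @export
#' @examples
#' model <- calibrate_model()
#' obs <- make_virtual_study(model, study_table()[2, ], seed = 1)
#' head(obs)
make_virtual_study <- function(model, study,
                               perturbation = c(),
                               residual_cv = 0.15,
                               sampling_times_h = default_sampling_times(),
                               n_replicates = 1,
                               seed = 1) {
  stopifnot(nrow(study) == 1, residual_cv >= 0, n_replicates >= 1)
  if (any(diff(sampling_times_h) <= 0)) {
    stop("sampling times must be strictly increasing")
  }
  reg <- study_regimen(study)
  horizon <- max(sampling_times_h)
  pert <- function(nm) {
    if (length(perturbation) == 0 || !nm %in% names(perturbation)) return(1)
    unname(perturbation[[nm]])
  }
  ind <- make_individual(
    model, study$body_weight_kg,
    cl_multiplier = pert("clearance"),
    muscle_multiplier = pert("muscle_volume"),
    fat_multiplier = pert("fat_volume"),
    subject_id = study$study_id
  )
  grid <- sort(unique(c(default_grid(reg, horizon_h = horizon), sampling_times_h)))
  if (grid[1] > 0) grid <- c(0, grid)
  prof <- simulate_profile(ind, reg, grid = grid)
  true_c <- stats::approx(prof$time_h, prof$conc_ug_ml, xout = sampling_times_h)$y
  set.seed(seed)
  sdlog <- if (residual_cv > 0) sqrt(log(1 + residual_cv^2)) else 0
  out <- purrr::map(seq_len(n_replicates), function(r) {
    eps <- if (sdlog > 0) {
      stats::rlnorm(length(true_c), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, length(true_c))
    }
    tibble::tibble(
      replicate = r,
      time_h = sampling_times_h,
      conc_obs_ug_ml = true_c * eps,
      conc_true_ug_ml = true_c
    )
  }) |> dplyr::bind_rows()
  attr(out, "truth") <- list(
    study_id = study$study_id,
    regimen = reg,
    body_weight_kg = study$body_weight_kg,
    perturbation = perturbation,
    cl_realized_ml_min_kg = ind$cl_realized_ml_min_kg,
    residual_cv = residual_cv,
    seed = seed
  )
  out
}

#' Default dense sampling schedule for synthetic studies
#'
#' End-of-injection sample at 1 min, every 2 min over the first 30 min,
#' every 15 min to 8 h, then hourly.
#'
#' @param horizon_h Last sample, hours.
#' @return Strictly increasing times in hours.
#' @export
default_sampling_times <- function(horizon_h = 24) {
  t_min <- c(1, seq(2, 30, by = 2), seq(45, 8 * 60, by = 15),
             seq(9 * 60, horizon_h * 60, by = 60))
  t_min[t_min <= horizon_h * 60] / 60
}

#' Write the packaged fixture tables
#'
#' Regenerates the shipped inputs from the in-code canonical values: the
#' nine-study design/exposure table, the propofol parameter file and the
#' therapeutic-window constants. Used to rebuild `inst/extdata` and to
#' round-trip-test the fixtures.
#'
#' @param dir Output directory.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture_tables <- function(dir = ".") {
  studies_path <- file.path(dir, "propofol_studies.csv")
  drug_path <- file.path(dir, "propofol.yaml")
  window_path <- file.path(dir, "therapeutic_window.yaml")
  utils::write.csv(canonical_study_table(), studies_path, row.names = FALSE,
                   quote = 2, na = "NA")
  yaml::write_yaml(canonical_drug_list(), drug_path)
  w <- therapeutic_window()
  yaml::write_yaml(unclass(w), window_path)
  invisible(c(studies = studies_path, drug = drug_path, window = window_path))
}

canonical_study_table <- function() {
  tibble::tibble(
    study_id = c("cockshott_1992", "nolan_reid_1993", "luiz_2012",
                 "reid_nolan_1996", "hall_1994", "hughes_nolan_1999",
                 "nolan_reid_grant_1993", "zoran_1993", "mandsager_1995"),
    label = c("Cockshott et al. (1992)", "Nolan and Reid (1993)", "Luiz (2012)",
              "Reid and Nolan (1996)", "Hall et al. (1994)",
              "Hughes and Nolan (1999)", "Nolan, Reid and Grant (1993)",
              "Zoran et al. (1993)", "Mandsager et al. (1995)"),
    bolus_mg_kg = c(7, 4, 8, 5, 6.9, 4, 6.5, 5, 10),
    bolus_s = rep(60, 9),
    rate1_mg_kg_min = c(0.47, 0.4, 0.4, NA, 0.4, 0.3, NA, NA, 0.4),
    dur1_min = c(360, 60, 60, NA, 120, 20, NA, NA, 120),
    rate2_mg_kg_min = c(NA, NA, NA, NA, NA, 0.2, NA, NA, NA),
    dur2_min = c(NA, NA, NA, NA, NA, 70, NA, NA, NA),
    body_weight_kg = c(17.9, 21.25, 10.7, 29, 21.5, 25.58, 29.5, 32.7, 25.5),
    n_animals = c(3, 7, 6, 6, 6, 8, 6, 10, 5),
    role = c("development", "development", "development", "development",
             "validation", "validation", "validation", "validation", "validation"),
    auc_pred_ug_h_ml = c(85.63, 13.81, 14.05, 2.25, 26.93, 10.92, 2.92, 2.19, 25.89),
    auc_obs_ug_h_ml = c(80.53, 12.04, 14.61, 2.86, 26.07, 8.87, 1.56, 1.51, 23.93)
  )
}

canonical_drug_list <- function() {
  list(
    name = "propofol",
    molecular_weight = 178.27,
    pka_acid = 11.1,
    logp = 3.49,
    solubility_ref = 0.12,
    bp_ratio = 2.36,
    fu_plasma = 0.02,
    hepatic_clearance_spec = 47.08,
    kp_scale = 1.0
  )
}
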