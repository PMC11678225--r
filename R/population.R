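#' Virtual population configuration
#'
#' Describes one simulated subgroup: the number of dogs, the uniform
#' body-weight range, the inter-individual variability model, and the seed.
#' Defaults follow the impairment study design: 1000 dogs of 7.5-13.5 kg.
#' Body weight is the only covariate; additional spread comes from
#' mean-one log-normal multipliers on realized clearance and on the two
#' exposure-sensitive organ volumes (muscle and fat).
#'
#' @param n Number of subjects (>= 1).
#' @param bw_min,bw_max Body-weight bounds, kg.
#' @param variability Named numeric vector of log-normal coefficients of
#'   variation; recognised names: `clearance`, `muscle_volume`,
#'   `fat_volume`.
#' @param seed Integer seed; every population drawn from the same config is
#'   bit-identical.
#' @return A list of class `"population_config"`.
#' @export
population_config <- function(n = 1000, bw_min = 7.5, bw_max = 13.5,
                              variability = c(clearance = 0.20,
                                              muscle_volume = 0.15,
                                              fat_volume = 0.15),
                              seed = 20124) {
  stopifnot(n >= 1, bw_min < bw_max, all(variability >= 0))
  cfg <- list(n = as.integer(n), bw_min = bw_min, bw_max = bw_max,
              variability = variability, seed = as.integer(seed))
  class(cfg) <- "population_config"
  cfg
}

#' Draw a virtual canine population
#'
#' Samples body weights uniformly and applies mean-one log-normal
#' multipliers according to the variability model. The result is a tibble
#' of subject covariates; subjects are materialized into full physiologies
#' lazily by [simulate_population()].
#'
#' @param config A `"population_config"`.
#' @param model A calibrated `"pbpk_model"` (used to record each subject's
#'   realized clearance).
#' @param impairment Fractional clearance reduction applied to the whole
#'   subgroup, in `[0, 1)`.
#' @return A tibble with columns `subject_id`, `bw_kg`, `cl_multiplier`,
#'   `muscle_multiplier`, `fat_multiplier`, `impairment`,
#'   `cl_realized_ml_min_kg`.
#' @export
#' @examples
#' model <- calibrate_model()
#' pop <- generate_population(population_config(n = 5, seed = 1), model)
#' pop
generate_population <- function(config, model, impairment = 0) {
  check_impairment(impairment)
  cv <- function(nm) {
    v <- config$variability[nm]
    if (is.na(v)) 0 else unname(v)
  }
  draw_lnorm <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  set.seed(config$seed)
  n <- config$n
  pop <- tibble::tibble(
    subject_id = sprintf("dog_%04d", seq_len(n)),
    bw_kg = stats::runif(n, config$bw_min, config$bw_max),
    cl_multiplier = draw_lnorm(n, cv("clearance")),
    muscle_multiplier = draw_lnorm(n, cv("muscle_volume")),
    fat_multiplier = draw_lnorm(n, cv("fat_volume")),
    impairment = impairment
  )
  pop$cl_realized_ml_min_kg <-
    model$cl_healthy_ml_min_kg * pop$cl_multiplier * (1 - impairment)
  pop
}

#' Simulate every subject of a population
#'
#' Runs the whole-body model for each row of the population table under a
#' common regimen and output grid. Execution is order-stable: the result is
#' identical whichever way the subjects are iterated.
#'
#' @param population Tibble from [generate_population()].
#' @param model A calibrated `"pbpk_model"`.
#' @param regimen A `"dose_regimen"` applied to every subject (per-kg doses
#'   resolve against each subject's weight).
#' @param grid Common output grid in hours; defaults to [default_grid()].
#' @param horizon_h Horizon used when `grid` is missing.
#' @return A long tibble with `subject_id`, `time_h`, `conc_ug_ml`.
#' @export
simulate_population <- function(population, model, regimen, grid = NULL,
                                horizon_h = 12) {
  if (is.null(grid)) grid <- default_grid(regimen, horizon_h)
  mat <- population_profile_matrix(population, model, regimen, grid)
  tibble::tibble(
    subject_id = rep(population$subject_id, each = length(grid)),
    time_h = rep(grid, times = nrow(population)),
    conc_ug_ml = as.numeric(t(mat))
  )
}

# subjects x times concentration matrix; the workhorse behind
# simulate_population() and the protocol layer.
population_profile_matrix <- function(population, model, regimen, grid) {
  profs <- purrr::map(seq_len(nrow(population)), function(i) {
    s <- population[i, ]
    ind <- make_individual(
      model, s$bw_kg,
      impairment = s$impairment,
      cl_multiplier = s$cl_multiplier,
      muscle_multiplier = s$muscle_multiplier,
      fat_multiplier = s$fat_multiplier,
      subject_id = s$subject_id
    )
    simulate_profile(ind, regimen, grid = grid)$conc_ug_ml
  })
  mat <- do.call(rbind, profs)
  rownames(mat) <- population$subject_id
  colnames(mat) <- sprintf("%.6g", grid)
  attr(mat, "grid_h") <- grid
  mat
}

#' Pointwise population summary of simulated profiles
#'
#' Median and central percentile band (or geometric mean and geometric SD
#' band) of a set of profiles sharing a common grid.
#'
#' @param profiles Long tibble from [simulate_population()] (columns
#'   `subject_id`, `time_h`, `conc_ug_ml`).
#' @param type `"median"` for median and percentiles, `"geometric"` for
#'   geometric mean with a geometric-SD band.
#' @param probs Lower and upper percentile for the `"median"` band.
#' @return A tibble of class `"population_summary"` with `time_h`,
#'   `central`, `lower`, `upper`, `n`.
#' @export
summarize_profiles <- function(profiles, type = c("median", "geometric"),
                               probs = c(0.025, 0.975)) {
  type <- match.arg(type)
  if (nrow(profiles) == 0) stop("no profiles to summarize")
  counts <- profiles |>
    dplyr::count(.data$subject_id) |>
    dplyr::distinct(.data$n)
  if (nrow(counts) > 1) {
    stop("profiles are not on a common grid (unequal numbers of samples per subject)")
  }
  out <- profiles |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      central = if (type == "median") stats::median(.data$conc_ug_ml)
                else exp(mean(log(pmax(.data$conc_ug_ml, 1e-12)))),
      lower = if (type == "median") stats::quantile(.data$conc_ug_ml, probs[1], names = FALSE)
              else {
                gm <- exp(mean(log(pmax(.data$conc_ug_ml, 1e-12))))
                gsd <- exp(stats::sd(log(pmax(.data$conc_ug_ml, 1e-12))))
                gm / gsd
              },
      upper = if (type == "median") stats::quantile(.data$conc_ug_ml, probs[2], names = FALSE)
              else {
                gm <- exp(mean(log(pmax(.data$conc_ug_ml, 1e-12))))
                gsd <- exp(stats::sd(log(pmax(.data$conc_ug_ml, 1e-12))))
                gm * gsd
              },
      n = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("population_summary", class(out))
  attr(out, "type") <- type
  out
}

#' Write and read concentration profiles as CSV
#'
#' The on-disk exchange format is a flat CSV with columns `subject_id`,
#' `time_h`, `conc_ug_ml` — one row per sample, any number of subjects.
#'
#' @param profiles A long profile tibble ([simulate_population()]) or a
#'   single-subject profile ([simulate_profile()]).
#' @param path CSV path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   returns the long tibble.
#' @export
write_profiles <- function(profiles, path) {
  if (!"subject_id" %in% names(profiles)) {
    profiles <- tibble::tibble(
      subject_id = attr(profiles, "subject_id") %||% "subject_1",
      time_h = profiles$time_h,
      conc_ug_ml = profiles$conc_ug_ml
    )
  }
  utils::write.csv(profiles[, c("subject_id", "time_h", "conc_ug_ml")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
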