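#' Construct an intravenous dose regimen
#'
#' A regimen is a short zero-order bolus (mg/kg over `bolus_s` seconds)
#' optionally followed by one or more zero-order infusion segments
#' (mg/kg/min). All doses are per kg of body weight; absolute input rates
#' are resolved against the subject at simulation time.
#'
#' @param bolus_mg_kg Bolus dose, mg/kg (0 for infusion-only designs).
#' @param bolus_s Bolus duration in seconds; must be >= 1 s when a bolus is
#'   given (a true instantaneous bolus is available only through the
#'   one-compartment closed form).
#' @param rate_mg_kg_min Infusion rate of the first segment, mg/kg/min.
#' @param infusion_min Duration of the first segment, minutes (0 = bolus
#'   only).
#' @param infusion_start_min Start of the first segment, minutes after the
#'   start of the bolus. Defaults to the end of the bolus.
#' @param extra_segments Optional tibble with columns `start_min`,
#'   `rate_mg_kg_min`, `duration_min` for additional infusion segments
#'   (e.g. step-down infusions).
#' @return A list of class `"dose_regimen"` with `bolus_mg_kg`, `bolus_s`
#'   and a `segments` tibble.
#' @export
#' @examples
#' standard_maintenance_regimen() # 5 mg/kg over 60 s + 0.13 mg/kg/min x 3 h
#' dose_regimen(7, 60, 0.47, 360) # 7 mg/kg bolus + 0.47 mg/kg/min x 6 h
dose_regimen <- function(bolus_mg_kg,
                         bolus_s = 60,
                         rate_mg_kg_min = 0,
                         infusion_min = 0,
                         infusion_start_min = NULL,
                         extra_segments = NULL) {
  stopifnot(
    "bolus_mg_kg must be >= 0" = bolus_mg_kg >= 0,
    "rate_mg_kg_min must be >= 0" = rate_mg_kg_min >= 0,
    "infusion_min must be >= 0" = infusion_min >= 0
  )
  if (bolus_mg_kg > 0 && bolus_s < 1) {
    stop("bolus_s must be >= 1 second; zero-duration boluses are not integrable")
  }
  if (is.null(infusion_start_min)) infusion_start_min <- bolus_s / 60
  segments <- tibble::tibble(
    start_min = numeric(), rate_mg_kg_min = numeric(), duration_min = numeric()
  )
  if (infusion_min > 0 && rate_mg_kg_min > 0) {
    segments <- tibble::tibble(
      start_min = infusion_start_min,
      rate_mg_kg_min = rate_mg_kg_min,
      duration_min = infusion_min
    )
  }
  if (!is.null(extra_segments)) {
    segments <- dplyr::bind_rows(segments, tibble::as_tibble(extra_segments))
  }
  out <- list(bolus_mg_kg = bolus_mg_kg, bolus_s = bolus_s, segments = segments)
  class(out) <- "dose_regimen"
  out
}

#' The standard canine maintenance regimen
#'
#' 5 mg/kg induction bolus over 60 s followed by a 3-hour continuous
#' infusion at 0.13 mg/kg/min — the healthy-dog reference protocol used
#' throughout the impairment analysis.
#'
#' @param rate_mg_kg_min Maintenance infusion rate, mg/kg/min.
#' @param infusion_min Maintenance duration, minutes.
#' @return A `"dose_regimen"`.
#' @export
standard_maintenance_regimen <- function(rate_mg_kg_min = 0.13, infusion_min = 180) {
  dose_regimen(5, 60, rate_mg_kg_min, infusion_min)
}

#' Total administered dose of a regimen
#'
#' @param regimen A `"dose_regimen"`.
#' @return Total dose in mg/kg.
#' @export
total_dose_mg_kg <- function(regimen) {
  regimen$bolus_mg_kg + sum(regimen$segments$rate_mg_kg_min * regimen$segments$duration_min)
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen> bolus %.3g mg/kg over %g s", x$bolus_mg_kg, x$bolus_s))
  if (nrow(x$segments) > 0) {
    for (i in seq_len(nrow(x$segments))) {
      s <- x$segments[i, ]
      cat(sprintf(" + %.3g mg/kg/min x %g min (from %g min)",
                  s$rate_mg_kg_min, s$duration_min, s$start_min))
    }
  }
  cat(sprintf("; total %.4g mg/kg\n", total_dose_mg_kg(x)))
  invisible(x)
}

# Piecewise-constant infusion schedule (absolute mg/min) for one subject.
# Returns a tibble of non-overlapping phases covering [0, horizon_min].
regimen_phases <- function(regimen, body_weight, horizon_min) {
  bolus_end <- regimen$bolus_s / 60
  events <- c(0, if (regimen$bolus_mg_kg > 0) bolus_end,
              regimen$segments$start_min,
              regimen$segments$start_min + regimen$segments$duration_min,
              horizon_min)
  events <- sort(unique(pmin(events, horizon_min)))
  t0 <- events[-length(events)]
  t1 <- events[-1]
  rate <- vapply(seq_along(t0), function(i) {
    mid <- (t0[i] + t1[i]) / 2
    r <- 0
    if (regimen$bolus_mg_kg > 0 && mid < bolus_end) {
      r <- r + regimen$bolus_mg_kg * body_weight / bolus_end
    }
    seg <- regimen$segments
    if (nrow(seg) > 0) {
      on <- mid >= seg$start_min & mid < seg$start_min + seg$duration_min
      r <- r + sum(seg$rate_mg_kg_min[on]) * body_weight
    }
    r
  }, numeric(1))
  tibble::tibble(t0_min = t0, t1_min = t1, rate_mg_min = rate)
}

#' Default simulation output grid for a regimen
#'
#' Dense sampling across the bolus, minute resolution through the infusion
#' and early washout, and coarser sampling out to the horizon. All phase
#' boundaries are included so piecewise-constant dosing is represented
#' exactly.
#'
#' @param regimen A `"dose_regimen"`.
#' @param horizon_h Simulation horizon in hours.
#' @param washout_step_min Step after the last infusion ends, minutes.
#' @return Strictly increasing numeric vector of times in hours.
#' @export
default_grid <- function(regimen, horizon_h = 12, washout_step_min = 1) {
  horizon_min <- horizon_h * 60
  bolus_end <- regimen$bolus_s / 60
  inf_end <- if (nrow(regimen$segments) > 0) {
    max(regimen$segments$start_min + regimen$segments$duration_min)
  } else {
    bolus_end
  }
  inf_end <- min(inf_end, horizon_min)
  pts <- c(
    seq(0, min(bolus_end, horizon_min), length.out = 13),
    # curvature is sharpest just after the bolus peak; sample at 5 s there
    seq(bolus_end, min(bolus_end + 3, horizon_min), by = 5 / 60),
    if (inf_end > bolus_end) seq(bolus_end, inf_end, by = 1),
    if (horizon_min > inf_end) seq(inf_end, min(horizon_min, 12 * 60), by = washout_step_min),
    if (horizon_min > 12 * 60) seq(12 * 60, horizon_min, by = 5),
    regimen$segments$start_min, inf_end, horizon_min
  )
  sort(unique(pmin(pts, horizon_min))) / 60
}
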