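#' Turn a model object into a tidy tibble
#'
#' Broom-style generics: `tidy()` returns one row per component or
#' parameter, `glance()` a one-row model-level summary.
#'
#' @param x An object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.pbpk_model <- function(x, ...) {
  drug <- x$drug
  tibble::tibble(
    parameter = c("molecular_weight", "pka_acid", "logp", "solubility_ref",
                  "bp_ratio", "fu_plasma", "hepatic_clearance_spec", "kp_scale",
                  "cl_realized_healthy"),
    value = c(drug$molecular_weight, drug$pka_acid, drug$logp, drug$solubility_ref,
              drug$bp_ratio, drug$fu_plasma, drug$hepatic_clearance_spec,
              drug$kp_scale, x$cl_healthy_ml_min_kg),
    unit = c("g/mol", "", "", "mg/mL", "", "", "mL/min/kg", "", "mL/min/kg")
  )
}

#' @rdname tidy
#' @export
glance.pbpk_model <- function(x, ...) {
  cal <- x$calibration
  val <- function(q) cal$value[cal$quantity == q]
  tibble::tibble(
    cl_realized_ml_min_kg = x$cl_healthy_ml_min_kg,
    cl_specified_ml_min_kg = x$drug$hepatic_clearance_spec,
    kp_scale = x$drug$kp_scale,
    kp_method = x$kp_method,
    clearance_residual = val("clearance_residual"),
    kp_residual = val("kp_residual")
  )
}

#' @rdname tidy
#' @export
tidy.adjustment_result <- function(x, ...) {
  tidy_adjustment_row(x)
}

#' @rdname tidy
#' @export
glance.adjustment_result <- function(x, ...) {
  tibble::tibble(
    impairment = x$impairment,
    adjusted_rate = x$adjusted_rate,
    rate_reduction_pct = 100 * (1 - x$adjusted_rate / x$reference_rate),
    auc_matched = abs(x$auc0_3_ratio_to_healthy - 1) <= 0.02,
    kruskal_p_auc0_3 = x$kruskal_p_auc0_3
  )
}

#' @rdname tidy
#' @export
tidy.group_comparison <- function(x, ...) {
  x$dunn
}

#' @rdname tidy
#' @export
glance.group_comparison <- function(x, ...) {
  x$kruskal
}
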