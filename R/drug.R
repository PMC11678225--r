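#' Load drug parameters
#'
#' Reads a drug parameter file (YAML) into a `"drug_parameters"` object.
#' The packaged default is propofol.
#'
#' @param path Path to a drug YAML file; defaults to the shipped propofol
#'   file.
#' @return A list of class `"drug_parameters"` with fields `name`,
#'   `molecular_weight` (g/mol), `pka_acid`, `logp`, `solubility_ref`
#'   (mg/mL), `bp_ratio` (blood:plasma), `fu_plasma` (fraction),
#'   `hepatic_clearance_spec` (mL/min/kg) and `kp_scale`.
#' @export
#' @examples
#' propofol <- drug_parameters()
#' propofol$logp
drug_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "propofol.yaml", package = "canipbpk")
  }
  drug <- yaml::read_yaml(path)
  validate_drug_parameters(drug)
  class(drug) <- "drug_parameters"
  drug
}

validate_drug_parameters <- function(drug) {
  stopifnot(
    "molecular_weight must be > 0" = drug$molecular_weight > 0,
    "fu_plasma must be in (0, 1]" = drug$fu_plasma > 0 && drug$fu_plasma <= 1,
    "bp_ratio must be > 0" = drug$bp_ratio > 0,
    "hepatic_clearance_spec must be >= 0" = drug$hepatic_clearance_spec >= 0,
    "kp_scale must be > 0" = drug$kp_scale > 0
  )
  invisible(drug)
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters> %s: MW %.2f g/mol, logP %.2f, fu %.3f, B:P %.2f\n",
              x$name, x$molecular_weight, x$logp, x$fu_plasma, x$bp_ratio))
  cat(sprintf("  specified hepatic clearance %.2f mL/min/kg, kp_scale %.4g\n",
              x$hepatic_clearance_spec, x$kp_scale))
  invisible(x)
}

#' Tissue:plasma partition coefficients from tissue composition
#'
#' Computes an equilibrium tissue:plasma partition coefficient (Kp) for each
#' organ from its water/lipid/protein composition and the drug's
#' lipophilicity and plasma protein binding, multiplied by the global
#' calibration factor `kp_scale`.
#'
#' Two schemes are available:
#' \describe{
#'   \item{`"composition"` (default)}{A lipid-fraction partitioning model
#'     with a tissue protein-binding correction:
#'     \deqn{Kp = \frac{P f_{nl,t} + (0.3P + 0.7) f_{ph,t} + f_{w,t}}
#'                     {P f_{nl,p} + (0.3P + 0.7) f_{ph,p} + f_{w,p}}
#'           \cdot \frac{fu_p}{fu_t}}
#'     with \eqn{P = 10^{logP}} and
#'     \eqn{fu_t = 1 / (1 + \frac{1-fu_p}{fu_p} \cdot f_{pr,t}/f_{pr,p})}.}
#'   \item{`"lipid_water"`}{A simpler two-phase scheme,
#'     \eqn{Kp = (f_{w,t} + P f_{lip,t}) / (f_{w,p} + P f_{lip,p})} with
#'     \eqn{f_{lip} = f_{nl} + f_{ph}}, no binding correction.}
#' }
#' Both schemes return exactly `kp_scale` when an organ has the same
#' composition as plasma.
#'
#' @param drug A `"drug_parameters"` object.
#' @param organs A tibble of organ compositions (columns `name`, `f_water`,
#'   `f_neutral_lipid`, `f_phospholipid`, `f_protein`), e.g.
#'   `build_reference_dog(10.5)$organs`, or a single-row tibble.
#' @param plasma One-row tibble with the plasma composition (same `f_*`
#'   columns).
#' @param method `"composition"` or `"lipid_water"`.
#' @return A tibble with columns `name`, `kp`, `method`.
#' @export
#' @examples
#' dog <- build_reference_dog(10.5)
#' compute_kp(drug_parameters(), dog$organs, dog$plasma_composition)
compute_kp <- function(drug, organs, plasma, method = c("composition", "lipid_water")) {
  method <- match.arg(method)
  frac_cols <- c("f_water", "f_neutral_lipid", "f_phospholipid", "f_protein")
  fr <- unlist(c(organs[frac_cols], plasma[frac_cols]))
  if (any(fr < 0)) stop("negative composition fractions are not allowed")
  p <- 10^drug$logp
  lipo <- function(fw, fnl, fph) p * fnl + (0.3 * p + 0.7) * fph + fw
  denom_comp <- lipo(plasma$f_water, plasma$f_neutral_lipid, plasma$f_phospholipid)
  denom_lw <- plasma$f_water + p * (plasma$f_neutral_lipid + plasma$f_phospholipid)
  if (denom_comp <= 0 || denom_lw <= 0) {
    stop("plasma composition gives a zero partition denominator")
  }
  kp <- switch(
    method,
    composition = {
      if (plasma$f_protein <= 0) stop("plasma protein fraction must be > 0 for the composition scheme")
      fu_p <- drug$fu_plasma
      fu_t <- 1 / (1 + ((1 - fu_p) / fu_p) * organs$f_protein / plasma$f_protein)
      lipo(organs$f_water, organs$f_neutral_lipid, organs$f_phospholipid) /
        denom_comp * (fu_p / fu_t)
    },
    lipid_water = {
      (organs$f_water + p * (organs$f_neutral_lipid + organs$f_phospholipid)) /
        denom_lw
    }
  )
  tibble::tibble(name = organs$name, kp = drug$kp_scale * kp, method = method)
}
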