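#' Load the canine whole-body physiology template
#'
#' Reads the packaged reference physiology for an adult dog: organ volume
#' fractions, regional blood-flow fractions, tissue composition, cardiac
#' output allometry and blood-pool sizes. The template is the single source
#' of anatomical truth for [build_reference_dog()].
#'
#' @param path Path to a physiology YAML file. Defaults to the file shipped
#'   with the package.
#' @return A list of class `"physiology_template"` with elements
#'   `reference_body_weight_kg`, `cardiac_output_ml_min_per_kg075`,
#'   `flow_exponent`, `hematocrit`, `venous_blood_fraction`,
#'   `arterial_blood_fraction`, `plasma_composition` (one-row tibble),
#'   `organs` (tibble, one row per organ) and `portal_organs`.
#' @export
#' @examples
#' tpl <- physiology_template()
#' tpl$organs
physiology_template <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "canine_physiology.yaml", package = "canipbpk")
  }
  raw <- yaml::read_yaml(path)
  organs <- dplyr::bind_rows(lapply(raw$organs, tibble::as_tibble))
  tpl <- list(
    reference_body_weight_kg = raw$reference_body_weight_kg,
    cardiac_output_ml_min_per_kg075 = raw$cardiac_output_ml_min_per_kg075,
    flow_exponent = raw$flow_exponent,
    hematocrit = raw$hematocrit,
    venous_blood_fraction = raw$venous_blood_fraction,
    arterial_blood_fraction = raw$arterial_blood_fraction,
    plasma_composition = tibble::as_tibble(raw$plasma_composition),
    organs = organs,
    portal_organs = raw$portal_organs
  )
  class(tpl) <- "physiology_template"
  tpl
}

#' Write a physiology template back to YAML
#'
#' Round-trips the structure produced by [physiology_template()] so that a
#' modified template can be saved and reloaded bit-identically.
#'
#' @param template A `"physiology_template"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_physiology_template <- function(template, path) {
  out <- list(
    reference_body_weight_kg = template$reference_body_weight_kg,
    cardiac_output_ml_min_per_kg075 = template$cardiac_output_ml_min_per_kg075,
    flow_exponent = template$flow_exponent,
    hematocrit = template$hematocrit,
    venous_blood_fraction = template$venous_blood_fraction,
    arterial_blood_fraction = template$arterial_blood_fraction,
    plasma_composition = as.list(template$plasma_composition),
    organs = lapply(seq_len(nrow(template$organs)), function(i) {
      as.list(template$organs[i, ])
    }),
    portal_organs = template$portal_organs
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Build a body-weight-scaled virtual dog
#'
#' Scales the reference canine physiology to a target body weight. Organ
#' volumes and blood pools scale linearly with body weight; cardiac output
#' (and therefore every regional flow) scales allometrically with
#' `BW^flow_exponent` (0.75 by default).
#'
#' @param body_weight Body weight in kg; must be a single positive finite
#'   number.
#' @param template Physiology template, see [physiology_template()].
#' @param hematocrit Optional hematocrit override (fraction).
#' @param lumped If `TRUE`, collapse the non-eliminating peripheral organs
#'   into two lumped compartments (richly and slowly perfused) for fast
#'   exploratory runs. The liver, lung, gut and spleen are kept explicit so
#'   hepatic elimination and portal drainage are unchanged.
#' @return A list of class `"canine_physiology"`: `body_weight` (kg),
#'   `cardiac_output` (mL/min), `hematocrit`, `venous_blood_volume` and
#'   `arterial_blood_volume` (mL), `portal_organs`, `plasma_composition`,
#'   and `organs` — a tibble with the template columns plus absolute
#'   `volume_ml` and `flow_ml_min`.
#' @export
#' @examples
#' dog <- build_reference_dog(10.5)
#' sum(dog$organs$volume_ml) / 1000 # litres of organ tissue
build_reference_dog <- function(body_weight,
                                template = physiology_template(),
                                hematocrit = NULL,
                                lumped = FALSE) {
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("`body_weight` must be a single positive finite number (kg), got: ",
         deparse(substitute(body_weight)), " = ", format(body_weight))
  }
  organs <- template$organs
  if (lumped) organs <- lump_organs(organs)
  co <- template$cardiac_output_ml_min_per_kg075 * body_weight^template$flow_exponent
  organs <- organs |>
    dplyr::mutate(
      volume_ml = .data$volume_fraction * body_weight * 1000,
      flow_ml_min = .data$flow_fraction * co
    )
  phys <- list(
    body_weight = body_weight,
    cardiac_output = co,
    hematocrit = if (is.null(hematocrit)) template$hematocrit else hematocrit,
    venous_blood_volume = template$venous_blood_fraction * body_weight * 1000,
    arterial_blood_volume = template$arterial_blood_fraction * body_weight * 1000,
    portal_organs = intersect(template$portal_organs, organs$name),
    plasma_composition = template$plasma_composition,
    organs = organs
  )
  class(phys) <- "canine_physiology"
  phys
}

# Collapse peripheral non-portal, non-eliminating organs into richly- and
# slowly-perfused pools; composition is volume-weighted so partitioning stays
# comparable to the full model.
lump_organs <- function(organs) {
  keep <- c("lung", "liver", "gut", "spleen")
  rich_names <- c("kidney", "brain", "heart", "rest")
  slow_names <- c("muscle", "fat", "skin", "bone")
  pool <- function(df, nm) {
    w <- df$volume_fraction / sum(df$volume_fraction)
    tibble::tibble(
      name = nm,
      volume_fraction = sum(df$volume_fraction),
      flow_fraction = sum(df$flow_fraction),
      f_water = sum(w * df$f_water),
      f_neutral_lipid = sum(w * df$f_neutral_lipid),
      f_phospholipid = sum(w * df$f_phospholipid),
      f_protein = sum(w * df$f_protein)
    )
  }
  dplyr::bind_rows(
    organs[organs$name %in% keep, ],
    pool(organs[organs$name %in% rich_names, ], "richly_perfused"),
    pool(organs[organs$name %in% slow_names, ], "slowly_perfused")
  )
}

#' Check the anatomical and circulatory invariants of a virtual dog
#'
#' Runs the conservation checks the simulator relies on: total tissue plus
#' blood volume close to body weight (assuming unit density), systemic flow
#' fractions summing to one at the venous pool, the lung carrying the whole
#' cardiac output, all fractions inside \[0, 1\], and tissue composition
#' fractions summing to at most one. Reports, never throws.
#'
#' @param phys A `"canine_physiology"` object.
#' @return A tibble with one row per check: `check`, `passed`, `value`,
#'   `detail`.
#' @export
#' @examples
#' validate_physiology(build_reference_dog(10.5))
validate_physiology <- function(phys) {
  organs <- phys$organs
  systemic <- organs[organs$name != "lung", ]
  total_vol_l <- (sum(organs$volume_ml) + phys$venous_blood_volume +
                    phys$arterial_blood_volume) / 1000
  vol_ratio <- total_vol_l / phys$body_weight
  flow_sum <- sum(systemic$flow_fraction)
  lung_flow <- organs$flow_fraction[organs$name == "lung"]
  comp_sum <- organs$f_water + organs$f_neutral_lipid +
    organs$f_phospholipid + organs$f_protein
  frac_cols <- c("volume_fraction", "flow_fraction", "f_water",
                 "f_neutral_lipid", "f_phospholipid", "f_protein")
  frac_vals <- unlist(organs[frac_cols])
  bad_comp <- organs$name[comp_sum > 1 + 1e-9]
  tibble::tibble(
    check = c("total_volume_vs_body_weight", "systemic_flow_conservation",
              "lung_receives_cardiac_output", "fractions_in_unit_interval",
              "composition_sums_le_one"),
    passed = c(
      vol_ratio > 0.85 && vol_ratio < 1.05,
      abs(flow_sum - 1) < 1e-6,
      length(lung_flow) == 1 && abs(lung_flow - 1) < 1e-9,
      all(frac_vals >= 0 & frac_vals <= 1),
      length(bad_comp) == 0
    ),
    value = c(vol_ratio, flow_sum, if (length(lung_flow)) lung_flow else NA_real_,
              max(frac_vals), max(comp_sum)),
    detail = c(
      sprintf("total volume / BW = %.4f (accepted range 0.85-1.05)", vol_ratio),
      sprintf("systemic flow fractions sum to %.8f", flow_sum),
      if (length(lung_flow)) sprintf("lung flow fraction = %.6f", lung_flow)
      else "no lung compartment found",
      sprintf("largest fraction = %.4f", max(frac_vals)),
      if (length(bad_comp) == 0) "all organ compositions sum to <= 1"
      else paste("composition exceeds 1 in:", paste(bad_comp, collapse = ", "))
    )
  )
}

#' @export
print.canine_physiology <- function(x, ...) {
  cat(sprintf("<canine_physiology> %.2f kg dog, CO %.0f mL/min, Hct %.2f\n",
              x$body_weight, x$cardiac_output, x$hematocrit))
  cat(sprintf("  %d organs + venous (%.0f mL) / arterial (%.0f mL) blood\n",
              nrow(x$organs), x$venous_blood_volume, x$arterial_blood_volume))
  invisible(x)
}
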