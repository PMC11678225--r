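#' Plot a concentration profile
#'
#' @param profile A `"concentration_profile"` tibble (or any tibble with
#'   `time_h` and `conc_ug_ml`).
#' @param window Optional `"therapeutic_window"` drawn as reference lines.
#' @param log_y Log-scale the concentration axis.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, window = NULL, log_y = FALSE) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$time_h, y = .data$conc_ug_ml)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Time (h)", y = expression("Plasma propofol ("*mu*"g/mL)"))
  p <- add_window_lines(p, window)
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p + ggplot2::theme_minimal()
}

#' Plot a population summary band
#'
#' @param object A `"population_summary"` from [summarize_profiles()].
#' @param window Optional `"therapeutic_window"` drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.population_summary <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$central), color = "steelblue4",
                       linewidth = 0.8) +
    ggplot2::labs(
      x = "Time (h)", y = expression("Plasma propofol ("*mu*"g/mL)"),
      title = sprintf("Population %s with central band (n = %d)",
                      attr(object, "type") %||% "median", max(object$n))
    )
  add_window_lines(p, window) + ggplot2::theme_minimal()
}

#' Compare population median profiles across impairment arms
#'
#' @param report An `"impairment_report"` from [run_full_analysis()].
#' @param adjusted Plot the adjusted-protocol medians instead of the
#'   unadjusted ones.
#' @return A ggplot object.
#' @export
plot_impairment_medians <- function(report, adjusted = FALSE) {
  if (adjusted) {
    dfs <- purrr::imap(report$adjustments, function(a, nm) {
      dplyr::mutate(a$median_profile, arm = nm)
    })
    healthy <- report$unadjusted[report$unadjusted$impairment == 0, ]
    dfs <- c(list(dplyr::mutate(healthy$median_profile[[1]], arm = "healthy")), dfs)
  } else {
    dfs <- purrr::map(seq_len(nrow(report$unadjusted)), function(i) {
      row <- report$unadjusted[i, ]
      dplyr::mutate(row$median_profile[[1]],
                    arm = sprintf("HI%02.0f", 100 * row$impairment))
    })
  }
  df <- dplyr::bind_rows(dfs)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$conc_ug_ml,
                                        color = .data$arm)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Time (h)", y = expression("Plasma propofol ("*mu*"g/mL)"),
                  color = "Arm")
  add_window_lines(p, report$window) + ggplot2::theme_minimal()
}

#' Predicted versus observed exposure plot
#'
#' @param tab Output of [pred_obs_table()].
#' @return A ggplot object with identity and two-fold error lines.
#' @export
plot_pred_obs <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$auc_obs, y = .data$auc_sim,
                                    shape = .data$role)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = log10(2), linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = -log10(2), linetype = 2) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression("Observed AUC ("*mu*"g·h/mL)"),
                  y = expression("Simulated AUC ("*mu*"g·h/mL)"),
                  shape = "Study role") +
    ggplot2::theme_minimal()
}

add_window_lines <- function(p, window) {
  if (is.null(window)) return(p)
  p +
    ggplot2::geom_hline(yintercept = c(window$lower, window$upper), linetype = 2,
                        color = "grey40") +
    ggplot2::geom_hline(yintercept = window$recovery_threshold, color = "black",
                        linewidth = 0.3)
}
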