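#' Plot replicate-level dose-response data
#'
#' Shows the individual well values and the per-concentration group means for
#' each endpoint of one or more materials. Concentrations are spaced on a
#' pseudo-log axis so the geometric series reads evenly.
#'
#' @param observations An observation tibble (see [read_observations()]).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(observations) {
  check_columns(observations,
                c("material", "endpoint", "concentration_ug_per_ml", "value"),
                "observations")
  means <- dplyr::summarise(
    dplyr::group_by(observations, .data$material, .data$endpoint,
                    .data$concentration_ug_per_ml),
    value = mean(.data$value), .groups = "drop"
  )
  ggplot2::ggplot(observations,
                  ggplot2::aes(x = .data$concentration_ug_per_ml, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = means, colour = "steelblue") +
    ggplot2::geom_point(data = means, colour = "steelblue", size = 2) +
    ggplot2::scale_x_continuous(trans = "pseudo_log") +
    ggplot2::facet_grid(endpoint ~ material, scales = "free_y") +
    ggplot2::labs(x = "concentration [µg/mL]", y = "endpoint value") +
    ggplot2::theme_bw()
}

#' Threshold plot for a prediction-model result
#'
#' Displays every significant endpoint LOAEC as a surface-area dose on a log
#' axis, one column per material, with the classification threshold as a
#' horizontal line. Points below the line are the flags that drive the
#' two-of-four rule; the material labels are coloured by the final call.
#'
#' @param object An `am_prediction` object from [run_prediction_model()].
#' @param threshold_mm2_per_ml Threshold line (default 6000 mm2/mL).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.am_prediction <- function(object, threshold_mm2_per_ml = 6000, ...) {
  flags <- object$flags[!is.na(object$flags$mm2_per_ml), ]
  order_tbl <- dplyr::arrange(object$classification, dplyr::desc(.data$n_below))
  flags$material <- factor(flags$material, levels = order_tbl$material)
  calls <- dplyr::select(object$classification, "material", "call")
  flags <- dplyr::left_join(flags, calls, by = "material")
  ggplot2::ggplot(flags,
                  ggplot2::aes(x = .data$material, y = .data$mm2_per_ml,
                               shape = .data$endpoint, colour = .data$call)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = threshold_mm2_per_ml, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "in vitro LOAEC [mm²/mL]",
                  colour = "in vitro call", shape = "endpoint") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.am_loaec <- function(object, ...) {
  tab <- object$p_table
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$concentration_ug_per_ml),
                                    y = .data$p_adj)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "concentration [µg/mL]",
                  y = "Dunnett-adjusted p",
                  title = sprintf("%s / %s", object$material, object$endpoint)) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
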