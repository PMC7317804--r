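#' Spaghetti plot of D-dimer trajectories by prospective VTE status
#'
#' One line per patient on the chosen scale, faceted by whether the patient
#' went on to develop VTE, with a LOESS moving average overlaid. Purely
#' descriptive: it conditions on the future event status.
#'
#' @param data An `analysis_dataset`.
#' @param scale `"original_ugml"` or `"log2"`.
#' @return A ggplot.
#' @export
plot_trajectories <- function(data, scale = c("original_ugml", "log2")) {
  scale <- match.arg(scale)
  df <- model_frame(data, scale, "days") |>
    dplyr::mutate(vte_group = ifelse(.data$event_type == "VTE",
                                     "VTE during follow-up", "No VTE"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_days, y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       alpha = 0.25, colour = "grey40") +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 1) +
    ggplot2::facet_wrap(~vte_group) +
    ggplot2::labs(x = "Days from baseline",
                  y = if (scale == "log2") "log2 D-dimer" else
                    "D-dimer (µg/mL)") +
    ggplot2::theme_minimal()
}
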