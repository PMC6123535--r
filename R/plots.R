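# Figure helpers: cost-effectiveness plane and sorted prediction panels.

#' Cost-effectiveness plane plot
#'
#' Scatter of per-patient (delta QALY, delta cost), BT minus TAU, with
#' concordant patients (received the recommended arm) drawn as crosses and
#' discordant patients as open circles, plus the willingness-to-pay ray
#' through the origin.
#'
#' @param records a [recommendation_records()] data.frame.
#' @param wtp threshold used for the ray; defaults to the one the records
#'   were built with.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(records, wtp = attr(records, "wtp") %||% 25000) {
  df <- ce_plane_export(records)
  df$status <- ifelse(df$concordant, "concordant", "discordant")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_q, y = .data$delta_c)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status,
                                     colour = .data$status), size = 2) +
    ggplot2::scale_shape_manual(values = c(concordant = 4, discordant = 1)) +
    ggplot2::scale_colour_manual(values = c(concordant = "forestgreen",
                                            discordant = "firebrick")) +
    ggplot2::labs(x = "Δ QALY (BT - TAU)", y = "Δ cost, € (BT - TAU)",
                  title = sprintf("Cost-effectiveness plane (WTP %s €/QALY)",
                                  format(wtp, big.mark = ",")),
                  shape = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Sorted predicted-vs-observed panel
#'
#' Predictions sorted in ascending order (line) with the corresponding
#' observed values overlaid (points) — a visual check of calibration and
#' spread for one arm and target.
#'
#' @param predictions,observed aligned numeric vectors (e.g. a
#'   `cv_result`'s held-out predictions).
#' @param label axis label for the target (e.g. `"QALY"` or `"cost (€)"`).
#' @return A ggplot object.
#' @export
plot_sorted_predictions <- function(predictions, observed, label = "value") {
  ord <- order(predictions)
  df <- data.frame(rank = seq_along(ord),
                   predicted = predictions[ord], observed = observed[ord])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "black",
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "blue") +
    ggplot2::labs(x = "patient (sorted by prediction)", y = label) +
    ggplot2::theme_minimal()
}
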