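# Additional plotting helpers (autoplot methods for fitted objects live
# with their classes).

#' Plot pooled Learned / Not-Learned learning curves
#'
#' @param pooled The `pooled` tibble from [classify_slots()].
#' @return A ggplot, one panel per rat.
#' @export
plot_learning_curves <- function(pooled) {
  ggplot2::ggplot(pooled, ggplot2::aes(x = .data$day, y = .data$value,
                                       colour = .data$slot_set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~rat_id) +
    ggplot2::scale_colour_manual(values = c(Learned = "firebrick",
                                            NotLearned = "steelblue")) +
    ggplot2::labs(x = "Training day", y = "Successes per reach",
                  colour = NULL)
}

#' Plot cross-array channel variability
#'
#' Bar chart of the red- versus green-channel standard deviation at
#' each signal percentile, the common-reference QC contrast.
#'
#' @param qc Tibble from [channel_variability()].
#' @return A ggplot.
#' @export
plot_channel_variability <- function(qc) {
  long <- tidyr::pivot_longer(qc[, c("percentile", "sd_red", "sd_green")],
                              cols = c("sd_red", "sd_green"),
                              names_to = "channel", values_to = "sd")
  long$channel <- ifelse(long$channel == "sd_red", "red (sample)",
                         "green (reference)")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$percentile),
                                     y = .data$sd, fill = .data$channel)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("red (sample)" = "grey20",
                                          "green (reference)" = "grey75")) +
    ggplot2::labs(x = "Signal percentile", y = "SD across arrays",
                  fill = NULL)
}
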