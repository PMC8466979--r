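# ggplot2 displays for the package's result types.

#' Plot a contingency table as a heatmap
#'
#' @param t A `contingency_table`.
#' @return A ggplot.
#' @export
plot_contingency <- function(t) {
  tidy(t) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$predicted),
                                 y = factor(.data$observed),
                                 fill = .data$count)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#d7301f") +
    ggplot2::labs(x = "predicted risk class", y = "observed risk class",
                  fill = "hours") +
    ggplot2::theme_minimal()
}

#' Plot a WBGT time series with risk-level bands
#'
#' @param data Output of [compute_wbgt()] with a `timestamp_local` column.
#' @param profile A [worker_profile()] whose reference limit draws the
#'   class boundaries (80%, 100%, 120% of the limit).
#' @return A ggplot.
#' @export
plot_wbgt_series <- function(data, profile = worker_profile()) {
  lim <- reference_limit(profile)
  long <- data |>
    tidyr::pivot_longer(dplyr::all_of(c("wbgt_shade_c", "wbgt_sun_c")),
                        names_to = "exposure", values_to = "wbgt_c",
                        names_pattern = "wbgt_(.*)_c")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timestamp_local,
                                     y = .data$wbgt_c,
                                     color = .data$exposure)) +
    ggplot2::geom_hline(yintercept = lim * c(0.8, 1, 1.2),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "WBGT (°C)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-area skill scores of a validation run
#'
#' @param object A `heatrisk_validation`.
#' @param scores Which scores to show.
#' @param ... Unused.
#' @return A ggplot: bars per area, faceted by score, one panel set per
#'   exposure.
#' @method autoplot heatrisk_validation
#' @export
autoplot.heatrisk_validation <- function(object,
                                         scores = c("hr", "csi", "pod1",
                                                    "pod2", "na", "fa"),
                                         ...) {
  tidy(object, level = "area") |>
    dplyr::filter(.data$score %in% scores) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$area, y = .data$value,
                                 fill = .data$exposure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::labs(x = "macro-area", y = "%", fill = "exposure") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
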