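#' Agreement and accuracy across clustering thresholds
#'
#' The classic sweep figure: the number of clusters relative to the
#' species count (*agreement*) and the fraction of species recovered as
#' perfect clusters (*taxonomic accuracy*), as the threshold moves from
#' oversplitting to lumping.
#'
#' @param sweep_tbl tibble from [threshold_sweep()].
#' @return A ggplot.
#' @export
plot_threshold_sweep <- function(sweep_tbl) {
  df <- tidyr::pivot_longer(
    sweep_tbl[, c("threshold", "agreement_pct", "accuracy_pct")],
    cols = c("agreement_pct", "accuracy_pct"),
    names_to = "metric", values_to = "pct"
  )
  df$metric <- ifelse(df$metric == "agreement_pct", "agreement",
                      "taxonomic accuracy")
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$threshold, y = .data$pct,
                                   color = .data$metric)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = c("agreement" = "#1f78b4",
                                           "taxonomic accuracy" = "#ff7f00")) +
    ggplot2::labs(x = "clustering threshold (% divergence)", y = "%",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Barcoding-gap histogram
#'
#' Overlaid distributions of the largest intraspecific distance and the
#' smallest congeneric interspecific distance; a gap between them is the
#' barcoding gap, overlap signals lumping risk.
#'
#' @param gap tibble from [barcoding_gap_table()].
#' @param binwidth histogram bin width on the p-distance scale.
#' @return A ggplot.
#' @export
plot_barcoding_gap <- function(gap, binwidth = 0.005) {
  df <- tidyr::pivot_longer(
    gap[, c("species", "max_intra", "min_inter_congeneric")],
    cols = c("max_intra", "min_inter_congeneric"),
    names_to = "statistic", values_to = "distance"
  )
  df <- df[!is.na(df$distance), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$statistic)) +
    ggplot2::geom_histogram(binwidth = binwidth, alpha = 0.6,
                            position = "identity") +
    ggplot2::scale_fill_manual(values = c(max_intra = "#1f78b4",
                                          min_inter_congeneric = "#ff7f00")) +
    ggplot2::labs(x = "uncorrected p-distance", y = "species", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Distance decay of Sørensen similarity
#'
#' @param sorensen_tbl tibble from [sorensen()] with a `distance_km`
#'   column; an optional `partition` column facets/colors by partition
#'   kind.
#' @return A ggplot.
#' @export
plot_distance_decay <- function(sorensen_tbl) {
  aes <- if ("partition" %in% names(sorensen_tbl)) {
    ggplot2::aes(x = .data$distance_km, y = .data$S, color = .data$partition)
  } else {
    ggplot2::aes(x = .data$distance_km, y = .data$S)
  }
  ggplot2::ggplot(sorensen_tbl, aes) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "distance between regions (km)",
                  y = "Sørensen similarity") +
    ggplot2::theme_minimal()
}
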