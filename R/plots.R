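#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a relation-index null distribution with observed pairs marked
#'
#' Histograms of the I, J and M null distributions over random disease
#' pairs, faceted by index, with a vertical line per observed disease pair
#' when a report is supplied — the standard picture for judging how far a
#' comorbid pair sits in the tail of the random-pair distribution.
#'
#' @param object A [relation_index_null()].
#' @param report Optional [relation_indices()] result whose observed
#'   indices are marked.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot relation_index_null
#' @export
autoplot.relation_index_null <- function(object, report = NULL, bins = 40,
                                         ...) {
  long <- tidyr::pivot_longer(object$values, cols = c("i", "j", "m"),
                              names_to = "index", values_to = "value")
  long$index <- toupper(long$index)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65",
                            colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(x = "index value under the random-pair null",
                  y = "replicates",
                  title = sprintf("Relation-index null (n = %d)",
                                  object$n)) +
    ggplot2::theme_minimal()
  if (!is.null(report)) {
    obs <- tidy(report)
    obs$index <- obs$index
    obs$pair <- paste(obs$disease_a, obs$disease_b, sep = " & ")
    p <- p + ggplot2::geom_vline(
      data = obs,
      ggplot2::aes(xintercept = .data$value, colour = .data$pair),
      linewidth = 0.6) +
      ggplot2::labs(colour = "observed pair")
  }
  p
}

#' Plot a connectivity null with the observed connectivity marked
#'
#' @param object A [score_connectivity()] result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot connectivity_report
#' @export
autoplot.connectivity_report <- function(object, bins = 30, ...) {
  df <- tibble::tibble(value = object$null$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65",
                            colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$observed,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("connectivity (%s) of degree-matched random networks",
                  object$statistic),
      y = "replicates",
      title = sprintf("Observed %d, p = %.3g (n = %d)", object$observed,
                      object$p_value, object$n_null)) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment table: connectivity rate against significance
#'
#' Each point is an overrepresented term, placed by its BH q-value
#' (-log10) and its connectivity rate; terms in the upper right are both
#' significant and tightly interconnected — the specific processes CR
#' ranking is designed to surface.
#'
#' @param object An enrichment table with CR filled (see
#'   [add_connectivity_rate()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enriched_processes
#' @export
autoplot.enriched_processes <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$cr), ]
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q_value),
                                   y = .data$cr, size = .data$k)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(x = expression(-log[10] * "(BH q-value)"),
                  y = "connectivity rate (CR)",
                  size = "study genes") +
    ggplot2::theme_minimal()
}
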