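#' Plot observed versus leave-one-out predicted rates
#'
#' @param object a [loocv_evaluate()] result.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.loocv_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "measured proliferation rate (1/h)",
                  y = "LOOCV-predicted rate (1/h)",
                  title = sprintf("validation R² = %.3f",
                                  glance(object)$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot the conserved-gene filter report
#'
#' Per-gene corrected distances on the two comparisons, with the
#' acceptance band.
#'
#' @param object a [filter_conserved_genes()] report.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_filter_report <- function(object, ...) {
  d <- filter(as_tibble(object), .data$in_all)
  band <- attr(object, "max_dist")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dist_array,
                                  y = .data$dist_rnaseq,
                                  colour = .data$passed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = band, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = band, linetype = "dashed") +
    ggplot2::labs(x = "|corrected reference - cohort array| (log2)",
                  y = "|corrected reference - cohort RNA-seq| (log2)") +
    ggplot2::theme_minimal()
}

#' Plot normalized enrichment scores
#'
#' @param object a [normalize_enrichment()] result.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, ...) {
  d <- as_tibble(object)
  d$p <- ifelse(d$es >= 0, d$p_pos, d$p_neg)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nes,
                                  y = stats::reorder(.data$pathway,
                                                     .data$nes),
                                  colour = .data$p)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "normalized enrichment score",
                  y = NULL, colour = "empirical p") +
    ggplot2::theme_minimal()
}

#' Heatmap of a flux matrix
#'
#' @param object a [batch_pfba()] flux matrix.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.flux_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reaction, y = .data$sample_id,
                                  fill = .data$flux)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "flux") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
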