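#' Cross-platform linear model
#'
#' The mapping from reference-platform to cohort-platform log2
#' expression is modeled as `e_cohort = alpha * e_reference + beta`,
#' where `alpha` is a platform-specific factor and `beta` a dataset
#' (sample-quantity) shift. The two parameters are estimated separately:
#' `alpha` from a matched dual-platform sample set (same samples, so
#' `beta = 0`) and `beta` from a same-platform comparison between the
#' reference and cohort datasets (same platform, so `alpha = 1`).
#'
#' @param alpha platform factor, finite and > 0.
#' @param beta dataset shift, finite.
#' @return an object of class `platform_model`.
#' @export
platform_model <- function(alpha, beta) {
  if (!(is.finite(alpha) && alpha > 0)) abort("`alpha` must be finite and > 0.")
  if (!is.finite(beta)) abort("`beta` must be finite.")
  structure(list(alpha = alpha, beta = beta), class = "platform_model")
}

#' @export
print.platform_model <- function(x, ...) {
  cat(sprintf("<platform_model> alpha = %.6g, beta = %.6g\n",
              x$alpha, x$beta))
  invisible(x)
}

#' @export
tidy.platform_model <- function(x, ...) {
  tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

# reduce a matrix (or named vector) to per-gene means
gene_means <- function(x, arg = "x") {
  if (is.matrix(x) || inherits(x, "log_expr")) {
    return(rowMeans(as_expr_matrix(x, arg)))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  abort(sprintf(
    "`%s` must be a genes x samples matrix or a named numeric vector.", arg))
}

#' Fit the platform factor alpha
#'
#' Zero-intercept least squares of cohort-platform on reference-platform
#' per-gene mean log2 expression over a matched (same-sample) set:
#' `alpha = sum(x * y) / sum(x^2)` with `x` the array means and `y` the
#' sequencing means, over the common gene set.
#'
#' @param matched_array,matched_rnaseq genes x samples matrices (or named
#'   per-gene mean vectors) covering the same samples.
#' @return the scalar `alpha`.
#' @export
fit_alpha <- function(matched_array, matched_rnaseq) {
  if ((is.matrix(matched_array) || inherits(matched_array, "log_expr")) &&
      (is.matrix(matched_rnaseq) || inherits(matched_rnaseq, "log_expr"))) {
    common_samples <- intersect(colnames(matched_array),
                                colnames(matched_rnaseq))
    if (length(common_samples) == 0L) {
      abort("the two matrices share no samples.")
    }
    matched_array <- as_expr_matrix(matched_array)[, common_samples,
                                                   drop = FALSE]
    matched_rnaseq <- as_expr_matrix(matched_rnaseq)[, common_samples,
                                                     drop = FALSE]
  }
  x <- gene_means(matched_array, "matched_array")
  y <- gene_means(matched_rnaseq, "matched_rnaseq")
  genes <- intersect(names(x), names(y))
  if (length(genes) == 0L) abort("no common genes between the platforms.")
  x <- x[genes]
  y <- y[genes]
  sxx <- sum(x^2)
  if (sxx == 0) abort("degenerate input: sum(x^2) is zero.")
  sum(x * y) / sxx
}

#' Fit the dataset shift beta
#'
#' Mean over the common gene set of the per-gene difference between
#' cohort and reference mean log2 expression, both measured on the same
#' platform.
#'
#' @param reference_means,cohort_means named per-gene mean vectors (or
#'   genes x samples matrices, reduced to row means).
#' @return the scalar `beta`.
#' @export
fit_beta <- function(reference_means, cohort_means) {
  r <- gene_means(reference_means, "reference_means")
  co <- gene_means(cohort_means, "cohort_means")
  genes <- intersect(names(r), names(co))
  if (length(genes) == 0L) abort("no common genes between the datasets.")
  mean(co[genes] - r[genes])
}

#' Apply the platform correction
#'
#' Elementwise `alpha * e + beta`, mapping reference-platform log2
#' expression onto the cohort-platform scale.
#'
#' @param reference_values numeric vector or matrix of log2 expression.
#' @param model a [platform_model()].
#' @return the corrected values, same shape as the input.
#' @export
correct_expression <- function(reference_values, model) {
  stopifnot(inherits(model, "platform_model"))
  model$alpha * reference_values + model$beta
}

#' Invert the platform correction
#'
#' Maps cohort-platform values back to the reference scale:
#' `(e - beta) / alpha`.
#'
#' @inheritParams correct_expression
#' @param cohort_values numeric vector or matrix on the cohort scale.
#' @export
uncorrect_expression <- function(cohort_values, model) {
  stopifnot(inherits(model, "platform_model"))
  (cohort_values - model$beta) / model$alpha
}

#' Filter genes with platform-conserved expression
#'
#' A gene passes when (i) it is present in all three mean maps, (ii) the
#' distance between its reference mean corrected by `beta` alone (same
#' platform, so `alpha = 1`) and its cohort array mean is strictly below
#' `max_dist`, and (iii) the distance between its reference mean
#' corrected by the full `(alpha, beta)` model and its cohort sequencing
#' mean is strictly below `max_dist`. With `max_dist = 1` on the log2
#' scale this is a corrected maximal difference of 2-fold.
#'
#' @param reference_array_means,cohort_array_means,cohort_rnaseq_means
#'   named per-gene mean log2 vectors (or matrices, reduced to row
#'   means).
#' @param model a [platform_model()].
#' @param max_dist band half-width on the log2 scale, > 0.
#' @return a tibble of class `gene_filter_report` with one row per gene
#'   of the union universe: `gene`, `dist_array`, `dist_rnaseq` (NA when
#'   absent from a map), `in_all`, `passed`; attributes `max_dist` and
#'   `universe_size`.
#' @export
filter_conserved_genes <- function(reference_array_means,
                                   cohort_array_means,
                                   cohort_rnaseq_means,
                                   model, max_dist = 1) {
  stopifnot(inherits(model, "platform_model"))
  if (!(max_dist > 0)) abort("`max_dist` must be > 0.")
  r <- gene_means(reference_array_means, "reference_array_means")
  ca <- gene_means(cohort_array_means, "cohort_array_means")
  cr <- gene_means(cohort_rnaseq_means, "cohort_rnaseq_means")
  universe <- sort(unique(c(names(r), names(ca), names(cr))))
  dist_array <- dist_rnaseq <- rep(NA_real_, length(universe))
  names(dist_array) <- names(dist_rnaseq) <- universe
  in_arr <- universe %in% names(r) & universe %in% names(ca)
  in_rna <- universe %in% names(r) & universe %in% names(cr)
  g_arr <- universe[in_arr]
  g_rna <- universe[in_rna]
  # (ii) same platform: beta-only correction (alpha = 1)
  dist_array[g_arr] <- abs((r[g_arr] + model$beta) - ca[g_arr])
  # (iii) cross platform: full model
  dist_rnaseq[g_rna] <-
    abs(correct_expression(r[g_rna], model) - cr[g_rna])
  in_all <- universe %in% names(r) & universe %in% names(ca) &
    universe %in% names(cr)
  passed <- in_all & !is.na(dist_array) & !is.na(dist_rnaseq) &
    dist_array < max_dist & dist_rnaseq < max_dist
  out <- tibble(gene = universe,
                dist_array = unname(dist_array),
                dist_rnaseq = unname(dist_rnaseq),
                in_all = in_all, passed = passed)
  structure(out, class = c("gene_filter_report", class(out)),
            max_dist = max_dist, universe_size = length(universe))
}

#' Fit the platform model and filter in one refined pass
#'
#' Convenience wrapper for the usual harmonization sequence: fit
#' `(alpha, beta)` on all shared genes, filter, then refit both
#' parameters on the passing genes only and filter once more. The
#' refinement step makes the estimates robust to genes whose expression
#' is not conserved across platforms (which otherwise bias the
#' all-gene fit); on a cohort without platform noise the refit recovers
#' the generating parameters exactly.
#'
#' @param reference genes x samples reference (cell-line) matrix or
#'   per-gene mean vector, array platform.
#' @param cohort_array,cohort_rnaseq cohort matrices (the array matrix
#'   is the dual-platform subset; both platforms must share samples for
#'   the `alpha` fit).
#' @param max_dist filter band, see [filter_conserved_genes()].
#' @param refine number of refit-and-refilter rounds (0 = single pass).
#' @return a list: `model` (a [platform_model()]), `report` (the final
#'   [filter_conserved_genes()] report), `genes` (passing gene ids).
#' @export
harmonize_platforms <- function(reference, cohort_array, cohort_rnaseq,
                                max_dist = 1, refine = 1L) {
  ref_means <- gene_means(reference, "reference")
  arr_means <- gene_means(cohort_array, "cohort_array")
  rna_means <- gene_means(cohort_rnaseq, "cohort_rnaseq")
  restrict <- function(x, genes) {
    if (is.matrix(x) || inherits(x, "log_expr")) {
      as_expr_matrix(x)[intersect(genes, rownames(x)), , drop = FALSE]
    } else {
      x[intersect(genes, names(x))]
    }
  }
  genes <- names(ref_means)
  model <- report <- NULL
  for (round in seq_len(refine + 1L)) {
    alpha <- fit_alpha(restrict(cohort_array, genes),
                       restrict(cohort_rnaseq, genes))
    beta <- fit_beta(ref_means[intersect(genes, names(ref_means))],
                     arr_means[intersect(genes, names(arr_means))])
    model <- platform_model(alpha, beta)
    report <- filter_conserved_genes(ref_means, arr_means, rna_means,
                                     model, max_dist = max_dist)
    genes <- passing_genes(report)
    if (length(genes) == 0L) {
      abort("no gene passed the conserved-expression filter.")
    }
  }
  list(model = model, report = report, genes = genes)
}

#' Genes passing the conserved-expression filter
#'
#' @param report a [filter_conserved_genes()] result.
#' @return character vector of passing gene ids.
#' @export
passing_genes <- function(report) {
  stopifnot(inherits(report, "gene_filter_report"))
  report$gene[report$passed]
}

#' @export
glance.gene_filter_report <- function(x, ...) {
  tibble(universe_size = attr(x, "universe_size"),
         n_in_all = sum(x$in_all), n_passed = sum(x$passed),
         max_dist = attr(x, "max_dist"))
}
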