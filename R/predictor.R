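#' Build second-order interaction features
#'
#' For `k` genes, emits one column per unordered gene pair (the product
#' of the two log2 expression values) plus one column per gene square,
#' i.e. `k*(k-1)/2 + k` columns. Columns are named `"a:b"` with
#' `a <= b` in the canonical (sorted) gene order; pair columns come
#' first (in lexicographic order), then the squares.
#'
#' @param gene_matrix genes x samples log2 matrix.
#' @param genes character vector of gene ids to combine (no duplicates).
#' @return a samples x features numeric matrix.
#' @export
build_interaction_features <- function(gene_matrix, genes) {
  m <- as_expr_matrix(gene_matrix, "gene_matrix")
  if (anyDuplicated(genes)) abort("duplicate gene in `genes`.")
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0L) {
    abort(sprintf("gene(s) not in the matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  genes <- sort(genes)
  e <- t(m[genes, , drop = FALSE])     # samples x genes
  k <- length(genes)
  cols <- list()
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        cols[[paste0(genes[i], ":", genes[j])]] <- e[, i] * e[, j]
      }
    }
  }
  for (i in seq_len(k)) {
    cols[[paste0(genes[i], ":", genes[i])]] <- e[, i]^2
  }
  out <- do.call(cbind, cols)
  rownames(out) <- colnames(m)
  out
}

parse_feature_names <- function(feature_names) {
  parts <- strsplit(feature_names, ":", fixed = TRUE)
  tibble(
    feature = feature_names,
    gene_a = vapply(parts, `[[`, "", 1L),
    gene_b = vapply(parts, function(p) {
      if (length(p) > 1L) p[[2L]] else NA_character_
    }, "")
  )
}

new_interaction_predictor <- function(features, coefficients, intercept,
                                      lambda) {
  stopifnot(nrow(features) == length(coefficients))
  structure(list(features = features,
                 coefficients = setNames(coefficients, features$feature),
                 intercept = intercept, lambda = lambda),
            class = "interaction_predictor")
}

#' @export
print.interaction_predictor <- function(x, ...) {
  cat(sprintf(paste0("<interaction_predictor> %d feature(s), %d non-zero, ",
                     "lambda = %.4g, intercept = %.4g\n"),
              length(x$coefficients), sum(x$coefficients != 0),
              x$lambda, x$intercept))
  invisible(x)
}

#' @export
tidy.interaction_predictor <- function(x, ...) {
  mutate(x$features, estimate = unname(x$coefficients))
}

#' @export
glance.interaction_predictor <- function(x, ...) {
  tibble(n_features = length(x$coefficients),
         n_nonzero = sum(x$coefficients != 0),
         lambda = x$lambda, intercept = x$intercept)
}

#' Fit an L1-regularized linear model with cross-validated strength
#'
#' Least squares with an L1 penalty along a regularization path; the
#' strength `lambda` is chosen as the one minimizing the k-fold
#' cross-validation mean squared error. Features are standardized
#' internally for the penalty and coefficients reported back on the
#' original feature scale.
#'
#' @param feature_matrix samples x features numeric matrix with named
#'   columns (single genes, or `"a:b"` products from
#'   [build_interaction_features()]).
#' @param targets numeric response, one value per sample.
#' @param seed integer seed controlling the fold assignment.
#' @param nfolds number of cross-validation folds.
#' @param lambda optional fixed penalty; when given, cross-validation is
#'   skipped and the coefficients at exactly this penalty are returned
#'   (0 gives the unpenalized least-squares limit).
#' @return an `interaction_predictor`.
#' @export
fit_lasso_cv <- function(feature_matrix, targets, seed = 1L, nfolds = 10,
                         lambda = NULL) {
  x <- feature_matrix
  if (is.null(colnames(x))) abort("feature columns must be named.")
  if (nrow(x) != length(targets)) {
    abort("`targets` must have one value per sample (row).")
  }
  if (anyNA(x) || any(!is.finite(x))) abort("non-finite feature values.")
  if (anyNA(targets) || any(!is.finite(targets))) {
    abort("non-finite target values.")
  }
  if (sd(targets) == 0) abort("constant target vector.")
  if (ncol(x) == 1L) {
    # a single surviving feature: the penalty path degenerates, so take
    # the unpenalized least-squares limit directly
    co <- stats::lm.fit(cbind(1, x), targets)$coefficients
    return(new_interaction_predictor(parse_feature_names(colnames(x)),
                                     unname(co[2L]), unname(co[1L]), 0))
  }
  if (is.null(lambda)) {
    if (nrow(x) < 10L) abort("need at least 10 samples.")
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, targets, alpha = 1, foldid = foldid,
                            standardize = TRUE,
                            grouped = nrow(x) >= 3L * nfolds)
    lam <- cv$lambda.min
    beta <- coef(cv, s = "lambda.min")
  } else {
    fit <- glmnet::glmnet(x, targets, alpha = 1, standardize = TRUE,
                          thresh = 1e-12)
    lam <- lambda
    beta <- coef(fit, s = lambda, exact = TRUE, x = x, y = targets,
                 thresh = 1e-12)
  }
  beta <- as.numeric(beta)[c(1L, seq_len(ncol(x)) + 1L)]
  new_interaction_predictor(parse_feature_names(colnames(x)),
                            beta[-1L], beta[1L], lam)
}

#' Select genes with clearly non-zero first-order coefficients
#'
#' @param first_order_fit an `interaction_predictor` whose features are
#'   all single genes.
#' @param tol absolute-coefficient threshold for "clearly non-zero".
#' @return sorted character vector of selected gene ids.
#' @export
select_nonzero_genes <- function(first_order_fit, tol = 1e-8) {
  stopifnot(inherits(first_order_fit, "interaction_predictor"))
  if (any(!is.na(first_order_fit$features$gene_b))) {
    abort("`first_order_fit` must contain single-gene features only.")
  }
  keep <- abs(first_order_fit$coefficients) > tol
  sort(first_order_fit$features$gene_a[keep])
}

#' Drop small coefficients and refit
#'
#' Removes the smallest quartile (fraction `q`) of the non-zero absolute
#' coefficients and refits the L1 model on the surviving features:
#' features at or below the interpolated `q` quantile of the non-zero
#' absolute coefficients are dropped, with the number of drops capped at
#' `floor(q * n_nonzero)` so a model whose support is already sparse is
#' not gutted (with, say, two non-zero coefficients the smallest
#' "quartile" is empty). The feature with the largest absolute
#' coefficient is always retained, so the model can never be emptied.
#'
#' @param fit an `interaction_predictor` with at least one non-zero
#'   coefficient.
#' @param q quantile of the non-zero absolute coefficients to cut at.
#' @param feature_matrix,targets the training data (needed for the
#'   refit).
#' @param seed integer seed for the refit's fold assignment.
#' @return the refit `interaction_predictor` on the surviving features.
#' @export
apply_coefficient_cutoff <- function(fit, q = 0.25, feature_matrix,
                                     targets, seed = 1L) {
  stopifnot(inherits(fit, "interaction_predictor"))
  ab <- abs(fit$coefficients)
  nz <- ab[ab > 0]
  if (length(nz) == 0L) abort("all coefficients are zero; nothing to cut.")
  if (q == 0) {
    keep <- ab > 0          # q = 0 disables the cutoff entirely
  } else {
    thr <- quantile(nz, q, type = 7, names = FALSE)
    keep <- ab > thr
    max_drop <- floor(q * length(nz))
    n_drop <- sum(ab > 0 & !keep)
    if (n_drop > max_drop) {
      # cap at the quartile's cardinality: spare the largest of the
      # would-be-dropped features
      ord <- order(ab, decreasing = TRUE)
      keep[ord[seq_len(length(nz) - max_drop)]] <- TRUE
    }
  }
  keep[which.max(ab)] <- TRUE
  cols <- fit$features$feature[keep]
  fit_lasso_cv(feature_matrix[, cols, drop = FALSE], targets, seed = seed)
}

#' The five fit metrics
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return a one-row tibble: `mse`, `rmse`, `mae`, `mre` (mean of
#'   `|p - o| / |o|` over non-zero `o`), `r_squared`
#'   (`1 - SS_res / SS_tot`; `NA` when the observations are constant).
#' @export
compute_fit_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) == 0L) {
    abort("`predicted` and `observed` must have equal non-zero length.")
  }
  err <- predicted - observed
  mse <- mean(err^2)
  nz <- observed != 0
  ss_tot <- sum((observed - mean(observed))^2)
  tibble(
    mse = mse,
    rmse = sqrt(mse),
    mae = mean(abs(err)),
    mre = if (any(nz)) mean(abs(err[nz]) / abs(observed[nz])) else NA_real_,
    r_squared = if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_
  )
}

#' Predict with an interaction predictor
#'
#' @param object an `interaction_predictor`.
#' @param newdata genes x samples log2 matrix containing every model
#'   gene.
#' @param ... unused.
#' @return numeric vector of predictions, one per sample.
#' @export
predict.interaction_predictor <- function(object, newdata, ...) {
  m <- as_expr_matrix(newdata, "newdata")
  ft <- object$features
  need <- unique(c(ft$gene_a, ft$gene_b[!is.na(ft$gene_b)]))
  missing <- setdiff(need, rownames(m))
  if (length(missing) > 0L) {
    abort(sprintf("model gene(s) missing from the matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  vals <- vapply(seq_len(nrow(ft)), function(i) {
    a <- m[ft$gene_a[i], ]
    if (is.na(ft$gene_b[i])) a else a * m[ft$gene_b[i], ]
  }, numeric(ncol(m)))
  if (ncol(m) == 1L) vals <- matrix(vals, nrow = 1L)
  drop(object$intercept + vals %*% unname(object$coefficients))
}

#' Predict proliferation rates for a cohort
#'
#' Applies a fitted predictor to a (harmonized) cohort expression matrix.
#' Negative predictions are returned as-is and flagged; the flux stage
#' skips them.
#'
#' @param model an `interaction_predictor`.
#' @param cohort_matrix genes x samples log2 matrix on the scale the
#'   model was trained on.
#' @return a tibble: `sample_id`, `rate`, `negative`.
#' @export
predict_rates <- function(model, cohort_matrix) {
  p <- predict(model, cohort_matrix)
  tibble(sample_id = colnames(as_expr_matrix(cohort_matrix)),
         rate = unname(p), negative = unname(p) < 0)
}

# full-data pass of the staged pipeline:
# 1st-order lasso -> gene selection -> interaction features -> 2nd-order
# lasso -> coefficient cutoff + refit
fit_pipeline_once <- function(gene_matrix, targets, seed, order, tol, q) {
  m <- as_expr_matrix(gene_matrix, "gene_matrix")
  x1 <- t(m)
  fit1 <- fit_lasso_cv(x1, targets, seed = seed)
  if (order == "first") {
    return(list(predictor = fit1, selected_genes = rownames(m),
                feature_matrix = x1, first_order_fit = fit1))
  }
  genes <- select_nonzero_genes(fit1, tol = tol)
  if (length(genes) == 0L) {
    abort("no gene passed first-order selection; lower `tol`.")
  }
  x2 <- build_interaction_features(m, genes)
  fit2 <- fit_lasso_cv(x2, targets, seed = seed)
  if (order == "second") {
    return(list(predictor = fit2, selected_genes = genes,
                feature_matrix = x2, first_order_fit = fit1))
  }
  final <- apply_coefficient_cutoff(fit2, q = q, feature_matrix = x2,
                                    targets = targets, seed = seed)
  list(predictor = final, selected_genes = genes,
       feature_matrix = x2[, final$features$feature, drop = FALSE],
       first_order_fit = fit1)
}

#' Fit the staged interaction predictor
#'
#' Runs the full model sequence on a training panel: a first-order L1
#' fit over all genes, selection of the clearly non-zero genes, a pure
#' second-order fit on their pairwise products and squares, and a
#' coefficient cutoff followed by a refit.
#'
#' @param gene_matrix genes x samples log2 training matrix.
#' @param targets proliferation rate per sample (column).
#' @param seed integer seed.
#' @param order `"second_cutoff"` (default, the full sequence),
#'   `"second"` (no cutoff) or `"first"` (plain first-order fit).
#' @param tol first-order selection threshold, see
#'   [select_nonzero_genes()].
#' @param q cutoff quantile, see [apply_coefficient_cutoff()].
#' @return a list of class `proliferation_fit`: `predictor` (the final
#'   `interaction_predictor`), `selected_genes`, `first_order_fit`,
#'   `train_metrics`.
#' @export
fit_proliferation_model <- function(gene_matrix, targets, seed = 1L,
                                    order = c("second_cutoff", "second",
                                              "first"),
                                    tol = 1e-8, q = 0.25) {
  order <- match.arg(order)
  fit <- fit_pipeline_once(gene_matrix, targets, seed, order, tol, q)
  fit$train_metrics <- compute_fit_metrics(
    predict(fit$predictor, gene_matrix), targets)
  fit$order <- order
  class(fit) <- "proliferation_fit"
  fit
}

#' @export
print.proliferation_fit <- function(x, ...) {
  cat(sprintf(paste0("<proliferation_fit> order '%s', %d selected gene(s), ",
                     "%d final feature(s), training R^2 = %.4f\n"),
              x$order, length(x$selected_genes),
              length(x$predictor$coefficients), x$train_metrics$r_squared))
  invisible(x)
}

#' @export
tidy.proliferation_fit <- function(x, ...) tidy(x$predictor)

#' @export
glance.proliferation_fit <- function(x, ...) {
  dplyr::bind_cols(glance(x$predictor), x$train_metrics,
                   tibble(order = x$order))
}

#' Leave-one-out evaluation of the staged predictor
#'
#' For each sample, trains on the remaining `n - 1` samples and predicts
#' the held-out one. In `"fixed_features"` mode the interaction-feature
#' set and the cutoff survivors come from a single full-data pass and
#' only the penalized coefficients are refit per fold (the fast variant;
#' note that the full-data selection leaks a small amount of information
#' into the folds). In `"nested"` mode the entire selection sequence is
#' redone inside every fold.
#'
#' @inheritParams fit_proliferation_model
#' @param mode `"fixed_features"` or `"nested"`.
#' @return a list of class `loocv_result`: `predictions` (tibble
#'   `sample_id`, `observed`, `predicted`), `metrics` (tibble with one
#'   `train` and one `validation` row of the five metrics, plus
#'   `strategy` and `order` columns), the full-data `fit`, `mode`.
#' @export
loocv_evaluate <- function(gene_matrix, targets,
                           mode = c("fixed_features", "nested"),
                           seed = 1L,
                           order = c("second_cutoff", "second", "first"),
                           tol = 1e-8, q = 0.25) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  m <- as_expr_matrix(gene_matrix, "gene_matrix")
  n <- ncol(m)
  if (n < 3L) abort("leave-one-out needs at least 3 samples.")
  if (length(targets) != n) abort("one target per sample is required.")

  full <- fit_proliferation_model(m, targets, seed = seed, order = order,
                                  tol = tol, q = q)
  preds <- numeric(n)
  if (mode == "fixed_features") {
    x <- full$feature_matrix
    for (i in seq_len(n)) {
      f <- fit_lasso_cv(x[-i, , drop = FALSE], targets[-i],
                        seed = seed + i)
      preds[i] <- drop(f$intercept +
                         x[i, f$features$feature, drop = FALSE] %*%
                           unname(f$coefficients))
    }
  } else {
    for (i in seq_len(n)) {
      f <- fit_pipeline_once(m[, -i, drop = FALSE], targets[-i],
                             seed = seed + i, order = order,
                             tol = tol, q = q)
      preds[i] <- predict(f$predictor, m[, i, drop = FALSE])
    }
  }
  validation <- compute_fit_metrics(preds, targets)
  metrics <- dplyr::bind_rows(
    mutate(full$train_metrics, strategy = "train"),
    mutate(validation, strategy = "validation")
  )
  metrics$order <- order
  structure(list(
    predictions = tibble(sample_id = colnames(m), observed = targets,
                         predicted = preds),
    metrics = metrics, fit = full, mode = mode
  ), class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> mode '%s', order '%s'\n", x$mode,
              x$metrics$order[1]))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.loocv_result <- function(x, ...) x$metrics

#' @export
glance.loocv_result <- function(x, ...) {
  v <- x$metrics[x$metrics$strategy == "validation", ]
  mutate(v, mode = x$mode)
}
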