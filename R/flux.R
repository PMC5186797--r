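#' Parsimonious FBA at a fixed proliferation rate
#'
#' Solves the linear program
#' `minimize sum_i v_i` subject to `S v = 0`, `v_i >= 0`,
#' `v_p = r_p`, i.e. the most economic non-negative flux distribution
#' achieving the required proliferation flux. No finite upper bounds are
#' needed: the objective keeps the feasible slice bounded.
#'
#' @param model an [to_irreversible()] model.
#' @param r_p required proliferation flux, > 0.
#' @param eps simplex pivot tolerance.
#' @return a list of class `pfba_solution`: `flux` (named vector),
#'   `objective` (total flux), `status` (`"optimal"`).
#' @export
pfba_fixed_growth <- function(model, r_p, eps = 1e-10) {
  stopifnot(inherits(model, "irreversible_model"))
  if (!(is.finite(r_p) && r_p > 0)) abort("`r_p` must be finite and > 0.")
  S0 <- model$stoichiometry
  if (!model$proliferation_reaction %in% colnames(S0)) {
    abort("proliferation reaction missing from the model.")
  }
  # presolve: a metabolite row whose non-zero coefficients all share one
  # sign forces every reaction touching it to zero flux (no producer or
  # no consumer at steady state); iterate to closure
  S <- S0
  repeat {
    dead <- apply(S, 1, function(row) {
      nz <- row[row != 0]
      length(nz) > 0L && (all(nz > 0) || all(nz < 0))
    })
    if (!any(dead)) break
    drop_cols <- colSums(S[dead, , drop = FALSE] != 0) > 0
    if (model$proliferation_reaction %in% colnames(S)[drop_cols]) {
      abort(sprintf(
        "pFBA infeasible: proliferation flux %.4g is unreachable.", r_p))
    }
    S <- S[!dead, !drop_cols, drop = FALSE]
  }
  S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  p <- match(model$proliferation_reaction, colnames(S))
  growth_row <- as.numeric(seq_len(ncol(S)) == p)
  sol <- boot::simplex(a = rep(1, ncol(S)),
                       A3 = rbind(S, growth_row),
                       b3 = c(rep(0, nrow(S)), r_p),
                       maxi = FALSE, eps = eps,
                       n.iter = 50L * (ncol(S) + nrow(S) + 1L))
  if (sol$solved != 1L) {
    abort(sprintf(
      "pFBA infeasible: proliferation flux %.4g is unreachable (status %d).",
      r_p, sol$solved))
  }
  v <- setNames(rep(0, ncol(S0)), colnames(S0))
  v[colnames(S)] <- as.numeric(sol$soln)
  structure(list(flux = v, objective = sum(v), status = "optimal"),
            class = "pfba_solution")
}

#' @export
print.pfba_solution <- function(x, ...) {
  cat(sprintf("<pfba_solution> %s, total flux %.6g, %d active reaction(s)\n",
              x$status, x$objective, sum(x$flux > 0)))
  invisible(x)
}

#' @export
tidy.pfba_solution <- function(x, ...) {
  tibble(reaction = names(x$flux), flux = unname(x$flux))
}

#' Batched pFBA across a cohort
#'
#' Solves one parsimonious FBA problem per sample, using the metabolic
#' model of the sample's panel and the sample's predicted proliferation
#' rate. Samples with non-positive rates are skipped and recorded;
#' per-sample infeasibilities are recorded and the run continues.
#'
#' Because the program is homogeneous in `r_p` (all right-hand sides are
#' 0 except `v_p = r_p`), the default `recycle = TRUE` solves each panel
#' model once at a reference rate and rescales the solution linearly per
#' sample; `recycle = FALSE` solves every sample from scratch.
#'
#' @param models named list of `irreversible_model`s, one per panel.
#' @param rates a tibble with columns `sample_id` and `rate`, or a named
#'   numeric vector.
#' @param panels named character vector `sample_id -> panel` (or a tibble
#'   with columns `sample_id`, `panel`).
#' @param recycle reuse one solve per panel via linear rescaling.
#' @return an object of class `flux_matrix`: `values` (samples x
#'   reactions, union of all panel reaction ids, absent reactions 0),
#'   `panel_labels`, `skipped_samples` (non-positive rates),
#'   `infeasible_samples`.
#' @export
batch_pfba <- function(models, rates, panels, recycle = TRUE) {
  if (is.data.frame(rates)) {
    rates <- setNames(rates$rate, rates$sample_id)
  }
  if (is.data.frame(panels)) {
    panels <- setNames(panels$panel, panels$sample_id)
  }
  samples <- names(rates)
  missing_panel <- setdiff(samples, names(panels))
  if (length(missing_panel) > 0L) {
    abort(sprintf("no panel label for sample(s): %s",
                  paste(missing_panel, collapse = ", ")))
  }
  used_panels <- unique(unname(panels[samples]))
  missing_model <- setdiff(used_panels, names(models))
  if (length(missing_model) > 0L) {
    abort(sprintf("no model for panel(s): %s",
                  paste(missing_model, collapse = ", ")))
  }
  all_rxns <- sort(unique(unlist(lapply(models[used_panels],
                                        function(m) m$reaction_ids))))
  skipped <- samples[rates[samples] <= 0]
  solved <- setdiff(samples, skipped)
  values <- matrix(0, nrow = length(solved), ncol = length(all_rxns),
                   dimnames = list(solved, all_rxns))
  infeasible <- character(0)
  base <- list()
  for (s in solved) {
    pn <- panels[[s]]
    v <- tryCatch({
      if (recycle) {
        if (is.null(base[[pn]])) {
          base[[pn]] <- pfba_fixed_growth(models[[pn]], 1)$flux
        }
        base[[pn]] * rates[[s]]
      } else {
        pfba_fixed_growth(models[[pn]], rates[[s]])$flux
      }
    }, error = function(e) NULL)
    if (is.null(v)) {
      infeasible <- c(infeasible, s)
    } else {
      values[s, names(v)] <- v
    }
  }
  if (length(infeasible) > 0L) {
    values <- values[setdiff(solved, infeasible), , drop = FALSE]
  }
  structure(list(values = values,
                 panel_labels = panels[rownames(values)],
                 skipped_samples = skipped,
                 infeasible_samples = infeasible),
            class = "flux_matrix")
}

#' @export
print.flux_matrix <- function(x, ...) {
  cat(sprintf(paste0("<flux_matrix> %d sample(s) x %d reaction(s), ",
                     "%d skipped, %d infeasible\n"),
              nrow(x$values), ncol(x$values), length(x$skipped_samples),
              length(x$infeasible_samples)))
  invisible(x)
}

#' @export
tidy.flux_matrix <- function(x, ...) {
  v <- x$values
  tibble(sample_id = rep(rownames(v), times = ncol(v)),
         panel = rep(unname(x$panel_labels[rownames(v)]), times = ncol(v)),
         reaction = rep(colnames(v), each = nrow(v)),
         flux = as.vector(v))
}

#' Keep fluxes that are non-zero in at least one sample
#'
#' @param fm a `flux_matrix`.
#' @param tol values with magnitude at or below `tol` count as zero.
#' @return the filtered `flux_matrix`.
#' @export
filter_informative_fluxes <- function(fm, tol = 1e-9) {
  stopifnot(inherits(fm, "flux_matrix"))
  keep <- apply(fm$values, 2, function(col) any(col > tol))
  fm$values <- fm$values[, keep, drop = FALSE]
  fm
}
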