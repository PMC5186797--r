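# shared fixtures and independent oracles, all built in code

# a small, fast ground truth for unit tests (the package default is the
# full-size study condition; tests that assert recovery at scale use it
# directly)
tiny_truth <- function(noise_sd = 1e-3, seed = 7L, n_signal_pairs = 2) {
  ground_truth(n_genes = 120, n_signal_pairs = n_signal_pairs,
               noise_sd = noise_sd, seed = seed)
}

two_panels <- function(n = 12L, shift = c(0, 0.02)) {
  tibble::tibble(name = c("pA", "pB"), n_samples = n, rate_shift = shift)
}

# independent pFBA oracle: exhaustive basic-solution enumeration of
# min 1'v  s.t.  S v = 0, v >= 0, v_p = r_p  (for small column counts)
pfba_vertex_oracle <- function(S, growth_idx, r_p, tol = 1e-9) {
  A <- rbind(S, as.numeric(seq_len(ncol(S)) == growth_idx))
  b <- c(rep(0, nrow(S)), r_p)
  m <- qr(A)$rank
  best <- Inf
  for (cols in utils::combn(ncol(A), m, simplify = FALSE)) {
    Ab <- A[, cols, drop = FALSE]
    qrAb <- qr(Ab)
    if (qrAb$rank < m) next
    x <- tryCatch(qr.coef(qrAb, b), error = function(e) NULL)
    if (is.null(x) || anyNA(x)) next
    if (max(abs(Ab %*% x - b)) > tol) next
    if (any(x < -tol)) next
    best <- min(best, sum(pmax(x, 0)))
  }
  best
}

# ad hoc irreversible model from a stoichiometry matrix
manual_irreversible <- function(S, growth, pathways = NULL) {
  structure(list(
    stoichiometry = S, reaction_ids = colnames(S),
    proliferation_reaction = growth,
    pathway_map = pathways %||%
      stats::setNames(rep("p", ncol(S)), colnames(S)),
    reverse_of = character(0)
  ), class = "irreversible_model")
}

# a ranked list built directly from scores (for enrichment unit tests)
manual_ranked_list <- function(abs_s, pathways) {
  ord <- order(-abs_s)
  structure(tibble::tibble(
    panel = "p", reaction = sprintf("r%03d", seq_along(abs_s))[ord],
    s = abs_s[ord], abs_s = abs_s[ord], pathway = pathways[ord]
  ), class = c("ranked_list", class(tibble::tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
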