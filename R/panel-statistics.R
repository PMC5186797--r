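#' Panel-specificity scores for fluxes
#'
#' For every panel `p` and reaction `i`,
#' `s_pi = log2(mu_pi + eps) - log2(mu_oi + eps)`, where `mu_pi` is the
#' mean flux over the samples in panel `p`, `mu_oi` the mean over all
#' other samples and `eps` a pseudocount guarding against zero means.
#' `s` is the log2 fold change of the flux inside versus outside the
#' panel: 0 marks a homogeneous flux, large `|s|` a panel-specific one.
#'
#' @param fm a [batch_pfba()] flux matrix with at least 2 panels.
#' @param pseudocount `eps`, >= 0 (0 reproduces the bare log ratio).
#' @return a tibble of class `specificity_table`: `panel`, `reaction`,
#'   `s`.
#' @export
compute_specificity <- function(fm, pseudocount = 1e-9) {
  stopifnot(inherits(fm, "flux_matrix"), pseudocount >= 0)
  pl <- unname(fm$panel_labels[rownames(fm$values)])
  panels <- sort(unique(pl))
  if (length(panels) < 2L) {
    abort("specificity needs at least 2 panels (the outside mean is undefined).")
  }
  out <- purrr::map_dfr(panels, function(p) {
    inside <- pl == p
    mu_p <- colMeans(fm$values[inside, , drop = FALSE])
    mu_o <- colMeans(fm$values[!inside, , drop = FALSE])
    tibble(panel = p, reaction = colnames(fm$values),
           s = unname(log2(mu_p + pseudocount) -
                        log2(mu_o + pseudocount)))
  })
  structure(out, class = c("specificity_table", class(out)),
            pseudocount = pseudocount)
}

#' Pool specificity scores into one absolute-value ranked list
#'
#' Entries across all panels and reactions are pooled and sorted by
#' `|s|` in decreasing order; ties are broken by (panel, reaction)
#' lexicographic order so the ranking is deterministic.
#'
#' @param st a [compute_specificity()] table.
#' @param pathway_map named character vector `reaction -> pathway` (e.g.
#'   the `pathway_map` of an irreversible model), or a data frame with
#'   columns `reaction` and `pathway`.
#' @return a tibble of class `ranked_list`: `panel`, `reaction`, `s`,
#'   `abs_s`, `pathway`, sorted as described.
#' @export
build_ranked_list <- function(st, pathway_map) {
  if (nrow(st) == 0L) abort("empty specificity table.")
  if (is.data.frame(pathway_map)) {
    pathway_map <- setNames(pathway_map$pathway, pathway_map$reaction)
  }
  out <- tibble(panel = st$panel, reaction = st$reaction, s = st$s,
                abs_s = abs(st$s),
                pathway = unname(pathway_map[st$reaction]))
  out$pathway[is.na(out$pathway)] <- "unassigned"
  out <- out[order(-out$abs_s, out$panel, out$reaction), ]
  structure(out, class = c("ranked_list", class(tibble())))
}

#' Raw enrichment score of a pathway in the ranked list
#'
#' Walks the ranked list accumulating a hit sum weighted by
#' `|s| / n_r` (`n_r` = total `|s|` over the pathway's entries) and a
#' miss sum of `1 / (n - n_h)` per non-member, and returns the running
#' deviation `P_h(i) - P_m(i)` at its extreme: the maximum if its
#' magnitude is at least that of the minimum, otherwise the minimum.
#' A pathway concentrated at the top of the list scores close to +1; one
#' concentrated at the bottom close to -1.
#'
#' @param rl a [build_ranked_list()] list.
#' @param pathway pathway name; must hit at least one entry and miss at
#'   least one.
#' @param both return both extremes (`c(max, min)`) instead of the
#'   larger-magnitude one.
#' @return the enrichment score (or both extremes).
#' @export
enrichment_score <- function(rl, pathway, both = FALSE) {
  es_from_labels(rl$abs_s, rl$pathway == pathway, both = both)
}

# core running-sum walk on a ranked weight vector and a hit indicator
es_from_labels <- function(abs_s, is_hit, both = FALSE) {
  n <- length(abs_s)
  n_h <- sum(is_hit)
  if (n_h == 0L || n_h == n) {
    abort("the pathway must have at least one hit and one miss in the list.")
  }
  n_r <- sum(abs_s[is_hit])
  p_hit <- cumsum(ifelse(is_hit, abs_s / n_r, 0))
  p_miss <- cumsum(ifelse(is_hit, 0, 1 / (n - n_h)))
  dev <- p_hit - p_miss
  hi <- max(dev)
  lo <- min(dev)
  if (both) return(c(max = hi, min = lo))
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Permutation-normalized enrichment across pathways
#'
#' For every pathway, the observed enrichment score is divided by the
#' mean score over `n_perm` random permutations of the pathway-label
#' column (the `|s|` values and their order stay fixed, so each
#' pathway's hit count is preserved): `NES = ES / mean(ES_perm)`.
#' Empirical p-values are taken separately on the two tails: `p_pos` is
#' the fraction of permuted scores at least the observed one (relevant
#' when `ES > 0`), `p_neg` the fraction at most the observed one. An
#' NES above 1 marks a pathway enriched in the panel-specific fluxes; an
#' NES below 1 one that behaves homogeneously across panels.
#'
#' @param rl a [build_ranked_list()] list covering every pathway of
#'   interest.
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed; results are reproducible given it.
#' @return a tibble of class `enrichment_result`: `pathway`, `es`,
#'   `nes` (`NA` when the permutation mean is numerically zero),
#'   `p_pos`, `p_neg`, `n_h`, `n_perm`.
#' @export
normalize_enrichment <- function(rl, n_perm = 100, seed = 1L) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  pathways <- sort(unique(rl$pathway))
  n <- nrow(rl)
  keep <- vapply(pathways,
                 function(p) {
                   h <- sum(rl$pathway == p)
                   h >= 1L && h < n
                 }, NA)
  pathways <- pathways[keep]
  if (length(pathways) == 0L) abort("no scorable pathway in the list.")
  obs <- vapply(pathways, function(p) enrichment_score(rl, p), 0)
  set.seed(seed)
  perm_es <- matrix(NA_real_, nrow = n_perm, ncol = length(pathways),
                    dimnames = list(NULL, pathways))
  for (b in seq_len(n_perm)) {
    labels <- sample(rl$pathway)
    for (p in pathways) {
      perm_es[b, p] <- es_from_labels(rl$abs_s, labels == p)
    }
  }
  mean_perm <- colMeans(perm_es)
  nes <- ifelse(abs(mean_perm) < 1e-12, NA_real_, obs / mean_perm)
  out <- tibble(
    pathway = pathways,
    es = unname(obs),
    nes = unname(nes),
    p_pos = vapply(pathways,
                   function(p) mean(perm_es[, p] >= obs[[p]]), 0),
    p_neg = vapply(pathways,
                   function(p) mean(perm_es[, p] <= obs[[p]]), 0),
    n_h = vapply(pathways, function(p) sum(rl$pathway == p), 0L),
    n_perm = n_perm
  )
  structure(out, class = c("enrichment_result", class(out)))
}
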