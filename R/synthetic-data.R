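#' Ground truth for synthetic cohorts
#'
#' Defines the generative model shared by all synthetic fixtures: a gene
#' universe with fixed mean log2 expression per gene, a sparse set of
#' two-gene interaction terms that determine proliferation rates, the set
#' of genes whose expression is conserved across platforms, and the true
#' cross-platform parameters (`alpha_true`, `beta_true`).
#'
#' Proliferation rates are generated as
#' `intercept + sum_k coef_k * e_i(k) * e_j(k) + N(0, noise_sd)`,
#' with `e` the log2 expression on the reference (cell-line array) scale.
#' Signal genes are always drawn from the conserved set and given means
#' in the well-quantified 7-9 log2 band; remaining gene means span 4-12.
#'
#' @param n_genes size of the gene universe.
#' @param n_signal_pairs number of two-gene products driving the rate.
#' @param conserved_fraction fraction of genes with platform-conserved
#'   expression.
#' @param intercept baseline proliferation rate (per hour).
#' @param coef_range absolute size range of the pair coefficients; signs
#'   alternate so panel means stay in a realistic band.
#' @param noise_sd standard deviation of the additive rate noise.
#' @param alpha_true true platform factor (array -> rnaseq slope), > 0.
#' @param beta_true true dataset shift on the array scale.
#' @param seed integer seed; the truth is deterministic given it.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(n_genes = 500, n_signal_pairs = 3,
                         conserved_fraction = 0.8,
                         intercept = 0.02,
                         coef_range = c(2e-4, 5e-4),
                         noise_sd = 1e-3,
                         alpha_true = 1.15, beta_true = 0.35,
                         seed = 1L) {
  stopifnot(n_genes >= 4, n_signal_pairs >= 1, noise_sd >= 0,
            alpha_true > 0, is.finite(beta_true),
            conserved_fraction > 0, conserved_fraction <= 1)
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  gene_means <- setNames(runif(n_genes, 4, 12), genes)
  n_cons <- max(2L * n_signal_pairs, ceiling(conserved_fraction * n_genes))
  conserved <- sort(sample(genes, n_cons))
  sig <- sample(conserved, 2L * n_signal_pairs)
  gene_means[sig] <- runif(length(sig), 7, 9)
  pairs <- matrix(sig, ncol = 2, byrow = TRUE)
  pairs <- t(apply(pairs, 1, sort))
  coefs <- runif(n_signal_pairs, coef_range[1], coef_range[2]) *
    rep_len(c(1, -1), n_signal_pairs)
  out <- structure(list(
    signal_pairs = tibble(gene_a = pairs[, 1], gene_b = pairs[, 2],
                          coefficient = coefs),
    intercept = intercept,
    noise_sd = noise_sd,
    conserved_genes = conserved,
    alpha_true = alpha_true,
    beta_true = beta_true,
    gene_means = gene_means
  ), class = "ground_truth")
  validate_ground_truth(out)
  out
}

validate_ground_truth <- function(truth) {
  sp <- truth$signal_pairs
  if (nrow(sp) < 1L) abort("at least one signal pair is required.")
  if (!all(is.finite(sp$coefficient))) abort("coefficients must be finite.")
  sig <- unique(c(sp$gene_a, sp$gene_b))
  missing_univ <- setdiff(sig, names(truth$gene_means))
  if (length(missing_univ) > 0L) {
    abort(sprintf("signal gene(s) outside the gene universe: %s",
                  paste(missing_univ, collapse = ", ")))
  }
  stray <- setdiff(sig, truth$conserved_genes)
  if (length(stray) > 0L) {
    abort(sprintf("signal gene(s) not in the conserved set: %s",
                  paste(stray, collapse = ", ")))
  }
  if (truth$noise_sd < 0) abort("noise_sd must be >= 0.")
  if (!(truth$alpha_true > 0)) abort("alpha_true must be > 0.")
  invisible(truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> %d genes (%d conserved), %d signal ",
                     "pair(s), intercept %.3g, noise_sd %.3g, alpha %.3g, ",
                     "beta %.3g\n"),
              length(x$gene_means), length(x$conserved_genes),
              nrow(x$signal_pairs), x$intercept, x$noise_sd,
              x$alpha_true, x$beta_true))
  invisible(x)
}

# rate = intercept + sum_k coef_k * e_a * e_b for a genes x samples matrix
true_rate_from_expression <- function(expr, truth) {
  sp <- truth$signal_pairs
  contrib <- vapply(seq_len(nrow(sp)), function(k) {
    sp$coefficient[k] * expr[sp$gene_a[k], ] * expr[sp$gene_b[k], ]
  }, numeric(ncol(expr)))
  if (ncol(expr) == 1L) contrib <- matrix(contrib, nrow = 1L)
  truth$intercept + rowSums(contrib)
}

#' Simulate a cell-line panel with measured proliferation rates
#'
#' Emulates a cell-line compendium: log2 expression drawn per gene around
#' its fixed mean, and a proliferation rate per line generated from the
#' ground truth's sparse interaction model plus Gaussian noise.
#'
#' @param truth a [ground_truth()] object.
#' @param n_lines number of cell lines (>= 10).
#' @param bio_sd per-gene biological standard deviation of log2
#'   expression across lines.
#' @param seed integer seed.
#' @return a list with `expression` (a `log_expr`, platform `"array"`)
#'   and `rates` (tibble: `sample_id`, `rate`, `doubling_time`).
#' @export
simulate_cell_line_panel <- function(truth, n_lines = 57, bio_sd = 1,
                                     seed = 1L) {
  validate_ground_truth(truth)
  if (n_lines < 10) abort("need at least 10 cell lines.")
  set.seed(seed)
  genes <- names(truth$gene_means)
  lines <- sprintf("line%03d", seq_len(n_lines))
  expr <- matrix(rnorm(length(genes) * n_lines,
                       mean = rep(truth$gene_means, n_lines), sd = bio_sd),
                 nrow = length(genes), dimnames = list(genes, lines))
  rates <- true_rate_from_expression(expr, truth) +
    rnorm(n_lines, 0, truth$noise_sd)
  list(
    expression = log_expr(expr, "array"),
    rates = tibble(sample_id = lines, rate = unname(rates),
                   doubling_time = log(2) / unname(rates))
  )
}

#' Convert between doubling times and proliferation rates
#'
#' Exponential growth gives `rate = ln(2) / doubling_time`; the inverse
#' transformation is identical, so one helper serves both directions.
#'
#' @param x doubling times (hours) or rates (per hour).
#' @return the corresponding rates or doubling times.
#' @export
rate_from_doubling_time <- function(x) log(2) / x

#' Simulate a dual-platform patient cohort
#'
#' Generates a cohort measured on a sequencing-like platform, a subset of
#' which is also measured on an array-like platform, with known true
#' proliferation rates per sample.
#'
#' The generative platform model: each sample carries latent expression
#' `e` on the reference (cell-line array) scale; the cohort's array
#' platform observes `e + beta_true` (a dataset shift on the common
#' platform) and its sequencing platform observes
#' `alpha_true * (e + beta_true)` (a zero-intercept platform rescaling of
#' the very same samples). Conserved genes follow this model; each
#' non-conserved gene gets an independent mean per platform, offset by at
#' least 1.5 log2 units, so it is guaranteed to violate the conserved-gene
#' filter band. True rates are computed from the latent `e` plus each
#' panel's `rate_shift` plus noise.
#'
#' @param truth a [ground_truth()] object.
#' @param panels a data frame with columns `name`, `n_samples`,
#'   `rate_shift` (one row per cancer panel).
#' @param dual_platform_fraction fraction (0, 1] of samples also measured
#'   on the array platform.
#' @param bio_sd per-gene biological standard deviation of latent log2
#'   expression across samples.
#' @param platform_noise_sd additive measurement noise per platform.
#' @param seed integer seed.
#' @return an object of class `cohort_bundle`: `rnaseq` and `array`
#'   `log_expr` matrices, a `reference` latent matrix, and a `samples`
#'   tibble (`sample_id`, `panel`, `true_rate`, `has_array`).
#' @export
simulate_patient_cohort <- function(truth, panels,
                                    dual_platform_fraction = 0.3,
                                    bio_sd = 1, platform_noise_sd = 0,
                                    seed = 1L) {
  validate_ground_truth(truth)
  panels <- as_tibble(panels)
  if (nrow(panels) == 0L) abort("`panels` must contain at least one panel.")
  stopifnot(all(c("name", "n_samples", "rate_shift") %in% names(panels)))
  if (!(dual_platform_fraction > 0 && dual_platform_fraction <= 1)) {
    abort("`dual_platform_fraction` must be in (0, 1].")
  }
  set.seed(seed)
  genes <- names(truth$gene_means)
  n_total <- sum(panels$n_samples)
  samples <- sprintf("s%04d", seq_len(n_total))
  panel_of <- rep(panels$name, panels$n_samples)
  shift_of <- rep(panels$rate_shift, panels$n_samples)

  latent <- matrix(rnorm(length(genes) * n_total,
                         mean = rep(truth$gene_means, n_total), sd = bio_sd),
                   nrow = length(genes), dimnames = list(genes, samples))
  rates <- true_rate_from_expression(latent, truth) + shift_of +
    rnorm(n_total, 0, truth$noise_sd)

  non_cons <- setdiff(genes, truth$conserved_genes)
  # independent platform-specific means for non-conserved genes; offsets of
  # >= 1.5 log2 units guarantee the filter has true negatives
  offset <- function(n) {
    sample(c(-1, 1), n, replace = TRUE) * runif(n, 1.5, 3.5)
  }
  mean_arr <- truth$gene_means
  mean_rna <- truth$gene_means
  if (length(non_cons) > 0L) {
    mean_arr[non_cons] <- mean_arr[non_cons] + offset(length(non_cons))
    mean_rna[non_cons] <- mean_rna[non_cons] + offset(length(non_cons))
  }

  arr <- latent + truth$beta_true
  rna <- truth$alpha_true * (latent + truth$beta_true)
  if (length(non_cons) > 0L) {
    arr[non_cons, ] <- matrix(
      rnorm(length(non_cons) * n_total,
            mean = rep(mean_arr[non_cons] + truth$beta_true, n_total),
            sd = bio_sd),
      nrow = length(non_cons))
    rna[non_cons, ] <- truth$alpha_true * matrix(
      rnorm(length(non_cons) * n_total,
            mean = rep(mean_rna[non_cons] + truth$beta_true, n_total),
            sd = bio_sd),
      nrow = length(non_cons))
  }
  if (platform_noise_sd > 0) {
    arr <- arr + rnorm(length(arr), 0, platform_noise_sd)
    rna <- rna + rnorm(length(rna), 0, platform_noise_sd)
  }

  n_dual <- max(2L, ceiling(dual_platform_fraction * n_total))
  n_dual <- min(n_dual, n_total)
  dual <- sort(sample(samples, n_dual))

  structure(list(
    rnaseq = log_expr(rna, "rnaseq"),
    array = log_expr(arr[, dual, drop = FALSE], "array"),
    reference = log_expr(latent, "array"),
    samples = tibble(sample_id = samples, panel = panel_of,
                     true_rate = unname(rates),
                     has_array = samples %in% dual)
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0("<cohort_bundle> %d samples (%d dual-platform), ",
                     "%d genes, %d panel(s)\n"),
              ncol(x$rnaseq), ncol(x$array), nrow(x$rnaseq),
              length(unique(x$samples$panel))))
  invisible(x)
}

#' Simulate toy metabolic models for a set of cancer panels
#'
#' Builds a small irreversible-splittable metabolic network (about 20
#' reaction columns after splitting) with exchange reactions, a
#' proliferation reaction draining three biomass precursors, and six
#' annotated pathways, then derives one variant per panel by removing the
#' reactions of selected pathways. Removals are chosen so every variant
#' still supports a positive proliferation flux and so that the pentose
#' shunt carries flux in exactly one panel (the panel whose glycolysis
#' reactions are removed), giving the downstream specificity and
#' enrichment statistics non-trivial structure.
#'
#' Panel variants cycle through: (1) pentose shunt removed, (2)
#' glycolysis removed (the shunt is present and carries all hexose
#' flux — with the default three panels this makes the shunt a pathway
#' present in exactly one panel's model), (3) the amino-acid salvage
#' route removed, (4) direct amino-acid synthesis removed (salvage
#' active), (5) the full network.
#'
#' @param n_panels number of panels (>= 1).
#' @param seed integer seed (generation is closed-form; the seed is
#'   accepted for interface uniformity).
#' @return a named list of `metabolic_model` objects, one per panel
#'   (`panel_1`, `panel_2`, ...).
#' @export
simulate_toy_models <- function(n_panels = 3, seed = 1L) {
  if (n_panels < 1) abort("need at least one panel.")
  set.seed(seed)
  base <- toy_base_model()
  removals <- list(
    c("PPP1", "PPP2", "PPP3"),
    c("GLY1", "GLY2"),                 # forces the pentose shunt
    c("SAL1", "SAL2", "SAL3"),
    c("AAS1"),                         # forces the salvage route
    character(0)
  )
  models <- lapply(seq_len(n_panels), function(i) {
    drop <- removals[[(i - 1L) %% length(removals) + 1L]]
    remove_reactions(base, drop)
  })
  names(models) <- sprintf("panel_%d", seq_len(n_panels))
  models
}

toy_base_model <- function() {
  rxn <- function(id, stoich, reversible, pathway) {
    list(id = id, stoich = stoich, reversible = reversible,
         pathway = pathway)
  }
  reactions <- list(
    rxn("EX_A",  c(A = 1),                     FALSE, "uptake"),
    rxn("EX_N",  c(N = 1),                     FALSE, "uptake"),
    rxn("GLY1",  c(A = -1, B = 1),             FALSE, "glycolysis"),
    rxn("GLY2",  c(B = -1, C = 1),             TRUE,  "glycolysis"),
    rxn("PPP1",  c(A = -1, P1 = 1),            FALSE, "pentose_shunt"),
    rxn("PPP2",  c(P1 = -1, P2 = 1),           FALSE, "pentose_shunt"),
    rxn("PPP3",  c(P2 = -1, C = 1),            FALSE, "pentose_shunt"),
    rxn("AAS1",  c(C = -1, N = -1, AA = 1),    FALSE, "aa_synthesis"),
    rxn("SAL1",  c(B = -1, N = -1, Q = 1),     FALSE, "aa_salvage"),
    rxn("SAL2",  c(Q = -1, Q2 = 1),            FALSE, "aa_salvage"),
    rxn("SAL3",  c(Q2 = -1, AA = 1),           FALSE, "aa_salvage"),
    rxn("FA1",   c(A = -1, F1 = 1),            FALSE, "lipid"),
    rxn("FA2",   c(F1 = -1, F2 = 1),           FALSE, "lipid"),
    rxn("FA3",   c(F2 = -1, L = 1),            FALSE, "lipid"),
    rxn("BIO",   c(C = -1, AA = -1, L = -1, W = 1), FALSE, "biomass"),
    rxn("DTX1",  c(W = -1, D = 1),             FALSE, "detox"),
    rxn("DTX2",  c(D = -1, E = 1),             TRUE,  "detox"),
    rxn("EX_E",  c(E = -1),                    FALSE, "detox")
  )
  mets <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  S <- matrix(0, nrow = length(mets), ncol = length(reactions),
              dimnames = list(mets, vapply(reactions, `[[`, "", "id")))
  for (r in reactions) S[names(r$stoich), r$id] <- r$stoich
  metabolic_model(
    stoichiometry = S,
    reactions = tibble(
      id = vapply(reactions, `[[`, "", "id"),
      reversible = vapply(reactions, `[[`, NA, "reversible"),
      pathway = vapply(reactions, `[[`, "", "pathway")
    ),
    objective = "BIO"
  )
}
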