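#' Pipeline configuration
#'
#' Collects every file path and tunable parameter of the end-to-end
#' analysis. All paths must exist when [run_pipeline()] is called.
#'
#' @param reference_expression TSV, reference (cell-line) genes x samples
#'   log2 matrix.
#' @param reference_rates CSV with columns `sample_id`, `rate`.
#' @param cohort_rnaseq TSV, cohort sequencing-platform matrix.
#' @param cohort_array TSV, cohort array-platform matrix (dual-platform
#'   subset of the same samples).
#' @param cohort_panels CSV with columns `sample_id`, `panel`.
#' @param models named character vector `panel -> model file` (JSON
#'   dialect or SBML, decided by extension).
#' @param out_dir output directory (created if missing).
#' @param max_dist conserved-gene filter band (log2 units).
#' @param tol first-order coefficient threshold.
#' @param q cutoff quantile for the final refit.
#' @param flux_tol non-zero flux tolerance.
#' @param pseudocount specificity pseudocount.
#' @param n_perm enrichment permutations.
#' @param loocv_mode `"fixed_features"` or `"nested"`.
#' @param seed integer seed recorded in the manifest and used for every
#'   stochastic step.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_expression, reference_rates,
                            cohort_rnaseq, cohort_array, cohort_panels,
                            models, out_dir,
                            max_dist = 1, tol = 1e-8, q = 0.25,
                            flux_tol = 1e-9, pseudocount = 1e-9,
                            n_perm = 100,
                            loocv_mode = c("fixed_features", "nested"),
                            seed = 42L) {
  structure(list(
    reference_expression = reference_expression,
    reference_rates = reference_rates,
    cohort_rnaseq = cohort_rnaseq, cohort_array = cohort_array,
    cohort_panels = cohort_panels, models = models, out_dir = out_dir,
    max_dist = max_dist, tol = tol, q = q, flux_tol = flux_tol,
    pseudocount = pseudocount, n_perm = n_perm,
    loocv_mode = match.arg(loocv_mode), seed = as.integer(seed)
  ), class = "pipeline_config")
}

read_model_any <- function(path) {
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
    read_model_sbml(path)
  } else {
    read_model_json(path)
  }
}

run_stage <- function(name, out_dir, expr) {
  message(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes harmonize -> filter -> train (with leave-one-out report) ->
#' predict -> batched pFBA -> specificity -> enrichment, writing every
#' intermediate as CSV and a JSON run manifest into the configured
#' output directory. Reruns with an identical configuration reproduce
#' the outputs byte for byte. On a stage error, partial outputs are
#' retained next to a `FAILED` marker file.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every intermediate result and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- unlist(config[c("reference_expression", "reference_rates",
                           "cohort_rnaseq", "cohort_array",
                           "cohort_panels", "models")])
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(sprintf("input file(s) not found: %s",
                  paste(missing, collapse = ", ")))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))

  inputs <- run_stage("read", out_dir, {
    list(
      reference = read_expression_matrix(config$reference_expression,
                                         "array"),
      rates = utils::read.csv(config$reference_rates),
      rnaseq = read_expression_matrix(config$cohort_rnaseq, "rnaseq"),
      array = read_expression_matrix(config$cohort_array, "array"),
      panels = utils::read.csv(config$cohort_panels),
      models = lapply(config$models, read_model_any)
    )
  })

  harmonized <- run_stage("harmonize", out_dir, {
    h <- harmonize_platforms(inputs$reference, inputs$array,
                             inputs$rnaseq, max_dist = config$max_dist)
    utils::write.csv(as_tibble(h$report),
                     file.path(out_dir, "filter_report.csv"),
                     row.names = FALSE)
    message(sprintf("[harmonize] alpha = %.4f, beta = %.4f; %d/%d genes pass",
                    h$model$alpha, h$model$beta, length(h$genes),
                    attr(h$report, "universe_size")))
    h
  })

  trained <- run_stage("train", out_dir, {
    genes <- intersect(harmonized$genes, rownames(inputs$reference))
    if (length(genes) == 0L) abort("no conserved gene in the reference matrix.")
    m <- unclass(inputs$reference)[genes, , drop = FALSE]
    rates <- setNames(inputs$rates$rate, inputs$rates$sample_id)
    m <- m[, names(rates), drop = FALSE]
    cv <- loocv_evaluate(m, unname(rates), mode = config$loocv_mode,
                         seed = config$seed, tol = config$tol, q = config$q)
    utils::write.csv(cv$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    write_predictor_json(cv$fit$predictor,
                         file.path(out_dir, "predictor.json"))
    message(sprintf("[train] validation R^2 = %.4f",
                    glance(cv)$r_squared))
    cv
  })

  predicted <- run_stage("predict", out_dir, {
    # map cohort sequencing values back onto the reference scale by
    # inverting the two fitted sub-models in sequence: first the platform
    # factor (rnaseq -> cohort array scale), then the dataset shift
    # (cohort array -> reference scale)
    pm <- harmonized$model
    on_array_scale <- unclass(inputs$rnaseq) / pm$alpha
    on_reference_scale <- on_array_scale - pm$beta
    pr <- predict_rates(trained$fit$predictor, on_reference_scale)
    utils::write.csv(pr, file.path(out_dir, "predicted_rates.csv"),
                     row.names = FALSE)
    message(sprintf("[predict] %d samples, %d negative rates",
                    nrow(pr), sum(pr$negative)))
    pr
  })

  fluxes <- run_stage("flux", out_dir, {
    irr <- lapply(inputs$models, to_irreversible)
    fm <- batch_pfba(irr,
                     setNames(predicted$rate, predicted$sample_id),
                     setNames(inputs$panels$panel,
                              inputs$panels$sample_id))
    fm <- filter_informative_fluxes(fm, tol = config$flux_tol)
    utils::write.csv(
      data.frame(sample_id = rownames(fm$values), fm$values,
                 check.names = FALSE),
      file.path(out_dir, "fluxes.csv"), row.names = FALSE)
    message(sprintf("[flux] %d samples solved, %d skipped, %d fluxes kept",
                    nrow(fm$values), length(fm$skipped_samples),
                    ncol(fm$values)))
    list(fm = fm, pathway_map = do.call(c, unname(
      lapply(irr, function(m) m$pathway_map)))[unique(unlist(
        lapply(irr, function(m) m$reaction_ids)))])
  })

  enriched <- run_stage("enrich", out_dir, {
    st <- compute_specificity(fluxes$fm, pseudocount = config$pseudocount)
    utils::write.csv(st, file.path(out_dir, "specificity.csv"),
                     row.names = FALSE)
    rl <- build_ranked_list(st, fluxes$pathway_map)
    er <- normalize_enrichment(rl, n_perm = config$n_perm,
                               seed = config$seed)
    utils::write.csv(er, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
    message(sprintf("[enrich] %d pathways scored", nrow(er)))
    list(specificity = st, ranked = rl, enrichment = er)
  })

  manifest <- list(
    package = "proliflux",
    version = as.character(utils::packageVersion("proliflux")),
    seed = config$seed,
    parameters = config[c("max_dist", "tol", "q", "flux_tol",
                          "pseudocount", "n_perm", "loocv_mode")],
    stages = list(
      harmonize = list(alpha = harmonized$model$alpha,
                       beta = harmonized$model$beta,
                       genes_passing = length(harmonized$genes)),
      train = list(validation_r_squared = glance(trained)$r_squared),
      predict = list(n_samples = nrow(predicted),
                     n_negative = sum(predicted$negative)),
      flux = list(n_solved = nrow(fluxes$fm$values),
                  n_skipped = length(fluxes$fm$skipped_samples),
                  n_fluxes = ncol(fluxes$fm$values)),
      enrich = list(n_pathways = nrow(enriched$enrichment))
    ),
    failed_stages = 0L
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(harmonized = harmonized, loocv = trained,
                 predicted = predicted, fluxes = fluxes$fm,
                 specificity = enriched$specificity,
                 enrichment = enriched$enrichment, manifest = manifest))
}

#' Serialize a fitted predictor as JSON
#'
#' @param model an `interaction_predictor`.
#' @param path output path.
#' @export
write_predictor_json <- function(model, path) {
  jsonlite::write_json(list(
    features = model$features,
    coefficients = unname(model$coefficients),
    intercept = model$intercept,
    lambda = model$lambda
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_predictor_json
#' @export
read_predictor_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  new_interaction_predictor(as_tibble(doc$features), doc$coefficients,
                            doc$intercept, doc$lambda)
}

#' Write a complete synthetic fixture to disk
#'
#' Generates a cell-line panel, a dual-platform cohort and per-panel toy
#' metabolic models from one ground truth and writes them in the
#' pipeline's file formats, returning a ready [pipeline_config()].
#'
#' @param dir fixture directory (created if missing).
#' @param seed integer seed for the whole fixture.
#' @param truth optional [ground_truth()]; the default truth is used
#'   when omitted.
#' @param panels cohort panel layout, see [simulate_patient_cohort()].
#' @param n_lines cell lines in the reference panel.
#' @param bio_sd,platform_noise_sd cohort noise levels.
#' @param ... further arguments passed to [pipeline_config()].
#' @return the `pipeline_config` pointing at the written files.
#' @export
write_synthetic_fixture <- function(dir, seed = 42L, truth = NULL,
                                    panels = tibble(
                                      name = c("panel_1", "panel_2",
                                               "panel_3"),
                                      n_samples = c(15L, 15L, 15L),
                                      rate_shift = c(0, 0.01, -0.005)),
                                    n_lines = 57, bio_sd = 1,
                                    platform_noise_sd = 0, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- truth %||% ground_truth(seed = seed)
  panel <- simulate_cell_line_panel(truth, n_lines = n_lines,
                                    bio_sd = bio_sd, seed = seed + 1L)
  cohort <- simulate_patient_cohort(truth, panels,
                                    bio_sd = bio_sd,
                                    platform_noise_sd = platform_noise_sd,
                                    seed = seed + 2L)
  models <- simulate_toy_models(n_panels = nrow(panels), seed = seed + 3L)
  names(models) <- panels$name

  p <- function(f) file.path(dir, f)
  write_expression_matrix(panel$expression, p("reference_expression.tsv"))
  utils::write.csv(panel$rates[, c("sample_id", "rate")],
                   p("reference_rates.csv"), row.names = FALSE)
  write_expression_matrix(cohort$rnaseq, p("cohort_rnaseq.tsv"))
  write_expression_matrix(cohort$array, p("cohort_array.tsv"))
  utils::write.csv(cohort$samples[, c("sample_id", "panel")],
                   p("cohort_panels.csv"), row.names = FALSE)
  utils::write.csv(cohort$samples[, c("sample_id", "true_rate")],
                   p("cohort_true_rates.csv"), row.names = FALSE)
  model_paths <- setNames(p(sprintf("model_%s.json", names(models))),
                          names(models))
  for (nm in names(models)) write_model_json(models[[nm]], model_paths[nm])

  pipeline_config(
    reference_expression = p("reference_expression.tsv"),
    reference_rates = p("reference_rates.csv"),
    cohort_rnaseq = p("cohort_rnaseq.tsv"),
    cohort_array = p("cohort_array.tsv"),
    cohort_panels = p("cohort_panels.csv"),
    models = model_paths,
    out_dir = file.path(dir, "out"),
    seed = seed, ...
  )
}
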