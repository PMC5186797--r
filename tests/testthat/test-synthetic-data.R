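test_that("noise-free rates follow the generative formula exactly and seeds reproduce", {
  truth <- tiny_truth(noise_sd = 0, n_signal_pairs = 1)
  panel <- simulate_cell_line_panel(truth, n_lines = 12, seed = 3)
  sp <- truth$signal_pairs
  expected <- truth$intercept + sp$coefficient[1] *
    panel$expression[sp$gene_a[1], ] * panel$expression[sp$gene_b[1], ]
  expect_equal(panel$rates$rate, unname(expected))

  again <- simulate_cell_line_panel(truth, n_lines = 12, seed = 3)
  expect_identical(panel, again)
  other <- simulate_cell_line_panel(truth, n_lines = 12, seed = 4)
  expect_false(identical(panel$expression, other$expression))
})

test_that("rates recomputed from the emitted matrix agree within the noise level", {
  truth <- ground_truth(n_genes = 500, n_signal_pairs = 3,
                        noise_sd = 1e-3, seed = 21)
  panel <- simulate_cell_line_panel(truth, n_lines = 57, seed = 22)
  # independent recomputation, plain loop over lines and pairs
  rec <- vapply(seq_len(ncol(panel$expression)), function(s) {
    r <- truth$intercept
    for (k in seq_len(nrow(truth$signal_pairs))) {
      sp <- truth$signal_pairs[k, ]
      r <- r + sp$coefficient * panel$expression[sp$gene_a, s] *
        panel$expression[sp$gene_b, s]
    }
    r
  }, 0)
  expect_lt(max(abs(panel$rates$rate - rec)), 5 * truth$noise_sd)
  expect_gt(var(panel$rates$rate), truth$noise_sd^2)
  expect_equal(panel$rates$doubling_time,
               rate_from_doubling_time(panel$rates$rate))
})

test_that("ground truth invariants are enforced", {
  expect_error(simulate_cell_line_panel(tiny_truth(), n_lines = 5),
               "at least 10")
  truth <- tiny_truth()
  bad <- truth
  bad$signal_pairs$gene_a[1] <- "g9999"
  expect_error(simulate_cell_line_panel(bad, n_lines = 12, seed = 1),
               "g9999")
  bad2 <- truth
  bad2$conserved_genes <- setdiff(bad2$conserved_genes,
                                  bad2$signal_pairs$gene_a[1])
  expect_error(proliflux:::validate_ground_truth(bad2), "conserved")
})

test_that("cohort platform structure matches the generative model", {
  truth <- tiny_truth()
  id_truth <- truth
  id_truth$alpha_true <- 1
  id_truth$beta_true <- 0
  co <- simulate_patient_cohort(id_truth, two_panels(), seed = 5)
  cons <- id_truth$conserved_genes
  expect_equal(unclass(co$rnaseq)[cons, ],
               unclass(co$reference)[cons, ])

  all_dual <- simulate_patient_cohort(truth, two_panels(),
                                      dual_platform_fraction = 1, seed = 5)
  expect_setequal(colnames(all_dual$array), colnames(all_dual$rnaseq))

  # the array platform carries the beta shift; rnaseq is its alpha-scaling
  co2 <- simulate_patient_cohort(truth, two_panels(), seed = 6,
                                 dual_platform_fraction = 1)
  expect_equal(unclass(co2$array)[cons, ],
               unclass(co2$reference)[cons, ] + truth$beta_true)
  expect_equal(unclass(co2$rnaseq)[cons, ],
               truth$alpha_true * unclass(co2$array)[cons, ])
})

test_that("panel rate shifts move panel means by the stated amount", {
  truth <- tiny_truth()
  co <- simulate_patient_cohort(truth,
                                tibble::tibble(name = c("pA", "pB"),
                                               n_samples = 80L,
                                               rate_shift = c(0, 0.02)),
                                seed = 11)
  means <- tapply(co$samples$true_rate, co$samples$panel, mean)
  expect_lt(abs((means["pB"] - means["pA"]) - 0.02), 5e-3)
  expect_error(simulate_patient_cohort(truth, tibble::tibble()),
               "at least one panel")
})

test_that("at least one non-conserved gene violates the filter band by construction", {
  truth <- tiny_truth(noise_sd = 0)
  co <- simulate_patient_cohort(truth, two_panels(), bio_sd = 0, seed = 2)
  ref <- simulate_cell_line_panel(truth, n_lines = 20, bio_sd = 0, seed = 3)
  pm <- platform_model(truth$alpha_true, truth$beta_true)
  report <- filter_conserved_genes(rowMeans(ref$expression),
                                rowMeans(co$array), rowMeans(co$rnaseq), pm)
  non_cons <- setdiff(names(truth$gene_means), truth$conserved_genes)
  violations <- report$gene[!report$passed & report$gene %in% non_cons]
  expect_gt(length(violations), 0)
  expect_false(any(non_cons %in% passing_genes(report)))
})

test_that("toy models are feasible, panel variants lack the removed reactions", {
  models <- simulate_toy_models(n_panels = 5, seed = 1)
  expect_length(models, 5)
  for (m in models) {
    sol <- pfba_fixed_growth(to_irreversible(m), 0.01)
    expect_equal(sol$status, "optimal")
    expect_gt(sol$objective, 0)
  }
  expect_false(any(c("PPP1", "PPP2", "PPP3") %in% models[[1]]$reactions$id))
  expect_false(any(c("GLY1", "GLY2") %in% models[[2]]$reactions$id))
  # a pathway removed from a panel's model carries no flux there
  sol2 <- pfba_fixed_growth(to_irreversible(models[[2]]), 0.01)
  expect_true(all(c("PPP1", "PPP2", "PPP3") %in% names(sol2$flux)))
  expect_error(simulate_toy_models(0), "at least one")
})
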