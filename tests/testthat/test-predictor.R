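test_that("interaction feature counts and values follow the pair+square scheme", {
  # k genes -> k(k-1)/2 products plus k squares
  set.seed(1)
  m <- matrix(rnorm(60 * 8, 8), nrow = 60,
              dimnames = list(sprintf("g%02d", 1:60),
                              sprintf("s%d", 1:8)))
  for (k in c(1, 2, 3, 5, 54)) {
    x <- build_interaction_features(m, rownames(m)[seq_len(k)])
    expect_identical(ncol(x), as.integer(k * (k - 1) / 2 + k))
  }
  x54 <- build_interaction_features(m, rownames(m)[1:54])
  info <- proliflux:::parse_feature_names(colnames(x54))
  expect_identical(sum(info$gene_a != info$gene_b), 1431L)
  expect_identical(sum(info$gene_a == info$gene_b), 54L)

  m2 <- matrix(c(3, 4), 2, 1, dimnames = list(c("a", "b"), "s1"))
  x2 <- build_interaction_features(m2, c("a", "b"))
  expect_equal(x2["s1", c("a:b", "a:a", "b:b")],
               c(`a:b` = 12, `a:a` = 9, `b:b` = 16))
  expect_error(build_interaction_features(m2, c("a", "a")), "duplicate")
  expect_error(build_interaction_features(m2, c("a", "zz")), "zz")
})

test_that("fit metrics match hand arithmetic and an independent loop", {
  m0 <- compute_fit_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m0), c(mse = 0, rmse = 0, mae = 0, mre = 0,
                             r_squared = 1))
  m1 <- compute_fit_metrics(c(2, 2), c(1, 2))
  expect_equal(m1$mse, 0.5)
  expect_equal(m1$rmse, sqrt(0.5))
  expect_equal(m1$mae, 0.5)
  expect_equal(m1$mre, 0.5)
  expect_equal(m1$r_squared, -1)

  set.seed(2)
  o <- rnorm(40, 5)
  p <- o + rnorm(40)
  got <- compute_fit_metrics(p, o)
  # plain-loop recomputation
  se <- ae <- re <- 0
  for (i in seq_along(o)) {
    se <- se + (p[i] - o[i])^2
    ae <- ae + abs(p[i] - o[i])
    re <- re + abs(p[i] - o[i]) / abs(o[i])
  }
  expect_equal(got$mse, se / 40)
  expect_equal(got$mae, ae / 40)
  expect_equal(got$mre, re / 40)
  expect_equal(got$rmse^2, got$mse)
  expect_equal(got$r_squared, 1 - se / sum((o - mean(o))^2))
  expect_error(compute_fit_metrics(1:3, 1:2), "equal")
})

test_that("the L1 path recovers sparse signals and its limits behave", {
  set.seed(3)
  n <- 40
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, sprintf("f%02d", 1:12)))
  y <- 3 * x[, 4] + rnorm(n, 0, 0.01)
  fit <- fit_lasso_cv(x, y, seed = 1)
  expect_gt(abs(fit$coefficients["f04"]), 1)
  expect_lt(max(abs(fit$coefficients[-4])), 0.05)

  # full-shrinkage limit: all coefficients zero, intercept = mean(y)
  big <- fit_lasso_cv(x, y, lambda = 1e6)
  expect_true(all(big$coefficients == 0))
  expect_equal(big$intercept, mean(y))

  # unpenalized limit matches the normal-equations oracle (n > p)
  y2 <- drop(x %*% seq(0.5, 6, length.out = 12)) + 2
  ols <- fit_lasso_cv(x, y2, lambda = 0)
  xd <- cbind(1, x)
  beta_hat <- solve(t(xd) %*% xd, t(xd) %*% y2)
  expect_equal(unname(ols$intercept), beta_hat[1], tolerance = 1e-6)
  expect_equal(unname(ols$coefficients), beta_hat[-1], tolerance = 1e-6)

  expect_error(fit_lasso_cv(x, rep(1, n), seed = 1), "constant")
  x[2, 2] <- NaN
  expect_error(fit_lasso_cv(x, y, seed = 1), "finite")
})

test_that("gene selection keeps clearly non-zero first-order coefficients", {
  fit <- proliflux:::new_interaction_predictor(
    proliflux:::parse_feature_names(c("g1", "g2", "g3")),
    c(0, 1e-12, 0.3), 0.1, 0.01)
  expect_identical(select_nonzero_genes(fit), "g3")
  zero <- proliflux:::new_interaction_predictor(
    proliflux:::parse_feature_names(c("g1", "g2")), c(0, 0), 0, 0.01)
  expect_length(select_nonzero_genes(zero), 0)
  inter <- proliflux:::new_interaction_predictor(
    proliflux:::parse_feature_names("g1:g2"), 1, 0, 0.01)
  expect_error(select_nonzero_genes(inter), "single-gene")
})

test_that("the coefficient cutoff drops the smallest quartile and refits", {
  set.seed(4)
  x <- matrix(rnorm(24 * 4), 24, 4,
              dimnames = list(NULL, c("a:a", "a:b", "b:b", "a:c")))
  beta <- c(1, 2, 3, 4)
  y <- drop(x %*% beta) + rnorm(24, 0, 0.01)
  fit <- proliflux:::new_interaction_predictor(
    proliflux:::parse_feature_names(colnames(x)), beta, 0, 0.01)
  cut <- apply_coefficient_cutoff(fit, q = 0.25, x, y, seed = 1)
  # quantile(c(1,2,3,4), .25) = 1.75; survivors are the three largest
  expect_setequal(cut$features$feature, c("a:b", "b:b", "a:c"))

  single <- proliflux:::new_interaction_predictor(
    proliflux:::parse_feature_names(colnames(x)), c(0, 0, 0, 2), 0, 0.01)
  kept <- apply_coefficient_cutoff(single, q = 0.25, x, y, seed = 1)
  expect_identical(kept$features$feature, "a:c")

  all_kept <- apply_coefficient_cutoff(fit, q = 0, x, y, seed = 1)
  expect_setequal(all_kept$features$feature, colnames(x))

  none <- proliflux:::new_interaction_predictor(
    proliflux:::parse_feature_names(colnames(x)), rep(0, 4), 0, 0.01)
  expect_error(apply_coefficient_cutoff(none, 0.25, x, y), "zero")
})

test_that("rate prediction is the intercept-plus-products form with flags", {
  m <- matrix(c(3, 4, 5, 6), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  flat <- proliflux:::new_interaction_predictor(
    proliflux:::parse_feature_names(c("a:b", "a:a")), c(0, 0), 0.02, 0.01)
  pr <- predict_rates(flat, m)
  expect_equal(pr$rate, c(0.02, 0.02))
  expect_false(any(pr$negative))

  model <- proliflux:::new_interaction_predictor(
    proliflux:::parse_feature_names(c("a:b", "b:b")), c(0.01, -0.02),
    0.1, 0.01)
  pr2 <- predict_rates(model, m)
  expect_equal(pr2$rate[1], 0.1 + 0.01 * 12 - 0.02 * 16)
  # permuting samples permutes predictions identically
  pr_rev <- predict_rates(model, m[, c("s2", "s1")])
  expect_equal(pr_rev$rate, rev(pr2$rate))
  expect_error(predict_rates(model, m[1, , drop = FALSE]), "b")
})

test_that("LOOCV reproduces the order ranking and recovers true pairs", {
  truth <- tiny_truth(noise_sd = 1e-3, seed = 41)
  panel <- simulate_cell_line_panel(truth, n_lines = 30, seed = 42)
  m <- panel$expression
  y <- panel$rates$rate
  cv1 <- loocv_evaluate(m, y, mode = "fixed_features", seed = 2,
                        order = "first")
  cv2 <- loocv_evaluate(m, y, mode = "fixed_features", seed = 2,
                        order = "second_cutoff")
  v1 <- glance(cv1)$r_squared
  v2 <- glance(cv2)$r_squared
  expect_gt(v2, v1)               # interaction model generalizes better
  expect_gt(v2, 0.9)
  # overfitting gap: first-order training beats its validation
  t1 <- cv1$metrics$r_squared[cv1$metrics$strategy == "train"]
  expect_gt(t1, v1)
  # all true interaction pairs among the final features
  sp <- truth$signal_pairs
  truep <- paste0(pmin(sp$gene_a, sp$gene_b), ":",
                  pmax(sp$gene_a, sp$gene_b))
  expect_true(all(truep %in% tidy(cv2$fit$predictor)$feature))
  expect_equal(cv2$metrics$rmse^2, cv2$metrics$mse, tolerance = 1e-12)
  expect_error(loocv_evaluate(m, y, mode = "bogus"), "arg")
})

test_that("nested LOOCV redoes selection per fold and stays predictive", {
  truth <- ground_truth(n_genes = 40, n_signal_pairs = 1, noise_sd = 1e-3,
                        seed = 51)
  panel <- simulate_cell_line_panel(truth, n_lines = 16, seed = 52)
  cv <- loocv_evaluate(panel$expression, panel$rates$rate,
                       mode = "nested", seed = 3)
  expect_gt(glance(cv)$r_squared, 0.5)
  expect_identical(nrow(cv$predictions), 16L)
})
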