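test_that("reversible splitting mirrors stoichiometry and preserves net action", {
  models <- simulate_toy_models(1)
  base <- models[[1]]
  irr <- to_irreversible(base)
  n_rev <- sum(base$reactions$reversible)
  expect_identical(ncol(irr$stoichiometry),
                   ncol(base$stoichiometry) + n_rev)
  for (rid in names(irr$reverse_of)) {
    fwd <- irr$reverse_of[[rid]]
    expect_equal(irr$stoichiometry[, rid], -irr$stoichiometry[, fwd])
    expect_identical(irr$pathway_map[[rid]], irr$pathway_map[[fwd]])
    # net action of the pair: forward minus backward spans the original
    expect_equal(irr$stoichiometry[, fwd] - irr$stoichiometry[, rid],
                 2 * base$stoichiometry[, fwd])
  }
  # a fully irreversible model passes through unchanged
  all_irrev <- base
  all_irrev$reactions$reversible <- FALSE
  expect_identical(ncol(to_irreversible(all_irrev)$stoichiometry),
                   ncol(base$stoichiometry))
})

test_that("pFBA solves a linear chain in closed form", {
  # uptake -> A -> proliferation, unit stoichiometry: every flux = r_p
  S <- matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("EX", "R1", "GROW")))
  model <- manual_irreversible(S, "GROW")
  sol <- pfba_fixed_growth(model, 0.02)
  expect_equal(unname(sol$flux), rep(0.02, 3))
  expect_equal(sol$objective, 0.06)
  expect_lt(max(abs(S %*% sol$flux)), 1e-7)
  expect_lt(abs(sol$flux[["GROW"]] - 0.02), 1e-9)
})

test_that("pFBA routes all flux through the shorter of two parallel paths", {
  # short: A -> B (1 step); long: A -> P1 -> P2 -> P3 -> B (4 steps)
  mets <- c("A", "P1", "P2", "P3", "B")
  rxns <- c("EX", "SHORT", "L1", "L2", "L3", "L4", "GROW")
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  S["A", "EX"] <- 1
  S["A", "SHORT"] <- -1; S["B", "SHORT"] <- 1
  S["A", "L1"] <- -1; S["P1", "L1"] <- 1
  S["P1", "L2"] <- -1; S["P2", "L2"] <- 1
  S["P2", "L3"] <- -1; S["P3", "L3"] <- 1
  S["P3", "L4"] <- -1; S["B", "L4"] <- 1
  S["B", "GROW"] <- -1
  model <- manual_irreversible(S, "GROW")
  sol <- pfba_fixed_growth(model, 0.05)
  expect_equal(sol$flux[["SHORT"]], 0.05)
  expect_equal(unname(sol$flux[c("L1", "L2", "L3", "L4")]), rep(0, 4))
  # the two route-pure solutions cost 3*r and 6*r; the solver finds 3*r
  expect_equal(sol$objective, 0.15)
})

test_that("pFBA objectives match exhaustive vertex enumeration on small models", {
  chain_S <- matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE,
                    dimnames = list(c("A", "B"), c("EX", "R1", "GROW")))
  branch_S <- matrix(0, 3, 6,
                     dimnames = list(c("A", "B", "C"),
                                     c("EX", "R1", "R2a", "R2b", "R3",
                                       "GROW")))
  branch_S["A", "EX"] <- 1
  branch_S["A", "R1"] <- -1; branch_S["B", "R1"] <- 1
  branch_S["B", "R2a"] <- -1; branch_S["C", "R2a"] <- 1
  branch_S["B", "R2b"] <- -1; branch_S["C", "R2b"] <- 2
  branch_S["C", "R3"] <- -1; branch_S["C", "GROW"] <- 0
  branch_S["C", "GROW"] <- -1; branch_S["C", "R3"] <- 0
  branch_S <- branch_S[, colnames(branch_S) != "R3"]
  for (case in list(list(S = chain_S, g = "GROW", r = 0.02),
                    list(S = branch_S, g = "GROW", r = 0.03),
                    list(S = chain_S, g = "GROW", r = 1))) {
    sol <- pfba_fixed_growth(manual_irreversible(case$S, case$g), case$r)
    oracle <- pfba_vertex_oracle(case$S,
                                 match(case$g, colnames(case$S)), case$r)
    expect_equal(sol$objective, oracle, tolerance = 1e-9)
    expect_lt(max(abs(case$S %*% sol$flux)), 1e-7)
    expect_lt(abs(sol$flux[[case$g]] - case$r), 1e-9)
  }
})

test_that("pFBA scales linearly in the proliferation rate", {
  irr <- to_irreversible(simulate_toy_models(1)[[1]])
  v1 <- pfba_fixed_growth(irr, 0.01)$flux
  v3 <- pfba_fixed_growth(irr, 0.03)$flux
  expect_equal(v3, 3 * v1, tolerance = 1e-9)
})

test_that("infeasible growth demands raise explicit errors", {
  # growth consumes a metabolite nothing produces
  S <- matrix(c(-1), 1, 1, dimnames = list("X", "GROW"))
  expect_error(pfba_fixed_growth(manual_irreversible(S, "GROW"), 0.1),
               "infeasible")
  irr <- to_irreversible(simulate_toy_models(1)[[1]])
  expect_error(pfba_fixed_growth(irr, -1), "r_p")
})

test_that("batched pFBA skips non-positive rates and recycling equals cold solves", {
  irr <- lapply(simulate_toy_models(3), to_irreversible)
  set.seed(6)
  rates <- setNames(runif(18, 0.01, 0.05), sprintf("s%02d", 1:18))
  rates[c(2, 9)] <- c(0, -0.01)
  panels <- setNames(rep(names(irr), each = 6), names(rates))

  fm <- batch_pfba(irr, rates, panels)
  expect_setequal(fm$skipped_samples, c("s02", "s09"))
  expect_identical(nrow(fm$values), 16L)
  expect_true(all(fm$values >= 0))

  cold <- batch_pfba(irr, rates, panels, recycle = FALSE)
  expect_lt(max(abs(fm$values - cold$values)), 1e-6)

  # identical rates within a panel give identical flux rows
  same <- batch_pfba(irr, c(a = 0.02, b = 0.02),
                     c(a = "panel_1", b = "panel_1"))
  expect_equal(same$values["a", ], same$values["b", ])

  allneg <- batch_pfba(irr, c(a = -1, b = 0), c(a = "panel_1",
                                                b = "panel_1"))
  expect_identical(nrow(allneg$values), 0L)
  expect_setequal(allneg$skipped_samples, c("a", "b"))
  expect_error(batch_pfba(irr, c(zz = 0.1), c(zz = "panel_9")),
               "panel_9")
})

test_that("the informative-flux filter equals a brute-force column scan", {
  irr <- lapply(simulate_toy_models(3), to_irreversible)
  set.seed(7)
  rates <- setNames(runif(12, 0.01, 0.05), sprintf("s%02d", 1:12))
  panels <- setNames(rep(names(irr), each = 4), names(rates))
  fm <- batch_pfba(irr, rates, panels)
  kept <- filter_informative_fluxes(fm, tol = 1e-9)
  manual <- colnames(fm$values)[apply(fm$values, 2, max) > 1e-9]
  expect_setequal(colnames(kept$values), manual)
  expect_lt(ncol(kept$values), ncol(fm$values))   # zero columns existed
})
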