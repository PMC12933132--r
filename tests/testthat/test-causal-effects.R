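test_that("single-boundary classes give degenerate effect summaries", {
  net <- buildTruthNetwork(2, 2, seed = 81)
  ct <- sampleCohort(net, 2000, seed = 82)
  eff <- estimateEffects(ct, list(c("X1", "X2")), "survival_2y")
  expect_equal(eff$min, eff$max)
  expect_equal(eff$median, eff$q1)
  fit <- attr(eff, "fits")[[1]]
  expect_equal(sort(fit@vars), c("X1", "X2"))
  expect_equal(eff$median[eff$variable == "X1"],
               unname(fit@coef["X1"]))
  ## direction tags follow the sign of the median sES
  expect_identical(eff$direction,
                   ifelse(eff$median >= 0, "promotes", "hampers"))
})

test_that("null variables inside a boundary shrink to zero effect", {
  net <- buildTruthNetwork(4, 1, effect_sizes = 0.8, seed = 83)
  ses <- vapply(1:10, function(s) {
    ct <- sampleCohort(net, 2000, seed = 90 + s)
    eff <- estimateEffects(ct, list(c("X1", "N2")), "survival_2y")
    eff$median[eff$variable == "N2"]
  }, 1.0)
  ## N2 is independent of the outcome: mean sES within 2 SE of zero
  expect_lt(abs(mean(ses)), 2 * sd(ses) / sqrt(length(ses)))
})

test_that("standardized coefficients are recovered from generative cohorts", {
  truth <- c(-0.75, 0.8, -0.6)
  net <- buildTruthNetwork(3, 3, effect_sizes = truth, seed = 85)
  ct <- sampleCohort(net, 4000, seed = 86)
  eff <- estimateEffects(ct, list(c("X1", "X2", "X3")), "survival_2y")
  est <- eff$median[match(paste0("X", 1:3), eff$variable)]
  expect_lt(mean(abs(est - truth) / abs(truth)), 0.2)
  ## generative coefficient inside the class [min, max] once several
  ## boundaries (here: bootstrap-like member subsets) contain the variable
  expect_true(all(sign(est) == sign(truth)))
})

test_that("perfect separation triggers the flagged ridge fallback", {
  set.seed(87)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  m <- cbind(sep = y, x = rnorm(n), survival_2y = y)
  fit <- fitBoundaryModel(m, c("sep", "x"), "survival_2y")
  expect_true(fit@separation)
  expect_true(all(is.finite(fit@coef)))
  ## flagged variables are excluded from intervention defaults
  eff <- estimateEffects(m, list(c("sep", "x")), "survival_2y")
  expect_true(eff$separation[eff$variable == "sep"])
})

test_that("interventions on zero-effect variables change nothing", {
  set.seed(88)
  m <- cbind(a = rnorm(200), b = rnorm(200),
             survival_2y = rbinom(200, 1, 0.6))
  model <- new("BoundaryModel", target = "survival_2y", vars = c("a", "b"),
               coef = c(`(Intercept)` = 0.4, a = 0, b = 0.7),
               centers = c(a = 0, b = 0), scales = c(a = 1, b = 1),
               separation = FALSE, converged = TRUE)
  iv <- simulateIntervention(model, m, "a")
  expect_equal(iv@p_post, iv@p_pre)
  expect_equal(iv@survival_fold, 1.0)
  expect_equal(iv@death_fold, 1.0)
})

test_that("intervention predictions equal the closed-form logistic values", {
  net <- buildTruthNetwork(0, 1, effect_sizes = -0.9, seed = 89,
                           cause_roles = "clinical-continuous")
  ct <- sampleCohort(net, 5000, seed = 90)
  bm <- fitBoundaryModel(ct, "X1", "survival_2y")
  iv <- simulateIntervention(bm, ct, "X1")
  ## hampering cause is set to its 5th percentile for everyone: the
  ## counterfactual mean is one closed-form logistic evaluation
  q5 <- quantile(cohortMatrix(ct)[, "X1"], 0.05, type = 7, names = FALSE)
  manual <- plogis(bm@coef[["(Intercept)"]] +
                     bm@coef[["X1"]] * (q5 - bm@centers[["X1"]]) /
                       bm@scales[["X1"]])
  expect_equal(iv@p_post, unname(manual), tolerance = 1e-6)
  ## only participants already beyond the 5th percentile can be made
  ## worse off by the uniform percentile assignment
  expect_lte(mean(iv@probs_post < iv@probs_pre), 0.06)
  expect_gt(iv@p_post, iv@p_pre)
})

test_that("direction-respecting interventions never reduce survival", {
  net <- buildTruthNetwork(4, 3, seed = 91)
  ct <- sampleCohort(net, 3000, seed = 92)
  bm <- fitBoundaryModel(ct, c("X1", "X2", "X3"), "survival_2y")
  iv <- simulateIntervention(bm, ct, c("X1", "X2", "X3"),
                             scope = "all-causes")
  expect_gte(iv@p_post, iv@p_pre)
  ## at most the tail fraction per intervened variable can move against
  ## the intervention direction
  expect_lte(mean(iv@probs_post < iv@probs_pre), 0.2)

  ## constant columns are skipped with a warning
  m <- survMB:::.asAnalysisMatrix(ct)
  m[, "X1"] <- 5
  bm2 <- new("BoundaryModel", target = "survival_2y",
             vars = c("X1", "X2"),
             coef = c(`(Intercept)` = 0.2, X1 = 0.5, X2 = 0.5),
             centers = c(X1 = 0, X2 = 0), scales = c(X1 = 1, X2 = 1),
             separation = FALSE, converged = TRUE)
  expect_warning(iv2 <- simulateIntervention(bm2, m, c("X1", "X2")),
                 "constant")
  expect_identical(iv2@variables, "X2")
})

test_that("fold changes follow the printed convention", {
  expect_equal(foldChange(0.5, 0.5, "survival"), 1.0)
  expect_equal(foldChange(0.5, 0.5, "death"), 1.0)
  expect_equal(foldChange(0.4, 0.8, "survival"), 2.0)
  ## raw ratio is available unrounded
  expect_equal(foldChange(0.25, 0.77, "death", rounded = FALSE), 75 / 23)
  ## rounding is half-up to one decimal
  expect_equal(foldChange(0.25, 0.77, "death"), 3.3)
  ## zero denominator: infinite-fold sentinel, not an error
  expect_identical(foldChange(0.4, 1, "death"), Inf)
  expect_error(foldChange(-0.1, 0.5), "probabilities")
})

test_that("percentile heatmaps are rank-based and effect-ordered", {
  set.seed(93)
  n <- 101
  m <- cbind(u = seq(0, 1, length.out = n), k = rep(2, n),
             v = rnorm(n), survival_2y = rbinom(n, 1, 0.5))
  eff <- data.frame(variable = c("u", "k", "v"),
                    median = c(0.5, -0.2, -0.9))
  hm <- percentileHeatmap(m, eff, m[, "survival_2y"])
  ## rows ordered by median effect, negative to positive
  expect_identical(rownames(hm), c("v", "k", "u"))
  ## uniform variable spans [0, 100]; constant maps to 50 by convention
  expect_equal(unname(range(hm["u", ])), c(0, 100))
  expect_true(all(hm["k", ] == 50))
  ## monotone transforms leave a row unchanged
  m2 <- m; m2[, "v"] <- exp(m2[, "v"])
  hm2 <- percentileHeatmap(m2, eff, m[, "survival_2y"])
  expect_equal(hm2["v", ], hm["v", ])
  ## columns grouped by outcome
  expect_true(!is.unsorted(attr(hm, "labels")))
})
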