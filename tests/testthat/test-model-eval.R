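test_that("stratified folds preserve class proportions to within one sample", {
  y <- c(rep(1, 30), rep(0, 70))
  f <- stratifiedSplit(y, 5, seed = 61)[[1]]
  pos_per_fold <- tapply(y, f, sum)
  expect_true(all(pos_per_fold == 6))          # divisible case is exact

  expect_identical(stratifiedSplit(y, 5, seed = 61),
                   stratifiedSplit(y, 5, seed = 61))

  ## 707 samples at a ~86% survival prevalence, 10 folds
  y7 <- c(rep(1, 608), rep(0, 99))
  f7 <- stratifiedSplit(y7, 10, seed = 62)[[1]]
  expect_lte(diff(range(tapply(y7, f7, sum))), 1)
  expect_lte(diff(range(table(f7))), 2)

  expect_error(stratifiedSplit(c(rep(0, 50), 1, 1), 5), "fewer members")
})

test_that("rank-based AUC equals exhaustive pairwise concordance", {
  set.seed(63)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    sc <- sample(round(rnorm(n), 1))   # rounding forces ties
    expect_equal(aucScore(sc, y), aucExhaustive(sc, y))
    expect_equal(survMB:::delongComponents(sc, y)$auc, aucExhaustive(sc, y))
  }
})

test_that("paired AUC comparison matches brute force and detects signal", {
  ## hand-checkable six-sample case
  y <- c(1, 1, 1, 0, 0, 0)
  a <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  b <- c(0.6, 0.5, 0.4, 0.5, 0.45, 0.3)
  cmp <- compareAUCs(a, b, y)
  expect_equal(cmp$difference, aucExhaustive(a, y) - aucExhaustive(b, y))

  expect_identical(compareAUCs(a, a, y)[c("difference", "p_value")],
                   list(difference = 0, p_value = 1))
  expect_error(compareAUCs(a, b[-1], y), "equal length")

  ## strong predictor vs pure noise at n = 500
  sig <- vapply(1:5, function(s) {
    set.seed(64 + s)
    yy <- rbinom(500, 1, 0.4)
    compareAUCs(yy + rnorm(500, 0, 0.7), rnorm(500), yy)$p_value < 0.05
  }, TRUE)
  expect_true(all(sig))

  ## agrees with the reference DeLong implementation when both curves
  ## point the same way
  set.seed(70)
  yy <- rbinom(300, 1, 0.5)
  sa <- yy + rnorm(300); sb <- 0.3 * yy + rnorm(300)
  cmp2 <- compareAUCs(sa, sb, yy)
  rt <- pROC::roc.test(pROC::roc(yy, sa, quiet = TRUE, direction = "<"),
                       pROC::roc(yy, sb, quiet = TRUE, direction = "<"),
                       paired = TRUE, method = "delong")
  expect_equal(cmp2$p_value, rt$p.value, tolerance = 1e-9)
})

test_that("nested CV scores perfect separation at 1 and selects the better config", {
  set.seed(71)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  X <- cbind(sep = y + runif(n, 0, 0.5), junk = rnorm(n))
  r <- nestedCV(X, y, list(ModelConfig("all-features", "logistic-glm")),
                outer = 4, inner = 3, repeats = 1, seed = 72)
  expect_equal(r@mean_auc, 1.0)
  expect_equal(r@sd_auc, 0)

  ## config 1 (plain logistic on a linear signal) beats config 2
  ## (a 3-tree forest) by construction
  set.seed(73)
  n <- 240
  x1 <- rnorm(n)
  yy <- rbinom(n, 1, plogis(1.8 * x1))
  XX <- cbind(x1 = x1, matrix(rnorm(n * 10), n, 10,
                              dimnames = list(NULL, paste0("j", 1:10))))
  cfgs <- list(ModelConfig("all-features", "logistic-glm"),
               ModelConfig("all-features", "random-forest",
                           list(num_trees = 3)))
  r2 <- nestedCV(XX, yy, cfgs, outer = 5, inner = 4, repeats = 4, seed = 74)
  expect_gte(mean(unlist(r2@winners) == 1), 0.9)
  expect_equal(length(r2@outer_auc), 20L)
})

test_that("holdout validation is exact, order-invariant and schema-checked", {
  set.seed(75)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  X <- cbind(sep = y + runif(n, 0, 0.4), noise = rnorm(n))
  rownames(X) <- paste0("S", 1:n)
  vr <- fitValidate(X, X, ModelConfig("all-features", "logistic-glm"),
                    train_labels = y, holdout_labels = y)
  expect_equal(vr@auc, 1.0)
  expect_equal(vr@ci[2], 1.0)

  ## permuted holdout labels: the CI covers chance
  set.seed(76)
  yp <- sample(y)
  vp <- fitValidate(X, X, ModelConfig("all-features", "logistic-glm"),
                    train_labels = y, holdout_labels = yp)
  expect_true(vp@ci[1] <= 0.5 && vp@ci[2] >= 0.5)

  ## row order of the holdout does not change the estimate
  ord <- sample(n)
  v2 <- fitValidate(X, X[ord, ], ModelConfig("all-features", "logistic-glm"),
                    train_labels = y, holdout_labels = y[ord])
  expect_equal(v2@auc, vr@auc)

  expect_error(
    fitValidate(X, X[, 1, drop = FALSE], ModelConfig(),
                train_labels = y, holdout_labels = y),
    "schema error")
})

test_that("permutation audit obeys its rank-based p-value definition", {
  set.seed(77)
  X <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(80, 1, 0.5)
  pipeline <- function(data, labels, seed) {
    set.seed(seed)
    runif(1)  # a stand-in score stream with no label dependence
  }
  expect_warning(pr <- permutationAudit(pipeline, X, y, 19, seed = 78),
                 "fewer than 20")
  expect_equal(pr@p_value,
               (1 + sum(pr@permuted >= pr@observed)) / (1 + 19))
  if (pr@observed < median(pr@permuted)) expect_gt(pr@p_value, 0.5)
  expect_length(pr@permuted, 19)
})
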