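## Predictive-modeling protocol: stratified repeated nested cross-validation
## for model selection with unbiased outer-loop error estimation, double
## holdout external validation, paired AUC comparison (DeLong), and the
## outcome-label permutation bias audit.

#' Construct a ModelConfig
#' @param feature_selector `"all-features"` or `"gll-k"`
#' @param classifier `"random-forest"` or `"logistic-glm"`
#' @param hyperparameters named list; forest: `num_trees` (500),
#'   `mtry_frac` (`"sqrt"` or `"third"`); logistic: `lambda` (ridge penalty,
#'   0 = plain ML); gll-k: `alpha`, `max_k`
#' @param seed integer
#' @export
ModelConfig <- function(feature_selector = "all-features",
                        classifier = "logistic-glm",
                        hyperparameters = list(), seed = 1L) {
  methods::new("ModelConfig", feature_selector = feature_selector,
               classifier = classifier, hyperparameters = hyperparameters,
               seed = as.integer(seed))
}

#' Registered default model menu
#'
#' The two selector families crossed with the two classifier families, with
#' small registered hyperparameter defaults (forest: 500 trees, mtry in
#' \{sqrt(p), p/3\}; logistic: plain and a 1/n ridge penalty).
#' @param seed integer
#' @export
defaultModelConfigs <- function(seed = 1L) {
  list(
    ModelConfig("all-features", "random-forest",
                list(num_trees = 500, mtry_frac = "sqrt"), seed),
    ModelConfig("all-features", "logistic-glm", list(lambda = 0), seed),
    ModelConfig("gll-k", "logistic-glm",
                list(lambda = 0, alpha = 0.05, max_k = 3), seed)
  )
}

#' Stratified fold assignment
#'
#' Each class is shuffled and dealt round-robin, so per-fold class counts
#' differ from perfect proportionality by at most one sample; deterministic
#' under `seed`.
#'
#' @param labels 0/1 labels
#' @param n_folds number of folds (>= 2); each class must have at least
#'   `n_folds` members
#' @param repeats number of independent assignments
#' @param seed integer
#' @return list of length `repeats`; each element an integer fold id per
#'   sample
#' @export
stratifiedSplit <- function(labels, n_folds, repeats = 1, seed = 1L) {
  labels <- stopIfNot01(labels)
  if (n_folds < 2) stop("n_folds must be >= 2")
  tab <- table(labels)
  if (length(tab) < 2) stop("both classes must be present")
  if (any(tab < n_folds))
    stop("a class has fewer members (", min(tab), ") than folds (",
         n_folds, ")")
  lapply(seq_len(repeats), function(r) {
    set.seed(childSeed(seed, r))
    fold <- integer(length(labels))
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

## -- model fitting -----------------------------------------------------------

## Fit one ModelConfig on a training matrix. The gll-k selector runs ONLY on
## the training rows it is handed (leakage is structurally impossible: test
## rows never enter this function).
fitModel <- function(X, y, config) {
  hp <- config@hyperparameters
  vars <- colnames(X)
  if (config@feature_selector == "gll-k") {
    cfg <- DiscoveryConfig(
      alpha = if (is.null(hp$alpha)) 0.05 else hp$alpha,
      max_k = if (is.null(hp$max_k)) 3 else hp$max_k,
      seed = config@seed)
    aug <- cbind(X, .mb_target = y)
    mb <- gllMB(aug, ".mb_target", cfg, candidates = colnames(X))
    vars <- mb@members
  }
  if (!length(vars))
    return(list(kind = "constant", score = mean(y), vars = character(),
                config = config))
  Xs <- X[, vars, drop = FALSE]
  if (config@classifier == "random-forest") {
    nt <- if (is.null(hp$num_trees)) 500 else hp$num_trees
    p <- length(vars)
    mtry <- switch(if (is.null(hp$mtry_frac)) "sqrt" else hp$mtry_frac,
                   "sqrt" = max(1, floor(sqrt(p))),
                   "third" = max(1, floor(p / 3)),
                   max(1, floor(sqrt(p))))
    fit <- ranger::ranger(
      x = Xs, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = nt, mtry = min(mtry, p), seed = config@seed,
      num.threads = 1)
    list(kind = "ranger", model = fit, vars = vars, config = config)
  } else {
    lambda <- if (is.null(hp$lambda)) 0 else hp$lambda
    if (lambda > 0) {
      fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                            lambda = lambda)
      list(kind = "glmnet", model = fit, vars = vars, config = config)
    } else {
      fit <- logisticFit(Xs, y)
      beta <- fit$coef; beta[is.na(beta)] <- 0
      list(kind = "glm", beta = beta, vars = vars, config = config)
    }
  }
}

predictModel <- function(fit, X) {
  switch(fit$kind,
    "constant" = rep(fit$score, nrow(X)),
    "ranger" = {
      pr <- predict(fit$model, data = X[, fit$vars, drop = FALSE],
                    num.threads = 1)$predictions
      pr[, "1"]
    },
    "glmnet" = as.numeric(predict(fit$model, X[, fit$vars, drop = FALSE],
                                  type = "response")),
    "glm" = {
      Xd <- cbind(1, X[, fit$vars, drop = FALSE])
      plogis(as.numeric(Xd %*% fit$beta))
    })
}

## -- nested cross-validation -------------------------------------------------

#' Stratified repeated nested cross-validation
#'
#' Inner loop: each candidate [ModelConfig-class] is scored by mean inner-CV
#' AUC on the outer-training fold; the winner is refit on the full
#' outer-training fold and scored once on the outer-test fold. Feature
#' selection (including the gll-k selector) runs strictly inside training
#' folds -- test rows never reach the selector or classifier during fitting.
#'
#' @param data samples-by-features numeric matrix or [CohortTable-class]
#' @param labels 0/1 outcome labels (for a CohortTable, pass
#'   `outcomeLabels(ct, h)`)
#' @param configs list of [ModelConfig-class]
#' @param outer,inner fold counts
#' @param repeats outer-loop repeats
#' @param seed integer
#' @return an [NCVResult-class]
#' @export
nestedCV <- function(data, labels, configs = defaultModelConfigs(),
                     outer = 10, inner = 10, repeats = 10, seed = 1L) {
  X <- if (is(data, "CohortTable")) cohortMatrix(data) else as.matrix(data)
  y <- stopIfNot01(labels)
  if (!length(configs)) stop("need at least one ModelConfig")
  outer_auc <- numeric(0)
  winners <- list()
  for (r in seq_len(repeats)) {
    folds <- stratifiedSplit(y, outer, 1, childSeed(seed, 17L * r))[[1]]
    for (f in seq_len(outer)) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      win <- 1L
      if (length(configs) > 1L) {
        inner_folds <- stratifiedSplit(
          ytr, inner, 1, childSeed(seed, 1000L * r + f))[[1]]
        inner_auc <- vapply(seq_along(configs), function(ci) {
          aucs <- vapply(seq_len(inner), function(g) {
            itr <- inner_folds != g
            fit <- fitModel(Xtr[itr, , drop = FALSE], ytr[itr], configs[[ci]])
            sc <- predictModel(fit, Xtr[!itr, , drop = FALSE])
            aucScore(sc, ytr[!itr])
          }, 1.0)
          mean(aucs, na.rm = TRUE)
        }, 1.0)
        win <- which.max(inner_auc)
      }
      fit <- fitModel(Xtr, ytr, configs[[win]])
      sc <- predictModel(fit, X[!tr, , drop = FALSE])
      outer_auc <- c(outer_auc, aucScore(sc, y[!tr]))
      winners[[length(winners) + 1L]] <- win
    }
  }
  methods::new("NCVResult", outer_auc = outer_auc,
               mean_auc = mean(outer_auc, na.rm = TRUE),
               sd_auc = sd(outer_auc), winners = winners,
               n_folds = as.integer(outer), repeats = as.integer(repeats),
               seed = as.integer(seed))
}

## -- external validation -----------------------------------------------------

#' Fit on training data, validate on an independent holdout
#'
#' The final model is fit on all training rows and scored once on the
#' holdout; the AUC 95% CI uses the DeLong variance with a normal
#' approximation, falling back to a 2000-replicate bootstrap when the
#' DeLong variance degenerates (e.g. perfect separation or heavy ties).
#'
#' @param train,holdout [CohortTable-class] objects (or numeric matrices,
#'   in which case `train_labels`/`holdout_labels` are required) with
#'   identical variable sets and disjoint samples
#' @param config a [ModelConfig-class]
#' @param horizon horizon id used to pull labels from CohortTables
#' @param train_labels,holdout_labels 0/1 labels for matrix inputs
#' @return a [ValidationResult-class] (predictions retained for paired
#'   comparison tests)
#' @export
fitValidate <- function(train, holdout, config = ModelConfig(),
                        horizon = NULL, train_labels = NULL,
                        holdout_labels = NULL) {
  if (is(train, "CohortTable")) {
    if (is.null(horizon)) horizon <- cohortHorizons(train)[1]
    train_labels <- outcomeLabels(train, horizon)
    Xtr <- cohortMatrix(train)
  } else Xtr <- as.matrix(train)
  if (is(holdout, "CohortTable")) {
    if (is.null(horizon)) horizon <- cohortHorizons(holdout)[1]
    holdout_labels <- outcomeLabels(holdout, horizon)
    Xho <- cohortMatrix(holdout)
  } else Xho <- as.matrix(holdout)
  if (!identical(colnames(Xtr), colnames(Xho)))
    stop("schema error: train and holdout variable sets differ")
  ytr <- stopIfNot01(train_labels)
  yho <- stopIfNot01(holdout_labels)

  fit <- fitModel(Xtr, ytr, config)
  sc <- predictModel(fit, Xho)
  auc <- aucScore(sc, yho)
  v <- tryCatch(delongVar(sc, yho), error = function(e) NA_real_)
  if (is.finite(v) && v > 0) {
    half <- qnorm(0.975) * sqrt(v)
    ci <- c(max(0, auc - half), min(1, auc + half))
  } else {
    ci <- .bootstrapAUCCI(sc, yho, seed = config@seed)
  }
  methods::new("ValidationResult", auc = auc, ci = ci,
               n = length(yho),
               predictions = data.frame(
                 sample = if (is.null(rownames(Xho)))
                   as.character(seq_along(yho)) else rownames(Xho),
                 score = sc, label = yho, stringsAsFactors = FALSE))
}

.bootstrapAUCCI <- function(scores, labels, B = 2000, seed = 1L) {
  set.seed(childSeed(seed, 555L))
  n <- length(labels)
  reps <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    aucScore(scores[i], labels[i])
  }, 1.0)
  reps <- reps[is.finite(reps)]
  if (!length(reps)) return(c(aucScore(scores, labels), aucScore(scores, labels)))
  unname(quantile(reps, c(0.025, 0.975), type = 7))
}

#' Paired comparison of two AUCs on shared samples
#'
#' DeLong's test for paired (correlated) ROC curves: the variance of the
#' AUC difference uses the covariance of the placement values, yielding a
#' normal CI and two-sided p-value. Degenerate cases (zero variance) fall
#' back to a paired bootstrap.
#'
#' @param preds_a,preds_b prediction scores on the same samples
#' @param labels shared 0/1 labels
#' @return list(difference, ci, p_value, auc_a, auc_b)
#' @export
compareAUCs <- function(preds_a, preds_b, labels) {
  if (length(preds_a) != length(preds_b) ||
      length(preds_a) != length(labels))
    stop("prediction vectors and labels must have equal length")
  y <- stopIfNot01(labels)
  ca <- delongComponents(preds_a, y)
  cb <- delongComponents(preds_b, y)
  diff <- ca$auc - cb$auc
  m <- length(ca$v10); n <- length(ca$v01)
  v <- var(ca$v10 - cb$v10) / m + var(ca$v01 - cb$v01) / n
  if (is.finite(v) && v > 1e-16) {
    z <- diff / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    half <- qnorm(0.975) * sqrt(v)
    return(list(difference = diff, ci = c(diff - half, diff + half),
                p_value = p, auc_a = ca$auc, auc_b = cb$auc))
  }
  if (abs(diff) < 1e-12)
    return(list(difference = 0, ci = c(0, 0), p_value = 1,
                auc_a = ca$auc, auc_b = cb$auc))
  ## bootstrap fallback for degenerate ties
  set.seed(1L)
  B <- 2000
  nn <- length(y)
  d <- vapply(seq_len(B), function(b) {
    i <- sample.int(nn, nn, replace = TRUE)
    aucScore(preds_a[i], y[i]) - aucScore(preds_b[i], y[i])
  }, 1.0)
  d <- d[is.finite(d)]
  p <- max(2 * min(mean(d <= 0), mean(d >= 0)), 2 / B)
  list(difference = diff,
       ci = unname(quantile(d, c(0.025, 0.975), type = 7)),
       p_value = min(p, 1), auc_a = ca$auc, auc_b = cb$auc)
}

## -- permutation bias audit --------------------------------------------------

#' Outcome-label permutation audit of a full modeling pipeline
#'
#' The pipeline closure must encapsulate the COMPLETE protocol (feature
#' selection included), so that protocol-level leakage inflates the permuted
#' distribution and is detectable. Labels are permuted wholesale per
#' replicate and the pipeline re-run.
#'
#' @param pipeline function(data, labels, seed) returning one performance
#'   estimate (an AUC)
#' @param data passed through to the pipeline
#' @param labels 0/1 labels
#' @param n_permutations number of label permutations (warning below 20:
#'   p-value resolution is 1/(n+1))
#' @param seed integer
#' @return a [PermutationResult-class]
#' @export
permutationAudit <- function(pipeline, data, labels, n_permutations = 100,
                             seed = 1L) {
  y <- stopIfNot01(labels)
  if (n_permutations < 20)
    warning("fewer than 20 permutations: p-value resolution is coarse")
  observed <- pipeline(data, y, childSeed(seed, 0L))
  permuted <- vapply(seq_len(n_permutations), function(b) {
    set.seed(childSeed(seed, b))
    yp <- sample(y)
    pipeline(data, yp, childSeed(seed, b))
  }, 1.0)
  p <- (1 + sum(permuted >= observed)) / (1 + n_permutations)
  methods::new("PermutationResult", observed = observed, permuted = permuted,
               p_value = p, n_permutations = as.integer(n_permutations),
               seed = as.integer(seed))
}

#' Flag estimation bias from a permutation audit
#'
#' An unbiased protocol has permuted-label performance centred on chance:
#' the audit flags bias when the permuted mean AUC exceeds 0.5 by more than
#' two standard errors.
#'
#' @param pr a [PermutationResult-class]
#' @return list(biased, permuted_mean, se)
#' @export
permutationBiased <- function(pr) {
  mu <- mean(pr@permuted)
  se <- sd(pr@permuted) / sqrt(length(pr@permuted))
  list(biased = (mu - 0.5) > 2 * se, permuted_mean = mu, se = se)
}
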