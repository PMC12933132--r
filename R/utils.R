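## Internal numerics shared across modules.

## Deterministic child-seed derivation: all randomness flows from one integer
## master seed. Linear-congruential style mix kept below 2^31.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629) + 1L
}

## Round half up to one decimal (paper-style fold rendering: 5.25 -> 5.3).
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## Rank-based AUC (Mann-Whitney; ties count 0.5). labels 0/1, scores numeric.
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## DeLong placement values and variance components for one score vector.
## Returns list(auc, v10, v01): structural components for positives/negatives.
delongComponents <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1L]   # positives
  y <- scores[labels == 0L]   # negatives
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both classes required for DeLong components")
  ## psi(x, y) = 1 if x > y, 0.5 if equal, 0 otherwise; use rank trick
  all_r <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rx) / n            # per-positive placements
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m    # per-negative placements
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

## DeLong variance of a single AUC.
delongVar <- function(scores, labels) {
  cmp <- delongComponents(scores, labels)
  s10 <- var(cmp$v10); s01 <- var(cmp$v01)
  s10 / length(cmp$v10) + s01 / length(cmp$v01)
}

## Empirical percentile of each value within its own vector, type-7 inverse:
## percentile = 100 * (rank - 1) / (n - 1), average ranks for ties.
## A constant vector maps to 50 by this convention.
percentileRanks <- function(x) {
  n <- length(x)
  if (n == 1L) return(50)
  100 * (rank(x, ties.method = "average") - 1) / (n - 1)
}

## Fast logistic log-likelihood fit via glm.fit on a design matrix (with
## intercept prepended). Returns list(deviance, df_model, coef, converged,
## fitted). Rank-deficient designs are handled by QR pivoting inside glm.fit.
logisticFit <- function(X, y) {
  n <- length(y)
  X <- if (is.null(X))
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  else cbind(`(Intercept)` = rep(1, n), X)
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), control = list(maxit = 50))
  )
  list(deviance = fit$deviance, df_model = fit$rank, coef = fit$coefficients,
       converged = fit$converged, fitted = fit$fitted.values)
}

## Geometric-mean re-centering on the log scale.
recenterFactors <- function(f) f / exp(mean(log(f)))

stopIfNot01 <- function(labels) {
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1 with no missing values")
  as.integer(labels)
}
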