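## Conditional-independence and association primitives.
##
## Three tests cover the mixed data the cohorts carry: a likelihood-ratio
## test for logistic models when the dependent variable is binary (the
## default against the survival outcome), Fisher's z on partial correlations
## among continuous variables, and a G^2 test on (possibly discretized)
## contingency tables. Tests whose effective sample per parameter falls
## below 5 are flagged unreliable and report independence -- the standard
## conservatism in constraint-based discovery that bounds false adjacencies.

## Analysis matrix: samples x (variables + label columns).
.asAnalysisMatrix <- function(data) {
  if (is(data, "CohortTable")) {
    m <- cohortMatrix(data)
    cd <- SummarizedExperiment::colData(data)
    lab_cols <- grep("^survival_.*y$", colnames(cd), value = TRUE)
    labm <- do.call(cbind, lapply(lab_cols, function(lc) as.numeric(cd[[lc]])))
    if (!is.null(labm)) {
      colnames(labm) <- lab_cols
      m <- cbind(m, labm)
    }
    m
  } else {
    as.matrix(data)
  }
}

.newCI <- function(x, y, Z, statistic, dof, p, method, n, reliable = TRUE) {
  methods::new("CITestResult", x = x, y = y, Z = as.character(Z),
               statistic = statistic, dof = dof,
               p_value = min(max(p, 0), 1), method = method,
               n_effective = as.integer(n), reliable = reliable)
}

#' Test conditional independence of two variables
#'
#' @param data a [CohortTable-class] or numeric matrix/data.frame (samples in
#'   rows; survival label columns of a cohort are addressable by name).
#' @param x,y variable ids (`logistic-lrt` requires binary `y`).
#' @param Z conditioning set (character, possibly empty).
#' @param method `"logistic-lrt"`, `"fisher-z"` or `"g2-discrete"`.
#' @param n_bins,scheme discretization settings for `g2-discrete` applied to
#'   variables with more than `max_levels` distinct values.
#' @param max_levels variables with at most this many distinct values are
#'   treated as already discrete by `g2-discrete`.
#' @return a [CITestResult-class]
#' @examples
#' m <- cbind(a = rnorm(100), b = rnorm(100))
#' testIndependence(m, "a", "b", method = "fisher-z")
#' @export
testIndependence <- function(data, x, y, Z = character(),
                             method = c("logistic-lrt", "fisher-z",
                                        "g2-discrete"),
                             n_bins = 3, scheme = "quantile",
                             max_levels = 5) {
  method <- match.arg(method)
  if (x == y) stop("x and y must differ")
  if (x %in% Z || y %in% Z) stop("Z must exclude x and y")
  m <- .asAnalysisMatrix(data)
  cols <- c(x, y, Z)
  missing_cols <- setdiff(cols, colnames(m))
  if (length(missing_cols))
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "))
  sub <- m[, cols, drop = FALSE]
  sub <- sub[complete.cases(sub), , drop = FALSE]
  n <- nrow(sub)

  ## degenerate inputs: constant variable carries no information
  if (n < 3 || sd(sub[, x]) == 0 || sd(sub[, y]) == 0)
    return(.newCI(x, y, Z, 0, 0, 1, method, n))

  switch(method,
    "fisher-z" = .fisherZ(sub, x, y, Z, n),
    "logistic-lrt" = .logisticLRT(sub, x, y, Z, n),
    "g2-discrete" = .g2Test(sub, x, y, Z, n, n_bins, scheme, max_levels))
}

.fisherZ <- function(sub, x, y, Z, n) {
  dof <- n - length(Z) - 3
  if (dof < 1 || n / (length(Z) + 3) < 5)  # below the reliability rule
    return(.newCI(x, y, Z, 0, max(dof, 0), 1, "fisher-z", n, reliable = FALSE))
  if (length(Z)) {
    D <- cbind(1, sub[, Z, drop = FALSE])
    rx <- qr.resid(qr(D), sub[, x])
    ry <- qr.resid(qr(D), sub[, y])
    if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
      return(.newCI(x, y, Z, 0, dof, 1, "fisher-z", n))
    r <- cor(rx, ry)
  } else {
    r <- cor(sub[, x], sub[, y])
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  stat <- atanh(r) * sqrt(dof)
  p <- 2 * pnorm(-abs(stat))
  .newCI(x, y, Z, stat, dof, p, "fisher-z", n)
}

.logisticLRT <- function(sub, x, y, Z, n) {
  yy <- sub[, y]
  if (!all(yy %in% c(0, 1)))
    stop("logistic-lrt requires binary y")
  n_par <- length(Z) + 2
  if (n / n_par < 5 || length(unique(yy)) < 2)
    return(.newCI(x, y, Z, 0, 1, 1, "logistic-lrt", n, reliable = FALSE))
  X0 <- if (length(Z)) sub[, Z, drop = FALSE] else NULL
  f0 <- logisticFit(X0, yy)
  f1 <- logisticFit(cbind(X0, sub[, x, drop = FALSE]), yy)
  dof <- f1$df_model - f0$df_model
  if (dof <= 0)  # x aliased with Z (e.g. exact duplicate): no information left
    return(.newCI(x, y, Z, 0, 0, 1, "logistic-lrt", n))
  stat <- max(f0$deviance - f1$deviance, 0)
  p <- pchisq(stat, dof, lower.tail = FALSE)
  .newCI(x, y, Z, stat, dof, p, "logistic-lrt", n)
}

.g2Test <- function(sub, x, y, Z, n, n_bins, scheme, max_levels) {
  disc <- function(v) {
    if (length(unique(v)) > max_levels)
      discretize(v, n_bins = n_bins, scheme = scheme)
    else as.integer(factor(v))
  }
  dx <- disc(sub[, x]); dy <- disc(sub[, y])
  dz <- if (length(Z)) {
    zz <- apply(sub[, Z, drop = FALSE], 2, disc)
    interaction(as.data.frame(zz), drop = TRUE)
  } else factor(rep(1, n))
  rx <- length(unique(dx)); ry <- length(unique(dy))
  dof <- (rx - 1) * (ry - 1) * nlevels(dz)
  if (dof == 0) return(.newCI(x, y, Z, 0, 0, 1, "g2-discrete", n))
  if (n / dof < 5)
    return(.newCI(x, y, Z, 0, dof, 1, "g2-discrete", n, reliable = FALSE))
  g2 <- 0
  for (lev in levels(dz)) {
    sel <- dz == lev
    tab <- table(dx[sel], dy[sel])
    nz <- sum(tab)
    if (nz == 0) next
    expd <- outer(rowSums(tab), colSums(tab)) / nz
    nonz <- tab > 0
    g2 <- g2 + 2 * sum(tab[nonz] * log(tab[nonz] / expd[nonz]))
  }
  p <- pchisq(g2, dof, lower.tail = FALSE)
  .newCI(x, y, Z, g2, dof, p, "g2-discrete", n)
}

#' Rank candidate variables by marginal association with a target
#'
#' Univariate prioritization for the GLL admission queue: strength is
#' -log10(p) from [testIndependence()] against the empty conditioning set,
#' with ties broken by |statistic| and then lexicographic variable id, so
#' the ordering is deterministic.
#'
#' @inheritParams testIndependence
#' @param target target variable id
#' @param candidates nonempty character vector of candidate ids
#' @param method CI test method (see [testIndependence()])
#' @return data.frame(variable, strength, statistic, p_value) in descending
#'   strength order
#' @export
associationRank <- function(data, target, candidates,
                            method = "logistic-lrt", ...) {
  if (!length(candidates)) stop("candidates must be nonempty")
  res <- lapply(candidates, function(v)
    testIndependence(data, v, target, character(), method = method, ...))
  p <- vapply(res, function(r) r@p_value, 1.0)
  stat <- vapply(res, function(r) r@statistic, 1.0)
  strength <- -log10(pmax(p, 1e-300))
  ord <- order(-strength, -abs(stat), candidates)
  data.frame(variable = candidates[ord], strength = strength[ord],
             statistic = stat[ord], p_value = p[ord],
             stringsAsFactors = FALSE)
}

#' Discretize a numeric vector into bins
#'
#' @param values numeric vector
#' @param n_bins number of bins (>= 2)
#' @param scheme `"quantile"` (near-equal occupancy) or `"uniform"`
#'   (equal width). Both are monotone in the input.
#' @return integer vector of bin labels 0..n_bins-1 (fewer if distinct
#'   values collapse, with a warning)
#' @export
discretize <- function(values, n_bins = 3, scheme = c("quantile", "uniform")) {
  scheme <- match.arg(scheme)
  if (n_bins < 2) stop("n_bins must be >= 2")
  nd <- length(unique(values))
  if (nd < n_bins)
    warning("fewer distinct values (", nd, ") than bins (", n_bins,
            "); bins collapsed")
  if (nd == 1L) return(rep(0L, length(values)))
  breaks <- if (scheme == "quantile") {
    unique(quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                    type = 7, names = FALSE))
  } else {
    seq(min(values), max(values), length.out = n_bins + 1)
  }
  if (length(breaks) < 2) return(rep(0L, length(values)))
  as.integer(cut(values, breaks = breaks, include.lowest = TRUE,
                 labels = FALSE)) - 1L
}
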