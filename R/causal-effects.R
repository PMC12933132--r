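## Standardized effect estimation over each Markov boundary, box summaries
## across the equivalence class, and in-silico percentile interventions.
##
## Per boundary, a logistic regression of the outcome on the boundary
## members is fit with continuous predictors z-scored (binary predictors
## stay 0/1, so their coefficient is the effect of a category flip); the
## coefficients are the standardized effect sizes (sES). Quasi-separation
## is caught and refit with a light ridge penalty (1/n) and flagged rather
## than hidden.

#' BoundaryModel: a standardized logistic fit on one boundary
#' @slot target outcome id; @slot vars predictor ids; @slot coef named
#'   coefficients (`(Intercept)` first) on the standardized scale;
#' @slot centers,scales standardization applied per predictor (0/1 for
#'   binary predictors); @slot separation TRUE if the ridge fallback was
#'   needed; @slot converged logical.
#' @export
setClass("BoundaryModel",
  representation(target = "character", vars = "character", coef = "numeric",
                 centers = "numeric", scales = "numeric",
                 separation = "logical", converged = "logical"))

setMethod("show", "BoundaryModel", function(object) {
  cat("BoundaryModel for '", object@target, "' on {",
      paste(object@vars, collapse = ", "), "}",
      if (object@separation) " [separation: ridge fallback]" else "",
      "\n", sep = "")
  print(round(object@coef, 4))
})

#' Fit a standardized logistic model on a variable set
#'
#' @param data [CohortTable-class] or samples-by-variables matrix (label
#'   columns addressable by name for cohorts)
#' @param members predictor variable ids
#' @param target binary outcome id
#' @return a [BoundaryModel-class]
#' @export
fitBoundaryModel <- function(data, members, target) {
  m <- .asAnalysisMatrix(data)
  y <- stopIfNot01(m[, target])
  if (!length(members)) {
    return(methods::new("BoundaryModel", target = target, vars = character(),
                        coef = c(`(Intercept)` = qlogis(pmin(pmax(mean(y),
                          1e-6), 1 - 1e-6))),
                        centers = numeric(), scales = numeric(),
                        separation = FALSE, converged = TRUE))
  }
  X <- m[, members, drop = FALSE]
  is_bin <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  centers <- ifelse(is_bin, 0, colMeans(X))
  scales <- ifelse(is_bin, 1, apply(X, 2, sd))
  scales[scales == 0] <- 1
  Xs <- sweep(sweep(X, 2, centers), 2, scales, "/")

  fit <- logisticFit(Xs, y)
  ## quasi-separation: diverging standardized coefficients or IRLS failure
  ## (a legitimate extreme covariate value is not separation)
  sep <- !fit$converged || any(abs(fit$coef[-1]) > 10, na.rm = TRUE)
  if (sep) {
    gn <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                         lambda = 1 / length(y), standardize = FALSE)
    beta <- as.numeric(coef(gn))
    names(beta) <- rownames(coef(gn))
    cf <- setNames(beta[c("(Intercept)", colnames(Xs))],
                   c("(Intercept)", colnames(Xs)))
    conv <- TRUE
  } else {
    cf <- fit$coef
    cf[is.na(cf)] <- 0
    conv <- fit$converged
  }
  methods::new("BoundaryModel", target = target, vars = members,
               coef = cf, centers = setNames(centers, members),
               scales = setNames(scales, members),
               separation = sep, converged = conv)
}

#' Predicted survival probabilities from a BoundaryModel
#' @param model a [BoundaryModel-class]
#' @param data cohort or matrix carrying the model's variables
#' @return numeric vector of probabilities
#' @export
predictBoundaryModel <- function(model, data) {
  m <- .asAnalysisMatrix(data)
  eta <- rep(model@coef[["(Intercept)"]], nrow(m))
  for (v in model@vars)
    eta <- eta + model@coef[[v]] * (m[, v] - model@centers[[v]]) /
      model@scales[[v]]
  plogis(eta)
}

#' Standardized effect estimates across an equivalence class
#'
#' Fits one standardized logistic model per boundary and summarizes each
#' variable's coefficients over the boundaries that contain it: min, Q1,
#' median, Q3, max, presence count/fraction, and a direction tag
#' (`promotes` / `hampers` survival by the sign of the median sES).
#' Separation-flagged fits are marked and their variables excluded from
#' intervention defaults.
#'
#' @param data [CohortTable-class] or matrix
#' @param ec an [EquivalenceClass-class] (or list of member character
#'   vectors)
#' @param target binary outcome id
#' @return data.frame(variable, presence, presence_frac, min, q1, median,
#'   q3, max, direction, separation) ordered by median sES; the fitted
#'   [BoundaryModel-class] objects are attached as attribute `"fits"`
#' @export
estimateEffects <- function(data, ec, target) {
  sets <- if (is(ec, "EquivalenceClass"))
    lapply(ec@boundaries, mbMembers) else ec
  if (!length(sets)) stop("no boundaries to estimate effects on")
  fits <- lapply(sets, fitBoundaryModel, data = data, target = target)
  nb <- length(sets)
  vars <- sort(unique(unlist(sets)))
  rows <- lapply(vars, function(v) {
    ses <- unlist(lapply(fits, function(f)
      if (v %in% f@vars) f@coef[[v]] else NULL))
    sep <- any(vapply(fits, function(f) v %in% f@vars && f@separation, TRUE))
    q <- quantile(ses, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    data.frame(variable = v, presence = length(ses),
               presence_frac = length(ses) / nb,
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               direction = if (q[3] >= 0) "promotes" else "hampers",
               separation = sep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$median, out$variable), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Select intervention variables from an equivalence class
#' @param ec an [EquivalenceClass-class]
#' @param roles named role vector (see [variableRoles()])
#' @param scope `"smrna-only"` (intersection members with molecular role) or
#'   `"all-causes"` (union over all boundaries)
#' @export
interventionVariables <- function(ec, roles,
                                  scope = c("smrna-only", "all-causes")) {
  scope <- match.arg(scope)
  if (scope == "all-causes") return(mbUnion(ec))
  v <- mbIntersection(ec)
  v[roles[v] == "smrna-count"]
}

#' Simulate an in-silico percentile intervention
#'
#' Each intervened variable is set, for every participant, to its 5th
#' training percentile if its fitted effect hampers survival or its 95th
#' training percentile if it promotes survival; the observational fit is
#' then re-evaluated on the modified covariates (a do-operation on the
#' inputs -- the model is not refit). Non-intervened variables are
#' untouched. Percentiles use type-7 (linear interpolation) quantiles
#' computed on the training cohort.
#'
#' @param model a [BoundaryModel-class]
#' @param cohort cohort to intervene on ([CohortTable-class] or matrix)
#' @param variables variables to intervene on (must carry effect directions,
#'   i.e. be model predictors); constant columns are skipped with a warning
#' @param percentile_low,percentile_high percentile settings (default 5/95)
#' @param scope label recorded in the result
#' @param train cohort whose empirical percentiles define the intervention
#'   values (default: `cohort`)
#' @return an [InterventionResult-class]
#' @export
simulateIntervention <- function(model, cohort, variables,
                                 percentile_low = 5, percentile_high = 95,
                                 scope = "custom", train = NULL) {
  m <- .asAnalysisMatrix(cohort)
  mt <- if (is.null(train)) m else .asAnalysisMatrix(train)
  missing_dir <- setdiff(variables, model@vars)
  if (length(missing_dir))
    stop("no effect direction available for: ",
         paste(missing_dir, collapse = ", "))
  probs_pre <- predictBoundaryModel(model, m)
  m_post <- m
  used <- character()
  for (v in variables) {
    tv <- mt[, v]
    if (sd(tv) == 0) {
      warning("variable '", v, "' is constant in the training cohort; skipped")
      next
    }
    p <- if (model@coef[[v]] >= 0) percentile_high else percentile_low
    m_post[, v] <- quantile(tv, p / 100, type = 7, names = FALSE)
    used <- c(used, v)
  }
  probs_post <- predictBoundaryModel(model, m_post)
  p_pre <- mean(probs_pre); p_post <- mean(probs_post)
  ## direction coherence: setting each variable to its favourable
  ## percentile should not reduce the cohort mean
  if (p_post < p_pre)
    warning("direction-respecting intervention decreased mean survival (",
            signif(p_pre, 3), " -> ", signif(p_post, 3), ")")
  methods::new("InterventionResult", variables = used,
               probs_pre = probs_pre, probs_post = probs_post,
               p_pre = p_pre, p_post = p_post,
               survival_fold = foldChange(p_pre, p_post, "survival"),
               death_fold = foldChange(p_pre, p_post, "death"),
               percentiles = c(percentile_low, percentile_high),
               scope = scope)
}

#' Fold change between pre- and post-intervention survival probabilities
#'
#' Survival direction reports the relative increase in survival probability
#' (p_post / p_pre); death direction reports the fold reduction in the
#' probability of death ((1 - p_pre) / (1 - p_post)). Values are rendered
#' rounded half-up to one decimal (e.g. survival 0.47 -> 0.90 is a 5.3-fold
#' death reduction); a zero denominator yields `Inf` (an "infinite-fold"
#' change), never an error.
#'
#' @param p_pre,p_post probabilities in (0,1) (boundary values allowed where
#'   the chosen direction's denominator is nonzero)
#' @param direction `"survival"` or `"death"`
#' @param rounded return the one-decimal rendering (default) or the raw
#'   ratio
#' @return numeric fold change
#' @examples
#' foldChange(0.47, 0.90, "death")    # 5.3
#' foldChange(0.47, 0.90, "survival") # 1.9
#' @export
foldChange <- function(p_pre, p_post, direction = c("survival", "death"),
                       rounded = TRUE) {
  direction <- match.arg(direction)
  if (any(c(p_pre, p_post) < 0 | c(p_pre, p_post) > 1))
    stop("probabilities must lie in [0,1]")
  raw <- if (direction == "survival") {
    if (p_pre == 0) Inf else p_post / p_pre
  } else {
    if (p_post == 1) Inf else (1 - p_pre) / (1 - p_post)
  }
  if (rounded && is.finite(raw)) roundHalfUp(raw, 1) else raw
}

#' Percentile heatmap matrix of equivalence-class variables
#'
#' Rows are the union variables ordered by median standardized effect from
#' negative to positive; each cell is the participant's within-variable
#' empirical percentile (type-7 convention; a constant variable maps to 50);
#' columns are grouped into outcome blocks (deceased first, then survivors).
#'
#' @param data cohort or matrix
#' @param effects output of [estimateEffects()]
#' @param labels 0/1 outcome labels per participant
#' @return numeric matrix (variables x participants) with attribute
#'   `"labels"` giving the column outcome block
#' @export
percentileHeatmap <- function(data, effects, labels) {
  m <- .asAnalysisMatrix(data)
  y <- stopIfNot01(labels)
  vars <- effects$variable[order(effects$median, effects$variable)]
  hm <- t(apply(m[, vars, drop = FALSE], 2, percentileRanks))
  rownames(hm) <- vars
  ord <- order(y)
  hm <- hm[, ord, drop = FALSE]
  attr(hm, "labels") <- y[ord]
  hm
}
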