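#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats anova aov as.formula binomial coef complete.cases cor
#'   glm glm.fit median na.omit pchisq plogis pnorm predict qlogis qnorm
#'   quantile rbinom rnbinom rnorm runif sd setNames var fivenum IQR
#' @importFrom utils combn head modifyList
NULL

## ---------------------------------------------------------------------------
## Ground-truth causal network (synthetic side)
## ---------------------------------------------------------------------------

#' TruthNetwork: a parameterized causal DAG with a terminal survival outcome
#'
#' Holds the generative ground truth for synthetic cohorts: variable nodes
#' with role tags, directed edges, per-node generative parameters, a logistic
#' outcome link per time horizon (all horizons share one latent risk residual,
#' giving nested survival labels), and the engineered information-equivalence
#' groups. The outcome nodes are terminal, so each horizon's Markov boundary
#' equals its parent set.
#'
#' @slot nodes data.frame with columns `id`, `role`
#'   (smrna-count | clinical-continuous | clinical-ordinal | age | outcome).
#' @slot edges data.frame with columns `from`, `to`.
#' @slot node_params named list of per-variable generative parameters,
#'   including closed-form population mean/sd used to standardize causes.
#' @slot outcome named list (one entry per horizon) of `intercept` and a
#'   named coefficient vector on population-standardized parents.
#' @slot equivalence_groups list of lists with `source`, `member`, `mode`
#'   (duplicate | noisy-copy | monotone-transform) and `snr`.
#' @slot block list(size, rho): optional block correlation of latent scores.
#' @slot seed integer seed the network was built from.
#'
#' @export
setClass("TruthNetwork",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    node_params = "list",
    outcome = "list",
    equivalence_groups = "list",
    block = "list",
    seed = "integer"
  )
)

setValidity("TruthNetwork", function(object) {
  msg <- character()
  g <- igraph::graph_from_data_frame(object@edges, directed = TRUE,
                                     vertices = object@nodes$id)
  if (!igraph::is_dag(g)) msg <- c(msg, "network graph must be acyclic")
  out_nodes <- object@nodes$id[object@nodes$role == "outcome"]
  if (length(out_nodes) == 0L) msg <- c(msg, "no outcome node")
  for (o in out_nodes) {
    if (any(object@edges$from == o))
      msg <- c(msg, sprintf("outcome node '%s' must be terminal (no children)", o))
  }
  for (eg in object@equivalence_groups) {
    if (!all(c("source", "member", "mode") %in% names(eg)))
      msg <- c(msg, "equivalence group missing source/member/mode")
    else if (!eg$mode %in% c("duplicate", "noisy-copy", "monotone-transform"))
      msg <- c(msg, sprintf("unknown equivalence mode '%s'", eg$mode))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Cohort container
## ---------------------------------------------------------------------------

#' CohortTable: samples-by-variables cohort with survival labels per horizon
#'
#' A [SummarizedExperiment::SummarizedExperiment] with variables in rows
#' (assay `"values"`), samples in columns, variable roles in `rowData()$role`,
#' binary survival labels per horizon in `colData()` (columns named
#' `survival_<h>y`), and a split tag per sample in `colData()$split`.
#' Count-role rows hold nonnegative integers; labels are exactly 0/1 with no
#' missing values. The split tags `discovery-subset` and `internal-validation`
#' together form the expanded discovery set.
#'
#' @export
setClass("CohortTable", contains = "SummarizedExperiment")

.valid_splits <- c("discovery-subset", "internal-validation",
                   "external-validation")
.valid_roles <- c("smrna-count", "clinical-continuous", "clinical-ordinal",
                  "age")

setValidity("CohortTable", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  if (!"role" %in% colnames(rd)) return("rowData must carry a 'role' column")
  if (!all(rd$role %in% .valid_roles))
    msg <- c(msg, "invalid variable role tag")
  lab_cols <- grep("^survival_.*y$", colnames(cd), value = TRUE)
  if (length(lab_cols) == 0L) msg <- c(msg, "no survival label column")
  for (lc in lab_cols) {
    v <- cd[[lc]]
    if (anyNA(v) || !all(v %in% c(0L, 1L)))
      msg <- c(msg, sprintf("label column '%s' must be 0/1 with no NA", lc))
  }
  if ("split" %in% colnames(cd) && !all(cd$split %in% .valid_splits))
    msg <- c(msg, "invalid split tag")
  a <- SummarizedExperiment::assay(object, "values")
  cnt <- rd$role == "smrna-count"
  if (any(cnt)) {
    vals <- a[cnt, , drop = FALSE]
    if (any(vals < 0) || any(vals != round(vals)))
      msg <- c(msg, "count-role variables must be nonnegative integers")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Conditional-independence test result
## ---------------------------------------------------------------------------

#' CITestResult: one conditional-independence test
#'
#' @slot x,y tested variable ids; @slot Z conditioning set;
#' @slot statistic,dof,p_value test outcome; @slot method test name;
#' @slot n_effective effective sample size; @slot reliable FALSE when the
#'   effective sample per parameter fell below the reliability rule (such
#'   tests report independence, p = 1 semantics preserved in `p_value`).
#' @export
setClass("CITestResult",
  representation(x = "character", y = "character", Z = "character",
                 statistic = "numeric", dof = "numeric", p_value = "numeric",
                 method = "character", n_effective = "integer",
                 reliable = "logical")
)

setValidity("CITestResult", function(object) {
  msg <- character()
  if (object@p_value < 0 || object@p_value > 1)
    msg <- c(msg, "p_value must be in [0,1]")
  if (object@dof < 0) msg <- c(msg, "dof must be >= 0")
  if (object@x %in% object@Z || object@y %in% object@Z)
    msg <- c(msg, "conditioning set must exclude x and y")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Discovery configuration and Markov boundary containers
## ---------------------------------------------------------------------------

#' DiscoveryConfig: settings for GLL Markov-boundary induction
#'
#' @slot alpha significance level for conditional-independence calls.
#' @slot max_k bound on conditioning-set size (the "K" of GLL-K).
#' @slot ci_method one of `logistic-lrt`, `fisher-z`, `g2-discrete`.
#' @slot max_candidates cap on the candidate queue (Inf = unlimited).
#' @slot seed integer seed for any stochastic sub-steps.
#' @export
setClass("DiscoveryConfig",
  representation(alpha = "numeric", max_k = "numeric", ci_method = "character",
                 max_candidates = "numeric", seed = "integer"),
  prototype(alpha = 0.05, max_k = 3, ci_method = "logistic-lrt",
            max_candidates = Inf, seed = 1L)
)

setValidity("DiscoveryConfig", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0,1)")
  if (object@max_k < 0) msg <- c(msg, "max_k must be >= 0")
  if (!object@ci_method %in% c("logistic-lrt", "fisher-z", "g2-discrete"))
    msg <- c(msg, "unknown ci_method")
  if (length(msg)) msg else TRUE
})

#' MarkovBoundary: one induced boundary with its sepset ledger
#'
#' @slot target outcome variable id.
#' @slot members retained variable ids, in admission order.
#' @slot sepsets named list: excluded variable -> conditioning set that
#'   rendered it independent of the target at eviction (or exclusion) time.
#' @slot config the [DiscoveryConfig-class] used.
#' @slot trace data.frame admission/elimination log (step, action, variable,
#'   sepset, p_value).
#' @export
setClass("MarkovBoundary",
  representation(target = "character", members = "character",
                 sepsets = "list", config = "DiscoveryConfig",
                 trace = "data.frame")
)

setValidity("MarkovBoundary", function(object) {
  msg <- character()
  if (length(intersect(object@members, names(object@sepsets))))
    msg <- c(msg, "members and sepset keys must be disjoint")
  k <- object@config@max_k
  if (length(object@sepsets) &&
      any(vapply(object@sepsets, length, 1L) > k))
    msg <- c(msg, "sepset larger than max_k")
  if (length(msg)) msg else TRUE
})

#' EquivalenceClass: the TIE*-style set of all equivalent Markov boundaries
#'
#' Intersection, union and per-variable frequency are derived from the stored
#' boundaries by [mbIntersection()], [mbUnion()] and [mbFrequency()], so the
#' containment invariants hold by construction.
#'
#' @slot target outcome variable id.
#' @slot boundaries list of [MarkovBoundary-class], pairwise distinct as sets.
#' @slot verification data.frame of per-candidate verifier results.
#' @slot config the [DiscoveryConfig-class] of the base inducer.
#' @slot flags character vector, e.g. "possibly-incomplete".
#' @export
setClass("EquivalenceClass",
  representation(target = "character", boundaries = "list",
                 verification = "data.frame", config = "DiscoveryConfig",
                 flags = "character")
)

setValidity("EquivalenceClass", function(object) {
  msg <- character()
  sets <- lapply(object@boundaries, function(b) sort(b@members))
  if (length(sets) > 1L && anyDuplicated(sets))
    msg <- c(msg, "boundaries must be pairwise distinct as sets")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Predictive-modeling result containers
## ---------------------------------------------------------------------------

#' ModelConfig: a registered feature-selector / classifier combination
#'
#' @slot feature_selector `"all-features"` or `"gll-k"`.
#' @slot classifier `"random-forest"` or `"logistic-glm"`.
#' @slot hyperparameters named list (forest: `num_trees`, `mtry_frac`;
#'   logistic: `lambda`; gll-k selector: `alpha`, `max_k`).
#' @slot seed integer.
#' @export
setClass("ModelConfig",
  representation(feature_selector = "character", classifier = "character",
                 hyperparameters = "list", seed = "integer"),
  prototype(feature_selector = "all-features", classifier = "logistic-glm",
            hyperparameters = list(), seed = 1L)
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@feature_selector %in% c("all-features", "gll-k"))
    msg <- c(msg, "unknown feature selector")
  if (!object@classifier %in% c("random-forest", "logistic-glm"))
    msg <- c(msg, "unknown classifier")
  if (length(msg)) msg else TRUE
})

#' NCVResult: nested cross-validation performance estimate
#' @slot outer_auc per outer-fold AUC estimates (folds x repeats).
#' @slot mean_auc,sd_auc summary over outer estimates.
#' @slot winners list of winning config index per outer fold.
#' @slot n_folds,repeats,seed fold specification.
#' @export
setClass("NCVResult",
  representation(outer_auc = "numeric", mean_auc = "numeric",
                 sd_auc = "numeric", winners = "list",
                 n_folds = "integer", repeats = "integer", seed = "integer")
)

setValidity("NCVResult", function(object) {
  msg <- character()
  if (length(object@outer_auc) != object@n_folds * object@repeats)
    msg <- c(msg, "fold count x repeats must equal number of outer estimates")
  if (object@sd_auc < 0) msg <- c(msg, "SD must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ValidationResult: holdout AUC with 95% confidence interval
#' @slot auc point estimate; @slot ci length-2 numeric (lower, upper);
#' @slot n holdout size; @slot predictions data.frame(sample, score, label).
#' @export
setClass("ValidationResult",
  representation(auc = "numeric", ci = "numeric", n = "integer",
                 predictions = "data.frame")
)

setValidity("ValidationResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "AUC must be in [0,1]")
  if (length(object@ci) != 2L || object@ci[1] > object@auc + 1e-12 ||
      object@ci[2] < object@auc - 1e-12)
    msg <- c(msg, "CI must bracket the AUC")
  if (length(msg)) msg else TRUE
})

#' PermutationResult: outcome-label permutation bias audit
#' @slot observed observed pipeline AUC; @slot permuted permuted-label AUCs;
#' @slot p_value (1 + #permuted >= observed) / (1 + n_permutations);
#' @slot n_permutations,seed bookkeeping.
#' @export
setClass("PermutationResult",
  representation(observed = "numeric", permuted = "numeric",
                 p_value = "numeric", n_permutations = "integer",
                 seed = "integer")
)

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (length(object@permuted) != object@n_permutations)
    msg <- c(msg, "distribution length must equal n_permutations")
  expect <- (1 + sum(object@permuted >= object@observed)) /
    (1 + object@n_permutations)
  if (abs(object@p_value - expect) > 1e-12)
    msg <- c(msg, "p-value inconsistent with rank definition")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Effects, interventions, normalization
## ---------------------------------------------------------------------------

#' InterventionResult: in-silico percentile intervention summary
#' @slot variables intervened variable ids.
#' @slot probs_pre,probs_post per-participant predicted survival probability.
#' @slot p_pre,p_post cohort means; @slot survival_fold,death_fold one-decimal
#'   fold changes; @slot percentiles c(low, high); @slot scope
#'   `"smrna-only"` or `"all-causes"` (or `"custom"`).
#' @export
setClass("InterventionResult",
  representation(variables = "character", probs_pre = "numeric",
                 probs_post = "numeric", p_pre = "numeric", p_post = "numeric",
                 survival_fold = "numeric", death_fold = "numeric",
                 percentiles = "numeric", scope = "character")
)

setValidity("InterventionResult", function(object) {
  msg <- character()
  pr <- c(object@probs_pre, object@probs_post, object@p_pre, object@p_post)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' NormalizationResult: trimmed-mean-of-M-values scale factors
#' @slot factors per-sample scale factor (geometric mean 1).
#' @slot reference reference sample id.
#' @slot trim_m,trim_a trim fractions used for M and A values.
#' @slot normalized counts divided by (library size x factor), per sample.
#' @export
setClass("NormalizationResult",
  representation(factors = "numeric", reference = "character",
                 trim_m = "numeric", trim_a = "numeric",
                 normalized = "matrix")
)

setValidity("NormalizationResult", function(object) {
  msg <- character()
  if (any(object@factors <= 0)) msg <- c(msg, "scale factors must be positive")
  if (abs(mean(log(object@factors))) > 1e-8)
    msg <- c(msg, "factors must have geometric mean 1")
  if (length(msg)) msg else TRUE
})

#' RunConfig: one fully reproducible end-to-end protocol run
#' @slot settings named list (paths, horizons, discovery, model menu, NCV
#'   settings, permutations, percentiles, output dir, master seed,
#'   normalization mode). See [readRunConfig()].
#' @export
setClass("RunConfig", representation(settings = "list"))
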