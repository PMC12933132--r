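## Generalized-local-learning (GLL) Markov boundary induction with bounded
## conditioning and full sepset bookkeeping.
##
## Admission is interleaved with elimination: candidates enter in marginal
## association order; after each admission every current member is re-tested
## against all conditioning subsets of the remaining members up to max_k
## (increasing size, then lexicographic), and the first accepting subset
## evicts the member and is recorded as its sepset. With max_k = 3 this is
## the "GLL-K-3" selector.

#' Construct a DiscoveryConfig
#' @param alpha significance level in (0,1)
#' @param max_k conditioning-set size bound
#' @param ci_method CI test method (see [testIndependence()])
#' @param max_candidates cap on the admission queue
#' @param seed integer
#' @export
DiscoveryConfig <- function(alpha = 0.05, max_k = 3,
                            ci_method = "logistic-lrt",
                            max_candidates = Inf, seed = 1L) {
  methods::new("DiscoveryConfig", alpha = alpha, max_k = max_k,
               ci_method = ci_method, max_candidates = max_candidates,
               seed = as.integer(seed))
}

## All subsets of vars with size <= max_k, increasing size then
## lexicographic; the empty set comes first.
.conditioningSubsets <- function(vars, max_k) {
  vars <- sort(vars)
  out <- list(character())
  for (k in seq_len(min(max_k, length(vars)))) {
    cm <- combn(vars, k)
    out <- c(out, asplit(cm, 2))
  }
  lapply(out, as.character)
}

#' Induce the Markov boundary of a binary target (GLL family)
#'
#' @param data a [CohortTable-class] or numeric matrix (samples x variables;
#'   survival label columns of a cohort are addressable by name).
#' @param target binary target variable id (e.g. `"survival_2y"`).
#' @param config a [DiscoveryConfig-class].
#' @param candidates candidate variable ids (default: all except target).
#' @return a [MarkovBoundary-class] with members, sepsets and a full
#'   admission/elimination trace.
#' @examples
#' net <- buildTruthNetwork(5, 2, seed = 3)
#' ct <- sampleCohort(net, 800, seed = 4)
#' gllMB(ct, "survival_2y", DiscoveryConfig())
#' @export
gllMB <- function(data, target, config = DiscoveryConfig(),
                  candidates = NULL) {
  m <- .asAnalysisMatrix(data)
  if (!target %in% colnames(m)) stop("unknown target '", target, "'")
  if (!all(m[, target] %in% c(0, 1)) && config@ci_method == "logistic-lrt")
    stop("target must be binary for logistic-lrt")
  if (is.null(candidates)) {
    candidates <- setdiff(colnames(m), target)
    ## other horizons' labels are outcomes, not candidate predictors
    candidates <- candidates[!grepl("^survival_.*y$", candidates)]
  }
  if (length(candidates) < 2) stop("need at least 2 candidate variables")
  alpha <- config@alpha

  rk <- associationRank(m, target, candidates, method = config@ci_method)
  queue <- rk$variable[rk$p_value < alpha]
  if (is.finite(config@max_candidates))
    queue <- head(queue, config@max_candidates)

  sepsets <- list()
  for (v in setdiff(candidates, queue)) sepsets[[v]] <- character()

  members <- character()
  trace <- list()
  step <- 0L
  ## CI results are pure given fixed data: memoize within the run (identical
  ## (v, Z) pairs recur across elimination sweeps)
  memo <- new.env(parent = emptyenv())
  ciTest <- function(v, Z) {
    key <- paste0(v, "|", paste(Z, collapse = ","))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- testIndependence(m, v, target, Z, method = config@ci_method)
    memo[[key]] <- res
    res
  }
  note <- function(action, variable, sepset = NA_character_,
                   p_value = NA_real_) {
    step <<- step + 1L
    trace[[step]] <<- data.frame(step = step, action = action,
                                 variable = variable, sepset = sepset,
                                 p_value = p_value, stringsAsFactors = FALSE)
  }

  for (cand in queue) {
    members <- c(members, cand)
    note("admit", cand,
         p_value = rk$p_value[match(cand, rk$variable)])
    ## elimination sweeps until no member can be evicted
    repeat {
      evicted <- FALSE
      for (v in rev(members)) {  # newest member first (semi-interleaved)
        rest <- setdiff(members, v)
        for (Z in .conditioningSubsets(rest, config@max_k)) {
          res <- ciTest(v, Z)
          if (res@p_value >= alpha) {
            members <- setdiff(members, v)
            sepsets[[v]] <- Z
            note("evict", v, paste(Z, collapse = ","), res@p_value)
            evicted <- TRUE
            break
          }
        }
        if (evicted) break
      }
      if (!evicted) break
    }
  }

  tr <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), action = character(), variable = character(),
               sepset = character(), p_value = numeric())
  methods::new("MarkovBoundary", target = target, members = members,
               sepsets = sepsets, config = config, trace = tr)
}

#' Explain why variables were excluded from a Markov boundary
#'
#' For each variable of interest, reports the recorded sepset -- the
#' conditioning set given which it became independent of the target. A
#' nonempty sepset identifies variables that mediate or confound the
#' variable's association with the outcome (no orientation is claimed);
#' an empty sepset marks a marginally independent variable; members are
#' reported as retained.
#'
#' @param mb a [MarkovBoundary-class]
#' @param variables_of_interest variable ids (default: all excluded + members)
#' @return data.frame(variable, status, sepset, interpretation)
#' @export
sepsetReport <- function(mb, variables_of_interest = NULL) {
  known <- c(mb@members, names(mb@sepsets))
  if (is.null(variables_of_interest)) variables_of_interest <- known
  unknown <- setdiff(variables_of_interest, known)
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  rows <- lapply(variables_of_interest, function(v) {
    if (v %in% mb@members)
      data.frame(variable = v, status = "retained", sepset = "",
                 interpretation = "markov-boundary-member")
    else {
      ss <- mb@sepsets[[v]]
      data.frame(variable = v, status = "excluded",
                 sepset = paste(ss, collapse = ","),
                 interpretation = if (length(ss)) "mediated-or-confounded"
                                  else "marginally-independent")
    }
  })
  do.call(rbind, rows)
}

#' Optional OR-symmetry filter on an induced boundary
#'
#' Re-runs local discovery around each member and checks the target appears
#' in the member's own neighborhood. With a terminal outcome this correction
#' is redundant, so it is off by default (`remove = FALSE` returns the input
#' unchanged); when on, asymmetric members are dropped with a trace entry,
#' never silently.
#'
#' @inheritParams gllMB
#' @param mb the boundary from [gllMB()] on the same data
#' @param remove apply the filter (default FALSE)
#' @return a [MarkovBoundary-class]
#' @export
symmetryCheck <- function(data, target, mb, config = mb@config,
                          remove = FALSE) {
  if (!remove) return(mb)
  m <- .asAnalysisMatrix(data)
  keep <- character(); dropped <- character()
  for (v in mb@members) {
    meth <- if (all(m[, v] %in% c(0, 1))) config@ci_method else "fisher-z"
    cfg_v <- DiscoveryConfig(alpha = config@alpha, max_k = config@max_k,
                             ci_method = meth, seed = config@seed)
    nb <- gllMB(m, v, cfg_v,
                candidates = setdiff(colnames(m), v))
    if (target %in% nb@members) keep <- c(keep, v) else dropped <- c(dropped, v)
  }
  if (!length(dropped)) return(mb)
  tr <- mb@trace
  for (v in dropped) {
    tr <- rbind(tr, data.frame(step = max(tr$step, 0) + 1L,
                               action = "symmetry-drop", variable = v,
                               sepset = NA_character_, p_value = NA_real_))
    mb@sepsets[[v]] <- character()
  }
  methods::new("MarkovBoundary", target = mb@target, members = keep,
               sepsets = mb@sepsets, config = mb@config, trace = tr)
}

#' Serialize a MarkovBoundary to JSON
#' @param mb a [MarkovBoundary-class]
#' @param path file path
#' @export
writeMarkovBoundary <- function(mb, path) {
  jsonlite::write_json(
    list(target = mb@target, members = mb@members, sepsets = mb@sepsets,
         config = list(alpha = mb@config@alpha, max_k = mb@config@max_k,
                       ci_method = mb@config@ci_method),
         trace = mb@trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
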