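## Enumeration of the full equivalence class of Markov boundaries
## (generate-and-verify, TIE*-style).
##
## Generative loop: induce a first boundary M0 on the full data; repeatedly
## mask removal subsets G of the union of variables seen in any accepted
## boundary (increasing cardinality: singletons, then pairs, ...), re-run the
## base inducer on the masked data, and accept the candidate boundary iff it
## is set-distinct from those already accepted AND passes a verification
## criterion evaluated on the ORIGINAL, unmasked data. The loop closes when
## no unprocessed removal set remains or the hypothesis budget is exhausted.

#' Enumerate all equivalent Markov boundaries of a target
#'
#' @inheritParams gllMB
#' @param verifier `"independence"` (joint likelihood-ratio check that the
#'   variables outside the candidate carry no further information about the
#'   target given the candidate) or `"performance-equivalence"`
#'   (cross-validated AUC non-inferiority against the reference boundary).
#' @param budget maximum number of masked re-inductions (hypotheses); if
#'   exhausted before closure the class is flagged `"possibly-incomplete"`.
#' @param max_removal_size largest removal-set cardinality generated
#'   (default 2: all singletons and pairs of the current union).
#' @param verify_alpha significance level of the independence verifier
#'   (deliberately conservative: rejecting a candidate's equivalence
#'   requires evidence at this level).
#' @param margin non-inferiority margin for the performance verifier.
#' @return an [EquivalenceClass-class]
#' @examples
#' net <- buildTruthNetwork(3, 2, seed = 5,
#'   equivalence_spec = list(list(source = "X1", mode = "duplicate")))
#' ct <- sampleCohort(net, 1500, seed = 6)
#' ec <- enumerateMBs(ct, "survival_2y", DiscoveryConfig())
#' mbFrequency(ec)
#' @export
enumerateMBs <- function(data, target, config = DiscoveryConfig(),
                         verifier = c("independence",
                                      "performance-equivalence"),
                         budget = 100L, max_removal_size = 2L,
                         verify_alpha = 0.01, margin = 0.02) {
  verifier <- match.arg(verifier)
  m <- .asAnalysisMatrix(data)
  all_cands <- setdiff(colnames(m), target)
  all_cands <- all_cands[!grepl("^survival_.*y$", all_cands)]

  m0 <- gllMB(m, target, config, candidates = all_cands)
  accepted <- list(m0)
  seen_sets <- list(sort(m0@members))
  verification <- list()
  flags <- character()

  removalKeys <- function(union_vars) {
    u <- sort(union_vars)
    keys <- list()
    for (k in seq_len(min(max_removal_size, length(u))))
      keys <- c(keys, asplit(combn(u, k), 2))
    lapply(keys, as.character)
  }

  tested <- character()
  used <- 0L
  repeat {
    u <- sort(unique(unlist(lapply(accepted, mbMembers))))
    if (!length(u)) break
    pend <- removalKeys(u)
    pend <- pend[!vapply(pend, function(g) paste(g, collapse = "|") %in% tested,
                         TRUE)]
    if (!length(pend)) break
    progressed <- FALSE
    for (G in pend) {
      if (used >= budget) break
      used <- used + 1L
      tested <- c(tested, paste(G, collapse = "|"))
      cand_vars <- setdiff(all_cands, G)
      if (length(cand_vars) < 2) next
      b <- gllMB(m, target, config, candidates = cand_vars)
      key <- sort(b@members)
      is_new <- length(key) > 0 &&
        !any(vapply(seen_sets, identical, TRUE, y = key))
      v <- verifyBoundary(m, target, b@members, m0, verifier = verifier,
                          alpha = verify_alpha, margin = margin,
                          seed = config@seed)
      verification[[length(verification) + 1L]] <- data.frame(
        removal = paste(G, collapse = ","),
        candidate = paste(key, collapse = ","),
        new = is_new, pass = v$pass, statistic = v$statistic,
        criterion = v$criterion, stringsAsFactors = FALSE)
      if (is_new && v$pass) {
        accepted[[length(accepted) + 1L]] <- b
        seen_sets[[length(seen_sets) + 1L]] <- key
        progressed <- TRUE
      }
    }
    if (used >= budget) {
      u_now <- sort(unique(unlist(lapply(accepted, mbMembers))))
      remaining <- removalKeys(u_now)
      remaining <- remaining[!vapply(remaining, function(g)
        paste(g, collapse = "|") %in% tested, TRUE)]
      if (length(remaining)) flags <- c(flags, "possibly-incomplete")
      break
    }
    if (!progressed) break
  }

  ver <- if (length(verification)) do.call(rbind, verification) else
    data.frame(removal = character(), candidate = character(),
               new = logical(), pass = logical(), statistic = numeric(),
               criterion = numeric())
  methods::new("EquivalenceClass", target = target, boundaries = accepted,
               verification = ver, config = config, flags = flags)
}

#' Verify that a candidate variable set is an equivalent Markov boundary
#'
#' Independence verifier: one joint likelihood-ratio test of
#' `target ~ candidate + W` against `target ~ candidate`, where W holds the
#' reference-boundary members outside the candidate plus a capped,
#' deterministic sample of the remaining outside variables; the candidate
#' passes iff the test does not reject at `alpha`. Performance verifier:
#' cross-validated logistic AUC of the candidate must be non-inferior to the
#' reference on shared folds (paired DeLong CI lower bound > -`margin`).
#'
#' @inheritParams enumerateMBs
#' @param candidate candidate variable set
#' @param reference the reference [MarkovBoundary-class] (or character
#'   vector of its members)
#' @param alpha level of the independence check
#' @param n_folds folds for the performance verifier
#' @param seed fold seed
#' @param cap maximum number of outside variables added beyond the
#'   reference members
#' @return list(pass, statistic, criterion, verifier)
#' @export
verifyBoundary <- function(data, target, candidate, reference,
                           verifier = c("independence",
                                        "performance-equivalence"),
                           alpha = 0.01, n_folds = 5, seed = 1L,
                           margin = 0.02, cap = 20L) {
  verifier <- match.arg(verifier)
  m <- .asAnalysisMatrix(data)
  ref_members <- if (is(reference, "MarkovBoundary")) reference@members
                 else as.character(reference)
  candidate <- as.character(candidate)
  if (!length(candidate) && length(ref_members))
    return(list(pass = FALSE, statistic = NA_real_, criterion = alpha,
                verifier = verifier))
  y <- m[, target]

  if (verifier == "independence") {
    outside <- setdiff(colnames(m), c(target, candidate))
    outside <- outside[!grepl("^survival_.*y$", outside)]
    w <- union(intersect(ref_members, outside),
               head(sort(setdiff(outside, ref_members)), cap))
    if (!length(w))
      return(list(pass = TRUE, statistic = 0, criterion = alpha,
                  verifier = verifier))
    X0 <- if (length(candidate)) m[, candidate, drop = FALSE] else NULL
    f0 <- logisticFit(X0, y)
    f1 <- logisticFit(cbind(X0, m[, w, drop = FALSE]), y)
    dof <- f1$df_model - f0$df_model
    stat <- max(f0$deviance - f1$deviance, 0)
    p <- if (dof > 0) pchisq(stat, dof, lower.tail = FALSE) else 1
    return(list(pass = p >= alpha, statistic = stat, criterion = p,
                verifier = verifier))
  }

  ## performance-equivalence: shared stratified folds, pooled out-of-fold
  ## predictions, paired DeLong CI on the AUC difference
  cvScores <- function(vars, folds) {
    sc <- rep(NA_real_, length(y))
    for (f in unique(folds)) {
      tr <- folds != f
      fit <- logisticFit(m[tr, vars, drop = FALSE], y[tr])
      beta <- fit$coef; beta[is.na(beta)] <- 0
      X <- cbind(1, m[!tr, vars, drop = FALSE])
      sc[!tr] <- plogis(as.numeric(X %*% beta))
    }
    sc
  }
  folds <- NULL
  for (try in 0:9) {  # refold on degenerate single-class folds
    fl <- stratifiedSplit(y, n_folds = n_folds, repeats = 1,
                          seed = childSeed(seed, 900L + try))[[1]]
    ok <- all(vapply(unique(fl), function(f)
      length(unique(y[fl == f])) == 2L, TRUE))
    if (ok) { folds <- fl; break }
  }
  if (is.null(folds)) stop("could not build two-class folds")
  sc_c <- cvScores(candidate, folds)
  sc_r <- if (length(ref_members)) cvScores(ref_members, folds) else
    rep(0.5, length(y))
  cmp <- compareAUCs(sc_c, sc_r, y)
  pass <- cmp$ci[1] > -margin
  list(pass = pass, statistic = cmp$difference, criterion = cmp$ci[1],
       verifier = verifier)
}

#' Summarize an equivalence class of Markov boundaries
#'
#' Per-variable frequency across boundaries, intersection membership (the
#' potential direct causes, given causal sufficiency), and the boundary-size
#' range; slots for per-boundary validation AUC are attached as an attribute
#' for the predictive-modeling stage to fill.
#'
#' @param ec an [EquivalenceClass-class]
#' @return data.frame(variable, frequency, in_intersection, interpretation)
#'   with attributes `boundary_sizes` and `boundary_auc`
#' @export
summarizeClass <- function(ec) {
  if (!length(ec@boundaries)) stop("equivalence class has no boundaries")
  freq <- mbFrequency(ec)
  inter <- mbIntersection(ec)
  df <- data.frame(
    variable = names(freq),
    frequency = unname(freq),
    in_intersection = names(freq) %in% inter,
    interpretation = ifelse(names(freq) %in% inter,
                            "potential direct cause (given causal sufficiency)",
                            "equivalence-class member"),
    stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$variable), ]
  rownames(df) <- NULL
  sizes <- vapply(ec@boundaries, function(b) length(b@members), 1L)
  attr(df, "boundary_sizes") <- range(sizes)
  attr(df, "boundary_auc") <- rep(NA_real_, length(ec@boundaries))
  df
}

#' Serialize an EquivalenceClass to JSON
#' @param ec an [EquivalenceClass-class]
#' @param path file path
#' @export
writeEquivalenceClass <- function(ec, path) {
  jsonlite::write_json(
    list(target = ec@target,
         boundaries = lapply(ec@boundaries, function(b)
           list(members = b@members, sepsets = b@sepsets)),
         intersection = mbIntersection(ec), union = mbUnion(ec),
         frequency = as.list(mbFrequency(ec)),
         flags = ec@flags),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
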