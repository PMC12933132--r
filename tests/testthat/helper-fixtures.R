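## Shared fixtures and independent oracles for the test suite.

## Exhaustive pairwise-concordance AUC (Mann-Whitney with ties = 0.5):
## the brute-force oracle against the rank-based implementation.
aucExhaustive <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## Member-set F1 against the ground-truth boundary.
memberF1 <- function(found, truth) {
  if (!length(found) && !length(truth)) return(1)
  tp <- length(intersect(found, truth))
  if (tp == 0) return(0)
  prec <- tp / length(found)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

## X -> M -> outcome mediation chain (M is the only outcome parent).
chainNetwork <- function(seed = 1L, b_xm = 0.8, b_my = 1.0) {
  customTruthNetwork(
    node_params = list(
      X = list(dist = "gaussian", mean = 0, sd = 1),
      M = list(dist = "gaussian-child", coef = c(X = b_xm), sd = 0.6)),
    roles = c(X = "clinical-continuous", M = "clinical-continuous"),
    outcome = list("2" = list(intercept = 0.5,
                              coefficients = c(M = b_my))),
    seed = seed)
}

## C -> X and C -> outcome; X has no direct edge to the outcome.
confounderNetwork <- function(seed = 1L) {
  customTruthNetwork(
    node_params = list(
      C = list(dist = "gaussian", mean = 0, sd = 1),
      X = list(dist = "gaussian-child", coef = c(C = 0.9), sd = 0.5)),
    roles = c(C = "clinical-continuous", X = "clinical-continuous"),
    outcome = list("2" = list(intercept = 0.3,
                              coefficients = c(C = 0.9))),
    seed = seed)
}

## Canonical MB bundle: build a MarkovBoundary object directly (for summary
## and report tests that do not need a discovery run).
mkBoundary <- function(members, sepsets = list(), target = "survival_2y") {
  new("MarkovBoundary", target = target, members = members,
      sepsets = sepsets, config = DiscoveryConfig(),
      trace = data.frame(step = integer(), action = character(),
                         variable = character(), sepset = character(),
                         p_value = numeric()))
}

mkClass <- function(member_sets, target = "survival_2y") {
  new("EquivalenceClass", target = target,
      boundaries = lapply(member_sets, mkBoundary, target = target),
      verification = data.frame(), config = DiscoveryConfig(),
      flags = character())
}
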