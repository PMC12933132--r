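## Synthetic cohorts with known causal ground truth.
##
## The generator emulates the statistical shape the analysis assumes: a
## terminal binary survival outcome per time horizon, a handful of direct
## causes among many noise variables, overdispersed count-like molecular
## variables, Gaussian/ordinal clinical variables, an age-like variable,
## class imbalance growing with the horizon, and engineered
## information-equivalence groups (duplicates, noisy copies, invertible
## monotone transforms of a source variable).

.default_survival_rates <- c(0.85, 0.55, 0.30)
.default_horizon_ids <- c(2, 5, 10)

popMoments <- function(p) {
  if (!is.null(p$pop_mean))
    return(c(mean = p$pop_mean, sd = p$pop_sd))
  switch(p$dist,
    "nbinom" = {
      m <- exp(p$log_mu + p$sigma_z^2 / 2)
      emu2 <- exp(2 * p$log_mu + 2 * p$sigma_z^2)
      v <- m + emu2 / p$dispersion + (emu2 - m^2)
      c(mean = m, sd = sqrt(v))
    },
    "gaussian" = c(mean = p$mean, sd = p$sd),
    "ordinal" = {
      k <- p$n_levels
      pr <- rep(1 / k, k)
      val <- 0:(k - 1)
      m <- sum(val * pr)
      c(mean = m, sd = sqrt(sum(val^2 * pr) - m^2))
    },
    stop("no closed-form moments for dist '", p$dist, "'")
  )
}

.roleCycle <- function(n) {
  ## 7:2:1 molecular / continuous / ordinal mix, age first
  pat <- c("smrna-count", "smrna-count", "smrna-count", "smrna-count",
           "smrna-count", "smrna-count", "smrna-count",
           "clinical-continuous", "clinical-continuous", "clinical-ordinal")
  roles <- rep(pat, length.out = max(n - 1, 0))
  if (n >= 1) roles <- c("age", roles)
  roles[seq_len(n)]
}

.drawNodeParams <- function(role, dispersion) {
  switch(role,
    "smrna-count" = list(dist = "nbinom", log_mu = runif(1, 2, 6),
                         sigma_z = 0.8, dispersion = dispersion),
    "clinical-continuous" = list(dist = "gaussian", mean = runif(1, -2, 10),
                                 sd = runif(1, 0.5, 3)),
    "clinical-ordinal" = list(dist = "ordinal", n_levels = 4L),
    "age" = list(dist = "gaussian", mean = 78, sd = 5.4),
    stop("unknown role '", role, "'")
  )
}

#' Build a ground-truth causal network for synthetic cohorts
#'
#' Constructs an acyclic [TruthNetwork-class] in which `n_direct_causes`
#' variables are parents of a terminal binary survival outcome at each of
#' `horizons` time horizons. All horizons share the declared coefficients
#' (on population-standardized cause values) and one latent risk residual;
#' intercepts differ per horizon so survival prevalence declines with the
#' horizon. Optional equivalence groups add variables engineered to carry
#' the same information about the outcome as their source.
#'
#' @param n_noise_vars number of outcome-independent variables.
#' @param n_direct_causes number of direct causes of the outcome.
#' @param effect_sizes logistic coefficients per cause on the standardized
#'   scale; default alternates +/-0.75.
#' @param equivalence_spec list of `list(source=, mode=, snr=)` with mode one
#'   of `duplicate`, `noisy-copy`, `monotone-transform`; `snr` applies to
#'   noisy copies (signal-to-noise ratio; `Inf` behaves as a duplicate).
#' @param horizons number of time horizons (labelled 2, 5, 10, ... years).
#' @param seed integer master seed.
#' @param intercepts optional per-horizon logistic intercepts; default gives
#'   survival rates ~0.85/0.55/0.30.
#' @param cause_roles optional role tags for the causes.
#' @param dispersion negative-binomial size parameter for count variables.
#' @param block_rho,block_size optional equicorrelation of molecular noise
#'   variables via latent block factors (default none).
#' @param horizon_extras optional list (one numeric vector per horizon) of
#'   effect sizes for extra horizon-specific causes.
#' @return a [TruthNetwork-class]
#' @examples
#' net <- buildTruthNetwork(10, 3, seed = 1)
#' trueMarkovBoundary(net, 1)
#' @export
buildTruthNetwork <- function(n_noise_vars, n_direct_causes,
                              effect_sizes = NULL,
                              equivalence_spec = list(),
                              horizons = 1L, seed = 1L,
                              intercepts = NULL, cause_roles = NULL,
                              dispersion = 5, block_rho = 0, block_size = 4,
                              horizon_extras = NULL) {
  if (n_noise_vars + n_direct_causes < 1)
    stop("network must contain at least one variable")
  if (is.null(effect_sizes))
    effect_sizes <- 0.75 * rep_len(c(-1, 1), n_direct_causes)
  if (length(effect_sizes) != n_direct_causes)
    stop("effect_sizes length must equal n_direct_causes")
  horizons <- as.integer(horizons)
  if (is.null(intercepts)) {
    sr <- rep_len(.default_survival_rates, horizons)
    intercepts <- qlogis(sr)
  }
  hz_ids <- rep_len(.default_horizon_ids, max(horizons, 1L))[seq_len(horizons)]

  cause_ids <- if (n_direct_causes > 0) paste0("X", seq_len(n_direct_causes)) else character()
  noise_ids <- if (n_noise_vars > 0) paste0("N", seq_len(n_noise_vars)) else character()
  if (is.null(cause_roles))
    cause_roles <- rep_len(c("smrna-count", "smrna-count", "smrna-count",
                             "clinical-continuous"), n_direct_causes)
  noise_roles <- .roleCycle(n_noise_vars)

  ids <- c(cause_ids, noise_ids)
  roles <- c(cause_roles, noise_roles)

  set.seed(childSeed(seed, 101L))
  node_params <- setNames(
    lapply(seq_along(ids), function(i) .drawNodeParams(roles[i], dispersion)),
    ids)

  edges <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  eq_groups <- list()
  for (i in seq_along(equivalence_spec)) {
    eg <- equivalence_spec[[i]]
    if (is.null(names(eg)) && length(eg) >= 2)
      eg <- list(source = eg[[1]], mode = eg[[2]],
                 snr = if (length(eg) >= 3) as.numeric(eg[[3]]) else Inf)
    if (!eg$source %in% c(ids, vapply(eq_groups, `[[`, "", "member")))
      stop("equivalence source '", eg$source, "' is not a network variable")
    if (!eg$mode %in% c("duplicate", "noisy-copy", "monotone-transform"))
      stop("unknown equivalence mode '", eg$mode, "'")
    member <- paste0(eg$source, "_eq", i)
    src_role <- if (eg$source %in% ids) roles[match(eg$source, ids)] else
      "clinical-continuous"
    member_role <- if (eg$mode == "duplicate") src_role else "clinical-continuous"
    ids <- c(ids, member)
    roles <- c(roles, member_role)
    node_params[[member]] <- list(dist = "derived", source = eg$source,
                                  mode = eg$mode,
                                  snr = if (is.null(eg$snr)) Inf else eg$snr)
    edges <- rbind(edges, data.frame(from = eg$source, to = member))
    eq_groups[[length(eq_groups) + 1L]] <-
      list(source = eg$source, member = member, mode = eg$mode,
           snr = if (is.null(eg$snr)) Inf else eg$snr)
  }

  ## optional latent block factors over molecular noise variables
  block <- list(size = block_size, rho = block_rho, assignment = list())
  if (block_rho > 0) {
    mol_noise <- noise_ids[noise_roles == "smrna-count"]
    nb <- ceiling(length(mol_noise) / block_size)
    for (b in seq_len(nb)) {
      fid <- paste0("BF", b)
      membs <- mol_noise[((b - 1) * block_size + 1):min(b * block_size,
                                                        length(mol_noise))]
      ids <- c(ids, fid)
      roles <- c(roles, "latent-factor")
      node_params[[fid]] <- list(dist = "latent")
      edges <- rbind(edges, data.frame(from = fid, to = membs))
      block$assignment[[fid]] <- membs
    }
  }

  ## horizon-specific extra causes
  extra_coefs <- vector("list", horizons)
  if (!is.null(horizon_extras)) {
    for (h in seq_len(horizons)) {
      ex <- horizon_extras[[h]]
      if (is.null(ex) || !length(ex)) next
      eids <- paste0("E", hz_ids[h], "_", seq_along(ex))
      for (j in seq_along(eids)) {
        ids <- c(ids, eids[j]); roles <- c(roles, "smrna-count")
        node_params[[eids[j]]] <- .drawNodeParams("smrna-count", dispersion)
      }
      extra_coefs[[h]] <- setNames(as.numeric(ex), eids)
    }
  }

  outcome <- list()
  for (h in seq_len(horizons)) {
    oid <- paste0("survival_", hz_ids[h], "y")
    ids <- c(ids, oid); roles <- c(roles, "outcome")
    coefs <- c(setNames(effect_sizes, cause_ids), extra_coefs[[h]])
    if (length(coefs))
      edges <- rbind(edges, data.frame(from = names(coefs), to = oid))
    outcome[[as.character(hz_ids[h])]] <-
      list(id = oid, intercept = intercepts[h],
           coefficients = if (length(coefs)) coefs else setNames(numeric(), character()))
  }

  methods::new("TruthNetwork",
    nodes = data.frame(id = ids, role = roles, stringsAsFactors = FALSE),
    edges = edges, node_params = node_params, outcome = outcome,
    equivalence_groups = eq_groups, block = block, seed = as.integer(seed))
}

#' Build a fully custom ground-truth network
#'
#' Low-level constructor for arbitrary DAG structures (mediator chains,
#' confounders) beyond the cause/noise layout of [buildTruthNetwork()].
#' Variable nodes may use dist `nbinom`, `gaussian`, `ordinal` (as in
#' [buildTruthNetwork()]) or `gaussian-child`
#' (`list(dist = "gaussian-child", coef = c(parent = b), sd = s,
#' intercept = 0)`, a linear Gaussian function of population-standardized
#' parents). Edges implied by `gaussian-child` coefficients and outcome
#' coefficients are added automatically.
#'
#' @param node_params named list of per-variable parameter lists
#' @param roles named role vector per variable
#' @param outcome list per horizon: `list(intercept =, coefficients = c(...))`
#'   (horizon names e.g. `"2"`)
#' @param equivalence_groups optional list as in [buildTruthNetwork()]
#' @param seed integer
#' @return a [TruthNetwork-class]
#' @export
customTruthNetwork <- function(node_params, roles, outcome,
                               equivalence_groups = list(), seed = 1L) {
  ids <- names(node_params)
  edges <- data.frame(from = character(), to = character())
  for (v in ids) {
    p <- node_params[[v]]
    if (identical(p$dist, "gaussian-child")) {
      edges <- rbind(edges, data.frame(from = names(p$coef), to = v))
      if (is.null(p$pop_mean)) {
        node_params[[v]]$pop_mean <-
          if (is.null(p$intercept)) 0 else p$intercept
        node_params[[v]]$pop_sd <- sqrt(sum(p$coef^2) + p$sd^2)
      }
    }
  }
  for (eg in equivalence_groups)
    edges <- rbind(edges, data.frame(from = eg$source, to = eg$member))
  out <- list()
  all_roles <- roles[ids]
  for (h in names(outcome)) {
    oid <- paste0("survival_", h, "y")
    ids <- c(ids, oid)
    all_roles <- c(all_roles, setNames("outcome", oid))
    co <- outcome[[h]]$coefficients
    if (length(co))
      edges <- rbind(edges, data.frame(from = names(co), to = oid))
    out[[h]] <- list(id = oid, intercept = outcome[[h]]$intercept,
                     coefficients = co)
  }
  methods::new("TruthNetwork",
    nodes = data.frame(id = ids, role = unname(all_roles),
                       stringsAsFactors = FALSE),
    edges = edges, node_params = node_params, outcome = out,
    equivalence_groups = equivalence_groups,
    block = list(size = 0, rho = 0, assignment = list()),
    seed = as.integer(seed))
}

#' Observed (cohort) variable ids of a network
#' @param network a [TruthNetwork-class]
#' @export
networkVariables <- function(network) {
  network@nodes$id[!network@nodes$role %in% c("outcome", "latent-factor")]
}

#' True Markov boundary of the survival outcome
#'
#' The outcome is terminal, so its Markov boundary is its parent set in the
#' ground-truth graph (before equivalence injection, this is also the unique
#' minimal sufficient set; see [minimalSufficientSets()]).
#'
#' @param network a [TruthNetwork-class]
#' @param horizon horizon index (1-based) or horizon id as character.
#' @return sorted character vector of variable ids
#' @export
trueMarkovBoundary <- function(network, horizon = 1) {
  oc <- .horizonOutcome(network, horizon)
  sort(names(oc$coefficients))
}

.horizonOutcome <- function(network, horizon) {
  if (is.character(horizon) && horizon %in% names(network@outcome))
    return(network@outcome[[horizon]])
  h <- as.integer(horizon)
  if (is.na(h) || h < 1 || h > length(network@outcome))
    stop("invalid horizon")
  network@outcome[[h]]
}

#' Sample a cohort from a ground-truth network
#'
#' Ancestral sampling in topological order: latent block factors, base
#' variables (counts via a negative-binomial with log link on the latent
#' Gaussian score), equivalence copies, then one shared uniform per sample
#' thresholded against each horizon's logistic survival probability --
#' so horizon labels are correlated (nested) and each horizon's marginal
#' model is exactly logistic in the standardized causes.
#'
#' @param network a [TruthNetwork-class]
#' @param n_samples number of samples (>= 1)
#' @param seed integer seed; identical seeds give identical tables
#' @param split_fractions named fractions for split tags (default mirrors a
#'   505/202/564 discovery / internal / external partition).
#' @return a [CohortTable-class]
#' @export
sampleCohort <- function(network, n_samples, seed = 1L,
                         split_fractions = c("discovery-subset" = 505,
                                             "internal-validation" = 202,
                                             "external-validation" = 564) / 1271) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  set.seed(childSeed(seed, 1L))
  n <- as.integer(n_samples)
  vars <- networkVariables(network)
  vals <- matrix(NA_real_, n, length(vars), dimnames = list(
    paste0("S", seq_len(n)), vars))

  ## latent block factors
  factors <- list()
  rho <- network@block$rho
  if (rho > 0)
    for (fid in names(network@block$assignment))
      factors[[fid]] <- rnorm(n)
  in_block <- if (rho > 0) unlist(network@block$assignment) else character()

  ## ancestral sampling in topological order (mediator chains, confounders
  ## and equivalence copies are all children of earlier variables)
  g <- igraph::graph_from_data_frame(network@edges, directed = TRUE,
                                     vertices = network@nodes$id)
  topo <- names(igraph::topo_sort(g, mode = "out"))
  eq_by_member <- setNames(network@equivalence_groups,
                           vapply(network@equivalence_groups, `[[`, "",
                                  "member"))
  for (v in intersect(topo, vars)) {
    p <- network@node_params[[v]]
    if (identical(p$dist, "derived")) {
      eg <- eq_by_member[[v]]
      src <- vals[, eg$source]
      vals[, v] <- switch(eg$mode,
        "duplicate" = src,
        "noisy-copy" = {
          s <- sd(src); if (!is.finite(s) || s == 0) s <- 1
          nsd <- if (is.finite(eg$snr)) s / sqrt(eg$snr) else 0
          src + rnorm(n, 0, nsd)
        },
        "monotone-transform" = {
          s <- sd(src); if (!is.finite(s) || s == 0) s <- 1
          exp((src - mean(src)) / (2 * s))
        })
      next
    }
    if (identical(p$dist, "gaussian-child")) {
      ## linear Gaussian child of earlier variables (standardized parents)
      eta <- rep(if (is.null(p$intercept)) 0 else p$intercept, n)
      for (pa in names(p$coef)) {
        mo <- popMoments(network@node_params[[pa]])
        eta <- eta + p$coef[[pa]] * (vals[, pa] - mo["mean"]) / mo["sd"]
      }
      vals[, v] <- eta + rnorm(n, 0, p$sd)
      next
    }
    z <- rnorm(n)
    if (v %in% in_block) {
      fid <- names(network@block$assignment)[vapply(
        network@block$assignment, function(m) v %in% m, TRUE)][1]
      z <- sqrt(rho) * factors[[fid]] + sqrt(1 - rho) * z
    }
    vals[, v] <- switch(p$dist,
      "nbinom" = rnbinom(n, mu = exp(p$log_mu + p$sigma_z * z),
                         size = p$dispersion),
      "gaussian" = p$mean + p$sd * z,
      "ordinal" = findInterval(z, qnorm((1:(p$n_levels - 1)) / p$n_levels)),
      stop("cannot sample dist '", p$dist, "'"))
  }

  ## outcomes: shared latent uniform thresholded per horizon
  u <- runif(n)
  labels <- list()
  for (hname in names(network@outcome)) {
    oc <- network@outcome[[hname]]
    eta <- rep(oc$intercept, n)
    for (v in names(oc$coefficients)) {
      mo <- popMoments(network@node_params[[v]])
      eta <- eta + oc$coefficients[[v]] * (vals[, v] - mo["mean"]) / mo["sd"]
    }
    labels[[oc$id]] <- as.integer(u <= plogis(eta))
  }

  splits <- NULL
  if (!is.null(split_fractions)) {
    counts <- floor(n * split_fractions)
    rem <- n - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
    splits <- sample(rep(names(split_fractions), counts))
  }

  roles <- setNames(network@nodes$role[match(vars, network@nodes$id)], vars)
  CohortTable(vals, roles, as.data.frame(labels), splits,
              provenance = list(seed = as.integer(seed),
                                network_seed = network@seed))
}

## ---------------------------------------------------------------------------
## Graphical oracles
## ---------------------------------------------------------------------------

#' Test d-separation in the ground-truth graph
#'
#' Classical moralization criterion: x and y are d-separated by Z iff they
#' are disconnected in the moralized ancestral graph of \{x, y\} U Z with Z
#' removed.
#'
#' @param network a [TruthNetwork-class]
#' @param x,y node ids
#' @param Z conditioning node ids (character, possibly empty)
#' @return logical
#' @export
dSeparated <- function(network, x, y, Z = character()) {
  stopifnot(x != y, !x %in% Z, !y %in% Z)
  g <- igraph::graph_from_data_frame(network@edges, directed = TRUE,
                                     vertices = network@nodes$id)
  anc <- unique(c(x, y, Z, unlist(lapply(c(x, y, Z), function(v)
    names(igraph::subcomponent(g, v, mode = "in"))))))
  sub <- igraph::induced_subgraph(g, anc)
  ## moralize: connect co-parents, then drop directions
  el <- igraph::as_edgelist(sub)
  extra <- NULL
  for (v in igraph::V(sub)$name) {
    pa <- names(igraph::neighbors(sub, v, mode = "in"))
    if (length(pa) > 1) {
      prs <- t(combn(pa, 2))
      extra <- rbind(extra, prs)
    }
  }
  und <- igraph::graph_from_edgelist(rbind(el, extra), directed = FALSE)
  und <- igraph::add_vertices(
    und, length(setdiff(anc, igraph::V(und)$name)),
    name = setdiff(anc, igraph::V(und)$name))
  und <- igraph::delete_vertices(und, intersect(Z, igraph::V(und)$name))
  if (!x %in% igraph::V(und)$name || !y %in% igraph::V(und)$name)
    return(TRUE)
  comp <- igraph::components(und)$membership
  comp[[x]] != comp[[y]]
}

## Information representative: exact-equivalence copies (duplicate or
## invertible monotone transform) collapse onto their source; noisy copies
## keep their own identity.
.infoRep <- function(network) {
  rep_map <- setNames(networkVariables(network), networkVariables(network))
  repeat {
    changed <- FALSE
    for (eg in network@equivalence_groups) {
      exact <- eg$mode %in% c("duplicate", "monotone-transform") ||
        (eg$mode == "noisy-copy" && is.infinite(eg$snr))
      if (exact && rep_map[[eg$member]] != rep_map[[eg$source]]) {
        rep_map[[eg$member]] <- rep_map[[eg$source]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rep_map
}

#' Brute-force enumeration of minimal sufficient variable sets
#'
#' Enumerates, over all subsets of the observed variables, the minimal sets S
#' such that every variable outside S is independent of the outcome given S.
#' Independence is decided in the ground-truth distribution: exact
#' information-equivalent copies are collapsed onto their source variable
#' (a deterministic copy of a conditioned variable is trivially independent
#' of everything given it), and remaining queries use graphical
#' d-separation. This is the oracle against which the data-driven boundary
#' enumeration is checked; intended for networks with <= ~12 observed
#' variables.
#'
#' @param network a [TruthNetwork-class]
#' @param horizon horizon index or id
#' @param candidates variable ids to search over (default all observed)
#' @return list of sorted character vectors, each one minimal sufficient set
#' @export
minimalSufficientSets <- function(network, horizon = 1,
                                  candidates = networkVariables(network)) {
  oc <- .horizonOutcome(network, horizon)
  rep_map <- .infoRep(network)
  all_vars <- networkVariables(network)

  indep <- function(v, S) {
    Sr <- unique(unname(rep_map[S]))
    vr <- unname(rep_map[[v]])
    if (vr %in% Sr) return(TRUE)
    dSeparated(network, vr, oc$id, setdiff(Sr, oc$id))
  }
  sufficient <- function(S) {
    outs <- setdiff(all_vars, S)
    all(vapply(outs, indep, TRUE, S = S))
  }

  suff <- list()
  nv <- length(candidates)
  for (k in 0:nv) {
    subs <- if (k == 0) list(character()) else
      asplit(combn(candidates, k), 2)
    for (S in subs) {
      S <- as.character(S)
      ## skip supersets of an already-found sufficient set (not minimal)
      if (any(vapply(suff, function(m) all(m %in% S), TRUE))) next
      if (sufficient(S)) suff[[length(suff) + 1L]] <- sort(S)
    }
  }
  suff
}

## ---------------------------------------------------------------------------
## Serialization
## ---------------------------------------------------------------------------

#' Write / read a TruthNetwork as JSON
#' @param network a [TruthNetwork-class]
#' @param path file path
#' @export
writeTruthNetwork <- function(network, path) {
  ## named numeric vectors serialize as bare arrays; coerce the outcome
  ## coefficient maps to lists so names survive the round trip
  outcome <- lapply(network@outcome, function(oc) {
    oc$coefficients <- as.list(oc$coefficients)
    oc
  })
  obj <- list(nodes = network@nodes, edges = network@edges,
              node_params = network@node_params, outcome = outcome,
              equivalence_groups = network@equivalence_groups,
              block = network@block, seed = network@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeTruthNetwork
#' @export
readTruthNetwork <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  fixnum <- function(p) {
    p <- lapply(p, function(x) if (is.list(x)) fixnum(x) else x)
    if (identical(p$dist, "derived") &&
        (is.null(p$snr) || is.character(p$snr)))
      p$snr <- if (is.null(p$snr)) Inf else as.numeric(p$snr)
    p
  }
  outcome <- lapply(obj$outcome, function(oc) {
    co <- unlist(oc$coefficients)
    list(id = oc$id, intercept = as.numeric(oc$intercept),
         coefficients = if (is.null(co)) setNames(numeric(), character()) else co)
  })
  eqg_raw <- obj$equivalence_groups
  if (is.data.frame(eqg_raw))
    eqg_raw <- lapply(seq_len(nrow(eqg_raw)),
                      function(i) as.list(eqg_raw[i, ]))
  eqg <- lapply(eqg_raw, function(eg) {
    eg$snr <- if (is.null(eg$snr) || is.na(suppressWarnings(
      as.numeric(eg$snr)))) Inf else as.numeric(eg$snr)
    eg
  })
  blk <- obj$block
  if (is.null(blk$assignment) || !length(blk$assignment)) blk$assignment <- list()
  edges <- as.data.frame(obj$edges)
  if (!nrow(edges))
    edges <- data.frame(from = character(), to = character())
  methods::new("TruthNetwork",
    nodes = as.data.frame(obj$nodes), edges = edges,
    node_params = fixnum(obj$node_params), outcome = outcome,
    equivalence_groups = eqg, block = blk, seed = as.integer(obj$seed))
}
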