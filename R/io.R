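## Readers/writers, TMM normalization, run configuration, and the
## end-to-end protocol driver.

#' Write a cohort as TSV plus JSON sidecar
#'
#' The TSV has samples in rows (first column `sample_id`, then one column
#' per variable, then the survival label columns); the sidecar carries the
#' variable roles, horizons, per-sample split tags and provenance.
#'
#' @param ct a [CohortTable-class]
#' @param path TSV path
#' @param sidecar JSON sidecar path (default: `path` + `.json`)
#' @export
writeCohort <- function(ct, path, sidecar = paste0(path, ".json")) {
  m <- cohortMatrix(ct)
  cd <- SummarizedExperiment::colData(ct)
  lab_cols <- grep("^survival_.*y$", colnames(cd), value = TRUE)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  for (lc in lab_cols) df[[lc]] <- as.integer(cd[[lc]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    roles = as.list(variableRoles(ct)),
    horizons = cohortHorizons(ct),
    label_columns = lab_cols,
    splits = sampleSplits(ct),
    provenance = S4Vectors::metadata(ct)$provenance)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a cohort from TSV plus JSON sidecar
#'
#' Role-consistent parsing: count-role variables must be nonnegative
#' integers; any non-numeric cell raises an error locating the row and
#' column; a sidecar horizon with no label column in the file is a schema
#' error naming the horizon.
#'
#' @param path TSV path (samples in rows, header row of variable ids)
#' @param sidecar JSON sidecar path
#' @return a [CohortTable-class]
#' @export
readCohort <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("schema error: no sample_id column")
  lab_expect <- paste0("survival_", meta$horizons, "y")
  missing_lab <- setdiff(lab_expect, colnames(df))
  if (length(missing_lab))
    stop("schema error: label column missing for horizon(s): ",
         paste(sub("^survival_(.*)y$", "\\1", missing_lab), collapse = ", "))
  var_ids <- names(meta$roles)
  missing_var <- setdiff(var_ids, colnames(df))
  if (length(missing_var))
    stop("schema error: variable(s) missing from file: ",
         paste(head(missing_var, 5), collapse = ", "))
  for (v in c(var_ids, lab_expect)) {
    col <- df[[v]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      stop("parse error: non-numeric value in column '", v, "', row ",
           if (length(bad)) bad[1] else "?", " ('",
           if (length(bad)) col[bad[1]] else "", "')")
    }
  }
  vals <- as.matrix(df[, var_ids, drop = FALSE])
  rownames(vals) <- df$sample_id
  roles <- unlist(meta$roles)
  cnt <- names(roles)[roles == "smrna-count"]
  if (length(cnt)) vals[, cnt] <- round(vals[, cnt])
  labels <- df[, lab_expect, drop = FALSE]
  splits <- meta$splits
  if (is.null(splits) || all(is.na(splits))) splits <- NULL
  CohortTable(vals, roles, labels, splits,
              provenance = if (is.null(meta$provenance)) list(source = "real")
                           else meta$provenance)
}

## ---------------------------------------------------------------------------
## TMM normalization
## ---------------------------------------------------------------------------

#' Trimmed mean of M-values (TMM) normalization
#'
#' Robinson-Oshlack scale factors for a nonnegative count matrix (features
#' in rows, samples in columns). The reference is the sample whose
#' upper-quartile/library-size ratio is closest to the mean such ratio.
#' For each sample, the factor is the weighted mean of gene-wise M-values
#' (log2 relative abundance vs the reference) after doubly trimming the
#' most extreme 30% of M-values and 5% of A-values, with weights equal to
#' inverse approximate asymptotic (binomial) variances; genes with a zero
#' count in either member of the pair drop out of that pair's computation.
#' Factors are re-centered to geometric mean 1.
#'
#' @param counts nonnegative integer matrix, features x samples (>= 2
#'   samples); an all-zero sample is an error naming the sample
#' @param trim_m,trim_a two-sided trim fractions for M and A values
#' @return a [NormalizationResult-class]
#' @export
tmmNormalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM requires at least 2 samples")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))

  uq <- apply(counts, 2, quantile, probs = 0.75, names = FALSE) / lib
  ref <- which.min(abs(uq - mean(uq)))

  onePair <- function(obs_i) {
    x <- counts[, obs_i]; r <- counts[, ref]
    nx <- lib[obs_i]; nr <- lib[ref]
    M <- log2((x / nx) / (r / nr))
    A <- 0.5 * log2((x / nx) * (r / nr))
    w <- (nx - x) / (nx * x) + (nr - r) / (nr * r)
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (!length(M) || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[keep] / w[keep], na.rm = TRUE) /
         sum(1 / w[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), onePair, 1.0)
  f <- recenterFactors(f)
  names(f) <- colnames(counts)
  norm <- sweep(counts, 2, lib * f, "/")
  methods::new("NormalizationResult", factors = f,
               reference = colnames(counts)[ref],
               trim_m = trim_m, trim_a = trim_a, normalized = norm)
}

## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

.defaultRunSettings <- function() {
  list(
    input = list(cohort = NULL, sidecar = NULL),
    horizons = NULL,                 # default: all horizons in the cohort
    discovery = list(alpha = 0.05, max_k = 3, ci_method = "logistic-lrt"),
    models = "default",
    ncv = list(outer = 10, inner = 10, repeats = 10),
    n_permutations = 50,
    percentiles = c(5, 95),
    normalization = "pso-passthrough",
    tie = list(budget = 100, max_removal_size = 2, verify_alpha = 0.01),
    output_dir = "survmb-run",
    seed = 1
  )
}

#' Build / read / write a RunConfig
#'
#' A [RunConfig-class] fully determines one protocol run (inputs, horizons,
#' discovery settings, model menu, NCV settings, permutation count,
#' intervention percentiles, normalization mode `pso-passthrough` or `tmm`,
#' output directory, master seed). Every stochastic stage derives its seed
#' from the master seed. Configs round-trip through YAML/JSON unchanged.
#'
#' @param ... settings overriding the defaults (see
#'   `survMB:::.defaultRunSettings()`)
#' @export
RunConfig <- function(...) {
  s <- modifyList(.defaultRunSettings(), list(...))
  if (!s$normalization %in% c("pso-passthrough", "tmm"))
    stop("normalization must be 'pso-passthrough' or 'tmm'")
  methods::new("RunConfig", settings = s)
}

#' @rdname RunConfig
#' @param path YAML (`.yml`/`.yaml`) or JSON config path
#' @export
readRunConfig <- function(path) {
  s <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(RunConfig, s)
}

#' @rdname RunConfig
#' @param config a [RunConfig-class]
#' @export
writeRunConfig <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config@settings, path)
  else jsonlite::write_json(config@settings, path, auto_unbox = TRUE,
                            digits = NA, null = "null")
  invisible(path)
}

## ---------------------------------------------------------------------------
## End-to-end protocol
## ---------------------------------------------------------------------------

#' Run the full discovery / validation / causal protocol
#'
#' Per horizon: nested cross-validation on the expanded discovery samples,
#' final fit and external validation on the held-out split, label
#' permutation audit, Markov-boundary induction and equivalence-class
#' enumeration, standardized effect estimation, in-silico percentile
#' interventions (molecular-only and all-causes scopes), and the sepset
#' report. Artifacts are written under the configured output directory with
#' an md5 manifest; the run is reproducible from config + seed.
#'
#' @param config a [RunConfig-class]
#' @param cohort optional in-memory [CohortTable-class] (otherwise read from
#'   the configured paths)
#' @param smrna_only restrict candidate variables to molecular (count-role)
#'   variables, mirroring a molecular-biomarker-only analysis
#' @return (invisibly) a list of per-horizon results plus the manifest
#' @export
runProtocol <- function(config, cohort = NULL, smrna_only = FALSE) {
  s <- config@settings
  seed <- as.integer(s$seed)
  t0 <- Sys.time()
  if (is.null(cohort)) {
    if (is.null(s$input$cohort)) stop("no cohort provided or configured")
    cohort <- readCohort(s$input$cohort,
                         if (is.null(s$input$sidecar))
                           paste0(s$input$cohort, ".json")
                         else s$input$sidecar)
  }
  dir.create(s$output_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(s$output_dir, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logfile,
                               append = TRUE)
  cat("", file = logfile)  # truncate
  logline("master seed: ", seed)

  horizons <- if (is.null(s$horizons)) cohortHorizons(cohort)
              else as.character(s$horizons)
  roles <- variableRoles(cohort)
  keep_vars <- if (smrna_only) names(roles)[roles == "smrna-count"]
               else names(roles)

  splits <- sampleSplits(cohort)
  has_splits <- !all(is.na(splits))
  disc <- if (has_splits) cohortSubset(cohort, "expanded-discovery") else cohort
  ext <- if (has_splits && "external-validation" %in% splits)
    cohortSubset(cohort, "external-validation") else NULL

  buildX <- function(ct) {
    X <- cohortMatrix(ct)[, keep_vars, drop = FALSE]
    if (identical(s$normalization, "tmm")) {
      cnt <- intersect(keep_vars, names(roles)[roles == "smrna-count"])
      if (length(cnt) >= 1) {
        nr <- tmmNormalize(t(X[, cnt, drop = FALSE]))
        X[, cnt] <- t(nr@normalized) * mean(colSums(t(X[, cnt, drop = FALSE])))
      }
    }
    X
  }
  Xd <- buildX(disc)
  Xe <- if (!is.null(ext)) buildX(ext) else NULL

  dcfg <- DiscoveryConfig(alpha = s$discovery$alpha,
                          max_k = s$discovery$max_k,
                          ci_method = s$discovery$ci_method, seed = seed)
  configs <- if (identical(s$models, "default")) defaultModelConfigs(seed)
             else s$models

  results <- list()
  for (h in horizons) {
    logline("horizon ", h, ": start ",
            format(Sys.time() - t0, digits = 3))
    yd <- outcomeLabels(disc, h)
    res <- list(horizon = h)

    ## predictive arm
    res$ncv <- nestedCV(Xd, yd, configs, outer = s$ncv$outer,
                        inner = s$ncv$inner, repeats = s$ncv$repeats,
                        seed = childSeed(seed, 11L))
    best <- as.integer(names(sort(table(unlist(res$ncv@winners)),
                                  decreasing = TRUE))[1])
    if (!is.null(Xe)) {
      ye <- outcomeLabels(ext, h)
      res$external <- fitValidate(Xd, Xe, configs[[best]],
                                  train_labels = yd, holdout_labels = ye)
    }
    cvPipeline <- function(data, labels, pseed) {
      folds <- stratifiedSplit(labels, 5, 1, pseed)[[1]]
      sc <- rep(NA_real_, length(labels))
      for (f in unique(folds)) {
        tr <- folds != f
        fit <- fitModel(data[tr, , drop = FALSE], labels[tr],
                        configs[[best]])
        sc[!tr] <- predictModel(fit, data[!tr, , drop = FALSE])
      }
      aucScore(sc, labels)
    }
    res$permutation <- permutationAudit(cvPipeline, Xd, yd,
                                        n_permutations = s$n_permutations,
                                        seed = childSeed(seed, 13L))

    ## causal arm
    target <- paste0("survival_", h, "y")
    A <- cbind(Xd, setNames(data.frame(yd), target))
    A <- as.matrix(A)
    res$ec <- enumerateMBs(A, target, dcfg,
                           budget = s$tie$budget,
                           max_removal_size = s$tie$max_removal_size,
                           verify_alpha = s$tie$verify_alpha)
    res$class_summary <- summarizeClass(res$ec)
    res$effects <- estimateEffects(A, res$ec, target)
    fits <- attr(res$effects, "fits")
    model <- fits[[1]]
    ok_vars <- res$effects$variable[!res$effects$separation]
    iv_mol <- intersect(interventionVariables(res$ec, roles, "smrna-only"),
                        intersect(model@vars, ok_vars))
    iv_all <- intersect(interventionVariables(res$ec, roles, "all-causes"),
                        intersect(model@vars, ok_vars))
    if (length(iv_mol))
      res$intervention_smrna <- simulateIntervention(
        model, A, iv_mol, s$percentiles[1], s$percentiles[2],
        scope = "smrna-only")
    if (length(iv_all))
      res$intervention_all <- simulateIntervention(
        model, A, iv_all, s$percentiles[1], s$percentiles[2],
        scope = "all-causes")
    res$sepsets <- sepsetReport(res$ec@boundaries[[1]])

    ## artifacts
    hz_dir <- file.path(s$output_dir, paste0("horizon_", h))
    dir.create(hz_dir, showWarnings = FALSE)
    jsonlite::write_json(
      list(mean_auc = res$ncv@mean_auc, sd_auc = res$ncv@sd_auc,
           outer_auc = res$ncv@outer_auc,
           external_auc = if (!is.null(res$external)) res$external@auc,
           external_ci = if (!is.null(res$external)) res$external@ci,
           permutation_p = res$permutation@p_value,
           permuted_mean = mean(res$permutation@permuted)),
      file.path(hz_dir, "performance.json"), auto_unbox = TRUE, digits = NA)
    writeEquivalenceClass(res$ec, file.path(hz_dir, "equivalence_class.json"))
    utils::write.table(res$class_summary,
                       file.path(hz_dir, "class_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$effects, file.path(hz_dir, "effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$sepsets, file.path(hz_dir, "sepsets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    iv <- list()
    if (!is.null(res$intervention_smrna))
      iv$smrna_only <- list(p_pre = res$intervention_smrna@p_pre,
                            p_post = res$intervention_smrna@p_post,
                            survival_fold = res$intervention_smrna@survival_fold,
                            death_fold = res$intervention_smrna@death_fold)
    if (!is.null(res$intervention_all))
      iv$all_causes <- list(p_pre = res$intervention_all@p_pre,
                            p_post = res$intervention_all@p_post,
                            survival_fold = res$intervention_all@survival_fold,
                            death_fold = res$intervention_all@death_fold)
    jsonlite::write_json(iv, file.path(hz_dir, "interventions.json"),
                         auto_unbox = TRUE, digits = NA)
    results[[h]] <- res
    logline("horizon ", h, ": done ", format(Sys.time() - t0, digits = 3))
  }

  files <- setdiff(list.files(s$output_dir, recursive = TRUE,
                              full.names = TRUE),
                   file.path(s$output_dir, c("manifest.json", "run.log")))
  manifest <- as.list(tools::md5sum(sort(files)))
  names(manifest) <- sub(paste0("^", s$output_dir, "/?"), "",
                         names(manifest))
  jsonlite::write_json(manifest, file.path(s$output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  logline("run complete: ", format(Sys.time() - t0, digits = 3))
  invisible(list(results = results, manifest = manifest))
}
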