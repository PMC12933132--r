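## Generics and accessors for the core containers.

#' @rdname MarkovBoundary-class
#' @param x a MarkovBoundary or EquivalenceClass object
#' @export
setGeneric("mbMembers", function(x) standardGeneric("mbMembers"))

#' @rdname MarkovBoundary-class
#' @export
setGeneric("mbSepsets", function(x) standardGeneric("mbSepsets"))

#' @rdname EquivalenceClass-class
#' @export
setGeneric("mbBoundaries", function(x) standardGeneric("mbBoundaries"))

#' @rdname EquivalenceClass-class
#' @export
setGeneric("mbIntersection", function(x) standardGeneric("mbIntersection"))

#' @rdname EquivalenceClass-class
#' @export
setGeneric("mbUnion", function(x) standardGeneric("mbUnion"))

#' @rdname EquivalenceClass-class
#' @export
setGeneric("mbFrequency", function(x) standardGeneric("mbFrequency"))

#' @export
#' @rdname MarkovBoundary-class
setMethod("mbMembers", "MarkovBoundary", function(x) x@members)

#' @export
#' @rdname MarkovBoundary-class
setMethod("mbSepsets", "MarkovBoundary", function(x) x@sepsets)

#' @export
#' @rdname EquivalenceClass-class
setMethod("mbBoundaries", "EquivalenceClass", function(x) x@boundaries)

#' @export
#' @rdname EquivalenceClass-class
setMethod("mbIntersection", "EquivalenceClass", function(x) {
  sets <- lapply(x@boundaries, mbMembers)
  if (!length(sets)) return(character())
  sort(Reduce(intersect, sets))
})

#' @export
#' @rdname EquivalenceClass-class
setMethod("mbUnion", "EquivalenceClass", function(x) {
  sort(unique(unlist(lapply(x@boundaries, mbMembers))))
})

#' @export
#' @rdname EquivalenceClass-class
setMethod("mbFrequency", "EquivalenceClass", function(x) {
  u <- mbUnion(x)
  if (!length(u)) return(setNames(numeric(), character()))
  b <- length(x@boundaries)
  freq <- vapply(u, function(v) {
    mean(vapply(x@boundaries, function(mb) v %in% mbMembers(mb), TRUE))
  }, 1.0)
  freq
})

## -- CohortTable accessors ---------------------------------------------------

#' Cohort accessors
#'
#' `cohortMatrix` returns the samples-by-variables numeric matrix;
#' `variableRoles` the named role vector; `outcomeLabels` the 0/1 survival
#' labels for one horizon; `sampleSplits` the split tag per sample;
#' `cohortHorizons` the available horizons; `cohortSubset` restricts to one
#' split tag (the pseudo-tag `"expanded-discovery"` selects the union of
#' `discovery-subset` and `internal-validation`).
#'
#' @param ct a [CohortTable-class]
#' @param horizon horizon identifier (e.g. `2`, matching label column
#'   `survival_2y`)
#' @param split split tag
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortMatrix <- function(ct) {
  t(SummarizedExperiment::assay(ct, "values"))
}

#' @rdname cohort-accessors
#' @export
variableRoles <- function(ct) {
  setNames(as.character(SummarizedExperiment::rowData(ct)$role), rownames(ct))
}

#' @rdname cohort-accessors
#' @export
outcomeLabels <- function(ct, horizon) {
  col <- paste0("survival_", horizon, "y")
  cd <- SummarizedExperiment::colData(ct)
  if (!col %in% colnames(cd))
    stop("no label column for horizon '", horizon, "'")
  as.integer(cd[[col]])
}

#' @rdname cohort-accessors
#' @export
sampleSplits <- function(ct) {
  cd <- SummarizedExperiment::colData(ct)
  if (!"split" %in% colnames(cd)) return(rep(NA_character_, ncol(ct)))
  as.character(cd$split)
}

#' @rdname cohort-accessors
#' @export
cohortHorizons <- function(ct) {
  cd <- SummarizedExperiment::colData(ct)
  cols <- grep("^survival_(.*)y$", colnames(cd), value = TRUE)
  sub("^survival_(.*)y$", "\\1", cols)
}

#' @rdname cohort-accessors
#' @export
cohortSubset <- function(ct, split) {
  tags <- sampleSplits(ct)
  keep <- if (identical(split, "expanded-discovery")) {
    tags %in% c("discovery-subset", "internal-validation")
  } else tags == split
  if (!any(keep)) stop("no samples with split '", split, "'")
  ct[, keep]
}

## -- show methods ------------------------------------------------------------

setMethod("show", "TruthNetwork", function(object) {
  nv <- sum(object@nodes$role != "outcome")
  nh <- sum(object@nodes$role == "outcome")
  cat("TruthNetwork:", nv, "variables,", nrow(object@edges), "edges,",
      nh, "horizon(s),", length(object@equivalence_groups),
      "equivalence member(s)\n")
  for (h in names(object@outcome)) {
    co <- object@outcome[[h]]$coefficients
    cat("  horizon ", h, ": intercept ", signif(object@outcome[[h]]$intercept, 3),
        ", causes {", paste(names(co), collapse = ", "), "}\n", sep = "")
  }
})

setMethod("show", "MarkovBoundary", function(object) {
  cat("MarkovBoundary for '", object@target, "' (alpha=", object@config@alpha,
      ", max_k=", object@config@max_k, ", ", object@config@ci_method, ")\n",
      sep = "")
  cat("  members (", length(object@members), "): ",
      paste(object@members, collapse = ", "), "\n", sep = "")
  cat("  sepsets recorded for", length(object@sepsets), "excluded variables\n")
})

setMethod("show", "EquivalenceClass", function(object) {
  cat("EquivalenceClass for '", object@target, "': ",
      length(object@boundaries), " boundary(ies)\n", sep = "")
  sizes <- vapply(object@boundaries, function(b) length(b@members), 1L)
  if (length(sizes))
    cat("  sizes ", min(sizes), "-", max(sizes),
        "; intersection {", paste(mbIntersection(object), collapse = ", "),
        "}\n", sep = "")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "NCVResult", function(object) {
  cat(sprintf("NCVResult: mean outer AUC %.3f (SD %.3f) over %d folds x %d repeats\n",
              object@mean_auc, object@sd_auc, object@n_folds, object@repeats))
})

setMethod("show", "ValidationResult", function(object) {
  cat(sprintf("ValidationResult: AUC %.3f (95%% CI %.3f, %.3f), n = %d\n",
              object@auc, object@ci[1], object@ci[2], object@n))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed AUC %.3f; permuted mean %.3f; p = %.4f (%d permutations)\n",
    object@observed, mean(object@permuted), object@p_value,
    object@n_permutations))
})

setMethod("show", "InterventionResult", function(object) {
  cat(sprintf(
    "InterventionResult [%s]: mean survival %.3f -> %.3f (%s-fold increase; %s-fold death reduction)\n",
    object@scope, object@p_pre, object@p_post,
    format(object@survival_fold, nsmall = 1),
    format(object@death_fold, nsmall = 1)))
  cat("  intervened:", paste(object@variables, collapse = ", "), "\n")
})

setMethod("show", "NormalizationResult", function(object) {
  cat("NormalizationResult (TMM): reference '", object@reference,
      "', trim M=", object@trim_m, " A=", object@trim_a, "\n", sep = "")
  print(round(object@factors, 4))
})
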