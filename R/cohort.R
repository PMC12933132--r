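#' Construct a CohortTable
#'
#' Assembles a [CohortTable-class] (a `SummarizedExperiment` with variables in
#' rows) from a samples-by-variables value matrix, per-variable role tags,
#' per-horizon 0/1 survival labels, and per-sample split tags.
#'
#' @param values numeric matrix, samples in rows, variables in columns
#'   (column names = variable ids, row names = sample ids).
#' @param roles named character vector of role tags per variable
#'   (`smrna-count`, `clinical-continuous`, `clinical-ordinal`, `age`).
#' @param labels data.frame of 0/1 labels, one column per horizon, columns
#'   named `survival_<h>y`.
#' @param splits character vector of split tags per sample, or `NULL`.
#' @param provenance list recorded in `metadata()` (e.g. seed, network id,
#'   or `list(source = "real")`).
#' @return a [CohortTable-class]
#' @export
CohortTable <- function(values, roles, labels, splits = NULL,
                        provenance = list()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("value matrix must have variable ids as column names")
  roles <- roles[colnames(values)]
  if (anyNA(roles)) stop("every variable needs a role tag")
  cd <- S4Vectors::DataFrame(labels, row.names = rownames(values))
  if (!is.null(splits)) cd$split <- splits
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values)),
    rowData = S4Vectors::DataFrame(role = unname(roles),
                                   row.names = colnames(values)),
    colData = cd,
    metadata = list(provenance = provenance)
  )
  methods::new("CohortTable", se)
}
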