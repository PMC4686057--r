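#' Expression study container
#'
#' Bundles a log2-scale probe-by-sample expression matrix with the
#' sample-to-group assignment of the four-arm fibroblast design
#' (patients and controls, each with and without ascorbic-acid treatment).
#' The matrix is expected to be normalized and on the log2 scale, as produced
#' by RMA summarisation of array data.
#'
#' @param values numeric matrix, genes (or probesets) in rows, samples in
#'   columns; rownames and colnames are required and must be unique.
#' @param groups character vector of group labels, one per sample, either
#'   named by sample id or in column order of `values`.
#' @return An object of class `expression_study` with elements `values`
#'   (the matrix) and `groups` (named character vector).
#' @examples
#' m <- matrix(rnorm(12, 7), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_study(m, c(s1 = "P", s2 = "P", s3 = "C", s4 = "C"))
#' @export
expression_study <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row and column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in `values`")
  if (any(is.infinite(values)) || any(is.nan(values)))
    stop("`values` contains non-finite entries")
  nm <- if (is.null(names(groups))) colnames(values) else names(groups)
  groups <- stats::setNames(as.character(groups), nm)
  if (length(groups) != ncol(values))
    stop("one group label per sample is required")
  if (!setequal(names(groups), colnames(values)))
    stop("group labels do not match sample identifiers")
  groups <- groups[colnames(values)]
  if (anyNA(groups)) stop("every sample must map to exactly one group")
  structure(list(values = values, groups = groups),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

# samples belonging to one group, in matrix column order
group_samples <- function(study, group) {
  s <- names(study$groups)[study$groups == group]
  if (length(s) == 0)
    stop(sprintf("group '%s' not present in the study", group))
  s
}

# subset of the matrix for one group
group_values <- function(study, group) {
  study$values[, group_samples(study, group), drop = FALSE]
}
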