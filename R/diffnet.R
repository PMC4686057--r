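#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson correlation of two vectors after pairwise deletion of
#' missing values, with the two-sided p-value from
#' `t = R * sqrt((n - 2) / (1 - R^2))` on `n - 2` degrees of freedom.
#' A perfect correlation (`|R| = 1`) gets `p = 0`.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with elements `r`, `p` and `n` (complete pairs used).
#' @export
pearson_with_pvalue <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("undefined correlation: fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Build a two-group differential co-expression network
#'
#' For every unordered pair of panel genes, Pearson correlation and p-value
#' are computed within the patient samples and within the control samples.
#' A pair is "significant in" a group iff `|R| > r_min` and `p < p_max`
#' there (both thresholds conjunctive, as in the
#' `|R| > 0.8, p < 0.005` network convention). Edge classes:
#' \describe{
#'   \item{patient_only}{significant in patients only}
#'   \item{control_only}{significant in controls only}
#'   \item{shared_concordant}{significant in both, same correlation sign}
#'   \item{shared_discordant}{significant in both, opposite signs}
#' }
#' Pairs significant in neither group are not retained. Note that with 6
#' samples per group, `p < 0.005` already requires `|R| > 0.94`, so the
#' default `r_min = 0.8` is not the binding constraint.
#'
#' @param study an [expression_study()].
#' @param panel character vector of genes to correlate.
#' @param group_patient,group_control group labels (default the untreated
#'   arms `P` and `C`).
#' @param r_min minimum absolute correlation.
#' @param p_max maximum p-value.
#' @return An object of class `diffnet`: list with `edges` (data frame with
#'   columns `gene_a`, `gene_b` in canonical order `gene_a < gene_b`,
#'   `r_patient`, `r_control`, `p_patient`, `p_control`, `class`,
#'   `degenerate` — `TRUE` where a retained correlation is exactly +/-1,
#'   usually a duplicated variable), `panel`, `thresholds`, `group_sizes`.
#' @export
build_group_network <- function(study, panel,
                                group_patient = "P", group_control = "C",
                                r_min = 0.8, p_max = 0.005) {
  missing_genes <- setdiff(panel, rownames(study$values))
  if (length(missing_genes) > 0)
    stop("panel genes absent from the study: ",
         paste(missing_genes, collapse = ", "))
  panel <- panel[order(panel)]
  xp <- group_values(study, group_patient)[panel, , drop = FALSE]
  xc <- group_values(study, group_control)[panel, , drop = FALSE]
  if (ncol(xp) < 3 || ncol(xc) < 3)
    stop("each group needs at least 3 samples")
  pairs <- t(utils::combn(panel, 2))
  cor_block <- function(m, a, b) pearson_with_pvalue(m[a, ], m[b, ])
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    cp <- cor_block(xp, a, b); cc <- cor_block(xc, a, b)
    c(r_patient = cp$r, r_control = cc$r,
      p_patient = cp$p, p_control = cc$p)
  })
  res <- do.call(rbind, res)
  sig_p <- abs(res[, "r_patient"]) > r_min & res[, "p_patient"] < p_max
  sig_c <- abs(res[, "r_control"]) > r_min & res[, "p_control"] < p_max
  class <- rep("none", nrow(res))
  class[sig_p & !sig_c] <- "patient_only"
  class[!sig_p & sig_c] <- "control_only"
  same <- sign(res[, "r_patient"]) == sign(res[, "r_control"])
  class[sig_p & sig_c & same] <- "shared_concordant"
  class[sig_p & sig_c & !same] <- "shared_discordant"
  keep <- class != "none"
  edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                      res[keep, , drop = FALSE], class = class[keep],
                      row.names = NULL)
  edges$degenerate <- (abs(edges$r_patient) >= 1 - 1e-12 & sig_p[keep]) |
                      (abs(edges$r_control) >= 1 - 1e-12 & sig_c[keep])
  structure(list(panel = panel, edges = edges,
                 thresholds = c(r_min = r_min, p_max = p_max),
                 group_sizes = c(patient = ncol(xp), control = ncol(xc)),
                 groups = c(patient = group_patient, control = group_control)),
            class = "diffnet")
}

#' @export
print.diffnet <- function(x, ...) {
  cat(sprintf("differential network: %d panel genes, %d retained edges (|R| > %g, p < %g)\n",
              length(x$panel), nrow(x$edges),
              x$thresholds["r_min"], x$thresholds["p_max"]))
  if (nrow(x$edges) > 0) print(table(x$edges$class))
  invisible(x)
}

#' Edge-class summary of a differential network
#' @param object a `diffnet` object.
#' @param ... unused.
#' @return named integer vector of edge counts per class.
#' @export
summary.diffnet <- function(object, ...) {
  cls <- c("patient_only", "control_only",
           "shared_concordant", "shared_discordant")
  out <- stats::setNames(integer(length(cls)), cls)
  tb <- table(object$edges$class)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Plot a differential network
#'
#' Draws the retained edges with the conventional colouring: black for
#' patient-only, grey for control-only, lilac for shared concordant and
#' orange for shared discordant edges; dashed lines mark negative
#' correlations. Requires the igraph package.
#'
#' @param x a `diffnet` object.
#' @param ... passed to `plot.igraph`.
#' @export
plot.diffnet <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting a diffnet requires the igraph package")
  e <- x$edges
  if (nrow(e) == 0) stop("no retained edges to plot")
  g <- igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  cols <- c(patient_only = "black", control_only = "grey60",
            shared_concordant = "orchid", shared_discordant = "darkorange")
  sign_r <- ifelse(e$class == "control_only", e$r_control, e$r_patient)
  plot(g, edge.color = cols[e$class],
       edge.lty = ifelse(sign_r < 0, 2, 1), ...)
  invisible(x)
}

#' Screen a phenotype table for strong pairwise correlations
#'
#' Tests every unordered pair of variables of a sample-by-variable table
#' (pairwise-complete observations) and retains pairs with
#' `|R| > r_min` and `p < p_max`, the convention used when relating miRNA
#' levels to histopathological and biochemical variables. Variables with
#' fewer than 3 observations are excluded with a warning.
#'
#' @param table numeric matrix or data frame, samples in rows.
#' @param r_min minimum absolute correlation (default 0.7).
#' @param p_max maximum p-value (default 0.05).
#' @return data frame sorted by p ascending with columns `variable_a`,
#'   `variable_b`, `p`, `r` and a `degenerate` flag for `|R| = 1` pairs.
#' @export
phenotype_correlation_screen <- function(table, r_min = 0.7, p_max = 0.05) {
  m <- as.matrix(table)
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  usable <- colSums(is.finite(m)) >= 3
  if (any(!usable)) {
    warning("excluding variables with < 3 observations: ",
            paste(colnames(m)[!usable], collapse = ", "))
    m <- m[, usable, drop = FALSE]
  }
  vars <- colnames(m)
  out <- NULL
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    res <- tryCatch(pearson_with_pvalue(m[, i], m[, j]),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (abs(res$r) > r_min && res$p < p_max)
      out <- rbind(out, data.frame(variable_a = vars[i], variable_b = vars[j],
                                   p = res$p, r = res$r,
                                   degenerate = abs(res$r) >= 1 - 1e-12))
  }
  if (is.null(out))
    out <- data.frame(variable_a = character(), variable_b = character(),
                      p = numeric(), r = numeric(), degenerate = logical())
  out[order(out$p), , drop = FALSE]
}
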