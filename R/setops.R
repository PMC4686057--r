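#' Construct a gene-level contrast result
#'
#' Bundles the up- and down-regulated gene lists of one contrast (gene-level,
#' i.e. after probeset collapsing). Lists are data frames with columns
#' `gene`, `fc`, `pfp`; a gene may not appear in both directions.
#'
#' @param name contrast label, e.g. `"P-C"`.
#' @param up,down data frames (`gene`, `fc`, `pfp`).
#' @return object of class `contrast_result`.
#' @export
contrast_result <- function(name, up, down) {
  for (d in list(up, down))
    stopifnot(all(c("gene", "fc", "pfp") %in% names(d)))
  if (length(intersect(up$gene, down$gene)) > 0)
    stop("a gene may not be both up- and down-regulated in one contrast")
  structure(list(up = up, down = down, name = name),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast %s: %d up, %d down, %d total unique genes\n",
              x$name, nrow(x$up), nrow(x$down), nrow(x$up) + nrow(x$down)))
  invisible(x)
}

all_genes <- function(cr) c(cr$up$gene, cr$down$gene)

norm_symbol <- function(z) toupper(trimws(z))

#' Overlap between two contrasts' regulated-gene sets
#'
#' Membership is by gene symbol over the union of each contrast's up- and
#' down-regulated lists, the computation behind statements such as
#' "N genes were common between the two comparisons".
#'
#' @param a,b `contrast_result` objects.
#' @return list with `common`, `unique_a`, `unique_b` character vectors.
#' @export
contrast_overlap <- function(a, b) {
  ga <- all_genes(a); gb <- all_genes(b)
  list(common = intersect(ga, gb),
       unique_a = setdiff(ga, gb),
       unique_b = setdiff(gb, ga))
}

#' Ascorbic-acid sign-reversion genes
#'
#' Finds genes whose expression the treatment moves back across the control
#' baseline: a gene is reported iff it is significant (present) in both the
#' disease contrast (P-C) and the treatment contrast (P_AA-P) and its signed
#' fold changes in the two contrasts have opposite signs. No fold-change
#' magnitude filter is applied. Output is sorted by the magnitude of the
#' disease-contrast fold change, descending within each direction group
#' (treatment-down first).
#'
#' @param pc `contrast_result` for the disease contrast (P-C).
#' @param paap `contrast_result` for the treatment contrast (P_AA-P).
#' @return data frame with columns `gene`, `fc_treatment` (P_AA-P),
#'   `fc_disease` (P-C); every row satisfies
#'   `sign(fc_treatment) != sign(fc_disease)`.
#' @export
reversion_genes <- function(pc, paap) {
  fc_of <- function(cr) {
    d <- rbind(cr$up, cr$down)
    stats::setNames(d$fc, d$gene)
  }
  f1 <- fc_of(pc); f2 <- fc_of(paap)
  common <- intersect(names(f1), names(f2))
  if (length(names(f1)) > 0 && length(names(f2)) > 0 && length(common) == 0)
    stop("the two contrasts share no genes: disjoint gene universes?")
  flip <- common[sign(f1[common]) != sign(f2[common])]
  out <- data.frame(gene = flip,
                    fc_treatment = unname(f2[flip]),
                    fc_disease = unname(f1[flip]))
  out <- out[order(out$fc_treatment >= 0, -abs(out$fc_disease)), ,
             drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(sign(out$fc_treatment) != sign(out$fc_disease)))
  out
}

#' Per-contrast up/down/total count table
#'
#' @param results list of `contrast_result` objects.
#' @return integer matrix with rows `UP`, `DOWN`, `TOTAL` and one column per
#'   contrast.
#' @export
summarize_counts <- function(results) {
  if (length(results) == 0)
    return(matrix(integer(), 3, 0,
                  dimnames = list(c("UP", "DOWN", "TOTAL"), NULL)))
  counts <- vapply(results, function(cr) {
    u <- nrow(cr$up); d <- nrow(cr$down)
    c(UP = u, DOWN = d, TOTAL = u + d)
  }, integer(3))
  colnames(counts) <- unname(vapply(results, function(cr) cr$name, ""))
  counts
}

#' Overlap of a contrast with an external gene list
#'
#' Symbol-level intersection after uppercasing and whitespace trimming,
#' used to compare fibroblast results with independently published gene
#' lists (e.g. from muscle biopsies or other fibroblast studies).
#'
#' @param result a `contrast_result`.
#' @param external character vector of gene symbols.
#' @return character vector of shared symbols (normalized form).
#' @export
cross_dataset_overlap <- function(result, external) {
  if (length(external) == 0) {
    warning("external gene list is empty")
    return(character())
  }
  intersect(norm_symbol(all_genes(result)), norm_symbol(external))
}
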