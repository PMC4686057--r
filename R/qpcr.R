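#' Delta-delta-Ct relative quantification
#'
#' Computes per-group signed fold changes of one qPCR/miRNA target relative
#' to a control group, normalized against the housekeeping (reference)
#' assay measured on the same samples:
#' `dCt_s = Ct_target,s - Ct_reference,s`,
#' `ddCt_s = dCt_s - mean(dCt over control samples)`, per-sample relative
#' expression `2^-ddCt_s`. Technical replicates are averaged on the CT scale
#' per (sample, target) before dCt. The group value is the arithmetic mean
#' of per-sample relative expression (`average = "geometric"` gives the
#' geometric mean instead); means below 1 are reported with the negative
#' reciprocal sign convention (0.5 becomes -2.0).
#'
#' @param table CT data frame with columns `sample`, `group`, `target`,
#'   `reference`, `ct_target`, `ct_reference`
#'   (see [simulate_ct_table()] for the layout).
#' @param target target assay id to quantify.
#' @param control_group label of the reference group.
#' @param average `"arithmetic"` (convention of qPCR fold-change tables) or
#'   `"geometric"`.
#' @return object of class `ddct`: data frame with one row per group and
#'   columns `group`, `n`, `fc_linear` (group mean of `2^-ddCt`),
#'   `fc_signed`, `sem` (standard error of the per-sample relative
#'   expression).
#' @export
ddct_fold_changes <- function(table, target, control_group = "control",
                              average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  need <- c("sample", "group", "target", "reference",
            "ct_target", "ct_reference")
  stopifnot(all(need %in% names(table)))
  tt <- table[table$target == target, , drop = FALSE]
  if (nrow(tt) == 0) stop("no CT rows for target ", target)
  if (any(!is.finite(tt$ct_target)) || any(tt$ct_target <= 0))
    stop("CT values must be positive and finite")
  if (any(!is.finite(tt$ct_reference)))
    stop("missing reference CT for sample(s): ",
         paste(unique(tt$sample[!is.finite(tt$ct_reference)]),
               collapse = ", "))
  # average technical replicates on the CT scale per sample
  ct_t <- tapply(tt$ct_target, tt$sample, mean)
  ct_r <- tapply(tt$ct_reference, tt$sample, mean)
  grp <- tapply(tt$group, tt$sample, function(z) z[1])
  samples <- names(ct_t)
  dct <- ct_t - ct_r
  ctrl <- grp == control_group
  if (!any(ctrl)) stop("no samples in control group '", control_group, "'")
  ddct <- dct - mean(dct[ctrl])
  rel <- 2^(-ddct)
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    v <- rel[grp == g]
    m <- if (average == "geometric") exp(mean(log(v))) else mean(v)
    data.frame(group = g, n = length(v), fc_linear = m,
               fc_signed = signed_fc(m),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  rownames(out) <- NULL
  class(out) <- c("ddct", "data.frame")
  attr(out, "target") <- target
  attr(out, "control_group") <- control_group
  out
}

# negative-reciprocal sign convention: linear ratio 0.5 -> -2.0
signed_fc <- function(r) ifelse(r >= 1, r, -1 / r)

#' @export
print.ddct <- function(x, ...) {
  cat(sprintf("ddCt fold changes for %s (relative to %s):\n",
              attr(x, "target"), attr(x, "control_group")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Fold-change significance call
#'
#' The conventional screening rule for qPCR fold changes: significant iff
#' the signed fold change is strictly above +1.5 or strictly below -1.5.
#'
#' @param fc signed fold change(s); `|fc| >= 1` by the sign convention.
#' @param threshold magnitude threshold (default 1.5).
#' @return logical vector.
#' @export
call_fc_significant <- function(fc, threshold = 1.5) {
  abs(fc) > threshold
}
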