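#' All-pairs log2 ratios for a two-group contrast
#'
#' Builds the input of the two-class rank-product statistic: one column per
#' (numerator sample, denominator sample) pair, each column holding the
#' per-gene difference of log2 expression. Column order is lexicographic in
#' (numerator index, denominator index). Genes with any missing value in the
#' contrast's samples are dropped (ranking requires complete vectors); the
#' number dropped is recorded in the `"n_dropped"` attribute.
#'
#' @param study an [expression_study()].
#' @param contrast contrast specification: either `c(numerator, denominator)`
#'   group labels or a single string `"NUM-DEN"`.
#' @return numeric matrix, genes x (n1*n2) log2 ratios.
#' @export
pairwise_log_ratios <- function(study, contrast) {
  ct <- parse_contrast(contrast)
  a <- group_values(study, ct[1])
  b <- group_values(study, ct[2])
  if (ncol(a) < 2 || ncol(b) < 2)
    stop(sprintf("contrast %s-%s needs at least 2 samples per group",
                 ct[1], ct[2]))
  keep <- stats::complete.cases(cbind(a, b))
  n_dropped <- sum(!keep)
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  idx <- expand.grid(j = seq_len(ncol(b)), i = seq_len(ncol(a)))
  ratios <- a[, idx$i, drop = FALSE] - b[, idx$j, drop = FALSE]
  colnames(ratios) <- paste0(colnames(a)[idx$i], ".vs.", colnames(b)[idx$j])
  attr(ratios, "n_dropped") <- n_dropped
  ratios
}

parse_contrast <- function(contrast) {
  if (length(contrast) == 1) {
    # split on the last "-" that leaves non-empty sides, so labels such as
    # "P_AA-P" parse as numerator "P_AA", denominator "P"
    parts <- strsplit(contrast, "-", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("contrast must name two groups")
    contrast <- c(paste(parts[-length(parts)], collapse = "-"),
                  parts[length(parts)])
  }
  if (length(contrast) != 2 || contrast[1] == contrast[2])
    stop("contrast must name two distinct groups")
  contrast
}

#' Rank-product statistic of an all-pairs ratio matrix
#'
#' Within every column, genes are ranked by their ratio — descending for
#' `direction = "up"` (largest ratio gets rank 1), ascending for `"down"` —
#' with ties given average ranks. The statistic is the geometric mean of a
#' gene's ranks over all columns; genes consistently at the extreme of every
#' pairwise comparison get values near 1.
#'
#' @param ratios matrix from [pairwise_log_ratios()].
#' @param direction `"up"` or `"down"`.
#' @return named numeric vector of per-gene rank products.
#' @export
rank_product_statistic <- function(ratios, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.matrix(ratios) || nrow(ratios) == 0 || ncol(ratios) == 0)
    stop("ratios must be a non-empty matrix")
  if (any(!is.finite(ratios))) stop("ratios must be finite")
  s <- if (direction == "up") -ratios else ratios
  rk <- apply(s, 2, rank, ties.method = "average")
  rk <- matrix(rk, nrow = nrow(ratios))
  stats::setNames(exp(rowMeans(log(rk))), rownames(ratios))
}

#' Fit two-class Rank Products with permutation-estimated pfp
#'
#' The model-fitting entry point of the package. For one two-group contrast
#' it computes the up- and down-regulation rank products from all pairwise
#' between-group log2 ratios, estimates the proportion of false positives
#' (pfp, the quantity reported as FDR in rank-product analyses) by
#' permutation, and attaches signed linear fold changes.
#'
#' For each permutation, expression values are shuffled across the
#' contrast's samples — by default independently within each gene, which
#' preserves every gene's marginal distribution under the null of no group
#' difference (`permutation = "whole-column"` instead applies one shared
#' sample shuffle to all genes, preserving gene-gene correlation). Null rank
#' products are pooled over permutations; for each observed value `RP(g)`,
#' `E(g)` is the average number of null values at or below it, and
#' `pfp(g) = E(g) / rank(g)` where genes are ranked by RP ascending. pfp is
#' made monotone non-decreasing along the RP ordering by cumulative maximum.
#' Stored pfp values are not clipped; reporting clips at 1.
#'
#' @param study an [expression_study()].
#' @param contrast two group labels or a `"NUM-DEN"` string.
#' @param n_permutations number of permutations (>= 1).
#' @param seed mandatory integer seed for the permutation stream.
#' @param permutation `"per-gene"` (default) or `"whole-column"`.
#' @return An object of class `rankprod`: list with `table` (data frame with
#'   columns `probe`, `rp_up`, `rp_down`, `pfp_up`, `pfp_down`, `fc_signed`,
#'   sorted by `min(pfp_up, pfp_down)`), `contrast`, `n_permutations`,
#'   `seed`, `n_dropped`.
#' @examples
#' sim <- simulate_expression_study(sim_config(n_genes = 100, seed = 3))
#' fit <- rank_products(sim$study, "P-C", n_permutations = 50, seed = 9)
#' head(summary(fit))
#' @export
rank_products <- function(study, contrast, n_permutations = 1000, seed,
                          permutation = c("per-gene", "whole-column")) {
  permutation <- match.arg(permutation)
  if (missing(seed)) stop("an explicit integer `seed` is required")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  ct <- parse_contrast(contrast)
  ratios <- pairwise_log_ratios(study, ct)
  G <- nrow(ratios)
  obs_up <- rank_product_statistic(ratios, "up")
  obs_dn <- rank_product_statistic(ratios, "down")
  fc <- fold_change(ratios)

  # permutations act on the contrast's samples in study column order, so the
  # null stream is identical whichever way the contrast is oriented and
  # swapping numerator/denominator exactly exchanges up with down
  in_ct <- study$groups %in% ct
  sam <- colnames(study$values)[in_ct]
  X <- study$values[rownames(ratios), sam, drop = FALSE]
  num_pos <- which(study$groups[sam] == ct[1])
  den_pos <- which(study$groups[sam] == ct[2])
  n <- ncol(X)
  cnt_up <- numeric(G); cnt_dn <- numeric(G)

  set.seed(as.integer(seed))
  for (b in seq_len(n_permutations)) {
    if (permutation == "per-gene") {
      u <- matrix(stats::runif(G * n), G, n)
      # row-wise order of random keys = independent shuffle per gene
      ord <- t(apply(u, 1, order))
      Xp <- matrix(X[cbind(rep(seq_len(G), n), as.vector(ord))], G, n)
    } else {
      Xp <- X[, sample.int(n), drop = FALSE]
    }
    rp <- perm_ratios(Xp, num_pos, den_pos)
    # with average ties, ascending rank = G + 1 - descending rank, so one
    # ranking pass serves both directions
    rk <- matrix(apply(-rp, 2, rank, ties.method = "average"), G)
    null_up <- exp(rowMeans(log(rk)))
    null_dn <- exp(rowMeans(log(G + 1 - rk)))
    cnt_up <- cnt_up + findInterval(obs_up, sort.int(unname(null_up),
                                                    method = "quick"))
    cnt_dn <- cnt_dn + findInterval(obs_dn, sort.int(unname(null_dn),
                                                    method = "quick"))
  }
  pfp_up <- pfp_from_counts(obs_up, cnt_up / n_permutations)
  pfp_dn <- pfp_from_counts(obs_dn, cnt_dn / n_permutations)

  tab <- data.frame(probe = rownames(ratios),
                    rp_up = unname(obs_up), rp_down = unname(obs_dn),
                    pfp_up = pfp_up, pfp_down = pfp_dn,
                    fc_signed = unname(fc))
  tab <- tab[order(pmin(tab$pfp_up, tab$pfp_down), pmin(tab$rp_up, tab$rp_down)), ]
  rownames(tab) <- NULL
  structure(list(table = tab, contrast = ct,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), permutation = permutation,
                 n_dropped = attr(ratios, "n_dropped")),
            class = "rankprod")
}

# all-pairs ratios between two column sets of an already-subsetted matrix
perm_ratios <- function(X, num_pos, den_pos) {
  idx <- expand.grid(j = seq_along(den_pos), i = seq_along(num_pos))
  X[, num_pos[idx$i], drop = FALSE] - X[, den_pos[idx$j], drop = FALSE]
}

# pfp = E / rank with cumulative-maximum monotonicity along the RP ordering;
# tied rank products share an average rank (and an identical count E), so
# they receive one common pfp
pfp_from_counts <- function(obs_rp, E) {
  o <- order(obs_rp)
  pfp_sorted <- cummax(E[o] / rank(obs_rp, ties.method = "average")[o])
  out <- numeric(length(obs_rp))
  out[o] <- pfp_sorted
  out
}

#' Signed fold change from an all-pairs ratio matrix
#'
#' The mean log2 ratio `m` is mapped to a signed linear fold change with the
#' negative-reciprocal convention of array tables: `2^m` when `2^m >= 1`,
#' otherwise `-2^-m` (so a halving is reported as -2.0, never 0.5, and no
#' value lies strictly between -1 and 1).
#'
#' @param ratios matrix from [pairwise_log_ratios()].
#' @return named numeric vector of signed fold changes.
#' @export
fold_change <- function(ratios) {
  m <- rowMeans(ratios)
  r <- 2^m
  stats::setNames(ifelse(r >= 1, r, -1 / r), rownames(ratios))
}

#' Call significant probes from a rank-product fit
#'
#' A probe is called up-regulated iff `pfp_up < fdr` and down-regulated iff
#' `pfp_down < fdr` (strict inequality). A probe passing in both directions
#' is assigned to the direction with the smaller pfp.
#'
#' @param fit a `rankprod` object.
#' @param fdr pfp threshold in (0, 1].
#' @return list with data frames `up` and `down`, each with columns
#'   `gene` (probe id), `fc`, `pfp`.
#' @export
call_significant <- function(fit, fdr = 0.05) {
  stopifnot(inherits(fit, "rankprod"))
  if (fdr <= 0 || fdr > 1) stop("fdr threshold must be in (0, 1]")
  t <- fit$table
  up <- t$pfp_up < fdr
  dn <- t$pfp_down < fdr
  both <- up & dn
  up[both] <- t$pfp_up[both] <= t$pfp_down[both]
  dn[both] <- !up[both]
  mk <- function(sel, pfp) {
    d <- data.frame(gene = t$probe[sel], fc = t$fc_signed[sel],
                    pfp = pfp[sel])
    d[order(d$pfp, -abs(d$fc)), , drop = FALSE]
  }
  list(up = mk(up, t$pfp_up), down = mk(dn, t$pfp_down))
}

#' Collapse probe-level calls to unique genes
#'
#' Maps probeset-level up/down lists to gene symbols using an annotation
#' table. Per gene the probe with the smallest pfp is kept; a gene with
#' probes in both direction lists is assigned the direction of its
#' smallest-pfp probe. Unannotated probes are dropped and counted.
#'
#' @param calls list with `up` and `down` data frames from
#'   [call_significant()].
#' @param annotation named character vector, probe -> gene symbol.
#' @param name optional contrast name carried into the result.
#' @return list of class `contrast_result`: data frames `up`, `down`
#'   (columns `gene`, `fc`, `pfp`), plus `n_unannotated` and `name`.
#' @export
collapse_probesets <- function(calls, annotation, name = "") {
  add_dir <- function(d, dir) {
    d$direction <- rep(dir, nrow(d))
    d
  }
  both <- rbind(add_dir(calls$up, "up"), add_dir(calls$down, "down"))
  known <- both$gene %in% names(annotation)
  n_unannot <- sum(!known)
  both <- both[known, , drop = FALSE]
  both$symbol <- unname(annotation[both$gene])
  both <- both[order(both$pfp, -abs(both$fc)), , drop = FALSE]
  best <- both[!duplicated(both$symbol), , drop = FALSE]
  mk <- function(dir) {
    d <- best[best$direction == dir, c("symbol", "fc", "pfp"), drop = FALSE]
    names(d)[1] <- "gene"
    rownames(d) <- NULL
    d
  }
  structure(list(up = mk("up"), down = mk("down"),
                 n_unannotated = n_unannot, name = name),
            class = "contrast_result")
}

#' @export
print.rankprod <- function(x, ...) {
  cat(sprintf("Rank Products fit: contrast %s-%s, %d probes, %d permutations (seed %d)\n",
              x$contrast[1], x$contrast[2], nrow(x$table),
              x$n_permutations, x$seed))
  n05 <- sum(pmin(x$table$pfp_up, x$table$pfp_down) < 0.05)
  cat(sprintf("probes with pfp < 0.05 in either direction: %d\n", n05))
  if (x$n_dropped > 0)
    cat(sprintf("probes dropped for missing values: %d\n", x$n_dropped))
  invisible(x)
}

#' Summary table of a rank-product fit
#'
#' @param object a `rankprod` object.
#' @param ... unused.
#' @return the per-probe table with pfp clipped at 1 for reporting.
#' @export
summary.rankprod <- function(object, ...) {
  t <- object$table
  t$pfp_up <- pmin(t$pfp_up, 1)
  t$pfp_down <- pmin(t$pfp_down, 1)
  t
}

#' @export
coef.rankprod <- function(object, ...) {
  stats::setNames(object$table$fc_signed, object$table$probe)
}

#' Fold-change versus significance plot of a rank-product fit
#'
#' Base-graphics diagnostic: signed log2 fold change against -log10 pfp
#' (best direction per probe), with the pfp threshold drawn.
#'
#' @param x a `rankprod` object.
#' @param fdr threshold line.
#' @param ... passed to [plot()].
#' @export
plot.rankprod <- function(x, fdr = 0.05, ...) {
  t <- x$table
  pfp <- pmin(pmax(pmin(t$pfp_up, t$pfp_down), 1 / (x$n_permutations * nrow(t))), 1)
  lfc <- sign(t$fc_signed) * log2(abs(t$fc_signed))
  plot(lfc, -log10(pfp), pch = 20, col = "grey40",
       xlab = "signed log2 fold change", ylab = "-log10 pfp", ...)
  graphics::abline(h = -log10(fdr), lty = 2)
  invisible(x)
}
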