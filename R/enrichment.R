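#' Gene-set over-representation test
#'
#' One-sided hypergeometric (Fisher) enrichment of a query gene list against
#' a GMT-style gene-set collection, restricted to a stated gene universe
#' (by default the genes on the analyzed array, matching array-background
#' logic). The `ease` variant removes one gene from each overlap before
#' testing (floored at zero), a deliberately conservative score. P-values
#' are Benjamini-Hochberg adjusted across all tested sets.
#'
#' This is a transparent generic ORA; it makes no attempt to reproduce the
#' versioned annotation databases of hosted enrichment services.
#'
#' @param query character vector of genes (must be a subset of `universe`).
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of background genes.
#' @param variant `"fisher"` or `"ease"`.
#' @return data frame sorted by raw p with columns `set`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p_raw`, `p_adjusted`.
#' @export
overrepresentation_test <- function(query, sets, universe,
                                    variant = c("fisher", "ease")) {
  variant <- match.arg(variant)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  out_q <- setdiff(query, universe)
  if (length(out_q) > 0)
    stop("query genes outside the universe: ",
         paste(out_q, collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(s, query))
    K <- length(s)
    k_eff <- if (variant == "ease") max(k - 1, 0) else k
    # P(X >= k_eff) for X ~ Hypergeom(K successes, N - K failures, n draws)
    p <- stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p_raw = p)
  })
  df <- do.call(rbind, rows)
  df$p_adjusted <- bh_adjust(df$p_raw)
  df <- df[order(df$p_raw), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input vector.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
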