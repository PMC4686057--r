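# Exhaustive rank-product pfp oracle for a 5-gene, 2-vs-2 design.
#
# Enumerates every joint within-gene arrangement (24^5, ~8M) of the four
# sample values, computes the null rank products for both directions, and
# derives pfp exactly as E / rank with cumulative-maximum monotonicity.
# Written independently of the package's permutation sampler: ranks come
# from direct pairwise comparisons (the fixture must have no ties) and the
# package's ranking code is not reused.
exhaustive_rp_pfp_2v2 <- function(X) {
  stopifnot(nrow(X) == 5, ncol(X) == 4)
  G <- 5
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(z) length(unique(z)) == 4), ,
                 drop = FALSE]                      # the 24 arrangements
  np <- nrow(perms)
  # per gene and arrangement: the 4 ratio columns (num slots 1,2 x den 3,4)
  ratio <- array(NA_real_, c(G, np, 4))
  for (g in 1:G) for (a in 1:np) {
    v <- X[g, perms[a, ]]
    ratio[g, a, ] <- c(v[1] - v[3], v[1] - v[4], v[2] - v[3], v[2] - v[4])
  }
  obs <- t(sapply(1:G, function(g)
    c(X[g, 1] - X[g, 3], X[g, 1] - X[g, 4],
      X[g, 2] - X[g, 3], X[g, 2] - X[g, 4])))
  obs_up <- exp(rowMeans(log(apply(-obs, 2, rank))))
  obs_dn <- exp(rowMeans(log(apply(obs, 2, rank))))

  cnt_up <- numeric(G); cnt_dn <- numeric(G); total <- 0
  inner <- as.matrix(expand.grid(a1 = 1:np, a2 = 1:np, a3 = 1:np))
  B <- nrow(inner)
  for (a4 in 1:np) for (a5 in 1:np) {
    lsum_up <- matrix(0, B, G)
    for (cc in 1:4) {
      V <- cbind(ratio[1, inner[, 1], cc], ratio[2, inner[, 2], cc],
                 ratio[3, inner[, 3], cc], rep(ratio[4, a4, cc], B),
                 rep(ratio[5, a5, cc], B))
      for (g in 1:G)   # descending rank = 1 + number of larger values
        lsum_up[, g] <- lsum_up[, g] + log1p(rowSums(V > V[, g]))
    }
    rp_up <- exp(lsum_up / 4)
    lsum_dn <- matrix(0, B, G)
    for (cc in 1:4) {
      V <- cbind(ratio[1, inner[, 1], cc], ratio[2, inner[, 2], cc],
                 ratio[3, inner[, 3], cc], rep(ratio[4, a4, cc], B),
                 rep(ratio[5, a5, cc], B))
      for (g in 1:G)
        lsum_dn[, g] <- lsum_dn[, g] + log1p(rowSums(V < V[, g]))
    }
    rp_dn <- exp(lsum_dn / 4)
    for (g in 1:G) {
      cnt_up[g] <- cnt_up[g] + sum(rp_up <= obs_up[g])
      cnt_dn[g] <- cnt_dn[g] + sum(rp_dn <= obs_dn[g])
    }
    total <- total + B
  }
  pfp_of <- function(obs_rp, E) {
    o <- order(obs_rp)
    out <- numeric(G)
    out[o] <- cummax((E / rank(obs_rp))[o])
    out
  }
  list(pfp_up = pfp_of(obs_up, cnt_up / total),
       pfp_down = pfp_of(obs_dn, cnt_dn / total),
       obs_up = obs_up, obs_down = obs_dn)
}
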