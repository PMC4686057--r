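mini_study <- function() {
  # 2 genes, 2 vs 2, exact values
  m <- rbind(g1 = c(5, 5, 3, 3), g2 = c(1, 1, 1, 1))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  expression_study(m, c(a1 = "P", a2 = "P", b1 = "C", b2 = "C"))
}

test_that("pairwise log ratios enumerate numerator x denominator pairs", {
  r <- pairwise_log_ratios(mini_study(), "P-C")
  expect_equal(dim(r), c(2, 4))
  expect_equal(unname(r["g1", ]), rep(2, 4))
  expect_equal(unname(r["g2", ]), rep(0, 4))

  sim <- small_sim(seed = 2, n_genes = 30)
  r6 <- pairwise_log_ratios(sim$study, "P-C")
  expect_equal(ncol(r6), 36)
  # antisymmetry under swapping the contrast
  rs <- pairwise_log_ratios(sim$study, "C-P")
  expect_equal(sort(unname(r6[5, ])), sort(-unname(rs[5, ])))

  one <- expression_study(matrix(1:4, 1, 4,
           dimnames = list("g", paste0("s", 1:4))),
           c(s1 = "P", s2 = "P", s3 = "P", s4 = "C"))
  expect_error(pairwise_log_ratios(one, "P-C"), "at least 2 samples")
})

test_that("rank product matches the hand-ranked example and tie convention", {
  ratios <- rbind(g1 = c(3, 3), g2 = c(2, 1), g3 = c(1, 2))
  rp <- rank_product_statistic(ratios, "up")
  expect_equal(unname(rp), c(1, sqrt(6), sqrt(6)))
  # the consistently largest gene attains the minimum RP of 1
  expect_equal(min(rp), 1)
  # a fully tied column gives every gene the average rank (G+1)/2
  tied <- matrix(5, 4, 1, dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(unname(rank_product_statistic(tied, "up")), rep(2.5, 4))
  expect_error(rank_product_statistic(ratios[0, , drop = FALSE]),
               "non-empty")
})

test_that("rank product is invariant under monotone column transforms", {
  set.seed(8)
  ratios <- matrix(rnorm(60), 10, 6)
  rownames(ratios) <- paste0("g", 1:10)
  warped <- ratios
  warped[, 2] <- exp(ratios[, 2])
  warped[, 5] <- ratios[, 5]^3
  for (dir in c("up", "down"))
    expect_equal(rank_product_statistic(ratios, dir),
                 rank_product_statistic(warped, dir))
})

test_that("signed fold change uses the negative-reciprocal convention", {
  ratios <- rbind(a = rep(1, 4), b = rep(-1, 4), c = rep(0, 4))
  fc <- fold_change(ratios)
  expect_equal(unname(fc), c(2, -2, 1))
  # never inside the open interval (-1, 1)
  set.seed(1)
  any_fc <- fold_change(matrix(rnorm(200), 50, 4))
  expect_true(all(abs(any_fc) >= 1))
})

test_that("pfp accumulation divides null counts by RP rank and is monotone", {
  # direct unit check of the estimator's arithmetic: E = 0 gives pfp 0,
  # and cumulative maximum enforces monotonicity along the RP ordering
  obs <- c(1.0, 2.0, 5.0, 9.0)
  E <- c(0, 0.5, 0.2, 3.0)
  pfp <- fibrodiff:::pfp_from_counts(obs, E)
  expect_equal(pfp, c(0, 0.25, 0.25, 0.75))
  expect_true(all(diff(pfp[order(obs)]) >= 0))
})

test_that("pfp is monotone in RP and swapping the contrast swaps directions", {
  sim <- small_sim(seed = 5, n_genes = 120)
  f1 <- rank_products(sim$study, "P-C", n_permutations = 40, seed = 3)
  t1 <- f1$table
  expect_true(all(diff(t1$pfp_up[order(t1$rp_up)]) >= 0))
  expect_true(all(diff(t1$pfp_down[order(t1$rp_down)]) >= 0))
  f2 <- rank_products(sim$study, "C-P", n_permutations = 40, seed = 3)
  m1 <- t1[order(t1$probe), ]
  m2 <- f2$table[order(f2$table$probe), ]
  expect_equal(m1$rp_up, m2$rp_down)
  expect_equal(m1$pfp_up, m2$pfp_down)
  expect_equal(m1$fc_signed, -m2$fc_signed)
})

test_that("significance calls use strict thresholds and direction tie-breaks", {
  fake <- structure(list(table = data.frame(
    probe = c("a", "b", "c", "d"),
    rp_up = c(1, 2, 3, 4), rp_down = c(4, 3, 2, 1),
    pfp_up = c(0.04, 0.05, 0.9, 0.01), pfp_down = c(0.9, 0.9, 0.03, 0.02),
    fc_signed = c(2, 1.5, -2, 3))), class = "rankprod")
  calls <- call_significant(fake, 0.05)
  expect_setequal(calls$up$gene, c("a", "d"))   # 0.05 itself is excluded
  expect_setequal(calls$down$gene, "c")         # d resolves to smaller pfp
  expect_error(call_significant(fake, 0), "\\(0, 1\\]")

  empty <- structure(list(table = fake$table[0, ]), class = "rankprod")
  e <- call_significant(empty, 0.05)
  expect_equal(nrow(e$up) + nrow(e$down), 0)
})

test_that("probeset collapsing keeps the best probe per gene", {
  calls <- list(
    up = data.frame(gene = c("p1", "p2", "p4"), fc = c(2.5, 1.8, 2.2),
                    pfp = c(0.01, 0.2, 0.001)),
    down = data.frame(gene = c("p3", "p5"), fc = c(-3, -1.7),
                      pfp = c(0.04, 0.02)))
  ann <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB", p4 = "GENEB",
           p5 = "GENEC")
  cr <- collapse_probesets(calls, ann, name = "P-C")
  # GENEA: both probes up, keep pfp 0.01; GENEB: up probe wins on pfp
  expect_equal(cr$up[cr$up$gene == "GENEA", "fc"], 2.5)
  expect_true("GENEB" %in% cr$up$gene)
  expect_false("GENEB" %in% cr$down$gene)
  expect_equal(nrow(cr$up) + nrow(cr$down), 3)
  expect_equal(cr$n_unannotated, 0)
})

test_that("planted DE genes dominate the ranking on simulated data", {
  sim <- small_sim(seed = 12, n_genes = 200, de_fraction = 0.05,
                   n_reversion_genes = 0)
  fit <- rank_products(sim$study, "P-C", n_permutations = 100, seed = 4)
  calls <- call_significant(fit, 0.05)
  truth_up <- sim$truth$de_up; truth_dn <- sim$truth$de_down
  expect_gte(mean(truth_up %in% calls$up$gene), 0.8)
  expect_gte(mean(truth_dn %in% calls$down$gene), 0.8)
  # directions are correct: no planted up gene called down
  expect_length(intersect(truth_up, calls$down$gene), 0)
})
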