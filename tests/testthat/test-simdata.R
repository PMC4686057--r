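test_that("invalid configurations are rejected with named constraints", {
  expect_error(sim_config(de_fraction = 1.2), "de_fraction")
  expect_error(sim_config(de_log2fc = 0), "de_log2fc")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_genes = 10, de_fraction = 0.5,
                          n_reversion_genes = 50),
               "exceed n_genes")
  expect_error(module_spec(10, r = 1), "\\(-1,1\\)")
  expect_error(module_spec(1, r = 0.5), "at least 2")
})

test_that("zero noise with no planted effects gives identical group means", {
  sim <- small_sim(seed = 3, n_genes = 50, noise_sd = 0, de_fraction = 0,
                   n_reversion_genes = 0)
  v <- sim$study$values
  g <- sim$study$groups
  means <- sapply(unique(g), function(gr)
    rowMeans(v[, g == gr, drop = FALSE]))
  expect_true(all(abs(means - means[, 1]) < 1e-12))
})

test_that("generator is bit-reproducible and truth categories are disjoint", {
  cfg <- sim_config(n_genes = 120, seed = 42,
                    module_specs = list(module_spec(8, 0.9)))
  s1 <- simulate_expression_study(cfg)
  s2 <- simulate_expression_study(cfg)
  expect_identical(s1$study$values, s2$study$values)
  expect_identical(s1$truth, s2$truth)
  mod <- unique(c(s1$truth$module_edges$gene_a, s1$truth$module_edges$gene_b))
  cats <- list(s1$truth$de_up, s1$truth$de_down, s1$truth$reversion, mod)
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(cats[[i]], cats[[j]]), 0)
  expect_true(all(s1$truth$module_edges$gene_a %in%
                  rownames(s1$study$values)))
})

test_that("planted shift is recovered as the generative group-mean difference", {
  # Monte-Carlo: average (mean P - mean C) over planted up genes and
  # replicates must sit within 3 standard errors of the planted log2FC
  reps <- 100
  diffs <- numeric(0)
  for (b in seq_len(reps)) {
    sim <- small_sim(seed = 1000 + b, n_genes = 40, de_fraction = 0.25,
                     de_log2fc = 2, noise_sd = 0.5, n_reversion_genes = 0)
    v <- sim$study$values
    g <- sim$study$groups
    up <- sim$truth$de_up
    diffs <- c(diffs, rowMeans(v[up, g == "P", drop = FALSE]) -
                      rowMeans(v[up, g == "C", drop = FALSE]))
  }
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 2), 3 * se)
})

test_that("a patient-only module induces the planted correlation structure", {
  sim <- simulate_expression_study(sim_config(
    n_genes = 60, n_per_group = 20, seed = 5, de_fraction = 0,
    n_reversion_genes = 0,
    module_specs = list(module_spec(10, 0.9, active = "P"))))
  mod <- unique(c(sim$truth$module_edges$gene_a,
                  sim$truth$module_edges$gene_b))
  v <- sim$study$values
  g <- sim$study$groups
  rP <- cor(t(v[mod, g == "P"]))
  rC <- cor(t(v[mod, g == "C"]))
  offdiag <- function(m) m[lower.tri(m)]
  expect_gt(median(offdiag(rP)), 0.7)
  expect_lt(median(abs(offdiag(rC))), 0.4)
})

test_that("downstream DE recovery improves with sample size", {
  recall <- sapply(c(4, 10), function(n) {
    sim <- simulate_expression_study(sim_config(
      n_genes = 150, n_per_group = n, seed = 7, de_fraction = 0.1,
      de_log2fc = 1, noise_sd = 1, n_reversion_genes = 0))
    fit <- rank_products(sim$study, "P-C", n_permutations = 60, seed = 70)
    calls <- call_significant(fit)
    truth <- c(sim$truth$de_up, sim$truth$de_down)
    mean(truth %in% c(calls$up$gene, calls$down$gene))
  })
  expect_gt(recall[2], recall[1])
})

test_that("simulated CT tables encode the requested fold changes", {
  # noiseless FC = 1: patient delta-CT equals the control-mean delta-CT
  t1 <- simulate_ct_table(1, 4, true_fold_changes = 1, ct_noise_sd = 0,
                          seed = 2)
  dct <- t1$ct_target - t1$ct_reference
  expect_equal(unname(dct[t1$group == "patient"]),
               rep(mean(dct[t1$group == "control"]), 4))
  # noiseless FC = 2: ddCt is exactly -1
  t2 <- simulate_ct_table(1, 4, true_fold_changes = 2, ct_noise_sd = 0,
                          seed = 2)
  dct2 <- t2$ct_target - t2$ct_reference
  ddct <- dct2[t2$group == "patient"] - mean(dct2[t2$group == "control"])
  expect_equal(unname(ddct), rep(-1, 4))
  expect_error(simulate_ct_table(1, 4, true_fold_changes = -2), "positive")
})

test_that("noisy CT recovery: geometric-mean fold change is unbiased", {
  fcs <- sapply(1:400, function(b) {
    tab <- simulate_ct_table(1, 6, true_fold_changes = 2, ct_noise_sd = 0.3,
                             seed = b)
    dct <- tapply(tab$ct_target - tab$ct_reference, tab$sample, mean)
    grp <- tapply(tab$group, tab$sample, `[`, 1)
    ddct <- dct - mean(dct[grp == "control"])
    exp(mean(log(2^(-ddct[grp == "patient"]))))
  })
  expect_lt(abs(exp(mean(log(fcs))) - 2) / 2, 0.05)
})

test_that("phenotype table plants the requested correlations and no others", {
  expect_error(simulate_phenotype_table(8, 3, list(c(1, 2, 1))), "< 1")
  expect_error(simulate_phenotype_table(8, 3,
                 list(c(1, 2, 0.5), c(2, 1, 0.4))), "duplicate")
  rs <- sapply(1:500, function(b)
    cor(simulate_phenotype_table(8, 2, list(c(1, 2, 0.9)), seed = b))[1, 2])
  expect_gt(mean(rs), 0.8)
  expect_lt(mean(rs), 0.95)
  # null table: few strong empirical correlations at n = 30
  X <- simulate_phenotype_table(30, 12, seed = 99)
  rr <- abs(cor(X)[lower.tri(diag(12))])
  expect_gte(mean(rr < 0.7), 0.9)
})
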