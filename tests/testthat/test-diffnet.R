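test_that("pearson_with_pvalue matches its closed form and guards inputs", {
  x <- c(1, 2, 3, 4, 5, 6)
  res <- pearson_with_pvalue(x, x)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  res2 <- pearson_with_pvalue(x, -x)
  expect_equal(res2$r, -1)
  expect_equal(res2$p, 0)

  set.seed(21)
  a <- rnorm(6); b <- rnorm(6)
  res3 <- pearson_with_pvalue(a, b)
  ct <- cor.test(a, b)            # independent reference implementation
  expect_equal(res3$r, unname(ct$estimate))
  expect_equal(res3$p, ct$p.value)

  expect_error(pearson_with_pvalue(1:2, 1:2), "fewer than 3")
  expect_error(pearson_with_pvalue(rep(1, 5), rnorm(5)), "zero variance")
  # pairwise deletion of missing values
  res4 <- pearson_with_pvalue(c(a, NA), c(b, 1))
  expect_equal(res4$n, 6)
})

test_that("analytic p agrees with a permutation oracle for random vectors", {
  set.seed(31)
  x <- rnorm(6); y <- rnorm(6)
  p_perm <- perm_cor_pvalue(x, y, n_perm = 1e5, seed = 2)
  # the permutation distribution at n = 6 is supported on at most 6!/2
  # points, so agreement is bounded by its granularity
  expect_lt(abs(pearson_with_pvalue(x, y)$p - p_perm),
            0.02 + 2 / factorial(6))
})

diag_study <- function() {
  # engineered correlation patterns over 4 panel genes, n = 6 per group:
  # in P:  B tracks A exactly; D tracks C exactly
  # in C:  B is noise;        D tracks C exactly but with flipped sign
  base <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(A = c(base, base),
             B = c(base, c(2, 1, 4, 3, 6, 5) + c(0.3, -0.2, 0.1, 0.25, -0.15, 0)),
             C = c(base + 0.5, base),
             D = c(base + 1, -base))
  colnames(m) <- c(paste0("p", 1:6), paste0("c", 1:6))
  expression_study(m, setNames(rep(c("P", "C"), each = 6), colnames(m)))
}

test_that("edges are classified by cross-group agreement", {
  net <- build_group_network(diag_study(), c("A", "B", "C", "D"),
                             r_min = 0.8, p_max = 0.005)
  e <- net$edges
  key <- paste(e$gene_a, e$gene_b)
  expect_equal(e$class[key == "A B"], "patient_only")
  expect_equal(e$class[key == "C D"], "shared_discordant")
  expect_equal(e$class[key == "A C"], "shared_concordant")
  expect_true(all(e$degenerate[key %in% c("A C", "C D")]))
  # classes partition retained edges
  expect_equal(sum(summary(net)), nrow(e))
  expect_error(build_group_network(diag_study(), c("A", "ZZZ")), "ZZZ")
})

test_that("swapping group labels swaps patient_only and control_only", {
  sim <- simulate_expression_study(sim_config(
    n_genes = 40, seed = 9, de_fraction = 0, n_reversion_genes = 0,
    module_specs = list(module_spec(6, 0.95, active = "P"),
                        module_spec(6, 0.95, active = "C"))))
  panel <- unique(c(sim$truth$module_edges$gene_a,
                    sim$truth$module_edges$gene_b))
  n1 <- build_group_network(sim$study, panel, "P", "C")
  n2 <- build_group_network(sim$study, panel, "C", "P")
  s1 <- summary(n1); s2 <- summary(n2)
  expect_equal(unname(s1["patient_only"]), unname(s2["control_only"]))
  expect_equal(unname(s1["control_only"]), unname(s2["patient_only"]))
  expect_equal(unname(s1["shared_concordant"]), unname(s2["shared_concordant"]))
  expect_equal(unname(s1["shared_discordant"]), unname(s2["shared_discordant"]))
})

test_that("module detection sharpens as group size grows", {
  recall_at <- function(n) {
    sim <- simulate_expression_study(sim_config(
      n_genes = 40, n_per_group = n, seed = 13, de_fraction = 0,
      n_reversion_genes = 0,
      module_specs = list(module_spec(8, 0.95, active = "P"))))
    panel <- unique(c(sim$truth$module_edges$gene_a,
                      sim$truth$module_edges$gene_b))
    net <- build_group_network(sim$study, panel)
    mean(net$edges$class == "patient_only") * nrow(net$edges) /
      nrow(sim$truth$module_edges)
  }
  expect_gt(recall_at(20), recall_at(4))
})

test_that("the phenotype screen flags duplicated variables as degenerate", {
  X <- simulate_phenotype_table(10, 3, seed = 4)
  X <- cbind(X, v4 = X[, 1])
  hits <- phenotype_correlation_screen(X)
  dup <- hits[hits$variable_a == "v1" & hits$variable_b == "v4", ]
  expect_equal(dup$r, 1)
  expect_true(dup$degenerate)
})

test_that("the phenotype screen has power at R=0.9 and controls null retention", {
  kept_alt <- kept_null <- logical(200)
  for (b in 1:200) {
    Xa <- simulate_phenotype_table(8, 2, list(c(1, 2, 0.9)), seed = b)
    ha <- phenotype_correlation_screen(Xa)
    kept_alt[b] <- nrow(ha[ha$variable_a == "v1" & ha$variable_b == "v2", ]) > 0
    Xn <- simulate_phenotype_table(8, 2, seed = 5000 + b)
    kept_null[b] <- nrow(phenotype_correlation_screen(Xn)) > 0
  }
  # the exact power of the |R|>0.7 & p<0.05 rule at n = 8, rho = 0.9 is
  # 0.944 (20,000-draw oracle); 0.89 allows three Monte-Carlo SEs
  expect_gte(mean(kept_alt), 0.89)
  expect_lte(mean(kept_null), 0.10)
})

test_that("variables with too few observations are excluded with a warning", {
  X <- simulate_phenotype_table(8, 3, seed = 6)
  X[3:8, 2] <- NA
  expect_warning(res <- phenotype_correlation_screen(X), "v2")
  expect_false(any(c(res$variable_a, res$variable_b) == "v2"))
})
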