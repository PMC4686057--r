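# shared fixture builders for the test suite

tiny_study <- function(values, groups) {
  expression_study(values, groups)
}

# a minimal 4-group study built by the generator, cached per options
small_sim <- function(seed = 1, n_genes = 300, ...) {
  simulate_expression_study(sim_config(n_genes = n_genes, seed = seed, ...))
}

identity_annotation <- function(study) {
  stats::setNames(rownames(study$values), rownames(study$values))
}

# gene-level contrast result straight from a data frame spec
cr_from_df <- function(name, genes, fc, pfp = rep(0.01, length(genes))) {
  up <- data.frame(gene = genes[fc > 0], fc = fc[fc > 0],
                   pfp = pfp[fc > 0])
  down <- data.frame(gene = genes[fc < 0], fc = fc[fc < 0],
                     pfp = pfp[fc < 0])
  contrast_result(name, up, down)
}

# brute-force two-sided permutation p-value for a Pearson correlation
perm_cor_pvalue <- function(x, y, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  r_obs <- abs(cor(x, y))
  n <- length(y)
  perm <- replicate(n_perm, abs(cor(x, y[sample.int(n)])))
  mean(perm >= r_obs - 1e-12)
}

# reference set of signed fold-change pairs (treatment contrast P_AA-P,
# disease contrast P-C) from the fibroblast ascorbic-acid reversion screen;
# every pair flips sign and several have |FC| < 1.5, exercising the absence
# of a magnitude filter
reversion_reference <- data.frame(
  gene = c("HLA-DRA", "KRTAP1-5", "EVI2A", "TNFRSF11B", "KRT19", "DUSP1",
           "SEMA3B", "GRIA1", "HMGA1", "FOS", "TIMP3", "SLC47A1", "GFRA1",
           "FXYD5", "TNXB", "TRIL", "ELN", "LCTL", "TNC", "C1QTNF3", "OGN",
           "ARHGAP28", "C5orf13", "COL1A1", "LRRC15", "DPT", "FGD6", "GNB4",
           "ANGPTL1", "ARRDC4", "CSRP2", "ADAM19", "COL10A1", "ACVR2A",
           "PDGFD", "VCAN", "IGF1", "NPNT", "IGSF10"),
  fc_treatment = c(-2.0799, -2.1133, -1.3430, -1.4997, -1.3663, -1.3470,
                   -1.4063, -2.3154, -1.3774, -1.7687, -1.3988, -1.3180,
                   -1.5015, -1.4225, -1.5475, 2.2708, 1.6928, 1.3947,
                   1.4138, 2.2280, 2.3625, 1.5783, 1.4576, 1.6571, 1.7660,
                   2.1617, 1.4797, 1.6055, 1.5504, 1.4529, 1.4479, 1.3157,
                   2.4221, 1.5374, 1.7902, 1.4575, 1.5920, 1.5610, 1.4776),
  fc_disease = c(2.3098, 2.1484, 2.1085, 2.0947, 1.9729, 1.9561, 1.8835,
                 1.8560, 1.7728, 1.7060, 1.6497, 1.6351, 1.6309, 1.5697,
                 1.7728, -2.2650, -2.1487, -2.1322, -2.0623, -2.0488,
                 -2.0416, -1.9912, -1.9893, -1.9391, -1.8854, -1.8734,
                 -1.8577, -1.8471, -1.8420, -1.8416, -1.8146, -1.7809,
                 -1.7746, -1.7553, -1.7188, -1.6998, -1.6075, -1.5337,
                 -1.4192))
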