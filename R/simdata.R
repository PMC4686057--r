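#' Configuration for the synthetic expression-study generator
#'
#' Describes a four-arm fibroblast study (patients `P`, controls `C`, and
#' their ascorbic-acid-treated counterparts `P_AA`, `C_AA`) with planted
#' differential expression, treatment-reversion genes and group-specific
#' co-expression modules. Defaults mirror the design the generator emulates:
#' 6 cell lines per arm, Gaussian log2-scale noise, a modest fraction of
#' differentially expressed genes at log2 fold change 2.
#'
#' Planted categories are disjoint: the first `de_fraction * n_genes` genes
#' carry the disease effect (half up, half down in patients, persisting under
#' treatment), the next `n_reversion_genes` are shifted in untreated patients
#' only (ascorbic acid returns them to the control baseline, so their fold
#' change flips sign between the P-C and P_AA-P contrasts), then module genes,
#' then unaffected genes.
#'
#' @param n_genes number of genes (probesets) to simulate.
#' @param n_per_group samples per group.
#' @param group_names the four ordered group labels.
#' @param de_fraction proportion of genes with a planted disease effect.
#' @param de_log2fc magnitude of the planted shift, log2 units (> 0).
#' @param n_reversion_genes number of planted treatment-reversion genes.
#' @param module_specs list of [module_spec()] co-expression modules.
#' @param noise_sd SD of i.i.d. Gaussian noise on the log2 scale (>= 0;
#'   0 gives the deterministic zero-noise limit).
#' @param baseline_mean,baseline_sd mean and SD of the per-gene baseline
#'   log2 expression, drawn once and shared by all four groups.
#' @param seed integer seed; the generator is fully reproducible given the
#'   seed and draws its random streams in a fixed order
#'   (baseline, effects, modules, noise).
#' @return A list of class `sim_config`.
#' @seealso [simulate_expression_study()]
#' @export
sim_config <- function(n_genes = 2000,
                       n_per_group = 6,
                       group_names = c("P", "C", "P_AA", "C_AA"),
                       de_fraction = 0.05,
                       de_log2fc = 2,
                       n_reversion_genes = 20,
                       module_specs = list(),
                       noise_sd = 0.5,
                       baseline_mean = 7,
                       baseline_sd = 2,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_per_group = as.integer(n_per_group),
              group_names = group_names,
              de_fraction = de_fraction,
              de_log2fc = de_log2fc,
              n_reversion_genes = as.integer(n_reversion_genes),
              module_specs = module_specs,
              noise_sd = noise_sd,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_genes < 1) stop("config error: n_genes must be positive")
  if (cfg$n_per_group < 1) stop("config error: n_per_group must be positive")
  if (length(cfg$group_names) != 4 || anyDuplicated(cfg$group_names))
    stop("config error: group_names must be four distinct labels")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("config error: de_fraction must be in [0,1]")
  if (cfg$de_log2fc <= 0) stop("config error: de_log2fc must be > 0")
  if (cfg$n_reversion_genes < 0)
    stop("config error: n_reversion_genes must be >= 0")
  if (cfg$noise_sd < 0) stop("config error: noise_sd must be >= 0")
  if (cfg$baseline_sd <= 0) stop("config error: baseline_sd must be > 0")
  for (m in cfg$module_specs) {
    if (!inherits(m, "module_spec"))
      stop("config error: module_specs must be built with module_spec()")
  }
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  n_mod <- sum(vapply(cfg$module_specs, function(m) m$n_genes, 0))
  if (n_de + cfg$n_reversion_genes + n_mod > cfg$n_genes)
    stop("config error: planted DE, reversion and module genes exceed n_genes")
  invisible(cfg)
}

#' Specify one planted co-expression module
#'
#' A module is a block of genes sharing one latent factor. In each group
#' where the module is active, gene g gets a loading of magnitude
#' `b = noise_sd * sqrt(r / (1 - r))` on the group's factor values, so that
#' the pairwise population Pearson correlation between same-sign genes is
#' exactly `r` after observation noise is added. `sign` per active group is
#' either `+1` (all loadings positive, all planted edges positive) or `-1`
#' (alternating loadings, so edges between opposite-parity genes are
#' negative) — the latter creates sign-discordant edges across groups.
#'
#' @param n_genes genes in the module.
#' @param r target within-group pairwise correlation, in (-1, 1), nonzero.
#' @param active character vector of groups in which the factor is active.
#' @param sign `+1` or `-1` per active group (recycled).
#' @return A list of class `module_spec`.
#' @export
module_spec <- function(n_genes, r, active = "P", sign = 1) {
  if (abs(r) >= 1 || r == 0)
    stop("config error: module correlation must be in (-1,1) and nonzero")
  if (n_genes < 2) stop("config error: a module needs at least 2 genes")
  sign <- rep_len(sign, length(active))
  if (!all(sign %in% c(-1, 1)))
    stop("config error: module sign must be +1 or -1")
  structure(list(n_genes = as.integer(n_genes), r = r,
                 active = active, sign = sign),
            class = "module_spec")
}

#' Simulate a four-arm fibroblast expression study with planted truth
#'
#' Generates a log2-scale gene-by-sample matrix under the model
#' `baseline + group effect + module factor + noise`, together with a
#' `planted_truth` record of which genes carry which planted structure.
#' Random draws follow a fixed stream order (baseline, effects, modules,
#' noise) so that the output is bit-reproducible given `config$seed`.
#'
#' Group effects: planted DE genes are shifted by `+/- de_log2fc` in both
#' patient arms (`P`, `P_AA`) relative to both control arms; reversion genes
#' are shifted in `P` only, so that treatment restores the control baseline
#' and the signed fold change flips between the P-C and P_AA-P contrasts
#' with magnitude `>= de_log2fc` in both.
#'
#' @param config a [sim_config()].
#' @return A list with elements `study` (an [expression_study()]) and
#'   `truth` (class `planted_truth`: character vectors `de_up`, `de_down`,
#'   `reversion`, and `module_edges`, a data frame with columns
#'   `gene_a`, `gene_b`, `group`, `sign`).
#' @examples
#' sim <- simulate_expression_study(sim_config(n_genes = 200, seed = 7))
#' sim$study
#' length(sim$truth$de_up)
#' @export
simulate_expression_study <- function(config) {
  validate_sim_config(config)
  cfg <- config
  G <- cfg$n_genes
  n <- cfg$n_per_group
  genes <- sprintf("g%05d", seq_len(G))
  groups <- rep(cfg$group_names, each = n)
  samples <- paste0(groups, "_", rep(seq_len(n), times = 4))
  grp <- stats::setNames(groups, samples)

  n_de <- round(cfg$de_fraction * G)
  n_up <- ceiling(n_de / 2)
  de_up <- genes[seq_len(n_up)]
  de_down <- genes[seq_len(n_de)[-seq_len(n_up)]]
  rev_idx <- n_de + seq_len(cfg$n_reversion_genes)
  reversion <- genes[rev_idx]
  mod_sizes <- vapply(cfg$module_specs, function(m) m$n_genes, 0L)
  mod_start <- n_de + cfg$n_reversion_genes
  mod_idx <- lapply(seq_along(mod_sizes), function(k) {
    mod_start + sum(mod_sizes[seq_len(k - 1)]) + seq_len(mod_sizes[k])
  })

  set.seed(cfg$seed)
  # stream 1: baseline, one draw per gene, shared by all groups; in the
  # deterministic zero-noise limit the baseline is snapped to a 2^-10 grid
  # so planted shifts survive floating-point subtraction exactly and
  # equally-shifted genes tie bitwise
  baseline <- stats::rnorm(G, cfg$baseline_mean, cfg$baseline_sd)
  if (cfg$noise_sd == 0) baseline <- round(baseline * 1024) / 1024
  M <- matrix(baseline, G, length(samples),
              dimnames = list(genes, samples))

  # stream 2: effects (signs for DE and reversion genes)
  pat_cols <- grp %in% cfg$group_names[c(1, 3)]   # P, P_AA
  p_cols <- grp == cfg$group_names[1]             # P only
  if (n_de > 0) {
    de_sign <- c(rep(1, n_up), rep(-1, n_de - n_up))
    M[seq_len(n_de), pat_cols] <- M[seq_len(n_de), pat_cols] +
      de_sign * cfg$de_log2fc
  }
  if (cfg$n_reversion_genes > 0) {
    rev_sign <- rep_len(c(1, -1), cfg$n_reversion_genes)
    M[rev_idx, p_cols] <- M[rev_idx, p_cols] + rev_sign * cfg$de_log2fc
  }

  # stream 3: modules — latent factor per module, loadings per gene x group
  module_edges <- NULL
  for (k in seq_along(cfg$module_specs)) {
    m <- cfg$module_specs[[k]]
    idx <- mod_idx[[k]]
    b <- cfg$noise_sd * sqrt(abs(m$r) / (1 - abs(m$r)))
    fac <- stats::rnorm(length(samples))          # factor value per sample
    for (a in seq_along(m$active)) {
      cols <- grp == m$active[a]
      if (!any(cols)) stop("config error: module active group not in design")
      load_sign <- if (m$sign[a] > 0) rep(1, length(idx))
                   else rep_len(c(1, -1), length(idx))
      if (m$r < 0) load_sign <- load_sign * rep_len(c(1, -1), length(idx))
      M[idx, cols] <- M[idx, cols] +
        (b * load_sign) %o% fac[cols]
      pr <- t(utils::combn(seq_along(idx), 2))
      module_edges <- rbind(module_edges, data.frame(
        gene_a = genes[idx[pr[, 1]]],
        gene_b = genes[idx[pr[, 2]]],
        group = m$active[a],
        sign = load_sign[pr[, 1]] * load_sign[pr[, 2]]))
    }
  }
  if (is.null(module_edges))
    module_edges <- data.frame(gene_a = character(), gene_b = character(),
                               group = character(), sign = numeric())

  # stream 4: observation noise
  if (cfg$noise_sd > 0)
    M <- M + matrix(stats::rnorm(length(M), 0, cfg$noise_sd), nrow(M))

  truth <- structure(list(de_up = de_up, de_down = de_down,
                          reversion = reversion,
                          module_edges = module_edges),
                     class = "planted_truth")
  list(study = expression_study(M, grp), truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", length(x$de_up), "up,", length(x$de_down), "down,",
      length(x$reversion), "reversion genes;",
      nrow(x$module_edges), "module edges\n")
  invisible(x)
}

#' Simulate a CT table for delta-delta-Ct recovery experiments
#'
#' Builds raw qPCR cycle-threshold (CT) measurements for `n_targets` assays
#' in a patient and a control group, normalized against a single reference
#' (housekeeping) assay, such that the expected relative expression
#' `2^-ddCt` of the patient group equals `true_fold_changes` per target.
#'
#' @param n_targets number of target assays.
#' @param n_samples_per_group samples in each of the two groups.
#' @param true_fold_changes positive linear fold changes, one per target.
#' @param ct_noise_sd SD of Gaussian noise added to each target CT (cycles).
#' @param seed integer seed.
#' @return A `data.frame` with columns `sample`, `group` (`patient` /
#'   `control`), `target`, `reference`, `ct_target`, `ct_reference`.
#' @export
simulate_ct_table <- function(n_targets = 2, n_samples_per_group = 6,
                              true_fold_changes = rep(2, n_targets),
                              ct_noise_sd = 0.2, seed = 1L) {
  if (length(true_fold_changes) != n_targets)
    stop("one true fold change per target is required")
  if (any(true_fold_changes <= 0))
    stop("fold changes must be positive")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  set.seed(as.integer(seed))
  n <- n_samples_per_group
  samples <- c(paste0("pat_", seq_len(n)), paste0("ctl_", seq_len(n)))
  group <- rep(c("patient", "control"), each = n)
  ct_ref <- stats::rnorm(2 * n, 20, 0.5)    # per-sample reference CT
  out <- NULL
  for (t in seq_len(n_targets)) {
    dct0 <- 5                                # control-group delta-CT baseline
    dct <- dct0 - ifelse(group == "patient", log2(true_fold_changes[t]), 0)
    noise <- if (ct_noise_sd > 0) stats::rnorm(2 * n, 0, ct_noise_sd) else 0
    out <- rbind(out, data.frame(
      sample = samples, group = group,
      target = paste0("target_", t), reference = "ref",
      ct_target = ct_ref + dct + noise,
      ct_reference = ct_ref))
  }
  rownames(out) <- NULL
  out
}

#' Simulate a sample-by-variable phenotype table with planted correlations
#'
#' Independent standard-normal variables except for the requested pairs,
#' which get the stated population Pearson correlation. Used to exercise the
#' phenotype correlation screen.
#'
#' @param n_samples rows.
#' @param n_variables columns.
#' @param correlated_pairs list of `c(i, j, r)` triples with `|r| < 1`;
#'   variable `j` is rebuilt as `r * x_i + sqrt(1 - r^2) * z`.
#' @param seed integer seed.
#' @return numeric matrix `n_samples x n_variables` with variable names
#'   `v1..vK` and sample rownames.
#' @export
simulate_phenotype_table <- function(n_samples, n_variables,
                                     correlated_pairs = list(),
                                     seed = 1L) {
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(n_samples * n_variables), n_samples, n_variables,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("v", seq_len(n_variables))))
  seen <- character()
  for (p in correlated_pairs) {
    if (length(p) != 3) stop("each pair spec must be c(i, j, r)")
    i <- p[1]; j <- p[2]; r <- p[3]
    if (abs(r) >= 1) stop("|target correlation| must be < 1")
    key <- paste(sort(c(i, j)), collapse = "-")
    if (key %in% seen) stop("duplicate pair specification: ", key)
    seen <- c(seen, key)
    X[, j] <- r * X[, i] + sqrt(1 - r^2) * stats::rnorm(n_samples)
  }
  X
}
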