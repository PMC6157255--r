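# Shared fixtures: tiny hand-built genotype matrices and small simulated
# cohorts used across the module tests.

make_geno <- function(dosages, chrom = NULL, pos = NULL, ids = NULL) {
  d <- as.matrix(dosages)
  m <- ncol(d)
  ids <- ids %||% sprintf("s%03d", seq_len(m))
  samples <- rownames(d) %||% sprintf("I%03d", seq_len(nrow(d)))
  rownames(d) <- samples
  colnames(d) <- ids
  structure(list(dosages = d, snp_ids = ids,
                 chrom = chrom %||% rep(1L, m),
                 pos = pos %||% (seq_len(m) * 1000L),
                 ref = rep("A", m), alt = rep("G", m),
                 sample_ids = samples),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_families = 30L, sibs_per_family = 2:3, n_snps = 60L,
                   n_cpgs = 30L, missing_rate = 0.02, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

null_cfg <- function(...) {
  small_cfg(n_causal_snps = 0L, n_causal_cpgs = 0L, snp_effect = 0,
            cpg_effect = 0, covariate_effects = c(age = 0, sex = 0, smoking = 0),
            polygenic_sd = 0, ...)
}

# Independent brute-force two-sided Wilcoxon rank-sum p-value: enumerates
# every split of the raw pooled values (recomputing mid-ranks from scratch)
# rather than reusing the package's statistic path.
brute_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  stat <- function(idx) sum(rank(pooled)[idx])
  obs <- stat(seq_len(n1))
  ew <- n1 * (n + 1) / 2
  splits <- utils::combn(n, n1)
  vals <- apply(splits, 2L, stat)
  mean(abs(vals - ew) >= abs(obs - ew) - 1e-9)
}
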