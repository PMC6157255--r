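# Synthetic sibship-cohort generator.

test_that("family structure counts, determinism and degenerate input", {
  fam <- simulate_families(sim_config(n_families = 2L, sibs_per_family = 3L))
  expect_length(fam$sample_ids, 6L)
  expect_equal(length(unique(fam$family_ids)), 2L)
  expect_false(any(duplicated(fam$sample_ids)))

  cfg <- sim_config(n_families = 150L, sibs_per_family = 2:4, seed = 9L)
  expect_identical(simulate_families(cfg), simulate_families(cfg))

  expect_error(sim_config(n_families = 0L), "n_families")
  expect_error(sim_config(sibs_per_family = 0L), "sibs_per_family")
  expect_error(sim_config(cpg_family_icc = 1), "cpg_family_icc")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("sibling genotypes are Mendelian-consistent with their founders", {
  cfg <- small_cfg(n_snps = 200L, include_founders = TRUE, missing_rate = 0)
  fam <- simulate_families(cfg)
  g <- simulate_genotypes(fam, cfg)
  sib <- fam$roles == "sibling"
  for (f in fam$families) {
    founders <- g$dosages[fam$family_ids == f & !sib, , drop = FALSE]
    lo <- (founders[1, ] == 2) + (founders[2, ] == 2)
    hi <- (founders[1, ] >= 1) + (founders[2, ] >= 1)
    kids <- g$dosages[fam$family_ids == f & sib, , drop = FALSE]
    expect_true(all(sweep(kids, 2L, lo, ">=") & sweep(kids, 2L, hi, "<=")))
  }
  # forced-cross corollary: AA x aa founders always give heterozygous sibs
  forced <- which(lo == 1 & hi == 1)  # from the last family checked
  if (length(forced)) expect_true(all(kids[, forced] == 1))
})

test_that("sib dosage mean matches the binomial expectation 2*MAF", {
  cfg <- sim_config(n_families = 250L, sibs_per_family = 2L, n_snps = 40L,
                    maf_range = c(0.3, 0.3), missing_rate = 0, seed = 5L)
  g <- simulate_genotypes(simulate_families(cfg), cfg)
  n <- nrow(g$dosages)
  se <- sqrt(2 * 0.3 * 0.7 / n)  # per-SNP SE of the mean dosage
  mean_dos <- colMeans(g$dosages)
  expect_true(mean(abs(mean_dos - 0.6) <= 3 * se) > 0.95)
  expect_lt(abs(mean(mean_dos) - 0.6), 3 * se / sqrt(40))
})

test_that("methylation betas live in (0,1) and honor the family ICC", {
  cfg0 <- small_cfg(cpg_family_icc = 0, n_cpgs = 50L)
  fam <- simulate_families(cfg0)
  m0 <- simulate_methylation(fam, cfg0)
  expect_true(all(m0$betas > 0 & m0$betas < 1))

  # ANOVA ICC estimator on M-values, averaged over sites
  anova_icc <- function(mv, famid) {
    sizes <- table(famid)
    n0 <- (sum(sizes) - sum(sizes^2) / sum(sizes)) / (length(sizes) - 1)
    apply(mv, 2L, function(v) {
      fit <- stats::aov(v ~ factor(famid))
      ms <- summary(fit)[[1]]$`Mean Sq`
      (ms[1] - ms[2]) / (ms[1] + (n0 - 1) * ms[2])
    })
  }
  cfg5 <- sim_config(n_families = 200L, sibs_per_family = 3L, n_cpgs = 60L,
                     n_snps = 10L, cpg_family_icc = 0.5, seed = 21L)
  fam5 <- simulate_families(cfg5)
  m5 <- simulate_methylation(fam5, cfg5)
  icc5 <- anova_icc(log2(m5$betas / (1 - m5$betas)), fam5$family_ids)
  expect_lt(abs(mean(icc5) - 0.5), 0.05)
  icc0 <- anova_icc(log2(m0$betas / (1 - m0$betas)), fam$family_ids)
  expect_lt(abs(mean(icc0)), 0.1)
})

test_that("phenotype: responder changes are below -30% and status matches truth", {
  cfg <- small_cfg()
  co <- simulate_cohort(cfg)
  r <- derive_response(co$tg)
  expect_identical(r$response, co$truth$response)
  expect_true(all(r$change[r$response == 1] < -0.30))
  expect_true(all(r$change[r$response == 0] >= -0.30))
})

test_that("responder fraction is calibrated to the target over replicates", {
  reps <- 50L
  fracs <- vapply(seq_len(reps), function(i) {
    co <- simulate_cohort(small_cfg(n_snps = 30L, n_cpgs = 10L, seed = 100L + i))
    mean(co$truth$response)
  }, numeric(1))
  n_per <- 75  # ~30 families x 2.5 sibs
  se <- sqrt(0.576 * 0.424 / (reps * n_per))
  expect_lt(abs(mean(fracs) - 0.576), 2 * se + 0.01)
})

test_that("cohort composition is aligned, seeded and records its truth", {
  cfg <- small_cfg(n_snps = 80L, n_cpgs = 40L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  n <- length(co1$families$sample_ids)
  expect_equal(dim(co1$genotypes$dosages), c(n, 80L))
  expect_equal(dim(co1$methylation$betas), c(n, 40L))
  expect_identical(rownames(co1$genotypes$dosages), co1$covariates$sample_id)
  expect_length(co1$truth$causal_snps, cfg$n_causal_snps)
  expect_true(all(co1$truth$causal_cpgs %in% co1$methylation$cpg_ids))
})

test_that("all-null configuration yields uniform association p-values", {
  co <- simulate_cohort(null_cfg(n_families = 120L, sibs_per_family = 2L,
                                 n_snps = 150L, missing_rate = 0, seed = 77L))
  y <- co$truth$response
  sc <- gee_scan(y, co$genotypes, co$families$family_ids)
  expect_gt(stats::ks.test(sc$p, "punif")$p.value, 0.01)
})
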