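# Family-adjusted marker screening: GEE logistic scan and kinship-LMM scan.

test_that("GEE with singleton clusters equals the logistic MLE with robust SE", {
  set.seed(21)
  n <- 400
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(drop(x %*% c(-0.4, 0.7, -0.6))))
  fit <- gee_logistic(y, x, clusters = seq_len(n))
  gl <- stats::glm(y ~ x[, 2] + x[, 3], family = binomial())
  expect_lt(max(abs(fit$coefficients - coef(gl))), 1e-6)
  expect_equal(fit$alpha, 0)
  vs <- sandwich::sandwich(gl)
  expect_lt(max(abs(fit$robust_cov - vs)), 1e-6)
})

test_that("a zero column yields slope 0 and the moment working correlation", {
  set.seed(22)
  fam <- rep(1:80, each = 3)
  u <- rnorm(80)[fam]
  y <- rbinom(240, 1, plogis(0.3 + u))
  x <- cbind(rep(1, 240), 0)
  fit <- gee_logistic(y, x, fam)
  expect_equal(unname(fit$coefficients[2]), 0)
  # independent moment oracle at the fitted mean
  mu <- plogis(fit$coefficients[1])
  r <- (y - mu) / sqrt(mu * (1 - mu))
  pair_sum <- sum(tapply(r, fam, function(v) (sum(v)^2 - sum(v^2)) / 2))
  alpha_oracle <- pair_sum / (80 * 3 - 2)
  expect_equal(fit$alpha, alpha_oracle, tolerance = 1e-6)
  expect_gt(fit$alpha, 0)  # family random effect induces positive correlation
})

test_that("gee_scan finds a planted SNP and is deterministic on duplicates", {
  cfg <- sim_config(n_families = 200L, sibs_per_family = 3L, n_snps = 120L,
                    n_cpgs = 5L, n_causal_snps = 1L, n_causal_cpgs = 0L,
                    snp_effect = 1.2, cpg_effect = 0,
                    covariate_effects = c(age = 0, sex = 0, smoking = 0),
                    polygenic_sd = 0.3, missing_rate = 0, seed = 61L)
  co <- simulate_cohort(cfg)
  y <- co$truth$response
  g <- co$genotypes
  # duplicate the causal SNP as an extra column
  ci <- match(co$truth$causal_snps, g$snp_ids)
  d <- cbind(g$dosages, dup = g$dosages[, ci])
  g2 <- make_geno(d, pos = c(g$pos, max(g$pos) + 1000L))
  res <- gee_scan(y, g2, co$families$family_ids)
  expect_equal(res$p[ci], res$p[121], tolerance = 1e-12)
  expect_equal(which.min(res$p[1:120]), ci)
  expect_true(all(abs(res$stat - res$beta / res$se) < 1e-12, na.rm = TRUE))
})

test_that("LMM REML handles degenerate inputs and recovers components", {
  set.seed(23)
  expect_error(lmm_reml_null(rep(1, 50), diag(50)), "constant")

  # identity kinship: only the total variance is identified
  y <- rnorm(80)
  f <- lmm_reml_null(y, diag(80))
  expect_false(f$identifiable)
  expect_equal(f$sigma_g2 + f$sigma_e2, var(y), tolerance = 1e-6)

  # sibling kinship, one replicate sanity check (full recovery is part of
  # the statistical acceptance checks)
  K <- kronecker(diag(150), matrix(c(1, 0.5, 0.5, 1), 2))
  g <- sqrt(0.5) * drop(crossprod(chol(K), rnorm(300)))
  yk <- g + rnorm(300, 0, sqrt(0.5))
  fk <- lmm_reml_null(yk, K)
  expect_true(fk$identifiable)
  expect_lt(abs(fk$sigma_g2 + fk$sigma_e2 - 1), 0.35)
  expect_gt(fk$sigma_g2, 0.05)
})

test_that("LMM scan with identity kinship equals per-site OLS", {
  set.seed(24)
  n <- 90
  y <- rnorm(n)
  m <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("c", 1:40)))
  res <- lmm_scan(y, m, k = diag(n))
  ols_p <- vapply(seq_len(40), function(j)
    summary(stats::lm(y ~ m[, j]))$coefficients[2, 4], numeric(1))
  expect_lt(max(abs(res$p - ols_p)), 1e-6)
  # constant site: effect 0, p 1
  m2 <- cbind(m, konst = 1)
  res2 <- lmm_scan(y, m2, k = diag(n))
  expect_equal(res2$beta[41], 0)
  expect_equal(res2$p[41], 1)
})

test_that("LMM scan is calibrated under family structure where OLS is not", {
  cfg <- sim_config(n_families = 150L, sibs_per_family = 3L, n_snps = 400L,
                    n_cpgs = 400L, n_causal_snps = 0L, n_causal_cpgs = 0L,
                    snp_effect = 0, cpg_effect = 0,
                    covariate_effects = c(age = 0, sex = 0, smoking = 0),
                    polygenic_sd = 1.0, cpg_family_icc = 0.5,
                    missing_rate = 0, seed = 71L)
  co <- simulate_cohort(cfg)
  y <- co$truth$response
  k <- kinship_grm(co$genotypes)
  res <- lmm_scan(y, co$methylation, k)
  lmm_rate <- mean(res$p < 0.05)
  ols_p <- apply(co$methylation$betas, 2L, function(v)
    summary(stats::lm(y ~ v))$coefficients[2, 4])
  ols_rate <- mean(ols_p < 0.05)
  # nominal 5%: the kinship LMM stays near it, naive OLS inflates
  expect_lt(lmm_rate, 0.09)
  expect_gt(ols_rate, lmm_rate)
})

test_that("planted CpG effect is the scan minimum", {
  cfg <- sim_config(n_families = 150L, sibs_per_family = 3L, n_snps = 20L,
                    n_cpgs = 150L, n_causal_snps = 0L, n_causal_cpgs = 1L,
                    snp_effect = 0, cpg_effect = 1.2,
                    covariate_effects = c(age = 0, sex = 0, smoking = 0),
                    polygenic_sd = 0.3, missing_rate = 0, seed = 81L)
  co <- simulate_cohort(cfg)
  k <- kinship_grm(co$genotypes)
  res <- lmm_scan(co$truth$response, co$methylation, k)
  expect_equal(res$marker_id[which.min(res$p)], co$truth$causal_cpgs)
})

test_that("select_markers applies a strict threshold with ordered output", {
  res <- data.frame(marker_id = c("m1", "m2", "m3"),
                    p = c(1e-5, 1e-4, 1e-3))
  expect_identical(select_markers(res, 1e-4), "m1")
  expect_identical(select_markers(data.frame(marker_id = letters[1:3],
                                             p = rep(0.5, 3))), character(0))
  resp <- data.frame(marker_id = c("b", "a", "c"), p = c(2e-5, 1e-5, 3e-5))
  expect_identical(select_markers(resp, 1e-4), c("a", "b", "c"))
  expect_identical(select_markers(resp[c(3, 1, 2), ], 1e-4), c("a", "b", "c"))
})
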