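# Synthetic family-cohort generator.
#
# Emulates a fenofibrate-style pharmacogenomic study on sibships: SNP dosages
# transmitted Mendelianly from two unobserved founders per family, CpG beta
# values with a family-level variance component, clinical covariates, and
# triglyceride (TG) measurements at four visits from which a binary drug
# response (TG drop of more than 30%) is derived.

#' Simulation configuration for a synthetic sibship cohort
#'
#' Bundles all knobs of the generator. Defaults describe a cohort of roughly
#' five hundred siblings in nuclear families with a responder fraction of
#' 57.6%, a handful of causal SNPs and CpG sites with moderate effects, and a
#' family-level (polygenic + shared environment) liability component.
#'
#' @param n_families Number of sibship families.
#' @param sibs_per_family Integer vector of allowed sibship sizes; each family
#'   draws its size uniformly from this set (a single value fixes the size).
#' @param n_snps,n_cpgs Number of SNPs / CpG sites to simulate.
#' @param maf_range Range (within (0, 0.5]) from which per-SNP founder minor
#'   allele frequencies are drawn uniformly.
#' @param n_causal_snps,n_causal_cpgs Number of markers with planted effects.
#' @param snp_effect Log-odds of response per alternate allele at each causal SNP.
#' @param cpg_effect Log-odds of response per SD of M-value at each causal CpG.
#' @param covariate_effects Named numeric vector with elements `age`, `sex`,
#'   `smoking`: log-odds per SD of age and per level of the binary codes.
#' @param polygenic_sd SD of the family-level liability component (log-odds scale).
#' @param cpg_family_icc Intraclass correlation of CpG M-values within family,
#'   in [0, 1).
#' @param target_response_rate Expected responder fraction in (0, 1).
#' @param missing_rate Fraction of genotype calls set missing, in [0, 1).
#' @param include_founders If `TRUE` the two founders per family enter the
#'   cohort alongside the siblings (default keeps sibships only).
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   configuration including this seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_families = 150L,
                       sibs_per_family = 2:4,
                       n_snps = 2000L,
                       n_cpgs = 1000L,
                       maf_range = c(0.05, 0.5),
                       n_causal_snps = 4L,
                       n_causal_cpgs = 4L,
                       snp_effect = 1.4,
                       cpg_effect = 1.0,
                       covariate_effects = c(age = 0.4, sex = 0.7, smoking = 0.9),
                       polygenic_sd = 0.5,
                       cpg_family_icc = 0.3,
                       target_response_rate = 0.576,
                       missing_rate = 0.01,
                       include_founders = FALSE,
                       seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              sibs_per_family = as.integer(sibs_per_family),
              n_snps = as.integer(n_snps), n_cpgs = as.integer(n_cpgs),
              maf_range = as.numeric(maf_range),
              n_causal_snps = as.integer(n_causal_snps),
              n_causal_cpgs = as.integer(n_causal_cpgs),
              snp_effect = snp_effect, cpg_effect = cpg_effect,
              covariate_effects = covariate_effects,
              polygenic_sd = polygenic_sd, cpg_family_icc = cpg_family_icc,
              target_response_rate = target_response_rate,
              missing_rate = missing_rate,
              include_founders = isTRUE(include_founders),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_families < 1L) stop("n_families must be >= 1", call. = FALSE)
  if (length(cfg$sibs_per_family) < 1L || any(cfg$sibs_per_family < 1L))
    stop("sibs_per_family must contain positive counts", call. = FALSE)
  if (cfg$n_snps < 1L || cfg$n_cpgs < 1L)
    stop("n_snps and n_cpgs must be >= 1", call. = FALSE)
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (cfg$n_causal_snps > cfg$n_snps) stop("n_causal_snps > n_snps", call. = FALSE)
  if (cfg$n_causal_cpgs > cfg$n_cpgs) stop("n_causal_cpgs > n_cpgs", call. = FALSE)
  if (cfg$cpg_family_icc < 0 || cfg$cpg_family_icc >= 1)
    stop("cpg_family_icc must lie in [0, 1)", call. = FALSE)
  if (cfg$target_response_rate <= 0 || cfg$target_response_rate >= 1)
    stop("target_response_rate must lie in (0, 1)", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (!all(c("age", "sex", "smoking") %in% names(cfg$covariate_effects)))
    stop("covariate_effects needs named elements age, sex, smoking", call. = FALSE)
  invisible(cfg)
}

#' Simulate the family structure of a sibship cohort
#'
#' Each family has two (unobserved by default) founders and a number of
#' siblings drawn from `sibs_per_family`. Only siblings enter the analysis
#' cohort unless `include_founders` is set in the configuration.
#'
#' @param config A [sim_config()].
#' @return A `family_structure`: list with `sample_ids`, `family_ids`, `roles`
#'   (founder/sibling) for the cohort, plus the per-family sibling counts.
#' @export
simulate_families <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    nf <- config$n_families
    sizes <- if (length(config$sibs_per_family) == 1L)
      rep(config$sibs_per_family, nf)
    else sample(config$sibs_per_family, nf, replace = TRUE)
    fam_ids <- sprintf("F%04d", seq_len(nf))
    sib_fam <- rep(fam_ids, sizes)
    sib_ids <- paste0(sib_fam, "_S", unlist(lapply(sizes, seq_len)))
    roles <- rep("sibling", length(sib_ids))
    if (config$include_founders) {
      fo_ids <- c(paste0(fam_ids, "_P1"), paste0(fam_ids, "_P2"))
      fo_fam <- rep(fam_ids, 2L)
      ord <- order(fo_fam)
      sib_ids <- c(sib_ids, fo_ids[ord])
      sib_fam <- c(sib_fam, fo_fam[ord])
      roles <- c(roles, rep("founder", 2L * nf))
    }
    structure(list(sample_ids = sib_ids, family_ids = sib_fam, roles = roles,
                   families = fam_ids, sib_counts = stats::setNames(sizes, fam_ids)),
              class = "family_structure")
  })
}

# Variant metadata shared by the genotype simulator and VCF writer: markers
# spread over the 22 autosomes with positions in increasing order.
sim_snp_map <- function(n_snps) {
  chrom <- sort(rep_len(1:22, n_snps))
  pos <- integer(n_snps)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    pos[idx] <- cumsum(sample(5000:50000, length(idx), replace = TRUE))
  }
  data.frame(snp_id = sprintf("snp%05d", seq_len(n_snps)),
             chrom = chrom, pos = pos,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Simulate genotype dosages by Mendelian transmission
#'
#' Per SNP, an alternate-allele frequency is drawn from `maf_range`; the two
#' founders of each family receive Hardy-Weinberg genotypes and each sibling
#' inherits one random allele from each founder, so full siblings share
#' alleles identical by descent. Missing calls are inserted completely at
#' random at `missing_rate`.
#'
#' @param fam A `family_structure`.
#' @param config A [sim_config()].
#' @return A `genotype_matrix`: list with `dosages` (samples x SNPs, values
#'   0/1/2 or `NA`), `snp_ids`, `chrom`, `pos`, `ref`, `alt`, `sample_ids`.
#' @export
simulate_genotypes <- function(fam, config) {
  validate_sim_config(config)
  if (length(fam$sample_ids) == 0L) stop("empty family structure", call. = FALSE)
  with_seed(derive_seed(config$seed, 2L), {
    nf <- length(fam$families)
    m <- config$n_snps
    map <- sim_snp_map(m)
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    # founder haplotypes: one alt-allele indicator per founder chromosome
    hap <- function() matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
    f1a <- hap(); f1b <- hap(); f2a <- hap(); f2b <- hap()
    sib <- fam$roles == "sibling"
    fam_idx <- match(fam$family_ids, fam$families)
    ns <- sum(sib)
    pick <- function(a, b) {
      u <- matrix(stats::runif(ns * m) < 0.5, ns, m)
      ifelse(u, a[fam_idx[sib], , drop = FALSE], b[fam_idx[sib], , drop = FALSE])
    }
    d_sib <- pick(f1a, f1b) + pick(f2a, f2b)
    dos <- matrix(NA_real_, length(fam$sample_ids), m)
    dos[sib, ] <- d_sib
    if (any(!sib)) {
      p1 <- f1a + f1b; p2 <- f2a + f2b
      fo <- which(!sib)
      first <- !duplicated(fam$family_ids[fo])
      dos[fo[first], ] <- p1[fam_idx[fo[first]], , drop = FALSE]
      dos[fo[!first], ] <- p2[fam_idx[fo[!first]], , drop = FALSE]
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(length(dos)) < config$missing_rate
      dos[miss] <- NA_real_
    }
    dimnames(dos) <- list(fam$sample_ids, map$snp_id)
    structure(list(dosages = dos, snp_ids = map$snp_id, chrom = map$chrom,
                   pos = map$pos, ref = map$ref, alt = map$alt,
                   sample_ids = fam$sample_ids),
              class = "genotype_matrix")
  })
}

#' Simulate CpG methylation beta values with family correlation
#'
#' Values are generated on the M-value (log2-logit) scale as site mean +
#' family random effect + individual noise, with the variance split so the
#' within-family intraclass correlation equals `cpg_family_icc`, then mapped
#' back to beta values in (0, 1).
#'
#' @inheritParams simulate_genotypes
#' @return A `methylation_matrix`: list with `betas` (samples x sites),
#'   `cpg_ids`, `chrom`, `pos`, `sample_ids`.
#' @export
simulate_methylation <- function(fam, config) {
  validate_sim_config(config)
  if (length(fam$sample_ids) == 0L) stop("empty family structure", call. = FALSE)
  with_seed(derive_seed(config$seed, 3L), {
    n <- length(fam$sample_ids)
    m <- config$n_cpgs
    icc <- config$cpg_family_icc
    sd_tot <- 0.7  # total per-site M-value SD; typical 450K mid-range site
    mu <- stats::runif(m, -3, 3)
    nf <- length(fam$families)
    fam_idx <- match(fam$family_ids, fam$families)
    fam_eff <- matrix(stats::rnorm(nf * m, 0, sd_tot * sqrt(icc)), nf, m)
    mval <- matrix(mu, n, m, byrow = TRUE) +
      fam_eff[fam_idx, , drop = FALSE] +
      matrix(stats::rnorm(n * m, 0, sd_tot * sqrt(1 - icc)), n, m)
    betas <- m_to_beta(mval)
    chrom <- sort(rep_len(1:22, m))
    pos <- integer(m)
    for (c in unique(chrom)) {
      idx <- which(chrom == c)
      pos[idx] <- cumsum(sample(10000:100000, length(idx), replace = TRUE))
    }
    ids <- sprintf("cg%06d", seq_len(m))
    dimnames(betas) <- list(fam$sample_ids, ids)
    structure(list(betas = betas, cpg_ids = ids, chrom = chrom, pos = pos,
                   sample_ids = fam$sample_ids),
              class = "methylation_matrix")
  })
}

#' Simulate clinical covariates
#'
#' Age is discrete uniform on 20-70 years, sex Bernoulli(0.5), smoking
#' Bernoulli(0.25), all independent of family.
#'
#' @inheritParams simulate_genotypes
#' @return Data frame with `sample_id`, `family_id`, `age`, `sex`, `smoking`.
#' @export
simulate_covariates <- function(fam, config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, 4L), {
    n <- length(fam$sample_ids)
    data.frame(sample_id = fam$sample_ids, family_id = fam$family_ids,
               age = sample(20:70, n, replace = TRUE),
               sex = stats::rbinom(n, 1L, 0.5),
               smoking = stats::rbinom(n, 1L, 0.25),
               stringsAsFactors = FALSE)
  })
}

#' Simulate triglyceride visit values carrying a planted drug response
#'
#' Builds a liability score from causal SNP dosages, causal CpG M-values
#' (per-SD scaled), covariates and a family-level component, converts it to a
#' response probability with an intercept calibrated so the expected responder
#' fraction equals `target_response_rate`, draws responder status, and then
#' emits four TG visit values whose derived fractional change
#' (mean(v3,v4) - mean(v1,v2)) / mean(v1,v2) is below -30% exactly for
#' responders. Visit-level noise perturbs individual visits but never the
#' derived status.
#'
#' @param geno,meth,covars,fam Sample-aligned components.
#' @param config A [sim_config()].
#' @return List with `tg` (data frame `sample_id`, `tg_v1`..`tg_v4`),
#'   `response` (0/1 vector), `liability`, and the calibrated intercept.
#' @export
simulate_phenotype <- function(geno, meth, covars, fam, config) {
  validate_sim_config(config)
  n <- length(fam$sample_ids)
  if (!identical(rownames(geno$dosages), fam$sample_ids) ||
      !identical(rownames(meth$betas), fam$sample_ids) ||
      !identical(covars$sample_id, fam$sample_ids))
    stop("components are not sample-aligned", call. = FALSE)
  with_seed(derive_seed(config$seed, 5L), {
    causal_snps <- if (config$n_causal_snps > 0L)
      sort(sample(config$n_snps, config$n_causal_snps)) else integer(0)
    causal_cpgs <- if (config$n_causal_cpgs > 0L)
      sort(sample(config$n_cpgs, config$n_causal_cpgs)) else integer(0)

    eta <- numeric(n)
    if (length(causal_snps)) {
      g <- geno$dosages[, causal_snps, drop = FALSE]
      for (j in seq_len(ncol(g))) {  # mean-impute the few missing calls
        nas <- is.na(g[, j]); if (any(nas)) g[nas, j] <- mean(g[, j], na.rm = TRUE)
      }
      eta <- eta + rowSums(g) * config$snp_effect
    }
    if (length(causal_cpgs)) {
      mv <- beta_to_m(meth$betas[, causal_cpgs, drop = FALSE])
      mv <- scale(mv)
      eta <- eta + rowSums(mv) * config$cpg_effect
    }
    ce <- config$covariate_effects
    eta <- eta + as.numeric(scale(covars$age)) * ce[["age"]] +
      covars$sex * ce[["sex"]] + covars$smoking * ce[["smoking"]]
    if (config$polygenic_sd > 0) {
      fe <- stats::rnorm(length(fam$families), 0, config$polygenic_sd)
      eta <- eta + fe[match(fam$family_ids, fam$families)]
    }
    # intercept calibrated so E[responder fraction] = target
    f <- function(b0) mean(stats::plogis(b0 + eta)) - config$target_response_rate
    b0 <- stats::uniroot(f, c(-40, 40))$root
    y <- stats::rbinom(n, 1L, stats::plogis(b0 + eta))

    tg_pre <- stats::rlnorm(n, log(150), 0.35)
    chg <- ifelse(y == 1L, stats::runif(n, -0.60, -0.32), stats::runif(n, -0.28, 0.10))
    tg_post <- tg_pre * (1 + chg)
    d1 <- stats::runif(n, 0, 0.05); d2 <- stats::runif(n, 0, 0.05)
    tg <- data.frame(sample_id = fam$sample_ids,
                     tg_v1 = tg_pre * (1 + d1), tg_v2 = tg_pre * (1 - d1),
                     tg_v3 = tg_post * (1 + d2), tg_v4 = tg_post * (1 - d2),
                     stringsAsFactors = FALSE)
    list(tg = tg, response = y, liability = eta, intercept = b0,
         causal_snps = geno$snp_ids[causal_snps],
         causal_cpgs = meth$cpg_ids[causal_cpgs])
  })
}

#' Simulate a complete aligned cohort
#'
#' Convenience composition of [simulate_families()], [simulate_genotypes()],
#' [simulate_methylation()], [simulate_covariates()] and
#' [simulate_phenotype()]. All components share one ordered sample list; the
#' planted truth (causal marker ids and effects) is recorded in `$truth`.
#'
#' @param config A [sim_config()].
#' @return A `cohort` object.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  fam <- simulate_families(config)
  geno <- simulate_genotypes(fam, config)
  meth <- simulate_methylation(fam, config)
  covars <- simulate_covariates(fam, config)
  ph <- simulate_phenotype(geno, meth, covars, fam, config)
  structure(list(genotypes = geno, methylation = meth, covariates = covars,
                 tg = ph$tg, families = fam,
                 truth = list(causal_snps = ph$causal_snps,
                              causal_cpgs = ph$causal_cpgs,
                              snp_effect = config$snp_effect,
                              cpg_effect = config$cpg_effect,
                              intercept = ph$intercept,
                              response = ph$response),
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples in %d families | %d SNPs, %d CpGs\n",
              length(x$families$sample_ids), length(x$families$families),
              length(x$genotypes$snp_ids), length(x$methylation$cpg_ids)))
  invisible(x)
}
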