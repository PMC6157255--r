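# Quality control and phenotype derivation: MAF filtering, stochastic
# genotype imputation from the empirical genotype distribution, PCA-based
# sample outlier flagging, the -30% TG drug-response rule, and leakage-safe
# feature standardization.

#' Filter SNPs by minor allele frequency
#'
#' MAF is computed on non-missing dosages as `min(p, 1 - p)` with `p` the mean
#' dosage / 2; SNPs with MAF below `threshold` are removed, order preserved.
#'
#' @param geno A `genotype_matrix`.
#' @param threshold MAF cutoff in \[0, 0.5\]; default 0.01.
#' @return The filtered `genotype_matrix` with attribute `n_removed`.
#' @export
maf_filter <- function(geno, threshold = 0.01) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 0.5)
    stop("threshold must lie in [0, 0.5]", call. = FALSE)
  p <- colMeans(geno$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(maf) & maf >= threshold)
  out <- subset_snps(geno, keep)
  attr(out, "n_removed") <- length(geno$snp_ids) - length(keep)
  out
}

subset_snps <- function(geno, idx) {
  structure(list(dosages = geno$dosages[, idx, drop = FALSE],
                 snp_ids = geno$snp_ids[idx], chrom = geno$chrom[idx],
                 pos = geno$pos[idx], ref = geno$ref[idx], alt = geno$alt[idx],
                 sample_ids = geno$sample_ids),
            class = "genotype_matrix")
}

subset_samples <- function(geno, idx) {
  g <- geno
  g$dosages <- geno$dosages[idx, , drop = FALSE]
  g$sample_ids <- geno$sample_ids[idx]
  g
}

#' Impute missing genotype calls from the per-SNP empirical distribution
#'
#' Each missing call is drawn from the observed frequencies of \{0, 1, 2\}
#' among the non-missing calls at that SNP. Observed calls are untouched.
#'
#' @param geno A `genotype_matrix`.
#' @param seed RNG seed for the draws.
#' @return The `genotype_matrix` with no missing entries; the number of
#'   imputed calls is in attribute `n_imputed`.
#' @export
impute_missing <- function(geno, seed = 1L) {
  d <- geno$dosages
  all_missing <- colSums(!is.na(d)) == 0L
  if (any(all_missing))
    stop("SNP(s) with all calls missing: ",
         paste(geno$snp_ids[all_missing][1:min(3, sum(all_missing))], collapse = ", "),
         call. = FALSE)
  n_imp <- 0L
  with_seed(seed, {
    for (j in which(colSums(is.na(d)) > 0L)) {
      obs <- d[!is.na(d[, j]), j]
      tab <- tabulate(obs + 1L, nbins = 3L)
      nas <- which(is.na(d[, j]))
      d[nas, j] <- sample(0:2, length(nas), replace = TRUE, prob = tab / sum(tab))
      n_imp <- n_imp + length(nas)
    }
  })
  geno$dosages <- d
  attr(geno, "n_imputed") <- n_imp
  geno
}

#' Flag sample outliers on principal-component scores
#'
#' Columns are z-standardized (constant columns dropped with a warning), a
#' PCA is taken, and any sample whose score on one of the top `n_pcs`
#' components exceeds `sd_mult` times that component's score SD is flagged.
#' This is a transparent single-pass surrogate for the usual combination of
#' hierarchical clustering and Eigenstrat-style outlier removal.
#'
#' @param x Numeric matrix, samples x features (no missing values).
#' @param n_pcs Number of leading components to inspect (default 10).
#' @param sd_mult Score-SD multiplier defining an outlier (default 6).
#' @return Character vector of flagged sample ids (rownames of `x`).
#' @export
pca_outliers <- function(x, n_pcs = 10L, sd_mult = 6) {
  if (n_pcs < 1L) stop("n_pcs must be >= 1", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warning("dropping constant column(s) before PCA", call. = FALSE)
    x <- x[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  xs <- scale(x)
  n_pcs <- min(n_pcs, nrow(xs) - 1L, ncol(xs))
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE, rank. = n_pcs)
  flag <- rep(FALSE, nrow(xs))
  for (k in seq_len(ncol(pc$x))) {
    s <- pc$x[, k]
    flag <- flag | abs(s) > sd_mult * stats::sd(s)
  }
  rownames(x)[flag] %||% which(flag)
}

#' Derive the binary drug response from TG visit values
#'
#' The pre-treatment level is the mean of visits 1 and 2, the post-treatment
#' level the mean of visits 3 and 4; the fractional change is
#' `(post - pre) / pre` and a sample is a responder (1) exactly when the
#' change is below the cutoff (strictly, i.e. reduced by more than 30%).
#'
#' @param tg Data frame with `sample_id` and positive `tg_v1`..`tg_v4`.
#' @param cutoff Fractional-change cutoff, default -0.30.
#' @return Data frame `sample_id`, `tg_pre`, `tg_post`, `change`, `response`.
#' @export
derive_response <- function(tg, cutoff = -0.30) {
  v <- as.matrix(tg[paste0("tg_v", 1:4)])
  if (anyNA(v) || any(v <= 0))
    stop("all four TG visits must be present and positive", call. = FALSE)
  pre <- (v[, 1] + v[, 2]) / 2
  post <- (v[, 3] + v[, 4]) / 2
  change <- (post - pre) / pre
  data.frame(sample_id = tg$sample_id, tg_pre = pre, tg_post = post,
             change = change, response = as.integer(change < cutoff),
             stringsAsFactors = FALSE)
}

#' Fit-and-apply column z-standardization without leakage
#'
#' Means and SDs are computed on `fit_rows` only (the training folds); the
#' stored transform is then applied unchanged to every row, so held-out rows
#' never influence it. Columns constant on the fit rows get scale 1 (their
#' fit rows map to 0).
#'
#' @param x Numeric matrix.
#' @param fit_rows Row indices used to fit the transform (default: all rows).
#' @return List with `x` (transformed matrix), `center`, `scale`.
#' @export
standardize_features <- function(x, fit_rows = seq_len(nrow(x))) {
  if (length(fit_rows) == 0L) stop("fit_rows must be nonempty", call. = FALSE)
  xf <- x[fit_rows, , drop = FALSE]
  ctr <- colMeans(xf)
  scl <- apply(xf, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(x = sweep(sweep(x, 2L, ctr), 2L, scl, "/"), center = ctr, scale = scl)
}

#' Run the standard QC sequence on a cohort
#'
#' Order: MAF filter, stochastic imputation, optional PCA outlier flagging on
#' both genotype and methylation matrices (union of flags, samples removed,
#' MAF filter re-run), then response derivation.
#'
#' @param cohort A `cohort`.
#' @param maf MAF threshold (default 0.01).
#' @param seed Imputation seed.
#' @param flag_outliers Whether to run [pca_outliers()] (default TRUE).
#' @param n_pcs,sd_mult Outlier-flagging parameters.
#' @return List with the QC'd `cohort`, the `response` data frame, and a
#'   `qc_report` (counts per QC action).
#' @export
qc_cohort <- function(cohort, maf = 0.01, seed = 1L, flag_outliers = TRUE,
                      n_pcs = 10L, sd_mult = 6) {
  g <- maf_filter(cohort$genotypes, maf)
  n_maf <- attr(g, "n_removed")
  g <- impute_missing(g, seed = derive_seed(seed, 7L))
  n_imp <- attr(g, "n_imputed")
  outliers <- character(0)
  if (flag_outliers) {
    outliers <- union(
      suppressWarnings(pca_outliers(g$dosages, n_pcs, sd_mult)),
      suppressWarnings(pca_outliers(cohort$methylation$betas, n_pcs, sd_mult)))
    if (length(outliers)) {
      keep <- !(cohort$families$sample_ids %in% outliers)
      cohort <- subset_cohort(cohort, keep)
      g <- subset_samples(g, keep)
      g <- maf_filter(g, maf)  # allele frequencies may shift after drops
    }
  }
  cohort$genotypes <- g
  resp <- derive_response(cohort$tg)
  report <- list(snps_removed_maf = n_maf, genotypes_imputed = n_imp,
                 outliers_flagged = outliers,
                 samples_retained = length(cohort$families$sample_ids))
  list(cohort = cohort, response = resp, qc_report = report)
}

subset_cohort <- function(cohort, keep) {
  idx <- which(keep)
  ids <- cohort$families$sample_ids[idx]
  cohort$genotypes <- subset_samples(cohort$genotypes, idx)
  m <- cohort$methylation
  m$betas <- m$betas[idx, , drop = FALSE]; m$sample_ids <- ids
  cohort$methylation <- m
  cohort$covariates <- cohort$covariates[idx, , drop = FALSE]
  cohort$tg <- cohort$tg[idx, , drop = FALSE]
  fam <- cohort$families
  fam$sample_ids <- ids
  fam$family_ids <- fam$family_ids[idx]
  fam$roles <- fam$roles[idx]
  fam$families <- unique(fam$family_ids)
  fam$sib_counts <- table(factor(fam$family_ids, levels = fam$families))
  cohort$families <- fam
  if (!is.null(cohort$truth)) cohort$truth$response <- cohort$truth$response[idx]
  cohort
}
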