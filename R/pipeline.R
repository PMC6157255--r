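# Orchestration: family-blocked 5-fold cross-validation of the stepwise
# predictor sets (random-SNP baseline; selected SNPs; +CpGs; +clinical),
# with marker selection re-run inside each training fold so held-out
# samples never influence feature choice, and exact Wilcoxon rank-sum
# comparison of consecutive models' fold errors.

#' Assign families to cross-validation folds
#'
#' Families are placed whole into folds (all siblings share a fold) by a
#' greedy balance: largest family first into the currently smallest fold,
#' with seeded random tie-breaking.
#'
#' @param fam A `family_structure`.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer fold index (1..k) per sample.
#' @export
family_folds <- function(fam, k = 5L, seed = 1L) {
  fams <- fam$families
  if (length(fams) < k) stop("fewer families than folds", call. = FALSE)
  sizes <- as.integer(fam$sib_counts[fams])
  with_seed(seed, {
    ord <- order(-sizes, stats::runif(length(sizes)))
    fold_of <- integer(length(fams))
    load <- numeric(k)
    for (i in ord) {
      cand <- which(load == min(load))
      pick <- if (length(cand) > 1L) sample(cand, 1L) else cand
      fold_of[i] <- pick
      load[pick] <- load[pick] + sizes[i]
    }
    fold_of[match(fam$family_ids, fams)]
  })
}

#' Draw the random-SNP baseline feature set
#'
#' @param geno A `genotype_matrix`.
#' @param n Number of SNPs (default 100).
#' @param seed RNG seed.
#' @return `n` distinct SNP ids drawn uniformly without replacement.
#' @export
baseline_random_features <- function(geno, n = 100L, seed = 1L) {
  if (n > length(geno$snp_ids)) stop("n exceeds SNP count", call. = FALSE)
  with_seed(seed, sample(geno$snp_ids, n))
}

# Per-fold marker selections, shared by all models in a stepwise run.
# Returns list per fold: selected snp ids, selected cpg ids.
fold_selections <- function(cohort, y, folds, kinship, p_threshold = 1e-4) {
  lapply(sort(unique(folds)), function(f) {
    tr <- which(folds != f)
    g_tr <- subset_samples(cohort$genotypes, tr)
    snp_res <- gee_scan(y[tr], g_tr, cohort$families$family_ids[tr],
                        threshold = p_threshold)
    k_tr <- list(values = kinship$values[tr, tr, drop = FALSE],
                 sample_ids = kinship$sample_ids[tr])
    class(k_tr) <- "kinship_matrix"
    m_tr <- cohort$methylation
    m_tr$betas <- m_tr$betas[tr, , drop = FALSE]
    m_tr$sample_ids <- m_tr$sample_ids[tr]
    cpg_res <- lmm_scan(y[tr], m_tr, k_tr, threshold = p_threshold)
    list(snps = select_markers(snp_res, p_threshold),
         cpgs = select_markers(cpg_res, p_threshold))
  })
}

# Assemble the feature matrix for one model on the full cohort.
build_features <- function(cohort, snp_ids = NULL, cpg_ids = NULL,
                           clinical = FALSE) {
  parts <- list()
  if (length(snp_ids))
    parts$snp <- cohort$genotypes$dosages[, match(snp_ids, cohort$genotypes$snp_ids),
                                          drop = FALSE]
  if (length(cpg_ids))
    parts$cpg <- cohort$methylation$betas[, match(cpg_ids, cohort$methylation$cpg_ids),
                                          drop = FALSE]
  if (clinical)
    parts$clin <- as.matrix(cohort$covariates[c("age", "sex", "smoking")])
  if (length(parts) == 0L) return(NULL)
  do.call(cbind, parts)
}

# Train/evaluate the ANN on one fold given a fixed feature matrix.
fold_fit <- function(xall, y, tr, te, ann_cfg, fold_seed) {
  if (is.null(xall) || ncol(xall) == 0L) {
    # no features: majority-class predictor on the training fold
    cls <- as.integer(mean(y[tr]) >= 0.5)
    return(list(train = error_rate(rep(cls, length(tr)), y[tr]),
                test = error_rate(rep(cls, length(te)), y[te])))
  }
  st <- standardize_features(xall, tr)
  cfg <- ann_cfg; cfg$seed <- fold_seed
  model <- init_ann(ncol(xall), cfg$n_hidden, cfg)
  fit <- ann_train(model, st$x[tr, , drop = FALSE], y[tr], cfg)
  list(train = error_rate(predict_class(fit$model, st$x[tr, , drop = FALSE]), y[tr]),
       test = error_rate(predict_class(fit$model, st$x[te, , drop = FALSE]), y[te]))
}

#' Cross-validated evaluation of one predictor set
#'
#' For each fold: marker selection is re-run on the training folds only
#' (unless fixed ids are supplied), features are standardized on the
#' training folds, the network is trained, and training / held-out error
#' rates are recorded. The summary SD is the sample SD over the k fold
#' errors.
#'
#' @param cohort A QC'd `cohort` (genotypes imputed).
#' @param y Binary response aligned with the cohort.
#' @param folds Fold assignment from [family_folds()].
#' @param features List describing the predictor set: `snps` is either a
#'   character vector of fixed SNP ids or `"selected"` for per-fold GEE
#'   selection; `cpgs` is `"selected"` or ids or `NULL`; `clinical` TRUE/FALSE.
#' @param kinship `kinship_matrix` for the CpG scan (needed when
#'   `cpgs = "selected"`).
#' @param ann_cfg An [ann_config()].
#' @param p_threshold Selection threshold (default 1e-4).
#' @param label Model label carried into the report.
#' @param selections Optional precomputed per-fold selections (internal reuse).
#' @return A `cv_report`: per-fold training/test errors, their mean and
#'   sample SD, and the per-fold feature ids.
#' @export
cv_evaluate <- function(cohort, y, folds, features, kinship = NULL,
                        ann_cfg = ann_config(), p_threshold = 1e-4,
                        label = "model", selections = NULL) {
  ks <- sort(unique(folds))
  need_sel <- identical(features$snps, "selected") || identical(features$cpgs, "selected")
  if (need_sel && is.null(selections)) {
    if (is.null(kinship)) {
      pruned <- ld_prune(cohort$genotypes)
      kinship <- kinship_grm(subset_snps(cohort$genotypes,
                                         match(pruned, cohort$genotypes$snp_ids)))
    }
    selections <- fold_selections(cohort, y, folds, kinship, p_threshold)
  }
  tr_err <- te_err <- numeric(length(ks))
  feat_ids <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    f <- ks[i]
    tr <- which(folds != f); te <- which(folds == f)
    snp_ids <- if (identical(features$snps, "selected")) selections[[i]]$snps
               else features$snps
    cpg_ids <- if (identical(features$cpgs, "selected")) selections[[i]]$cpgs
               else features$cpgs
    if (length(unique(y[te])) < 2L)
      warning(sprintf("fold %d holds a single class", f), call. = FALSE)
    xall <- build_features(cohort, snp_ids, cpg_ids, isTRUE(features$clinical))
    if (is.null(xall) && (identical(features$snps, "selected") ||
                          identical(features$cpgs, "selected")))
      warning(sprintf("fold %d: no markers selected; majority-class fallback", f),
              call. = FALSE)
    res <- fold_fit(xall, y, tr, te, ann_cfg, derive_seed(ann_cfg$seed, 100L + i))
    tr_err[i] <- res$train; te_err[i] <- res$test
    feat_ids[[i]] <- list(snps = snp_ids, cpgs = cpg_ids,
                          clinical = isTRUE(features$clinical))
  }
  structure(list(model_label = label, folds = ks,
                 train_error = tr_err, test_error = te_err,
                 mean_train = mean(tr_err), sd_train = stats::sd(tr_err),
                 mean_test = mean(te_err), sd_test = stats::sd(te_err),
                 n_features = vapply(feat_ids, function(fi)
                   length(fi$snps) + length(fi$cpgs) + 3L * fi$clinical, integer(1)),
                 feature_ids = feat_ids),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: test %.2f%% +/- %.2f%% (train %.2f%% +/- %.2f%%)\n",
              x$model_label, 100 * x$mean_test, 100 * x$sd_test,
              100 * x$mean_train, 100 * x$sd_train))
  invisible(x)
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' For combined sample size up to 20 the null distribution of the
#' (mid-rank, tie-adjusted) rank-sum statistic is enumerated exhaustively
#' and the two-sided p-value is the probability of a statistic at least as
#' far from its null mean as observed; above 20 a tie-corrected normal
#' approximation is used.
#'
#' @param a,b Numeric vectors (e.g. per-fold error rates of two models).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty input", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  rk <- rank(c(a, b))                     # mid-ranks for ties
  w_obs <- sum(rk[seq_len(n1)])
  e_w <- n1 * (n + 1) / 2
  if (n <= 20L) {
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(rk[combs], nrow = n1))
    p <- mean(abs(sums - e_w) >= abs(w_obs - e_w) - 1e-9)
  } else {
    tie_tab <- table(rk)
    var_w <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (var_w <= 0) return(1)
    z <- (w_obs - e_w) / sqrt(var_w)
    p <- 2 * stats::pnorm(-abs(z))
  }
  min(p, 1)
}

#' Stepwise stratified model comparison under cross-validation
#'
#' Runs [cv_evaluate()] for the four predictor sets in fixed order --
#' random-SNP baseline, selected SNPs, SNPs + CpGs, SNPs + CpGs + clinical
#' -- reusing one per-fold marker selection, and compares consecutive
#' models' held-out fold errors with the exact Wilcoxon rank-sum test. A
#' CpG-only model is included when `include_cpg_only` is set.
#'
#' @param cohort A QC'd `cohort` (imputed genotypes).
#' @param y Binary response vector.
#' @param k Number of folds (default 5).
#' @param seed Master seed for folds, baseline draw and network inits.
#' @param ann_cfg An [ann_config()].
#' @param p_threshold Marker selection threshold (default 1e-4).
#' @param ld_threshold,window_bp LD pruning parameters for the kinship SNPs.
#' @param baseline_n Number of random baseline SNPs (default 100).
#' @param include_cpg_only Also evaluate a CpG-only model (default FALSE).
#' @return A `stepwise_report`: ordered `cv_report`s, Wilcoxon p-values
#'   between consecutive models, fold assignment and settings.
#' @export
stepwise_run <- function(cohort, y, k = 5L, seed = 1L, ann_cfg = ann_config(),
                         p_threshold = 1e-4, ld_threshold = 0.2,
                         window_bp = 5e5, baseline_n = 100L,
                         include_cpg_only = FALSE) {
  folds <- family_folds(cohort$families, k, derive_seed(seed, 11L))
  pruned <- ld_prune(cohort$genotypes, ld_threshold, window_bp)
  kin <- kinship_grm(subset_snps(cohort$genotypes,
                                 match(pruned, cohort$genotypes$snp_ids)))
  sel <- fold_selections(cohort, y, folds, kin, p_threshold)
  base_ids <- baseline_random_features(cohort$genotypes,
                                       min(baseline_n, length(cohort$genotypes$snp_ids)),
                                       derive_seed(seed, 13L))
  acfg <- ann_cfg; acfg$seed <- derive_seed(seed, 17L)
  run <- function(label, feats) cv_evaluate(cohort, y, folds, feats, kin, acfg,
                                            p_threshold, label, selections = sel)
  reports <- list(
    baseline = run("baseline_random_snps", list(snps = base_ids)),
    snp = run("snp", list(snps = "selected")),
    snp_cpg = run("snp_cpg", list(snps = "selected", cpgs = "selected")),
    snp_cpg_clinical = run("snp_cpg_clinical",
                           list(snps = "selected", cpgs = "selected", clinical = TRUE)))
  if (include_cpg_only)
    reports$cpg <- run("cpg", list(cpgs = "selected"))
  wil <- list(
    snp_vs_baseline = wilcoxon_rank_sum(reports$snp$test_error,
                                        reports$baseline$test_error),
    snp_cpg_vs_snp = wilcoxon_rank_sum(reports$snp_cpg$test_error,
                                       reports$snp$test_error),
    all_vs_snp_cpg = wilcoxon_rank_sum(reports$snp_cpg_clinical$test_error,
                                       reports$snp_cpg$test_error))
  structure(list(reports = reports, wilcoxon = wil, folds = folds,
                 n_pruned_snps = length(pruned),
                 settings = list(k = k, seed = seed, p_threshold = p_threshold,
                                 ld_threshold = ld_threshold,
                                 baseline_n = baseline_n)),
            class = "stepwise_report")
}

#' @export
print.stepwise_report <- function(x, ...) {
  cat("<stepwise_report>\n")
  for (r in x$reports)
    cat(sprintf("  %-22s test %.2f%% +/- %.2f%%\n",
                r$model_label, 100 * r$mean_test, 100 * r$sd_test))
  cat(sprintf("  Wilcoxon snp+cpg vs snp: p = %.4f\n", x$wilcoxon$snp_cpg_vs_snp))
  invisible(x)
}

#' Summarize a stepwise report as a table
#'
#' One row per model with mean and SD of training and test error (percent),
#' mirroring the usual stepwise results layout.
#' @param report A `stepwise_report`.
#' @return Data frame.
#' @export
stepwise_table <- function(report) {
  do.call(rbind, lapply(report$reports, function(r)
    data.frame(model = r$model_label,
               train_error_pct = 100 * r$mean_train,
               train_sd_pct = 100 * r$sd_train,
               test_error_pct = 100 * r$mean_test,
               test_sd_pct = 100 * r$sd_test,
               mean_n_features = mean(r$n_features),
               row.names = NULL)))
}

#' Simulate a cohort and run the full stepwise analysis
#'
#' Chains the synthetic generator, QC and [stepwise_run()] under one master
#' seed; the result is a deterministic function of the configuration and
#' seed.
#'
#' @param config A [sim_config()] (its own seed drives the simulation).
#' @param seed Master seed for QC imputation, folds and network training.
#' @param ... Passed to [stepwise_run()].
#' @param maf MAF threshold for QC (default 0.01).
#' @param flag_outliers Run PCA outlier flagging during QC (default TRUE).
#' @return List with the `stepwise_report`, the QC report, and the cohort's
#'   truth ledger.
#' @export
simulate_and_run <- function(config = sim_config(), seed = 1L, maf = 0.01,
                             flag_outliers = TRUE, ...) {
  cohort <- simulate_cohort(config)
  qc <- qc_cohort(cohort, maf = maf, seed = seed, flag_outliers = flag_outliers)
  rep <- stepwise_run(qc$cohort, qc$response$response, seed = seed, ...)
  list(report = rep, qc_report = qc$qc_report, truth = qc$cohort$truth,
       response_rate = mean(qc$response$response),
       n_samples = length(qc$response$response))
}
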