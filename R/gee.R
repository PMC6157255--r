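# Generalized estimating equations: logistic marginal model with an
# exchangeable working correlation over family clusters and a robust
# (sandwich) covariance. The exchangeable structure gives closed-form
# cluster inverses, so each Fisher-scoring step reduces to a handful of
# grouped sums (rowsum) and a p x p solve -- fast enough for per-SNP scans.

# Precompute the cluster bookkeeping shared by every fit in a scan.
gee_cluster_index <- function(clusters) {
  f <- factor(clusters)
  sizes <- tabulate(f)
  list(f = f, idx = as.integer(f), sizes = sizes,
       n_pairs = sum(sizes * (sizes - 1)) / 2,
       max_size = max(sizes), n_clusters = nlevels(f))
}

#' Fit a logistic GEE with exchangeable working correlation
#'
#' Solves the GEE score equations for a binary outcome with logit link and
#' binomial variance, alternating Fisher-scoring coefficient updates with a
#' moment update of the exchangeable correlation, until the relative
#' coefficient change is below `tol`. The returned covariance is the robust
#' sandwich estimator, so inference is valid even when the working
#' correlation is wrong. With singleton clusters the fit reduces to the
#' ordinary logistic MLE with heteroskedasticity-robust standard errors.
#'
#' @param y Binary 0/1 response vector.
#' @param x Design matrix (including the intercept column), full column rank.
#' @param clusters Cluster (family) id per sample, or a precomputed index
#'   from the internal `gee_cluster_index()`.
#' @param tol Relative coefficient-change convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return A `gee_fit`: coefficients, robust covariance `robust_cov`,
#'   exchangeable `alpha`, `n_clusters`, `converged`, `iterations`, and a
#'   `separation` flag (any |coefficient| > 15).
#' @export
gee_logistic <- function(y, x, clusters, tol = 1e-8, max_iter = 100L) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  ci <- if (is.list(clusters) && !is.null(clusters$idx)) clusters
        else gee_cluster_index(clusters)
  if (length(ci$idx) != length(y)) stop("clusters do not partition samples", call. = FALSE)
  p <- ncol(x)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 0.02), 0.98))  # intercept start
  alpha <- 0
  converged <- FALSE
  iter <- 0L
  grp <- ci$idx
  nlev <- ci$n_clusters
  size_of <- ci$sizes
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    sw <- sqrt(w)
    r <- (y - mu) / sw                       # standardized Pearson residuals
    # moment estimate of the exchangeable correlation
    if (ci$n_pairs > 0) {
      sum_r <- rowsum(r, grp, reorder = FALSE)
      sum_r2 <- rowsum(r * r, grp, reorder = FALSE)
      alpha <- sum((sum_r^2 - sum_r2) / 2) / max(ci$n_pairs - p, 1)
      lo <- -1 / (ci$max_size - 1) + 1e-6
      alpha <- min(max(alpha, lo), 0.99)
    }
    # closed-form inverse of R = (1-a) I + a J per cluster:
    # R^{-1} = 1/(1-a) [I - c J], c = a / (1 - a + n_i a)
    cfac <- alpha / (1 - alpha + size_of * alpha)   # per cluster
    s <- x * sw
    S <- rowsum(s, grp, reorder = FALSE)            # cluster sums of s rows
    Rr <- rowsum(r, grp, reorder = FALSE)           # cluster sums of residuals
    A <- (crossprod(s) - crossprod(S * cfac, S)) / (1 - alpha)
    U <- (crossprod(s, r) - crossprod(S * cfac, Rr)) / (1 - alpha)
    delta <- tryCatch(solve(A, U),
                      error = function(e) MASS::ginv(A) %*% U)
    beta_new <- beta + drop(delta)
    if (max(abs(beta_new - beta)) / max(1, max(abs(beta_new))) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  # sandwich covariance at the final estimate
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  sw <- sqrt(w)
  r <- (y - mu) / sw
  cfac <- alpha / (1 - alpha + size_of * alpha)
  s <- x * sw
  S <- rowsum(s, grp, reorder = FALSE)
  Rr <- rowsum(r, grp, reorder = FALSE)
  A <- (crossprod(s) - crossprod(S * cfac, S)) / (1 - alpha)
  Umat <- (rowsum(s * r, grp, reorder = FALSE) - (S * cfac) * drop(Rr)) / (1 - alpha)
  M <- crossprod(Umat)
  Ainv <- tryCatch(solve(A), error = function(e) MASS::ginv(A))
  vc <- Ainv %*% M %*% Ainv
  vc <- (vc + t(vc)) / 2
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 robust_cov = vc, alpha = alpha,
                 n_clusters = nlev, converged = converged,
                 iterations = iter,
                 separation = any(abs(beta) > 15)),
            class = "gee_fit")
}

#' Per-SNP GEE logistic scan
#'
#' Fits [gee_logistic()] for each SNP on a design of intercept + dosage
#' (+ optional covariates), takes the two-sided Wald p-value from the robust
#' standard error, and marks a SNP selected when p is strictly below
#' `threshold`. Per-marker fit failures are recorded (p = NA), never fatal.
#'
#' @param y Binary response vector aligned with `geno`.
#' @param geno A `genotype_matrix`, imputed and MAF-filtered.
#' @param clusters Family id per sample.
#' @param covariates Optional numeric matrix of additional fixed covariates.
#' @param threshold Selection p-value threshold (default 1e-4).
#' @return A `selection_result` data frame: `marker_id`, `chrom`, `pos`,
#'   `beta`, `se`, `stat`, `p`, `selected`.
#' @export
gee_scan <- function(y, geno, clusters, covariates = NULL, threshold = 1e-4) {
  d <- geno$dosages
  if (anyNA(d)) stop("genotypes contain missing values; impute first", call. = FALSE)
  m <- ncol(d)
  ci <- gee_cluster_index(clusters)
  xc <- if (is.null(covariates)) NULL else as.matrix(covariates)
  beta <- se <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- d[, j]
    if (stats::sd(g) == 0) { beta[j] <- 0; se[j] <- NA_real_; next }
    x <- if (is.null(xc)) cbind(1, g) else cbind(1, g, xc)
    fit <- tryCatch(gee_logistic(y, x, ci), error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$separation) next
    v <- fit$robust_cov[2, 2]
    if (is.finite(v) && v > 0) {
      beta[j] <- fit$coefficients[2]
      se[j] <- sqrt(v)
    }
  }
  stat <- beta / se
  p <- 2 * stats::pnorm(-abs(stat))
  p[is.na(se) & !is.na(beta)] <- 1  # constant dosage: no test
  structure(data.frame(marker_id = geno$snp_ids,
                       chrom = geno$chrom %||% rep(NA_integer_, m),
                       pos = geno$pos %||% rep(NA_integer_, m),
                       beta = beta, se = se, stat = stat, p = p,
                       selected = !is.na(p) & p < threshold,
                       stringsAsFactors = FALSE),
            class = c("selection_result", "data.frame"),
            threshold = threshold)
}
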