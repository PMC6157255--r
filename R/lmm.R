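# Kinship linear mixed model: REML null fit by spectral decomposition and a
# fixed-variance-component (EMMAX-style) per-site association scan. The
# binary drug response is treated as quantitative (linear probability
# model), which is the pragmatic choice for screening binary phenotypes with
# kinship LMM software.

#' Fit the kinship LMM null model by REML
#'
#' Model: y = W b + g + e with g ~ (0, sigma_g^2 K) and e ~ (0, sigma_e^2 I).
#' One spectral decomposition of K rotates the problem so each evaluation of
#' the REML log-likelihood in the variance ratio lambda = sigma_g^2/sigma_e^2
#' is O(n); lambda is profiled on a log-spaced grid and refined with a local
#' 1-D optimizer. Boundary solutions (sigma_g^2 = 0) are allowed.
#'
#' @param y Numeric response vector (a 0/1 response is treated as
#'   quantitative).
#' @param k A `kinship_matrix` (or plain symmetric matrix) aligned with `y`.
#' @param covariates Optional numeric matrix of fixed covariates (an
#'   intercept is always included).
#' @return An `lmm_null_fit` with `sigma_g2`, `sigma_e2`, `delta`
#'   (= sigma_e2/sigma_g2), `reml_loglik`, `fixed_effects`, an
#'   `identifiable` flag (FALSE when K is essentially the identity so only
#'   the total variance is determined), and the rotation reused by
#'   [lmm_scan()].
#' @export
lmm_reml_null <- function(y, k, covariates = NULL) {
  kv <- if (inherits(k, "kinship_matrix")) k$values else as.matrix(k)
  n <- length(y)
  if (nrow(kv) != n) stop("kinship matrix not aligned with y", call. = FALSE)
  if (stats::sd(y) == 0) stop("response is constant", call. = FALSE)
  w <- cbind(`(Intercept)` = rep(1, n), covariates)
  p <- ncol(w)
  e <- eigen((kv + t(kv)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop("kinship matrix is not PSD (clip negative eigenvalues first)", call. = FALSE)
  d <- pmax(e$values, 0)
  u <- e$vectors
  ys <- drop(crossprod(u, y))
  ws <- crossprod(u, w)

  reml <- function(log_lambda) {
    v <- exp(log_lambda) * d + 1
    wi <- 1 / v
    a <- crossprod(ws, ws * wi)
    b <- drop(crossprod(ws, ys * wi))
    bhat <- solve(a, b)
    res <- ys - drop(ws %*% bhat)
    rss <- sum(res^2 * wi)
    s2 <- rss / (n - p)
    as.numeric(-0.5 * ((n - p) * log(s2) + sum(log(v)) +
                         determinant(a, logarithm = TRUE)$modulus + (n - p)))
  }
  grid <- seq(-10, 10, length.out = 81)
  ll <- vapply(grid, reml, numeric(1))
  best <- which.max(ll)
  identifiable <- stats::sd(d) > 1e-8 * max(d) && (max(ll) - min(ll)) > 1e-6
  if (identifiable) {
    lo <- grid[max(best - 1L, 1L)]; hi <- grid[min(best + 1L, length(grid))]
    opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-8)
    # allow the boundary sigma_g2 = 0 when the edge beats the interior
    if (best == 1L && ll[1] >= opt$objective) {
      log_lambda <- -Inf; llmax <- reml(-300)
    } else { log_lambda <- opt$maximum; llmax <- opt$objective }
  } else {
    log_lambda <- grid[best]; llmax <- ll[best]
  }
  lam <- exp(min(log_lambda, 300))
  v <- lam * d + 1
  wi <- 1 / v
  a <- crossprod(ws, ws * wi)
  bhat <- solve(a, drop(crossprod(ws, ys * wi)))
  res <- ys - drop(ws %*% bhat)
  sigma_e2 <- sum(res^2 * wi) / (n - p)
  structure(list(sigma_g2 = lam * sigma_e2, sigma_e2 = sigma_e2,
                 delta = if (lam > 0) 1 / lam else Inf,
                 lambda = lam, reml_loglik = llmax,
                 fixed_effects = stats::setNames(drop(bhat), colnames(w)),
                 identifiable = identifiable,
                 rotation = list(u = u, d = d, weights = wi, ys = ys, ws = ws)),
            class = "lmm_null_fit")
}

#' Kinship-LMM association scan over CpG sites
#'
#' EMMAX-style approximation: the variance components are held at the null
#' fit and each site's beta-value column is added to the fixed effects; the
#' generalized-least-squares effect, standard error and two-sided p-value
#' (t reference with n - p - 1 df, so the scan reduces exactly to per-site
#' OLS when K is the identity) are computed in the rotated space. Constant
#' sites get effect 0 and p = 1. Sites are marked selected when p is
#' strictly below `threshold`.
#'
#' @param y Response vector (binary treated as quantitative).
#' @param meth A `methylation_matrix` aligned with `y` (or a plain matrix).
#' @param k A `kinship_matrix`; ignored when `null` is supplied.
#' @param covariates Optional fixed-covariate matrix (must match the null fit).
#' @param null Optional [lmm_reml_null()] fit to reuse.
#' @param threshold Selection p-value threshold (default 1e-4).
#' @return A `selection_result` data frame (see [gee_scan()]).
#' @export
lmm_scan <- function(y, meth, k = NULL, covariates = NULL, null = NULL,
                     threshold = 1e-4) {
  mm <- if (inherits(meth, "methylation_matrix")) meth$betas else as.matrix(meth)
  if (is.null(null)) {
    if (is.null(k)) stop("supply a kinship matrix or a null fit", call. = FALSE)
    null <- lmm_reml_null(y, k, covariates)
  }
  rot <- null$rotation
  n <- length(y)
  p <- ncol(rot$ws)
  wi <- rot$weights
  ms <- crossprod(rot$u, mm)            # rotate all sites at once
  # residualize y and every site on the null fixed effects under weights wi
  a <- crossprod(rot$ws, rot$ws * wi)
  proj <- function(z) z - rot$ws %*% solve(a, crossprod(rot$ws, z * wi))
  ey <- drop(proj(rot$ys))
  em <- proj(ms)
  sxx <- colSums(wi * em^2)
  sxy <- colSums(wi * em * ey)
  syy <- sum(wi * ey^2)
  df <- n - p - 1L
  beta <- ifelse(sxx > 1e-12, sxy / sxx, 0)
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- ifelse(sxx > 1e-12, sqrt(rss / df / sxx), NA_real_)
  stat <- beta / se
  pval <- 2 * stats::pt(-abs(stat), df)
  pval[sxx <= 1e-12] <- 1
  beta[sxx <= 1e-12] <- 0
  ids <- if (inherits(meth, "methylation_matrix")) meth$cpg_ids else colnames(mm)
  chrom <- if (inherits(meth, "methylation_matrix")) meth$chrom else NULL
  pos <- if (inherits(meth, "methylation_matrix")) meth$pos else NULL
  mn <- ncol(mm)
  structure(data.frame(marker_id = ids %||% paste0("site", seq_len(mn)),
                       chrom = chrom %||% rep(NA_integer_, mn),
                       pos = pos %||% rep(NA_integer_, mn),
                       beta = beta, se = se, stat = stat, p = pval,
                       selected = !is.na(pval) & pval < threshold,
                       stringsAsFactors = FALSE),
            class = c("selection_result", "data.frame"),
            threshold = threshold)
}

#' Select markers below a p-value threshold
#'
#' @param res A `selection_result`.
#' @param threshold Strict p-value cutoff (default 1e-4).
#' @return Marker ids with p < threshold, ordered by ascending p with ties
#'   broken by marker id.
#' @export
select_markers <- function(res, threshold = 1e-4) {
  hit <- !is.na(res$p) & res$p < threshold
  sel <- res[hit, , drop = FALSE]
  sel$marker_id[order(sel$p, sel$marker_id)]
}
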