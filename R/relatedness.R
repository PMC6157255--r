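# LD pruning and empirical kinship (genomic relationship matrix).

#' Squared correlation (r^2) between two dosage vectors
#'
#' Linkage-disequilibrium measure used by the pruner: squared Pearson
#' correlation of additive dosages; defined as 0 when either vector is
#' constant.
#'
#' @param g1,g2 Equal-length numeric dosage vectors with no missing values.
#' @return Squared correlation in \[0, 1\].
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length", call. = FALSE)
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) return(0)
  stats::cor(g1, g2)^2
}

#' Greedy LD pruning of a genotype matrix
#'
#' SNPs must be sorted by (chromosome, position) and fully imputed. Scanning
#' left to right within each chromosome, a SNP is retained exactly when its
#' r^2 with every already-retained SNP within `window_bp` is below
#' `ld_threshold`; ties therefore resolve to the leftmost SNP. Deterministic.
#'
#' @param geno A `genotype_matrix`, no missing dosages.
#' @param ld_threshold r^2 threshold in (0, 1\]; default 0.2.
#' @param window_bp Base-pair window within which pairs are tested
#'   (default 500 kb).
#' @return Character vector of retained SNP ids (in input order).
#' @export
ld_prune <- function(geno, ld_threshold = 0.2, window_bp = 5e5) {
  if (ld_threshold <= 0 || ld_threshold > 1)
    stop("ld_threshold must lie in (0, 1]", call. = FALSE)
  if (anyNA(geno$dosages)) stop("dosages contain missing values; impute first", call. = FALSE)
  ord <- order(geno$chrom, geno$pos)
  if (!identical(ord, seq_along(ord)))
    stop("SNPs must be sorted by (chromosome, position)", call. = FALSE)
  d <- geno$dosages
  keep <- logical(ncol(d))
  for (chr in unique(geno$chrom)) {
    idx <- which(geno$chrom == chr)
    retained <- integer(0)
    for (j in idx) {
      inwin <- retained[geno$pos[retained] >= geno$pos[j] - window_bp]
      ok <- TRUE
      if (length(inwin)) {
        sj <- stats::sd(d[, j])
        if (sj > 0) {
          r <- suppressWarnings(stats::cor(d[, j], d[, inwin, drop = FALSE]))
          r[is.na(r)] <- 0  # constant retained column: r^2 defined as 0
          ok <- all(r^2 < ld_threshold)
        }
      }
      if (ok) {
        keep[j] <- TRUE
        retained <- c(retained, j)
      }
    }
  }
  geno$snp_ids[keep]
}

#' Empirical kinship from a pruned genotype matrix (VanRaden GRM)
#'
#' K = Z Z' / (2 * sum_j p_j (1 - p_j)) where Z centers each dosage column by
#' twice its sample alt-allele frequency p_j. Monomorphic SNPs are excluded.
#' Under this scaling the diagonal is about 1 and full siblings about 0.5.
#'
#' @param geno A `genotype_matrix` with no missing dosages (use the LD-pruned
#'   subset).
#' @return A `kinship_matrix`: list with symmetric `values` and `sample_ids`.
#' @export
kinship_grm <- function(geno) {
  d <- geno$dosages
  if (anyNA(d)) stop("dosages contain missing values; impute first", call. = FALSE)
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2L) stop("need at least 2 polymorphic SNPs", call. = FALSE)
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(d, 2L, 2 * p)
  k <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  k <- (k + t(k)) / 2
  dimnames(k) <- list(geno$sample_ids, geno$sample_ids)
  structure(list(values = k, sample_ids = geno$sample_ids),
            class = "kinship_matrix")
}

# Clip negative eigenvalues to zero; returns the adjusted matrix.
clip_psd <- function(k, tol = 1e-8) {
  e <- eigen(k, symmetric = TRUE)
  if (min(e$values) >= -tol && all(e$values >= 0)) return(k)
  v <- pmax(e$values, 0)
  k2 <- e$vectors %*% (v * t(e$vectors))
  (k2 + t(k2)) / 2
}

#' Write / read a kinship matrix as TSV
#'
#' Sample ids appear as both header row and first column.
#' @param k A `kinship_matrix`.
#' @param path File path.
#' @export
write_kinship <- function(k, path) {
  df <- data.frame(sample_id = k$sample_ids, k$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample_id
  structure(list(values = v, sample_ids = df$sample_id), class = "kinship_matrix")
}
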