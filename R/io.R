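# Reading and writing the pipeline's standard file formats:
# VCF v4.2 for genotypes, tab-separated tables for methylation betas,
# clinical covariates and TG visit values, and a JSON truth ledger for
# simulated cohorts. All tables are UTF-8, tab-delimited, '.' for missing.

#' Read genotypes from a VCF file into a dosage matrix
#'
#' Dosage is the alternate-allele count of the GT field (0/1/2); `./.` becomes
#' missing. Multi-allelic records are skipped with a warning.
#'
#' @param path Path to a VCF (v4.x) file with GT genotypes.
#' @return A `genotype_matrix` (samples x SNPs dosages plus variant metadata).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)), call. = FALSE)
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  allele_count <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- t(apply(gt, 1L, allele_count))
  if (nrow(fix) == 1L) dos <- matrix(dos, nrow = 1L, dimnames = dimnames(gt))
  dos <- t(dos)  # samples x SNPs
  colnames(dos) <- fix$ID
  structure(list(dosages = dos, snp_ids = fix$ID,
                 chrom = suppressWarnings(as.integer(fix$CHROM)),
                 pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                 sample_ids = rownames(dos)),
            class = "genotype_matrix")
}

#' Write a genotype matrix as VCF v4.2
#'
#' @param geno A `genotype_matrix` with dosages in \{0, 1, 2, NA\}.
#' @param path Output path.
#' @export
write_vcf <- function(geno, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- geno$dosages
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$sample_ids), collapse = "\t"))
  body <- vapply(seq_along(geno$snp_ids), function(j) {
    g <- ifelse(is.na(d[, j]), "./.", gt_code[as.character(d[, j])])
    paste(c(geno$chrom[j], geno$pos[j], geno$snp_ids[j], geno$ref[j],
            geno$alt[j], ".", "PASS", ".", "GT", g), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read methylation, covariate and TG tables
#'
#' Expects tab-separated files: methylation with `sample_id` then one column
#' per CpG (betas in \[0, 1\]); covariates with `sample_id`, `family_id`,
#' `age`, `sex`, `smoking`; TG with `sample_id`, `tg_v1`..`tg_v4`. Samples
#' with a missing TG visit are flagged for exclusion rather than dropped here.
#'
#' @param meth_path,covar_path,tg_path File paths.
#' @return List with `methylation` (a `methylation_matrix`), `covariates`
#'   (data frame) and `tg` (data frame with attribute `incomplete` listing
#'   samples missing a visit).
#' @export
read_tables <- function(meth_path, covar_path, tg_path) {
  rt <- function(p) utils::read.delim(p, check.names = FALSE, na.strings = c("NA", "."),
                                      comment.char = "#", stringsAsFactors = FALSE)
  me <- rt(meth_path)
  betas <- as.matrix(me[, -1, drop = FALSE])
  rownames(betas) <- me$sample_id
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value outside [0,1] for sample %s at site %s",
                 rownames(betas)[bad[1, 1]], colnames(betas)[bad[1, 2]]),
         call. = FALSE)
  meth <- structure(list(betas = betas, cpg_ids = colnames(betas),
                         chrom = NULL, pos = NULL,
                         sample_ids = rownames(betas)),
                    class = "methylation_matrix")
  covars <- rt(covar_path)
  need <- c("sample_id", "family_id", "age", "sex", "smoking")
  if (!all(need %in% names(covars)))
    stop("covariate table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(covars[need])) stop("missing values in covariate table", call. = FALSE)
  tg <- rt(tg_path)
  vcols <- paste0("tg_v", 1:4)
  if (!all(c("sample_id", vcols) %in% names(tg)))
    stop("TG table must have columns sample_id, tg_v1..tg_v4", call. = FALSE)
  incomplete <- tg$sample_id[!stats::complete.cases(tg[vcols])]
  attr(tg, "incomplete") <- incomplete
  list(methylation = meth, covariates = covars, tg = tg)
}

#' Assemble an aligned cohort from its component tables
#'
#' Intersects the sample sets of all components, drops samples missing any key
#' variable (any TG visit, methylation, covariates, or every genotype call)
#' and reorders everything to one ordered sample list. Drop counts per reason
#' are recorded in the returned object's `drops` attribute.
#'
#' @param geno A `genotype_matrix`.
#' @param meth A `methylation_matrix`.
#' @param covars Covariate data frame (`sample_id`, `family_id`, `age`, `sex`,
#'   `smoking`).
#' @param tg TG data frame (`sample_id`, `tg_v1`..`tg_v4`).
#' @return A `cohort` with all components indexed by one sample list.
#' @export
assemble_cohort <- function(geno, meth, covars, tg) {
  ids <- Reduce(intersect, list(geno$sample_ids, meth$sample_ids,
                                covars$sample_id, tg$sample_id))
  drops <- list(
    not_in_all = setdiff(unique(c(geno$sample_ids, meth$sample_ids,
                                  covars$sample_id, tg$sample_id)), ids),
    incomplete_tg = intersect(ids, attr(tg, "incomplete") %||%
                                tg$sample_id[!stats::complete.cases(tg[paste0("tg_v", 1:4)])]),
    all_geno_missing = ids[rowSums(!is.na(geno$dosages[ids, , drop = FALSE])) == 0]
  )
  keep <- setdiff(ids, union(drops$incomplete_tg, drops$all_geno_missing))
  if (length(keep) == 0L) stop("no samples shared by all inputs", call. = FALSE)
  keep <- covars$sample_id[covars$sample_id %in% keep]  # covariate order wins
  g <- geno; g$dosages <- geno$dosages[keep, , drop = FALSE]; g$sample_ids <- keep
  m <- meth; m$betas <- meth$betas[keep, , drop = FALSE]; m$sample_ids <- keep
  cv <- covars[match(keep, covars$sample_id), , drop = FALSE]
  rownames(cv) <- NULL
  tgk <- tg[match(keep, tg$sample_id), , drop = FALSE]
  rownames(tgk) <- NULL
  fam_ids <- unique(cv$family_id)
  fam <- structure(list(sample_ids = keep, family_ids = cv$family_id,
                        roles = rep("sibling", length(keep)),
                        families = fam_ids,
                        sib_counts = table(factor(cv$family_id, levels = fam_ids))),
                   class = "family_structure")
  structure(list(genotypes = g, methylation = m, covariates = cv, tg = tgk,
                 families = fam, truth = NULL, config = NULL, drops = drops),
            class = "cohort")
}

#' Write a cohort to its standard on-disk representation
#'
#' Emits `genotypes.vcf`, `methylation.tsv`, `covariates.tsv`, `tg.tsv` and
#' (for simulated cohorts) `truth.json` into `dir`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  wb <- data.frame(sample_id = cohort$methylation$sample_ids,
                   cohort$methylation$betas, check.names = FALSE)
  utils::write.table(wb, file.path(dir, "methylation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  covar_path <- file.path(dir, "covariates.tsv")
  writeLines("# sex: 0=female 1=male; smoking: 0=non-smoker 1=smoker", covar_path)
  suppressWarnings(utils::write.table(
    cohort$covariates[c("sample_id", "family_id", "age", "sex", "smoking")],
    covar_path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  utils::write.table(cohort$tg[c("sample_id", paste0("tg_v", 1:4))],
                     file.path(dir, "tg.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth[c("causal_snps", "causal_cpgs",
                                        "snp_effect", "cpg_effect")],
                         file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Directory holding `genotypes.vcf`, `methylation.tsv`,
#'   `covariates.tsv` and `tg.tsv`.
#' @return An assembled `cohort`.
#' @export
read_cohort <- function(dir) {
  geno <- read_vcf(file.path(dir, "genotypes.vcf"))
  tabs <- read_tables(file.path(dir, "methylation.tsv"),
                      file.path(dir, "covariates.tsv"),
                      file.path(dir, "tg.tsv"))
  assemble_cohort(geno, tabs$methylation, tabs$covariates, tabs$tg)
}
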