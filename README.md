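# stratpred

Stratified multi-omics prediction of drug response in family cohorts.

## What it does

In pharmacogenomic family studies — e.g. fenofibrate trials where the
outcome is whether circulating triglycerides (TG) drop by more than 30%
between pre- and post-treatment visits — predictors come in strata: SNP
genotypes, CpG methylation, and clinical covariates. Siblings are
correlated in both genotype and outcome, so marker screening must adjust
for family structure, and cross-validation must not split families.

`stratpred` implements the full stratified pipeline:

1. **Response**: responder = fractional TG change
   `(mean(v3,v4) − mean(v1,v2)) / mean(v1,v2) < −0.30` (strict).
2. **QC**: MAF ≥ 0.01 filter, stochastic imputation of missing genotypes
   from each SNP's empirical distribution, PCA-score outlier flagging.
3. **Relatedness**: greedy LD pruning at r² < 0.2, then a VanRaden genomic
   relationship matrix `K = ZZ′ / (2Σ pⱼ(1−pⱼ))` (full sibs ≈ 0.5).
4. **Screening**: per-SNP logistic **GEE** (exchangeable working
   correlation, sandwich Wald test) and per-CpG **kinship LMM** (REML by
   spectral decomposition, EMMAX-style per-site test); markers kept at
   p < 1e-4.
5. **Prediction**: three-layer network — `tansig` hidden layer
   (`−1 + 2/(1+e^(−2n))`, i.e. tanh), linear output — trained full-batch by
   adaptive gradient descent with momentum (η = 0.01, μ = 0.4) under the
   least-mean-squares criterion.
6. **Comparison**: family-blocked 5-fold CV of four nested predictor sets
   (100 random SNPs → selected SNPs → +CpGs → +clinical), selection re-run
   inside every training fold, consecutive models compared by exact
   Wilcoxon rank-sum on fold errors.

A synthetic sibship-cohort generator (Mendelian genotype transmission,
family-correlated methylation, liability-model response calibrated to a
57.6% responder fraction) makes every stage testable without restricted
data; it writes/reads standard formats (VCF v4.2, TSV).

## Worked example

```r
library(stratpred)

cfg <- sim_config(n_families = 165, n_snps = 2000, n_cpgs = 1000, seed = 204)
res <- simulate_and_run(cfg, seed = 204, ann_cfg = ann_config(max_epochs = 300))
stepwise_table(res$report)[, c("model", "test_error_pct", "test_sd_pct")]
#>                  model test_error_pct test_sd_pct
#>   baseline_random_snps          48.79        5.20
#>                    snp          38.85        4.08
#>                snp_cpg          24.09        5.15
#>       snp_cpg_clinical          25.10        5.43
```

Read: the random-SNP baseline approximates a random-guess error for a
~58%-responder cohort; the GEE-selected SNPs cut the held-out error; adding
LMM-selected CpG sites cuts it further — the stratified pattern the design
is built to expose. `res$report$wilcoxon` holds the exact rank-sum p-values
between consecutive models, e.g. `snp_cpg_vs_snp`.

Lower-level entry points: `gee_scan()`, `lmm_scan()`, `ld_prune()`,
`kinship_grm()`, `ann_train()`, `cv_evaluate()`, `wilcoxon_rank_sum()`;
file I/O via `read_vcf()`, `read_tables()`, `assemble_cohort()`,
`write_cohort()`.

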