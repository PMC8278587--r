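#!/usr/bin/env Rscript
## Sample QC, replicate identity, per-category FFPE FDR estimation, AAF
## filtering summaries, and population-AF concordance on the simulated
## cohort written by 01_simulate.R.

suppressMessages(library(bbdburden))

samples <- read_sample_sheet("results/sample_sheet.tsv")
variants <- read_variants("results/cohort_variants.vcf",
                          "results/cohort_annotation.tsv")
known_snps <- utils::read.delim("results/known_snps.tsv")

## sample-level QC: mean UMT coverage >= 20x, SNP call rate >= 80%
qc <- sample_qc(samples, known_snps, variants)
write_results_tsv(qc, "results/sample_qc.tsv")
cat(sprintf("sample QC: %d/%d pass\n", sum(qc$qc_pass), nrow(qc)))

## replicate identity via Spearman of SNP AAFs
m <- snp_aaf_matrix(samples, known_snps, variants)
ri <- replicate_identity(m)
is_rep <- matrix(FALSE, nrow(m), nrow(m), dimnames = dimnames(ri$correlation))
for (ids in split(samples$sample_id, samples$replicate_set)) {
  is_rep[ids, ids] <- TRUE
}
ut <- upper.tri(ri$correlation)
cat(sprintf("replicate pairs: min rho %.3f; unrelated pairs: max rho %.3f\n",
            min(ri$correlation[ut & is_rep]),
            max(ri$correlation[ut & !is_rep])))
write_results_tsv(as.data.frame(ri$correlation), "results/identity_matrix.tsv")

## FFPE FDR per mutation category from the paired truth set
ffpe <- read_variants("results/paired_ffpe.vcf",
                      "results/paired_ffpe_annotation.tsv")
frozen <- read_variants("results/paired_frozen.vcf",
                        "results/paired_frozen_annotation.tsv")
pairs <- utils::read.delim("results/paired_key.tsv")
fdr <- estimate_fdr(ffpe, frozen, pairs)
write_results_tsv(fdr, "results/fdr_by_category.tsv")
cat("estimated FDR by category:\n")
print(fdr[, c("category", "n_ffpe_calls", "fdr")], digits = 3)

## survivors per AAF strategy after technical filtering
tech <- filter_technical(variants)
counts <- vapply(c("liberal", "classical", "strict"),
                 function(s) nrow(apply_aaf_filter(tech, s)), 0L)
cat(sprintf("calls surviving AAF filters: liberal %d, classical %d, strict %d (of %d)\n",
            counts[1], counts[2], counts[3], nrow(tech)))

## population allele-frequency concordance on rsID sites, classical filter
prim <- qc[qc$is_primary & qc$qc_pass, ]
cla <- apply_aaf_filter(tech[tech$sample_id %in% prim$sample_id, ],
                        "classical")
conc <- population_af_concordance(cla, prim$sample_id, by_category = TRUE)
cat(sprintf("population AF concordance (Spearman): %.3f over %d sites\n",
            conc$overall[["correlation"]], conc$overall[["n"]]))
write_results_tsv(conc$by_category, "results/af_concordance_by_category.tsv")
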