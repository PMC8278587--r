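#!/usr/bin/env Rscript
## Gene-level burden association: the 12 filter-by-method combinations for
## the all-cases contrast, plus the ER+ and ER- secondary contrasts, and the
## consensus table.

suppressMessages(library(bbdburden))

samples <- read_sample_sheet("results/sample_sheet.tsv")
variants <- read_variants("results/cohort_variants.vcf",
                          "results/cohort_annotation.tsv")
known_snps <- utils::read.delim("results/known_snps.tsv")
fdr <- utils::read.delim("results/fdr_by_category.tsv")

qc <- sample_qc(samples, known_snps, variants)
prim <- qc[qc$is_primary & qc$qc_pass, ]
cat(sprintf("analysis set: %d samples (%s)\n", nrow(prim),
            paste(names(table(prim$group)), table(prim$group),
                  sep = "=", collapse = ", ")))

for (contrast in c("all_cases_vs_control", "er_pos_vs_control",
                   "er_neg_vs_control")) {
  res <- run_all_combinations(variants, prim, contrast, fdr_table = fdr)
  out <- sprintf("results/association_%s.tsv", contrast)
  write_results_tsv(res, out)
  sig <- sum(res$testable & !is.na(res$p_value) & res$p_value < 0.05)
  cat(sprintf("%s: %d rows, %d nominally significant (p < 0.05); -> %s\n",
              contrast, nrow(res), sig, out))
}

res_all <- utils::read.delim("results/association_all_cases_vs_control.tsv")
cc <- consensus_count(res_all)
cc <- cc[order(-cc$n_nominal, cc$gene), ]
write_results_tsv(cc, "results/consensus_table.tsv")
cat(sprintf("genes with p < 0.05 in >= 4 of 12 combinations: %d\n",
            sum(cc$n_nominal >= 4)))
cat(sprintf("Bonferroni threshold for %d genes: %.5f\n",
            length(unique(res_all$gene)),
            bonferroni_threshold(length(unique(res_all$gene)))))
planted <- utils::read.delim("results/planted_effects.tsv")
cat(sprintf("planted genes in consensus top 15: %d/10\n",
            sum(planted$gene %in% head(cc$gene, 15))))
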