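#!/usr/bin/env Rscript
# Stage 2 — marker diagnostics for the genotype database.
#
# Per-locus allele counts, observed and unbiased expected heterozygosity,
# polymorphic information content, Monte-Carlo exact Hardy-Weinberg tests
# and a null-allele screen, plus the aggregate mother-offspring mismatch
# rate that calibrates the likelihood error parameter used in parentage.

library(kinfaces)

ped <- read_pedigree("results/pedigree.tsv")
gt <- read_genotypes("results/genotypes_observed.tsv")

dx <- genotype_diagnostics(gt, n_perm = 10000L, seed = 1)
tab <- dx$per_locus
write.table(tab, "results/locus_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

mo <- mother_offspring_error_rate(ped, gt)

cat("Across-locus summaries (mean +/- SD):\n")
for (v in c("k", "Ho", "He", "PIC")) {
  cat(sprintf("  %-3s %.2f +/- %.2f\n", v, dx$across_loci["mean", v],
              dx$across_loci["sd", v]))
}
n_hwe_dev <- sum(tab$hwe_p < 0.05 / nrow(tab), na.rm = TRUE)
cat(sprintf("Loci out of HWE (Bonferroni 5%%): %d of %d\n",
            n_hwe_dev, nrow(tab)))
cat(sprintf("Null-allele flags: %d\n", sum(tab$null_allele_flag)))
cat(sprintf("Mother-offspring mismatch rate: %.1f%% (%d of %d pairs)\n",
            100 * mo$rate, mo$n_mismatched, mo$n_pairs))
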