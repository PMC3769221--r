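#!/usr/bin/env Rscript
# Generate the two synthetic study cohorts and their case/control labels.
#
# Emulated structures:
#   * African-American: two 5-SNP haplotypes GTAGC/TAGAT at 0.436/0.564,
#     all five SNPs in near-perfect LD.
#   * Chilean: a 4-SNP block (TAGC/AGAT at 0.339/0.661) with rs2549782
#     only partially linked (target D' 0.53 with the block).
# Both cohorts: n = 1100, per-SNP missingness 0.3%, null case model with a
# case fraction of 528/1103.

suppressPackageStartupMessages(library(erap2hap))
out_dir <- "results/cohorts"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260901L

for (pop in c("african_american_5snp", "chilean_4snp_plus_partial")) {
  cfg <- preset(pop, n_samples = 1100, seed = seed)
  coh <- simulate_cohort(cfg)
  labs <- attach_case_status(coh, list(intercept = qlogis(528 / 1103)),
                             seed = seed + 1L)
  write_genotypes(coh, file.path(out_dir, paste0(pop, ".csv")), "csv")
  write_genotypes(coh, file.path(out_dir, paste0(pop, ".vcf.gz")), "vcf")
  write.csv(as.data.frame(unclass(labs)),
            file.path(out_dir, paste0(pop, "_labels.csv")), row.names = FALSE)
  cat(sprintf("%s: %d samples, %d missing calls, %d cases\n",
              pop, length(coh$samples), sum(is.na(coh$dosage)),
              sum(labs$status == "case")))
  for (s in coh$snps$id) {
    cat(sprintf("  %s minor-allele frequency %.3f\n", s,
                allele_frequency(genotype_counts(coh, s))))
  }
}
cat("cohorts written under", out_dir, "\n")
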