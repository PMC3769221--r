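# Shared fixture builders: tiny genotype tables constructed in code.

# Two generic SNPs for pair-level fixtures (minor allele second letter).
pair_defs <- function() {
  rbind(snp_def("snpA", "A", "G"), snp_def("snpB", "T", "C"))
}

# Genotype table straight from dosage vectors (one vector per SNP).
table_from_dosage <- function(defs, ...) {
  dos <- cbind(...)
  genotype_table(sprintf("S%03d", seq_len(nrow(dos))), defs, dos)
}

# Cohort drawn deterministically from explicit 2-locus haplotype pairs:
# `pairs` is an n x 2 matrix of haplotype strings.
table_from_diplotypes <- function(defs, pairs) {
  K <- nrow(defs)
  dos <- t(apply(pairs, 1, function(p) {
    vapply(seq_len(K), function(j) {
      (substr(p[1], j, j) == defs$minor[j]) +
        (substr(p[2], j, j) == defs$minor[j])
    }, numeric(1))
  }))
  genotype_table(sprintf("S%03d", seq_len(nrow(pairs))), defs, dos)
}

# The reconstructed Chilean fetal two-SNP cohort (1097 typed + 3 missing).
fetal_cohort <- function(with_labels = FALSE) {
  cohort_from_compound_counts(
    chilean_fetal_compound_counts("all"), n_missing = 3,
    case_counts = if (with_labels) chilean_fetal_compound_counts("case"))
}

# Independent fixed-point oracle for the 2-locus EM on the fetal table:
# iterate the coupling-mass equation for the A-T / G-G resolution of the
# 248 double heterozygotes.
fetal_em_oracle <- function() {
  m <- 0
  for (i in 1:500) {
    num <- (241 + m) * (219 + m)
    m <- 248 * num / (num + (505 - m) * (1229 - m))
  }
  n2 <- 2 * 1097
  list(m = m,
       freqs = c(AT = (241 + m) / n2, AG = (505 - m) / n2,
                 GT = (1229 - m) / n2, GG = (219 + m) / n2))
}
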