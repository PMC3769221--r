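# Published summary data for the Chilean ERAP2 cohorts, usable as inputs:
# the fetal rs2248374 x rs2549782 compound-genotype counts and the reported
# marginal allele frequencies. A cohort reconstructed from these counts
# carries exactly the published two-SNP information (genotype counts are
# sufficient statistics for everything downstream of phase).

#' Published Chilean fetal compound-genotype counts
#'
#' The 3x3 table of rs2248374 (rows: AA, AG, GG) by rs2549782 (columns:
#' TT, GT, GG) genotype counts for the Chilean fetal (neonatal) cohort
#' (n = 1097 typed at both SNPs, of 1100), overall or split by group.
#' Note the complete absence of both double homozygote classes AA,TT and
#' GG,GG.
#'
#' @param group `"all"`, `"control"` or `"case"`.
#' @return 3x3 integer matrix with dimnames.
#' @export
chilean_fetal_compound_counts <- function(group = c("all", "control", "case")) {
  group <- match.arg(group)
  m <- switch(group,
    all = rbind(AA = c(0, 90, 43), AG = c(151, 248, 81), GG = c(346, 138, 0)),
    control = rbind(AA = c(0, 41, 28), AG = c(93, 126, 41),
                    GG = c(176, 69, 0)),
    case = rbind(AA = c(0, 49, 15), AG = c(58, 122, 40), GG = c(170, 69, 0)))
  colnames(m) <- c("TT", "GT", "GG")
  storage.mode(m) <- "integer"
  m
}

#' Reconstruct a two-SNP cohort from a compound-genotype count table
#'
#' Expands a 3x3 count table for the rs2248374 / rs2549782 pair into a
#' [genotype_table()] with one sample per counted individual (plus
#' optionally `n_missing` samples with missing calls), and matching
#' [cohort_labels()] when case/control tables are supplied. Sample order is
#' deterministic.
#'
#' @param counts 3x3 matrix, rows rs2248374 AA/AG/GG, columns rs2549782
#'   TT/GT/GG (as from [chilean_fetal_compound_counts()]).
#' @param n_missing Extra samples with both calls missing.
#' @param stratum Stratum for labels.
#' @param case_counts Optional 3x3 matrix of the case subset; the remainder
#'   are labeled controls.
#' @return List with `table` and (when `case_counts` given) `labels`.
#' @export
cohort_from_compound_counts <- function(counts, n_missing = 0L,
                                        stratum = "fetal",
                                        case_counts = NULL) {
  defs <- erap2_snps()[c(3, 1), ]  # rs2248374, rs2549782
  # rows AA/AG/GG are rs2248374 dosage 2/1/0; cols TT/GT/GG are rs2549782
  # dosage 0/1/2
  dos_a <- c(2L, 1L, 0L); dos_b <- c(0L, 1L, 2L)
  expand <- function(m) {
    idx <- which(m > 0, arr.ind = TRUE)
    do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1]; j <- idx[k, 2]
      matrix(rep(c(dos_a[i], dos_b[j]), m[i, j]), ncol = 2, byrow = TRUE)
    }))
  }
  if (is.null(case_counts)) {
    dosage <- expand(counts)
    status <- NULL
  } else {
    control_counts <- counts - case_counts
    if (any(control_counts < 0)) stop("case counts exceed totals", call. = FALSE)
    d_case <- expand(case_counts); d_ctrl <- expand(control_counts)
    dosage <- rbind(d_case, d_ctrl)
    status <- c(rep("case", nrow(d_case)), rep("control", nrow(d_ctrl)))
  }
  if (n_missing > 0L) {
    dosage <- rbind(dosage, matrix(NA_integer_, n_missing, 2))
    if (!is.null(status)) status <- c(status, rep("control", n_missing))
  }
  samples <- sprintf("R%04d", seq_len(nrow(dosage)))
  tab <- genotype_table(samples, defs, dosage)
  out <- list(table = tab)
  if (!is.null(status)) {
    out$labels <- cohort_labels(samples, status, rep(stratum, length(samples)),
                                table = tab)
  }
  out
}

#' Published Chilean marginal allele counts for rs2248374
#'
#' Minor-allele (A) counts and group sizes for rs2248374 in the Chilean
#' cohorts, as `genotype-free` allele summaries: list of `minor_count` and
#' `n_individuals` per group. Fetal cases carried 348 A alleles among 528
#' individuals and controls 400 among 575.
#'
#' @export
chilean_rs2248374_allele_counts <- function() {
  list(
    fetal = list(case = list(minor = 348L, n = 528L),
                 control = list(minor = 400L, n = 575L)),
    maternal = list(case = list(minor = 348L, n = 528L),
                    control = list(minor = 376L, n = 575L))
  )
}
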