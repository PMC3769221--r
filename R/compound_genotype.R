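# Two-SNP compound-genotype analysis: 3x3 observed tables, expected counts
# from observed allele frequencies, per-cell observed-vs-expected tests,
# compound-homozygote detection power, and genotype-to-expression dosage
# prediction for the ERAP2 rs2248374 / rs2549782 pair.

geno_labels <- function(major, minor) {
  lab <- function(a, b) paste0(sort(c(a, b)), collapse = "")
  c(hom_major = lab(major, major), het = lab(major, minor),
    hom_minor = lab(minor, minor))
}

#' Compound-genotype 3x3 table for a SNP pair
#'
#' Cross-tabulates the unphased genotypes at two SNPs over samples with
#' calls at both (pairwise deletion). With cohort labels, tables are
#' returned per group (`all`, `case`, `control`); the group tables sum to
#' the `all` table.
#'
#' @param table A [genotype_table()].
#' @param snp_a,snp_b SNP ids; rows of each 3x3 table are genotypes at
#'   `snp_a` (hom-major, het, hom-minor), columns genotypes at `snp_b`.
#' @param labels Optional [cohort_labels()]; unlabeled samples are dropped
#'   from the group tables but kept in `all`.
#' @return Object of class `compound_table`: list with `snp_pair`, `labels`
#'   (genotype strings per axis), and one 3x3 integer matrix per group.
#' @export
compound_table <- function(table, snp_a, snp_b, labels = NULL) {
  ia <- snp_index(table, snp_a); ib <- snp_index(table, snp_b)
  dos <- table$dosage[, c(ia, ib), drop = FALSE]
  keep <- stats::complete.cases(dos)
  if (!any(keep)) stop("no samples typed at both ", snp_a, " and ", snp_b,
                       call. = FALSE)
  lab_a <- geno_labels(table$snps$major[ia], table$snps$minor[ia])
  lab_b <- geno_labels(table$snps$major[ib], table$snps$minor[ib])
  tab3 <- function(rows) {
    m <- table(factor(dos[rows, 1], 0:2), factor(dos[rows, 2], 0:2))
    m <- matrix(as.integer(m), 3, 3, dimnames = list(lab_a, lab_b))
    m
  }
  out <- list(snp_pair = c(snp_a, snp_b),
              labels = list(a = lab_a, b = lab_b),
              all = tab3(keep))
  if (!is.null(labels)) {
    bad <- setdiff(labels$sample, table$samples)
    if (length(bad)) stop("unknown labeled sample: ", bad[1], call. = FALSE)
    status <- labels$status[match(table$samples, labels$sample)]
    out$case <- tab3(keep & !is.na(status) & status == "case")
    out$control <- tab3(keep & !is.na(status) & status == "control")
  }
  structure(out, class = "compound_table")
}

#' @export
print.compound_table <- function(x, ...) {
  cat("compound_table:", x$snp_pair[1], "(rows) x", x$snp_pair[2],
      "(cols), n =", sum(x$all), "\n")
  print(x$all)
  invisible(x)
}

#' Expected compound-genotype counts from allele frequencies
#'
#' Builds the 3x3 table of expected counts for a SNP pair from marginal
#' allele frequencies, under one of two nulls:
#'
#' * `naive_product`: each cell's frequency is the plain product of its
#'   four constituent allele frequencies, with no heterozygote multiplicity
#'   factor (e.g. the AA,TT cell is `fa^2 * fb^2`, and the AA,TG cell is
#'   `fa^2 * fb * (1-fb)`, not twice that). Cell frequencies then sum to
#'   less than 1 whenever either SNP is polymorphic. This is the
#'   reproduction mode for published ERAP2 compound-genotype expectations.
#' * `hwe_multinomial`: product of the two Hardy-Weinberg genotype
#'   probabilities (`2pq` for heterozygotes), which sums to exactly n and is
#'   the statistically standard null for new analyses.
#'
#' @param freq_a_minor Minor-allele frequency at the first SNP (rows).
#' @param freq_b_major Major-allele frequency at the second SNP (columns).
#' @param n Cohort size.
#' @param mode `"naive_product"` or `"hwe_multinomial"`.
#' @return Object of class `expected_counts`: list with `mode`, `freq_a`,
#'   `freq_b`, `n`, and `expected`, a 3x3 matrix with rows (hom-major, het,
#'   hom-minor at SNP A) and columns likewise for SNP B.
#' @examples
#' # expected AA,TT compound homozygotes at published Chilean fetal
#' # frequencies: 0.34^2 * 0.67^2 * 1100 = 57
#' e <- expected_counts(0.34, 0.67, 1100, mode = "naive_product")
#' e$expected["hom_minor", "hom_major"]
#' @export
expected_counts <- function(freq_a_minor, freq_b_major, n,
                            mode = c("naive_product", "hwe_multinomial")) {
  mode <- match.arg(mode)
  if (freq_a_minor <= 0 || freq_a_minor >= 1 ||
      freq_b_major <= 0 || freq_b_major >= 1) {
    warning("degenerate allele frequency: some expected cells are zero")
  }
  if (n <= 0) stop("n must be positive", call. = FALSE)
  qa <- freq_a_minor; pa <- 1 - qa          # minor / major at A
  pb <- freq_b_major; qb <- 1 - pb          # major / minor at B
  cell <- function(f1a, f2a, f1b, f2b, hw_a, hw_b) {
    if (mode == "naive_product") f1a * f2a * f1b * f2b else hw_a * hw_b
  }
  g_a <- rbind(hom_major = c(pa, pa), het = c(pa, qa), hom_minor = c(qa, qa))
  g_b <- rbind(hom_major = c(pb, pb), het = c(pb, qb), hom_minor = c(qb, qb))
  hw <- function(g) if (g[1] == g[2]) g[1]^2 else 2 * g[1] * g[2]
  expected <- matrix(0, 3, 3,
                     dimnames = list(rownames(g_a), rownames(g_b)))
  for (i in 1:3) for (j in 1:3) {
    expected[i, j] <- n * cell(g_a[i, 1], g_a[i, 2], g_b[j, 1], g_b[j, 2],
                               hw(g_a[i, ]), hw(g_b[j, ]))
  }
  structure(list(mode = mode, freq_a = qa, freq_b = pb, n = n,
                 expected = expected),
            class = "expected_counts")
}

#' @export
print.expected_counts <- function(x, ...) {
  cat("expected_counts (", x$mode, "), n = ", x$n, ", freq_a_minor = ",
      x$freq_a, ", freq_b_major = ", x$freq_b, "\n", sep = "")
  print(round(x$expected, 1))
  invisible(x)
}

#' Observed-versus-expected test for compound-genotype cells
#'
#' For each requested cell, a 1-df chi-square compares the observed count
#' against its expectation as a cell-versus-rest binomial split:
#' `(obs - exp)^2 / exp + ((n - obs) - (n - exp))^2 / (n - exp)`.
#'
#' @param observed A 3x3 observed matrix (or a single count).
#' @param expected An [expected_counts()] object (or a single expectation
#'   when `observed` is a single count).
#' @param n Cohort size; taken from `expected` when that is an
#'   `expected_counts` object.
#' @return A data frame with one row per tested cell: `row`, `col`,
#'   `observed`, `expected`, `statistic`, `p_value`.
#' @export
observed_vs_expected_test <- function(observed, expected, n = NULL) {
  if (inherits(expected, "expected_counts")) {
    n <- expected$n
    exp_mat <- expected$expected
  } else {
    if (is.null(n)) stop("n required when expected is a plain matrix/number",
                         call. = FALSE)
    exp_mat <- expected
  }
  obs <- as.matrix(observed); exp_mat <- as.matrix(exp_mat)
  stopifnot(all(dim(obs) == dim(exp_mat)))
  idx <- which(!is.na(obs), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    o <- obs[i, j]; e <- exp_mat[i, j]
    if (e <= 0) stop("expected count is zero for cell [", i, ",", j, "]",
                     call. = FALSE)
    stat <- (o - e)^2 / e + ((n - o) - (n - e))^2 / (n - e)
    data.frame(row = rownames(obs)[i] %||% i, col = colnames(obs)[j] %||% j,
               observed = o, expected = e, statistic = stat,
               p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Power to detect a compound homozygote
#'
#' @param p_cell Population frequency of the compound-homozygote class.
#' @param n Cohort size.
#' @param model `"at_least_one"`: probability that at least one carrier is
#'   sampled, `1 - (1 - p_cell)^n` (alpha is not used). `"chisq_gof"`:
#'   power of the 1-df cell-vs-rest chi-square test of the observed count
#'   against `n * p_cell`, at level `alpha`, when the true cell frequency is
#'   `p_alt`; computed by summing binomial tail probabilities over rejecting
#'   counts.
#' @param alpha Test level for `chisq_gof`.
#' @param p_alt True cell frequency under the alternative (required for
#'   `chisq_gof`).
#' @return Power in `[0, 1]`.
#' @export
detection_power <- function(p_cell, n, model = c("at_least_one", "chisq_gof"),
                            alpha = 0.05, p_alt = NULL) {
  model <- match.arg(model)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (p_cell < 0 || p_cell > 1) stop("p_cell must be in [0,1]", call. = FALSE)
  if (model == "at_least_one") {
    return(1 - (1 - p_cell)^n)
  }
  if (is.null(p_alt)) stop("chisq_gof power needs an alternative frequency p_alt",
                           call. = FALSE)
  e <- n * p_cell
  crit <- stats::qchisq(1 - alpha, 1)
  x <- 0:n
  stat <- (x - e)^2 / e + ((n - x) - (n - e))^2 / (n - e)
  sum(stats::dbinom(x[stat >= crit], n, p_alt))
}

# ---- expression prediction -------------------------------------------------

normalize_geno <- function(g) paste0(sort(strsplit(g, "")[[1]]), collapse = "")

#' Predict ERAP2 protein and 392N dosage from the rs2248374/rs2549782 pair
#'
#' ERAP2 full-length protein dosage equals the count of rs2248374 A alleles
#' (the G allele is a functional null via a splice variant and
#' nonsense-mediated decay). The 392N variant (encoded by the rs2549782 T
#' allele) is expressed only from a haplotype that carries rs2248374 A, so
#' its dosage is the number of A-with-T pairings across the two
#' chromosomes. For the double heterozygote AG,GT this depends on phase:
#' unphased input yields `"phase_dependent"`, and an explicit phase (two
#' haplotypes over the pair, e.g. `c("AT", "GG")` in SNP order rs2248374,
#' rs2549782) resolves it.
#'
#' @param genotype_a rs2248374 genotype string (`"AA"`, `"AG"`, `"GG"`; letter
#'   order irrelevant).
#' @param genotype_b rs2549782 genotype string (`"TT"`, `"GT"`, `"GG"`).
#' @param phase Optional character vector of two 2-letter haplotypes in SNP
#'   order (rs2248374 allele, rs2549782 allele); must be consistent with
#'   both genotypes.
#' @return List with `erap2_dosage` (0-2) and `n392_dosage` (0, 1, 2 or
#'   `"phase_dependent"`).
#' @examples
#' predict_expression("AA", "TT")             # full ERAP2, two 392N alleles
#' predict_expression("GG", "TT")             # no ERAP2 at all
#' predict_expression("AG", "GT")             # phase dependent
#' predict_expression("AG", "GT", phase = c("AT", "GG"))
#' @export
predict_expression <- function(genotype_a, genotype_b, phase = NULL) {
  ga <- normalize_geno(genotype_a); gb <- normalize_geno(genotype_b)
  if (!ga %in% c("AA", "AG", "GG")) stop("invalid rs2248374 genotype: ",
                                         genotype_a, call. = FALSE)
  if (!gb %in% c("GG", "GT", "TT")) stop("invalid rs2549782 genotype: ",
                                         genotype_b, call. = FALSE)
  n_a <- sum(strsplit(ga, "")[[1]] == "A")
  n_t <- sum(strsplit(gb, "")[[1]] == "T")
  if (!is.null(phase)) {
    stopifnot(length(phase) == 2L, all(nchar(phase) == 2L))
    ph_a <- substr(phase, 1, 1); ph_b <- substr(phase, 2, 2)
    if (normalize_geno(paste0(ph_a, collapse = "")) != ga ||
        normalize_geno(paste0(ph_b, collapse = "")) != gb) {
      stop("phase inconsistent with genotypes", call. = FALSE)
    }
    n392 <- sum(ph_a == "A" & ph_b == "T")
  } else if (n_a == 1L && n_t == 1L) {
    n392 <- "phase_dependent"
  } else {
    n392 <- min(n_a, n_t)
  }
  list(erap2_dosage = n_a, n392_dosage = n392)
}

#' Compound-genotype report in the published table layout
#'
#' Joins observed counts, expected counts under both nulls, per-cell
#' observed-vs-expected p-values (naive-product null), and the expression
#' prediction for each of the nine rs2248374 x rs2549782 compound
#' genotypes.
#'
#' @param ct A [compound_table()] for the pair (rows rs2248374, columns
#'   rs2549782).
#' @param freq_a_minor,freq_b_major Allele frequencies for the
#'   expectations; defaults are computed from the table margins.
#' @param digits Round frequencies to this many decimals before building
#'   expectations (2 reproduces published tables); `NULL` for full
#'   precision.
#' @return Data frame with one row per compound genotype.
#' @export
compound_report <- function(ct, freq_a_minor = NULL, freq_b_major = NULL,
                            digits = 2) {
  n <- sum(ct$all)
  if (is.null(freq_a_minor)) {
    freq_a_minor <- sum(ct$all * matrix(0:2, 3, 3)) / (2 * n)
  }
  if (is.null(freq_b_major)) {
    freq_b_major <- 1 - sum(ct$all * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  }
  if (!is.null(digits)) {
    freq_a_minor <- round(freq_a_minor, digits)
    freq_b_major <- round(freq_b_major, digits)
  }
  e_naive <- expected_counts(freq_a_minor, freq_b_major, n, "naive_product")
  e_hwe <- expected_counts(freq_a_minor, freq_b_major, n, "hwe_multinomial")
  tst <- observed_vs_expected_test(ct$all, e_naive)
  rows <- expand.grid(i = 1:3, j = 1:3)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(k) {
    i <- rows$i[k]; j <- rows$j[k]
    pe <- predict_expression(ct$labels$a[i], ct$labels$b[j])
    data.frame(
      genotype_a = ct$labels$a[[i]], genotype_b = ct$labels$b[[j]],
      observed = ct$all[i, j],
      expected_naive = e_naive$expected[i, j],
      expected_hwe = e_hwe$expected[i, j],
      p_value = tst$p_value[tst$row == ct$labels$a[[i]] &
                              tst$col == ct$labels$b[[j]]],
      erap2_dosage = pe$erap2_dosage,
      n392_dosage = as.character(pe$n392_dosage),
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "freqs") <- c(freq_a_minor = freq_a_minor,
                          freq_b_major = freq_b_major, n = n)
  out
}
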