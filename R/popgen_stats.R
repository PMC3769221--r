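# Single-SNP population-genetic tests: Hardy-Weinberg equilibrium,
# case-control association, Bonferroni control.

test_result <- function(statistic, df, p_value, method, ...) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, ...),
            class = "erap2hap_test")
}

#' @export
print.erap2hap_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests genotype counts at one SNP against the Hardy-Weinberg proportions
#' (p^2, 2pq, q^2) implied by the observed allele frequencies. The chi-square
#' mode is the 1-df goodness-of-fit test; the exact mode sums the
#' probabilities of all heterozygote counts no more probable than the one
#' observed, under the distribution of heterozygote count conditional on the
#' allele counts. By default the exact test is used when the minor-allele
#' count is below 100 and the chi-square test otherwise.
#'
#' @param counts A `genotype_counts` object.
#' @param method `"auto"`, `"chisq"` or `"exact"`.
#' @return An object with elements `statistic`, `df`, `p_value`, `method`.
#' @export
hwe_test <- function(counts, method = c("auto", "chisq", "exact")) {
  method <- match.arg(method)
  n_aa <- counts[["hom_major"]]; n_ab <- counts[["het"]]
  n_bb <- counts[["hom_minor"]]
  n <- n_aa + n_ab + n_bb
  if (n == 0L) stop("no non-missing genotypes", call. = FALSE)
  n_minor <- 2L * n_bb + n_ab
  if (n_minor == 0L || n_minor == 2L * n) {
    warning("monomorphic SNP: HWE test is degenerate, p = 1")
    return(test_result(0, NA_integer_, 1,
                       if (method == "exact") "hwe_exact" else "chisq"))
  }
  if (method == "auto") method <- if (n_minor < 100L) "exact" else "chisq"
  if (method == "chisq") {
    q <- n_minor / (2 * n); p <- 1 - q
    expected <- n * c(p^2, 2 * p * q, q^2)
    stat <- sum((c(n_aa, n_ab, n_bb) - expected)^2 / expected)
    test_result(stat, 1L, stats::pchisq(stat, 1, lower.tail = FALSE), "chisq")
  } else {
    test_result(NA_real_, NA_integer_, hwe_exact_p(n_aa, n_ab, n_bb),
                "hwe_exact")
  }
}

# Exact HWE p-value: distribution of the heterozygote count conditional on
# allele counts (Levene/Haldane); two-sided by summing configurations with
# probability <= that of the observed table.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_b <- 2L * n_bb + n_ab          # minor allele count
  hets <- seq.int(n_b %% 2L, min(n_b, 2L * n - n_b), by = 2L)
  log_p <- vapply(hets, function(h) {
    bb <- (n_b - h) / 2; aa <- n - h - bb
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(n_b + 1) + lgamma(2 * n - n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_p - max(log_p)); prob <- prob / sum(prob)
  p_obs <- prob[match(n_ab, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' Allelic case-control association (Fisher's exact test)
#'
#' Builds the 2x2 table of minor/major allele counts in cases and controls
#' and applies the two-sided Fisher exact test (summing the probabilities of
#' tables no more probable than the one observed). The odds ratio is the
#' sample OR of the allele table, with the Haldane-Anscombe 0.5 correction
#' applied only when a cell is zero.
#'
#' @param case,control `genotype_counts` objects for the two groups.
#' @return Test object with `p_value`, `odds_ratio` and the 2x2 `table`
#'   (rows case/control, columns minor/major).
#' @export
allelic_association <- function(case, control) {
  tab <- rbind(
    case    = allele_counts(case),
    control = allele_counts(control)
  )
  if (any(rowSums(tab) == 0)) stop("a group has zero typed alleles", call. = FALSE)
  ft <- stats::fisher.test(tab)
  or <- if (any(tab == 0)) {
    ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  test_result(NA_real_, NA_integer_, ft$p.value, "fisher_exact",
              odds_ratio = unname(or), table = tab)
}

allele_counts <- function(counts) {
  c(minor = 2L * counts[["hom_minor"]] + counts[["het"]],
    major = 2L * counts[["hom_major"]] + counts[["het"]])
}

#' Genotypic case-control association (Pearson chi-square)
#'
#' Pearson chi-square on the 3x2 genotype-by-group table. Genotype rows with
#' zero total are dropped and the degrees of freedom reduced accordingly
#' (df = remaining rows - 1).
#'
#' @param case,control `genotype_counts` objects.
#' @return Test object with `statistic`, `df`, `p_value`.
#' @export
genotypic_association <- function(case, control) {
  tab <- cbind(case = unclass(case)[1:3], control = unclass(control)[1:3])
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L) {
    stop("degenerate genotype table: fewer than two genotype classes observed",
         call. = FALSE)
  }
  if (any(colSums(tab) == 0)) stop("a group has zero typed samples", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(unname(ct$statistic), nrow(tab) - 1L, unname(ct$p.value), "chisq")
}

#' Bonferroni multiple-testing control
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Family-wise error rate, in (0, 1).
#' @return List with the corrected `threshold` (`alpha / m`), logical
#'   `reject` per test, and `p_adjusted` (`min(1, m * p)`).
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("empty p-value list", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  m <- length(p_values)
  list(threshold = alpha / m,
       reject = p_values <= alpha / m,
       p_adjusted = stats::p.adjust(p_values, method = "bonferroni"))
}
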