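# Seeded synthetic cohorts with a specified haplotype structure:
# random-mating diploid sampling from given haplotype frequencies, genotype
# missingness, and case/control labels from a logistic risk model. Presets
# emulate the two published ERAP2 haplotype structures.

#' Simulation configuration
#'
#' @param snp_defs Data frame of [snp_def()] rows, in locus order.
#' @param haplotypes Character vector of K-letter haplotype strings over the
#'   SNPs' alleles.
#' @param haplotype_freqs Frequencies of the haplotypes; must sum to 1.
#' @param n_samples Cohort size.
#' @param missing_rate Per-SNP probability that a call is missing.
#' @param case_model List with `intercept` (log-odds) and optionally
#'   `dosage_log_or` (named per SNP id: per-minor-allele log odds ratio)
#'   and/or `haplotype_log_or` (named per haplotype string: per-copy log
#'   odds ratio), and `interaction_log_or` (named `"snpA:snpB"`, log OR per
#'   dosage product unit).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(snp_defs, haplotypes, haplotype_freqs,
                       n_samples = 1100L, missing_rate = 0.003,
                       case_model = list(intercept = 0), seed = 1L) {
  K <- nrow(snp_defs)
  stopifnot(length(haplotypes) == length(haplotype_freqs))
  if (any(nchar(haplotypes) != K)) {
    stop("haplotype strings must have one letter per SNP", call. = FALSE)
  }
  for (j in seq_len(K)) {
    letters_j <- substr(haplotypes, j, j)
    legal <- c(snp_defs$major[j], snp_defs$minor[j])
    if (!all(letters_j %in% legal)) {
      stop("haplotype allele not in {", paste(legal, collapse = ","),
           "} at ", snp_defs$id[j], call. = FALSE)
    }
  }
  if (any(haplotype_freqs < 0) || abs(sum(haplotype_freqs) - 1) > 1e-8) {
    stop("haplotype frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0,1)", call. = FALSE)
  }
  structure(list(snp_defs = snp_defs, haplotypes = haplotypes,
                 haplotype_freqs = haplotype_freqs,
                 n_samples = as.integer(n_samples),
                 missing_rate = missing_rate, case_model = case_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Built-in population presets
#'
#' * `african_american_5snp`: the two-haplotype five-SNP system
#'   (rs2549782, rs2548538, rs2248374, rs2287988, rs1056893) with
#'   haplotypes GTAGC (all minor alleles) at 0.436 and TAGAT (all major)
#'   at 0.564 — near-perfect LD among all five SNPs.
#' * `chilean_4snp_plus_partial`: a four-SNP block (rs2548538, rs2248374,
#'   rs2287988, rs1056893) with haplotypes TAGC at 0.339 and AGAT at 0.661,
#'   onto which rs2549782 alleles (G at 0.33) are mixed so that the
#'   rs2549782-block D' is intermediate (target 0.53). The four 5-SNP
#'   haplotype classes (rs2549782 allele x block haplotype) are free
#'   parameters; `class_freqs` overrides the default mix, in order
#'   (G+TAGC, T+TAGC, G+AGAT, T+AGAT), and is renormalized. Setting the
#'   T+TAGC (rs2248374 A with rs2549782 T) class to zero makes the AA,TT
#'   compound homozygote structurally impossible.
#'
#' @param name Preset name.
#' @param n_samples,missing_rate,case_model,seed Passed to [sim_config()].
#' @param class_freqs Optional override of the Chilean haplotype-class mix.
#' @param dprime_target For the Chilean preset, the rs2549782-block D' used
#'   to derive the default mix (0.53).
#' @return A `sim_config`.
#' @export
preset <- function(name = c("african_american_5snp",
                            "chilean_4snp_plus_partial"),
                   n_samples = 1100L, missing_rate = 0.003,
                   case_model = list(intercept = 0), seed = 1L,
                   class_freqs = NULL, dprime_target = 0.53) {
  name <- match.arg(name)
  defs <- erap2_snps()
  if (name == "african_american_5snp") {
    haps <- c("GTAGC", "TAGAT")
    freqs <- c(0.436, 0.564)
  } else {
    # four 5-SNP classes: rs2549782 allele prepended to a block haplotype.
    # Block haplotype TAGC carries rs2248374 A (minor), AGAT carries G.
    p_g <- 0.33    # rs2549782 G (minor) frequency
    p_blk <- 0.339 # TAGC block-haplotype frequency
    if (is.null(class_freqs)) {
      d_max <- min(p_g * (1 - p_blk), (1 - p_g) * p_blk)
      d <- dprime_target * d_max
      g_tagc <- p_g * p_blk + d
      class_freqs <- c(g_tagc, p_blk - g_tagc, p_g - g_tagc,
                       1 - p_blk - (p_g - g_tagc))
    }
    if (any(class_freqs < 0)) stop("negative haplotype-class frequency",
                                   call. = FALSE)
    freqs <- class_freqs / sum(class_freqs)
    haps <- c("GTAGC", "TTAGC", "GAGAT", "TAGAT")
    keep <- freqs > 0
    haps <- haps[keep]; freqs <- freqs[keep]
  }
  sim_config(defs, haps, freqs, n_samples = n_samples,
             missing_rate = missing_rate, case_model = case_model,
             seed = seed)
}

#' Simulate a cohort from a configuration
#'
#' Each sample receives two independent haplotype draws (random mating),
#' collapsed to unphased minor-allele dosages; missing calls are then
#' applied independently per (sample, SNP). The true diplotypes are kept in
#' the result for downstream oracles.
#'
#' @param config A [sim_config()].
#' @return A [genotype_table()] with an extra element `diplotypes`, an
#'   n x 2 matrix of haplotype-string draws.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  K <- nrow(config$snp_defs)
  hap_idx <- matrix(sample.int(length(config$haplotypes), 2 * n, replace = TRUE,
                               prob = config$haplotype_freqs), n, 2)
  hap_dosage <- t(vapply(config$haplotypes, function(h) {
    as.integer(strsplit(h, "")[[1]] == config$snp_defs$minor)
  }, integer(K)))
  dosage <- hap_dosage[hap_idx[, 1], , drop = FALSE] +
    hap_dosage[hap_idx[, 2], , drop = FALSE]
  if (config$missing_rate > 0) {
    dosage[matrix(stats::runif(n * K) < config$missing_rate, n, K)] <- NA_integer_
  }
  tab <- genotype_table(sprintf("S%04d", seq_len(n)), config$snp_defs, dosage)
  tab$diplotypes <- matrix(config$haplotypes[hap_idx], n, 2)
  tab
}

#' Draw case/control labels from a logistic risk model
#'
#' The per-sample linear predictor is the model intercept plus any per-SNP
#' dosage effects, per-haplotype copy effects (computed from the true
#' diplotypes), and dosage-product interaction effects. Case status is a
#' Bernoulli draw from the inverse-logit of that predictor.
#'
#' @param cohort A cohort from [simulate_cohort()] (diplotypes required for
#'   haplotype effects).
#' @param case_model See [sim_config()].
#' @param stratum Stratum recorded in the labels (`"fetal"` default).
#' @param seed Integer seed.
#' @return A [cohort_labels()] covering every sample.
#' @export
attach_case_status <- function(cohort, case_model = list(intercept = 0),
                               stratum = "fetal", seed = 1L) {
  n <- length(cohort$samples)
  eta <- rep(case_model$intercept %||% 0, n)
  true_dosage <- NULL
  if (!is.null(case_model$dosage_log_or) ||
      !is.null(case_model$interaction_log_or)) {
    if (is.null(cohort$diplotypes)) {
      true_dosage <- cohort$dosage  # observed calls; NA treated as 0 effect
    } else {
      K <- nrow(cohort$snps)
      hd <- vapply(seq_len(K), function(j)
        (substr(cohort$diplotypes[, 1], j, j) == cohort$snps$minor[j]) +
          (substr(cohort$diplotypes[, 2], j, j) == cohort$snps$minor[j]),
        numeric(n))
      true_dosage <- matrix(hd, n, K, dimnames = list(NULL, cohort$snps$id))
    }
  }
  for (snp in names(case_model$dosage_log_or)) {
    if (!snp %in% cohort$snps$id) stop("case model references unknown SNP: ",
                                       snp, call. = FALSE)
    d <- true_dosage[, snp]
    eta <- eta + ifelse(is.na(d), 0, d) * case_model$dosage_log_or[[snp]]
  }
  for (hap in names(case_model$haplotype_log_or)) {
    if (is.null(cohort$diplotypes)) {
      stop("haplotype effects need the true diplotypes", call. = FALSE)
    }
    if (!(hap %in% cohort$diplotypes)) {
      stop("case model references unknown haplotype: ", hap, call. = FALSE)
    }
    copies <- (cohort$diplotypes[, 1] == hap) + (cohort$diplotypes[, 2] == hap)
    eta <- eta + copies * case_model$haplotype_log_or[[hap]]
  }
  for (pair in names(case_model$interaction_log_or)) {
    snps <- strsplit(pair, ":")[[1]]
    if (!all(snps %in% cohort$snps$id)) {
      stop("case model references unknown SNP pair: ", pair, call. = FALSE)
    }
    prod_dose <- true_dosage[, snps[1]] * true_dosage[, snps[2]]
    eta <- eta + ifelse(is.na(prod_dose), 0, prod_dose) *
      case_model$interaction_log_or[[pair]]
  }
  set.seed(seed)
  is_case <- stats::runif(n) < stats::plogis(eta)
  cohort_labels(cohort$samples,
                ifelse(is_case, "case", "control"),
                rep(stratum, n), table = cohort)
}
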