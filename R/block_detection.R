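# Haplotype-block calling from pairwise LD, under the three classic rules:
# D'-confidence-interval (Gabriel-style), four-gamete, and solid spine.
# SNP "position" is input order; no physical distances are used.

block_set <- function(method, blocks, snps, parameters, diagnostics = list()) {
  structure(list(method = method, blocks = blocks, snps = snps,
                 parameters = parameters, diagnostics = diagnostics),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat("block_set (", x$method, "): ", length(x$blocks), " block(s)\n", sep = "")
  for (b in x$blocks) {
    cat("  ", paste(x$snps[b[1]:b[2]], collapse = " - "), "\n")
  }
  invisible(x)
}

#' SNP membership of each block
#' @param bs A `block_set`.
#' @return List of character vectors of SNP ids, one per block.
#' @export
block_members <- function(bs) {
  lapply(bs$blocks, function(b) bs$snps[b[1]:b[2]])
}

# Likelihood-based confidence interval for |D'| of one SNP pair, from the
# 2-locus genotype likelihood profiled over a |D'| grid at the observed
# allele-frequency margins (the construction popularized by Haploview).
dprime_ci <- function(table, snp_a, snp_b, grid_step = 0.01) {
  ia <- snp_index(table, snp_a); ib <- snp_index(table, snp_b)
  dos <- table$dosage[, c(ia, ib), drop = FALSE]
  dos <- dos[stats::complete.cases(dos), , drop = FALSE]
  if (!nrow(dos)) return(NULL)
  counts <- table(factor(dos[, 1], 0:2), factor(dos[, 2], 0:2))
  p_a <- mean(dos[, 1]) / 2; p_b <- mean(dos[, 2]) / 2
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) return(NULL)
  mle <- pair_ld(table, snp_a, snp_b)
  sgn <- if (is.na(mle$D) || mle$D >= 0) 1 else -1
  d_max <- if (sgn > 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else         min(p_a * p_b, (1 - p_a) * (1 - p_b))
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, function(d) {
    p11 <- p_a * p_b + sgn * d * d_max
    pair_loglik(counts, p11, p_a, p_b)
  }, numeric(1))
  w <- exp(ll - max(ll)); w <- w / sum(w)
  cs <- cumsum(w)
  low <- grid[min(which(cs >= 0.05))]
  high <- grid[max(which(rev(cumsum(rev(w))) >= 0.05))]
  list(low = low, high = high, mle = mle$D_prime)
}

# Log-likelihood of a 3x3 unphased genotype count table given the
# minor-minor haplotype frequency p11 and allele-frequency margins.
pair_loglik <- function(counts, p11, p_a, p_b) {
  h_mm <- p11
  h_mM <- p_a - p11            # minor at A, major at B
  h_Mm <- p_b - p11            # major at A, minor at B
  h_MM <- 1 - p_a - p_b + p11
  h <- c(h_mm, h_mM, h_Mm, h_MM)
  if (any(h < -1e-12)) return(-Inf)
  h <- pmax(h, 1e-12)
  P <- matrix(0, 3, 3)  # rows dosage at A, cols dosage at B
  P[1, 1] <- h[4]^2;          P[1, 2] <- 2 * h[4] * h[3]; P[1, 3] <- h[3]^2
  P[2, 1] <- 2 * h[4] * h[2]; P[2, 2] <- 2 * (h[1] * h[4] + h[2] * h[3])
  P[2, 3] <- 2 * h[3] * h[1]
  P[3, 1] <- h[2]^2;          P[3, 2] <- 2 * h[1] * h[2]; P[3, 3] <- h[1]^2
  sum(counts * log(pmax(P, 1e-300)))
}

# Greedy block assembly: candidate spans evaluated longest first, accepted
# when valid() holds and they do not overlap an accepted block.
assemble_blocks <- function(K, valid) {
  spans <- list()
  for (len in seq.int(K, 2L)) {
    for (i in seq_len(K - len + 1L)) spans <- c(spans, list(c(i, i + len - 1L)))
  }
  taken <- rep(FALSE, K)
  blocks <- list()
  for (s in spans) {
    rng <- s[1]:s[2]
    if (any(taken[rng])) next
    if (valid(s[1], s[2])) {
      blocks <- c(blocks, list(s))
      taken[rng] <- TRUE
    }
  }
  blocks[order(vapply(blocks, `[`, integer(1), 1))]
}

#' Haplotype blocks by D' confidence intervals (Gabriel-style)
#'
#' Classifies each SNP pair by a likelihood-based confidence interval on
#' |D'|: "strong LD" when the lower bound is at least `ci_low` and the upper
#' at least `ci_high`; "strong evidence of recombination" when the upper
#' bound falls below `recomb_bound`. A span of SNPs is a block when its
#' outermost pair is in strong LD and at least `informative_fraction` of its
#' informative pairs (strong LD + recombination) are strong LD. Spans are
#' accepted longest-first without overlap.
#'
#' @param table A [genotype_table()].
#' @param snps SNP ids in locus order.
#' @param ci_low,ci_high Strong-LD bounds on the D' CI (defaults 0.70/0.98).
#' @param informative_fraction Minimum strong-LD share of informative pairs.
#' @param recomb_bound CI upper bound below which a pair counts as
#'   recombinant.
#' @return A `block_set`.
#' @export
blocks_confidence_interval <- function(table, snps, ci_low = 0.70,
                                       ci_high = 0.98,
                                       informative_fraction = 0.95,
                                       recomb_bound = 0.90) {
  K <- length(snps)
  if (K < 2L) return(block_set("confidence_interval", list(), snps,
                               list(ci_low = ci_low, ci_high = ci_high)))
  strong <- recomb <- matrix(FALSE, K, K)
  ci_store <- list()
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      ci <- dprime_ci(table, snps[i], snps[j])
      if (is.null(ci)) next
      ci_store[[paste(snps[i], snps[j], sep = "|")]] <- ci
      strong[i, j] <- strong[j, i] <- ci$low >= ci_low && ci$high >= ci_high
      recomb[i, j] <- recomb[j, i] <- ci$high < recomb_bound
    }
  }
  valid <- function(i, j) {
    if (!strong[i, j]) return(FALSE)
    pairs <- utils::combn(i:j, 2)
    s <- sum(strong[t(pairs)]); r <- sum(recomb[t(pairs)])
    inf <- s + r
    inf > 0 && s / inf >= informative_fraction
  }
  block_set("confidence_interval", assemble_blocks(K, valid), snps,
            list(ci_low = ci_low, ci_high = ci_high,
                 informative_fraction = informative_fraction,
                 recomb_bound = recomb_bound),
            diagnostics = list(ci = ci_store))
}

#' Haplotype blocks by the four-gamete rule
#'
#' For each adjacent SNP pair the four 2-locus haplotype (gamete)
#' frequencies are estimated by EM; a recombination break is declared
#' between the two SNPs when all four gametes reach frequency
#' `fourth_gamete_min`. Maximal unbroken runs of at least two SNPs are
#' blocks.
#'
#' @inheritParams blocks_confidence_interval
#' @param fourth_gamete_min Minimum frequency for a gamete to count as
#'   observed (default 0.01).
#' @return A `block_set`.
#' @export
blocks_four_gamete <- function(table, snps, fourth_gamete_min = 0.01) {
  K <- length(snps)
  params <- list(fourth_gamete_min = fourth_gamete_min)
  if (K < 2L) return(block_set("four_gamete", list(), snps, params))
  breaks <- logical(K - 1L)
  gametes <- integer(K - 1L)
  for (i in seq_len(K - 1L)) {
    dist <- em_haplotype_freqs(table, snps[c(i, i + 1L)])
    gametes[i] <- sum(dist$freq >= fourth_gamete_min)
    breaks[i] <- gametes[i] == 4L
  }
  blocks <- list()
  start <- 1L
  for (i in seq_len(K - 1L)) {
    if (breaks[i]) {
      if (i > start) blocks <- c(blocks, list(c(start, i)))
      start <- i + 1L
    }
  }
  if (K > start) blocks <- c(blocks, list(c(start, K)))
  block_set("four_gamete", blocks, snps, params,
            diagnostics = list(n_gametes = gametes))
}

#' Haplotype blocks by solid-spine-of-LD
#'
#' A run of SNPs forms a spine when its first and its last SNP each have
#' D' of at least `dprime_min` with every intermediate SNP (for a run of
#' two, with each other). Runs are accepted longest-first without overlap.
#' Whether all interior pairs of each block are themselves in strong LD is
#' reported as a per-block diagnostic (`min_inner_dprime` and any weak
#' pairs), not enforced by the rule.
#'
#' @inheritParams blocks_confidence_interval
#' @param dprime_min Spine threshold on D' (default 0.80).
#' @return A `block_set`.
#' @export
blocks_solid_spine <- function(table, snps, dprime_min = 0.80) {
  K <- length(snps)
  params <- list(dprime_min = dprime_min)
  if (K < 2L) return(block_set("solid_spine", list(), snps, params))
  lm <- ld_matrix(table, snps)
  Dp <- lm$D_prime
  valid <- function(i, j) {
    if (j == i + 1L) return(isTRUE(Dp[i, j] >= dprime_min))
    mid <- (i + 1L):(j - 1L)
    all(Dp[i, mid] >= dprime_min, na.rm = FALSE) &&
      all(Dp[mid, j] >= dprime_min, na.rm = FALSE)
  }
  blocks <- assemble_blocks(K, valid)
  diag <- lapply(blocks, function(b) {
    pairs <- utils::combn(b[1]:b[2], 2)
    vals <- Dp[t(pairs)]
    weak <- which(vals < dprime_min)
    list(min_inner_dprime = min(vals),
         weak_pairs = if (length(weak)) {
           apply(pairs[, weak, drop = FALSE], 2,
                 function(p) paste(snps[p], collapse = "|"))
         } else character(0))
  })
  block_set("solid_spine", blocks, snps, params,
            diagnostics = list(per_block = diag, ld = lm))
}

#' Blocks report as a data frame
#'
#' One row per block: `method`, `block_index`, `first_snp`, `last_snp`,
#' `n_snps`. Suitable for writing as TSV.
#' @param bs A `block_set`.
#' @export
block_table <- function(bs) {
  if (!length(bs$blocks)) {
    return(data.frame(method = character(0), block_index = integer(0),
                      first_snp = character(0), last_snp = character(0),
                      n_snps = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(
    method = bs$method,
    block_index = seq_along(bs$blocks),
    first_snp = vapply(bs$blocks, function(b) bs$snps[b[1]], character(1)),
    last_snp = vapply(bs$blocks, function(b) bs$snps[b[2]], character(1)),
    n_snps = vapply(bs$blocks, function(b) b[2] - b[1] + 1L, integer(1)),
    stringsAsFactors = FALSE
  )
}
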