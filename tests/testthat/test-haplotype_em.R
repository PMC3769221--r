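test_that("a cohort homozygous at both SNPs yields a single haplotype", {
  tab <- table_from_dosage(pair_defs(), snpA = rep(2L, 10), snpB = rep(2L, 10))
  d <- em_haplotype_freqs(tab, c("snpA", "snpB"))
  expect_equal(d$haplotype, "GC")
  expect_equal(d$freq, 1)
})

test_that("EM on the Chilean fetal pair matches the fixed-point oracle", {
  co <- fetal_cohort()
  d <- em_haplotype_freqs(co$table, c("rs2248374", "rs2549782"))
  oracle <- fetal_em_oracle()
  expect_equal(oracle$m, 25.05, tolerance = 0.01)
  got <- setNames(d$freq, d$haplotype)
  expect_equal(got[["AT"]], oracle$freqs[["AT"]], tolerance = 1e-3)
  expect_equal(got[["AG"]], oracle$freqs[["AG"]], tolerance = 1e-3)
  expect_equal(got[["GT"]], oracle$freqs[["GT"]], tolerance = 1e-3)
  expect_equal(got[["GG"]], oracle$freqs[["GG"]], tolerance = 1e-3)
  expect_equal(d$n_used, 1097L)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  co <- fetal_cohort()
  d <- em_haplotype_freqs(co$table, c("rs2248374", "rs2549782"))
  expect_true(all(diff(d$log_likelihood_path) > -1e-9))
  cfg <- preset("chilean_4snp_plus_partial", n_samples = 300, seed = 9)
  coh <- simulate_cohort(cfg)
  d5 <- em_haplotype_freqs(coh, coh$snps$id)
  expect_true(all(diff(d5$log_likelihood_path) > -1e-9))
})

test_that("EM margins equal observed allele frequencies exactly", {
  set.seed(31)
  for (i in 1:10) {
    cfg <- preset("chilean_4snp_plus_partial", n_samples = 150,
                  missing_rate = 0, seed = i)
    coh <- simulate_cohort(cfg)
    snps <- c("rs2248374", "rs2549782")
    d <- em_haplotype_freqs(coh, snps, prune = 0)
    for (s in snps) {
      obs <- allele_frequency(genotype_counts(coh, s))
      pos <- match(s, snps)
      minor <- coh$snps$minor[match(s, coh$snps$id)]
      em_freq <- sum(d$freq[substr(d$haplotype, pos, pos) == minor])
      expect_equal(em_freq, obs, tolerance = 1e-7)
    }
  }
})

test_that("2-locus EM equals a grid-search likelihood maximizer", {
  # oracle: brute-force over the one free coupling frequency at fixed
  # observed margins, maximizing the unphased-genotype likelihood
  grid_oracle <- function(counts9) {
    n <- sum(counts9)
    pa <- sum(counts9 * matrix(0:2, 3, 3)) / (2 * n)
    pb <- sum(counts9 * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
    lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
    grid <- seq(lo, hi, by = 1e-4)
    ll <- vapply(grid, function(p11) {
      h <- c(p11, pa - p11, pb - p11, 1 - pa - pb + p11)
      if (any(h < 0)) return(-Inf)
      h <- pmax(h, 1e-12)
      P <- matrix(0, 3, 3)
      P[1, 1] <- h[4]^2;          P[1, 2] <- 2 * h[4] * h[3]; P[1, 3] <- h[3]^2
      P[2, 1] <- 2 * h[4] * h[2]; P[2, 2] <- 2 * (h[1] * h[4] + h[2] * h[3])
      P[2, 3] <- 2 * h[3] * h[1]
      P[3, 1] <- h[2]^2;          P[3, 2] <- 2 * h[1] * h[2]; P[3, 3] <- h[1]^2
      sum(counts9 * log(pmax(P, 1e-300)))
    }, numeric(1))
    grid[which.max(ll)]
  }
  set.seed(17)
  for (i in 1:8) {
    counts9 <- matrix(rmultinom(1, sample(15:50, 1), rep(1 / 9, 9)), 3, 3)
    pa <- sum(counts9 * matrix(0:2, 3, 3)) / (2 * sum(counts9))
    pb <- sum(counts9 * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * sum(counts9))
    if (pa %in% c(0, 1) || pb %in% c(0, 1)) next
    # expand counts into a dosage table and run the package EM
    idx <- which(counts9 > 0, arr.ind = TRUE)
    dos <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
      matrix(rep(c(idx[k, 1] - 1L, idx[k, 2] - 1L), counts9[idx[k, 1], idx[k, 2]]),
             ncol = 2, byrow = TRUE)
    }))
    tab <- table_from_dosage(pair_defs(), snpA = dos[, 1], snpB = dos[, 2])
    d <- em_haplotype_freqs(tab, c("snpA", "snpB"), prune = 0)
    em_p11 <- sum(d$freq[d$haplotype == "GC"])  # minor-minor haplotype
    expect_equal(em_p11, grid_oracle(counts9), tolerance = 1e-3)
  }
})

test_that("EM recovers the generating 5-SNP haplotype frequencies", {
  cfg <- preset("african_american_5snp", n_samples = 1100, seed = 101)
  coh <- simulate_cohort(cfg)
  d <- em_haplotype_freqs(coh, coh$snps$id)
  se <- sqrt(0.436 * 0.564 / (2 * 1100))
  got <- setNames(d$freq, d$haplotype)
  expect_lt(abs(got[["GTAGC"]] - 0.436), 3 * se)
  expect_lt(abs(got[["TAGAT"]] - 0.564), 3 * se)
})

test_that("pairwise LD matches closed forms on the fetal pair", {
  co <- fetal_cohort()
  d <- em_haplotype_freqs(co$table, c("rs2248374", "rs2549782"))
  ld <- pairwise_ld(d, co$table$snps)
  oracle <- fetal_em_oracle()
  p_a <- oracle$freqs[["AT"]] + oracle$freqs[["AG"]]   # rs2248374 A
  p_b <- oracle$freqs[["AG"]] + oracle$freqs[["GG"]]   # rs2549782 G
  D <- oracle$freqs[["AG"]] - p_a * p_b
  d_max <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
  expect_equal(ld$D, D, tolerance = 1e-3)
  expect_equal(abs(ld$D), 0.107, tolerance = 0.01)
  expect_equal(ld$D_prime, D / d_max, tolerance = 1e-3)
  expect_equal(ld$D_prime, 0.49, tolerance = 0.005)
  expect_equal(ld$r_squared,
               D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)), tolerance = 1e-3)
  expect_equal(ld$r_squared, 0.23, tolerance = 0.01)
})

test_that("two-haplotype systems give D' = 1 and r2 = 1", {
  cfg <- preset("african_american_5snp", n_samples = 400, seed = 5)
  coh <- simulate_cohort(cfg)
  ld <- erap2hap:::pair_ld(coh, "rs2549782", "rs2248374")
  expect_equal(ld$D_prime, 1, tolerance = 1e-6)
  expect_equal(ld$r_squared, 1, tolerance = 1e-6)
  # balanced two-haplotype system likewise
  pairs <- cbind(rep(c("AT", "GC"), each = 10), rep(c("AT", "GC"), 10))
  tab <- table_from_diplotypes(pair_defs(), pairs)
  ld2 <- erap2hap:::pair_ld(tab, "snpA", "snpB")
  expect_equal(ld2$D_prime, 1)
  expect_equal(ld2$r_squared, 1)
})

test_that("r2 <= D'^2 and both lie in [0,1] for random tables", {
  set.seed(53)
  for (i in 1:20) {
    f <- rgamma(4, 1); f <- f / sum(f)
    haps <- c("AT", "AC", "GT", "GC")
    draws <- matrix(sample(haps, 120, TRUE, prob = f), ncol = 2)
    tab <- table_from_diplotypes(pair_defs(), draws)
    ld <- tryCatch(erap2hap:::pair_ld(tab, "snpA", "snpB"),
                   error = function(e) NULL)
    if (is.null(ld) || isTRUE(ld$monomorphic)) next
    expect_gte(ld$D_prime, 0); expect_lte(ld$D_prime, 1)
    expect_gte(ld$r_squared, 0); expect_lte(ld$r_squared, 1)
    expect_lte(ld$r_squared, ld$D_prime^2 + 1e-9)
  }
})

test_that("a vanished haplotype class forces D' = 1", {
  # only three of the four gametes present
  draws <- rbind(matrix(rep(c("AT", "AT"), 20), ncol = 2, byrow = TRUE),
                 matrix(rep(c("GC", "GC"), 15), ncol = 2, byrow = TRUE),
                 matrix(rep(c("AC", "GC"), 12), ncol = 2, byrow = TRUE))
  tab <- table_from_diplotypes(pair_defs(), draws)
  ld <- erap2hap:::pair_ld(tab, "snpA", "snpB")
  expect_equal(ld$D_prime, 1, tolerance = 1e-6)
})

test_that("monomorphic SNPs yield a flagged LD result", {
  tab <- table_from_dosage(pair_defs(), snpA = rep(0L, 20),
                           snpB = sample(0:2, 20, TRUE))
  d <- em_haplotype_freqs(tab, c("snpA", "snpB"))
  ld <- pairwise_ld(d, tab$snps)
  expect_true(ld$monomorphic)
  expect_true(is.na(ld$D_prime))
})

test_that("ld_matrix is symmetric with unit r2 for perfectly linked SNPs", {
  cfg <- preset("african_american_5snp", n_samples = 300, seed = 13)
  coh <- simulate_cohort(cfg)
  lm <- ld_matrix(coh, coh$snps$id)
  off <- lm$r_squared[upper.tri(lm$r_squared)]
  expect_length(off, 10)
  expect_true(all(abs(off - 1) < 1e-6))
  expect_identical(lm$D_prime, t(lm$D_prime))
  expect_identical(lm$r_squared, t(lm$r_squared))
  expect_true(all(is.na(diag(lm$r_squared))))
})

test_that("Chilean preset shows a strong 4-SNP core and intermediate D'", {
  cfg <- preset("chilean_4snp_plus_partial", n_samples = 1100, seed = 19)
  coh <- simulate_cohort(cfg)
  lm <- ld_matrix(coh, coh$snps$id)
  core <- setdiff(coh$snps$id, "rs2549782")
  core_dp <- lm$D_prime[core, core]
  expect_true(all(abs(core_dp[upper.tri(core_dp)] - 1) < 0.02))
  partial <- lm$D_prime["rs2549782", core]
  se3 <- 0.1  # recovery band for the mixing target
  expect_true(all(abs(partial - 0.53) < se3))
})
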