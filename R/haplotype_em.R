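# EM estimation of multi-locus haplotype frequencies from unphased
# genotypes (Excoffier-Slatkin style gene counting), and the pairwise LD
# statistics D, D' and r^2 derived from the fitted 2-locus distribution.
#
# Haplotypes over K SNPs are encoded as integers 0 .. 2^K - 1, one bit per
# SNP (bit set = minor allele), and rendered as allele-letter strings for
# output. Samples are collapsed to unique multi-locus dosage patterns before
# the EM loop, so cost scales with 3^K patterns, not cohort size.

hap_index_to_string <- function(idx, snp_defs) {
  K <- nrow(snp_defs)
  vapply(idx, function(h) {
    bits <- bitwAnd(bitwShiftR(h, seq_len(K) - 1L), 1L)
    paste0(ifelse(bits == 1L, snp_defs$minor, snp_defs$major), collapse = "")
  }, character(1))
}

# Enumerate the unordered haplotype pairs compatible with one dosage
# pattern. Returns a 2-column matrix of haplotype codes; the first listed
# heterozygous site is pinned to haplotype 1 so each unordered pair appears
# once.
compatible_pairs <- function(dosage) {
  K <- length(dosage)
  base <- sum(bitwShiftL(1L, which(dosage == 2L) - 1L))
  het <- which(dosage == 1L)
  if (!length(het)) return(matrix(base, 1, 2))
  first <- bitwShiftL(1L, het[1] - 1L)
  rest <- het[-1]
  n_rest <- length(rest)
  subsets <- if (n_rest == 0L) 0L else {
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), n_rest))
    bits <- bitwShiftL(1L, rest - 1L)
    as.integer(as.matrix(combos) %*% bits)
  }
  het_mask <- sum(bitwShiftL(1L, het - 1L))
  h1 <- base + first + subsets
  h2 <- base + (het_mask - (first + subsets))
  cbind(h1, h2)
}

#' EM haplotype-frequency estimation from unphased genotypes
#'
#' Maximum-likelihood estimation of population haplotype frequencies over K
#' ordered SNPs, treating each sample's two haplotypes as latent. The
#' expectation step distributes each ambiguous diplotype across its
#' compatible haplotype pairs in proportion to the current frequency
#' products; the maximization step is gene counting. The log-likelihood is
#' non-decreasing across iterations; the best of `restarts` initializations
#' is returned (the first start splits ambiguous mass equally, the rest are
#' random).
#'
#' Samples with a missing call at any of the K SNPs are dropped
#' (complete-case), consistent with per-SNP pairwise deletion elsewhere.
#' Haplotypes with fitted frequency below `prune` are reported as zero and
#' the remainder renormalized.
#'
#' @param table A [genotype_table()].
#' @param snps Ordered character vector of 2 to 10 SNP ids.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations per start.
#' @param restarts Number of initializations.
#' @param seed Integer seed for the random restarts.
#' @param prune Reporting threshold for tiny frequencies.
#' @return Object of class `haplotype_freqs`: `snp_order`, `haplotype`
#'   (letter strings), `freq`, `log_likelihood`, `n_iterations`,
#'   `converged`, `n_used`.
#' @export
em_haplotype_freqs <- function(table, snps, tol = 1e-9, max_iter = 1000L,
                               restarts = 5L, seed = 1L, prune = 1e-6) {
  K <- length(snps)
  if (K < 2L || K > 10L) stop("need between 2 and 10 SNPs", call. = FALSE)
  idx <- vapply(snps, snp_index, integer(1), table = table)
  dos <- table$dosage[, idx, drop = FALSE]
  complete <- stats::complete.cases(dos)
  if (!any(complete)) stop("no samples with complete calls at the requested SNPs",
                           call. = FALSE)
  dos <- dos[complete, , drop = FALSE]
  pat_key <- apply(dos, 1, paste, collapse = "")
  pat_count <- table(pat_key)
  pat_dos <- dos[match(names(pat_count), pat_key), , drop = FALSE]
  fit <- em_fit_patterns(pat_dos, as.vector(pat_count), K, tol, max_iter,
                         restarts, seed)
  freq <- fit$freq
  freq[freq < prune] <- 0
  freq <- freq / sum(freq)
  keep <- freq > 0
  ord <- order(freq[keep], decreasing = TRUE)
  haps <- hap_index_to_string(which(keep) - 1L, table$snps[idx, , drop = FALSE])
  structure(list(snp_order = snps,
                 haplotype = haps[ord],
                 freq = unname(freq[keep][ord]),
                 log_likelihood = fit$loglik,
                 n_iterations = fit$iter,
                 converged = fit$converged,
                 log_likelihood_path = fit$loglik_path,
                 n_used = sum(complete)),
            class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat("haplotype frequencies (", paste(x$snp_order, collapse = ", "), "), n =",
      x$n_used, "\n")
  for (i in seq_along(x$haplotype)) {
    cat(sprintf("  %s  %.4f\n", x$haplotype[i], x$freq[i]))
  }
  cat(sprintf("logLik %.3f after %d iterations%s\n", x$log_likelihood,
              x$n_iterations, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# EM core on collapsed dosage patterns. pat_dos: patterns x K dosage matrix,
# counts: pattern multiplicities.
em_fit_patterns <- function(pat_dos, counts, K, tol, max_iter, restarts, seed) {
  n_hap <- 2L^K
  pairs <- lapply(seq_len(nrow(pat_dos)), function(i)
    compatible_pairs(pat_dos[i, ]) + 1L)  # 1-based
  n2 <- 2 * sum(counts)
  run_once <- function(freq) {
    loglik_prev <- -Inf; iter <- 0L; converged <- FALSE
    loglik_path <- numeric(0)
    repeat {
      iter <- iter + 1L
      hap_mass <- numeric(n_hap)
      loglik <- 0
      for (i in seq_along(pairs)) {
        pr <- pairs[[i]]
        w <- freq[pr[, 1]] * freq[pr[, 2]] * ifelse(pr[, 1] == pr[, 2], 1, 2)
        tot <- sum(w)
        if (tot <= 0) { loglik <- -Inf; break }
        loglik <- loglik + counts[i] * log(tot)
        w <- w / tot * counts[i]
        for (r in seq_len(nrow(pr))) {
          hap_mass[pr[r, 1]] <- hap_mass[pr[r, 1]] + w[r]
          hap_mass[pr[r, 2]] <- hap_mass[pr[r, 2]] + w[r]
        }
      }
      freq <- hap_mass / n2
      loglik_path <- c(loglik_path, loglik)
      if (is.finite(loglik) && abs(loglik - loglik_prev) < tol) {
        converged <- TRUE
        loglik_prev <- loglik
        break
      }
      loglik_prev <- loglik
      if (iter >= max_iter) break
    }
    list(freq = freq, loglik = loglik_prev, iter = iter, converged = converged,
         loglik_path = loglik_path)
  }
  # first start: equal split of ambiguous mass == EM step from uniform freqs
  starts <- list(rep(1 / n_hap, n_hap))
  if (restarts > 1L) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    for (s in seq_len(restarts - 1L)) {
      g <- stats::rgamma(n_hap, shape = 1)
      starts[[s + 1L]] <- g / sum(g)
    }
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
  fits <- lapply(starts, run_once)
  best <- which.max(vapply(fits, `[[`, numeric(1), "loglik"))
  out <- fits[[best]]
  if (!out$converged) {
    warning("EM did not converge within ", max_iter, " iterations")
  }
  out
}

#' Pairwise LD statistics from a 2-SNP haplotype distribution
#'
#' Computes D, D' and r^2 for a SNP pair from fitted 2-locus haplotype
#' frequencies. D is defined on the haplotype carrying the minor allele at
#' both SNPs: `D = p_mm - p_a * p_b` with `p_a`, `p_b` the minor-allele
#' frequencies. `D' = |D| / D_max` where `D_max = min(p_a (1 - p_b),
#' (1 - p_a) p_b)` for D > 0 and `min(p_a p_b, (1 - p_a)(1 - p_b))` for
#' D < 0; `r^2 = D^2 / (p_a (1-p_a) p_b (1-p_b))`.
#'
#' @param dist A `haplotype_freqs` object over exactly 2 SNPs, or a
#'   length-4 numeric vector of haplotype frequencies named with 2-letter
#'   strings plus attributes supplied by the internal pair fitter.
#' @param snp_defs SNP definitions for the pair (taken from the
#'   distribution when fitted through [em_haplotype_freqs()]).
#' @return Object of class `ld_stats`: `D`, `D_prime`, `r_squared`, `p_a`,
#'   `p_b`, `n_used`, `monomorphic`.
#' @export
pairwise_ld <- function(dist, snp_defs = NULL) {
  if (!inherits(dist, "haplotype_freqs") || length(dist$snp_order) != 2L) {
    stop("pairwise_ld needs a 2-SNP haplotype distribution", call. = FALSE)
  }
  if (is.null(snp_defs)) stop("snp_defs required", call. = FALSE)
  minor1 <- snp_defs$minor[1]; minor2 <- snp_defs$minor[2]
  a1 <- substr(dist$haplotype, 1, 1); a2 <- substr(dist$haplotype, 2, 2)
  p_a <- sum(dist$freq[a1 == minor1])
  p_b <- sum(dist$freq[a2 == minor2])
  ld_from_freqs(sum(dist$freq[a1 == minor1 & a2 == minor2]), p_a, p_b,
                n_used = dist$n_used)
}

ld_from_freqs <- function(p_mm, p_a, p_b, n_used = NA_integer_) {
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    return(structure(list(D = NA_real_, D_prime = NA_real_,
                          r_squared = NA_real_, p_a = p_a, p_b = p_b,
                          n_used = n_used, monomorphic = TRUE),
                     class = "ld_stats"))
  }
  D <- p_mm - p_a * p_b
  d_max <- if (D >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else        min(p_a * p_b, (1 - p_a) * (1 - p_b))
  D_prime <- if (d_max == 0) 1 else min(1, abs(D) / d_max)
  r2 <- D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  structure(list(D = D, D_prime = D_prime, r_squared = min(1, r2),
                 p_a = p_a, p_b = p_b, n_used = n_used, monomorphic = FALSE),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  if (isTRUE(x$monomorphic)) {
    cat("ld_stats: monomorphic pair, LD undefined\n")
  } else {
    cat(sprintf("ld_stats: D = %.4f, D' = %.3f, r2 = %.3f (n = %s)\n",
                x$D, x$D_prime, x$r_squared, x$n_used))
  }
  invisible(x)
}

# Fit the 2-locus EM for one SNP pair and return ld_stats; shared by
# ld_matrix and the block callers.
pair_ld <- function(table, snp_a, snp_b, tol = 1e-9, max_iter = 1000L,
                    restarts = 5L, seed = 1L) {
  dist <- em_haplotype_freqs(table, c(snp_a, snp_b), tol = tol,
                             max_iter = max_iter, restarts = restarts,
                             seed = seed)
  defs <- table$snps[c(snp_index(table, snp_a), snp_index(table, snp_b)), ]
  pairwise_ld(dist, defs)
}

#' Pairwise LD matrix over a SNP set
#'
#' Runs the 2-locus EM for every SNP pair and assembles symmetric matrices
#' of D' and r^2 (diagonal NA). Monomorphic pairs are flagged with NA
#' entries rather than raising.
#'
#' @inheritParams em_haplotype_freqs
#' @return Object of class `ld_matrix`: list with `snps`, matrices
#'   `D`, `D_prime`, `r_squared`, and `n_used`.
#' @export
ld_matrix <- function(table, snps, tol = 1e-9, max_iter = 1000L,
                      restarts = 5L, seed = 1L) {
  K <- length(snps)
  if (K < 2L) stop("need at least 2 SNPs", call. = FALSE)
  D <- Dp <- R2 <- NU <- matrix(NA_real_, K, K, dimnames = list(snps, snps))
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      ld <- tryCatch(pair_ld(table, snps[i], snps[j], tol, max_iter,
                             restarts, seed),
                     error = function(e) NULL)
      if (!is.null(ld) && !isTRUE(ld$monomorphic)) {
        D[i, j] <- D[j, i] <- ld$D
        Dp[i, j] <- Dp[j, i] <- ld$D_prime
        R2[i, j] <- R2[j, i] <- ld$r_squared
        NU[i, j] <- NU[j, i] <- ld$n_used
      }
    }
  }
  structure(list(snps = snps, D = D, D_prime = Dp, r_squared = R2,
                 n_used = NU),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("ld_matrix over", length(x$snps), "SNPs; r2:\n")
  print(round(x$r_squared, 3))
  invisible(x)
}

#' Export an LD matrix as a long-format data frame
#'
#' One row per SNP pair (upper triangle): `snp_i`, `snp_j`, `D`, `D_prime`,
#' `r2`, `n_used`. Suitable for writing as TSV.
#' @param lm An `ld_matrix` object.
#' @export
ld_matrix_table <- function(lm) {
  K <- length(lm$snps)
  idx <- which(upper.tri(lm$D), arr.ind = TRUE)
  data.frame(snp_i = lm$snps[idx[, 1]], snp_j = lm$snps[idx[, 2]],
             D = lm$D[idx], D_prime = lm$D_prime[idx], r2 = lm$r_squared[idx],
             n_used = lm$n_used[idx], stringsAsFactors = FALSE)
}
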