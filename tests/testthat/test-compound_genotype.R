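test_that("compound_table recovers the nine published fetal cells", {
  co <- fetal_cohort(with_labels = TRUE)
  ct <- compound_table(co$table, "rs2248374", "rs2549782", labels = co$labels)
  ref <- chilean_fetal_compound_counts("all")
  # canonical axes are (hom_major, het, hom_minor): GG/AG/AA x TT/GT/GG
  got <- ct$all[c("AA", "AG", "GG"), c("TT", "GT", "GG")]
  expect_equal(unname(got), unname(ref))
  expect_equal(sum(ct$all), 1097)
  # group additivity
  expect_equal(ct$case + ct$control, ct$all)
  expect_equal(unname(ct$case[c("AA", "AG", "GG"), c("TT", "GT", "GG")]),
               unname(chilean_fetal_compound_counts("case")))
})

test_that("compound_table rejects SNPs with no joint coverage", {
  defs <- pair_defs()
  tab <- table_from_dosage(defs, snpA = c(1L, NA), snpB = c(NA, 1L))
  expect_error(compound_table(tab, "snpA", "snpB"), "typed at both")
  expect_error(compound_table(table_from_dosage(defs, snpA = 1L, snpB = 1L),
                              "snpA", "nope"), "unknown SNP")
})

test_that("naive-product expectations reproduce the published worked example", {
  e <- expected_counts(0.34, 0.67, 1100, mode = "naive_product")
  f_aatt <- e$expected["hom_minor", "hom_major"] / 1100
  expect_equal(round(f_aatt, 3), 0.052)
  expect_equal(f_aatt, 0.34 * 0.34 * 0.67 * 0.67, tolerance = 1e-12)
  # the five published fetal cells, after rounding
  expect_equal(round(e$expected["hom_minor", "hom_major"]), 57)   # AA,TT
  expect_equal(round(e$expected["hom_minor", "het"]), 28)         # AA,TG
  expect_equal(round(e$expected["hom_minor", "hom_minor"]), 14)   # AA,GG
  expect_equal(round(e$expected["het", "hom_major"]), 111)        # AG,TT
  expect_equal(round(e$expected["hom_major", "hom_major"]), 215)  # GG,TT
})

test_that("HWE-multinomial expectations include multiplicity and sum to n", {
  e <- expected_counts(0.34, 0.67, 1100, mode = "hwe_multinomial")
  expect_equal(e$expected["hom_minor", "het"],
               0.34^2 * (2 * 0.67 * 0.33) * 1100, tolerance = 1e-9)
  expect_equal(round(e$expected["hom_minor", "het"], 1), 56.2)
  expect_equal(sum(e$expected), 1100, tolerance = 1e-9)
  # the naive product omits the heterozygote factor, so sums below n
  en <- expected_counts(0.34, 0.67, 1100, mode = "naive_product")
  expect_lt(sum(en$expected), 1100)
  expect_equal(en$expected["hom_minor", "het"] * 2,
               e$expected["hom_minor", "het"], tolerance = 1e-9)
})

test_that("expectation modes agree on homozygote cells for any frequencies", {
  set.seed(61)
  for (i in 1:10) {
    fa <- runif(1, 0.05, 0.95); fb <- runif(1, 0.05, 0.95)
    n <- sample(100:2000, 1)
    en <- expected_counts(fa, fb, n, "naive_product")
    eh <- expected_counts(fa, fb, n, "hwe_multinomial")
    for (cell in c("hom_major", "hom_minor")) {
      expect_equal(en$expected[cell, "hom_major"],
                   eh$expected[cell, "hom_major"], tolerance = 1e-9)
    }
    expect_equal(sum(eh$expected), n, tolerance = 1e-6)
    expect_lt(sum(en$expected), n)
  }
})

test_that("observed-vs-expected chi-square uses the cell-vs-rest contrast", {
  r <- observed_vs_expected_test(matrix(0), matrix(0.052 * 1100), n = 1100)
  expect_equal(r$statistic, 60.3, tolerance = 0.1)
  expect_lt(r$p_value, 1e-13)
  # observed equal to expected: zero statistic, p = 1
  r2 <- observed_vs_expected_test(matrix(57), matrix(57), n = 1100)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  # the large GG,TT excess is detected at p < 1e-9
  r3 <- observed_vs_expected_test(matrix(346), matrix(215.09), n = 1100)
  expect_lt(r3$p_value, 1e-9)
  expect_error(observed_vs_expected_test(matrix(1), matrix(0), n = 10),
               "zero")
})

test_that("detection power follows its closed forms and monotonicity", {
  expect_equal(detection_power(0, 100), 0)
  expect_equal(detection_power(0.052, 1), 0.052)
  expect_equal(detection_power(0.052, 100), 1 - 0.948^100, tolerance = 1e-12)
  expect_equal(round(detection_power(0.052, 100), 3), 0.995)
  # monotone in both arguments
  p_grid <- seq(0.01, 0.3, by = 0.02)
  pw <- vapply(p_grid, detection_power, numeric(1), n = 50)
  expect_true(all(diff(pw) > 0))
  n_grid <- seq(10, 500, by = 20)
  pw_n <- vapply(n_grid, function(n) detection_power(0.02, n), numeric(1))
  expect_true(all(diff(pw_n) > 0))
})

test_that("chi-square GOF power sums binomial mass over rejections", {
  pw <- detection_power(0.052, 200, model = "chisq_gof", alpha = 0.05,
                        p_alt = 0.1)
  # oracle: direct enumeration
  e <- 200 * 0.052; crit <- qchisq(0.95, 1)
  x <- 0:200
  stat <- (x - e)^2 / e + ((200 - x) - (200 - e))^2 / (200 - e)
  expect_equal(pw, sum(dbinom(x[stat >= crit], 200, 0.1)), tolerance = 1e-12)
  # at the null the rejection rate is near alpha
  expect_lt(detection_power(0.1, 500, "chisq_gof", 0.05, p_alt = 0.1), 0.08)
  expect_error(detection_power(0.05, 10, alpha = 0), "alpha")
})

test_that("expression prediction reproduces the full published rule table", {
  rules <- list(
    list("AA", "TT", 2L, 2L), list("AA", "GT", 2L, 1L), list("AA", "GG", 2L, 0L),
    list("AG", "TT", 1L, 1L), list("AG", "GG", 1L, 0L),
    list("GG", "TT", 0L, 0L), list("GG", "GT", 0L, 0L), list("GG", "GG", 0L, 0L)
  )
  for (r in rules) {
    p <- predict_expression(r[[1]], r[[2]])
    expect_equal(p$erap2_dosage, r[[3]])
    expect_equal(p$n392_dosage, r[[4]])
  }
  # the double heterozygote is phase dependent
  p <- predict_expression("AG", "GT")
  expect_equal(p$erap2_dosage, 1L)
  expect_equal(p$n392_dosage, "phase_dependent")
  expect_equal(predict_expression("AG", "GT", phase = c("AT", "GG"))$n392_dosage, 1L)
  expect_equal(predict_expression("AG", "GT", phase = c("AG", "GT"))$n392_dosage, 0L)
  expect_error(predict_expression("AG", "GT", phase = c("AT", "GT")),
               "inconsistent")
})

test_that("phase ambiguity arises exactly when phases disagree", {
  genos_a <- c("AA", "AG", "GG"); genos_b <- c("TT", "GT", "GG")
  for (ga in genos_a) for (gb in genos_b) {
    unphased <- predict_expression(ga, gb)$n392_dosage
    # enumerate all phases consistent with the pair
    a_all <- strsplit(ga, "")[[1]]; b_all <- strsplit(gb, "")[[1]]
    phases <- unique(list(
      c(paste0(a_all[1], b_all[1]), paste0(a_all[2], b_all[2])),
      c(paste0(a_all[1], b_all[2]), paste0(a_all[2], b_all[1]))
    ))
    vals <- unique(vapply(phases, function(ph)
      predict_expression(ga, gb, phase = ph)$n392_dosage, integer(1)))
    if (length(vals) > 1) {
      expect_equal(unphased, "phase_dependent")
    } else {
      expect_equal(unphased, vals)
    }
  }
})

test_that("compound_report mirrors the published table layout", {
  co <- fetal_cohort()
  ct <- compound_table(co$table, "rs2248374", "rs2549782")
  rep <- compound_report(ct, digits = 2)
  expect_equal(nrow(rep), 9)
  expect_setequal(names(rep), c("genotype_a", "genotype_b", "observed",
                                "expected_naive", "expected_hwe", "p_value",
                                "erap2_dosage", "n392_dosage"))
  aatt <- rep[rep$genotype_a == "AA" & rep$genotype_b == "TT", ]
  expect_equal(aatt$observed, 0)
  expect_equal(round(aatt$expected_naive), 57)  # n = 1097 typed pairs
  expect_lt(aatt$p_value, 1e-10)
  expect_equal(aatt$n392_dosage, "2")
  expect_equal(sum(rep$observed), 1097)
})
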