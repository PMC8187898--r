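# manual chi-square oracles, independent of stats::chisq.test
chi2_oracle <- function(tab, yates = FALSE) {
  m <- as.matrix(tab)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  adj <- if (yates) pmax(abs(m - E) - 0.5, 0) else abs(m - E)
  stat <- sum(adj^2 / E)
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

fisher_oracle <- function(tab) {
  m <- as.matrix(tab)
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  sum(probs[probs <= dhyper(a, r1, n - r1, c1) * (1 + 1e-7)])
}

test_that("Pearson and Yates statistics match the textbook formulas", {
  tabs <- published_tables()
  for (tab in tabs) {
    expect_equal(pearson_chi2(tab), chi2_oracle(tab), tolerance = 1e-12)
    expect_equal(yates_chi2(tab), chi2_oracle(tab, yates = TRUE),
                 tolerance = 1e-12)
    # continuity correction only ever shrinks the statistic
    expect_lte(yates_chi2(tab)$statistic, pearson_chi2(tab)$statistic)
  }
})

test_that("equal carrier proportions give statistic 0 and p 1", {
  flat <- carrier_table(10, 110, 10, 110)
  expect_equal(pearson_chi2(flat)$statistic, 0)
  expect_equal(pearson_chi2(flat)$p, 1)
  expect_equal(yates_chi2(flat)$statistic, 0)
  expect_equal(yates_chi2(flat)$p, 1)
})

test_that("degenerate margins are rejected", {
  expect_error(pearson_chi2(carrier_table(0, 10, 0, 10)), "degenerate")
  expect_error(pearson_chi2(carrier_table(10, 10, 10, 10)), "degenerate")
})

test_that("the Pearson statistic is the squared two-proportion z", {
  for (tab in published_tables()) {
    p1 <- tab$a / tab$case_total
    p2 <- tab$c / tab$control_total
    p <- (tab$a + tab$c) / (tab$case_total + tab$control_total)
    z <- (p1 - p2) / sqrt(p * (1 - p) *
                            (1 / tab$case_total + 1 / tab$control_total))
    expect_equal(pearson_chi2(tab)$statistic, z^2, tolerance = 1e-12)
  }
})

test_that("Fisher's exact p agrees with hypergeometric enumeration", {
  tabs <- list(carrier_table(8, 51, 1, 94), carrier_table(1, 3, 1, 3),
               carrier_table(3, 12, 6, 15), carrier_table(0, 10, 5, 12))
  for (tab in tabs) {
    expect_equal(fisher_exact(tab), fisher_oracle(tab), tolerance = 1e-9)
  }
  # symmetry of mirrored tables and the balanced minimal table
  expect_equal(fisher_exact(carrier_table(0, 10, 10, 10)),
               fisher_exact(carrier_table(10, 10, 0, 10)))
  expect_equal(fisher_exact(carrier_table(1, 3, 1, 3)), 1)
})

test_that("small expected cells trigger the continuity correction", {
  expect_equal(select_test(carrier_table(8, 51, 1, 94)), "yates")
  expect_equal(min(expected_counts(carrier_table(8, 51, 1, 94))),
               9 * 51 / 145, tolerance = 1e-12)
  expect_equal(select_test(carrier_table(18, 145, 10, 179)), "pearson")
  expect_equal(select_test(carrier_table(11, 261, 4, 344)), "pearson")
})

test_that("the selection rule reproduces every published carrier-rate p", {
  printed <- c(drb1_oxc = 0.002, b3802_cbz = 0.03, a2402_pool = 0.047,
               a3001_pool = 0.043, b3501_pool = 0.02, b3802_pool = 0.03,
               drb1_pool = 0.02)
  tabs <- published_tables()
  for (nm in names(printed)) {
    res <- carrier_test(tabs[[nm]])
    digits <- nchar(sub("^0\\.", "", format(printed[[nm]])))
    expect_equal(round(res$p, digits), printed[[nm]],
                 info = nm, tolerance = 1e-12)
  }
  expect_equal(carrier_test(tabs$drb1_oxc)$test_used, "yates")
  # uncorrected Pearson would NOT reproduce the sparse-table p
  expect_lt(pearson_chi2(tabs$drb1_oxc)$p, 0.001)
})

test_that("Woolf odds ratios and intervals match the published values", {
  r <- odds_ratio_woolf(carrier_table(8, 51, 1, 94))
  expect_equal(round(r$or, 2), 17.30)
  expect_equal(round(r$ci_low, 2), 2.10)
  expect_equal(round(r$ci_high, 2), 142.72)
  r2 <- odds_ratio_woolf(carrier_table(18, 145, 10, 179))
  expect_equal(round(r2$or, 2), 2.40)
  expect_equal(round(r2$ci_low, 2), 1.07)
  expect_equal(round(r2$ci_high, 2), 5.37)
})

test_that("an equal-odds table gives OR 1 with a CI straddling 1", {
  r <- odds_ratio_woolf(carrier_table(5, 15, 5, 15))
  expect_equal(r$or, 1)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
})

test_that("zero cells get the Haldane correction; absent markers are NA", {
  r <- odds_ratio_woolf(carrier_table(0, 10, 5, 15))
  expect_true(r$haldane)
  expect_equal(r$or, (0.5 * 10.5) / (10.5 * 5.5))
  r2 <- odds_ratio_woolf(carrier_table(0, 10, 0, 15))
  expect_true(r2$undefined)
  expect_true(is.na(r2$or))
})

test_that("exchanging case and control rows inverts the OR and mirrors the CI", {
  tab <- carrier_table(18, 145, 10, 179)
  fwd <- odds_ratio_woolf(tab)
  rev <- odds_ratio_woolf(carrier_table(10, 179, 18, 145))
  expect_equal(rev$or, 1 / fwd$or, tolerance = 1e-12)
  expect_equal(rev$ci_low, 1 / fwd$ci_high, tolerance = 1e-12)
  expect_equal(rev$ci_high, 1 / fwd$ci_low, tolerance = 1e-12)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.002, 19), 0.038)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.123, 1), 0.123)
  expect_error(bonferroni(0.1, 0))
})

test_that("a planted strong effect ranks first in the locus scan", {
  cfg <- simulation_config(
    n_cases = 80, n_controls = 160,
    model = risk_model(intercept = qlogis(0.05),
                       effects = c("HLA-DRB1*04:06" = log(5))),
    missingness = 0, seed = 902)
  hits <- vapply(1:20, function(i) {
    cfg$seed <- 902L + i
    coh <- simulate_cohort(cfg)
    scan <- scan_locus(coh, "DRB1")
    scan$allele[1] == "HLA-DRB1*04:06"
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("scan multiplicity uses the unfiltered allele count", {
  coh <- simulate_cohort(simulation_config(n_cases = 50, n_controls = 100,
                                           missingness = 0, seed = 31))
  scan <- scan_locus(coh, "B", min_carriers = 10)
  enum <- enumerate_alleles(coh, "B")
  expect_true(all(scan$multiplicity == nrow(enum)))
  expect_lt(nrow(scan), nrow(enum))
  expect_equal(scan$p_corrected, pmin(1, scan$p * nrow(enum)))
  expect_true(all(diff(scan$p) >= 0))
})

test_that("a single-allele locus has multiplicity 1 and p uncorrected", {
  coh <- make_count_cohort("HLA-A*24:02", 0, 20, 0, 30)
  # locus C holds only the constant filler allele: multiplicity 1, and the
  # carrier table is degenerate (everyone carries), so the p is NA
  scan <- scan_locus(coh, "C")
  expect_equal(nrow(scan), 1L)
  expect_equal(scan$multiplicity, 1L)
  expect_equal(scan$p_corrected, scan$p)
  expect_true(is.na(scan$p))
  # with a real contrast, multiplicity 1 leaves the p unchanged
  het <- make_count_cohort("HLA-DRB1*04:06", 5, 20, 3, 30)
  sc2 <- scan_locus(het, "DRB1")
  drb <- sc2[sc2$multiplicity == 2 & sc2$allele == "HLA-DRB1*04:06", ]
  expect_equal(drb$p_corrected, pmin(1, 2 * drb$p))
})

test_that("locus-wise type-I error under the null stays at or below nominal", {
  set.seed(555)
  reps <- 400
  # equal carrier probabilities in both arms, n = 150/arm: the family-wise
  # rate of min corrected p < 0.05 must not exceed 0.05 (Bonferroni is
  # conservative), and the per-table test holds its size.
  profile <- allele_profile(A = c("24:02" = 0.10, "11:01" = 0.25,
                                  "02:01" = 0.20, "33:03" = 0.15))
  fam_hits <- 0L
  single_p <- numeric(reps)
  for (i in 1:reps) {
    geno <- simulate_genotypes(profile, 300, seed = 7000 + i)
    geno$group <- rep(c("case", "control"), each = 150)
    coh <- hla_cohort(geno)
    scan <- scan_locus(coh, "A")
    fam_hits <- fam_hits + (min(scan$p_corrected) < 0.05)
    single_p[i] <- scan$p[scan$allele == "HLA-A*11:01"]
  }
  band <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lte(fam_hits / reps, 0.05 + band)
  expect_lt(abs(mean(single_p < 0.05) - 0.05), 0.05)
})
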