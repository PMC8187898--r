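demo_studies <- function() {
  meta_studies(study_id = paste0("s", 1:4),
               case_carriers = c(12, 30, 8, 20),
               case_total = c(50, 120, 40, 90),
               control_carriers = c(10, 40, 15, 30),
               control_total = c(100, 300, 80, 200))
}

test_that("per-study effects are Woolf log-ORs with zero-cell correction", {
  st <- meta_studies("s1", case_carriers = 8, case_total = 51,
                     control_carriers = 1, control_total = 94)
  eff <- study_effects(st)
  expect_equal(exp(eff$log_or), 17.302, tolerance = 1e-3)
  expect_equal(eff$var_log_or, 1 / 8 + 1 / 43 + 1 / 1 + 1 / 93)
  expect_false(eff$haldane)

  zero <- meta_studies("s2", case_carriers = 0, case_total = 20,
                       control_carriers = 5, control_total = 40)
  ez <- study_effects(zero)
  expect_true(ez$haldane)
  expect_true(is.finite(ez$log_or) && is.finite(ez$var_log_or))
  expect_equal(exp(ez$log_or), (0.5 * 35.5) / (20.5 * 5.5))

  balanced <- meta_studies("s3", case_carriers = 10, case_total = 50,
                           control_carriers = 10, control_total = 50)
  expect_equal(study_effects(balanced)$log_or, 0)
})

test_that("a single study is its own pooled result under both models", {
  st <- meta_studies("only", case_carriers = 18, case_total = 145,
                     control_carriers = 10, control_total = 179)
  or <- (18 * 169) / (127 * 10)
  res <- meta_analyze(st)
  expect_equal(res$fixed$or, or, tolerance = 1e-12)
  expect_equal(res$random$or, or, tolerance = 1e-12)
  expect_equal(res$q, 0)
  expect_equal(res$i2, 0)
  expect_equal(res$tau2, 0)
  expect_equal(res$model_selected, "fixed")
  fd <- forest_data(res)
  expect_equal(fd$weight[!fd$pooled], 100)
})

test_that("duplicating a study keeps the OR and narrows the CI", {
  one <- meta_studies("a", case_carriers = 18, case_total = 145,
                      control_carriers = 10, control_total = 179)
  two <- meta_studies(c("a", "b"),
                      case_carriers = c(18, 18), case_total = c(145, 145),
                      control_carriers = c(10, 10),
                      control_total = c(179, 179))
  p1 <- pool_fixed_mh(one)
  p2 <- pool_fixed_mh(two)
  expect_equal(p2$or, p1$or, tolerance = 1e-12)
  expect_lt(p2$ci_high - p2$ci_low, p1$ci_high - p1$ci_low)
  # identical studies: no heterogeneity at all
  het <- heterogeneity(two)
  expect_equal(het$q, 0, tolerance = 1e-12)
  expect_equal(het$i2, 0)
  expect_equal(het$tau2, 0)
})

test_that("random-effects pooling reduces to inverse-variance at tau2 = 0", {
  st <- demo_studies()
  eff <- study_effects(st)
  w <- 1 / eff$var_log_or
  iv_fixed <- sum(w * eff$log_or) / sum(w)
  rd <- pool_random_dl(st, tau2 = 0)
  expect_equal(rd$log_or, iv_fixed, tolerance = 1e-12)
  expect_equal(rd$se_log_or, sqrt(1 / sum(w)), tolerance = 1e-12)
})

test_that("the heterogeneity rule is a conjunction with audited parts", {
  expect_equal(select_model(0.05, 60)$model, "random")
  expect_equal(select_model(0.05, 30)$model, "fixed")
  expect_equal(select_model(0.5, 60)$model, "fixed")
  expect_equal(select_model(NA, 0)$model, "fixed")
  sel <- select_model(0.05, 30)
  expect_true(sel$q_significant)
  expect_false(sel$i2_high)
})

test_that("MH pooled OR stays within the range of the study ORs", {
  set.seed(909)
  for (i in 1:20) {
    st <- simulate_meta_studies(6, mu = log(2), tau = 0.4,
                                control_freq = 0.25, seed = 100 + i)
    eff <- study_effects(st)
    mh <- pool_fixed_mh(st)
    expect_gte(mh$or, min(exp(eff$log_or)) - 1e-9)
    expect_lte(mh$or, max(exp(eff$log_or)) + 1e-9)
  }
})

test_that("identical-margin identical-OR studies pool to the common OR", {
  st <- meta_studies(c("a", "b", "c"),
                     case_carriers = c(20, 20, 20), case_total = 60,
                     control_carriers = c(10, 10, 10), control_total = 60)
  common <- (20 * 50) / (40 * 10)
  expect_equal(pool_fixed_mh(st)$or, common, tolerance = 1e-12)
  expect_equal(pool_random_dl(st)$or, common, tolerance = 1e-12)
})

test_that("fixed and random pooling agree with metafor on real-shaped data", {
  skip_if_not_installed("metafor")
  st <- demo_studies()
  cells <- data.frame(ai = st$case_carriers,
                      bi = st$case_total - st$case_carriers,
                      ci = st$control_carriers,
                      di = st$control_total - st$control_carriers)
  mh <- metafor::rma.mh(ai = ai, bi = bi, ci = ci, di = di, data = cells,
                        measure = "OR", correct = FALSE)
  ours_mh <- pool_fixed_mh(st)
  expect_equal(ours_mh$log_or, as.numeric(mh$beta), tolerance = 1e-10)
  expect_equal(ours_mh$se_log_or, mh$se, tolerance = 1e-10)

  dl <- metafor::rma(ai = ai, bi = bi, ci = ci, di = di, data = cells,
                     measure = "OR", method = "DL")
  het <- heterogeneity(st)
  ours_dl <- pool_random_dl(st)
  expect_equal(het$tau2, dl$tau2, tolerance = 1e-10)
  expect_equal(het$q, dl$QE, tolerance = 1e-10)
  expect_equal(het$i2, dl$I2, tolerance = 1e-6)
  expect_equal(ours_dl$log_or, as.numeric(dl$beta), tolerance = 1e-10)
  expect_equal(ours_dl$se_log_or, dl$se, tolerance = 1e-10)
})

test_that("I2 is bounded and tau2 vanishes when Q is small", {
  set.seed(33)
  for (i in 1:30) {
    st <- simulate_meta_studies(5, mu = 0, tau = 0.3, seed = 300 + i)
    het <- heterogeneity(st)
    expect_gte(het$i2, 0)
    expect_lte(het$i2, 100)
    if (het$q <= het$k - 1) expect_equal(het$tau2, 0)
  }
})

test_that("Q holds its size under homogeneity and finds heterogeneity", {
  reps <- 300
  null_p <- vapply(1:reps, function(i) {
    heterogeneity(simulate_meta_studies(8, mu = log(1.5), tau = 0,
                                        control_freq = 0.25,
                                        case_sizes = 80,
                                        control_sizes = 150,
                                        seed = 40000 + i))$q_p
  }, numeric(1))
  expect_lt(abs(mean(null_p < 0.1) - 0.1), 3 * sqrt(0.1 * 0.9 / reps) + 0.02)

  alt_i2 <- vapply(1:reps, function(i) {
    heterogeneity(simulate_meta_studies(8, mu = log(1.5), tau = 1,
                                        control_freq = 0.25,
                                        case_sizes = 80,
                                        control_sizes = 150,
                                        seed = 50000 + i))$i2
  }, numeric(1))
  expect_gt(mean(alt_i2 > 50), 0.5)
})

test_that("pooled estimates recover a planted common OR", {
  reps <- 300
  ors <- vapply(1:reps, function(i) {
    pool_fixed_mh(simulate_meta_studies(10, mu = log(2), tau = 0,
                                        control_freq = 0.2,
                                        case_sizes = 200,
                                        control_sizes = 200,
                                        seed = 60000 + i))$or
  }, numeric(1))
  expect_lt(abs(mean(ors) - 2) / 2, 0.05)
})

test_that("random-effects CIs cover the true mean at the nominal rate", {
  reps <- 300
  covered <- vapply(1:reps, function(i) {
    rd <- pool_random_dl(simulate_meta_studies(12, mu = log(2), tau = 0.5,
                                               control_freq = 0.2,
                                               case_sizes = 150,
                                               control_sizes = 150,
                                               seed = 70000 + i))
    rd$ci_low <= 2 && 2 <= rd$ci_high
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 3 * sqrt(0.95 * 0.05 / reps) + 0.03)
})

test_that("forest weights normalise and equal studies weigh equally", {
  st <- demo_studies()
  res <- meta_analyze(st)
  fd <- forest_data(res)
  expect_equal(sum(fd$weight[!fd$pooled]), 100, tolerance = 1e-9)
  expect_equal(nrow(fd), res$k + 1)
  expect_equal(fd$or[fd$pooled], res$selected$or)

  eq <- meta_studies(c("a", "b"), case_carriers = c(20, 20),
                     case_total = 60, control_carriers = c(10, 10),
                     control_total = 60)
  fd_eq <- forest_data(meta_analyze(eq))
  w <- fd_eq$weight[!fd_eq$pooled]
  expect_equal(w[1], w[2], tolerance = 1e-12)
})

test_that("study tables round-trip through the CSV reader", {
  st <- demo_studies()
  st$allele <- "HLA-A*24:02"
  st$population <- "Han"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(st, path, row.names = FALSE)
  rt <- read_studies(path)
  expect_equal(rt$case_carriers, st$case_carriers)
  expect_equal(rt$allele, st$allele)
  bad <- st
  names(bad)[names(bad) == "control_total"] <- "ctrl_n"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_studies(path), "control_total")
})
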