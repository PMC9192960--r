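test_that("pooled t from summaries reproduces printed demographics", {
  madrs <- pooled_t_from_summary(15.28, 9.49, 43, 1.13, 1.23, 24)
  expect_lt(abs(madrs$t - 7.247), 5e-3)
  expect_equal(madrs$df, 65L)
  age <- pooled_t_from_summary(33.05, 10.67, 43, 30.96, 11.98, 24)
  expect_lt(abs(age$t - 0.735), 5e-3)
  equal <- pooled_t_from_summary(5, 1, 10, 5, 1, 12)
  expect_equal(equal$t, 0)
  expect_equal(equal$p, 1)
  expect_error(pooled_t_from_summary(1, 0, 5, 2, 0, 5), "infinite")
  expect_equal(pooled_t_from_summary(3, 0, 5, 3, 0, 5)$t, 0)
})

test_that("pooled t from raw data equals t from that data's summaries", {
  set.seed(6)
  for (i in 1:5) {
    x <- rnorm(17, 1); y <- rnorm(12)
    direct <- t.test(x, y, var.equal = TRUE)
    ours <- pooled_t_from_summary(mean(x), sd(x), 17, mean(y), sd(y), 12)
    expect_equal(ours$t, unname(direct$statistic), tolerance = 1e-10)
    expect_equal(ours$p, direct$p.value, tolerance = 1e-10)
  }
})

test_that("Yates chi-squared reproduces printed gender tests", {
  expect_lt(abs(yates_chi2(21, 22, 10, 14)$chisq - 0.095), 1e-3)
  expect_lt(abs(yates_chi2(18, 3, 12, 4)$chisq - 0.161), 1e-3)
  expect_equal(yates_chi2(10, 10, 5, 5)$chisq, 0)
  # agrees with the base implementation
  ref <- chisq.test(matrix(c(21, 10, 22, 14), 2, 2), correct = TRUE)
  expect_equal(yates_chi2(21, 22, 10, 14)$chisq, unname(ref$statistic),
               tolerance = 1e-10)
  expect_error(yates_chi2(0, 0, 3, 4), "margin")
})

test_that("Cohen's d and CI reproduce printed effect sizes", {
  ocd <- cohens_d_from_t(-2.908, 43, 24)
  expect_lt(abs(ocd$d - 0.74), 5e-3)
  expect_lt(abs(ocd$ci_low - 0.23), 5e-3)
  expect_lt(abs(ocd$ci_high - 1.26), 5e-3)
  bdd <- cohens_d_from_t(-1.595, 21, 16)
  expect_lt(abs(bdd$d - 0.53), 5e-3)
  expect_lt(abs(bdd$ci_low - (-0.13)), 5e-3)
  expect_lt(abs(bdd$ci_high - 1.19), 5e-3)
  # sign invariance and the null case
  expect_equal(cohens_d_from_t(2.908, 43, 24)$d, ocd$d)
  null <- cohens_d_from_t(0, 10, 10)
  expect_equal(null$d, 0)
  expect_equal(null$ci_low, -null$ci_high)
})

test_that("correlation inference reproduces printed p-values and CIs", {
  expect_lt(abs(pearson_test(0.456, 21)$p - 0.038), 1e-3)
  expect_lt(abs(pearson_test(0.608, 14)$p - 0.021), 1e-3)
  expect_lt(abs(pearson_test(0.094, 29)$p - 0.628), 1e-3)
  ci <- pearson_test(0.328, 43)
  expect_lt(abs(ci$ci_low - 0.030), 1e-3)
  expect_lt(abs(ci$ci_high - 0.572), 1e-3)
  null <- pearson_test(0, 30)
  expect_equal(null$p, 1)
  expect_equal(null$ci_low, -null$ci_high)
  perfect <- pearson_test(1, 10)
  expect_true(perfect$degenerate)
  expect_equal(perfect$p, 0)
})

test_that("Fisher interval contains its estimate and narrows with n", {
  set.seed(44)
  for (i in 1:20) {
    r <- runif(1, -0.95, 0.95)
    n <- sample(5:200, 1)
    ci <- pearson_test(r, n)
    expect_lte(ci$ci_low, r)
    expect_gte(ci$ci_high, r)
    wider <- pearson_test(r, max(4, n - 1) + 0L)
    if (n > 4) expect_lt(ci$ci_high - ci$ci_low,
                         wider$ci_high - wider$ci_low + 1e-12)
  }
  # p-value agrees with the base test on raw data
  set.seed(45)
  x <- rnorm(25); y <- 0.4 * x + rnorm(25)
  ref <- cor.test(x, y)
  ours <- pearson_test(cor(x, y), 25)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("MANCOVA df structure matches the two study designs", {
  des <- cohort_design(n_patients = 43, n_controls = 24, seed = 10)
  tab <- generate_cohort(des, generate_series = FALSE)$cohort
  fit <- mancova_pillai(tab, c("dec_obs_1", "dec_obs_2", "dec_obs_3"),
                        "group", c("age", "gender", "dvars"))
  expect_equal(fit$df_hyp, 3)
  expect_equal(fit$df_err, 60)   # n = 67: F(3, 60)
  ph <- posthoc_group_regressions(tab, "dec_obs_1")
  expect_equal(ph$df, 62L)       # 67 - 5 columns
  des2 <- cohort_design(n_patients = 21, n_controls = 16, seed = 11)
  tab2 <- generate_cohort(des2, generate_series = FALSE)$cohort
  ph2 <- posthoc_group_regressions(tab2, "dec_obs_1")
  expect_equal(ph2$df, 32L)      # n = 37
  sr <- symptom_regression(dplyr::filter(tab, group == "patient"), "ybocs",
                           c("dec_obs_1", "dec_obs_2", "dec_obs_3"))
  expect_equal(unique(sr$df), 39L)  # 43 patients, 4-column design
})

test_that("Pillai agrees with the base manova implementation", {
  des <- cohort_design(n_patients = 25, n_controls = 20,
                       group_dec_offset = -0.3, seed = 21)
  tab <- generate_cohort(des, generate_series = FALSE)$cohort
  ours <- mancova_pillai(tab, c("dec_obs_1", "dec_obs_2", "dec_obs_3"),
                         "group", c("age", "gender", "dvars"))
  ref <- summary(manova(
    cbind(dec_obs_1, dec_obs_2, dec_obs_3) ~ age + gender + dvars + group,
    data = tab), test = "Pillai")$stats
  expect_equal(ours$pillai, ref["group", "Pillai"], tolerance = 1e-10)
  expect_equal(ours$f, ref["group", "approx F"], tolerance = 1e-10)
  expect_equal(ours$df_err, unname(ref["group", "den Df"]))
  expect_equal(ours$p, ref["group", "Pr(>F)"], tolerance = 1e-10)
})

test_that("Pillai respects its bounds and affine rescaling of outcomes", {
  des <- cohort_design(n_patients = 20, n_controls = 20, seed = 31)
  tab <- generate_cohort(des, generate_series = FALSE)$cohort
  a <- mancova_pillai(tab, c("dec_obs_1", "dec_obs_2", "dec_obs_3"), "group",
                      c("age", "gender", "dvars"))
  expect_gte(a$pillai, 0)
  expect_lte(a$pillai, 1)
  tab$dec_obs_2 <- 100 * tab$dec_obs_2 - 7
  b <- mancova_pillai(tab, c("dec_obs_1", "dec_obs_2", "dec_obs_3"), "group",
                      c("age", "gender", "dvars"))
  expect_equal(a$pillai, b$pillai, tolerance = 1e-10)
  tab$dup <- tab$age
  expect_error(mancova_pillai(tab, c("dec_obs_1", "dec_obs_2", "dec_obs_3"),
                              "group", c("age", "dup")), "collinear")
})

test_that("type-I error is calibrated for MANCOVA and post-hoc models", {
  reps <- 200
  rej_m <- rej_p <- rej_s <- logical(reps)
  for (i in seq_len(reps)) {
    des <- cohort_design(n_patients = 21, n_controls = 16,
                         group_dec_offset = 0, symptom_slope = 0,
                         seed = 5000 + i)
    tab <- generate_cohort(des, generate_series = FALSE)$cohort
    m <- mancova_pillai(tab, c("dec_obs_1", "dec_obs_2", "dec_obs_3"),
                        "group", c("age", "gender", "dvars"))
    rej_m[i] <- m$p < 0.05
    ph <- posthoc_group_regressions(tab, "dec_obs_1")
    rej_p[i] <- ph$p < 0.05
    sr <- symptom_regression(dplyr::filter(tab, group == "patient"), "ybocs",
                             c("dec_obs_1", "dec_obs_2", "dec_obs_3"))
    rej_s[i] <- any(sr$p_bonferroni < 0.05)
  }
  expect_gte(mean(rej_m), 0.02); expect_lte(mean(rej_m), 0.08)
  expect_gte(mean(rej_p), 0.02); expect_lte(mean(rej_p), 0.08)
  # family-wise error under Bonferroni stays at or below nominal + MC noise
  expect_lte(mean(rej_s), 0.08)
})

test_that("a symptom slope on one connection is found as the top term", {
  hits <- logical(100)
  for (i in seq_len(100)) {
    des <- cohort_design(n_patients = 43, n_controls = 5,
                         symptom_slope = 25, symptom_noise_sd = 4,
                         between_subject_sd = 0.15, seed = 7000 + i)
    tab <- generate_cohort(des, generate_series = FALSE)$cohort
    sr <- symptom_regression(dplyr::filter(tab, group == "patient"), "ybocs",
                             c("dec_obs_1", "dec_obs_2", "dec_obs_3"))
    hits[i] <- sr$connection[which.max(abs(sr$t))] == "dec_obs_1"
  }
  expect_gt(mean(hits), 0.8)
})

test_that("medication interaction model has the right structure and nulls", {
  des <- cohort_design(n_patients = 43, n_controls = 5, symptom_slope = 0,
                       medication_fraction = 0.33, seed = 55)
  tab <- dplyr::filter(generate_cohort(des, generate_series = FALSE)$cohort,
                       group == "patient")
  out <- medication_interaction(tab, "ybocs", "dec_obs_1")
  expect_equal(nrow(out$model), 4)    # intercept, dec, med, interaction
  expect_equal(unique(out$model$df), 39L)
  expect_setequal(out$strata$stratum, c("medicated", "unmedicated"))
  # printed stratum example: r = 0.608 at n = 14
  expect_lt(abs(pearson_test(0.608, 14)$p - 0.021), 1e-3)
  tab$medicated <- 0
  expect_error(medication_interaction(tab, "ybocs", "dec_obs_1"),
               "strata")
  # interaction t is centered under a null generator
  ts <- vapply(1:60, function(i) {
    des <- cohort_design(n_patients = 40, n_controls = 5, symptom_slope = 0,
                         medication_fraction = 0.5, seed = 8000 + i)
    tt <- dplyr::filter(generate_cohort(des, generate_series = FALSE)$cohort,
                        group == "patient")
    out <- medication_interaction(tt, "ybocs", "dec_obs_1")
    out$model$t[grepl(":", out$model$term)]
  }, numeric(1))
  expect_lt(abs(mean(ts)), 3 * sd(ts) / sqrt(length(ts)) + 0.05)
})

test_that("Bonferroni correction is monotone and capped", {
  set.seed(61)
  tab <- generate_cohort(cohort_design(n_patients = 20, n_controls = 15,
                                       seed = 66),
                         generate_series = FALSE)$cohort
  ph <- posthoc_group_regressions(tab, c("dec_obs_1", "dec_obs_2",
                                         "dec_obs_3"))
  expect_true(all(ph$p_bonferroni >= ph$p))
  expect_true(all(ph$p_bonferroni <= 1))
})

test_that("required n uses the noncentral t and flags the limit cases", {
  # equal-allocation cross-check against the base power routine
  ref <- power.t.test(delta = 0.74, sd = 1, sig.level = 0.05, power = 0.85,
                      alternative = "one.sided")
  ours <- required_n(0.74, power = 0.85)
  expect_equal(ours$n_total, 2 * ceiling(ref$n))
  expect_gte(ours$achieved_power, 0.85)
  # a huge effect needs the minimum group sizes
  expect_equal(required_n(50, power = 0.8)$n_total, 4)
  # brute-force parity point: power 0.5 at one-sided alpha 0.5 holds wherever
  # the noncentrality equals the critical value; scan confirms the smallest n
  out <- required_n(0.8, power = 0.5, alpha = 0.5)
  scan <- vapply(4:out$n_total, function(nt) {
    n2 <- max(2, round(nt / 2)); n1 <- nt - n2
    df <- n1 + n2 - 2
    pt(qt(0.5, df), df, ncp = 0.8 * sqrt(n1 * n2 / (n1 + n2)),
       lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(scan[-length(scan)] < 0.5))
  expect_gte(scan[length(scan)], 0.5)
})
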