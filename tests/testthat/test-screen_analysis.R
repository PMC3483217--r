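test_that("thrashing classification follows the consistent 3-of-4 rule", {
  ctrl <- c(.90, .80, .60, .40)
  expect_equal(classify_thrashing(c(1, .92, .70, .50), ctrl)$phenotype, "long")
  expect_equal(classify_thrashing(ctrl, ctrl)$phenotype, "none")
  expect_equal(classify_thrashing(c(.79, .70, .52, .34), ctrl)$phenotype, "short")
  # a sign flip breaks consistency even with three strong days
  expect_equal(classify_thrashing(c(1.125, 1.125, 1.125, 0.675) * 0.8,
                                  rep(0.8, 4))$phenotype, "none")
  # exactly 2 qualifying days is not enough
  expect_equal(classify_thrashing(c(1, .92, .61, .41), ctrl)$phenotype, "none")
})

test_that("classification is antisymmetric and monotone in the threshold", {
  set.seed(14)
  for (i in 1:40) {
    ctrl <- stats::runif(4, 0.3, 0.75)
    delta <- stats::runif(4, -0.25, 0.25)  # 0.75 * 1.25 < 1: no clipping
    treated <- ctrl * (1 + delta)
    mirrored <- ctrl * (1 - delta)
    a <- classify_thrashing(treated, ctrl)$phenotype
    b <- classify_thrashing(mirrored, ctrl)$phenotype
    flip <- c(long = "short", short = "long", none = "none")
    expect_equal(b, unname(flip[a]))
    # raising the threshold can only move calls toward none
    hi <- classify_thrashing(treated, ctrl, threshold = 0.2)$phenotype
    if (a == "none") expect_equal(hi, "none") else expect_true(hi %in% c(a, "none"))
  }
})

test_that("indeterminate control days are excluded, all-zero errors", {
  r <- classify_thrashing(c(.5, .92, .70, .50), c(0, .80, .60, .40),
                          min_timepoints = 3)
  expect_equal(r$n_indeterminate, 1)
  expect_true(is.na(r$changes[1]))
  expect_error(classify_thrashing(c(.1, .1, .1, .1), rep(0, 4)),
               "indeterminate")
})

test_that("Kaplan-Meier estimates mean, median, and handles censoring", {
  d <- survival_dataset(c(10, 20))
  km <- km_estimate(d)
  expect_equal(km$surv, c(0.5, 0))
  expect_equal(km$median, 10)
  expect_equal(km$mean, 15)

  single <- km_estimate(survival_dataset(7))
  expect_equal(single$mean, 7)
  expect_equal(single$surv, 0)

  expect_error(km_estimate(survival_dataset(c(5, 6), events = c(0, 0))),
               "censored")

  # without censoring the KM mean is exactly the arithmetic mean of deaths
  set.seed(2)
  for (i in 1:10) {
    t <- stats::rexp(sample(5:40, 1), 1 / 15) + 1
    expect_equal(km_estimate(survival_dataset(t))$mean, mean(t))
  }
})

test_that("log-rank matches a hand-computed risk-set table", {
  a <- survival_dataset(c(10, 12, 15), group = "a")
  b <- survival_dataset(c(11, 18, 25), group = "b")
  got <- logrank_test(a, b)
  want <- oracle_logrank(a$times, a$events, b$times, b$events)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-10)

  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- logrank_test(survival_dataset(c(5, 5, 5)),
                      survival_dataset(c(50, 50, 50)))
  expect_lt(sep$p_value, 0.05)

  expect_error(logrank_test(a, survival_dataset(c(4, 5), events = c(0, 0))),
               "death")
})

test_that("percent changes compare KM mean and last-quartile maximum", {
  tr <- survival_dataset(rep(25, 8))
  ct <- survival_dataset(rep(20, 8))
  pc <- percent_changes(tr, ct)
  expect_equal(pc$pct_delta_mean, 25)
  expect_equal(pc$pct_delta_max, 25)

  eq <- percent_changes(ct, ct)
  expect_equal(eq$pct_delta_mean, 0)
  expect_equal(eq$pct_delta_max, 0)

  pc2 <- percent_changes(survival_dataset(c(10, 20, 30, 40)),
                         survival_dataset(c(10, 20, 30, 32)))
  expect_equal(pc2$pct_delta_mean, 100 * (25 - 23) / 23)
  expect_equal(pc2$pct_delta_max, 25)

  expect_error(percent_changes(survival_dataset(c(10, 20, 30)), ct), "4 deaths")
})

test_that("screen summaries enforce the verification funnel ordering", {
  s <- screen_summary(374, 101, 55, 45, 12, 19, 11)
  expect_equal(s$verified_long, 19)
  expect_error(screen_summary(100, 10, 5, 12, 2, 1, 0), "retested")
  expect_error(screen_summary(100, 10, 5, 8, 2, 9, 0), "verified")
})

test_that("frequencies, extrapolation, folds, and rates use half-up rounding", {
  s <- screen_summary(374, 101, 55, 45, 12, 19, 11)
  expect_equal(verification_frequency(s, "long"), 5.1)
  expect_equal(verification_frequency(s, "short"), 2.9)
  expect_equal(verification_frequency(s, "long", digits = 2), 5.08)
  zero <- screen_summary(100, 0, 0, 0, 0, 0, 0)
  expect_equal(verification_frequency(zero, "long"), 0)

  expect_equal(extrapolate_verified(101, 45, 19, 374), list(count = 42, percent = 11.2))
  expect_equal(extrapolate_verified(55, 12, 11, 374), list(count = 50, percent = 13.4))
  expect_equal(extrapolate_verified(10, 10, 10, 100), list(count = 10, percent = 10))
  expect_error(extrapolate_verified(10, 0, 0, 100), "at least 1")

  expect_equal(fold_improvement(3, 3)$fold, 1)
  expect_equal(fold_improvement(2, c(1, 3))$ratio, 1)
  expect_error(fold_improvement(2, c(0, 1)), "positive")

  expect_equal(primary_detection_rates(147, 47, 21), list(any = 46, long = 32, short = 14))
  expect_equal(primary_detection_rates(184, 45, 27), list(any = 39, long = 24, short = 15))
  expect_equal(primary_detection_rates(43, 9, 7), list(any = 37, long = 21, short = 16))
  expect_error(primary_detection_rates(0, 0, 0), "zero")
})

test_that("effect summaries deduplicate genes and count modest effects", {
  eff <- data.frame(gene = c("g1", "g2", "g2", "g3"),
                    pct_delta_mean = c(5, 12, 12, -8))
  s <- summarize_effects(eff, "long")
  expect_equal(s$n, 2)            # g1, g2 (g2 dedup; g3 is negative)
  expect_equal(s$mean_pct_delta, 8.5)
  expect_equal(s$n_modest, 1)     # only g1 below 10
  one <- summarize_effects(data.frame(gene = "g", pct_delta_mean = 5), "long")
  expect_equal(one, list(n = 1, mean_pct_delta = 5, n_modest = 1L))
  expect_error(summarize_effects(data.frame(gene = "g", pct_delta_mean = -3), "long"),
               "direction")
})
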