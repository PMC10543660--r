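test_that("per-unit risk is false-positive mass over non-preictal exposure", {
  lab0 <- rep(0L, 100)
  pred <- c(rep(0L, 40), 1L, 1L, 1L, rep(0L, 57))
  expect_equal(empirical_unit_risk(pred, lab0), 0.03)
  expect_equal(empirical_unit_risk(rep(0L, 20), rep(0L, 20)), 0)
  lab <- c(rep(0, 5), rep(1, 5))
  expect_equal(empirical_unit_risk(lab, lab), 0) # perfect prediction
  expect_error(empirical_unit_risk(rep(1L, 4), rep(1L, 4)), "exposure")
  expect_error(empirical_unit_risk(c(0, 1), c(0, 1, 0)), "length")
})

test_that("event-rate risk counts merged alarm events per non-preictal hour", {
  # 6 separate alarms over 2 non-preictal hours at 60 s/sample
  lab <- binary_series(rep(0L, 120), sample_period = 60)
  pred <- rep(0L, 120)
  pred[c(3, 20, 40, 60, 80, 100)] <- 1L
  pred <- binary_series(pred, sample_period = 60)
  expect_equal(empirical_unit_risk(pred, lab, risk = "event_rate"), 3)
  # an alarm touching preictal time is not a false positive
  lab2 <- binary_series(c(rep(0L, 50), rep(1L, 10), rep(0L, 60)),
                        sample_period = 60)
  pred2 <- binary_series(c(rep(0L, 49), rep(1L, 3), rep(0L, 68)),
                         sample_period = 60)
  expect_equal(
    empirical_unit_risk(pred2, lab2, risk = "event_rate"), 0
  )
})

test_that("CLT p-values match hand-computed normal quantiles", {
  # mean exactly at alpha: z = 0
  expect_equal(clt_pvalue(c(0.04, 0.06), 0.05), 0.5)
  # all-zero risks: degenerate evidence fully below alpha
  expect_equal(clt_pvalue(rep(0, 10), 0.05), 0)
  expect_equal(clt_pvalue(rep(0.2, 10), 0.05), 1)
  # n = 25, mean 0.02, sd 0.05, alpha 0.05 -> Phi(-3)
  set.seed(1)
  x <- rnorm(25)
  risks <- 0.02 + (x - mean(x)) * (0.05 / sd(x)) # exact sample moments
  expect_equal(mean(risks), 0.02, tolerance = 1e-12)
  expect_equal(sd(risks), 0.05, tolerance = 1e-12)
  expect_equal(clt_pvalue(risks, 0.05), 0.0013498980, tolerance = 1e-6)
  expect_error(clt_pvalue(0.1, 0.05), "at least two")
})

test_that("CLT p-values track the exact binomial p-value for Bernoulli risks", {
  # agreement holds where the evidence is decisive (the regime in which the
  # calibrator acts); near the boundary the CLT is anti-conservative against
  # the exact tail, a known limitation noted in the methods vignette
  set.seed(8)
  risks0 <- rep(0, 100)
  expect_lt(abs(clt_pvalue(risks0, 0.05) - bf_binom_pvalue(risks0, 0.05)),
            0.02)
  for (true_rate in c(0.15, 0.3)) {
    risks <- as.numeric(runif(100) < true_rate)
    expect_lt(abs(clt_pvalue(risks, 0.05) - bf_binom_pvalue(risks, 0.05)),
              0.02)
  }
})

test_that("Bonferroni and FST selections match their definitions", {
  lam <- c(0.6, 0.7, 0.8)
  expect_equal(bonferroni_select(lam, c(0.2, 0.004, 0.001), 0.05),
               c(0.7, 0.8))
  expect_equal(bonferroni_select(lam, rep(1, 3), 0.05), numeric(0))
  expect_equal(bonferroni_select(0.5, 0.04, 0.05), 0.5) # |grid| = 1
  # FST walks from the largest lambda and stops at the first failure
  lam4 <- c(0.9, 0.8, 0.7, 0.6)
  expect_equal(fst_select(lam4, c(0.001, 0.03, 0.2, 0.01), 0.05),
               c(0.8, 0.9))
  expect_equal(fst_select(lam4, c(0.2, 0.001, 0.001, 0.001), 0.05),
               numeric(0))
  expect_equal(fst_select(lam4, rep(0.04, 4), 0.05), sort(lam4))
})

test_that("selection procedures agree with brute force on random grids", {
  set.seed(13)
  pool <- c(0.0001, 0.002, 0.02, 0.05, 0.2, 0.9, 1)
  for (i in 1:400) {
    m <- sample(1:6, 1)
    lam <- sort(runif(m))
    p <- sample(pool, m, replace = TRUE)
    delta <- sample(c(0.05, 0.1, 0.2), 1)
    expect_equal(bonferroni_select(lam, p, delta), bf_bonferroni(lam, p, delta))
    expect_equal(fst_select(lam, p, delta), bf_fst(lam, p, delta))
  }
})

test_that("Bonferroni selects a subset of FST under monotone p-values", {
  set.seed(14)
  for (i in 1:50) {
    m <- sample(2:8, 1)
    lam <- sort(runif(m))
    p <- sort(runif(m, 0, 0.3), decreasing = TRUE) # non-increasing in lambda
    b <- bonferroni_select(lam, p, 0.1)
    f <- fst_select(lam, p, 0.1)
    expect_true(all(b %in% f))
    if (length(b) > 0 && length(f) > 0) expect_lte(min(f), min(b))
  }
})

test_that("calibration returns a validated set with controlled risk", {
  d <- simulate_alarm_dataset(synth_params(
    event_rate = 0.01, label_window_len = 8, flip_prob = 0,
    series_len = 500, n_series = 60, seed = 31
  ))
  cal <- calibrate_alarms(d, alpha = 0.05, delta = 0.1,
                          lambda_grid = seq(0.51, 0.91, by = 0.1))
  expect_gt(length(cal$valid_set), 0)
  expect_equal(cal$chosen_lambda, min(cal$valid_set))
  expect_lte(glance(cal)$risk_at_chosen, 0.05)
  # with a perfect oracle and vote window 10, no 10-sample window ending on
  # a non-preictal sample can exceed a 9/10 fraction: lambda >= 0.9 has
  # exactly zero empirical risk
  td <- tidy(cal)
  expect_equal(td$mean_risk[td$lambda == 0.91], 0)
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
})

test_that("an uncontrollable risk yields an empty set, not an error", {
  d <- tibble::tibble(
    series_id = 1:4,
    label = replicate(4, rep(0L, 60), simplify = FALSE),
    prediction = replicate(4, rep(1L, 60), simplify = FALSE)
  )
  pp <- pp_params(vote_window_len = 5, pooling_enabled = FALSE)
  cal <- calibrate_alarms(d, alpha = 0.01, lambda_grid = c(0.5, 0.9),
                          postprocess = pp)
  expect_equal(length(cal$valid_set), 0)
  expect_true(is.na(cal$chosen_lambda))
  # ... unless the degenerate lambda = 1 (which silences all alarms) is there
  cal1 <- calibrate_alarms(d, alpha = 0.01, lambda_grid = c(0.5, 0.9, 1),
                           postprocess = pp)
  expect_equal(cal1$valid_set, 1)
  expect_equal(cal1$chosen_lambda, 1)
})

test_that("calibration is deterministic and anti-monotone in lambda", {
  d <- simulate_alarm_dataset(synth_params(n_series = 40, series_len = 400,
                                           seed = 77))
  c1 <- calibrate_alarms(d, alpha = 0.05)
  c2 <- calibrate_alarms(d, alpha = 0.05)
  expect_identical(tidy(c1), tidy(c2))
  expect_true(all(diff(tidy(c1)$mean_risk) <= 1e-12))
  expect_true(all(diff(tidy(c1)$p_value) <= 1e-9))
})

test_that("calibrated predictors control risk across repeated calibrations", {
  # (alpha, delta)-RCP coverage: over independent calibration draws, the
  # held-out risk at the chosen lambda exceeds alpha in at most a
  # delta + 3 SE fraction of replicates.
  alpha <- 0.05
  delta <- 0.1
  grid <- seq(0.51, 0.99, by = 0.04)
  pp <- pp_params(vote_window_len = 10, pooling_enabled = FALSE)
  gen <- function(n, seed) {
    simulate_alarm_matrices(synth_params(
      event_rate = 0.005, label_window_len = 8, flip_prob = 0.05,
      series_len = 400, n_series = n, seed = seed
    ))
  }
  # one large held-out set estimates the true risk curve
  hold <- gen(800, 424242)
  true_risk <- colMeans(lttcal:::risk_profile_mats(
    hold$labels, hold$predictions, grid, pp
  )$risks)
  R <- 200
  exceed <- logical(R)
  for (r in seq_len(R)) {
    m <- gen(120, 1000 + r)
    risks <- lttcal:::risk_profile_mats(m$labels, m$predictions, grid,
                                        pp)$risks
    p <- vapply(seq_along(grid), function(j) clt_pvalue(risks[, j], alpha),
                numeric(1))
    valid <- fst_select(grid, p, delta)
    exceed[r] <- length(valid) > 0 &&
      true_risk[match(min(valid), grid)] > alpha
  }
  expect_lte(mean(exceed), delta + 3 * sqrt(delta * (1 - delta) / R))
})
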