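# A small but complete instance of the validation protocol, shared across
# the assertions below.
study_small <- run_synthetic_study(study_config(
  alpha_list = c(0.001, 0.05, 1),
  n_experiments = 6,
  synthetic = synth_params(event_rate = 0.005, label_window_len = 8,
                           flip_prob = 0.05, series_len = 1000,
                           n_series = 600, seed = 20260920),
  pooling_variants = c(TRUE, FALSE)
))

test_that("the realised test risk stays at or below every requested bound", {
  s <- study_small$summary
  expect_true(all(s$mean_far <= s$alpha + 1e-12, na.rm = TRUE))
  expect_true(all(s$n_empty == 0))
  expect_true(all(s$sd_far >= 0, na.rm = TRUE))
})

test_that("a vacuous bound selects the least restrictive lambda everywhere", {
  e1 <- dplyr::filter(study_small$experiments, alpha == 1)
  expect_true(all(e1$chosen_lambda == 0.51))
})

test_that("chosen lambda is non-increasing in alpha within an experiment", {
  wide <- study_small$experiments |>
    dplyr::select(experiment, pooling, method, alpha, chosen_lambda) |>
    tidyr::pivot_wider(names_from = alpha, values_from = chosen_lambda,
                       names_prefix = "a")
  expect_true(all(wide$a0.001 >= wide$a0.05, na.rm = TRUE))
  expect_true(all(wide$a0.05 >= wide$a1, na.rm = TRUE))
})

test_that("FST never chooses a larger lambda than Bonferroni", {
  wide <- study_small$experiments |>
    dplyr::select(experiment, pooling, alpha, method, chosen_lambda) |>
    tidyr::pivot_wider(names_from = method, values_from = chosen_lambda)
  expect_true(all(wide$fst <= wide$bonferroni, na.rm = TRUE))
})

test_that("the study is a pure function of its configuration", {
  cfg <- study_config(
    alpha_list = 0.05, n_experiments = 2,
    synthetic = synth_params(n_series = 200, series_len = 500, seed = 5),
    pooling_variants = TRUE
  )
  expect_identical(run_synthetic_study(cfg)$experiments,
                   run_synthetic_study(cfg)$experiments)
})

test_that("scale shrinks the protocol without touching the conditions", {
  cfg <- study_config(scale = 0.01)
  expect_equal(cfg$n_experiments, 2)
  expect_equal(cfg$synthetic$n_series, 100)
  expect_equal(cfg$synthetic$series_len, 1000) # length untouched
  expect_equal(cfg$synthetic$event_rate, 0.005)
  expect_error(study_config(scale = 0), "scale")
})

test_that("record evaluation reports raw vs calibrated clinical metrics", {
  recs <- make_record_set(5, 600, seed = 50, flip = 0.08, period = 60)
  records <- tibble::tibble(
    record = paste0("r", 1:5),
    label = lapply(recs, `[[`, "label"),
    prediction = lapply(recs, `[[`, "prediction")
  )
  cal <- calibrate_alarms(
    records, alpha = 2, delta = 0.1, # generous bound: chooses min lambda
    lambda_grid = c(0.51, 0.7),
    postprocess = pp_params(vote_window_len = 5, pool_size = 5),
    risk = "event_rate"
  )
  rep <- run_record_evaluation(records, cal)
  td <- tidy(rep)
  expect_equal(nrow(td), 5)
  expect_true(all(td$far_cal <= td$far_raw))
  expect_true(all(td$reduction_pct >= 0 & td$reduction_pct <= 100))
  g <- glance(rep)
  expect_true(g$sensitivity_cal <= g$sensitivity_raw + 1e-9)
  expect_gte(g$mean_reduction, min(td$reduction_pct))
  expect_lte(g$mean_reduction, max(td$reduction_pct))
})

test_that("silencing calibration gives 100 % reduction and 0 % sensitivity", {
  recs <- make_record_set(3, 400, seed = 90, flip = 0.05, period = 60)
  records <- tibble::tibble(
    label = lapply(recs, `[[`, "label"),
    prediction = lapply(recs, `[[`, "prediction")
  )
  cal <- calibrate_alarms(
    records, alpha = 10, delta = 0.1, lambda_grid = c(1),
    postprocess = pp_params(vote_window_len = 5, pool_size = 5),
    risk = "event_rate"
  )
  expect_equal(cal$chosen_lambda, 1) # lambda = 1 kills every alarm
  rep <- run_record_evaluation(records, cal)
  g <- glance(rep)
  expect_equal(g$sensitivity_cal, 0)
  expect_equal(g$far_cal_total, 0)
  expect_equal(g$mean_reduction, 100)
})

test_that("a calibration without a validated set refuses record evaluation", {
  recs <- make_record_set(3, 400, seed = 91, period = 60)
  records <- tibble::tibble(
    label = lapply(recs, `[[`, "label"),
    prediction = lapply(recs, function(r) {
      binary_series(rep(1L, length(r$label)), sample_period = 60)
    })
  )
  cal <- calibrate_alarms(
    records, alpha = 0.001, delta = 0.1, lambda_grid = c(0.5),
    postprocess = pp_params(vote_window_len = 5, pooling_enabled = FALSE)
  )
  expect_true(is.na(cal$chosen_lambda))
  expect_error(run_record_evaluation(records, cal), "alpha = 0.001")
})

test_that("plot methods return ggplot objects", {
  expect_s3_class(autoplot(study_small), "ggplot")
  d <- simulate_alarm_dataset(synth_params(n_series = 30, series_len = 300,
                                           seed = 2))
  expect_s3_class(autoplot(calibrate_alarms(d, alpha = 0.05)), "ggplot")
  expect_s3_class(autoplot(aggregate_records(example_record_table())),
                  "ggplot")
})
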