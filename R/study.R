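#' Configuration of the synthetic validation study
#'
#' Describes the full protocol: for each experiment, generate a dataset of
#' label/prediction series pairs, split it into calibration and test halves,
#' calibrate lambda at each risk level with each multiple-testing method and
#' post-processing variant, and evaluate the realised false alarm rate and
#' accuracy on the test half at the chosen lambda.
#'
#' The reference protocol uses 200 experiments of 10,000 series of length
#' 1,000 (label window 8) per risk level; `scale` shrinks the number of
#' experiments and series proportionally for desk-scale runs while leaving
#' series length and all other conditions untouched.
#'
#' @param alpha_list risk bounds to calibrate at.
#' @param n_experiments experiments per risk bound.
#' @param synthetic a [synth_params()] object (its `seed` is the master
#'   seed; each experiment re-derives per-series substreams from it).
#' @param vote_window_len,pool_size post-processing aggregation sizes.
#' @param pooling_variants logical vector: which pooling settings to run
#'   (`TRUE` = with max-pooling, `FALSE` = majority vote only).
#' @param methods multiple-testing corrections to compare.
#' @param delta familywise error rate for the calibration.
#' @param lambda_grid candidate thresholds.
#' @param split_fraction fraction of series used for calibration (the rest
#'   is the test half).
#' @param scale overall scale factor applied to `n_experiments` and
#'   `n_series` (minimum 1 each).
#' @return A list of class `study_config`.
#' @export
study_config <- function(alpha_list = c(0.001, 0.005, 0.01, 0.05, 0.1, 1),
                         n_experiments = 200,
                         synthetic = synth_params(
                           event_rate = 0.005, label_window_len = 8,
                           flip_prob = 0.05, series_len = 1000,
                           n_series = 10000, seed = 1
                         ),
                         vote_window_len = 10, pool_size = 10,
                         pooling_variants = c(TRUE, FALSE),
                         methods = c("fst", "bonferroni"),
                         delta = 0.1,
                         lambda_grid = seq(0.51, 0.99, by = 0.01),
                         split_fraction = 0.5,
                         scale = 1) {
  stopifnot(length(alpha_list) >= 1, all(alpha_list >= 0))
  if (split_fraction <= 0 || split_fraction >= 1) {
    abort("`split_fraction` must lie in (0, 1)")
  }
  if (scale <= 0 || scale > 1) abort("`scale` must lie in (0, 1]")
  n_experiments <- max(1L, as.integer(round(n_experiments * scale)))
  if (scale < 1) {
    synthetic <- synth_params(
      event_rate = synthetic$event_rate,
      label_window_len = synthetic$label_window_len,
      flip_prob = synthetic$flip_prob,
      series_len = synthetic$series_len,
      n_series = max(4L, as.integer(round(synthetic$n_series * scale))),
      seed = synthetic$seed
    )
  }
  methods <- match.arg(methods, c("fst", "bonferroni"), several.ok = TRUE)
  structure(
    list(
      alpha_list = alpha_list, n_experiments = n_experiments,
      synthetic = synthetic, vote_window_len = as.integer(vote_window_len),
      pool_size = as.integer(pool_size),
      pooling_variants = pooling_variants, methods = methods, delta = delta,
      lambda_grid = lambda_grid, split_fraction = split_fraction
    ),
    class = "study_config"
  )
}

# Fresh master seed per experiment, prefix-stable in the experiment index.
experiment_seed <- function(master, e) {
  as.integer((abs(master) %% 2147483647 + e * 1048583) %% 2147483647)
}

#' Run the synthetic risk-control validation study
#'
#' Executes the protocol of [study_config()]: per experiment and
#' post-processing variant, per-unit risks on the calibration half feed CLT
#' p-values for every lambda on the grid; each (alpha, method) pair selects
#' its validated set and chooses the smallest validated lambda; the test
#' half then yields the realised false alarm rate (per-sample fraction at
#' the output resolution) and pointwise accuracy at that lambda.
#' Experiments with an empty validated set are counted and excluded from
#' risk means, never dropped silently. Deterministic given the config.
#'
#' @param config a [study_config()].
#' @param progress print a line per experiment?
#' @return An object of class `ltt_study`: `$experiments` (one row per
#'   experiment x variant x alpha x method), `$summary` (one row per cell
#'   with mean/sd false alarm rate, accuracy, modal chosen lambda, empty-set
#'   and exceedance counts), and the config. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
run_synthetic_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  sp0 <- config$synthetic
  n_cal <- max(2L, as.integer(floor(sp0$n_series * config$split_fraction)))
  if (sp0$n_series - n_cal < 2L) {
    abort("too few series to split into calibration and test halves")
  }
  grid <- config$lambda_grid
  rows <- vector("list", 0L)
  for (e in seq_len(config$n_experiments)) {
    sp <- sp0
    sp$seed <- experiment_seed(sp0$seed, e)
    m <- simulate_alarm_matrices(sp)
    cal_idx <- seq_len(n_cal)
    test_idx <- (n_cal + 1L):sp$n_series
    for (pooling in config$pooling_variants) {
      pp <- pp_params(vote_threshold = 0, # placeholder; grid supplies lambda
                      vote_window_len = config$vote_window_len,
                      pool_size = config$pool_size,
                      pooling_enabled = pooling)
      cal <- risk_profile_mats(m$labels[, cal_idx, drop = FALSE],
                               m$predictions[, cal_idx, drop = FALSE],
                               grid, pp)
      test <- risk_profile_mats(m$labels[, test_idx, drop = FALSE],
                                m$predictions[, test_idx, drop = FALSE],
                                grid, pp)
      out_period <- if (pooling) config$pool_size else 1L
      for (alpha in config$alpha_list) {
        p_values <- vapply(seq_along(grid), function(j) {
          clt_pvalue(cal$risks[, j], alpha)
        }, numeric(1))
        for (method in config$methods) {
          valid <- switch(method,
            bonferroni = bonferroni_select(grid, p_values, config$delta),
            fst = fst_select(grid, p_values, config$delta)
          )
          if (length(valid) == 0L) {
            rows[[length(rows) + 1L]] <- tibble(
              experiment = e, pooling = pooling, alpha = alpha,
              method = method, n_valid = 0L, chosen_lambda = NA_real_,
              test_far = NA_real_, test_far_per_step = NA_real_,
              accuracy = NA_real_
            )
            next
          }
          lam <- min(valid)
          j <- match(lam, grid)
          far <- mean(test$risks[, j])
          acc <- mean((test$frac > lam) == (test$labels > 0L))
          rows[[length(rows) + 1L]] <- tibble(
            experiment = e, pooling = pooling, alpha = alpha,
            method = method, n_valid = length(valid), chosen_lambda = lam,
            test_far = far, test_far_per_step = far / out_period,
            accuracy = acc
          )
        }
      }
    }
    if (progress) {
      message(sprintf("experiment %d/%d done", e, config$n_experiments))
    }
  }
  experiments <- dplyr::bind_rows(rows)
  summary <- experiments |>
    dplyr::group_by(.data$alpha, .data$pooling, .data$method) |>
    dplyr::summarise(
      n_experiments = dplyr::n(),
      n_empty = sum(is.na(.data$chosen_lambda)),
      mean_far = mean(.data$test_far, na.rm = TRUE),
      sd_far = sd(.data$test_far, na.rm = TRUE),
      mean_far_per_step = mean(.data$test_far_per_step, na.rm = TRUE),
      mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
      sd_accuracy = sd(.data$accuracy, na.rm = TRUE),
      modal_lambda = modal_value(.data$chosen_lambda),
      n_exceed = sum(.data$test_far > .data$alpha, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(experiments = experiments, summary = summary, config = config),
    class = "ltt_study"
  )
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

# Risk profile over the lambda grid from label/prediction matrices
# (series in columns). Returns per-unit risks (units x lambdas) plus the
# pooled vote fractions and labels for accuracy evaluation.
risk_profile_mats <- function(lab, prd, grid, pp) {
  frac <- vote_fraction(prd, pp$vote_window_len)
  if (pp$pooling_enabled) {
    frac <- block_max(frac, pp$pool_size)
    lab <- block_max(lab, pp$pool_size)
  }
  nonpre <- lab == 0L
  expo <- colSums(nonpre)
  if (any(expo == 0L)) {
    abort("undefined risk: a unit has no non-preictal exposure")
  }
  risks <- vapply(grid, function(lam) {
    colSums((frac > lam) & nonpre) / expo
  }, numeric(ncol(lab)))
  list(risks = matrix(risks, ncol = length(grid)), frac = frac, labels = lab)
}

#' @export
print.ltt_study <- function(x, ...) {
  cat(sprintf(
    "<ltt_study> %d experiments x %d alphas; %s pooling variant(s); %s\n",
    x$config$n_experiments, length(x$config$alpha_list),
    length(x$config$pooling_variants),
    paste(x$config$methods, collapse = " & ")
  ))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname run_synthetic_study
#' @param x,object an `ltt_study`.
#' @param ... unused.
#' @export
tidy.ltt_study <- function(x, ...) x$summary

#' @rdname run_synthetic_study
#' @export
glance.ltt_study <- function(x, ...) {
  tibble(
    n_experiments = x$config$n_experiments,
    n_series = x$config$synthetic$n_series,
    series_len = x$config$synthetic$series_len,
    delta = x$config$delta,
    n_cells = nrow(x$summary),
    n_empty_total = sum(x$summary$n_empty),
    max_exceed_fraction = max(
      x$summary$n_exceed / pmax(x$summary$n_experiments - x$summary$n_empty,
                                1L)
    )
  )
}

#' @rdname run_synthetic_study
#' @export
autoplot.ltt_study <- function(object, ...) {
  df <- object$summary
  df$variant <- paste0(ifelse(df$pooling, "pooled", "unpooled"), ", ",
                       df$method)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$mean_far,
                                   colour = .data$variant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(alpha), y = "mean test false alarm rate",
      colour = NULL,
      title = "Realised risk stays below the requested bound"
    ) +
    ggplot2::theme_minimal()
}

#' Evaluate raw vs calibrated alarms on a set of records
#'
#' Applies a calibrated transform to each record's raw alarm series and
#' tabulates the clinical comparison: event-based sensitivity, false alarms
#' per non-preictal hour, and the per-record reduction, aggregated with
#' [aggregate_records()]. Sample periods are taken from the series (seconds).
#'
#' @param records tibble with list-columns `label` and `prediction` (raw,
#'   binary, at the base resolution) and optionally a `record` id column.
#' @param calibration an [calibrate_alarms()] result with a chosen lambda.
#' @return An `alarm_report` (see [aggregate_records()]).
#' @export
run_record_evaluation <- function(records, calibration) {
  stopifnot(is.data.frame(records),
            all(c("label", "prediction") %in% names(records)),
            inherits(calibration, "ltt_calibration"))
  if (is.na(calibration$chosen_lambda)) {
    abort(paste0(
      "no calibrated threshold: the validated set was empty at alpha = ",
      calibration$alpha
    ))
  }
  pp <- calibration$postprocess
  pp$vote_threshold <- calibration$chosen_lambda
  ids <- if ("record" %in% names(records)) as.character(records$record) else {
    as.character(seq_len(nrow(records)))
  }
  per <- lapply(seq_len(nrow(records)), function(i) {
    lab <- records$label[[i]]
    prd <- records$prediction[[i]]
    raw <- evaluate_alarms(prd, lab, record = ids[i])
    cal_alarm <- apply_g_lambda(prd, pp)
    cal <- evaluate_alarms(cal_alarm, pool_labels(lab, pp), record = ids[i])
    tibble(
      record = ids[i],
      n_seizures = raw$n_seizures,
      n_predicted_raw = raw$n_predicted,
      n_predicted_cal = min(cal$n_predicted, raw$n_seizures),
      fp_raw = raw$false_positive_events,
      fp_cal = cal$false_positive_events,
      non_preictal_hours = raw$non_preictal_hours,
      far_raw = raw$false_alarm_rate,
      far_cal = cal$false_alarm_rate,
      duration_hours = raw$duration_hours
    )
  })
  aggregate_records(dplyr::bind_rows(per))
}
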