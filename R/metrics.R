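#' Evaluate one record's alarms against its preictal labels
#'
#' Event-based clinical bookkeeping for a single recording. Each maximal run
#' of ones in `label` is one seizure's preictal window; a seizure counts as
#' predicted when at least one alarm sample falls inside its window. Alarm
#' events (maximal runs of ones in `prediction`) that never touch preictal
#' time are false positives — a conservative definition under which ictal and
#' "nearly preictal" alarms all count as false.
#'
#' @param prediction binary alarm series.
#' @param label binary preictal-label series, same length and resolution.
#' @param record optional record identifier carried into the output.
#' @return A one-row tibble: `record`, `n_seizures`, `n_predicted`,
#'   `false_positive_events`, `non_preictal_hours`, `duration_hours`,
#'   `false_alarm_rate` (per hour; `NA` when there is no non-preictal time).
#'   The sample period of `prediction` is taken to be in seconds.
#' @examples
#' lab <- binary_series(c(0, 0, 1, 1, 0, 0), sample_period = 1800)
#' alm <- binary_series(c(1, 0, 0, 1, 0, 1), sample_period = 1800)
#' evaluate_alarms(alm, lab)
#' @export
evaluate_alarms <- function(prediction, label, record = NA_character_) {
  p <- as_binary_values(prediction, "prediction")
  l <- as_binary_values(label, "label")
  if (length(p) != length(l)) {
    abort("`prediction` and `label` must have the same length")
  }
  sp <- sample_period(prediction)
  seiz <- detect_alarm_events(l)
  alarms <- detect_alarm_events(p)
  predicted <- 0L
  if (nrow(seiz) > 0L && any(p == 1L)) {
    alarm_idx <- which(p == 1L) - 1L # 0-based
    predicted <- sum(vapply(seq_len(nrow(seiz)), function(i) {
      any(alarm_idx >= seiz$start[i] & alarm_idx < seiz$end[i])
    }, logical(1)))
  }
  fp <- 0L
  if (nrow(alarms) > 0L) {
    pre_idx <- which(l == 1L) - 1L
    fp <- sum(vapply(seq_len(nrow(alarms)), function(i) {
      !any(pre_idx >= alarms$start[i] & pre_idx < alarms$end[i])
    }, logical(1)))
  }
  non_pre_h <- sum(l == 0L) * sp / 3600
  tibble(
    record = record,
    n_seizures = nrow(seiz),
    n_predicted = as.integer(predicted),
    false_positive_events = as.integer(fp),
    non_preictal_hours = non_pre_h,
    duration_hours = length(l) * sp / 3600,
    false_alarm_rate = if (non_pre_h > 0) fp / non_pre_h else NA_real_
  )
}

#' Event-based sensitivity, pooled over records
#'
#' The percentage of seizures for which at least one alarm was raised during
#' the preictal window, pooled over all records: `100 * TP / (TP + FN)`.
#'
#' @param evals a data frame with columns `n_predicted` and `n_seizures`
#'   (one row per record), e.g. rows from [evaluate_alarms()].
#' @return Sensitivity in percent.
#' @examples
#' sensitivity(data.frame(n_predicted = c(1, 0), n_seizures = c(2, 1)))
#' @export
sensitivity <- function(evals) {
  stopifnot(is.data.frame(evals),
            all(c("n_predicted", "n_seizures") %in% names(evals)))
  total <- sum(evals$n_seizures)
  if (total < 1) abort("undefined sensitivity: no seizures in the records")
  if (any(evals$n_predicted > evals$n_seizures | evals$n_predicted < 0)) {
    abort("`n_predicted` must lie in [0, n_seizures] per record")
  }
  100 * sum(evals$n_predicted) / total
}

#' False alarms per non-preictal hour
#'
#' @param false_positive_events count of false alarm events.
#' @param non_preictal_hours non-preictal exposure in hours, > 0.
#' @return The rate in 1/hour.
#' @examples
#' false_alarm_rate(6, 2)
#' @export
false_alarm_rate <- function(false_positive_events, non_preictal_hours) {
  if (any(non_preictal_hours <= 0)) {
    abort("undefined false alarm rate: non-preictal exposure must be > 0")
  }
  if (any(false_positive_events < 0)) {
    abort("`false_positive_events` must be non-negative")
  }
  false_positive_events / non_preictal_hours
}

#' Percentage reduction of the false alarm rate
#'
#' `100 * (raw - calibrated) / raw`; 100 when calibration removes every false
#' alarm, 0 when nothing changes. Undefined (an error) when the raw rate is
#' zero — there is nothing to reduce.
#'
#' @param raw_rate raw (uncalibrated) false alarm rate, > 0.
#' @param calibrated_rate false alarm rate after calibration.
#' @param round_to digits for reporting; `NULL` keeps full precision.
#' @return Reduction in percent (vectorised).
#' @examples
#' reduction_percent(5.8, 2.1)
#' @export
reduction_percent <- function(raw_rate, calibrated_rate, round_to = 0) {
  if (any(raw_rate <= 0)) {
    abort("undefined reduction: `raw_rate` must be positive")
  }
  out <- 100 * (raw_rate - calibrated_rate) / raw_rate
  if (!is.null(round_to)) out <- round(out, round_to)
  out
}

#' Pointwise accuracy of alarms against labels
#'
#' Fraction of samples on which the alarm series agrees with the label
#' series. Both must live at the same temporal resolution; when alarms were
#' max-pooled, pool the labels identically first (see [max_pool()]).
#'
#' @param prediction,label binary series of equal length.
#' @return A fraction in \[0, 1\].
#' @export
pointwise_accuracy <- function(prediction, label) {
  p <- as_binary_values(prediction, "prediction")
  l <- as_binary_values(label, "label")
  if (length(p) != length(l)) {
    abort("`prediction` and `label` must have the same length")
  }
  mean(p == l)
}

#' Aggregate per-record evaluations into a study report
#'
#' Takes a table with one row per record comparing a raw and a calibrated
#' system, and produces pooled sensitivities, total false alarm rates and the
#' mean false-alarm-rate reduction, unweighted and duration-weighted.
#'
#' Expected columns: `n_seizures`, `n_predicted_raw`, `n_predicted_cal`,
#' `far_raw`, `far_cal`, `duration_hours`; optional `record`, `n_items`,
#' `fp_raw`, `fp_cal`, `non_preictal_hours`, and `reduction_pct`. A supplied
#' `reduction_pct` column (e.g. transcribed from a published table) is used
#' as-is; otherwise per-record reductions are computed from the rates and
#' rounded to the nearest percent for reporting. Total false alarm rates pool
#' false positives over summed exposure when `fp_*` and `non_preictal_hours`
#' are available, and otherwise fall back to duration-weighted means of the
#' per-record rates.
#'
#' @param evals the per-record data frame described above.
#' @param weighting `"duration"` (weights = record durations) or
#'   `"unweighted"` for the reported mean reduction; both are kept in the
#'   output.
#' @return An object of class `alarm_report` with [tidy()] (per-record rows,
#'   reduction filled in) and [glance()] (one summary row) methods.
#' @examples
#' tbl <- tibble::tibble(
#'   n_seizures = c(1, 2), n_predicted_raw = c(1, 2), n_predicted_cal = c(1, 1),
#'   far_raw = c(4, 6), far_cal = c(0, 3), duration_hours = c(2, 3)
#' )
#' glance(aggregate_records(tbl))
#' @export
aggregate_records <- function(evals, weighting = c("duration", "unweighted")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(evals), nrow(evals) >= 1L)
  needed <- c("n_seizures", "n_predicted_raw", "n_predicted_cal",
              "far_raw", "far_cal", "duration_hours")
  missing_cols <- setdiff(needed, names(evals))
  if (length(missing_cols) > 0L) {
    abort(paste("`evals` lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  evals <- as_tibble(evals)
  if (!"reduction_pct" %in% names(evals)) {
    evals$reduction_pct <- reduction_percent(evals$far_raw, evals$far_cal)
  }
  w <- switch(weighting,
    duration = evals$duration_hours,
    unweighted = rep(1, nrow(evals))
  )
  sens_raw <- sensitivity(data.frame(n_predicted = evals$n_predicted_raw,
                                     n_seizures = evals$n_seizures))
  sens_cal <- sensitivity(data.frame(n_predicted = evals$n_predicted_cal,
                                     n_seizures = evals$n_seizures))
  pooled_far <- function(rates, fp_col) {
    if (fp_col %in% names(evals) && "non_preictal_hours" %in% names(evals)) {
      sum(evals[[fp_col]]) / sum(evals$non_preictal_hours)
    } else {
      weighted.mean(rates, evals$duration_hours)
    }
  }
  summary <- tibble(
    n_records = nrow(evals),
    total_seizures = sum(evals$n_seizures),
    sensitivity_raw = sens_raw,
    sensitivity_cal = sens_cal,
    far_raw_total = pooled_far(evals$far_raw, "fp_raw"),
    far_cal_total = pooled_far(evals$far_cal, "fp_cal"),
    mean_reduction = weighted.mean(evals$reduction_pct, w),
    mean_reduction_unweighted = mean(evals$reduction_pct),
    weighting = weighting
  )
  structure(
    list(per_record = evals, summary = summary, weighting = weighting),
    class = "alarm_report"
  )
}

#' @export
print.alarm_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<alarm_report> %d records, %d seizures\n",
      "sensitivity: %.0f%% raw -> %.0f%% calibrated\n",
      "false alarm rate: %.2f -> %.2f per hour (%s-weighted totals)\n",
      "mean reduction: %.2f%% (%s), %.2f%% (unweighted)\n"
    ),
    s$n_records, s$total_seizures, s$sensitivity_raw, s$sensitivity_cal,
    s$far_raw_total, s$far_cal_total,
    if (x$weighting == "duration") "duration" else "un",
    s$mean_reduction, x$weighting, s$mean_reduction_unweighted
  ))
  invisible(x)
}

#' @rdname aggregate_records
#' @param x,object an `alarm_report`.
#' @param ... unused.
#' @export
tidy.alarm_report <- function(x, ...) x$per_record

#' @rdname aggregate_records
#' @export
glance.alarm_report <- function(x, ...) x$summary

#' @rdname aggregate_records
#' @export
autoplot.alarm_report <- function(object, ...) {
  df <- object$per_record
  df$record <- if ("record" %in% names(df)) as.character(df$record) else {
    as.character(seq_len(nrow(df)))
  }
  long <- tidyr::pivot_longer(
    df[, c("record", "far_raw", "far_cal")],
    cols = c("far_raw", "far_cal"),
    names_to = "stage", values_to = "far"
  )
  long$stage <- factor(long$stage, levels = c("far_raw", "far_cal"),
                       labels = c("raw", "calibrated"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$record, y = .data$far,
                               fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "record", y = "false alarms per hour", fill = NULL,
                  title = "False alarm rate before and after calibration") +
    ggplot2::theme_minimal()
}

#' Write / read a per-record evaluation table
#'
#' Plain-CSV persistence for the per-record schema of [aggregate_records()],
#' so published record-level results can be replayed through the aggregator.
#'
#' @param evals per-record data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_record_evaluations <- function(evals, path) {
  readr::write_csv(as_tibble(evals), path)
  invisible(path)
}

#' @rdname write_record_evaluations
#' @export
read_record_evaluations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Example record-level evaluation table
#'
#' The seven test records of a published patient-specific deep-learning
#' seizure predictor evaluated on the Siena scalp EEG corpus, before (raw)
#' and after Learn-Then-Test calibration, as shipped in `inst/extdata/`.
#' Rates are false alarms per non-preictal hour; `reduction_pct` is the
#' published integer reduction column.
#'
#' @return A tibble with one row per record.
#' @examples
#' glance(aggregate_records(example_record_table()))
#' @export
example_record_table <- function() {
  read_record_evaluations(
    system.file("extdata", "siena_test_records.csv", package = "lttcal",
                mustWork = TRUE)
  )
}
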