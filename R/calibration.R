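#' Per-unit empirical false-alarm risk
#'
#' The risk of one calibration unit (one series or one record) at a fixed
#' transform: false-positive mass divided by non-preictal exposure.
#'
#' Two estimators are available. `"sample_fraction"` is the synthetic-study
#' risk: the fraction of non-preictal samples on which an alarm is raised.
#' `"event_rate"` is the clinical risk: merged alarm events with no overlap
#' with preictal time, divided by non-preictal hours (the sample period of
#' `prediction` is taken to be in seconds).
#'
#' @param prediction binary alarm series (already post-processed).
#' @param label binary preictal-label series at the same resolution.
#' @param risk `"sample_fraction"` or `"event_rate"`.
#' @return A single non-negative number.
#' @examples
#' empirical_unit_risk(c(0, 1, 0, 1), c(0, 0, 0, 0))
#' @export
empirical_unit_risk <- function(prediction, label,
                                risk = c("sample_fraction", "event_rate")) {
  risk <- match.arg(risk)
  p <- as_binary_values(prediction, "prediction")
  l <- as_binary_values(label, "label")
  if (length(p) != length(l)) {
    abort("`prediction` and `label` must have the same length")
  }
  nonpre <- l == 0L
  if (!any(nonpre)) {
    abort("undefined risk: the unit has no non-preictal exposure")
  }
  if (risk == "sample_fraction") {
    sum(p == 1L & nonpre) / sum(nonpre)
  } else {
    ev <- detect_alarm_events(p)
    fp <- 0L
    if (nrow(ev) > 0L) {
      pre_idx <- which(l == 1L) - 1L # 0-based
      fp <- sum(vapply(seq_len(nrow(ev)), function(i) {
        !any(pre_idx >= ev$start[i] & pre_idx < ev$end[i])
      }, logical(1)))
    }
    hours <- sum(nonpre) * sample_period(prediction) / 3600
    fp / hours
  }
}

#' One-sided CLT p-value for a risk bound
#'
#' Tests the null hypothesis that the true mean per-unit risk exceeds `alpha`,
#' by studentising the sample mean: `p = pnorm((mean - alpha) * sqrt(n) / s)`
#' with `s` the sample standard deviation (n - 1 divisor). Small p-values are
#' evidence that the risk is controlled at `alpha`.
#'
#' When all units have identical risk (`s = 0`) the z statistic degenerates;
#' the limit is used: p = 0 if the common risk is at most `alpha`, else 1.
#'
#' @param risks numeric vector of per-unit risks, length at least 2.
#' @param alpha the risk bound being tested.
#' @return A p-value in \[0, 1\].
#' @examples
#' clt_pvalue(rep(c(0, 0.05), 25), alpha = 0.05)
#' @export
clt_pvalue <- function(risks, alpha) {
  if (!is.numeric(risks) || length(risks) < 2L || anyNA(risks) ||
      any(!is.finite(risks))) {
    abort("`risks` must be at least two finite per-unit risks")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    abort("`alpha` must be a single non-negative risk bound")
  }
  m <- mean(risks)
  s <- sd(risks)
  if (s == 0) {
    return(as.numeric(m > alpha))
  }
  z <- (m - alpha) * sqrt(length(risks)) / s
  min(max(pnorm(z), 0), 1)
}

#' Familywise-error-controlling selection of valid thresholds
#'
#' Given one p-value per candidate lambda (null: risk above `alpha` at that
#' lambda), return the lambdas whose nulls are rejected while controlling the
#' familywise error rate at `delta`.
#'
#' `bonferroni_select()` rejects where `p <= delta / length(lambda)`; it is
#' valid under arbitrary dependence. `fst_select()` is fixed-sequence
#' testing: it walks lambdas from the largest (strictest alarm control, hence
#' smallest risk) downward, rejecting at full level `delta`, and stops at the
#' first p-value above `delta`. FST is valid here because the post-processing
#' risk is non-increasing in lambda, making the p-values monotone.
#'
#' @param lambda numeric vector of candidate thresholds.
#' @param p_values numeric vector of p-values, same order as `lambda`.
#' @param delta familywise error rate in (0, 1).
#' @return The selected lambdas (possibly empty), in increasing order.
#' @examples
#' bonferroni_select(c(0.6, 0.7, 0.8), c(0.2, 0.004, 0.001), delta = 0.05)
#' fst_select(c(0.6, 0.7, 0.8), c(0.2, 0.004, 0.001), delta = 0.05)
#' @export
bonferroni_select <- function(lambda, p_values, delta) {
  check_selection_args(lambda, p_values, delta)
  sort(lambda[p_values <= delta / length(lambda)])
}

#' @rdname bonferroni_select
#' @export
fst_select <- function(lambda, p_values, delta) {
  check_selection_args(lambda, p_values, delta)
  ord <- order(lambda, decreasing = TRUE)
  rejected <- numeric(0)
  for (i in ord) {
    if (p_values[i] <= delta) rejected <- c(rejected, lambda[i]) else break
  }
  sort(rejected)
}

check_selection_args <- function(lambda, p_values, delta) {
  if (length(lambda) == 0L || length(lambda) != length(p_values)) {
    abort("`lambda` and `p_values` must be non-empty and the same length")
  }
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("`p_values` must lie in [0, 1]")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1) {
    abort("`delta` must be a single value in (0, 1)")
  }
}

# Per-unit risk at every lambda on the grid: an n_units x n_lambda matrix.
# The majority-vote fraction is computed once per unit; thresholding by
# lambda commutes with block maxima, so pooled alarms at every lambda come
# from one pooled fraction vector. Fast matrix path when all units share one
# length and the sample-fraction risk is used.
lambda_risk_matrix <- function(labels, predictions, lambda_grid, postprocess,
                               risk = "sample_fraction") {
  n <- length(labels)
  lens <- lengths(labels)
  w <- postprocess$vote_window_len
  k <- postprocess$pool_size
  pooled <- postprocess$pooling_enabled
  if (any(lengths(predictions) != lens)) {
    abort("labels and predictions must be paired series of equal lengths")
  }
  if (any(lens < w)) {
    abort("`vote_window_len` cannot exceed the shortest series")
  }
  if (risk == "sample_fraction" && length(unique(lens)) == 1L) {
    lab <- matrix(unlist(labels, use.names = FALSE), nrow = lens[1])
    prd <- matrix(unlist(predictions, use.names = FALSE), nrow = lens[1])
    frac <- vote_fraction(prd, w)
    if (pooled) {
      frac <- block_max(frac, k)
      lab <- block_max(lab, k)
    }
    nonpre <- lab == 0L
    expo <- colSums(nonpre)
    if (any(expo == 0L)) {
      abort("undefined risk: a unit has no non-preictal exposure")
    }
    out <- vapply(lambda_grid, function(lam) {
      colSums((frac > lam) & nonpre) / expo
    }, numeric(n))
    return(matrix(out, nrow = n))
  }
  # General path: per unit, per lambda.
  out <- matrix(NA_real_, nrow = n, ncol = length(lambda_grid))
  for (i in seq_len(n)) {
    sp <- sample_period(predictions[[i]])
    frac <- vote_fraction(as_binary_values(predictions[[i]], "prediction"), w)
    lab <- as_binary_values(labels[[i]], "label")
    if (pooled) {
      frac <- block_max(frac, k)
      lab <- as.integer(block_max(lab, k))
      sp <- sp * k
    }
    for (j in seq_along(lambda_grid)) {
      alarm <- binary_series(as.integer(frac > lambda_grid[j]),
                             sample_period = sp)
      out[i, j] <- empirical_unit_risk(alarm, lab, risk = risk)
    }
  }
  out
}

#' Calibrate the alarm threshold with Learn-Then-Test
#'
#' For every lambda on the grid, applies the post-processing transform to
#' each calibration unit, computes per-unit false-alarm risks and a one-sided
#' CLT p-value for the null "risk above `alpha`", then selects the validated
#' set with a familywise-error-controlling correction at level `delta`. Any
#' lambda in the validated set yields an (alpha, delta) risk-controlling
#' predictor; the returned `chosen_lambda` is by default the smallest one,
#' the least restrictive choice (best sensitivity given the monotone
#' trade-off). An empty validated set is a legitimate outcome — the risk is
#' not controllable at this `alpha` with this calibration set — reported as
#' `chosen_lambda = NA`, never an error.
#'
#' @param data a data frame with list-columns `label` and `prediction`
#'   holding paired binary series (one row per calibration unit), e.g. from
#'   [simulate_alarm_dataset()].
#' @param alpha risk bound, in the units of the chosen risk estimator
#'   (per-sample fraction, or alarms per non-preictal hour).
#' @param delta familywise error rate in (0, 1); the probability, over the
#'   draw of the calibration set, that a validated lambda fails to control
#'   the risk.
#' @param lambda_grid strictly increasing candidate thresholds in \[0, 1\].
#' @param method multiple-testing correction: `"fst"` (fixed-sequence
#'   testing, tighter control) or `"bonferroni"`.
#' @param postprocess a [pp_params()] object; its `vote_threshold` is ignored
#'   (lambda is what is being calibrated).
#' @param risk risk estimator, see [empirical_unit_risk()].
#' @param select_fn optional secondary-metric selector: a function taking the
#'   validated lambdas and the per-lambda summary tibble, returning one
#'   lambda. Defaults to the minimum validated lambda.
#' @return An object of class `ltt_calibration` with [tidy()], [glance()],
#'   [autoplot()] and `print()` methods.
#' @examples
#' d <- simulate_alarm_dataset(synth_params(n_series = 50, series_len = 400, seed = 2))
#' cal <- calibrate_alarms(d, alpha = 0.05, lambda_grid = seq(0.51, 0.91, 0.1))
#' glance(cal)
#' @export
calibrate_alarms <- function(data, alpha, delta = 0.1,
                             lambda_grid = seq(0.51, 0.99, by = 0.01),
                             method = c("fst", "bonferroni"),
                             postprocess = pp_params(),
                             risk = c("sample_fraction", "event_rate"),
                             select_fn = NULL) {
  method <- match.arg(method)
  risk <- match.arg(risk)
  stopifnot(is.data.frame(data))
  if (!all(c("label", "prediction") %in% names(data)) || nrow(data) < 2L) {
    abort("`data` needs `label`/`prediction` list-columns and >= 2 units")
  }
  if (length(lambda_grid) == 0L || is.unsorted(lambda_grid, strictly = TRUE) ||
      any(lambda_grid < 0 | lambda_grid > 1)) {
    abort("`lambda_grid` must be strictly increasing within [0, 1]")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    abort("`alpha` must be a single non-negative risk bound")
  }
  risks <- lambda_risk_matrix(data$label, data$prediction, lambda_grid,
                              postprocess, risk = risk)
  p_values <- vapply(seq_along(lambda_grid), function(j) {
    clt_pvalue(risks[, j], alpha)
  }, numeric(1))
  valid <- switch(method,
    bonferroni = bonferroni_select(lambda_grid, p_values, delta),
    fst = fst_select(lambda_grid, p_values, delta)
  )
  summary_tbl <- tibble(
    lambda = lambda_grid,
    mean_risk = colMeans(risks),
    sd_risk = apply(risks, 2L, sd),
    p_value = p_values,
    selected = lambda_grid %in% valid
  )
  chosen <- NA_real_
  if (length(valid) > 0L) {
    chosen <- if (is.null(select_fn)) min(valid) else {
      select_fn(valid, summary_tbl)
    }
    if (!chosen %in% valid) {
      abort("`select_fn` must return a lambda from the validated set")
    }
  }
  structure(
    list(
      summary = summary_tbl,
      valid_set = valid,
      chosen_lambda = chosen,
      alpha = alpha, delta = delta, method = method,
      postprocess = postprocess, risk = risk, n_units = nrow(data)
    ),
    class = "ltt_calibration"
  )
}

#' @export
print.ltt_calibration <- function(x, ...) {
  cat(sprintf(
    "<ltt_calibration> alpha = %g, delta = %g, %s over %d lambdas, n = %d\n",
    x$alpha, x$delta, x$method, nrow(x$summary), x$n_units
  ))
  if (is.na(x$chosen_lambda)) {
    cat("validated set empty: risk not controllable at this alpha\n")
  } else {
    cat(sprintf(
      "validated set: %d lambdas in [%g, %g]; chosen lambda = %g\n",
      length(x$valid_set), min(x$valid_set), max(x$valid_set), x$chosen_lambda
    ))
  }
  invisible(x)
}

#' @rdname calibrate_alarms
#' @param x,object an `ltt_calibration` object.
#' @param ... unused.
#' @export
tidy.ltt_calibration <- function(x, ...) {
  x$summary
}

#' @rdname calibrate_alarms
#' @export
glance.ltt_calibration <- function(x, ...) {
  tibble(
    alpha = x$alpha,
    delta = x$delta,
    method = x$method,
    n_units = x$n_units,
    n_lambda = nrow(x$summary),
    n_valid = length(x$valid_set),
    chosen_lambda = x$chosen_lambda,
    risk_at_chosen = if (is.na(x$chosen_lambda)) NA_real_ else {
      x$summary$mean_risk[match(x$chosen_lambda, x$summary$lambda)]
    }
  )
}

#' @rdname calibrate_alarms
#' @export
autoplot.ltt_calibration <- function(object, ...) {
  df <- object$summary
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$p_value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected)) +
    ggplot2::geom_hline(yintercept = object$delta, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(lambda), y = "p-value (log scale)",
      colour = "validated",
      title = sprintf("Learn-Then-Test calibration (alpha = %g, %s)",
                      object$alpha, object$method)
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$chosen_lambda)) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$chosen_lambda,
                                   linetype = 3)
  }
  gg
}
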