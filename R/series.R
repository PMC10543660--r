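#' Binary series
#'
#' A binary series is the package's elementary object: an ordered vector of
#' 0/1 samples with a known sample period. Labels, raw model alarms and
#' calibrated alarms are all binary series. The constructor attaches the
#' sample period as an attribute; every operation in the package also accepts
#' a plain 0/1 vector, in which case the period defaults to 1 "step".
#'
#' @param values vector coercible to integer, each element 0 or 1.
#' @param sample_period positive duration of one sample. Dimensionless steps
#'   are allowed; pass seconds when working with clocked recordings.
#' @return An integer vector of class `binary_series` with a `sample_period`
#'   attribute.
#' @examples
#' binary_series(c(0, 1, 1, 0), sample_period = 60)
#' @export
binary_series <- function(values, sample_period = 1) {
  x <- as.integer(values)
  if (length(x) < 1L) abort("a binary series needs at least one sample")
  if (anyNA(x) || !all(x == 0L | x == 1L)) {
    abort("binary series values must all be 0 or 1")
  }
  if (!is.numeric(sample_period) || length(sample_period) != 1L ||
      !is.finite(sample_period) || sample_period <= 0) {
    abort("`sample_period` must be a single positive number")
  }
  structure(x, sample_period = sample_period, class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf(
    "<binary_series> %d samples, period %g, %d positive\n",
    length(x), sample_period(x), sum(x)
  ))
  invisible(x)
}

#' Sample period of a series
#'
#' @param x a `binary_series` or plain vector (period 1 assumed).
#' @return The sample period as a single number.
#' @export
sample_period <- function(x) {
  sp <- attr(x, "sample_period")
  if (is.null(sp)) 1 else sp
}

# Coerce a plain 0/1 vector, validating; used by every public operation.
as_binary_values <- function(x, arg = "series") {
  v <- as.integer(x)
  if (length(v) < 1L) abort(sprintf("`%s` must have at least one sample", arg))
  if (anyNA(v) || !all(v == 0L | v == 1L)) {
    abort(sprintf("`%s` must contain only 0/1 values", arg))
  }
  v
}

#' Threshold a probability series into binary alarms
#'
#' Adapter from probabilistic model outputs to the binary alarms the
#' calibration pipeline operates on. A sample is positive iff its probability
#' strictly exceeds the threshold.
#'
#' @param prob numeric vector of probabilities in \[0, 1\].
#' @param threshold scalar in \[0, 1\]; default 0.5.
#' @param sample_period see [binary_series()].
#' @return A `binary_series`.
#' @examples
#' binarize(c(0.2, 0.9, 0.5), threshold = 0.5)
#' @export
binarize <- function(prob, threshold = 0.5, sample_period = 1) {
  if (!is.numeric(prob) || anyNA(prob) || any(prob < 0 | prob > 1)) {
    abort("`prob` must be probabilities in [0, 1]")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single probability in [0, 1]")
  }
  binary_series(as.integer(prob > threshold), sample_period = sample_period)
}

#' Merge consecutive alarm samples into alarm events
#'
#' A clinically meaningful alarm is an uninterrupted stretch of positive
#' samples, not each positive sample separately. Returns maximal runs of ones
#' as half-open, 0-based `[start, end)` sample intervals.
#'
#' @param series binary series (alarms).
#' @return A tibble with integer columns `start`, `end` (half-open, 0-based)
#'   and `length`; zero rows when there is no alarm.
#' @examples
#' detect_alarm_events(c(0, 1, 1, 0, 1))
#' @export
detect_alarm_events <- function(series) {
  v <- as_binary_values(series)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  tibble(
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep]),
    length = as.integer(r$lengths[keep])
  )
}
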