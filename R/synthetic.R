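#' Parameters of the synthetic alarm-series generator
#'
#' The generator emulates the structure of seizure-prediction data: rare
#' Bernoulli event points widened into fixed-length windows of ones (the
#' "preictal" label), and model predictions equal to the ground truth except
#' for independent pointwise flips (a noisy oracle). The regime of interest is
#' `event_rate * label_window_len` well below 1, so labels are sparse windows.
#'
#' @param event_rate per-sample probability of an event point, in \[0, 1\].
#' @param label_window_len length (samples) of the window of ones each event
#'   point is widened into.
#' @param flip_prob probability in \[0, 1) that a prediction sample disagrees
#'   with the ground truth.
#' @param series_len number of samples per series.
#' @param n_series number of independent series pairs to generate.
#' @param seed master seed; each series draws from its own substream derived
#'   from it, so enlarging `n_series` never reshuffles earlier series.
#' @return A list of class `synth_params`.
#' @examples
#' synth_params(event_rate = 0.005, series_len = 1000, n_series = 10, seed = 1)
#' @export
synth_params <- function(event_rate = 0.005, label_window_len = 8,
                         flip_prob = 0.05, series_len = 1000,
                         n_series = 1, seed = 1) {
  check_prob(event_rate, "event_rate")
  if (!is.numeric(flip_prob) || length(flip_prob) != 1L ||
      flip_prob < 0 || flip_prob >= 1) {
    abort("`flip_prob` must be a single probability in [0, 1)")
  }
  check_count(label_window_len, "label_window_len")
  check_count(series_len, "series_len")
  check_count(n_series, "n_series")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer")
  }
  if (event_rate * label_window_len >= 1) {
    warn(paste0(
      "event_rate * label_window_len = ",
      signif(event_rate * label_window_len, 3),
      " >= 1: labels will not be sparse event windows"
    ))
  }
  structure(
    list(
      event_rate = event_rate,
      label_window_len = as.integer(label_window_len),
      flip_prob = flip_prob,
      series_len = as.integer(series_len),
      n_series = as.integer(n_series),
      seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a positive integer", name))
  }
}

# Prefix-stable substream seed for series i under a master seed: growing the
# dataset never changes earlier series. Knuth multiplicative constant, kept
# inside 32-bit signed range (doubles are exact well past 2^53 here).
series_seed <- function(master, i) {
  as.integer((abs(master) %% 2147483647 + (i %% 65536) * 2654435.761 +
                i * 97003) %% 2147483647)
}

#' Generate a sparse Bernoulli point series
#'
#' Each sample is independently 1 with probability `event_rate`, using the
#' ambient RNG stream (seed it yourself, or use [simulate_alarm_dataset()]
#' for the seeded multi-series protocol).
#'
#' @param series_len number of samples.
#' @inheritParams synth_params
#' @return A `binary_series` of event points.
#' @export
gen_point_series <- function(series_len, event_rate) {
  check_count(series_len, "series_len")
  check_prob(event_rate, "event_rate")
  binary_series(as.integer(runif(series_len) < event_rate))
}

# Causal running sum over a window of w samples (sum of x[t-w+1..t], shorter
# at the left edge). Works on a vector or column-wise on a matrix.
running_sum <- function(x, w) {
  if (is.matrix(x)) {
    cs <- apply(x, 2L, cumsum)
    if (w < nrow(x)) {
      lag <- rbind(
        matrix(0, nrow = w, ncol = ncol(x)),
        cs[seq_len(nrow(x) - w), , drop = FALSE]
      )
      cs - lag
    } else {
      cs
    }
  } else {
    cs <- cumsum(x)
    if (w < length(x)) {
      cs - c(rep(0, w), cs[seq_len(length(x) - w)])
    } else {
      cs
    }
  }
}

#' Widen event points into windows of ones
#'
#' Every event point spreads forward over `label_window_len` samples
#' (indices t .. t+w-1), truncated at the end of the series: the convolution
#' of the point series with a rectangular window, thresholded above zero.
#' Overlapping windows merge.
#'
#' @param points binary series of event points.
#' @inheritParams synth_params
#' @return A `binary_series` of the same length.
#' @examples
#' widen_to_windows(c(0, 1, 0, 0, 0), label_window_len = 3)
#' @export
widen_to_windows <- function(points, label_window_len) {
  v <- as_binary_values(points, "points")
  check_count(label_window_len, "label_window_len")
  if (label_window_len > length(v)) {
    abort("`label_window_len` cannot exceed the series length")
  }
  out <- as.integer(running_sum(v, label_window_len) > 0)
  binary_series(out, sample_period = sample_period(points))
}

#' Flip a ground-truth series into noisy-oracle predictions
#'
#' Each sample equals the truth with probability `1 - flip_prob` and its
#' complement otherwise, independently, using the ambient RNG stream.
#'
#' @param truth binary ground-truth series.
#' @inheritParams synth_params
#' @return A `binary_series` of predictions, same length and period as
#'   `truth`.
#' @export
noisy_oracle <- function(truth, flip_prob) {
  v <- as_binary_values(truth, "truth")
  if (!is.numeric(flip_prob) || length(flip_prob) != 1L ||
      flip_prob < 0 || flip_prob >= 1) {
    abort("`flip_prob` must be a single probability in [0, 1)")
  }
  flips <- runif(length(v)) < flip_prob
  binary_series(
    ifelse(flips, 1L - v, v),
    sample_period = sample_period(truth)
  )
}

# Matrix backend: labels and predictions as series_len x n_series integer
# matrices. Each series consumes exactly 2 * series_len uniforms from its own
# substream (points first, then flips), so the label of series i is invariant
# to flip_prob and to n_series.
simulate_alarm_matrices <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  T <- params$series_len
  n <- params$n_series
  u <- vapply(seq_len(n), function(i) {
    set.seed(series_seed(params$seed, i))
    runif(2L * T)
  }, numeric(2L * T))
  points <- u[seq_len(T), , drop = FALSE] < params$event_rate
  storage.mode(points) <- "integer"
  labels <- running_sum(points, params$label_window_len) > 0
  storage.mode(labels) <- "integer"
  flips <- u[T + seq_len(T), , drop = FALSE] < params$flip_prob
  predictions <- ifelse(flips, 1L - labels, labels)
  storage.mode(predictions) <- "integer"
  list(labels = labels, predictions = predictions)
}

#' Simulate a dataset of label/prediction series pairs
#'
#' Draws `n_series` independent pairs: a sparse event-window label series and
#' a noisy-oracle prediction series. Fully reproducible from the master seed,
#' with one substream per series.
#'
#' @param params a [synth_params()] object.
#' @return A tibble with one row per series: `series_id`, and list-columns
#'   `label` and `prediction` holding integer 0/1 vectors of length
#'   `series_len`.
#' @examples
#' simulate_alarm_dataset(synth_params(n_series = 3, series_len = 50, seed = 7))
#' @export
simulate_alarm_dataset <- function(params) {
  m <- simulate_alarm_matrices(params)
  tibble(
    series_id = seq_len(params$n_series),
    label = lapply(seq_len(ncol(m$labels)), function(j) m$labels[, j]),
    prediction = lapply(seq_len(ncol(m$predictions)), function(j) {
      m$predictions[, j]
    })
  )
}

#' Write / read a simulated dataset as delimited text
#'
#' One series pair per row, values packed as 0/1 strings, with the generator
#' parameters in a JSON sidecar (`<path>.params.json`) so experiments can be
#' replayed.
#'
#' @param data a tibble as returned by [simulate_alarm_dataset()].
#' @param path file path for the TSV; the sidecar goes next to it.
#' @param params the [synth_params()] used (written to the sidecar).
#' @return `path`, invisibly (writer); the dataset tibble with a `params`
#'   attribute (reader).
#' @export
write_alarm_dataset <- function(data, path, params = NULL) {
  stopifnot(is.data.frame(data), all(c("label", "prediction") %in% names(data)))
  out <- tibble(
    series_id = data$series_id,
    label = vapply(data$label, paste, character(1), collapse = ""),
    prediction = vapply(data$prediction, paste, character(1), collapse = "")
  )
  readr::write_tsv(out, path)
  if (!is.null(params)) {
    jsonlite::write_json(
      unclass(params), paste0(path, ".params.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_alarm_dataset
#' @export
read_alarm_dataset <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      series_id = readr::col_integer(),
      label = readr::col_character(),
      prediction = readr::col_character()
    )
  )
  unpack <- function(s) {
    lapply(strsplit(s, ""), function(ch) as.integer(ch))
  }
  out <- tibble(
    series_id = raw$series_id,
    label = unpack(raw$label),
    prediction = unpack(raw$prediction)
  )
  sidecar <- paste0(path, ".params.json")
  if (file.exists(sidecar)) {
    p <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "params") <- do.call(synth_params, p)
  }
  out
}
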