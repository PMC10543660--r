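#' Post-processing transform parameters
#'
#' The calibrated transform g_lambda has two temporal-aggregation stages:
#' a causal majority vote (a sample is positive iff the fraction of positives
#' in the window of `vote_window_len` samples ending at it strictly exceeds
#' `vote_threshold`), then optional max-pooling onto a coarser time grid in
#' disjoint blocks of `pool_size` samples. Only `vote_threshold` (lambda) is
#' calibrated; the window and pool sizes are held fixed.
#'
#' @param vote_threshold lambda in \[0, 1\].
#' @param vote_window_len causal vote window length, samples.
#' @param pool_size pooling block length, samples.
#' @param pooling_enabled apply the max-pooling stage?
#' @return A list of class `pp_params`.
#' @examples
#' pp_params(vote_threshold = 0.51, vote_window_len = 10, pool_size = 10)
#' @export
pp_params <- function(vote_threshold = 0.5, vote_window_len = 10,
                      pool_size = 10, pooling_enabled = TRUE) {
  check_prob(vote_threshold, "vote_threshold")
  check_count(vote_window_len, "vote_window_len")
  check_count(pool_size, "pool_size")
  if (!is.logical(pooling_enabled) || length(pooling_enabled) != 1L ||
      is.na(pooling_enabled)) {
    abort("`pooling_enabled` must be TRUE or FALSE")
  }
  structure(
    list(
      vote_threshold = vote_threshold,
      vote_window_len = as.integer(vote_window_len),
      pool_size = as.integer(pool_size),
      pooling_enabled = pooling_enabled
    ),
    class = "pp_params"
  )
}

# Fraction of positives in the causal window ending at each sample, with the
# pre-record past treated as zeros (alarm-free). Window sums are integers in
# doubles, so fraction > lambda is exact for grid values like 0.51.
vote_fraction <- function(x, w) {
  running_sum(x, w) / w
}

#' Causal majority vote
#'
#' `out[t] = 1` iff the fraction of ones among samples `t-w+1 .. t` strictly
#' exceeds `vote_threshold`. Samples before the start of the record count as
#' zeros, the conservative (alarm-free) choice, so the output has the same
#' length as the input.
#'
#' @param series binary series.
#' @inheritParams pp_params
#' @return A `binary_series`, same length and sample period.
#' @examples
#' majority_vote(c(1, 1, 0, 0, 1, 1), vote_threshold = 0.5, vote_window_len = 3)
#' @export
majority_vote <- function(series, vote_threshold, vote_window_len) {
  v <- as_binary_values(series)
  check_prob(vote_threshold, "vote_threshold")
  check_count(vote_window_len, "vote_window_len")
  if (vote_window_len > length(v)) {
    abort("`vote_window_len` cannot exceed the series length")
  }
  out <- as.integer(vote_fraction(v, vote_window_len) > vote_threshold)
  binary_series(out, sample_period = sample_period(series))
}

# Block maxima over disjoint blocks of k samples; trailing partial block kept.
# Vector or column-wise matrix input; returns same type.
block_max <- function(x, k) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  nb <- ceiling(n / k)
  if (is.matrix(x)) {
    out <- x[pmin(seq(1L, by = k, length.out = nb), n), , drop = FALSE]
    for (j in seq_len(k - 1L)) {
      idx <- seq(1L + j, by = k, length.out = nb)
      ok <- idx <= n
      if (!any(ok)) break
      out[ok, ] <- pmax(out[ok, , drop = FALSE], x[idx[ok], , drop = FALSE])
    }
    out
  } else {
    starts <- seq(1L, by = k, length.out = nb)
    vapply(starts, function(s) max(x[s:min(s + k - 1L, n)]), x[1] * 1)
  }
}

#' Max-pool a series onto a coarser time grid
#'
#' One output sample per disjoint block of `pool_size` inputs, equal to the
#' block maximum; a trailing partial block is pooled over the samples that
#' exist. The output sample period is the input period times `pool_size`.
#'
#' @param series binary series.
#' @inheritParams pp_params
#' @return A `binary_series` of length `ceiling(length(series) / pool_size)`.
#' @examples
#' max_pool(c(1, 0, 0, 1), pool_size = 2)
#' @export
max_pool <- function(series, pool_size) {
  v <- as_binary_values(series)
  check_count(pool_size, "pool_size")
  binary_series(
    as.integer(block_max(v, pool_size)),
    sample_period = sample_period(series) * pool_size
  )
}

#' Apply the full post-processing transform g_lambda
#'
#' Majority vote, then max-pooling when enabled. Deterministic; pointwise
#' anti-monotone in `vote_threshold` (raising lambda can only switch output
#' samples from 1 to 0).
#'
#' @param series binary series of raw model alarms.
#' @param params a [pp_params()] object.
#' @return A `binary_series` at the output resolution.
#' @examples
#' apply_g_lambda(
#'   rep(c(0, 1), 10),
#'   pp_params(vote_threshold = 0.51, vote_window_len = 4, pool_size = 2)
#' )
#' @export
apply_g_lambda <- function(series, params) {
  stopifnot(inherits(params, "pp_params"))
  out <- majority_vote(series, params$vote_threshold, params$vote_window_len)
  if (params$pooling_enabled) out <- max_pool(out, params$pool_size)
  out
}

#' Bring labels to the transform's output resolution
#'
#' Max-pools a label series exactly as [apply_g_lambda()] pools alarms: a
#' pooled block is preictal iff any sample in it is. Identity when pooling
#' is disabled. Use this before comparing calibrated alarms with labels.
#'
#' @param label binary label series at the base resolution.
#' @param params the [pp_params()] used for the alarms.
#' @return A `binary_series` at the transform's output resolution.
#' @export
pool_labels <- function(label, params) {
  if (params$pooling_enabled) max_pool(label, params$pool_size) else
    binary_series(as_binary_values(label, "label"),
                  sample_period = sample_period(label))
}
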