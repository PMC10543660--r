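#' Design the EEG bandpass filter
#'
#' Linear-phase FIR bandpass (window method, Hamming window) passing
#' `low`-`high` Hz. Applied forward and backward ([bandpass_filter()]) the
#' response is zero-phase and the attenuation doubles in dB.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param low,high band edges in Hz; the band must sit inside (0, Nyquist).
#' @param n_taps filter length; default four seconds of taps (made odd),
#'   giving a transition narrow enough to suppress sub-0.25 Hz drift by more
#'   than 40 dB per pass at typical EEG rates.
#' @return Numeric coefficient vector with attributes `sampling_rate`, `low`,
#'   `high`.
#' @export
design_bandpass <- function(sampling_rate, low = 0.5, high = 75,
                            n_taps = NULL) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be positive")
  }
  nyq <- sampling_rate / 2
  if (!(low > 0 && high > low && high < nyq)) {
    abort("band edges must satisfy 0 < low < high < Nyquist")
  }
  if (is.null(n_taps)) {
    n_taps <- as.integer(round(4 * sampling_rate)) + 1L
    if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  }
  b <- as.numeric(signal::fir1(n_taps - 1L, c(low, high) / nyq,
                               type = "pass"))
  structure(b, sampling_rate = sampling_rate, low = low, high = high)
}

# Magnitude response of an FIR filter at frequencies f (Hz).
fir_gain <- function(b, f, sampling_rate) {
  vapply(f, function(ff) {
    Mod(sum(b * exp(-2i * pi * ff * (seq_along(b) - 1) / sampling_rate)))
  }, numeric(1))
}

#' Zero-phase bandpass filtering of an EEG record
#'
#' Applies the FIR bandpass of [design_bandpass()] forward and backward
#' (`signal::filtfilt`) to every channel, removing slow drift and
#' high-frequency acquisition noise without phase distortion. Length is
#' preserved.
#'
#' @param record an [eeg_record()].
#' @inheritParams design_bandpass
#' @return The filtered [eeg_record()].
#' @export
bandpass_filter <- function(record, low = 0.5, high = 75, n_taps = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  b <- design_bandpass(record$sampling_rate, low, high, n_taps)
  filtered <- apply(record$signals, 2L, function(x) {
    signal::filtfilt(b, 1, x)
  })
  colnames(filtered) <- colnames(record$signals)
  eeg_record(filtered, record$sampling_rate, record$seizure_onsets)
}

# --- individual features -------------------------------------------------

# One-sided tapered periodogram: frequencies (Hz) and power.
periodogram <- function(x, sampling_rate) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  p <- Mod(fft((x - mean(x)) * w))^2
  half <- seq_len(floor(n / 2) + 1L)
  list(freq = (half - 1) * sampling_rate / n, power = p[half])
}

#' Relative band powers
#'
#' Fraction of spectral energy in each of the five classical EEG bands —
#' delta (0.4, 4\], theta (4, 8\], alpha (8, 13\], beta (13, 30\] and gamma
#' (30, 48\] Hz — relative to the total power in the analysis band
#' (`total_band`). The analysis band spans from the delta band's lower edge
#' to the bandpass filter's upper edge, so that every band is contained in
#' the denominator: fractions are non-negative and the five sum to at most 1.
#'
#' @param x numeric signal window.
#' @param sampling_rate Hz.
#' @param total_band two-element vector, denominator band in Hz.
#' @return Named numeric vector `delta`, `theta`, `alpha`, `beta`, `gamma`.
#' @export
band_power_fractions <- function(x, sampling_rate,
                                 total_band = c(0.4, 75)) {
  bands <- list(delta = c(0.4, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30), gamma = c(30, 48))
  pg <- periodogram(x, sampling_rate)
  denom_idx <- pg$freq > total_band[1] & pg$freq <= total_band[2]
  denom <- sum(pg$power[denom_idx])
  if (denom <= 0) {
    return(vapply(bands, function(b) 0, numeric(1)))
  }
  vapply(bands, function(b) {
    sum(pg$power[pg$freq > b[1] & pg$freq <= b[2]]) / denom
  }, numeric(1))
}

#' Spectral entropy
#'
#' Shannon entropy of the normalised power spectrum inside the analysis
#' band, divided by the log of the number of bins, so the value lies in
#' \[0, 1\]: 0 for a pure tone, 1 for a flat spectrum.
#'
#' @inheritParams band_power_fractions
#' @return A value in \[0, 1\].
#' @export
spectral_entropy <- function(x, sampling_rate, total_band = c(0.5, 75)) {
  pg <- periodogram(x, sampling_rate)
  keep <- pg$freq > total_band[1] & pg$freq <= total_band[2]
  p <- pg$power[keep]
  tot <- sum(p)
  if (tot <= 0 || sum(keep) < 2L) return(0)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(sum(keep))
}

#' Hjorth mobility and complexity
#'
#' Classical time-domain EEG descriptors in the continuous-time convention:
#' mobility is the RMS angular frequency
#' `sqrt(var(dx/dt) / var(x))` (so a pure sinusoid at f Hz has mobility
#' close to `2*pi*f` rad/s), and complexity is the mobility of the
#' derivative divided by the mobility of the signal (1 for a sinusoid,
#' larger for broader spectra). Derivatives are first differences scaled by
#' the sampling rate.
#'
#' @inheritParams band_power_fractions
#' @return Named numeric vector `mobility` (rad/s) and `complexity`
#'   (dimensionless); zeros for a constant window.
#' @export
hjorth_params <- function(x, sampling_rate) {
  v0 <- var(x)
  if (v0 == 0) return(c(mobility = 0, complexity = 0))
  d1 <- diff(x) * sampling_rate
  d2 <- diff(d1) * sampling_rate
  mob <- sqrt(var(d1) / v0)
  mob_d <- if (var(d1) > 0) sqrt(var(d2) / var(d1)) else 0
  c(mobility = mob, complexity = if (mob > 0) mob_d / mob else 0)
}

#' Detrended fluctuation analysis exponent
#'
#' Scaling exponent of the root-mean-square fluctuation of the integrated,
#' linearly detrended signal across box sizes (first-order DFA). Around 0.5
#' for white noise, 1 for 1/f noise, 1.5 for Brownian motion. Box sizes are
#' log-spaced from `min_box` to a quarter of the window.
#'
#' @param x numeric signal window.
#' @param min_box smallest box size in samples.
#' @param n_sizes number of box sizes.
#' @return The DFA exponent; 0 for a constant window.
#' @export
dfa_exponent <- function(x, min_box = 4L, n_sizes = 10L) {
  n <- length(x)
  if (var(x) == 0 || n < 4L * min_box) return(0)
  prof <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(min_box), log(n / 4), length.out =
                                  n_sizes))))
  fluct <- vapply(sizes, function(s) {
    nb <- floor(n / s)
    m <- matrix(prof[seq_len(nb * s)], nrow = s)
    t_c <- seq_len(s) - (s + 1) / 2
    slope <- colSums(m * t_c) / sum(t_c^2)
    resid <- m - outer(t_c, slope) -
      matrix(colMeans(m), nrow = s, ncol = nb, byrow = TRUE)
    sqrt(mean(resid^2))
  }, numeric(1))
  ok <- fluct > 0
  if (sum(ok) < 2L) return(0)
  unname(coef(stats::lm(log(fluct[ok]) ~ log(sizes[ok])))[2])
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of the signal graph from the scaling of
#' mean curve length with the time delay k (k = 1 .. `k_max`). Close to 2
#' for white noise and 1 for a smooth curve.
#'
#' @param x numeric signal window.
#' @param k_max largest delay.
#' @return The fractal dimension; 0 for a constant window.
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  n <- length(x)
  if (var(x) == 0 || n <= k_max + 1L) return(0)
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      (sum(abs(diff(x[idx]))) * (n - 1)) / (floor((n - m) / k) * k)
    }, numeric(1))
    mean(lm_k, na.rm = TRUE) / k
  }, numeric(1))
  ok <- lk > 0
  if (sum(ok) < 2L) return(0)
  k <- seq_len(k_max)
  -unname(coef(stats::lm(log(lk[ok]) ~ log(k[ok])))[2])
}

#' Extract windowed EEG features
#'
#' Slides a `window_len`-second window with `step`-second hops over every
#' channel of a (filtered) record and computes the ten features: five
#' relative band powers, spectral entropy, DFA exponent, Hjorth mobility and
#' complexity, and Higuchi fractal dimension. Deterministic; scale-free
#' features are invariant to amplitude scaling. A zero-variance window gets
#' all-zero features and `zero_variance = TRUE`.
#'
#' @param record an [eeg_record()], ideally already through
#'   [bandpass_filter()].
#' @param window_len,step window length and hop in seconds.
#' @return A tibble with one row per (window, channel):
#'   `window_start` (s), `channel`, the ten feature columns, and
#'   `zero_variance`. The number of windows is
#'   `floor((duration - window_len) / step) + 1`.
#' @export
extract_features <- function(record, window_len = 6, step = 3) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate
  if (record$duration < window_len) {
    abort("record shorter than one analysis window")
  }
  n_win <- floor((record$duration - window_len) / step) + 1L
  starts <- (seq_len(n_win) - 1L) * step
  wl <- round(window_len * fs)
  channels <- colnames(record$signals)
  rows <- vector("list", n_win * length(channels))
  r <- 0L
  for (wi in seq_len(n_win)) {
    i0 <- round(starts[wi] * fs)
    idx <- (i0 + 1L):(i0 + wl)
    for (ch in seq_along(channels)) {
      x <- record$signals[idx, ch]
      r <- r + 1L
      if (var(x) == 0) {
        rows[[r]] <- tibble(
          window_start = starts[wi], channel = channels[ch],
          delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0,
          spectral_entropy = 0, dfa = 0, hjorth_mobility = 0,
          hjorth_complexity = 0, higuchi_fd = 0, zero_variance = TRUE
        )
      } else {
        bp <- band_power_fractions(x, fs)
        hj <- hjorth_params(x, fs)
        rows[[r]] <- tibble(
          window_start = starts[wi], channel = channels[ch],
          delta = bp[["delta"]], theta = bp[["theta"]],
          alpha = bp[["alpha"]], beta = bp[["beta"]], gamma = bp[["gamma"]],
          spectral_entropy = spectral_entropy(x, fs),
          dfa = dfa_exponent(x),
          hjorth_mobility = hj[["mobility"]],
          hjorth_complexity = hj[["complexity"]],
          higuchi_fd = higuchi_fd(x),
          zero_variance = FALSE
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Preictal labels for feature windows
#'
#' A window is preictal (label 1) iff its start time lies within
#' \[onset - 60 min, onset - 30 s) of any seizure onset. The 30 s exclusion
#' keeps the task a prediction problem rather than detection; ictal and
#' post-ictal time are labelled 0.
#'
#' @param duration record duration in seconds.
#' @param onsets seizure onset times in seconds (sorted or not).
#' @param window_starts window start times in seconds.
#' @param horizon preictal horizon before onset, seconds (default 60 min).
#' @param exclusion pre-onset exclusion, seconds (default 30 s).
#' @return A `binary_series` over the windows (sample period = the window
#'   hop when starts are regular, else 1).
#' @export
label_preictal <- function(duration, onsets, window_starts,
                           horizon = 3600, exclusion = 30) {
  onsets <- as.numeric(onsets)
  if (any(onsets < 0 | onsets > duration)) {
    warn("seizure onsets outside the record were clipped")
    onsets <- pmin(pmax(onsets, 0), duration)
  }
  onsets <- sort(onsets)
  lab <- vapply(window_starts, function(s) {
    any(s >= onsets - horizon & s < onsets - exclusion)
  }, logical(1))
  sp <- if (length(window_starts) > 1L) {
    d <- diff(window_starts)
    if (all(abs(d - d[1]) < 1e-9) && d[1] > 0) d[1] else 1
  } else 1
  binary_series(as.integer(lab), sample_period = sp)
}
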