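# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals they are checked against.

bf_majority_vote <- function(x, lambda, w) {
  padded <- c(rep(0L, w - 1L), x)
  vapply(seq_along(x), function(t) {
    as.integer(mean(padded[t:(t + w - 1L)]) > lambda)
  }, integer(1))
}

bf_max_pool <- function(x, k) {
  starts <- seq(1L, length(x), by = k)
  vapply(starts, function(s) max(x[s:min(s + k - 1L, length(x))]), integer(1))
}

bf_event_count <- function(x) {
  sum(diff(c(0L, x)) == 1L)
}

bf_bonferroni <- function(lambda, p, delta) {
  keep <- logical(length(p))
  for (i in seq_along(p)) keep[i] <- p[i] <= delta / length(p)
  sort(lambda[keep])
}

bf_fst <- function(lambda, p, delta) {
  ord <- order(lambda, decreasing = TRUE)
  out <- numeric(0)
  for (i in ord) {
    if (p[i] > delta) break
    out <- c(out, lambda[i])
  }
  sort(out)
}

# Exact one-sided binomial p-value for Bernoulli per-unit risks under the
# null "true mean risk > alpha": P(Binom(n, alpha) <= observed successes).
bf_binom_pvalue <- function(risks, alpha) {
  stopifnot(all(risks %in% c(0, 1)))
  stats::pbinom(sum(risks), length(risks), alpha)
}

# Small synthetic record set with known structure for record evaluation.
make_record_set <- function(n_records, len, seed, flip = 0.1, period = 60) {
  lapply(seq_len(n_records), function(i) {
    set.seed(seed + i)
    pts <- as.integer(runif(len) < 0.01)
    lab <- as.integer(lttcal::widen_to_windows(pmax(pts, 0L), 10))
    prd <- as.integer(ifelse(runif(len) < flip, 1L - lab, lab))
    list(
      label = lttcal::binary_series(lab, sample_period = period),
      prediction = lttcal::binary_series(prd, sample_period = period)
    )
  })
}
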