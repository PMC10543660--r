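---
title: "Risk-controlling calibration of binary alarm models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-controlling calibration of binary alarm models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lttcal)
```

## The problem

A seizure-prediction system watches a stream of model outputs and raises
alarms. Clinically, the cost structure is asymmetric: a missed seizure is
bad, but a system that cries wolf several times per hour is unusable, and
most published predictors fail on exactly that axis. `lttcal` addresses the
false-alarm side without touching the model: it treats the predictor as a
black box and calibrates a post-processing transform so that the *false
alarm rate* — false positives per unit of non-preictal time — is controlled
at a user-chosen level with an explicit statistical guarantee.

## The method

### The transform

Raw binary outputs $Y[t]$ pass through a transform $g_\lambda$ with two
temporal-aggregation stages:

1. **Causal majority vote.** With a window of $w$ samples,
   $Y_{MV}[t] = \mathbb{1}\!\left[\tfrac{1}{w}\sum_{i=0}^{w-1} Y[t-i] >
   \lambda\right]$. Samples before the record start count as zeros — the
   conservative, alarm-free convention — so output length equals input
   length. The inequality is strict, so $\lambda = 1$ silences everything;
   for $w = 10$, thresholds in $[0.5, 0.51)$ are equivalent (window
   fractions are multiples of $1/10$).
2. **Max-pooling** (optional). The vote output is decimated onto a coarser
   grid by taking maxima over *disjoint* blocks of $k$ samples; a trailing
   partial block is pooled over the samples that exist rather than dropped.
   The output sample period is $k$ times the input period.

Only $\lambda$ is calibrated; $w$ and $k$ stay fixed. Raising $\lambda$ can
only turn output ones into zeros, so every positive-count metric — in
particular the false alarm rate — is non-increasing in $\lambda$. This
anti-monotonicity is what the selection procedure below exploits.

### Learn-Then-Test calibration

For each candidate $\lambda$ on a grid $\Lambda$, the calibration set of $n$
units (series or records) yields per-unit risks
$R_i(\lambda)$ and the one-sided hypothesis
$H_\lambda:\ \mathbb{E}[R(\lambda)] > \alpha$. A central-limit-theorem
p-value is
$p_\lambda = \Phi\!\big((\bar R - \alpha)\sqrt{n}/s\big)$, with $s$ the
sample standard deviation ($n-1$ divisor). Rejecting a family of these
nulls with a familywise-error-rate (FWER) controlling procedure at level
$\delta$ yields a validated set $\hat\Lambda$ such that every
$\hat\lambda \in \hat\Lambda$ satisfies the $(\alpha,\delta)$
risk-controlling property
$\mathbb{P}\big[\mathbb{E}[R(\hat\lambda)] \le \alpha\big] \ge 1-\delta$,
the probability being over the draw of the calibration set.

Two corrections are implemented:

* **Bonferroni** — reject where $p_\lambda \le \delta/|\Lambda|$; valid
  under arbitrary dependence but conservative.
* **Fixed-sequence testing (FST)** — test $\lambda$ in decreasing order
  (strictest alarm control first), each at full level $\delta$, stopping at
  the first failure. Valid here because the risk, and hence the p-value, is
  monotone in $\lambda$. FST typically validates a strictly larger set, so
  its chosen threshold is never larger than Bonferroni's.

Within $\hat\Lambda$ the package picks the *minimum* validated $\lambda$:
by monotonicity it maximises sensitivity among validated choices. A hook
(`select_fn`) lets callers optimise any other secondary metric instead. An
empty $\hat\Lambda$ is a legitimate, explicit outcome — "this risk level is
not attainable with this model and calibration set" — reported as
`chosen_lambda = NA`, and by the CLI as a distinct exit status, never as an
error mid-computation.

### Risk estimators

Two per-unit estimators are exposed, and the calibrator is told which to
use:

* `sample_fraction` — alarms on non-preictal samples divided by
  non-preictal samples, the natural per-step risk for synthetic series;
* `event_rate` — merged alarm events (maximal runs of ones) with no overlap
  with preictal time, per non-preictal *hour*, the clinical definition used
  for real recordings. Alarms during ictal or "nearly preictal" time count
  as false, a deliberately conservative convention.

## The synthetic generator

The generator emulates the *structure* of seizure-prediction data, nothing
more: sparse Bernoulli event points at per-sample rate $p$, each widened
forward into a window of $w_\ell$ ones (overlaps merge), and a noisy-oracle
predictor that flips each ground-truth sample independently with
probability $p_{flip}$. Defaults are $p = 0.005$, $w_\ell = 8$,
$p_{flip} = 0.05$: the sparse regime $p\,w_\ell = 0.04 \ll 1$ with an
oracle that is good but visibly imperfect, which is the interesting
operating point for calibration — these two rates are package choices, and
both are configurable. Each series draws from its own substream of the
master seed, so enlarging a dataset never reshuffles existing series.

What the generator deliberately does **not** model: temporally correlated
model errors, drift or nonstationarity, class-dependent error rates, and
the non-i.i.d. structure of real record splits. Passing the validation
study therefore demonstrates that the calibration machinery delivers its
finite-sample guarantee under i.i.d. conditions; it does not certify any
particular EEG model, and on real data with few records the CLT p-values
are only asymptotically valid.

## The validation study

`run_synthetic_study()` reproduces the full protocol: per experiment,
generate a dataset, split it 50/50 by series into calibration and test
halves (the split ratio is a package choice, recorded in the config),
calibrate at each $\alpha$ with each correction and pooling variant, and
measure the realised test false alarm rate and pointwise accuracy at the
chosen $\lambda$ (labels max-pooled to the output resolution when pooling
is on). Cells report mean ± sd over experiments, the modal chosen
$\lambda$, the count of empty validated sets (excluded from risk means,
never silently dropped), and the count of experiments whose realised risk
exceeded $\alpha$ — which the $(\alpha,\delta)$ guarantee bounds by roughly
$\delta$.

The reference protocol is 200 experiments of 10,000 series of length 1,000
per $\alpha \in \{0.001, 0.005, 0.01, 0.05, 0.1, 1\}$ (the vacuous
$\alpha = 1$ row is retained for protocol fidelity), with vote window 10
and pooling 10. The package's tests and acceptance script run the same
protocol at desk scale — 20 experiments of 2,000 series for the risk-bound
checks, 50 paired experiments of 400 series for the pooling comparison,
and 200 replicates of 120 calibration series (against one large held-out
risk curve) for the coverage property — sizes chosen to exercise every
claim comfortably on a laptop. When comparing pooled and unpooled variants
the rates are first put on the shared base-sample clock
(`test_far_per_step`), since a pooled sample spans $k$ base steps.

## Numerical choices and edge cases

* **Degenerate p-value** ($s = 0$): the limit of the z-statistic is used —
  $p = 0$ if $\bar R \le \alpha$, else $1$. This makes an all-zero risk
  vector (e.g. a silenced transform at $\lambda = 1$) decisively
  controlled, as it should be.
* **Vote smoothing spills.** Even a perfect predictor raises alarms for up
  to a few samples after each label window: just past a window of eight
  ones, a ten-sample vote window still holds fraction $0.8, 0.7, \dots$.
  Consequently the minimum validated $\lambda$ generally has small positive
  risk, and the empirical risk is exactly zero only for $\lambda \ge 0.9$
  (no ten-sample window ending on a non-preictal sample can exceed $9/10$).
  This is a property of causal smoothing, not an implementation artefact.
* **CLT versus exact binomial.** For Bernoulli-like per-unit risks the CLT
  p-value agrees with the exact binomial tail when the evidence is
  decisive, but near the boundary it is *anti-conservative* (the Wald-style
  studentisation uses the sample standard deviation, the exact tail the
  null rate); at $n = 100$ the discrepancy can reach a few percentage
  points for very sparse nonzero risks. This is an inherited property of
  CLT p-values; users needing finite-sample-exact control at small $n$
  should enlarge the calibration set.
* **Grid default** $\{0.51, 0.52, \dots, 0.99\}$: sub-majority thresholds
  are degenerate for a majority vote, and the 0.01 step resolves every
  distinct behaviour of a window-10 vote with headroom for other window
  sizes.
* **$\delta$ default 0.1**: a conventional FWER level for calibration;
  fully configurable.
* **Published-table replay.** `aggregate_records()` accepts a transcribed
  integer `reduction_pct` column and aggregates it as printed; when absent,
  reductions are recomputed from the rates and rounded to the nearest
  percent. Totals pool false positives over summed exposure when counts are
  available and otherwise fall back to duration-weighted means of the
  per-record rates. Pooled sensitivities are reported unrounded.

## The EEG front end

For real recordings, `read_edf()` ingests 16-bit EDF (a minimal reader
written for this package, with a companion writer used to build synthetic
fixtures), `bandpass_filter()` applies a zero-phase FIR bandpass
(Hamming-window design, default 0.5–75 Hz, four seconds of taps — about
40 dB suppression of 0.1 Hz drift per pass at typical EEG rates), and
`extract_features()` computes, per 6 s window with 3 s hops and per
channel: five relative band powers (delta 0.4–4, theta 4–8, alpha 8–13,
beta 13–30, gamma 30–48 Hz), spectral entropy, a first-order DFA exponent,
Hjorth mobility and complexity, and the Higuchi fractal dimension.

Conventions worth stating: band fractions are normalised by the power in
0.4–75 Hz — the span from the delta band's lower edge to the filter's upper
edge — so the five fractions are proper and sum to at most 1; spectral
entropy is Shannon entropy of the normalised periodogram divided by the log
bin count, giving $[0,1]$; Hjorth parameters follow the classical
definitions (mobility $=\sqrt{\mathrm{var}(\dot x)/\mathrm{var}(x)}$, so a
pure sinusoid at $f$ Hz has mobility $2\pi f$; complexity is the mobility
ratio, 1 for a sinusoid); DFA uses first-order detrending over
log-spaced boxes from 4 samples to a quarter window; Higuchi uses
$k_{max} = 10$. Zero-variance windows get all-zero features plus a
`zero_variance` flag rather than NaNs. Preictal labels mark window starts
in $[\text{onset} - 60\,\text{min}, \text{onset} - 30\,\text{s})$; the 30 s
exclusion keeps the task prediction rather than detection.

## A worked example

```{r example}
params <- synth_params(event_rate = 0.005, label_window_len = 8,
                       flip_prob = 0.05, series_len = 1000,
                       n_series = 400, seed = 42)
data <- simulate_alarm_dataset(params)
cal <- data[1:200, ]
test <- data[201:400, ]

fit <- calibrate_alarms(cal, alpha = 0.05, delta = 0.1)
glance(fit)

# realised risk on held-out series at the chosen threshold
pp <- fit$postprocess
pp$vote_threshold <- fit$chosen_lambda
mean(vapply(seq_len(nrow(test)), function(i) {
  empirical_unit_risk(apply_g_lambda(test$prediction[[i]], pp),
                      pool_labels(test$label[[i]], pp))
}, numeric(1)))
```

## Limitations

The guarantee is on the *expected* risk over the calibration draw, at the
stated $\alpha$ and $\delta$; it is not a per-record worst-case bound. It
requires i.i.d. calibration units — record-level splits of small clinical
datasets violate this, and the package's conservative correction choices
mitigate but cannot repair that. The CLT p-values are asymptotic, with the
boundary behaviour described above. And calibration can only trade
sensitivity for specificity within what the base model offers: a weak
predictor controlled to a strict false alarm rate will simply miss more
events.
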