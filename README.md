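# lttcal

Statistically controlled false alarm rates for binary alarm models on time
series — built for epileptic-seizure prediction, usable for any black-box
predictor that emits a 0/1 alarm stream.

Seizure predictors are judged on two clinical axes: event-based
sensitivity (did at least one alarm fall in the 60 min–30 s preictal window
before each seizure?) and the false alarm rate (false alarm events per
non-preictal hour). Most models fail clinically on the second axis, and
retraining the model to fix it couples two hard problems. `lttcal`
decouples them: it post-processes any model's outputs with a
λ-parameterised transform and calibrates λ with Learn-Then-Test (LTT) risk
control, so the false alarm rate is provably bounded without touching the
model.

## The method in brief

Raw alarms pass through `g_λ`: a causal majority vote over a window of `w`
samples (positive iff the window's positive fraction strictly exceeds λ),
then optional max-pooling over disjoint blocks of `k` samples onto a
coarser clock. Raising λ only removes alarms, so the false alarm rate
`R(λ)` is non-increasing in λ.

Calibration turns each candidate λ into the hypothesis
`H_λ : E[R(λ)] > α`, computes a one-sided CLT p-value
`p_λ = Φ((R̄ − α)√n / s)` from the per-unit risks of `n` calibration units,
and applies a familywise-error-controlling correction at level δ —
Bonferroni, or fixed-sequence testing (FST) descending in λ, which is
valid here by monotonicity and less conservative. Every λ in the validated
set `Λ̂` then satisfies the (α, δ) risk-controlling property

```
P[ E[R(λ̂)] ≤ α ] ≥ 1 − δ
```

over the draw of the calibration set; the package picks the smallest
validated λ (best sensitivity), and an empty `Λ̂` is reported as an explicit
"not controllable at this α", never an error. A synthetic generator (sparse
event windows + a noisy oracle that flips truth with probability
`p_flip`), a full validation-study driver, clinical metrics, and an EEG
front end (EDF ingestion, FIR bandpass, ten windowed spectral/nonlinear
features, preictal labelling) round out the toolkit.

## Worked example

Calibrate a noisy oracle on 200 simulated series and check the realised
risk on 200 held-out series:

```r
library(lttcal)

params <- synth_params(event_rate = 0.005, label_window_len = 8,
                       flip_prob = 0.05, series_len = 1000,
                       n_series = 400, seed = 42)
data <- simulate_alarm_dataset(params)

fit <- calibrate_alarms(data[1:200, ], alpha = 0.05, delta = 0.1)
fit
#> <ltt_calibration> alpha = 0.05, delta = 0.1, fst over 49 lambdas, n = 200
#> validated set: 49 lambdas in [0.51, 0.99]; chosen lambda = 0.51

test <- data[201:400, ]
pp <- fit$postprocess
pp$vote_threshold <- fit$chosen_lambda
mean(vapply(seq_len(nrow(test)), function(i) {
  empirical_unit_risk(apply_g_lambda(test$prediction[[i]], pp),
                      pool_labels(test$label[[i]], pp))
}, numeric(1)))
#> [1] 0.01990753
```

Every λ on the grid was validated at α = 0.05, the least restrictive
(λ = 0.51) was chosen, and the held-out false alarm fraction (~0.02 per
pooled sample) sits comfortably under the requested bound of 0.05.
`tidy(fit)` gives the per-λ risk/p-value table and `autoplot(fit)` plots
it.

The clinical aggregation works the same way on record-level tables. The
package ships the per-record test results of a published deep-learning
seizure predictor on the Siena scalp EEG corpus, before and after
calibration:

```r
aggregate_records(example_record_table())
#> <alarm_report> 7 records, 9 seizures
#> sensitivity: 100% raw -> 56% calibrated
#> false alarm rate: 5.60 -> 0.45 per hour (duration-weighted totals)
#> mean reduction: 93.51% (duration), 92.43% (unweighted)
```

Calibration eliminated false alarms entirely in five of seven records
(e.g. 4.8 → 0 per hour) at the cost of missing four of nine seizures —
the sensitivity/specificity trade the guarantee makes explicit.

A thin CLI wraps the same functions for shell use
(`inst/cli/lttcal.R`): subcommands `generate`, `calibrate`, `evaluate`,
`study`, `features`. See `?cli_main`.

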