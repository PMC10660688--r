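# rarliver

Rest–activity rhythms from wrist actigraphy, and their survey-weighted
associations with liver-function biomarkers.

## What this package is for

The 24-h rest–activity rhythm (RAR) is a behavioural proxy for circadian
function that can be measured objectively at population scale with a wrist
accelerometer. Epidemiologists studying whether weakened circadian rhythms
accompany impaired liver function need a chain of tools: quality filtering
of minute-epoch actigraphy, parametric and non-parametric rhythm metrics,
clinically defined abnormality scoring of liver biomarkers (ALT, AST, ALP,
GGT, albumin, bilirubin), and survey-weighted regression connecting the
two. `rarliver` implements that full chain as composable, pipe-friendly
functions, plus a synthetic-data generator with known ground truth so every
stage can be validated by parameter and odds-ratio recovery.

## The models at the core

**Sigmoidally-transformed extended cosine model.** A participant's 5-minute
binned activity \(y(t)\) is fit by bounded least squares to

    y(t) = min + A · F(cos(2π (t − φ) / 24))
    F(c) = exp(β (c − α)) / (1 + exp(β (c − α)))

where `min` is the nadir level, `A` the (asymptotic) amplitude, `φ` the
acrophase (clock time of peak activity), `α` the width and `β` the
steepness of the anti-logistic link — large `β` approaches a square wave.
Derived quantities: amplitude (fitted-curve peak minus nadir), mesor
(`min + amplitude/2`), amplitude:mesor ratio, and the **pseudo-F
statistic**

    F = [(RSS₀ − RSS) / (k − 1)] / [RSS / (n − k)],   k = 5,

the goodness-of-fit ratio against a flat-mean model; higher F means more
robust overall rhythmicity.

**Non-parametric metrics.** Interdaily stability
`IS = (hour-of-day variance) / (total variance)` (1 for a perfectly
repeating day, ≈ 1/d for d days of noise), intradaily variability
`IV = (mean squared successive difference) / variance` of the hourly
series (≈ 2 for white noise), and the **L5 midpoint** — the centre of the
least-active 5 consecutive hours, used with circular statistics to flag
probable night-shift work.

**Scoring and models.** All seven RAR parameters are grouped into
survey-weighted quintiles; composite scores count least-healthy quintiles
(impaired rhythmicity, 0–3+) and abnormal biomarkers (0–3+, sex-specific
clinical cut-offs with strict inequalities). Associations are estimated by
weighted logistic regression (abnormality flags), weighted linear
regression on log levels, and weighted proportional-odds regression (the
composite), all with HC0 sandwich standard errors, Wald trend tests across
quintiles, design-effect-corrected likelihood-ratio interaction tests,
stratified runs and sensitivity variants.

## Worked example

Simulate a week of minute-epoch actigraphy from a known rhythm, then derive
every RAR parameter:

```r
library(rarliver)

truth  <- rhythm_truth(minimum = 10, amplitude = 100, acrophase = 14,
                       alpha = 0, beta = 8, noise_sd = 15, n_days = 7)
epochs <- simulate_actigraphy(truth, participant_id = "P00001", seed = 11)
derive_rhythms(epochs)
#>   pseudo_F amplitude  mesor amp_mesor_ratio acrophase    IS    IV l5_midpoint
#> 1 26009.39    97.021 61.133           1.587    14.017 0.999 0.131        1.75
```

The fitted acrophase (14.02 h) and amplitude (97.0; the truth curve's
peak-to-nadir range is 99.9) recover the generating rhythm; IS near 1 and
a small IV reflect the highly regular simulated days; the L5 midpoint sits
opposite the activity peak, inside the simulated sleep window.

Simulate a 4000-participant cohort in which the lowest quintile of overall
rhythmicity doubles the odds of abnormal GGT, then estimate that odds
ratio back with the survey-weighted engine:

```r
cfg    <- cohort_config(4000, true_log_odds = list(ggt = c(log(2), 0, 0, 0, 0)),
                        seed = 7)
cohort <- simulate_cohort(cfg)
panel  <- simulate_biomarkers(cohort, cfg, seed = 8)
d <- dplyr::bind_cols(cohort, panel[, setdiff(names(panel), "participant_id")])
d$quintile_pseudo_F <- d$exposure_quintile

fit_weighted_logistic(d, "abnormal_ggt", "quintile_pseudo_F",
                      covariates = c("age", "gender"), reference = 5)
#>   level   n weighted_pct estimate conf.low conf.high p.value
#> 1     5 757        9.222    1.000       NA        NA      NA
#> 2     1 789       20.294    2.521    1.796     3.537   0.000
#> 3     2 793       11.975    1.338    0.919     1.949   0.129
#> 4     3 786        9.742    1.064    0.714     1.584   0.762
#> 5     4 756       10.164    1.114    0.761     1.629   0.579
```

Q1 vs Q5 recovers an OR near the planted 2 (2.52 with a 95% CI of
1.80–3.54 in this single replicate; across 500 replicates the mean log-OR
is within 0.05 of log 2), the other quintiles sit near the null, and the
Wald trend p-value for this cohort is 7.5e-08. `run_full_analysis()`
executes the same fit for every RAR parameter × biomarker × adjustment
model and returns one tidy results table; `autoplot()` draws the forest
plot of any single fit.

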