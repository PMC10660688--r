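---
title: "Rest–activity rhythm metrics and weighted liver-function associations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest–activity rhythm metrics and weighted liver-function associations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarliver)
```

This vignette is the package's own account of the science it implements:
the models, the quality-filtering rules, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one convention was defensible.

## From epochs to analysable series

The raw unit is one minute of wrist actigraphy: a participant identifier,
a day index, a minute of day (0–1439), a non-negative activity summary
(e.g. a MIMS triaxial value) and a state label in `wake`, `sleep`,
`nonwear`, `unknown`. Two dialects are read — a plain CSV with exactly
those columns, and NHANES-style SAS-transport minute files, whose state
codes (1 wake, 2 sleep, 3 non-wear) and negative missing-value sentinels
are normalized on ingestion. Unrecognized state codes become `unknown`;
duplicated (participant, day, minute) keys are an error, because silently
averaging duplicates would hide upstream corruption.

Two filters gate everything downstream:

* a **valid day** has at least 1200 minutes (20 h) labelled wake or
  sleep — non-wear, unknown and absent minutes do not count;
* a **retained participant** has at least 4 valid days.

Both thresholds are inclusive (1200 minutes is valid, 1199 is not; 4 days
retained, 3 dropped) and are asserted by the aggregation functions
themselves: series that violate them never reach the fitting stage.
Days are calendar-indexed from the device's first midnight, so partial
first/last days are screened by the 1200-minute rule with no special
casing.

Valid-day epochs are averaged into 288 five-minute bins per day. Bins are
anchored at midnight and half-open (`[5b, 5b + 5)` minutes); only wake and
sleep minutes with an activity value contribute, and a bin with no usable
minute is missing rather than zero — zero-filling would deflate the
estimated mesor. Bin values are timestamped at the bin **centre**
(`5b + 2.5` minutes): labelling at the bin start shifts every bin's
effective time by half a bin and biases the fitted acrophase by the same
amount, which is visible in noiseless recovery experiments.

Two behavioural covariates come from the same filtered epochs: sleep
duration (mean over valid days of minutes labelled sleep, min/day) and
total activity (mean over valid days of the day's summed activity across
wake and sleep minutes — a daily total, averaged, which matches the
magnitude conventionally reported for daily activity counts).

## The sigmoidally-transformed extended cosine model

The mean curve is

$$y(t) = \mathrm{min} + A \cdot F\!\big(\cos(2\pi (t - \varphi)/24)\big),
\qquad F(c) = \frac{e^{\beta (c - \alpha)}}{1 + e^{\beta (c - \alpha)}},$$

with nadir level $\mathrm{min}$ (activity units, bounded below at 0),
asymptotic amplitude $A \ge 0$, acrophase $\varphi$ (clock hours), width
$\alpha \in (-1, 1)$ and steepness $\beta > 0$. Small $\beta$ gives a
near-sinusoid; large $\beta$ approaches a square wave, which is the shape
real wake/rest cycles often take. The model assumes one dominant 24-h
component with a stable waveform across days; participants with severely
fragmented or non-24-h rhythms violate that assumption, and for them the
pseudo-F statistic (below) is exactly the quantity that flags the poor
fit.

**Reported parameters.** The curve's peak-to-nadir range — not the raw
parameter $A$ — is reported as the amplitude, and the clock time of the
curve's maximum as the acrophase, both read off a 1-minute grid of the
fitted curve (earliest time on ties). The distinction matters: the
anti-logistic link never fully saturates, so the attained range is
$A\,[F(1) - F(-1)]$, up to tens of percent below $A$ for shallow $\beta$.
The mesor is defined as $\mathrm{min} + \mathrm{amplitude}/2$ and the
amplitude:mesor ratio as their quotient; the identity holds exactly for
every emitted fit. The pseudo-F statistic,

$$F = \frac{(\mathrm{RSS}_0 - \mathrm{RSS})/(k - 1)}{\mathrm{RSS}/(n - k)},
\qquad k = 5,$$

compares the fit against the flat-mean model ($\mathrm{RSS}_0$). The
degrees-of-freedom convention (4 numerator, $n - 5$ denominator) is fixed
and documented; downstream use is quintile-based, so any monotone
variant would produce identical quintile assignments. A constant series
gives $F = 0$ by convention (no improvement over the mean).

**Optimization.** The objective is multimodal in the acrophase, so the
bounded Levenberg–Marquardt fit is multi-started from a grid of acrophase
values every 2 h crossed with $\alpha \in \{-0.6, 0, 0.6\}$ (36 starts),
keeping the best-RSS solution. $(\mathrm{min}, A)$ start at the series'
5th percentile and 90% central spread; $\beta$ starts at 2 and is bounded
to $[0.1, 50]$ to keep the optimizer away from degenerate step functions;
$\alpha$ is bounded to $[-0.99, 0.99]$. Convergence tolerances are tight
(`ftol = 1e-12`) because near-square waveforms create long flat valleys
in $(A, \alpha, \beta)$; with looser tolerances the optimizer reports
convergence some tenths of a percent away from the optimum. Missing bins
are simply omitted from the least-squares sum; a fit requires at least
576 non-missing bins (two days' worth) by default. Noiseless series are
recovered with zero residual sum of squares, and time-shift and
positive-scale equivariance hold to optimizer tolerance.

## Non-parametric metrics

IS and IV are computed on hourly means built from the 5-minute bins —
60-minute binning is the dominant convention for these statistics, and the
bin width is an explicit argument of the pipeline rather than a hidden
constant. With $x_i$ the concatenated valid-day hourly series, $\bar x_h$
the mean over days for hour-of-day $h$ and $\bar x$ the grand mean:

$$\mathrm{IS} = \frac{\frac{1}{p}\sum_h (\bar x_h - \bar x)^2}
                   {\frac{1}{N}\sum_i (x_i - \bar x)^2},
\qquad
\mathrm{IV} = \frac{\frac{1}{n_\mathrm{pairs}}\sum (x_i - x_{i-1})^2}
                   {\frac{1}{N}\sum_i (x_i - \bar x)^2}.$$

$p$ is the number of hour-of-day slots actually observed (24 when data are
complete, recovering the textbook form). Successive differences are taken
only between truly adjacent hour slots — never across a gap from a missing
hour or a dropped day — because differencing across gaps manufactures
spurious IV. A perfectly repeating day gives IS = 1; $d$ days of
independent noise give IS ≈ $1/d$ and IV ≈ 2; an alternating 0/1 series
gives IV = 4 exactly; a constant series leaves both undefined (missing,
with a warning). Both metrics are invariant to positive rescaling of
activity and to relabelling the day origin.

The L5 midpoint scans the across-days average 24-h profile by default
(per-day profiles are noisier and can straddle different troughs; a
per-day variant with circular averaging of daily midpoints is available as
an option) with a 5-h
window advancing in 5-minute steps and wrapping midnight, and returns the
centre of the lowest-mean window, earliest on ties. The metric is missing
when more than half the profile bins are. Night-shift work or
unconventional sleep timing is flagged when a participant's L5 midpoint
lies more than two circular standard deviations from the cohort's circular
median midpoint; all three statistics live on the 24-h circle because a
clock-time SD is distorted by the midnight wrap. The inequality is strict,
so a zero-spread cohort flags nobody; fewer than 10 midpoints is an error
because the dispersion estimate is too unstable to threshold.

## Scoring

Quintile cut-points are weighted 20/40/60/80th percentiles (weighted
type-2: the weighted CDF is cut at each probability, averaging adjacent
values at exact jumps, which reduces to `quantile(type = 2)` under equal
weights). Survey weights enter because every downstream analysis is
weighted; an unweighted switch exists for sensitivity. Values equal to a
cut-point go to the lower quintile — a fixed tie rule that makes labels
invariant under strictly monotone transforms. The reference (presumed
lowest-risk) quintile is Q1 for acrophase and IV and Q5 for the other five
parameters; `reference_quintiles()` centralizes the convention and every
fit accepts an explicit override.

The impaired-rhythmicity score counts how many of {F statistic, amplitude,
mesor} fall in Q1 plus acrophase in Q5, capped at 3 ("3+"). The
abnormal-biomarker composite counts abnormal markers among the six, capped
at 3; abnormality uses the clinical cut-offs with strict inequalities
(ALT > 47 IU/L men / > 30 women; AST > 33; ALP > 113; GGT > 65 men / > 36
women; albumin < 3.7 g/dL; bilirubin > 1.3 mg/dL). Markers with a missing
flag simply do not count toward the composite; a panel with no flags at
all yields a missing score.

## The exclusion cascade

Eligibility is applied as a fixed sequence — age under 20; age 80+ (ages
are top-coded at 80 in public data, so exact age is unknowable there);
pregnancy; no actigraphy; fewer than 4 valid days; no liver biomarker
measure — with a ledger recording each stage's excluded and remaining
counts. The final analytic set equals the intersection of the inclusion
predicates; only the attribution of an exclusion to a stage depends on
order, and a property test asserts exactly that. Ledger arithmetic
(`remaining_k = remaining_{k-1} − excluded_k`, all counts non-negative) is
validated on construction, and `ledger_from_counts()` rebuilds a ledger
from published stage counts to check a reported flow. "No biomarker
measure" is read as missing **all six** measures; each biomarker's own
model further restricts to complete cases on that outcome.

## The weighted association engine

All models take the survey weight as a frequency-type weight in the
estimating equations, normalized to mean 1 inside the fit (normalization
changes no estimate and calibrates likelihood-scale statistics), with HC0
sandwich standard errors and normal-theory 95% intervals
(`estimate ± 1.96 SE`). This is a deliberate weights-only design: no
strata or PSU information is used, so variances reproduce a
weights-plus-sandwich analysis rather than full design-based survey
variance. Under equal weights every fit collapses to its unweighted
counterpart exactly.

* **Binary outcomes** (abnormality flags): weighted logistic regression on
  quintile indicator contrasts against the reference quintile, reporting
  per-quintile n, weighted prevalence, OR and CI. Possible
  quasi-separation (fitted probabilities at the boundary, or extreme
  coefficients) is flagged in the output rather than allowed to diverge
  silently.
* **Continuous outcomes**: weighted least squares on natural-log levels
  (levels must be positive; multiplying all levels by a constant shifts
  only the intercept).
* **Composite outcome**: weighted proportional-odds regression; with only
  two observed outcome levels the model *is* binary logistic and is fitted
  as such.
* **Trend**: the quintile index re-entered as a single continuous
  covariate; Wald p from the sandwich SE, invariant to affine recoding of
  the index.
* **Interaction**: a working (pseudo-likelihood) LRT between nested
  weighted fits would be the textbook choice, but with weights unrelated
  to the outcome its null distribution is inflated by roughly
  $E[w^2]/E[w]^2$ — measured at a 12.9% type-I rate under this package's
  simulated cohorts at the nominal 5%. The implemented test therefore
  divides the working LRT by the mean squared normalized weight (a
  first-order Rao–Scott-style design-effect correction) before referring
  it to $\chi^2$ with one df per cross-product term; measured size is
  5.9% over 1000 null replicates, and with equal weights the factor is
  exactly 1 so the ordinary LRT is recovered. An eigenvalue-based
  correction (model-based vs sandwich variance of the tested block) was
  evaluated and rejected: with sparse interaction cells the sandwich
  block estimate is too noisy and the corrected test still ran at 8–9%.
* **Stratified and sensitivity runs**: per-stratum refits flag any
  stratum with under 5 events in an exposure cell; the shift-worker
  sensitivity refit drops flagged participants and reports how many.

`run_full_analysis()` crosses every RAR parameter's quintiles with every
binary outcome and adjustment model (model 1: age, gender; model 2 adds
sociodemographics, smoking, alcohol and hepatitis B/C/E; models 3 and 4
add diabetes and BMI onto model 2; a behavioural sensitivity set adds
total activity and sleep duration), attaches the trend p per cell, and
records per-cell failures without aborting the run. Complete-case handling
is per model; no multiplicity correction is applied.

## The synthetic-data generator

The generator exists so that every stage has a recoverable ground truth.

* **Actigraphy**: minute epochs whose noiseless mean is exactly the
  extended cosine curve, plus additive Gaussian noise truncated at zero
  (a heavier-tailed Student-t option sits behind a switch). The sleep
  window defaults to 8 h centred on the curve nadir, so sleep-epoch
  activity is near the minimum by construction without breaking the
  mean-curve contract; non-wear blocks carry missing activity and may not
  overlap sleep. The activity-count noise distribution of real devices is
  not characterized here; the Gaussian choice is a stand-in, and recovery
  results should be read accordingly.
* **Cohort**: demographic, lifestyle and serology covariates with
  plausible US-adult marginals, lognormal survey weights normalized to
  mean 1 (positive and right-skewed, like real sampling weights), a
  uniform exposure quintile, per-participant rhythm-truth parameters whose
  noise level falls with the quintile (so higher quintiles genuinely show
  more robust rhythms), and eligibility fields with configurable rates so
  the exclusion cascade has real work to do.
* **Biomarkers**: abnormality drawn from a logit model with configured
  per-quintile log-odds and optional age/sex terms; continuous levels then
  sampled from the correct side of the sex-specific cut-off, so the
  generated flags and levels can never contradict each other — a property
  asserted over whole simulated cohorts.

Determinism is a contract: one master seed, per-participant streams
derived by a fixed splitting rule (`(seed + 7919 · index) mod (2³¹ − 1)`),
byte-identical output for identical seeds.

What the generator does **not** emulate: multistage survey design
(strata/PSUs — the analysis is weights-only by design), device-level
artefacts (autocorrelated noise, gain drift, wear-position effects),
seasonal or weekday structure, informative missingness (non-wear is
placed, not behaviourally driven), and correlation between covariates and
rhythm parameters beyond the quintile-noise link. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to every feature of field data.

## Validation scale and numerical conventions

The shipped verification uses problem sizes chosen to exercise the
asymptotics meaningfully on a single CPU: 200 simulated 7-day participants
(2016 five-minute bins each) for rhythm recovery, with amplitude-to-noise
ratios of at least 2; 500 replicates of 4000-participant cohorts for
odds-ratio recovery and CI coverage; 1000 null replicates for the size of
the trend and interaction tests; 500 replicates of 168-hour white noise
for the IS/IV limits. Observed results: median absolute acrophase error
about 0.01 h, median relative amplitude error about 3%, mean recovered OR
2.005 against a true 2, 96% CI coverage, 4.7%/5.9% type-I for trend and
interaction, mean IV 1.998 and mean 7-day IS 0.137 against limits 2 and
1/7. `scripts/acceptance.R` recomputes all of these from a caller-supplied
seed.

Numerical conventions worth knowing: quintile ties go down; L5 and
acrophase ties go to the earliest time; the acrophase is reported on a
1-minute grid; IS/IV return missing (never NaN) on degenerate input;
the cosine fit's `converged` flag reflects the optimizer status of the
best start, and non-converged fits are excluded downstream.

## Known limitations

Cross-sectional associations only — nothing here supports temporal or
causal claims. The extended cosine model assumes a cosine-like waveform;
the pseudo-F statistic detects but does not repair departures from it.
Variance estimation is weights-plus-sandwich, not full design-based
survey variance. The proportional-odds model's common-OR assumption is
not tested internally. The generator's independence assumptions (weights
independent of outcomes, noise independent across epochs) are what make
the design-effect LRT correction exact to first order; strongly
informative weights would require the full survey machinery instead.
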