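---
title: "Dosimetry and dose-response modelling for larval zebrafish blast TBI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosimetry and dose-response modelling for larval zebrafish blast TBI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastdose)
```

## The assay and what this package computes

In the weight-drop blast TBI assay, larval zebrafish sit in 1 ml of media
inside a closed 10 or 20 ml syringe. A calibration weight dropped down a
guide tube strikes the plunger and drives a pressure wave through the
liquid; an in-line automotive pressure transducer, sampled by a
microcontroller ADC, records the pressure time course for (nominally) one
second after a photoresistor trigger. Injury "dose" is characterised by
the maximal pressure of the trace, the number of pressure waves (the
weight bounces, so secondary waves follow the first), and the timing
between waves. Phenotypes — seizure-like hyperactivity, prolonged
inactivity, loss of stimulus response, tau pathology — are then related to
dose with linear and logistic regressions, and group contrasts are tested
with one-way ANOVA plus Dunnett comparisons against a shared uninjured
control.

`blastdose` implements that analysis chain end to end, plus a synthetic
generator that produces inputs with the same structure so the chain can be
exercised and validated without animals.

## Signal chain and units

The transducer conversion is fixed by three published constants applied in
sequence: `voltage = 5 * output / 1023` (10-bit ADC, 5 V reference), `PSI
= (voltage - 0.5) * 37.5` (0.5 V zero offset, 37.5 PSI/V), `kPa = PSI *
6.895`. `adc_to_kpa()` composes them exactly; the map is affine, so one
ADC step spans `5/1023 * 37.5 * 6.895 ≈ 1.264` kPa — the quantization
floor every downstream comparison inherits.

Samples below the 0.5 V offset convert to negative kPa. They are retained
and flagged rather than clipped: clipping would silently bias baseline
estimation, and a rail-sitting sensor is something an analyst should see.

Units are fixed throughout the interfaces: time in ms, pressure in kPa,
mass in g, height in cm, activity in the tracking export's distance units
per bin. The sampling rate is never assumed; timestamps in the trace file
are authoritative (the synthetic generator defaults to 0.2 ms spacing).

## Wave segmentation

A pressure wave is defined as the excursion of the trace from baseline
back to baseline. Two practical choices sit on top of that rule:

* **Baseline** is estimated from data (`estimate_baseline()`), by default
  the mean of the trailing 100 ms of the trace, because the sensor offset
  can drift and the recording is triggered before impact; a leading
  window is available for long pre-impact recordings. The window must
  contain at least 10 samples.
* **Exceedance threshold.** The literal "above baseline" rule is
  noise-free only in prose. A wave opens at the first sample strictly
  above `baseline + exceedance` and closes at the first sample back at or
  below it. The default exceedance is `max(3 * noise_sd, 1)` kPa: three
  noise standard deviations make spurious openings rare under Gaussian
  noise, and the 1 kPa floor (below one ADC step) handles noise-free
  traces. Waves shorter than `min_duration_ms` (default 1 ms;
  configurable to 0 for the literal rule) are discarded as single-sample
  spikes.

Per-wave peak and mean pressure are computed over the above-threshold
samples, with the mean taken over samples (identical to a time average
under uniform sampling, which is what the capture produces). Maximal
pressure is deliberately *not* a segmentation output: it is the global
maximum of the trace and therefore invariant to every segmentation
parameter.

Inter-wave intervals are reported start-to-start, because "time between
waves" is ambiguous between start-start and end-start conventions;
`summarize_drop()` returns the end-to-start gaps as well so both can be
reported. Replicate drops are summarised by the mean, SEM (sample SD with
the n−1 denominator over √n) and RSD (100 × SD/mean) of the per-drop
maxima — per-drop maxima and the mean of maxima are kept separate in all
outputs to avoid conflating the two.

Two physics helpers complete the dosimetry: `expected_static_pressure()`
(Pascal's principle, weight over barrel cross-section, with g = 9.80665
m/s² exactly) supports the static calibration check against resting
masses, and `potential_energy()`/`pe_ratio()` express drop energy, a
second dose axis that separates configurations with similar maximal
pressure (200 g from 27 cm carries 50% of the energy of 100 g from
108 cm).

## Behaviour metrics

Activity traces are per-larva binned distance-moved series. The
high-activity (seizure-candidate) threshold is 64% of the highest per-bin
activity anywhere in the uninjured group, pooled across the session's
control larvae (the rule references *the* uninjured group, singular, so
pooling — not per-plate thresholds — is used). The threshold is applied to
per-bin activity, the quantity the export actually contains. Inactivity
bouts are maximal runs of bins with activity at or below `epsilon`
(default 0: strictly no movement) lasting at least 60 s; shorter pauses do
not count, and total inactive time sums only qualifying bouts. Both
detectors are pinned in the tests to literal run-length-scan oracles,
including the exact-60 s boundary.

Larvae with zero total activity are flagged candidate-dead but never
dropped automatically: floating and heartbeat are not observable in the
activity table, so exclusion requires confirmation, and the pipeline log
records how many larvae each filter removed. Fin-poke response rates
exclude non-heartbeat-verified larvae from the denominator. Seizure stage
labels (none / stage I / stage II–III) are manual, blinded scores ingested
as data; automated staging is out of scope.

## Dose-response models

* `fit_linear()` — ordinary least squares with R² and the two-sided slope
  p-value.
* `fit_logistic()` — maximum-likelihood logit fit (via `glm`). Covariates
  are untransformed (kPa, drop counts), so `exp(beta)` is the per-unit
  odds ratio; 95% CIs are Wald intervals on the log-odds scale, the
  conventional reporting choice. Discrimination is the ROC AUC of fitted
  probabilities. Complete separation is detected by a class-overlap check
  and raised as an error naming the covariate — no silent penalized
  fallback. The fit requires both outcome classes and at least 10
  observations per covariate.
* `scale_odds_ratio()` — odds ratios compose multiplicatively, so the OR
  per k units is the per-unit OR to the k-th power; percent changes are
  rounded to one decimal in reports and kept at full precision
  internally. An OR of 1.005/kPa is +64.7% per 100 kPa; 1.099/drop is
  +9.9% per drop; 1.004/kPa is +49.1% per 100 kPa (which prints as 49% at
  integer rounding).
* `roc_auc()` — the Mann–Whitney formulation via midranks, which equals
  the all-positive-negative-pairs count with ties at half credit.
* `anova_dunnett()` — one-way ANOVA followed by Dunnett's two-sided
  comparisons of every treatment group against the shared control, using
  the pooled error variance. The equicorrelated multivariate-t machinery
  comes from `multcomp::glht()`; unadjusted pooled-t p-values are
  reported alongside so the adjustment is auditable (adjusted ≥
  unadjusted, always). When the residual variance is indistinguishable
  from roundoff (all groups constant), the comparison degenerates to "no
  difference" (p = 1) rather than dividing by a machine-noise variance.

In the session pipeline each larva inherits its group's mean maximal
pressure: larvae share a syringe, so individual pressure is not
observable, and the control group is coded 0 kPa. The shared control is
reused across panels by design and flagged in validation findings.

## The synthetic generator

`simulate_drop_trace()` models the dropped weight as a point mass:
impact speed `v0 = sqrt(2 g h)`; bounce k strikes at `v0 e^k` (e the
restitution coefficient) after a flight time `2 v0 e^k / g`, and produces
a pulse (half-sine by default, 5 ms wide) with amplitude
`pressure_per_velocity × v0 e^k`. The bounce train is truncated when the
amplitude falls below `min_pulse_fraction` of the first pulse. Gaussian
sensor noise is added and the signal is pushed through the *inverse*
calibration chain to integer ADC counts, saturating at the 10-bit rails,
so synthetic files are bit-compatible with real captures.

The amplitude-proportional-to-velocity law is a modelling choice, not
measured physics: it reproduces the qualitative structure (heavier/higher
drops give larger pressures; bouncing gives decaying secondary waves with
geometrically shrinking gaps) but makes no claim to the absolute kPa of
any physical rig — holder rigidity and syringe size enter only as a
multiplier on `pressure_per_velocity`. Defaults were chosen once to land
in the regimes the assay reports: restitution 0.18 puts inter-wave
intervals in the tens-of-ms range (≈84 ms for a 27 cm drop), and
`pressure_per_velocity` values of 20–235 kPa/(m/s) span the ≈33–1105 kPa
working range of the hardest-hitting configuration.

`simulate_activity()` emulates the biphasic behavioural structure:
truncated-Normal per-bin baseline activity; a seizure bout (activity ×
`seizure_gain`) inserted with probability following a triangular bump
over the 90–300 kPa detectability band; and a ≥60 s zero-activity run
inserted with probability logistic in dose — moderate doses produce
hyperactivity, high doses produce inactivity. `simulate_phenotypes()` is
the generative inverse of the logistic model: Bernoulli outcomes from
`logit p = β0 + β1·kPa + β2·drops`, with defaults β1 = ln(1.005) and
β2 = ln(1.099) over the working dose span. Every generator takes an
explicit seed and is bit-reproducible; there is no hidden entropy.

What passing tests on these simulations shows — and does not show: the
round trips (pulse count and peaks recovered to within one ADC step at
zero noise; generative OR recovered within its Wald CI end to end)
validate the *analysis chain*, i.e. that segmentation, conversion and
fitting are mutually consistent and correctly implemented. They cannot
validate transducer dynamics, real larval behaviour, or the absolute
pressure scale of a physical rig, which only hardware calibration can.

## Numerical choices and problem sizes

Tolerances and tie-breaks worth knowing: ADC quantization bounds every
pressure comparison at ~1.264 kPa; AUC ties get half credit (midranks);
the degenerate-ANOVA cutoff is `sqrt(machine eps)` scaled by the squared
response mean; waves still open at the end of a recording are closed at
the final sample. Statistical validation in the test suite runs at sizes
chosen to make the checks sharp but quick: 100+ randomized segmentation
fixtures against a literal scan oracle, 200 logistic simulations at
n = 500 for Wald CI coverage (accepting 93–97%), 2000 four-group null
replicates for the Dunnett family-wise error (accepting a 3-SD binomial
band around 5%), and synthetic sessions with 3 drops × 6 configurations
and 25–80 larvae per dose group.

## Known limitations

* Maximal pressure is a static-calibrated reading; the transducer's
  dynamic response is uncharacterised, so fast peaks may be under- or
  over-read in ways the package cannot correct.
* The bounce model is kinematic, not constitutive; use it for pipeline
  validation, not for predicting rig pressures.
* Seizure staging is manual by design; the high-activity detector only
  proposes time points for scoring.
* Group-level dosimetry means all within-group larvae share one pressure
  value; dose-response slopes are therefore driven by between-group
  contrast.
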