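---
title: "Methods: transcriptomic circadian phenotyping on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic circadian phenotyping on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circphen)
```

`circphen` validates a blood-based transcriptomic circadian clock against the
standard phase measures — dim-light melatonin onset (DLMO), rest–activity
rhythms from wrist actigraphy, and questionnaire chronotype (MEQ) — on
simulated cohorts whose statistical structure mirrors a two-sample clinical
protocol in older adults. This vignette is the package's account of its
models, conventions, and limitations.

## The generative model

Every subject carries one latent phase offset $\delta$ (hours, positive =
advanced internal clock). All modalities are deterministic functions of
$\delta$ plus modality-specific noise:

* **Expression.** Gene $g$ follows a cosinor,
  $x_g(t) = m_g + A_g \cos\!\big(2\pi\,(t - (\phi_g - \delta))/24\big) +
  \varepsilon$, with $\varepsilon \sim N(0, \sigma_g)$. Mesors
  $m_g \sim N(7, 1)$ (log-scale units), amplitudes $N(1, 0.2)$ truncated
  below at 0.2, acrophases uniform over the day so the panel tiles the
  circadian cycle. The default amplitude:noise ratio is 2:1
  ($\sigma_g = 0.5$), a level at which a 40-gene panel recovers phase to
  well under an hour.
* **Melatonin.** Plasma is a piecewise-linear "hockey stick": baseline
  2 pg/mL until the rise starts at $21.6 - \delta$ h, then +8 pg/mL/h.
  Saliva is $0.3 \times$ plasma plus $N(0, 0.5)$ assay noise truncated at 0.
  The piecewise-linear form gives the threshold crossing a closed form
  (`dlmo_truth()`), so estimator error is measurable exactly. The operational
  DLMO — the crossing of the saliva threshold equivalent to plasma
  10 pg/mL — falls 1 h after the kink, i.e. around 20:35 on average, about
  two hours before bedtime, matching the protocol's evening sampling margin.
* **Actigraphy.** A two-level square wave: awake (counts
  $\sim N(300, 60)$, truncated at 0) between waketime $9.1 - \delta$ and
  bedtime $24.8 - \delta$, rest ($\sim N(15, 25)$) otherwise, for 7 days of
  1-min epochs. Each epoch flips to the opposite behavioural state with
  probability $0.2 \times \text{fragmentation}$, emulating arousals and naps.
  Diary rest intervals list the complete nights verbatim.
* **MEQ.** $\text{round}(53 + 5\delta + N(0, 3.5))$, clipped to the
  instrument range 16–86. Labels use the conventional bands; the boundary
  scores 59 and 41, unassigned by the study's printed ranges, map to morning
  and evening respectively.

Chronotype strata are sampled 70% morning / 30% intermediate with stratum
phase-offset means +2.7 h and +0.5 h (SD 1.5 h), reproducing a
morning-weighted older-adult cohort of 40 with Table-1-like timing: mean
bedtime ≈ 22:45, waketime ≈ 07:05, DLMO ≈ 20:35, M10 amplitude ≈ 280 counts.

Randomness is organised as one sub-stream per subject per modality, keyed by
a stable hash of the subject id, so enlarging a cohort never perturbs
existing subjects, and identical `(config, seed)` pairs are bit-identical
end to end. The gene panel is drawn once and *shared* between cohorts that
feed the same clock — panel parameters are gene biology, not cohort
membership.

## The clock and the two-sample geometry

The clock is two ridge regressions of $\cos(2\pi t/24)$ and $\sin(2\pi t/24)$
on within-subject-normalized expression, fitted in closed form; predicted
time is the phase angle of the fitted pair. The ridge penalty is chosen by
leave-one-*subject*-out cross-validation over $\{10^{-2}, 10^{-1}, 1, 10\}$,
minimizing mean absolute angular error (subjects, not samples, are held out,
because a subject's two samples share $\delta$).

Within-subject centering of a **two-sample** protocol has a sharp geometric
consequence worth stating, because it shapes both the training design and the
interpretation of per-sample errors. After centering, the two feature vectors
of a subject are exact negatives of each other, so a linear readout can only
resolve the *midpoint* phase of the pair: per-sample predictions necessarily
land at midpoint ± 6 h, whatever the true spacing. Two corollaries:

* With the clinical protocol's ~14 h spacing (20:00 and 10:00 the next
  morning), every sample carries a deterministic ±1 h offset
  (= 14/2 − 6). The offsets have opposite signs for the two samples and
  **cancel exactly in the AM/PM average** — the package's per-subject
  Transcriptomic Angle is therefore clean even though per-sample errors are
  biased. This is a principled reason to average the two sessions rather
  than use either alone.
* A 12 h spacing makes the offset zero and the phase map exactly linear, so
  **training cohorts** use a rotating design: each training subject is
  sampled at a uniform random start time plus 12 h, covering the full day.
  Training at two fixed clock times would be degenerate — the regression
  targets would take only two values and the fitted clock would ignore
  phase entirely.

The clock's zero angle is defined by its training population: a cohort's
mean angle is its mean phase advance *relative to the training reference*.
`run_validation()` therefore trains on a zero-centered reference cohort
(emulating a clock trained on young adults), which is what makes the
morning-shifted test cohort's mean angle positive (≈ +2 h) rather than zero.

Accuracy is the fraction of samples within tolerance $h$, for $h$ over
[0, 12]. The normalized AUC integrates the empirical step curve exactly,
$\mathrm{nAUC} = 1 - \overline{\min(|\text{angle}|, 12)}/12$; the 0.1 h grid
in the returned curve is for reporting and plotting only. The exact
integral, rather than a fixed-grid trapezoid, keeps closed-form cases honest
(a single 6 h error gives exactly 0.5).

## DLMO

The saliva threshold is `plasma_equivalent * mean(saliva/plasma)` over
concurrent pairs — the mean of per-pair ratios, matching how assay-specific
thresholds are calibrated against the 10 pg/mL plasma criterion. Profile
inclusion codifies the usual visual "hockey stick" screen as three
deterministic rules: a strictly sub-threshold sample must precede the first
up-crossing; at least two consecutive samples must sit at/above threshold
after it; and the profile must not return below threshold after that
sustained crossing. With multiple up-crossings (noisy profiles) the
*sustained* crossing defines DLMO and earlier transients are ignored — a
reproducible substitute for case-by-case visual judgement. DLMO itself is
the linear interpolation between the last sub-threshold sample before the
sustained crossing and the first sample at/above it.

Evening times live on a monotone session axis (24.5 = 00:30 the next
morning) so interpolation never spans a midnight wrap; results are reported
modulo 24 only at presentation time.

## Actigraphy

IS and IV use the standard nonparametric definitions on 60-min bins
(configurable): IS is the clock-time-locked between-day variance over total
variance (1 = identical days, ≈ 1/`n_days` for structureless noise); IV is
the normalized mean squared successive difference (≈ 0.068 for an hourly
24 h sinusoid, 2 for white noise, 4 for a strictly alternating series). M10
and L5 are the extreme contiguous 10 h / 5 h windows of the day-averaged
profile, circular with wrap-around, ties resolved to the earliest start;
amplitude is their difference on the raw count scale (relative amplitude is
also returned but unused downstream). Days with under 80% epoch coverage are
dropped from the average profile — a missing-data rule that synthetic
recordings never trigger but real exports need. Sleep variables are
diary-anchored: within each rest interval an epoch is asleep if its counts
fall below 40 (the package default wake threshold); TST, WASO, and
efficiency follow per night and are averaged across nights, with circular
means for all clock times.

## Agreement statistics

Partial correlations residualize both variables on an intercept plus
covariates (age, sex by default) and correlate the residuals, with
$n - 2 - k$ degrees of freedom; with no covariates this reduces exactly to
Pearson's test. Bland–Altman analyses z-score both measures first (the
phenotypes have incommensurable units); consequently the mean difference is
analytically zero and the informative output is the limits of agreement,
whose half-width is $1.96\sqrt{2 - 2r}$. Clock-time measures where larger
means *delayed* (DLMO, bedtime, waketime, M10 start) are negated before
z-scoring so both axes share the angle's "positive = advanced" orientation;
without this, agreement plots of negatively correlated measures are
uninterpretable. MEQ is not negated. Group comparisons follow the
cohort-table convention: equal-variance Student's t for continuous
variables, chi-squared without continuity correction for categorical ones,
flagged at p < 0.05 with no multiple-testing correction. The
Kolmogorov–Smirnov normality screen estimates mean and SD from the sample
and says so in a warning (the Lilliefors caveat): treat its p-values as
conservative screening, not inference.

Clock-time phenotype columns are unwrapped around their cohort circular mean
onto a linear hour scale before any correlation or t-test, and stratified
summaries report clock times as circular mean ± circular SD in minutes.

## Problem sizes and numerical conventions

The test suite exercises cohorts of 5–200 subjects with 1–7 recording days;
the acceptance checks use 40-subject training and test cohorts (the study's
cohort size) with a 40-gene panel, 2 000 subject-pairs for the AM/PM
consistency expectation $r = \sigma^2_\delta/(\sigma^2_\delta + \sigma^2_e)
= 4/5$, 100-series brute-force oracle sweeps, and a 200-subject default run
for the qualitative sign pattern. Ridge systems are solved directly
(Cholesky via `solve`) with an unpenalized intercept; a singular unpenalized
fit on a degenerate design raises an error rather than pseudo-inverting.
Angles use the half-open convention [−12, 12), antipodal differences
reporting −12; `atan2` outputs pass through a double modulo so tiny negative
angles cannot round to 24.0.

## Limitations

The generator is deliberately idealized where the study's data are richest:
between-subject differences in rhythm *amplitude* are not modelled (so
synthetic amplitude SDs are far tighter than real cohorts'), activity is a
two-level square wave rather than graded daytime behaviour, day-to-day
schedule variability within subject is absent (IS runs high), melatonin
rises linearly rather than sigmoidally, and expression noise is i.i.d.
Gaussian with no platform or batch structure. Passing tests therefore
demonstrate the *estimators* and the *pipeline logic* — recovery of known
latent phase, exactness of closed forms, direction and strength of
cross-modal agreement — not robustness to the biological and technical
messiness of real cohorts. The clock also assumes the test panel was
measured on the training platform's scale up to per-subject offsets (which
within-subject normalization removes); cross-platform harmonization beyond
that is out of scope.
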