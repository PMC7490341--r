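---
title: "Quantifying rest fragmentation in home-cage activity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rest fragmentation in home-cage activity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous home-cage monitoring systems record a nonnegative per-minute
activity signal for each cage, around the clock, for months. In
neurodegeneration models such as SOD1G93A mice (an ALS model), the light
phase — when nocturnal mice normally rest — progressively fills with short,
erratic activity bouts long before gross activity levels change. The
Regularity Disruption Index (RDI) quantifies this fragmentation: it is the
sample entropy of the thresholded, band-pass-filtered minute-binned
activity. A phase in which all minutes carry similar activity scores near
0; a phase of erratic minute-to-minute switching scores high. Because the
entropy tolerance scales with the SD of the analyzed series, RDI is
invariant to rescaling the activity and therefore insensitive to the
absolute amount of movement.

`rdikit` implements the full chain: data model and exclusion rules,
preprocessing, the entropy engine with four RDI variants, companion
circadian activity metrics, group statistics with a correlation-aware
multiplicity correction, and a seeded simulator that provides ground truth
for validation.

## The RDI pipeline

For one analyzed segment (720 minutes of a light or dark phase, or a 60-min
window):

1. **Threshold.** Activity strictly below `lambda = 0.005` (activity units
   on the \[0, 1\] scale of the capacitive sensor metric) is set to 0;
   values equal to or above it are kept. This removes sub-threshold sensor
   noise that would otherwise register as spurious irregularity.
2. **Band-pass.** A digital Butterworth band-pass of order 4 with
   normalized cutoff frequencies 1/2000 and 1/300, applied zero-phase
   (forward–backward). Cutoffs are fractions of the Nyquist frequency
   (0.5 cycles/min at 1-min binning), the convention of the filter-design
   tooling the pipeline standardizes on.
3. **Sample entropy.** SampEn(m = 2, r = 0.2·SD): with `B` the number of
   pairs of length-2 templates whose Chebyshev distance is at most `r` and
   `A` the analogous count for length-3 templates (self-matches excluded,
   both counts over the first `N - m` templates), RDI = −ln(A/B). The SD is
   the population (1/N) standard deviation of the post-filter series.

Variants: *day* and *night* use the two 720-min phases of an analysis day
(a "day" runs lights-on to the next lights-on, 07:00–07:00 by default, so
hour 0 of every profile is lights-on); *least-active-hour* uses the 60
consecutive minutes with the lowest mean raw activity (ties broken
earliest); *moving-RDI* slides a centered 60-min window across the day.
Weekly values are arithmetic means of the available per-cage daily values.

## Numerical design of the filter

The transfer-function (b, a) realization of this band-pass is an 8-pole
filter whose poles cluster very close to `z = 1`; at double precision it is
numerically unstable — a constant input can come out amplified by orders of
magnitude, and an in-band sinusoid explodes. The package therefore designs
and applies the filter entirely in zero-pole-gain / second-order-section
form: analog Butterworth prototype, low-pass-to-band-pass transform,
bilinear transform, and pairing of conjugate pole pairs into biquads (zeros
at `z = ±1`, sections ordered with poles closest to the unit circle last).
Zero-phase application uses odd-reflection padding (3·(2·sections + 1)
samples) and steady-state initial conditions per section, so start-up
transients are strongly suppressed and bout positions are not shifted
relative to the light cycle. A causal single pass is available via
`rdi_params(zero_phase = FALSE)`. The test suite pins the filter against
frozen outputs of an independent SOS forward–backward implementation and
against the filter's own analytic magnitude response.

Two scope choices the pipeline exposes because the convention genuinely
matters:

* **`filter_scope`** — whether the two 720-min phases are filtered
  independently (default) or the 1440-min day is filtered once and then
  split. Results differ only near the phase boundary.
* **60-min windows** (moving-RDI, least-active-hour RDI) are always taken
  from the day-level filtered series: a band-pass whose longest passband
  period is 2000 samples is not meaningful on an isolated 60-sample
  window. Thresholding is pointwise, so window-local and day-level
  thresholding coincide. The entropy tolerance is window-local
  (`0.2 · SD(window)`).

## Degenerate entropy cases

* A **zero-variance** (constant) series carries no irregularity: RDI is
  defined as exactly 0 and flagged degenerate. `compute_rdi` detects
  constancy on the raw segment before filtering, so filter round-off
  cannot manufacture spurious entropy; a post-filter SD at the round-off
  floor (≤ 1e−12 relative to the segment scale) is treated the same way.
* **No template matches** (`B = 0`, or `A = 0` with `B > 0`) on a
  non-constant series leaves −ln(A/B) undefined. The value is missing and
  flagged; weekly means include the constant-series zeros (genuine
  "perfectly regular" observations) but exclude undefined days. At
  N = 720 with r = 0.2·SD this case is essentially unreachable; at N = 60
  it can occur, and imposing a finite cap would invent information the
  data do not contain.
* Moving-RDI windows at the day edges (first and last 30 min) are missing
  rather than padded.

## Exclusion and aggregation rules

The cage is the statistical unit. Cage-change days are excluded from all
analyses (handling disturbs the light phase massively). A cage in which a
mouse dies before the scheduled endpoint is excluded whole from group
metrics by default (`exclude_dead_cage = TRUE`); truncation at the death
date is available as a config switch. Any analysis day with at least one
missing minute is excluded (`incomplete_day`): entropy on gapped series is
ill-defined, and partially recorded boundary days are dropped rather than
guessed at. Weeks of age are 7-day blocks anchored at the cage's rack-entry
date (entry at age 7 weeks by default). Group testing is restricted to
weeks at or below 20, where all cages are still present; later weeks enter
descriptive curves and the week 16–24 decline-slope fits (which in turn use
only weeks with two mice in the cage).

## Group statistics

Per-week comparisons are Student's pooled-variance two-sample t-tests
(`df = n_a + n_b − 2`; the published degrees of freedom, 15 for 8 vs 9
cages and 19 for 11 vs 10, force the pooled rather than Welch form).
Because weekly outcomes of the same cages are strongly correlated,
Bonferroni is too conservative; the D/AP procedure shrinks the effective
number of tests to `k_eff = k^(1 − r̄)` and tests each week at
`α_adj = 1 − (1 − α)^(1/k_eff)`. With `r̄ = 1` this is no correction; with
`r̄ = 0` it is the Šidák level `1 − (1 − α)^(1/k)`, numerically close to
Bonferroni's `α/k` (the package reports classical Bonferroni `α/k`
alongside, and the significance sets nest: Bonferroni ⊆ D/AP ⊆
uncorrected). The mean outcome correlation r̄ is not prescribed by the
procedure itself; the package estimates it as the mean upper-triangle
pairwise Pearson correlation between week columns across all cages of both
groups pooled, clipped to \[0, 1\], and accepts a user-supplied value as an
override (per-metric or per-group estimation are then one argument away).
The onset of a group difference is the earliest tested week significant
under D/AP. The rank-based longitudinal ANOVA-type statistic used alongside
these tests in the original analyses is deliberately not re-implemented;
`posthoc_weeks` output is designed so externally computed results of that
kind can sit next to it.

## The simulator

`sim_config()` / `simulate_study()` generate minute-binned activity with
the statistical structure the analysis assumes, plus the matching metadata,
calendar and ground truth. Per minute, activity is the sum of a nocturnal
circadian drive, a two-state (rest/active) Markov bout process, and rare
resting "twitches", clipped to \[0, 1\]:

* **Circadian drive** (dark phase only): base level 0.05 with two Gaussian
  peaks (height 0.5, SD 60 min) just after lights-off and before
  lights-on — the classic bimodal nocturnal profile — times multiplicative
  noise (SD 0.2).
* **Bout process**: rest→active probability ρ/60 per minute (ρ in
  bouts/hour; 0.15 in the light phase for controls, 6 at night),
  active→rest probability 1/3 (geometric bouts, mean 3 min). Active
  minutes draw amplitudes uniformly (0.05–0.3 by day, 0.2–0.8 at night)
  with 10% multiplicative noise.
* **Twitches**: with probability 0.005 per resting minute, an exponential
  magnitude of mean 0.003 — mostly below the λ = 0.005 threshold. Resting
  activity is otherwise exactly 0, matching the observation that control
  cages always contain a consecutive hour of essentially zero activity.
* **Cage heterogeneity**: one lognormal multiplier per cage (SD 0.08 on
  the log scale) on all bout rates, constant over the study. This is what
  makes weekly outcomes of a cage correlate — the premise of the D/AP
  correction.
* **Disease schedule** (TG cages): the diurnal bout rate gains an extra
  component that takes off at the onset week (16), rising as
  `ρ_peak · u^0.4` of the normalized onset-to-peak position `u` to its
  maximum (6 bouts/h) at week 20, then declining by 25% of the peak per
  week — an abrupt symptomatic take-off followed by decline as motor
  impairment suppresses movement, producing the bell-shaped fragmentation
  trajectory. The nocturnal amplitude multiplier declines by 0.08/week
  from onset (floor 0.2), producing the late nocturnal activity decline.
* **Husbandry**: weekly cage changes (Tuesdays) add 30 bouts/h with
  night-scale amplitudes to that day's light phase; two weekdays carry
  in-room procedures; weekends are quiet.

The generator emulates the *structure* the analysis relies on — circadian
segregation, sparse diurnal rest with consolidated quiet hours, minute-
scale bout fragmentation that rises and falls with disease progression,
persistent cage differences, husbandry artifacts. It does not emulate
sex differences, ultradian rhythm fine structure, sensor drift, missing
data, or deaths (metadata supports endpoint dates, but none are generated
by default). Passing recovery tests therefore shows the pipeline detects
the modeled fragmentation signal at realistic effect sizes and noise
levels; it does not certify behavior on pathologies the generator does not
produce.

A note on dynamic range: after this narrow low-frequency band-pass, sample
entropy operates on a strongly smoothed series, so RDI values compress
into a narrow range (roughly 0.01–0.016 on simulated data) and saturate at
high bout rates. Group contrasts, onset detection and the bell shape
survive this compression — the validation suite checks exactly that — but
the index is a rank-scale instrument here, not an absolute fragmentation
scale.

## Validation problem sizes

The packaged checks run at deliberately modest sizes: entropy
oracle-equivalence on 200 random series of length 30–300; recovery studies
of 6 control + 6 transgenic cages over weeks 7–24 across 20 seeds (onset
recovered within ±1 week of the configured week 16 in at least 80% of
seeds; the 3-week-smoothed transgenic group curve peaking within weeks
18–22 in at least 90%; control group trends flatter than transgenic in
all); per-week type-I error of the D/AP post-hoc on 1000 null replicates
of a 2-group × 5-week design; and exact lag recovery for shifted bell
curves with 90% recovery at SNR 10. The "peak week" of a noisy weekly
curve is read from a 3-week centered moving average, the same way one
reads a peak off a published group curve.

## Known limitations

* The cutoff convention of the published filter is stated only as
  "normalized"; the package fixes the Nyquist-fraction reading and exposes
  both edges as parameters.
* Whether the original pipeline filtered 720-min phases independently or
  split a filtered full day is ambiguous; `filter_scope` covers both.
* r̄ estimation for D/AP is not prescribed anywhere; the pooled-Pearson
  estimator is a documented, replaceable choice.
* RDI values are not comparable across different filter settings, and the
  compressed dynamic range (above) makes absolute values uninformative;
  comparisons should stay within a study.
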