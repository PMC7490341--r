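# rdikit

Quantifying rest/sleep fragmentation in continuously monitored home-cage
activity.

Digital home-cage monitoring racks record a nonnegative per-minute
activity value per cage, 24/7, for months. In mouse models of
neurodegeneration (e.g. the SOD1G93A ALS model), the light phase — when
nocturnal mice normally rest — progressively fills with short, erratic
activity bouts well before overall activity levels change. `rdikit` is for
researchers analyzing such minute-binned traces: it implements the
**Regularity Disruption Index (RDI)**, a sample-entropy-based digital
biomarker of that fragmentation, together with the surrounding study
machinery — circadian activity summaries, exclusion rules, group
statistics with a correlation-aware multiplicity correction, and a seeded
activity simulator for validation and power analysis.

## The index

For an analyzed segment of `N` minute bins (a 720-min light or dark phase,
the least active hour, or a sliding 60-min window):

1. activity below a threshold λ = 0.005 is set to 0;
2. a 4th-order Butterworth band-pass (normalized cutoffs 1/2000 and 1/300,
   fractions of Nyquist) is applied zero-phase, in numerically stable
   second-order-section form;
3. RDI = SampEn(m = 2, r = 0.2·SD) = −ln(A/B), where B counts pairs of
   length-m templates within Chebyshev distance r, A the same for length
   m + 1, self-matches excluded.

Constant activity gives RDI = 0; erratic minute-to-minute switching gives
high RDI; multiplying activity by a positive scalar leaves RDI unchanged.
Weekly per-cage means of day-phase RDI are the primary disease-progression
readout; the onset of a group difference is the earliest week significant
under the D/AP-corrected post-hoc test, which tests each of `k` correlated
weekly outcomes at `α_adj = 1 − (1 − α)^(1/k_eff)`, `k_eff = k^(1 − r̄)`.

## Worked example

Simulate a small study (6 wild-type and 6 transgenic cages, weeks of age
7–24, fragmentation onset configured at week 16, peak at 20), compute
weekly day-phase RDI, and test group differences:

```r
library(rdikit)

cfg <- sim_config(cages_per_group = 6, sexes = "M", seed = 42)
study <- simulate_study(cfg)

weekly <- do.call(rbind, lapply(study$traces, function(tr) {
  days <- split_analysis_days(tr, study$calendar)
  days <- apply_exclusions(days, study$calendar, study$meta)
  weekly_rdi(rdi_by_variant(days, rdi_params()), study$meta)
}))
rdi_day <- weekly[weekly$metric == "rdi_day", ]

ph <- posthoc_weeks(rdi_day, study$meta)   # pooled t per week <= 20
tail(ph, 5)
#>    week    t df    p_raw sig_none sig_bonferroni sig_dap
#> 10   16 3.94 10 0.002765     TRUE           TRUE    TRUE
#> 11   17 5.09 10 0.000472     TRUE           TRUE    TRUE
#> 12   18 6.13 10 0.000111     TRUE           TRUE    TRUE
#> 13   19 3.30 10 0.008061     TRUE          FALSE   FALSE
#> 14   20 4.96 10 0.000574     TRUE           TRUE    TRUE
detect_onset(ph)
#> [1] 16
```

Each row is a pooled-variance two-sample t-test on per-cage weekly values
(`df = 6 + 6 − 2 = 10`); the three flags apply no correction, Bonferroni
(α/k), and the D/AP correction (here r̄ = 0.05, α_adj ≈ 0.0042 over k = 14
tested weeks). The detected onset, week 16, recovers the configured
ground truth.

A command-line wrapper is installed with the package
(`exec/rdikit`): `rdikit validate`, `rdikit simulate`, `rdikit rdi` and
`rdikit stats` cover the validation-report, simulation, RDI-table and
post-hoc-table workflows on CSV/YAML inputs.

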