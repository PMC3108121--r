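# tremorspec

Quantitative spectral analysis of hand-tremor accelerometry in R, for
researchers comparing tremor in occupationally manganese-exposed workers
(welders with suspected manganism), de novo idiopathic Parkinson's disease
(IPD) and essential tremor (ET). The package provides the full chain needed
to study and stress-test this kind of analysis without access to patient
recordings: a calibrated synthetic tremor-signal simulator, the classical
five-parameter spectral tremor panel, the cohort statistics layer, and a
transparent rule-based group classifier.

## The measurements

All metrics are read from a Welch power spectral density `P(f)` (Hann
window, 4 s segments, 50% overlap) of the acceleration signal, normalized
so its full-range integral equals the signal variance and restricted to the
tremor band **B = [0.9, 15] Hz**:

- **Tremor intensity** (m/s²): band RMS, `sqrt( ∫_B P(f) df )`.
- **Center frequency Cf** (Hz): power-weighted mean frequency,
  `∫_B f P(f) df / ∫_B P(f) df`.
- **Frequency dispersion** (Hz): width of the narrowest window symmetric
  about the median frequency containing ≥ 68% of band power — a regularity
  measure (small = very regular tremor).
- **Energy distribution**: fractions of band power in the low `[3, 6.5]` Hz
  and high `(6.5, 10]` Hz sub-bands.
- **Harmonic index HI** ∈ (0, 1]: fraction of band power within ±0.5 Hz of
  the modal peak; 1.00 for a single harmonic oscillation, lower when the
  tremor is composed of many oscillations.

The simulator renders `a(t) = A sin(2π φ(t)) + n(t)` with a mean-reverting
(Ornstein–Uhlenbeck) instantaneous-frequency wander and band-limited
Gaussian noise, calibrated per group so that simulated cohorts reproduce
the published group means of the three study groups as population targets.
The statistics layer covers group mean ± SEM summaries, rest-to-postural
fold changes with paired t-tests, two-way (position × side) ANOVA variance
partitions, two-sided Fisher exact tests on clinical-sign 2×2 tables, and
slope-vs-zero OLS regressions. The classifier encodes the headline
discrimination logic: parkinsonian tremor does not intensify with arms
extended and oscillates slowly; among the others, a fast rest tremor
(Cf ≥ 6.5 Hz) indicates the welder phenotype rather than ET.

## Worked example

```r
library(tremorspec)

# render a welder-like rest tremor and measure it
rec <- render_tremor_signal(
  component_from_targets(intensity = 0.774, center_freq = 7.05,
                         harmonic_fraction = 0.94, freq_jitter_sd = 0.6),
  signal_spec(seed = 1))
tremor_metrics(rec)
#>  subject_id condition side intensity center_freq median_freq dispersion
#>          S1      rest    R    0.7705       6.904       6.718      1.064
#>  low_band_fraction high_band_fraction harmonic_index
#>             0.3116             0.6591         0.7912
```

The measured band RMS (0.77 m/s²) and center frequency (6.9 Hz) sit at the
requested targets within single-recording estimation noise; about 66% of
band energy lies in the fast 6.6–10 Hz band, typical of the simulated
welder phenotype.

```r
# a small three-group cohort, end to end
sim <- simulate_cohort(n_per_group = c(6, 6, 6), seed = 1)
cohort <- attach_metrics(sim$cohort, analyze_records(sim$records))

fold_change(cohort, "WELDER", "R")
#> <fold_change> WELDER R intensity: 0.459 -> 1.371 (2.99-fold),
#>               paired t(5) = 2.02, p = 0.0988

fisher_exact(7, 25, 0, 17)   # limb cramping, welders vs IPD
#> <contingency_result> OR = 10.294 (0.5 continuity), two-sided Fisher p = 0.07975

evaluate_classifier(cohort)
#> <classifier_evaluation> accuracy 0.556 over 18 subjects
```

The fold change shows the welder hallmark (tremor intensifying when the
arm is extended); the Fisher panel reproduces the published clinical-sign
arithmetic. Classifier accuracy on simulated cohorts is limited by the
large published between-subject spreads — see the methods vignette
(`vignettes/tremor-analysis.Rmd`) for why.

A shell interface over the same functions lives in `inst/cli/tremorspec.R`:

```sh
Rscript inst/cli/tremorspec.R simulate --out cohort_dir --seed 1
Rscript inst/cli/tremorspec.R analyze  --in cohort_dir --out metrics.tsv
Rscript inst/cli/tremorspec.R reproduce-table2
```

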