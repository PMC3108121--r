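---
title: "Methods: spectral tremor analysis and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral tremor analysis and the synthetic cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorspec)
```

# Scope and model

`tremorspec` implements a quantitative tremor-accelerometry workflow for
three-group comparisons: occupationally manganese-exposed welders with a
clinical picture of manganism, de novo idiopathic Parkinson's disease
(IPD), and essential tremor (ET). Hand acceleration is recorded in two
conditions — *rest* (hands on the lap) and *postural* (arms extended at
shoulder level) — on each side, with a pen-held biaxial accelerometer.
Because no recordings of this kind are publicly deposited, the package
pairs the measurement layer with a forward simulator whose population
targets are the published group summary tables, so every downstream
statistic can be exercised on data with known ground truth.

## Spectral estimation

All tremor metrics derive from a Welch power spectral density: Hann
window, 4 s segments, 50% overlap, one-sided density scaling, computed per
axis after removing the signal mean, and averaged across axes for biaxial
records. On the default 16 s, 128 Hz recording this gives a 0.25 Hz grid
and 7 averaged segments. Two numerical choices matter:

- **Exact Parseval normalization.** The density is rescaled so that its
  full-range integral equals the per-axis sample variance exactly. A raw
  Welch estimate drifts a few percent per realization on 16 s records
  (window-weighting noise), which would leak into every band-power
  quantity; after normalization, band powers are an exact partition of
  signal variance. This also reflects the convention of reporting a
  *normalized* power distribution. Because the mean is removed first, a DC
  offset provably changes nothing.
- **Band restriction.** Metrics are read from the restriction to
  [0.9, 15] Hz (inclusive). The sampling rate must exceed twice the band
  top; the simulator enforces ≥ 64 Hz.

## The five tremor parameters

For band masses $m_i = P(f_i)\,\Delta f$:

- **Intensity** $= \sqrt{\sum_i m_i}$ (m/s², band RMS).
- **Center frequency** $= \sum_i f_i m_i / \sum_i m_i$ (Hz).
- **Median frequency**: interpolated 50% point of the cumulative band
  power. The 50% crossing is symmetrized (average of the 49.5% and 50.5%
  crossings): for unimodal spectra this is indistinguishable from the
  plain crossing, while for a spectrum split evenly across two separated
  lines it places the median midway between them instead of snapping to
  whichever line carries infinitesimally more power — the same convention
  by which the sample median averages the two central observations.
- **Dispersion**: width of the narrowest window symmetric about the median
  containing ≥ 68% of band power, found by symmetric expansion over the
  grid. For a pure line this is at most two grid steps (0.5 Hz).
- **Energy distribution**: band-power fractions in [3, 6.5] Hz and
  (6.5, 10] Hz. The low band is closed and the high band open at the
  shared 6.5 Hz edge so a line exactly on the edge is counted once.
- **Harmonic index**: fraction of band power within ±0.5 Hz of the modal
  (peak-density) bin, ties broken toward the lower frequency. This
  satisfies the two defining properties of the published index — exactly
  1.00 for a single harmonic oscillation, decreasing as power spreads over
  many components — but the index used by the original acquisition
  hardware is not publicly specified, so numeric HI values here are a
  package-defined operationalization, not a reproduction (see
  *Limitations*).

Degenerate inputs (zero band power, e.g. a constant signal) raise a typed
`undefined-metric` error rather than returning NaNs.

# The synthetic cohort generator

## Signal model

Each recording cell is rendered as
$a(t) = A\,\sin(2\pi\varphi(t)) + n(t)$ with
$\dot\varphi = f_0 + j(t)$, where $j$ is a mean-reverting
(Ornstein–Uhlenbeck) process with stationary SD `freq_jitter_sd` and
timescale 1 s — the simplest stationary process giving tunable, unimodal
spectral line broadening — and $n(t)$ is Gaussian noise band-limited to
[0.9, 15] Hz. The core RMS is $A/\sqrt2$ and the noise RMS is scaled
exactly, so total band RMS equals the target intensity by construction.

Default recording parameters (128 Hz, 16 s) are package design choices:
the hardware settings behind the published tables are not stated, 128 Hz
oversamples the 15 Hz band top more than 8-fold, and 16 s supports a
0.25 Hz Welch grid with meaningful averaging.

## Calibration to the published group tables

Each group archetype carries, per condition × side cell, the published
mean and SEM of intensity and Cf, and the published mean dispersion and
HI. Between-subject SDs are reconstructed as $\mathrm{SEM}\sqrt{n}$
(n = 37/20/20). Mapping targets to signal parameters:

- **Intensity** is drawn *lognormal*, moment-matched to the published mean
  and SD. This deviates deliberately from truncated-normal resampling: the
  reconstructed SDs exceed the means for most intensity cells, and a
  zero-truncated normal would inflate the population mean by 50–70%,
  breaking mean recovery. The lognormal has positive support and exact
  first two moments.
- **Cf** is drawn truncated-normal (resampled into the band). For every
  cell but one the bounds are ≥ 3.8 SD away and truncation is negligible;
  the welder postural-left cell's published SEM (1.54 Hz) implies a 9.4 Hz
  SD, which truncation visibly recenters — the printed value is honoured
  as-is rather than second-guessed as a typo.
- **Cf de-biasing.** Flat band noise contributes a mean frequency of
  (0.9+15)/2 = 7.95 Hz to the power-weighted Cf, so the harmonic core is
  placed at $f_0 = (\mathrm{Cf} - (1-h)\,7.95)/h$ (clamped to
  [1.0, 14.5] Hz), making the population Cf estimate unbiased for the
  drawn target.
- **Dispersion → jitter**: `freq_jitter_sd` = half the target dispersion
  (the 68% window of the broadened line is ≈ 2.15 SD wide when the line
  dominates).
- **HI → harmonic fraction**: the harmonic core carries a fraction of band
  power equal to the published HI.
- **Within-subject structure.** A latent severity trait (log-intensity
  scale) and a latent frequency trait are shared across the four cells
  with 80% of the between-subject variance (`shared_frac = 0.8`). The
  choice is a priori: the published paired rest-vs-postural t-statistics
  are only attainable with strongly correlated within-subject
  measurements (the welder right-side pairing implies r ≈ 0.9), and
  test–retest correlations of tremor metrics are typically in this range.
  Cell margins are unaffected by the split.
- Demographics come from the published group table (age, onset, sex ratio,
  and for welders exposure years); clinical signs are independent
  Bernoulli draws at the published per-sign frequencies (no joint
  distribution is published). The ET group's signs were not tabulated; the
  archetype presents tremor in every ET subject and no parkinsonian signs.

## What the generator does and does not emulate

It emulates: group-level spectral summary distributions (intensity, Cf),
their within-subject correlation structure, spectral line broadening,
broadband noise floors, clinical-sign frequencies, and demographic
moments. It does not emulate: tremor physiology or medication response,
nonstationarity (bursting, re-emergent tremor), harmonics of the
fundamental, device/firmware specifics, sign co-occurrence, or any joint
dependence of spectral metrics on demographics (no built-in age trends —
which is exactly what makes it a clean null for the regression layer).
Passing recovery tests on simulated cohorts therefore validates the
estimator chain and the statistics, not clinical performance on real
recordings.

# Statistics layer

- **Fisher exact tests** use the standard two-sided convention (sum of
  hypergeometric probabilities no larger than the observed table's) —
  the convention that reproduces the published clinical-sign p-values.
  Odds ratios are sample cross-product ratios with a flagged 0.5
  continuity substitute when a cell is zero, never applied to the p-value.
  Two published rows (dyshidrosis, cog-wheel rigidity) are not reproduced
  by this convention under the printed counts; they are reported but
  carry no reproduction claim.
- **Fold change** is the ratio of group means (postural/rest), matching
  the published fold values, with a paired t-test across subjects.
- **Two-way ANOVA** treats the four condition × side observations per
  subject as cells of an ordinary fixed-effects two-factor model with
  interaction (the published variance-fraction footnote does not state a
  repeated-measures structure), reporting percent of total sum of squares
  per factor; the partition sums to 100 by construction.
- **Regressions** are ordinary least squares with a two-sided slope test;
  a constant response returns slope 0 and $R^2 = 0$ by convention.
- **No multiplicity correction** is applied anywhere, matching per-row
  reporting; reports carry a note saying so.

# The rule classifier

Features per subject, averaged over available sides: rest Cf, postural
Cf, and the per-side postural/rest intensity ratio. The decision tree:

1. ratio < 1.5 **and** postural Cf < 6.5 Hz → IPD;
2. otherwise rest Cf ≥ 6.5 Hz → WELDER;
3. otherwise → ET.

No classifier is published; this module operationalizes the study's
qualitative claims, with thresholds read from the gaps between the
published group means (welder rest Cf ≈ 7.0–7.6 Hz vs ET ≈ 5.8–6.0 Hz;
IPD postural Cf ≈ 6.1–6.3 Hz with ratio ≈ 1) and exposed in
configuration. The published narrative itself is internally inconsistent
about the direction of the welder-vs-ET rest-Cf difference in one place;
the group tables and the figure captions support "higher in welders", and
the defaults follow the tables. Decisions are scale-invariant in
intensity (only the ratio enters) and every classification carries a
trace of the branch that fired.

# Test design and problem sizes

The suite checks every metric against independent oracles: closed forms
for sinusoids, exhaustive hypergeometric enumeration for Fisher tests
(all 2×2 tables with N ≤ 60), a brute-force symmetric-window search for
dispersion, normal-equation closed forms for OLS, hand-computed
sum-of-squares decompositions for the ANOVA, and a time-domain band-pass
oracle (2048-tap windowed-sinc FIR, zero-phase) for band RMS. Recovery of
the archetype targets is checked on 200 simulated subjects per group
(tolerance 3 SEM-equivalents, i.e. $3\,\mathrm{SD}/\sqrt{200}$); the
slope test's type-I error is checked over 500 null cohorts of 200
subjects at the binomial 3-sigma tolerance. These sizes are the package's
chosen compromise between the tightness of stochastic tolerances and a
test suite that stays pleasant to run.

# Limitations

- **HI vs dispersion are jointly unreachable.** Under this package's HI
  definition, a spectrum whose 68% window is wider than 1 Hz cannot keep
  94% of its power inside a 1 Hz window: published cells pair dispersions
  of 1.2–2.9 Hz with HIs of 0.91–0.96, which no spectrum satisfies under
  these two definitions simultaneously. The generator calibrates to the
  dispersion target and lets realized HI land lower (≈ 0.6–0.7 on
  simulated records). HI anchors are therefore exact only for the pure
  single-harmonic case.
- **Parseval scope.** The 1% agreement between spectral band power and
  time-domain band-passed RMS holds for band-limited signals (everything
  the renderer produces). For inputs with substantial out-of-band power,
  the realization noise of any 7-segment Welch estimate (~6% relative SD
  on a band integral of broadband noise) makes a universal per-realization
  1% claim unattainable; full-range Parseval, by contrast, is exact by
  normalization on any input.
- **Classifier accuracy on simulated cohorts is modest.** With
  between-subject SDs reconstructed as $\mathrm{SEM}\sqrt{n}$, the three
  groups overlap heavily in all three rule features (Cf SDs of 1.3–1.7 Hz
  against group separations of ≈ 1.4 Hz; intensity CVs above 100%), and
  the threshold rule's simulated accuracy stays far below what the
  population-mean feature vectors suggest. This is a property of the
  published spreads, not of the rule's thresholds: no deterministic rule
  on these three features separates distributions this wide. Group-level
  discrimination (of means) and subject-level discrimination are very
  different claims, and only a prospective blinded study could establish
  the latter.
- The simulator inherits every printed value as ground truth, including
  a welder postural-left Cf SEM that is plausibly a misprint; honouring
  it widens that cell's Cf distribution to near-uniform over the band.
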