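---
title: "Place-cell rate maps, fields and stability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Place-cell rate maps, fields and stability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ratemapr)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The pipeline targets a standard rodent
experiment: single units recorded from hippocampal CA1 while an animal
freely explores a circular open field (64 cm diameter here) for 30-minute
sessions, typically two sessions per day over two days with distal visual
cues removed in the final "probe" session. The questions it answers are the
classic place-cell ones — how specific, how informative and how stable is
each cell's spatial map, and do those quantities differ between groups
(e.g. a knockout line vs wildtype)?

## From tracking to rate maps

**Speed and activity filtering.** Speed is a central finite difference on
the tracked positions, then a 0.4-s boxcar. The smoothing window is short
enough not to bias a 3 cm/s threshold crossing (typical accelerations at
that scale are slow) while suppressing frame-to-frame tracker jitter, which
otherwise inflates speed and leaks inactive samples past the cut. Samples
with speed below 3 cm/s are excluded from all spatial analysis; the
retained active intervals are half-open `[start, end)` with each active
sample contributing one sample period, so active + inactive time equals the
session duration to within one sample.

**Occupancy and rates.** The arena's bounding square is tiled with
2 × 2 cm bins, half-open `[edge, edge + 2)`. Each active sample adds one
sample period to its bin. A bin is valid if it holds at least 200 ms of
sampling *and* overlaps the circular arena; bins wholly outside the wall
are invalid regardless of (jitter-induced) occupancy. Each spike is placed
at the linearly interpolated position at its time (nearest-sample
assignment is available via `pipeline_config(interp = "nearest")`); per-bin
rate is spike count over occupancy time.

**Smoothing.** "Radius 2" smoothing is read as 2 *bins* (4 cm) — the
plausible alternative reading, 2 cm, would span a single bin and do almost
nothing. The kernel is a flat disk (13 bins at radius 2), renormalized over
the valid bins actually present so the arena wall and unvisited holes do
not bleed zeros inward. Invalid bins stay invalid. A truncated Gaussian
(σ = 1 bin) is available behind `pipeline_config(kernel = "gaussian")`.
One subtlety worth recording: mask-renormalized mean filters preserve a
constant map exactly and never leave the input's `[min, max]` range, but
they conserve the *global* valid-bin mean only approximately near the
boundary (interior bins exactly); on full 32 × 32 grids the discrepancy is
well under 1% and is tested at that tolerance.

## Per-cell metrics

**Fields.** A place field is a connected component of valid bins firing
above 30% of the map's maximum, with area strictly greater than 10 bins.
"Adjacent" is read conservatively as 4-connectivity (orthogonal
neighbours); 8-connectivity is a config switch. Detection runs on the
smoothed map, mirroring the display pipeline; the companion "active pixel"
count — valid bins above the same fractional threshold on the *unsmoothed*
map, with no contiguity requirement — is reported separately because the
two measures answer subtly different questions (contiguous field extent vs
total active area).

A consequence of the fractional threshold deserves emphasis: it is
*relative*. Any unit that fires at all has a maximum, and for a spatially
untuned unit the 30%-of-max set covers a large, connected part of the
arena. The inclusion rule "a place cell is a unit with at least one field
in at least one session" (`classify_place_cell()`, `filter_place_cells()`)
is therefore permissive: it excludes silent and near-silent units but not
diffusely firing ones. The quantities that actually separate tuned from
untuned units are spatial information and the specificity ratio, and the
group comparisons in this package are run on those.

**Spatial information.** Skaggs information per spike,
`Σ p_i (λ_i/λ̄) log2(λ_i/λ̄)`, computed on the *unsmoothed* normalized map
by default: smoothing correlates neighbouring bins and inflates apparent
information. (`pipeline_config(si_smoothed = TRUE)` switches.) Zero-rate
bins contribute zero; a cell with no spikes in valid bins has undefined
information and is flagged missing rather than zeroed. The implementation
is checked to 1e-12 against an independent term-by-term summation, and
against the analytic values 0 (uniform firing) and log2(N) (all firing in
one of N equally occupied bins).

**Specificity.** In-field over out-field mean firing rate, both
occupancy-weighted — i.e. the rates an observer would measure during time
spent in vs out of the field. The weighting is a choice (an unweighted bin
mean is equally defensible); time-weighting was chosen because it makes
the ratio independent of how finely the out-field area is binned.
Undefined ratios (no fields, no out-field bins, zero out-field rate) are
flagged and excluded from group statistics.

## Stability

Stability is the Pearson correlation over bins valid in *both* maps, with
at least 20 shared bins required (degenerate correlations on a handful of
bins are noise; the threshold is logged when it bites and the score is
missing, not zero). Within-session stability splits the session into
half-open equal-duration halves or quarters and rebuilds the *entire*
pipeline per segment — speed filter, occupancy, validity mask, smoothing —
because a bin validly sampled in one half is often unsampled in the other;
correlations use the mask intersection. Quarters are compared as the three
adjacent pairs by default (all six pairs via `quarter_pairs = "all"`).
Between-session stability correlates full-session smoothed maps of the
same unit across the two sessions of a day, labelled by cue condition
("full-full" for sessions 1–2, "full-probe" for 3–4). Smoothed maps are
used on both sides; the main alternative (unsmoothed) lowers all
correlations roughly uniformly without changing group contrasts.

## Group statistics

`mann_whitney_u()` reports `U = min(U1, U2)` with midrank ties; the
two-tailed p is exact (null permutation distribution) when there are no
ties and `n1*n2 ≤ 400`, otherwise a tie-corrected normal approximation
with continuity correction. `anova2()` fits `value ~ A * B` and reports
Type-II sums of squares, chosen because per-cell session data are
inherently unbalanced (cells drop in and out across sessions); on balanced
designs Type-II reduces to the classical decomposition, which the tests
verify to 1e-10 by hand-computed sums of squares. Observations are treated
as independent cells, matching the degrees of freedom convention of
per-cell analyses in this literature; aggregating to per-animal means
before testing is the conservative alternative and is a one-line
`dplyr::summarise()` on the metrics table. `bonferroni_pairs()` contrasts
the two groups within each stratum using the pooled ANOVA residual
variance and multiplies p by the number of comparisons (capped at 1).

## The synthetic session generator

The generator exists so that every stage above is testable with known
ground truth; it emulates the study conditions, not any particular
dataset.

**Trajectory.** A mean-reverting 2-D velocity process: velocity relaxes at
rate `speed_relaxation` (2 s⁻¹) toward `mean_speed` (5 cm/s) along the
current heading while isotropic noise (`speed_noise`, 4 cm s⁻¹ √s⁻¹)
diffuses the heading; the wall reflects specularly, and a small outward
radial acceleration (`wall_bias = 0.1` of a 30 cm/s² full scale)
reproduces thigmotaxis. These four numbers were calibrated once, jointly,
so that a default 30-min session yields a median active-sample running
speed of ≈ 5.8 cm/s and a mean distance from the arena centre of ≈ 25 cm —
the values reported for freely exploring mice in this paradigm — and were
not revisited afterwards. Position samples at 25 Hz, every sample strictly
inside the wall, bit-reproducible from the seed.

**Spikes.** Each unit is a sum of Gaussian place fields over a uniform
baseline; spike trains are drawn by thinning a homogeneous Poisson process
at the rate bound `baseline + Σ peaks`, which is exact up to the linear
interpolation of position between tracking samples (40 ms — negligible at
these speeds relative to 4–12 cm field widths). Within-session instability
is modelled as linear translation of each field centre at `drift_rate`
(cm per 15 min, so a half-session displacement is half the number), the
simplest monotone mechanism; each session draws a fresh drift direction
and restarts from the unit's base centre.

**Profiles.** `default_profiles()` encodes two phenotypes as parameter
distributions (clamped normals). The stable/specific profile: σ ~ 5 ± 1 cm
fields, 12 ± 3 Hz peaks, 0.5 ± 0.2 Hz baseline, drift 1 ± 0.5 cm/15 min.
The drifting/broad profile: σ 7.5 ± 1.5 cm, peaks 9 ± 3 Hz, baseline
1.0 ± 0.3 Hz, drift 5 ± 1.5 cm/15 min. Three knobs carry the group
contrast — field width (area), peak-to-baseline ratio (specificity,
information) and drift (stability) — and their directions match the
impaired-phenotype ordering; the magnitudes are round numbers chosen a
priori from typical CA1 tuning values, not fitted to any dataset. Cells
keep their tuning across the four-session protocol; in the probe session a
`remap_on_probe` fraction (default 0.25, a modelling choice — the
experimental literature gives no number) of units redraws its field
centres.

**What the generator does not emulate.** Theta modulation and phase
precession, rate remapping, over-dispersion of spike counts, correlated
noise between simultaneously recorded cells, tracker dropouts, and
cluster-quality artefacts beyond a 1-D drifting feature series
(`simulate_feature_drift()`, used to exercise the 3-SD cluster-drift QC).
Passing tests on synthetic cohorts therefore demonstrate that the
*pipeline* recovers planted structure correctly — not that real data obey
the model.

## Numerical and edge-case conventions

- Bin intervals are half-open; spike and sample assignment is
  deterministic at edges. Temporal segments are half-open with the last
  segment closed, so splitting partitions samples and spikes losslessly.
- Undefined quantities (information with zero mean rate, specificity with
  no out-field, correlations with < 20 shared bins or a constant map) are
  `NA` with a machine-readable `reason`, never silently 0.
- The cluster-drift statistic is the absolute difference between last- and
  first-decile feature means in pooled within-decile SD units; it is
  invariant to affine rescaling, and a zero difference is "no drift" even
  when the pooled SD is zero. A 0/0 never raises an error.
- Pyramidal-cell classification (rate ≤ 8 Hz and mean autocorrelogram lag
  ≥ 8 ms within 50 ms) is a surrogate for waveform-based criteria; a
  maximally bursty unit with all its autocorrelogram mass at 2–5 ms can
  fall below the lag threshold, which is documented behaviour, and the
  thresholds are configurable.
- The Mann-Whitney exact/approximate switch is at `n1*n2 = 400`; midranks
  and the tie-corrected variance are always used in the approximation.

## Problem sizes used in the tests

The test-suite simulations use the smallest sizes at which each property
is stable: single sessions of 10–30 min for per-cell checks, 20 cells × 5
seeds per drift level for the drift–stability monotonicity, and ten
replicate cohorts of 2 profiles × 3 animals × 20 cells × 4 × 30-min
sessions for the phenotype contrast — a deliberate scale-down from a full
experiment (5 animals per group, several experiments each), sized so the
group contrasts are tested at realistic per-group cell counts (60) rather
than at the asymptote.

## Known limitations

- No adaptive-binning or kernel-density rate estimation; no rotational
  alignment search before between-session correlation (plain pixel
  correlations only).
- Field analytics stop at area, peak and centroid — no shape descriptors,
  no multi-session field tracking beyond unit identity.
- The statistics layer deliberately omits mixed-effects models; cells are
  the unit of analysis unless the user aggregates per animal first.
- Field-size units are bins and cm² only; reported field sizes are not
  comparable across different bin sizes without rescaling.
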