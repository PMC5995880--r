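# ratemapr

Tidyverse-native analysis of hippocampal place-cell recordings in open-field
arenas. The package covers the full path from raw tracking and sorted spike
times to group-level statistics: speed filtering, occupancy-normalized and
smoothed firing-rate maps, place-field detection, spatial-information and
specificity metrics, within- and between-session stability correlations, and
the inferential layer (Mann-Whitney U, two-way Type-II ANOVA with Bonferroni
contrasts). It is aimed at electrophysiologists comparing spatial coding
between groups — e.g. a knockout line against wildtype littermates across
repeated exploration sessions with a cue-removal probe.

Because real tetrode datasets of this kind are rarely shared, the package
ships a synthetic session generator (smooth mean-reverting-velocity
trajectories in a 64-cm circular arena, inhomogeneous-Poisson place-cell
spike trains with Gaussian tuning and controllable within-session field
drift, and two genotype-style tuning profiles) so every pipeline stage is
testable end to end without any recorded data.

## The metrics

For a map with occupancy probability `p_i` and firing rate `λ_i` in bin `i`
(2 × 2 cm bins, bins with < 200 ms of sampling excluded, inactivity below
3 cm/s removed first):

- **Skaggs spatial information per spike**:
  `I = Σ_i p_i (λ_i/λ̄) log2(λ_i/λ̄)` with `λ̄ = Σ_i p_i λ_i` (bits/spike).
- **Place fields**: connected components (4-connected) of valid bins with
  rate above 30% of the map maximum, keeping components larger than 10 bins;
  detection runs on the disk-smoothed map (radius 2 bins), and an
  `active-pixel` count on the unsmoothed map is reported alongside.
- **Specificity ratio**: occupancy-weighted mean in-field rate divided by
  the occupancy-weighted mean out-field rate.
- **Stability**: Pearson correlation across bins valid in both maps, for
  session halves, adjacent quarters, and same-day session pairs
  (full-cue vs probe).

## Worked example

Simulate a 30-min session, one place cell with a field at (10, 5) cm
(σ = 6 cm, 15 Hz peak over a 0.5-Hz baseline), and run the pipeline:

```r
library(ratemapr)

tr  <- simulate_trajectory(duration = 1800, seed = 3)
tun <- place_tuning(field_centers = matrix(c(10, 5), 1, 2), field_sigma = 6,
                    peak_rate = 15, baseline_rate = 0.5)
st  <- simulate_place_cell(tr, tun, seed = 11)

sp  <- compute_speed(tr)
iv  <- filter_inactive(tr, sp, threshold = 3)
occ <- compute_occupancy(tr, iv)
rm0 <- compute_ratemap(restrict_spikes(st, iv), tr, occ)
rms <- smooth_ratemap(rm0)
rms
#> <rate_map> 32x32 bins (2 cm), 804 valid, smoothed; max 12.43 Hz, mean 0.88 Hz

detect_fields(rms)[, c("area_bins", "area_cm2", "peak_rate",
                       "centroid_x", "centroid_y")]
#> # A tibble: 1 × 5
#>   area_bins area_cm2 peak_rate centroid_x centroid_y
#>       <int>    <dbl>     <dbl>      <dbl>      <dbl>
#> 1        77      308      12.4       11.0       5.21

spatial_information(rm0)          # 1.232 bits/spike
specificity_ratio(rms, detect_fields(rms))   # 11.08

rec <- session_recording(tr, tibble::tibble(unit_id = "u1", t = st))
within_session_stability(rec, "u1", kind = "halves")
#> # A tibble: 1 × 5
#>       r kind   pair_label n_shared_bins reason
#>   <dbl> <chr>  <chr>              <int> <chr>
#> 1 0.915 halves S1H1-S1H2            586 <NA>
```

The detected field sits on the planted centre, its 77-bin (308 cm²) extent
is the 30%-of-peak contour of the smoothed bump, the cell carries
1.23 bits/spike, fires ~11× faster inside its field than outside, and its
two half-session maps correlate at r = 0.92 — a stable, specific place
cell. Setting `drift_rate` in `place_tuning()` degrades that correlation;
the KO-like profile in `default_profiles()` does this (plus broader fields
and higher baseline) cohort-wide.

Cohort-level use goes through `simulate_cohort()` (or `read_session()` on
your own CSVs), `analyze_cohort()`, `filter_place_cells()`,
`panel_summary()`, `anova2()`/`tidy()` and `bonferroni_pairs()`;
`autoplot()` on maps, `plot_trajectory()` and `plot_panel_summary()` cover
the standard figures.

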