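# drivecb

Coding and analysis of change-detection experiments embedded in simulated
driving, for researchers studying change blindness, visuospatial
complexity and attentional strategies with head-mounted eye tracking.

A participant drives through three urban environments of increasing
visuospatial complexity (low / medium / high, traversed in a group-specific
order) while 72 scripted changes occur in 36 pairs along the route: each
pair holds one *behaviour change* of a road user (behaviour-relevant or
behaviour-irrelevant to the driving task) followed, after a gap of 0, 1,
2, 4, 6 or 8 s, by one *property change* of a static object. Detections
are reported with two steering-wheel buttons (right = behaviour,
left = property). The package turns the session logs — gaze at 120 Hz,
driving telemetry, button presses, the change schedule and the
time-indexed 3D geometry of each change's area of interest (AOI) — into a
validated per-change outcome table and the derived analyses.

What it computes:

* **Fixations** by spherical I-DT: maximal windows whose maximum pairwise
  angular separation stays below a threshold (default 1.0°, range
  0.7–1.3°) for 100–500 ms; long windows split, blinks never bridged.
  The window kernel is compiled (Rcpp) and test-proven equivalent to an
  exhaustive brute-force oracle.
* **AOI dwell**: a fixation lands when its centroid is within
  `atan(radius / distance)` of the head→AOI direction; dwell is clipped
  to the half-open window `[trigger − 4 s, trigger + 4 s)` and binned
  into eight 1 s event-aligned bins.
* **Response coding**: C1 (matching button side) + C2 (before the next
  same-side change), screened by a reaction-time cutoff of
  mean + 3 SD pooled across the cohort (or the conventional fixed 4.1 s);
  presses are attributed once or logged as false alarms.
* **LBFTS errors** (looked-but-failed-to-see): misses with ≥ 100 ms AOI
  dwell in both the pre and post window; both denominators (both-window
  gazers and all changes) are reported.
* **Derived tables**: detection rates by any crossing of participant ×
  type × complexity × gap, rate-of-change slopes between complexity
  levels, driving metrics (time-weighted speed, completion time, brake
  rising edges), temporal-proximity and first-vs-last-segment learning
  comparisons.
* **Inference**: one-way and factorial ANOVA with partial eta squared
  (`SS_eff / (SS_eff + SS_err)`), paired t with Cohen's d
  (`mean(diff)/sd(diff)`), Tukey HSD and Bonferroni post hocs —
  participant-level cell means as the unit of analysis.

A synthetic-data generator (`simulate_cohort()`) emulates the full study
design with known ground truth so every stage is testable without human
data; see the methods vignette (`vignettes/change-detection-driving.Rmd`)
for the generative model and its limits.

## Worked example

```r
library(drivecb)

res <- run_pipeline(pipeline_config(n = 2, seed = 5))
res
#> <cb_report> 2 participants, 144 coded changes; cutoff 4.880 s (derived)
#>   overall detection rate: 58.3%

res$cutoff
#> <cb_cutoff> 4.880 s (derived, n = 86); 83.2% of presses inside / 16.8% outside the window

res$detection_by_complexity
#> # A tibble: 3 x 4
#>   complexity     n n_detected rate_pct
#>   <chr>      <int>      <int>    <dbl>
#> 1 high          48         20     41.7
#> 2 low           48         33     68.8
#> 3 medium        48         31     64.6
```

The cutoff line says the mean + 3 SD rule, derived from the 86 matched
reaction times of this small cohort, lands near 4.9 s, and what fraction
of all presses fall inside that legitimate window. The detection table
shows the expected monotone cost of visuospatial complexity (the
generator's default detection probabilities decrease with complexity).
`res$outcomes` holds one row per participant × change with detection, RT,
gaze category, pre/post AOI dwell and the LBFTS flag; `res$lbfts`,
`res$temporal_proximity`, `res$learning`, `res$driving` and `res$stats`
hold the derived tables and tests. Setting `out_dir` in
`pipeline_config()` writes all tables as CSV plus a markdown report, and
`inst/cli/drivecb.R` wraps simulate / process / report for shell use.

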