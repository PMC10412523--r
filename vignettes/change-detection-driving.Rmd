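---
title: "Coding and analysing change detection during simulated driving"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding and analysing change detection during simulated driving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

drivecb implements the behavioural coding pipeline for a change-blindness
experiment embedded in simulated driving. A participant drives through
three urban environments of increasing visuospatial complexity (labelled
`low`, `medium`, `high`) while 72 scripted changes occur along the route —
sudden behaviour changes of road users (further split into
behaviour-relevant and behaviour-irrelevant) and unrealistic property
changes of static objects — and reports them by pressing a right- or
left-side steering-wheel button respectively. The package turns the raw
multimodal logs (gaze at 120 Hz, driving telemetry, button presses, the
change schedule and the time-indexed geometry of each change's area of
interest) into a validated per-change outcome table and the derived
analyses: dwell on AOIs, looked-but-failed-to-see (LBFTS) errors,
event-aligned gaze time-courses, driving metrics, temporal-proximity and
learning effects, with an ANOVA / paired-t inference layer on top.

Because such cohort data are rarely shareable, the package ships a
synthetic-data generator that emulates the study design end to end; every
pipeline stage is exercised against it in the test suite.

## The experimental design as a schedule object

`build_schedule()` lays out one session: 12 pairs of changes per
complexity level (36 pairs, 72 changes), each pair holding one behaviour
change followed by one property change at a gap of 0, 1, 2, 4, 6 or 8 s
(each gap level used six times, twice per level), with at least 10 s
between consecutive pairs and the three complexity blocks ordered per
group (A: medium–high–low, B: high–low–medium, C: low–medium–high).
`validate_schedule()` re-checks all of these invariants and returns any
violations as data, which keeps hand-edited or externally produced
schedules honest.

Two design details are under-determined and were fixed here once: the
behaviour changes are split evenly (6 relevant / 6 irrelevant per level),
the only symmetric choice absent a published inventory; and gap levels are
balanced *within* each complexity level, the stricter of the two readings,
so every gap × complexity cell has the same trial count. Inter-pair
spacing is drawn uniformly from 10–60 s, which keeps a session near
20 minutes at the enforced 30 km/h speed limit.

## Fixation detection (I-DT)

`detect_fixations()` implements dispersion-threshold identification on the
sphere: a window of consecutive unit gaze directions grows while its
dispersion — the **maximum pairwise angular separation**, the spherical
analogue of the classic I-DT extent — stays at or below the threshold, and
the maximal window is emitted when it lasts at least `min_dur_s`.
Tunables, with defaults:

* `dispersion_deg = 1.0`° — the midpoint of the 0.7–1.3° guideline range
  for this headset-mounted tracker class; the range ends are worth
  checking as a robustness pass.
* `min_dur_s = 0.100`, `max_dur_s = 0.500` — the conventional duration
  band. Windows longer than 500 ms are *split* into consecutive fixations
  rather than discarded, preserving dwell time while honouring the bound
  (`split_long = FALSE` disables this). A trailing remnant shorter than
  100 ms is dropped.
* `max_gap_s = 0.050` — invalid samples are excluded, and a window breaks
  wherever the retained stream jumps more than 50 ms, so blinks are never
  bridged but a single dropped frame at 120 Hz (8.3 ms) is.

The window-growth kernel is compiled (Rcpp) and works in cosine space; the
test suite proves it equivalent to an independent brute-force oracle that
recomputes the all-pairs dispersion from scratch for every candidate
window, across 200 random traces of up to 2000 samples.

Ties at the threshold are decided by the `<=` comparison in cosine space;
boundary-equal cases are measure-zero for real data. Fewer than two
samples yield an empty result, not an error; non-monotone timestamps are a
validation error.

## AOI dwell and event-aligned time-courses

A fixation *lands* on an AOI when the angle between its centroid direction
and the head-to-AOI-centre direction is at most `atan(radius / distance)`,
with the AOI centre linearly interpolated at the fixation midpoint — a
membership test on the fixation as a unit, matching the convention that
fixations (not samples, and never saccades) land on targets.
`event_timecourse()` apportions the landing intervals, clipped to the
half-open window `[trigger − 4 s, trigger + 4 s)`, into eight 1 s bins in
milliseconds; bin totals equal the clipped dwell by construction (to
floating-point addition order).

## Response coding

Two buttons disambiguate the change types: right marks behaviour changes,
left marks property changes (C1). A press counts for a change only if it
also precedes the next change *requiring the same side* (C2) — the
same-side reading is forced by the 0 s-gap pairs, where the behaviour and
property change fire simultaneously and only the button side can separate
the two reports. Presses are screened by a reaction-time cutoff of
mean + 3 sample standard deviations, pooled across all subjects and
conditions; coding is two-stage (a preliminary C1 match with a generous
10 s window supplies the RTs, then matching is re-run under the derived
cutoff). All windows are half-open, so a press at exactly
`trigger + cutoff` is outside. Ties break deterministically: earliest
press wins a change, earliest change wins a press; every press is either
attributed once or logged as a false alarm. `cutoff_mode =
"paper_default"` pins the window at the conventional 4.1 s instead of
deriving it.

A change is an LBFTS error when it was missed although AOI dwell reached
100 ms in both the 4 s pre- and post-change windows; the 2 s pre-window
variant is available via `lbfts_config(pre_window_s = 2)`, and LBFTS
tables report both denominators (both-window gazers, the default reading,
and all changes) because published summaries are ambiguous between them.

## The synthetic driver

`driver_params()` collects the generative model; the defaults are the
package's reference cohort conditions:

* **Detection** — a 3 × 3 probability matrix (change type × complexity),
  weakly decreasing in complexity within each type, with the steepest
  medium→high drop for behaviour-irrelevant changes; cohort-level
  detection lands in the mid-50s percent. Property-change detection gains
  `learning_slope` (default 0.002) per encounter, the one place a
  learning effect is modelled.
* **Reaction times** — lognormal(−0.15, 0.75) seconds truncated at 10 s:
  positively skewed, realised mean + 3 SD ≈ 4.1 s, so the derived cutoff
  is meaningfully inside the data. The law is configurable because no
  empirical RT distribution is available to copy.
* **Gaze** — an alternating fixation/saccade renewal process at 120 Hz
  from a static head. Baseline fixations aim at a forward road region
  (alternating sides, ~0.05° within-fixation jitter), durations
  lognormal-truncated to 100–500 ms, at per-complexity rates
  (3.57/2.93/3.18 fixations s⁻¹ for low/medium/high — more, shorter
  fixations under load). For each change an AOI dwell of ≥ 100 ms is
  planted in the pre/post window with type-specific probabilities;
  behaviour-relevant changes get an *anticipatory* onset concentrated
  `anticipatory_lead_s` (1.5 s) before the trigger, and detected property
  changes *linger* with extra dwell near +3 s. Saccade transit is a fixed
  30 ms.
* **Driving** — per-complexity mean speeds 26/25/18 km h⁻¹ under a
  30 km/h limit, brake-press events at 8/6/4 per minute (fewer brake hits
  as complexity rises). The absolute brake rates are a realistic choice,
  not an empirical copy.
* **Noise** — wrong-side presses (2%) and uniform false alarms
  (0.3 min⁻¹).

AOI geometry is synthesised alongside: targets 8–15 m away at 15–35°
azimuth, 1 m radius (≈ 4–7° angular radius), pair members on opposite
sides of the road so their AOIs never overlap and the forward road region
stays clear of both.

What the generator deliberately does **not** emulate: head movement,
smooth pursuit, blinks/invalid samples (the detector's gap handling is
unit-tested directly instead), correlation between gazing and detecting
(dwell and detection are drawn independently, so generator-level LBFTS
closure is exactly `p_pre · p_post · (1 − p_detect)`), visual scene
content, and simulator-sickness or questionnaire responses. Green tests
therefore certify the *pipeline mechanics* on data with known structure —
not that real cohorts obey these laws.

## Calibration and recovery checks

The suite ties the layers together at desk scale (sizes chosen to keep the
default test run in minutes):

* *Parameter recovery*: 50 replicates of an 80-participant press-only
  cohort with known per-cell detection probabilities (0.2/0.5/0.8 mixed
  across cells); the pipeline estimate must fall in the exact binomial
  95% interval of the truth in ≥ 90% of replicates for every cell. This
  check fixes the cutoff at the RT truncation bound (10 s) and silences
  wrong-button/false-alarm noise so the estimate is a clean binomial —
  with a derived mean + 3 SD cutoff, the ~1–2% of true detections beyond
  the cutoff would bias the estimate by design, which is the coding rule
  working as intended, not an estimation failure.
* *Learning*: a slope of 0.004 per encounter on property changes must be
  picked up by the first-versus-third-segment paired comparison, and flat
  parameters must not be.
* *Type-I calibration*: under 1000 null simulations the one-way ANOVA,
  the factorial ANOVA and the paired t all keep their empirical α within
  [0.035, 0.065] at nominal .05.

## Statistics conventions

The unit of analysis is the participant: per-participant cell means feed
the ANOVAs (trial-level tables are available but are not the default),
partial eta squared is `SS_effect / (SS_effect + SS_error)`, paired
Cohen's d is `mean(diff) / sd(diff)`. Factorial designs are balanced by
construction, where Type I/II/III sums of squares coincide. Degenerate
inputs have defined behaviour: identical paired vectors return a null
result (t = 0, d = 0, p = 1), while zero-variance differences with a
nonzero mean are rejected as degenerate rather than reported as infinite
evidence.

## Known limitations

The on-disk session format is this package's own (CSV streams + JSON
metadata); raw eye-tracker exports must be converted upstream. The
dispersion metric is the spherical max-pairwise extent — device guidelines
sometimes mean per-axis rectangles, which is why the threshold is
configurable across 0.7–1.3°. Dwell apportioning is exact only up to
floating-point addition order. The learning comparison equates "session"
with complexity segment (first vs third), the only reading compatible
with a three-block route.
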