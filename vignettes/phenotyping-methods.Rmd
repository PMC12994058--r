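---
title: "Methods: percentile-threshold phenotyping of stress-exposed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: percentile-threshold phenotyping of stress-exposed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresspheno)
```

## The model

`stresspheno` treats stress phenotyping as a nonparametric classification
problem anchored entirely in reference distributions observed in the same
experiment. No distributional form is assumed for any behavioral variable;
every decision boundary is an order statistic of either the unshocked
control (No-FS) group or the foot-shocked (FS) group, so the procedure is
invariant to monotone measurement rescaling and can be replayed from the
threshold audit alone.

Eight variables, two per test, are scored 0 ("adapted") to 3 ("severely
altered"):

| test (day) | variables | rule |
|---|---|---|
| novel context (D16) | % freezing, % escaping | `FS_TAIL` |
| novel object (D16) | % freezing, % escaping | `FS_TAIL` |
| elevated-plus maze (D18) | % open-arm time, open-arm velocity | `BIDIRECTIONAL` |
| air-puff startle (D23) | amplitude ratio, latency-to-peak ratio | `STARTLE_RATIO` |

The composite severity score is the sum of the eight scores (0–24). The
day-14 cue-reminder freezing/escaping scores (also `FS_TAIL`) enter only
the intrusion radar domain; day-28 full-context behavior drives the second
classification step; the pre-stress open-field variables are carried for
baseline comparisons and never scored.

### Percentiles

All percentiles use sorted linear interpolation with inclusive endpoints
(fractional rank $1 + (n-1)p/100$), i.e. the type-7 sample quantile. The
method is fixed once so that thresholds, sleep scores and activation
scores are all derived by the same estimator; `pctl()` is the single
implementation.

### Score maps, tie-breaks and degenerate references

*`FS_TAIL`.* Control values for the conditioned-fear and neophobia
variables cluster near zero and cannot grade severity, so score 0 is
"within the control range" (≤ control P95) and scores 1–3 are cut at the
FS P75 and P95. Cuts are clamped monotone (`cummax`) if the FS tail lies
below the control P95. Values exactly on a cut take the lower-severity
score.

*`BIDIRECTIONAL`.* Open-arm time and velocity have an adverse (anxious)
and a protective (risk-taking) direction. With control statistics
$\{\min, P5, P25, P75, P95\}$, the map on the adverse side is: inside
$[P25, P95]$ → 0, $(P5, P25)$ → 1, $[\min, P5]$ → 2, below the control
minimum → 3; protective deviations beyond P95 score 1, capped there. The
cap encodes that risk-taking is atypical but not graded as severe
pathology. This concrete map is a package decision: the source convention
("opposing behaviors scored in opposite directions relative to 0") fixes
the anchors but not the full map, so we chose the one that preserves
0 = adapted and monotone severity along the adverse direction.

*`STARTLE_RATIO`.* Hyperarousal gates are fixed constants, inclusive on
the hyperarousal side exactly as printed: amplitude ratio ≥ 0.95 and
latency ratio ≤ 1.05 score at least 1. Scores 2/3 are cut at the control
median and P75 (amplitude) or median and P25 (latency) beyond the gate.
When a control statistic falls on the habituated side of its gate the cut
is clamped onto the gate; in that regime the map can jump from 1 to 3 with
no occupied score-2 band. This degeneracy is inherent to combining a fixed
printed gate with cohort-dependent percentiles and is surfaced in the
threshold audit rather than hidden by re-deriving the gate.

*Missing data.* A non-finite value scores `NA`, and any missing composite
component voids the composite: the animal is excluded (complete-case
analysis) and listed in `fit$excluded`. No imputation is attempted.

### Two-step classification

The susceptibility cut-off is the **maximum control composite**,
recomputed from the supplied controls on every fit. A composite strictly
above the cut-off is susceptible; equality is resilient, because the
cut-off is itself a control value and controls must remain
non-susceptible. Step 2 is escape-primary: one escape attempt (wall climb
or jump) on day 28 makes an escaper, regardless of freezing, because the
attempt criterion is the stated discriminator; the control P95 of day-28
freezing is retained as QC metadata only, and a susceptible animal with
neither high freezing nor any attempt is a freezer carrying the
`low_freezing_no_escape` flag.

## Sleep module

Hypnograms are sequences of `WAKE`/`SWS`/`REM` in 5-s epochs. Design
choices:

- **Episode** = maximal run of identical epochs, no smoothing. A
  `merge_gap_epochs` option exists (bridging interruptions up to a set
  length) but defaults off: the unsmoothed rule is the simplest auditable
  one.
- **Onset latency** = start, in minutes from the recording origin, of the
  first episode lasting ≥ 25 s (5 epochs). Baseline recordings originate
  at lights-on, day-14 recordings at the cue exposure; both coincide with
  epoch 1 of the file. When no qualifying episode exists the latency is
  `NA` and the animal is excluded from latency group statistics; for radar
  scoring such an animal takes the maximal latency score of 3 (never
  entering the state is the extreme of impaired entry).
- **Conservation.** State percentages are `100 k / n` on epoch counts and
  sum to 100 up to double-precision rounding (≤ 1e-9); episode count ×
  mean duration reproduces total state time the same way.
- **Radar scores.** Each of latency, episode count, percent time and mean
  duration is scored 0–3 against the control distribution with the
  bidirectional map; entry = latency + episodes, continuity = percent +
  duration, each 0–6. The adverse direction is fixed as longer latency,
  fewer episodes, less time, shorter episodes for both sleep states. This
  direction convention is a package decision (the source never states
  one); under it a *higher* entry score means *worse* entry. Wake is not
  radar-scored.
- **Classifier.** The rule-based epoch classifier mirrors the standard
  spectral signatures: EMG above `emg_wake` (default 3, in the units of
  the feature table) → WAKE; otherwise theta/delta above `rem_theta_delta`
  (default 2) → REM; else SWS. The defaults sit at the geometric gaps of
  the generator's documented state means (wake EMG 10 vs sleep ≈ 1; REM
  theta/delta ≈ 4.7 vs SWS 0.25). It is a transparent stand-in for full
  polysomnographic scoring, adequate when the features separate well, and
  is evaluated against generated ground truth rather than assumed correct.

## Imaging module

Detection is smoothing (Gaussian, σ = 2 px) → threshold → local maxima
(minimum distance 5 px) as seeds → seeded region growing over the binary
mask → area filter (≥ 9 px²). The threshold defaults to a per-image
quantile (0.99) combined with a robust background guard
(median + 6 × MAD of the smoothed image): the quantile adapts to staining
intensity while the guard ensures a signal-free image produces no
objects. All parameters are recorded in the `spot_params` object. Nuclei
are c-Fos⁺ when their footprint overlaps the c-Fos mask (per-pixel AND;
any overlap by default, a fraction is configurable). Objects are assigned
to the ROI containing their centroid; densities are counts per mm² from
the ROI pixel area and the supplied pixel size (µm/px). Per-animal
regional values are medians over up to three slices, flagged when fewer
than three are available.

Activation scores use one-sided cuts at the control {median, P75,
maximum}: activation below the control median is "control-like" (0) and
only elevations are graded, so the control P25 plays no role under this
one-sided reading. Combined scores are BLA = BA + LA, CeA = CeL + CeM and
the anterior + posterior dorsal/ventral PAG columns, each 0–6. ROIs are
supplied as label masks — atlas registration and PKC-δ-based CeL
delineation are upstream of this package — and left/right structures are
distinct ROI labels.

## Statistics

Group comparisons wrap the standard nonparametric tests: tie-corrected
Kruskal–Wallis (omnibus, all four phenotypes), Friedman for repeated
measures (complete cases only), Wilcoxon signed-rank against a
theoretical value (habituation ratios vs 1), and Spearman rank
correlation. Significance is p < 0.05 with a (0.05, 0.07] trend
annotation. Post hoc pairwise comparisons attach only when the omnibus
test is significant; the method is Dunn's rank z comparisons with the
pooled tie-corrected variance, unadjusted by default with an optional
Holm flag — the original analyses used a commercial package whose post
hoc procedure is unstated, so our choice is logged in the report rather
than attributed. Signed-rank p-values are exact for n ≤ 25 without ties
or zero differences and use the continuity-corrected normal approximation
otherwise; ties therefore always take the approximation, which the test
suite verifies against full sign-pattern enumeration on the exact branch.

## The synthetic cohort

The generator exists so that every stage has a testable input with known
truth. It emulates:

- a 4-group cohort (defaults NoFS 16, Res 11, Frz 13, Esc 7) with
  truncated-normal percentages on [0, 100], log-normal velocities and
  ratios, and zero-inflated shifted-Poisson escape counts — freezers
  freeze in novel settings and avoid open arms, escapers escape and fail
  to habituate to the startle stimulus, resilient animals are control-like
  on non-conditioned tests but freeze strongly to the day-14 cue;
- first-order Markov hypnograms at 5-s resolution with REM reachable only
  from SWS; the day-14 resilient matrix raises SWS→REM entry and REM
  maintenance, planting the resilient-specific post-stress REM increase
  (and hence a negative REM-vs-composite correlation across the cohort);
- state-conditional log-normal epoch features; and Gaussian-profile
  two-channel images with planted spot lists, including overlapping spots
  as watershed fixtures.

Reproducibility uses one master seed with per-animal substreams
`(seed + 104729·i + 7919·stream) mod (2³¹−1)`, so single animals can be
regenerated without rerunning the cohort.

It does **not** emulate: within-animal correlations between tests beyond
group membership, circadian structure or ultradian cycling in the sleep
chain (transition probabilities are time-homogeneous), raw EEG/EMG
waveforms, measurement artefacts (tracking dropouts, staining gradients),
females or estrous effects, or longitudinal drift across test days.
Passing the recovery tests therefore shows the pipeline is correct and
well-calibrated under its own assumptions — not that those assumptions
hold for any particular real dataset.

Default archetype parameters are package constants chosen once to
reproduce the qualitative group orderings described above at realistic
effect sizes; they are documented in `default_behavior_params()` and
friends and are not estimates of any published dataset.

## Problem sizes and numerical tolerances

The test suite exercises: oracle equivalence on ≥ 10⁴ random
value/threshold pairs and ≥ 10³ instances per rank statistic; phenotype
recovery on 200 synthetic animals (50 per archetype); one 24-h recording
(17,280 epochs) for the classifier and a 10-day simulation for the
stationary-distribution check (tolerance 2 percentage points, absolute);
512×512 px images with 50–60 planted spots (exact recovery noise-free,
≤ 5% error at noise SD 20% of peak). Floating-point identities
(percentage sums, time conservation) are asserted at 1e-9–1e-12;
rank-statistic oracles at 1e-9; percentile oracles at 1e-12.

## Known limitations

- Threshold classification is unstable for animals near the cut-off; at
  small cohort sizes a few boundary crossings between resilient and
  susceptible are expected and visible in the worked example.
- The composite cut-off is a sample maximum and hence noisy in small
  control groups; it grows with control n, making step 1 conservative in
  large cohorts.
- The startle score-2 band can be empty when control habituation is
  strong (see above).
- The epoch classifier is not a substitute for validated vigilance-state
  scoring on real recordings with overlapping feature distributions.
- Activation scoring assumes ROI masks are correct; segmentation errors
  propagate directly into densities.
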