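---
title: "Scoring dyadic stag-beetle behaviour from pose tracks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dyadic stag-beetle behaviour from pose tracks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagpose)
```

## The measurement problem

Markerless pose estimation turns video of two interacting beetles into
per-frame coordinates for five labelled body parts per individual —
labrum, left mandible, right mandible, scutellum, abdomen — each with
an estimation likelihood. `stagpose` converts those trajectories into
thirteen behavioural endpoints per individual per 10-minute trial,
pairwise aggression indices, and multivariate summaries. Every
endpoint is a deterministic function of inter-body-part distances, so
the whole pipeline is auditable: no classifier, no hidden state.

The endpoint definitions are distance thresholds on specific part
pairs:

* **Mandible extension (display)** — the gape, i.e. the distance
  between an individual's left and right mandible, strictly exceeding
  0.5 cm. Stag beetles raise and spread their mandibles as a threat
  display, so time-above-threshold is a display measure.
* **Mandible contact (fighting)** — the minimum over the four
  cross-individual mandible pairs strictly below 3 cm. Grappling
  necessarily brings opposing mandibles together.
* **Chasing (pursuit, directional)** — the chaser's labrum within the
  proximity threshold of the chased individual's abdomen. The
  definition is inherently directional; `chase(i, j)` and
  `chase(j, i)` are different series, and the pair-level endpoint is
  the per-frame OR of the two directions.
* **Interaction** — the minimum over all 25 cross-individual part
  pairs below the proximity threshold; unlike contact it is not
  restricted to mandibles.
* **Locomotion** — total path length and average speed of a reference
  point, the per-frame partition of instantaneous speed into
  freezing / normal / rapid, and thigmotaxis (time within a band of
  the arena walls).

Ratios are percentages of *valid* observation time for that series;
"longest" endpoints are the maxima over bouts (maximal runs of
predicate-true frames).

## Coordinate conditioning

Raw estimates pass three stages:

1. **Likelihood cutoff** (`pcutoff`, default 0.6): any sample with
   likelihood below the cutoff becomes missing. The boundary is
   inclusive-keep (likelihood exactly at the cutoff is retained); the
   convention is documented because it is testable, not because the
   choice matters at realistic noise levels.
2. **Gap interpolation** (`max_gap_frames`, default 10): interior
   missing runs of at most 10 frames (0.4 s at 25 fps) are filled
   linearly per coordinate. Longer runs, and leading/trailing gaps,
   stay missing — fights frequently occlude mandibles for seconds at
   a time, and inventing coordinates through a grapple would corrupt
   exactly the endpoints that matter most. Interpolated values can
   never leave the segment between their two anchors.
3. **Calibration** (`px_per_cm`): a single isotropic scale, supplied
   by the user from their own arena calibration. The default assumes
   the 13-cm arena width spans the full 1024-px frame
   (78.77 px/cm). Geometry downstream uses distances only, so image
   orientation (origin top-left, y down) needs no correction.

Frames invalid for a series are excluded from both numerator and
denominator of that series' ratio, so different endpoints can have
different denominators; the denominator is reported beside every
value.

## Parameters and defaults

| key | default | units | rationale |
|---|---|---|---|
| `pcutoff` | 0.6 | — | standard conditioning cutoff for this assay |
| `max_gap_frames` | 10 | frames | 0.4 s at 25 fps; occlusions longer than this are not bridged |
| `gape_thr_cm` | 0.5 | cm | extension threshold; strict `>` ("exceeding") |
| `contact_thr_cm` | 3.0 | cm | fighting proxy; strict `<` ("below") |
| `chase_thr_cm` | 3.0 | cm | not separately established; the contact threshold is the only printed proximity scale, reused |
| `interaction_thr_cm` | 3.0 | cm | same reasoning |
| `freeze_thr_cm_s` | 0.1 | cm/s | speed-bin convention (three-bin partition); no published value exists for this assay |
| `rapid_thr_cm_s` | 2.0 | cm/s | as above |
| `band_cm` | 1.5 | cm | thigmotaxis band, about one beetle body-width |
| `merge_gap_frames` | 0 | frames | no debouncing by default |
| `min_bout_frames` | 1 | frames | as above |
| `reference_part` | scutellum | — | thorax centre; most stable landmark of the skeleton |

Both strict inequalities follow the verbal definitions of the
thresholds ("exceeding", "below"); the boundary convention is
asserted by tests. Speed-class thresholds and the chase/interaction
thresholds are package defaults, not published constants, which is
why they are echoed into every output table: any figure built from
the tables carries its own provenance. `fps` has no silent default in
the command-line tool because every time-denominated endpoint depends
on it; the R API defaults to 25 fps in `trial_meta()`.

The reference point for locomotion is the scutellum; when it fails
the cutoff the centroid of the remaining valid parts substitutes, and
a frame with no valid part is invalid. Movement classification is
per-frame with no minimum duration, keeping the endpoint a pure
ratio; users who want debounced freezing bouts can run
`bouts_from_mask()` on the labels.

## Aggression indices

For a dyad with endpoint values \(x_A, x_B \ge 0\) the index is

\[ I_{AB} = \frac{x_A - x_B}{x_A + x_B} \in [-1, 1], \]

computed per trial for four endpoints: extension percentage, freezing
time, total distance ("relative movement distance") and directional
chasing percentage. The denominator is the pair sum, not a cohort
sum — the index of a pair should not change because other pairs
behaved differently. When neither individual expressed the behaviour
the index is reported as 0 and flagged degenerate rather than NA, so
cohort means stay defined; the flag lets users drop those trials.
Species-level summaries are means of per-trial indices with s.e.m.
over trials, not indices of summed endpoints, so every trial carries
equal weight. The relative-distance index is computed from each
individual's total distance travelled; mean inter-individual
proximity is a defensible alternative reading and can be obtained by
supplying a custom endpoint mapping to `build_index_table()`.

## Multivariate summaries

The observation unit is the pair-trial: per-individual endpoints are
averaged within a trial (pair-symmetric endpoints pass through
unchanged), matching the design in which each point of an ordination
is one dyad. Per-individual matrices are available via
`endpoint_matrix(unit = "individual")`.

Columns are z-scored before PCA and clustering. The endpoint battery
mixes percentages, seconds and centimetres; unscaled, total distance
(hundreds of cm) would dominate every component. This is a declared
choice — analyses that skip scaling will produce different variance
fractions. Clustering is agglomerative with Euclidean distance and
average (UPGMA) linkage; robustness is assessed by mean silhouette
width at cuts k = 2…8. Correlations against morphology (mandible
length, body length) are plain Pearson coefficients with pairwise
complete observations; zero-variance series yield missing entries
rather than errors.

## The trajectory simulator

The generator exists so that every pipeline stage can be tested
without video. It emulates the study conditions: two individuals,
five parts each, a 13 × 8 cm arena imaged at 1024 × 768 px, 600-s
trials at 25 fps, keypoint jitter, and likelihood dropouts below the
0.6 cutoff (retained samples draw likelihood uniformly from
[0.6, 1], dropped samples from [0, 0.6)).

Behaviour is a semi-Markov state machine — explicit dwell-time
distributions per state, so longest-bout endpoints have controllable
ground truth. Solo states (roam, freeze, display) run per individual;
chase and fight are joint states owned by the pair. The body is a
rigid five-point skeleton: labrum 1.2 cm ahead of the scutellum,
abdomen 1.3 cm behind, mandibles 0.3 cm ahead of the labrum and
separated by the state-dependent gape (0.8 cm in display, 0.3 cm
otherwise). The geometry is built so the predicates are mutually
exclusive by construction: fighting pairs face off with a 1 cm labrum
gap (cross-mandible minimum ≈ 0.4 cm < 3, labrum-to-abdomen ≥ 3.5 cm
> 3); chasing pairs move on a circle with the chaser's labrum held
exactly 1.5 cm from the chased abdomen (cross-mandible minimum >
3 cm); apart individuals are confined to home zones whose separation
keeps all 25 cross pairs above 3 cm. Consequently, in the noise-free
limit every thresholded endpoint equals its closed-form truth value
exactly, up to one frame per bout edge — the package's core
self-validation property, exercised by the test suite.

Each state has one nominal speed (freeze 0, fight 0, display 0.8,
roam 1.2, chase 3.0 cm/s), so the truth movement classes follow from
the state timeline: freeze *and fight* are truth-freezing (stationary
grappling), display and roam are normal, chase is rapid. Transitions
between joint and solo states reposition the individuals, so truth
total distance is the nominal-speed integral and is approximate
(single-frame displacement spikes at state boundaries); the exact
endpoints are the thresholded ones. Default jitter is 0.02 cm
(≈ 1.5 px), a typical part-wise localisation error; note that at
25 fps even this small jitter inflates apparent instantaneous speed
by ~0.5–1 cm/s, which makes frame-level freezing detection
noise-limited — as it is in real tracks. That is a property of
frame-differenced speed, not of the generator; the optional window-3
rolling median (`smooth = TRUE`) mitigates it.

What the generator does **not** emulate: identity swaps between
individuals, anisotropic optics, autocorrelated localisation error,
partial-body occlusion structure (dropouts are independent
Bernoulli), wall-climbing, and any within-bout behavioural
micro-structure. Passing the recovery tests therefore demonstrates
the correctness of the measurement pipeline, not that the thresholds
are optimal for any particular real dataset.

## Problem sizes in the shipped tests

The suite validates the planted-bout recovery on a full 600-s trial
at 25 fps; the oracle-equivalence property on 200 random trials of
60–250 frames; the end-to-end phenotype recovery on a cohort of two
planted phenotypes × 7 pair-trials of 300 s each, with default noise;
and the algebraic invariants on 10^3–10^4 random cases. These sizes
give the properties room to fail while keeping the default test run
fast.

## Known limitations

* Endpoint magnitudes depend on thresholds that are partly package
  defaults (chase, interaction, speed bins); cross-study comparisons
  must match configurations, which is why the tables embed them.
* Frame-level speed classification is sensitive to keypoint jitter
  at high frame rates (see above).
* Identity-swap correction is assumed to have happened upstream in
  the pose tool; a swapped track silently exchanges the directional
  endpoints of the two individuals.
* The pipeline exports tidy tables for inferential statistics; it
  deliberately performs none itself.
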