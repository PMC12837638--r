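---
title: "Tracking dense fish schools: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking dense fish schools: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FishMOT)
```

FishMOT links per-frame detector boxes into identity-bearing fish
trajectories and scores the result with the standard multi-object-tracking
metric suite. This vignette is the package's own account of the method: the
models and their assumptions, the parameters that matter and why their
defaults are what they are, what the synthetic scenes do and do not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## The motion model

Each track carries a constant-velocity Kalman filter over the
8-vector (cx, cy, a, h, vcx, vcy, va, vh): box centre, width/height aspect
ratio, box height, and their per-frame velocities. The measurement is
(cx, cy, a, h) extracted from a detection box. This parameterisation is the
established one in tracking-by-detection: it makes the filter scale-aware
(all pixel-valued noise scales with h) and keeps box shape in the state
without tracking four corner coordinates.

Noise is specified as fractions of the current box height:

| parameter        | default | meaning                                          |
|------------------|---------|--------------------------------------------------|
| `posNoiseWeight` | 1/20    | position/height std per frame, × h               |
| `velNoiseWeight` | 1/160   | velocity std per frame, × h                      |
| aspect process   | 1e-2 / 1e-5 | fixed stds for a and va (dimensionless)      |
| aspect measurement | 1e-1  | fixed measurement std for a                      |

The initial covariance doubles the position stds and takes 10× the velocity
stds, encoding "position known from one box, velocity unknown". Updates use
the Joseph form, and covariances are symmetrised after every step, so the
filter stays symmetric positive-semidefinite through arbitrarily long
predict/update cycles (property-tested over 1000 random cycles). The time
step is fixed at one frame; frame-rate effects belong to the data, not the
filter.

The gating distance is the squared Mahalanobis distance of a candidate
measurement under the predicted innovation distribution. A singular
innovation covariance signals a collapsed state and raises an error rather
than returning something.

## The association cascade

Per frame, three stages run in a fixed order — motion, IoU, distance — each
restricted to the tracks and detections left unmatched by earlier stages,
each building a gated cost matrix and solving it with the Hungarian
algorithm (implemented in C++; optimality is tested against permutation
brute force on matrices up to 6 × 6):

* **Motion** — cost d², infeasible where d² > `motionGate`. The default gate
  9.4877 is the chi-square 95th percentile with 4 degrees of freedom, the
  standard contract for Mahalanobis association; nothing else about the gate
  is special.
* **IoU** — cost 1 − IoU, infeasible below `iouGate` = 0.1. The gate is
  deliberately loose: swimming fish deform, so a strict overlap requirement
  would reject true continuations the motion stage already missed.
* **Distance** — cost is the Euclidean distance between the predicted and
  detected centroids, infeasible beyond `distGateFactor` (default 1.0) times
  the mean of the two boxes' diagonals. Scaling the gate by box size keeps
  it meaningful for both 40 px and 160 px fish. Predicted (not last-seen)
  centroids are used, consistent with the propagation model.

Infeasible cells are masked with a large constant before the solve and any
assignment through a masked cell is dropped afterwards, so a gated pair can
never be reported as a match; with the mask in place the solver returns the
maximum number of feasible matches first and the minimum total cost among
those. Ties resolve deterministically, so identical inputs always give
identical output.

## Track lifecycle

* Detections with score below `preThresh` (0.4) are never ingested.
* An unmatched detection with score strictly above `thetaNew` (0.4) spawns a
  new track. Identities increase strictly and are never reused. New tracks
  join the cascade from the next frame; there is no same-frame rematching.
* A matched track adopts the detection's score and resets its miss counter.
  Its output record carries the detection box itself (not the posterior
  state box): the detector's box is the best available localisation, and
  this is what makes perfect input reproduce ground truth exactly.
* An unmatched track coasts: it keeps moving under its motion model and its
  score decays multiplicatively by `decayFactor` (0.9) per missed frame. The
  decay form is a design choice — only the existence of a decay is inherent
  to the method — so it is config-exposed.
* A track whose consecutive misses exceed `maxAge` (3) is purged: a track
  missing exactly 3 frames may still revive on the 4th frame's match, one
  missing 4 is gone and its identity never returns. This boundary is
  unit-tested, and re-identification after a purge is explicitly out of
  scope.

Coasted records are flagged in the per-frame output. They are part of the
algorithm's output, but standard evaluation counts unsupported predicted
boxes as false positives, so the pipeline and CLI exclude them from written
result files by default (`suppressCoasted`); set the flag to keep them.

## Occlusion loss arithmetic

The loss operations are standalone array math (no autodiff, no network):

* `focalLoss(pt, yt)` = mean of (1 − pt)² · [−yt log pt − (1 − yt) log(1 − pt)],
  with probabilities clipped to [1e-7, 1 − 1e-7]. As printed, the modulation
  factor uses 1 − pt for both label values; the conventional focal loss
  modulates by the label-aligned probability instead. The printed form is
  the default here, and it has a real behavioural consequence: it
  *down-weights* confident false positives (pt = 0.9, yt = 0 scores lower
  than pt = 0.6, yt = 0). `standard = TRUE` selects the conventional
  variant, under which harder negatives are penalised more.
* `diceLoss(p, y, eps = 1)` = 1 − (2 Σ p·y + eps)/(Σ p + Σ y + eps); the
  smoothing constant bounds the loss in [0, 1] and makes the all-empty case
  come out 0.
* `adaptWeights()` — the adaptive rule as literally printed
  (w·sign ∇L + 1e-8) could flip a weight's sign or zero it, which
  contradicts the balancing role it is meant to play. It is therefore read
  as a sign-driven multiplicative step w ← w·(1 − η·sign ∇L) with η = 0.05,
  floored at 1e-8, followed by renormalising α + β = 1. Positivity and unit
  sum survive arbitrary gradient sequences (property-tested).
* `totalLoss()` applies `wBase` to the whole weighted sum,
  w_base·(α·L_focal + β·L_dice) — the reading consistent with w_base being a
  single overall occlusion-loss weight rather than a per-term factor.

## Evaluation conventions

The metric definitions are standard; the conventions below are the
decisions a reimplementation needs to know:

* **CLEAR matching** persists the most recent gt↔prediction correspondence
  while it remains valid (IoU ≥ threshold, both present) before optimally
  reassigning the remainder — the continuity rule that gives identity
  switches their usual meaning. Reassignment maximises the number of
  matches, then total IoU. A switch is counted when a ground-truth object's
  matched identity differs from its most recent previous match, including
  across gaps.
* **MOTP** is the mean of 1 − IoU over matched pairs: lower is better, 0 is
  perfect localisation. (An overlap percentage would be the complement; the
  lower-better orientation matches how small published values ~0.2 are
  read as good.)
* **Identity metrics** come from a dummy-augmented minimum-cost bipartite
  matching between whole trajectories, with pair cost equal to the number of
  non-co-located frames on both sides; IDTP is the co-located frame count of
  the chosen matching. Equivalence with exhaustive enumeration over all
  trajectory matchings is tested on random micro-scenes.
* **HOTA** is computed at the single localisation threshold α = 0.5 by
  default (`hotaMetrics(..., alphas = seq(0.05, 0.95, by = 0.05))` gives the
  multi-threshold average for cross-paper comparability). Per-frame matching
  maximises association-weighted similarity, and A(c) uses the standard
  TPA/FNA/FPA counts for the (gt id, pred id) pair of each true positive —
  the established reading, since the per-detection association score is not
  otherwise pinned down.
* **Degenerate inputs**: ratio metrics with zero denominators report 0 with
  a warning instead of erroring, so batch evaluation survives empty clips;
  the low-level `mota()`/`motp()` primitives, by contrast, refuse undefined
  input loudly.
* MT counts trajectories tracked for **at least** 80% of their lifespan; ML
  those tracked for **less than** 20%.

## The synthetic fish school

`simulateSchool()` is a minimal zonal heading model, not a calibrated
biological simulation: each fish steers away from neighbours inside a
repulsion radius, otherwise blends alignment with nearby headings and
attraction toward the local centroid, with wall avoidance near the boundary,
a per-frame turn-rate cap, and Gaussian heading noise. Defaults emulate the
recording conditions the tracker targets: 75 fish, 1920 × 1080 px arena,
30 FPS, 25-frame clips, body lengths 40–160 px (a declared convenience
mapping of 8–25 cm fish onto a 1080 px frame), cruise speeds 1–3 body
lengths per second.

Two modelling choices deserve emphasis:

* **Boxes.** Box height encodes the fish's (fixed) body length; box width
  follows heading — a side-on fish fills its length, a head-on fish only its
  body depth — modulated by a sinusoidal tail beat (`tailBeatAmp`,
  2–4 Hz). Width is where swimming deformation shows up; height is the
  stable size cue a detector would also see.
* **Solid bodies.** Fish centres may not approach closer than 40% of the
  pair's mean body length (enforced at placement and per step). Fish are
  solid; without a hard core, two simulated fish can occupy the same spot
  for several frames, which no box-only tracker — this one or any other —
  can disambiguate even from perfect detections. Boxes still overlap
  heavily (that is what drives the occlusion statistics); only centre
  coincidence is excluded.

`corruptDetections()` then models the detector: independent Gaussian jitter
on each box edge, random dropout (`dropProb`), occlusion-conditional dropout
in which the smaller box of a pair overlapping above
`occlusionIouThreshold` is hidden with probability `occlusionDropProb` (a
simple 2-D depth proxy: the fish that looks smaller is behind), Poisson
clutter, and a score model that penalises jitter and overlap. Presets
(`simPreset()`) bundle corruption archetypes — `mf25-like`, `normal`,
`severe-occlusion`, `severely-deformed`, `multi-density` — as qualitative
analogues of dense-tank clips, not calibrated replicas; the true occlusion
and dropout rates of any real recording are unknown here.

What passing tests on these scenes shows: the association logic, lifecycle
bookkeeping and metric implementations are correct, and the tracker degrades
gracefully (median IDF1 non-increasing in dropout; coasting recovers
occlusions up to `maxAge` frames). What it does not show: performance on
real imagery, where detector errors are correlated, appearance is
informative, fish leave and re-enter the frame, and depth ordering is real.
With all corruption off, the full pipeline — simulate, track through files,
evaluate — must and does score MOTA = IDF1 = HOTA = 1, MOTP = 0, IDSW = 0
exactly, which pins down coordinate conventions, file round-tripping and
matcher boundary conditions at once.

## Numerical choices

* Infeasible assignment cells are masked at 1e12, far above any feasible
  stage cost (gated d² ≤ 9.49, 1 − IoU ≤ 1, centroid distances bounded by
  the diagonal gate), and filtered after the solve.
* Identical boxes short-circuit to IoU exactly 1: computing
  (l + w) − l in floating point otherwise leaves ~1e-16 residue that would
  contaminate exact-closure checks.
* Kalman updates use the Joseph covariance form plus explicit
  symmetrisation; innovation covariances are Cholesky-factorised, and
  failure to factorise raises a contextual error.
* File output uses fixed formats (4 decimals for coordinates, 6 for scores),
  making every artifact byte-stable; pipeline evaluation compares the
  written gt and result files so both sides share that precision.
* Assignment ties are broken deterministically by the solver's fixed
  scan order; runs are reproducible bit-for-bit from a scene sidecar or run
  manifest.

## Problem sizes in the test suite

The suite exercises: assignment optimality on 1000 random matrices up to
6 × 6; metric-oracle equivalence on 100 random micro-scenes (≤ 4 objects,
≤ 5 frames) against exhaustive enumeration; exact pipeline closure on a
75-fish, 25-frame uncorrupted scene; 200 seeded occlusion-recovery trials at
gaps of 3 and 5 frames; and dropout degradation over 20 seeds × 4 dropout
levels on 20-fish scenes. These sizes keep the full suite under a few
minutes while covering every contract; all larger-scale behaviour follows
the same code paths.

## Known limitations

* No appearance model: identity through occlusion rests entirely on motion
  and geometry, and a purged identity is never re-identified.
* The simulator is 2-D; occlusion depth is proxied by box size, and stereo
  or world coordinates are ignored throughout (written as −1 in files).
* HOTA defaults to a single localisation threshold; use the alpha grid for
  comparisons with published multi-threshold HOTA values.
* The CLEAR persistence rule keeps a correspondence across arbitrary gaps;
  evaluators differing in that detail can count switches slightly
  differently on fragmented data.
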