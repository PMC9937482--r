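---
title: "Models and methods behind panogaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panogaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panogaze)
```

`panogaze` analyses eye and head movements made while observers explore
360° panoramic scenes across an encoding phase and an old/new recognition
phase. This vignette explains the models implemented, the choices made where
the design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## Coordinate frame and geometry

Locations on the stimulus sphere are longitude λ ∈ [−180°, 180°) (eastward)
and latitude φ ∈ [−90°, 90°] (toward the north pole). The world "forward"
direction — where the trial-start fixation cross sits — is (0°, 0°); in
Cartesian terms forward = +x, east = +y, up = +z. The pole longitude is
defined as 0 to remove an undefined coordinate.

All distances are great-circle central angles, computed with the
Vincenty/atan2 form, which is numerically stable both for near-identical and
for near-antipodal points. The spherical mean is the normalized resultant
vector; sets whose resultant is numerically zero (e.g. a pair of antipodes)
raise an explicit degenerate-mean error rather than returning an arbitrary
direction.

Head orientation is a unit quaternion (canonicalized to non-negative scalar
part, since q and −q encode the same rotation). Interpolation between poses
uses spherical linear interpolation along the shorter arc, with a normalized
linear fallback when the endpoints are within ~1e−7 of each other, so the
rotation angle from the start grows linearly in the interpolation parameter.

## From raw streams to gaze series

Raw input is an eye-in-head unit-vector stream at 250 Hz and a head
quaternion stream at ~70 Hz. The head stream is slerp-interpolated to the
eye timestamps; outside the recorded head span the nearest frame is held
constant (the alternative — extrapolating rotation — would fabricate
movement). The world-frame *eye point* is the rotated eye-in-head vector
projected to the sphere; the *head point* is the rotated forward axis.
Eye-in-head longitude/latitude are retained for head-centered analyses.
Timestamps are trial-relative milliseconds and all intervals are half-open
[start, end), which keeps duration arithmetic unambiguous.

## Fixation detection

Fixations are detected with a dispersion-threshold (I-DT) scan adapted to
the sphere. A candidate window must span at least the minimum duration
(default 80 ms) in its timestamps; its dispersion is the **maximum pairwise
great-circle distance** among window samples. If the dispersion is within
the threshold (default 3°) the window grows sample-by-sample while it stays
within; the fixation's centroid is the spherical mean of the window, and the
scan restarts after it. Otherwise the window start advances one sample.

Two open choices were fixed as follows:

* *Dispersion metric.* Maximum pairwise distance (a "diameter" criterion)
  rather than distance-to-centroid (a "radius" criterion): it is rotation
  invariant, pole-safe, and does not depend on an intermediate centroid
  estimate. The threshold is therefore interpreted as a diameter.
* *Duration rule.* A window qualifies when its timestamp span reaches the
  minimum duration. At 4 ms sampling a 79 ms plateau spans at most 76 ms and
  is never detected; reported durations use the half-open convention
  (end = last sample + one sample period).

Because every comparison is an angular distance, detection commutes with
global rotations — a property the test suite checks directly, including for
trajectories lifted to the pole, where projected-coordinate (planar I-DT)
implementations break up fixations as longitudes diverge.

Head fixations are defined as the spherical mean of head points over each
eye fixation's window (raw head data are too smooth to segment on their
own). Saccade amplitudes and head shifts are distances between successive
centroids; the exploration tendency is the mean distance of each fixation
after the first from the first.

## Spatial statistics

**Spreads.** Per trial, longitudes are rotated so their circular mean is 0°,
wrapped to [−180°, 180°), and summarised by their ordinary SD (likewise
latitudes). Phase-level summaries are across-trial medians, with the old/new
recognition sub-phases pooled into one recognition phase. The recentred
linear SD treats longitude circularly only through the recentring; for
spreads approaching the full circle the statistic saturates — a caveat
inherited by any seam-wrapped SD.

**Heatmaps.** Each fixation centroid deposits a Gaussian kernel
exp(−d²/2σ²) with σ = 4° of *angular distance*, truncated at 3σ, on a 1°
equirectangular grid. Each point's kernel is normalized to unit mass before
accumulation: grid cells pack denser in longitude toward the poles, so an
unnormalized kernel would systematically overweight high-latitude points.
The truncation loses < 0.2% of kernel mass; the final grid is normalized to
total mass 1.

**Weighted correlation.** Heatmap pairs are compared by Pearson correlation
with per-cell weights cos(φ) — the exact inverse of the equirectangular area
stretch 1/cos(φ) — so each region of the sphere contributes in proportion to
its true area. The weights enter only the correlation, not the smoothing:
smoothing is already area-faithful through the angular kernel and per-point
normalization.

**Same vs different scenes.** For each scene the correlation of its two
matched maps (encoding↔recognition of one target, or eye↔head within one
phase) is compared with the correlation against a different scene's map,
chosen by a seeded random derangement (no scene paired with itself), and the
two sets are compared by a paired t test across scenes.

## Cross-recurrence analysis

Encoding and recognition fixation sequences are adjusted to a common length
by truncating the longer one (dropping trailing fixations, preserving
alignment from trial onset — resampling would distort the temporal
structure). Cell (i, j) of the recurrence matrix is 1 when fixations e_i and
r_j are within the radius; ties at exactly the radius count as recurrent
(with a 1e−9° guard against floating-point noise in the distances).

The nine measures:

* **REC** — percentage of recurrent cells out of N².
* **DET** — percentage of recurrent points on diagonal runs of length ≥ 2
  (any diagonal parallel to the main one): trajectories repeated in order.
* **vLAM/vTT** — percentage on vertical runs (consecutive encoding indices
  at one recognition fixation) and their mean length: regions scanned
  briefly at encoding and dwelled on at recognition; **hLAM/hTT** the
  horizontal duals.
* **CORM** — 100·Σ(j−i)r_ij / ((N−1)·Σr_ij): positive when recurrence mass
  lies above the diagonal, i.e. recognition dwells on locations fixated
  early in encoding (primacy); the (N−1) normalization makes the extreme
  corners ±100.
* **CLUST** — percentage of recurrent points in 8-connected components of
  at least 8 recurrences.
* **ENT** — Shannon entropy (nats) of the distribution of diagonal run
  lengths ≥ 2.

Minimum line length 2 is the standard recurrence-quantification convention;
natural logarithms are used for ENT. Measures whose denominator is empty (no
recurrences; no qualifying runs) are reported as missing and excluded
listwise from condition means, since treating them as 0 would conflate "no
structure" with "no data".

**Radius calibration.** Mean REC over a set of pairs is a nondecreasing step
function of the radius; 64 bisection steps on [0°, 180°] return the smallest
radius whose mean REC reaches the target (7% by default, low enough to be
selective while leaving enough recurrences to quantify). Targets that are
unreachable — e.g. already exceeded at radius 0 by degenerate pairs — are
reported explicitly.

## Study-level analysis

Four pairing conditions cross participant and image identity: Sp-Si pairs
each old recognition trial with the same participant's encoding of the same
scene; Sp-Di pairs each new recognition trial with a seeded-random scene
from the D-set (encoded but not re-shown), drawn without replacement so the
D-set is used evenly; Dp-Si and Dp-Di take the encoding side from a
seeded-random other participant. Pairing the *new* recognition trials in the
Di conditions follows the original design even though it confounds image
novelty with image change; it is replicated, not corrected.

Per-pair measures are averaged within participant × condition (listwise per
measure over non-missing pairs), then summarised across participants. The
2×2 repeated-measures ANOVA over per-participant condition means is plain
`stats::aov` with an error stratum — plumbing, not a contribution of this
package. Memory tables label encoding trials Hit/Miss by the later
recognition response to the same scene, old recognition trials Hit/Miss and
new trials CR/FA, and contrast each measure between correct and incorrect
trials with an exact Mann–Whitney U test: full permutation enumeration
(tie-safe) when the number of group assignments is at most 2×10⁵, the exact
no-tie distribution for both n ≤ 25, and the continuity-corrected normal
approximation otherwise.

## The synthetic-study generator

No raw recordings ship with the package; a generative model produces studies
with the design constants of the target paradigm — 80 encoding trials, 40
old + 40 new recognition trials, 10 s each, eye samples at 250 Hz, head pose
at ~70 Hz, 21 participants — and controllable behavioural structure.

**Scenes** are 12 weighted von Mises–Fisher regions of interest (ROIs):
longitudes uniform, latitudes von Mises-concentrated on the horizon
(κ = 8, circular-normal SD ≈ 20°, matching the horizontal bias of panorama
viewing), weights Dirichlet(1). Fixation targets scatter around an ROI
center with κ = 40 (≈ 9°), the scale of an object-sized region.

**Scanpaths.** Each trial starts at the fixation cross (0°, 0°). Plateau
durations are gamma (shape 4, mean 200 ms — right-skewed, matching reported
fixation-duration scales) truncated below at 100 ms so every ground-truth
plateau is detectable; saccades are great-circle arcs of duration
20 ms + 2 ms/deg. Successive targets are redrawn until at least 6° apart
(twice the dispersion threshold) so two plateaus can never merge under the
detector — this makes noise-free ground-truth recovery exact, which the
acceptance suite exploits. With probability ρ (default 0.2) a target comes
from the participant's private ROI set instead of the scene's, which is what
generates participant-idiosyncratic scanpath structure. During recognition
only the ceil(f·n) highest-weight ROIs are eligible (f = 0.5 by default;
both scene and private sets are narrowed): checking a scene against memory
concentrates on fewer regions, producing the smaller recognition spreads.

**Head model.** The head aims at a point pulled 70% of the way from the
fixation target to its ROI center (`head_coarseness`) — the head indexes the
coarse region while the eyes inspect detail points — with the aim latitude
scaled by `head_gain` (0.85; heads pitch less than gaze). The head follows
this aim with a 50 ms delay and a first-order pursuit with τ = 30 ms, so it
lags and under-shoots the eye. An earlier design that scaled the whole arc
from the trial-start direction was rejected: on full-sphere content a radial
gain map *stretches* tangential separations for far-hemisphere targets and
tears apart near-antipodal clusters, which inverts the empirically expected
ordering of the calibrated radii. The region-oriented head reproduces the
expected structure — head spreads below eye spreads, head maps more
reproducible across phases than eye maps, and a calibrated head radius below
the eye radius. A per-participant log-normal multiplier on the gain
(SD 0.15) captures "movers" versus "nonmovers"; setting τ = ∞ freezes the
head (useful for head-fixed controls), and coarseness = 0, gain = 1,
lag = τ = 0 gives perfect eye-head coupling.

**Round-trip exactness.** Eye-in-head vectors are computed against the same
slerp-interpolated head pose that preprocessing reconstructs, so the
generator→pipeline round trip is exact to floating point for noise-free
trials. Within-fixation gaze jitter is vMF with κ = 12000 (≈ 0.5°), a
typical tracker-noise scale; it occasionally splits a plateau into two
detected fixations, which is realistic tracker behaviour.

**Responses.** The old/new response is Bernoulli with
p(correct) = logistic(logit(0.92) + z_enc − z_rec) for old scenes and
logistic(logit(0.92) − z_rec) for new scenes, where z is the ground-truth
exploration tendency standardized at the generator's expected scale (mean
90°, SD 20° — uniform ROI longitudes put the mean distance from the start
direction near 90°). The intercept anchors accuracy near the high
recognition rates typical of distinctive panoramic scenes; the slopes
reproduce the *direction* of the memory effects (more encoding exploration →
later recognition; less recognition exploration → correct responses) without
claiming their magnitude.

**What passing tests do and do not show.** The generator emulates
horizon-biased, ROI-driven fixation sequences, eye-head coupling with lag
and undershoot, image-driven versus idiosyncratic structure, and
exploration-dependent recognition. It does not emulate photorealistic
saliency, depth or vergence, blinks and tracker loss, body rotation, or
fixation-duration dependence on content. Tests that pass on synthetic
studies therefore validate the *pipeline* — geometry, detection, statistics,
recurrence quantification — under known ground truth; they do not certify
behavioural claims about real observers.

## Problem sizes and numerical choices

The test suite and the acceptance script run reduced-size studies sized to
keep Monte-Carlo error small relative to the effects under test within a
desk-scale runtime: the spread-direction check uses 100 studies of one
participant × 64 re-shown scenes (the spread comparison needs matched
phases, and scene diversity — not participant count — is what stabilizes the
across-trial medians; even so, the *latitude* narrowing under ROI
restriction is only about 2° against a comparable between-study spread, so
its direction holds in most but not all studies of this size, unlike the
longitude narrowing, which is an order of magnitude larger); the
condition-recurrence checks use 20 participants × 8 scenes; the heatmap
contrast uses 3 participants × 40 scenes; the acceptance script reports a
6-participant × 20-scene study. Bisection uses 64 iterations (interval
< 1e−17°); kernel truncation at 3σ; recurrence tie guard 1e−9°; unit-norm
invariants are enforced to 1e−9 throughout. All randomness flows from a
single study seed through deterministic per-scene, per-participant and
per-trial seeds, so every result in this package is exactly reproducible
from its configuration.

## Known limitations

* The recentred-linear longitude SD saturates for near-uniform longitude
  distributions; comparisons remain valid but absolute values compress.
* Heatmap cells are compared on the equirectangular grid; the cos-latitude
  weighting corrects area, not shape, distortion.
* The exact U test switches to the normal approximation for large tied
  samples, where exact enumeration is infeasible.
* CLUST counts all recurrent points in qualifying components, including
  points that also lie on diagonal or laminar lines; alternative conventions
  exist and would change absolute CLUST values.
* The generator's response model is intentionally minimal (logistic in one
  covariate); it supports direction checks only.
* The recognition-phase narrowing acts on ROI *identity*, so its effect on
  latitude spread is indirect (ROI latitudes all cluster on the horizon) and
  small relative to scene-to-scene variability; latitude-spread contrasts
  need many more scenes than longitude contrasts for the same power.
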