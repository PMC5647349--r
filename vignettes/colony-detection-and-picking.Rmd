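---
title: "Label-free colony detection, tracking and picking-time prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free colony detection, tracking and picking-time prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

colonyscope turns a bright-field time-lapse of a reprogramming culture into
per-colony picking decisions. This vignette is the package's account of the
models it implements, the assumptions behind them, the tunable parameters
that matter, and what the synthetic-data validation does and does not show.

## The problem

Induced pluripotent stem cell (iPSC) colonies must be harvested ("picked") in
a narrow window: too early and the colony is immature, too late and it risks
random differentiation. Fluorescent reporters make colonies easy to see but
perturb the biology; bright-field imaging is label-free but hard to read.
Colonies do, however, carry a characteristic *texture* that distinguishes
them from the surrounding fibroblast/somatic background, and their area
follows a sigmoid trajectory over roughly days 7–22 after induction. The
pipeline exploits both facts: texture finds the colonies, the growth curve
tells their phase.

## Detection: sliding-window texture classification

Single cells in bright-field are ambiguous — edges overlap and boundaries
are fuzzy — so the unit of detection is a fixed 96 x 96 px window, scanned
from the top-left corner at a stride of one window (a non-overlapping
tiling; overlap is supported for finer boundaries). Each window is scored
with a trainable classifier as P(iPSC texture), and windows at or above the
threshold (default 0.5) paint their footprint into a binary map. With
stride < window a pixel is set when *any* covering window passes. The
right/bottom remainder narrower than one window is not scored; this is a
documented information loss, not padded away.

Brightness varies across wells and days, so every frame is first normalized
with a percentile-clipped linear stretch (`autolevels()`): intensities at or
below the 1st percentile map to 0, at or above the 99th to 65535, linear in
between. The point of the operation is invariance — a frame transformed by
any positive affine intensity map (gain/offset) normalizes to the same image
up to quantization, which the tests assert directly. A constant frame maps
to a constant mid-range frame rather than erroring.

The binary map is then cleaned in a fixed order: enclosed holes are filled,
the 0/1 mask is blurred with a Gaussian (σ = 48 px, half a window), the
result is re-thresholded at 0.5, and 8-connected components smaller than one
window (9216 px²) are discarded as sparse residuals. σ, the re-binarization
threshold and the minimum area are exposed in the configuration; the
defaults are the package's own choices since only the order of operations is
fixed by the protocol.

### The classifier contract

Any model mapping a 96 x 96 patch to a probability, trainable on a CPU in
minutes, satisfies the detection stage. The reference implementation is a
single-hidden-layer feed-forward network (8 hidden units, logistic output,
weight decay 1e-3) over 10 summary texture features per patch: intensity
mean, spread (sd, MAD), gradient energy along both axes, lag-1 and lag-4
spatial autocorrelations, and the standard deviation of 12 x 12 block means.
These features separate textures that differ in mean level, variance or
correlation length — precisely the contrasts the synthetic generator
produces and, qualitatively, the contrast between colony and background in
real bright-field frames. A convolutional network would fit the same
contract; at the package's scale the feature network trains in seconds,
deterministically given a seed, and serializes to a JSON artifact that
reloads with bit-identical predictions.

The dataset layer keeps the field's label convention — 0 = iPSC texture,
1 = non-iPSC — but every probability the package reports is P(iPSC), so no
double negation ever appears downstream.

Corrective fine-tuning (`fine_tune()`) appends operator-relabelled windows
to the training set and refits, warm-started from the current weights. The
returned model is guaranteed not to do worse on the correction set: if the
refit did not help there, the previous model is kept.

## Segmentation and tracking

Up to the seed day (day 12 by default — a protocol-specific setting, not a
constant), colonies are simply the 8-connected components of the cleaned
binary map. Later, colonies are larger and closer, and tiled detection
under-resolves their boundaries, so labels are propagated by a seeded random
walker on the intensity image: each pixel is assigned the label whose seeds
a random walk, with edge weights `w = exp(-beta * dI^2)` on the 4-connected
lattice (intensities range-normalized to [0, 1], β = 130), reaches first.
The probabilities solve the combinatorial Dirichlet problem; the
implementation solves the sparse linear system directly and the tests check
it to 1e-6 against an absorbing-Markov-chain oracle computed from the
fundamental matrix on small grids.

Seeds are built symmetrically: each prior-day label eroded by 5 px seeds its
colony; background seeds sit just outside a 5 px dilation of the detection
support. Symmetric radii matter: on pure texture (no strong edge) the walker
places the boundary near the geometric midpoint between seeds, so an
asymmetric pair (e.g. background seeds 15 px out) biases every boundary
outward by half the difference, and the bias compounds day over day. The
refined labels are additionally confined to a dilated envelope of the
detection map. Because colonies can grow faster than an eroded prior
footprint, the interior of the *current* detection map (eroded 5 px) also
seeds foreground, labelled by the unique prior colony it overlaps;
components touching two priors are left to the walker.

Tracking is backward, mirroring how colonies are registered from the
end of the experiment: each region on day *d* links to the region on the
previous day with maximal pixel overlap, accepted when
overlap / min(area) ≥ 0.3; ties break toward the larger candidate, then the
lower region id. Tracks start from final-frame regions (and optionally from
seed-day regions); a region appearing only on an intermediate day starts no
track. How colonies first appearing after the seed day should be handled is
genuinely open; admitting them as new tracks is this package's reading. The
per-track area series, in px² with missing days left absent, is the growth
curve everything downstream consumes.

## The growth-phase model

Colony phase is modelled with a hidden Markov model over four per-day
features: the first-order area difference, the second-order difference, the
area itself, and the number of days since the colony first appeared.
Differences undefined at the start of a track are set to zero (dropping
those days is available behind a flag). Whether "growth rate" means the
absolute or the relative area difference is ambiguous in the protocol;
absolute is the default, relative sits behind the `rate_type` flag.

* **States and topology.** Four states, left-to-right (upper-triangular
  transition matrix): phases of colony formation progress and do not
  regress. A full matrix is available behind the `topology` flag.
* **Emissions.** Diagonal Gaussians over the four features, z-scored over
  the training set (the transform is stored in the model). The emission
  family is the package's choice — continuous features, small cohorts —
  and is stated here prominently because nothing in the protocol fixes it.
* **Partial labels.** Two stages are labelled per training colony: *first*
  (from the start of the track through two days after the colony first
  shows) clamps state 1, and *mature* (from one day ahead of the expert
  picking day to the end) clamps state 4. Clamping is exact during the
  E-step: the emission mask zeroes all other states on labelled days. The
  unlabelled middle is initialized by splitting it into two contiguous
  periods of similar length (states 2 and 3).
* **Fitting.** Multi-restart Baum–Welch; the default of 2000 restarts
  honors the protocol, while tests and the bundled validation use 10–20
  (the likelihood surface under clamped labels and segmented initialization
  is benign — restarts agree in practice). Each restart jitters the
  segmented-initialization moments and dwell probabilities, runs EM until
  the log-likelihood gain drops below 1e-6 (at most 500 iterations), floors
  emission variances at 1e-6 on the z-scored scale, and the best-likelihood
  restart wins. Degenerate restarts (zero-probability clamp conflicts) are
  skipped; if all restarts degenerate the fit errors.
* **Decoding.** Viterbi paths (ties toward the lower state index; the
  left-to-right topology makes decoded paths monotone) and forward–backward
  posteriors. Both are checked exactly against exhaustive path enumeration
  on small instances, to 1e-10 for likelihoods and exact path identity for
  Viterbi.

### Picking decision

The mature-phase posterior — the smoothed probability of state 4 — rises
from 0 to 1 as a colony matures. The trigger is its first crossing of the
picking threshold, default 0.3. The protocol's phrasing ("the closest score
to 0.3") admits a second reading, implemented as `rule = "closest"`; first
crossing is the default because it is monotone in the threshold and robust
to posterior plateaus. A posterior reaching 1 (≥ 0.99 numerically) flags
overgrowth risk. `calibrate_threshold()` grid-searches the threshold
minimizing the mean absolute day error against expert picking days, ties
resolving to the smaller threshold. On the package's clean synthetic
cohorts the posterior rises sharply around the labelled mature onset, so
calibration lands near the top of the grid; on noisier real curves the rise
is gradual and the calibrated value more informative — a difference worth
remembering when transferring thresholds.

### Abnormality filter

Over/undergrown colonies are excluded before model fitting by the mean
first-order difference of the growth curve between days 10 and 20 (per-day
rate over consecutive observed days; curves with fewer than two points in
the window are rejected with an explicit reason). Default bounds are robust
estimates of the cohort's 5th/95th percentiles: median ± z(0.95) · 1.4826 ·
MAD. Empirical cohort quantiles would be self-defeating here — with 10%
gross outliers, the empirical 95th percentile lies *inside* the outlier
cluster, so at most ~5% of curves can ever sit above it regardless of how
extreme the outliers are. The robust bounds estimate the same percentiles
from the central mass, which outliers cannot shift. Explicit bounds can be
passed to override.

## The synthetic generator: what it emulates, what it does not

`generate_scene()` produces 16-bit frames (one per day, days 7–22 by
default, matching the daily imaging cadence of the human protocol; other
cadences are a config choice) containing disk-shaped colonies whose areas
follow a logistic law — carrying capacity K, rate r/day, onset day — with
colony and background textures drawn as band-limited Gaussian noise
differing in mean, variance and correlation length. Ground truth includes
per-day label masks (mask areas match the closed-form logistic to within
rasterization error of the order of the perimeter), the area table, each
colony's first-positive day, and its picking day, defined as the first day
the noiseless curve reaches 60% of K — a fixed, arbitrary stand-in for
expert "best picking time" labels. `generate_reporter()` adds a fluorescence
channel covering a configurable fraction (default 0.9, mirroring the ~10%
reporter-negative fraction seen in reporter systems) of the true colony
area, at a configurable SNR. `simulate_growth_cohort()` is the fast tabular
counterpart for the phase model, with optional planted overgrowers (default
3x rate and capacity).

What the generator does **not** emulate: phase-contrast optics, single
cells, colony merging/splitting, vignetting or illumination gradients,
debris, or texture drift as colonies mature. Passing the end-to-end tests
therefore shows that the pipeline's machinery is correct and calibrated on
separable textures and logistic growth — it does not certify recognition
rates on real microscopy, which require the corrective fine-tuning loop and
per-system threshold calibration.

Texture contrast is deliberately a knob, not a constant: nothing in the
source protocol quantifies colony/background contrast, so classifier tests
can be made easy (defaults) or hard (the fine-tuning test narrows the mean
gap to 1000 of 65535 and inflates the background correlation length).

## Problem sizes used in validation

The bundled tests and `scripts/acceptance.R` use: a 1600 x 1600 px
validation scene with three colonies of K ≈ 2.2–2.6 x 10⁵ px² (mature
colonies must be large relative to the fixed 96 px window for pixel-level
scores to be meaningful — with one-window tiling, boundary quantization
alone bounds precision near (r/(r+h))² for halo h up to one window);
500 training patches per class; a 97-colony labelled training cohort and a
40-colony held-out cohort for picking-day recovery; 200 sequences of length
16 for parameter recovery of a known 4-state model; exhaustive-enumeration
checks at K ≤ 4, T ≤ 8; and random-walker oracle checks on all grids up to
4 x 4 with up to 3 labels. These sizes are the package's validation
choices: large enough that every acceptance property is exercised at its
stated tolerance, small enough to run on one CPU in minutes.

## Numerical choices and degenerate inputs

* Forward–backward runs scaled (per-step normalizers) with a per-row
  log-max shift before exponentiation, so late-day posteriors of
  far-from-training tracks do not underflow.
* Emission variances are floored at 1e-6 (z-scored scale) every M-step;
  collapse therefore re-floors and continues rather than erroring.
* Viterbi ties break toward the lower state index; the enumeration oracle
  in the tests implements the same rule, so agreement is exact.
* Track-linking ties break by overlap, then candidate area, then region id,
  making tracking independent of label enumeration order.
* The random walker adds 1e-10 to every edge weight to keep the lattice
  connected at extreme β; the linear solve's residual is checked against
  the stated tolerance and reported on failure.
* Constant frames: `autolevels()` returns a constant mid-range frame;
  `pearson_overlap()` reports r as undefined with a reason instead of
  erroring.
* A prior colony absent from the current detection map yields an empty
  region (the colony is lost) without an exception; a track simply has no
  area that day and the growth curve omits the day.
* Model files store doubles at 17 significant digits, the round-trip-exact
  precision for IEEE doubles, so reloaded models decode bit-identically.

## Known limitations

Colony merge and split events are not handled; boundaries are pixel-, not
sub-pixel-accurate; the classifier contract is texture-level, so a real
deployment needs the corrective fine-tuning loop against operator labels;
the picking threshold is protocol-specific and should be re-calibrated per
cell system; and the 16-bit label masks are written as TIFF (the PNG writer
available to the package is 8-bit only).
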