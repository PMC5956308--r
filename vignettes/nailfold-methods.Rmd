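---
title: "Measuring nailfold capillary structure and flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nailfold capillary structure and flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nailfold)
```

## The measurement problem

At the nailfold the distal-row capillaries run parallel to the skin surface,
so a magnified video camera sees each one as a hairpin: two roughly parallel
limbs joined by an apical turn. In systemic sclerosis (SSc) these loops
dilate (up to "giant" calibre), become tortuous and disorganised, drop out
(reduced density), and carry slower blood. Primary Raynaud's phenomenon
(PRP), by contrast, leaves the capillaries structurally normal, which makes
the SSc-vs-PRP/HC contrast the clinically interesting classification.

`nailfold` implements a fully automated measurement chain from raw video
frames to six per-nailfold parameters and on to cohort-level statistics:

1. **mosaic** — register overlapping frames by translation and composite a
   still image;
2. **detect** — find every distal-row capillary apex, trace the path along
   both limbs to 100 µm, and measure width and orientation at each point;
3. **flow** — estimate the mean red-blood-cell speed along each path by
   optical flow;
4. **morphometry** — collapse paths to capillary, nailfold and participant
   summaries;
5. **cohortstats** — ANOVA/Tukey group comparisons, per-parameter ROC areas,
   and stepwise logistic combination scored by leave-one-out cross-validation
   (LOOCV).

Because no clinical images ship with the package, a **software phantom**
generates hairpin capillaries with exact ground truth (geometry, widths,
orientations, cell speeds, stage offsets); every stage is validated against
it.

## The six parameters

For each traced capillary the per-point orientations θ (axial, defined
modulo π) are summarised by the *mean resultant length of the doubled
angles*,

$$R = \left| \tfrac1n \sum_k e^{2 i \theta_k} \right| \in [0, 1],$$

which is 1 when all orientations coincide and 0 for balanced axial spread.
Doubling is what makes the statistic well defined for orientations, where θ
and θ + π are the same axis. Per capillary this is the **shape score** (a
straight hairpin's two limbs share one axis, so R is high; a tortuous
capillary's orientations wander, so R is low; the apex turn itself
contributes a fixed penalty, which is why even clean hairpins score well
below 1 once the turn is included). The capillary's **principal
orientation** is the corresponding axial circular mean,
arg(Σ e^{2iθ})/2 — an arithmetic mean of raw angles would be ill-defined
mod π.

The image-level parameters for one digit are then

* (a) **capillary density**: `n / span` apices per millimetre, the span
  measured from the left-most to the right-most apex. The alternative
  `(n − 1)/span` convention was considered and rejected in favour of the
  literal "number of apices per millimetre" reading; the choice is applied
  identically to ground truth and measurement, so validation is unaffected.
* (b) **mean width** and (c) **max width** over capillaries, each capillary
  contributing its mean per-point width;
* (d) **shape score**: mean of the per-capillary shape scores;
* (e) **derangement score**: the same dispersion statistic applied to the
  capillaries' principal orientations — low when capillaries point every
  which way;
* (f) **mean flow velocity** over the capillaries with a valid flow
  estimate.

Participant-level values are unweighted means over the available digits,
with per-parameter exclusion: a digit with unmeasurable flow still
contributes its structural parameters, and a digit with fewer than two
apices contributes everything except density.

## Phantom model

`phantom_spec()` fixes the study conditions; the defaults are a
healthy-control nailfold imaged by the system the package models: 120
frames/s, 1 µm/pixel, 640 × 480 frames, ~150 µm apex spacing, 11.8 µm
capillary width, 0.311 mm/s cell speed (the HC cohort means reported for
this class of system), 100 µm limbs, and moderate tortuosity (0.2 rad) and
derangement spread (0.25 rad about vertical). SSc-like phantoms are made by
widening, slowing and disorganising these values (see `phantom_cohort()`).

Geometry is generated in micrometres and only converted to pixels at render
time. A hairpin is two limbs of fixed arc length joined by a semicircular
apex turn; the turn radius defaults to 1.5 × width so the limbs are clearly
resolved at all widths probed (8–25 µm, the upper end standing in for the
giant-capillary regime). Tortuosity is smooth band-limited angular noise
added to the limb tangents, rescaled to the requested SD; the turn is kept
clean so "the apex" stays a well-defined point. Principal orientations are
drawn from a wrapped normal about vertical.

The photometric model is dark-on-bright with a Gaussian cross-section whose
**full width at half the profile depth equals the ground-truth width** —
the same definition `measure_widths()` estimates, so width ground truth is
meaningful end to end. Videos add dark elliptical cell blobs advected along
the centreline at exactly `velocity × 1000 / frame_rate` µm per frame with
Poisson-spaced plasma gaps, over static, lower-contrast vessel walls. A
smooth static "skin texture" field (SD 0.04, 12 µm correlation length) and
per-frame white noise complete the scene; the texture matters because a
perfectly flat background makes translation registration ill-posed along a
straight vessel (the aperture problem), which real nailfold images never
exhibit. Cells wrapping from the venous back to the arterial end are the
one deliberate artefact of the cell model; they occasionally produce a
single outlying frame-pair speed, which the per-pair mean absorbs.

What the phantom does **not** emulate: haemorrhages, avascular areas,
illumination gradients, lens distortion, out-of-plane motion, pulsatile
flow. Passing phantom validation therefore demonstrates the correctness of
the measurement chain, not clinical performance.

## Stage design choices

**Mosaicking.** Translation-only registration (the motorised stage moves
in-plane): normalised cross-correlation over a ±20 px window around the
nominal stage offset, parabolic sub-pixel refinement, and per-pixel mean
compositing, which doubles as temporal denoising. The 20 px default covers
the worst-case difference of two ±10 px nominal jitters. A pair with
insufficient overlap or a correlation below 0.3 falls back to its nominal
offset and flags the mosaic rather than failing.

**Detection.** A multiscale ridge filter: Gaussian second-derivative
(Hessian) kernels at scales matched to vessel widths of 8–16 µm (σ =
width/2.355), γ-normalised by σ², larger eigenvalue kept where positive
(dark tube), per-pixel maximum over scales; the orientation map is the
along-ridge eigenvector direction mod π. Apices are found where the
response is high *and* the smoothed doubled-angle orientation field curves
rapidly *and* the ridge continues on both sides along the local tangent —
the last factor distinguishes the apical turn from a limb end, where the
orientation field also curves sharply as the response dies. Candidates are
greedily non-maximum-suppressed at 50 µm, refined to the topmost
strong-ridge pixel of their turn, and restricted to the distal row, kept as
a 40 µm band below the topmost apex (the paper-level notion "distal row"
needs an operational rule; a band half-height comfortably above the apex
placement jitter and below the limb length works across all phantoms).
Tracing steps 1 µm along the orientation field with ridge-crest re-centring
and stops at 100 µm arc length, the image border, or when the response
falls below 25% of the apex response.

**Width.** At each path point the intensity profile perpendicular to the
local orientation is sampled (±40 µm, 0.25 px steps), lightly smoothed; the
width is the full width at the half-depth level, background taken as the
95th percentile of the profile. Points whose profile leaves the image or
shows no crossing are flagged non-measurable and excluded; a capillary with
more than half its points unmeasurable raises an error and is dropped (with
a warning) rather than reporting a biased width.

**Flow.** Dense gradient-based optical flow: structure-tensor (Lucas-Kanade
style) solves over a 15 px window, three warp iterations, and a two-level
pyramid so the ~4 px/frame displacements of fast capillaries (0.5 mm/s at
120 fps, 1 µm/px) stay inside the linearisation range. Validity requires a
well-conditioned structure tensor. Per consecutive visible-frame pair the
flow is sampled at the path points and projected on the local tangent;
**speed**, the absolute projection, is averaged because arterial-vs-venous
sign is not defined for an axial path. Only *motion-active* points count —
local temporal-difference energy above max(1.5 × median, median + 6 × MAD)
of the crop — otherwise static wall texture between cells dilutes the
average; with no active point the pair contributes 0 (a genuinely static
scene). Per-pair speeds are converted by px/frame × µm/px × frames/s /
1000 = mm/s and averaged (a trimmed-mean option exists but is off by
default). A capillary needs at least one consecutive pair of frames with
its apex visible (inside the frame with 20 px margin); otherwise it is
excluded from the flow average and logged.

**Statistics.** Group differences use `aov()` and `TukeyHSD()` (the
Tukey-Kramer form handles the unequal 50/12/50-style group sizes). ROC
areas use the rank (Mann-Whitney) statistic with half-credit ties —
identical to the trapezoidal area — with Hanley-McNeil standard errors; the
single-parameter ROCs auto-orient so the reported area is ≥ 0.5. The
combined models follow the classic stepwise recipe: bidirectional AIC moves
on an initial all-main-effects *linear* fit, then a maximum-likelihood
logistic refit of the selected terms (inputs z-scored; coefficients
reported on the original scale; perfect separation falls back to a
ridge-penalised fit and is flagged). The selection is implemented directly
on model matrices for speed inside cross-validation loops and is
unit-tested to reproduce `stats::step()` move for move. LOOCV reruns the
*entire* selection-plus-fit per held-out subject; an intercept-only fold is
scored as an uninformative tie (0.5) because its leave-one-out prevalence
is perfectly anti-correlated with the held-out label and would bias the
null cross-validated area towards 0. The combined ROC on out-of-fold
probabilities uses fixed orientation (higher probability = SSc), which is
what keeps the null calibration centred at 0.5. The structure-only model
uses parameters (a)–(e); the full model adds flow.

LOOCV is accepted from four subjects upward so that small demonstration
cohorts can produce a complete report; areas from such cohorts carry large
standard errors and are illustrative only.

## Validation suite and problem sizes

The package's own acceptance checks (also recomputed by
`scripts/acceptance.R`) run at these sizes, chosen to finish in a few
minutes on one CPU while keeping every operating point of interest:

* dispersion statistic vs a brute-force resultant-length oracle on 1,000
  random orientation sets (agreement to 1e−12; {0, 0, π/2} gives exactly
  1/3);
* ROC area vs exhaustive pairwise counting on 500 random integer-score
  instances (exact agreement);
* mosaic offsets on 3-tile phantoms with ≤ 10 px nominal jitter, 20 seeds:
  maximum error ≤ 0.5 px;
* apex counts within ±1 across 4–12 capillaries, 20 seeds; width bias
  ≤ 10% at true widths 8, 12, 16 and 25 µm on noise-free phantoms; density
  exact on ground-truth geometry;
* flow within 15% of truth at 0.1, 0.235, 0.311 and 0.5 mm/s (the SSc and
  HC group means among them), 10 seeds per speed, 20-frame videos; static
  video at or below 0.02 mm/s;
* LOOCV null calibration: median combined area over 50 null cohorts
  (n = 100) inside [0.45, 0.55]; on a strongly separated synthetic cohort
  the combined model at least matches the best single parameter within one
  standard error;
* a six-subject, two-digits-each synthetic cohort runs end to end to a
  complete report, bit-identically under a fixed seed.

## Numerical conventions and degenerate inputs

Images are matrices with rows = y (downward), columns = x, 0-based pixel
coordinates at integer centres; offsets place the moving frame's origin in
the fixed frame. All geometry is stored in µm; `pixel_scale_um` converts at
render/measure time only. Every generator is a pure function of
`(spec, seed)` and restores the caller's RNG state. Degenerate inputs are
defined rather than left to chance: a constant image yields zero ridge
response and an empty apex list; identical group values yield F = 0 with no
flags; an all-tie score vector yields area 0.5; a single-apex digit has
undefined density but valid widths; equal-score apex merges keep the
leftmost candidate.

## Known limitations

* The detector is a hand-crafted ridge/curvature pipeline, not a learned
  one; on real images with haemorrhages or low contrast its recall would
  need re-evaluation.
* Width estimates inherit the FWHM definition; absolute widths from other
  definitions (e.g. edge-to-edge on deconvolved profiles) will differ
  systematically.
* Flow is reported as unsigned speed; pulsatility and direction are out of
  scope.
* Phantom realism bounds what the validation can claim (see above); in
  particular the phantom's vessel contrast and noise place it in a
  high-SNR regime (SNR ≥ 10).
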