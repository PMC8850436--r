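---
title: "Measuring vocal size exaggeration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vocal size exaggeration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vtmod)
```

# The scientific problem

Speakers can volitionally raise or lower the larynx, shortening or
lengthening the vocal tract and shifting the spacing of formant
frequencies; listeners read this spacing as a cue to body size.  vtmod
implements a measurement chain for this behaviour in three linked
domains:

1. **Articulation** — the shape of the vocal-tract air channel in
   midsagittal real-time MRI, summarized by functional PCA, with one
   component quantifying tract length (larynx raising/lowering).
2. **Acoustics** — fundamental frequency and the first four formants,
   expressed as semitone modulation relative to baseline and pooled into
   an apparent vocal tract length (aVTL).
3. **Perception** — listeners' height ratings of modulated voices,
   analysed with a linear mixed model.

Per speaker, skill is quantified by the difference of condition medians:
the vocal-tract modulation skill score is the median length-component
score over frames imitating *small* targets minus the median over frames
imitating *large* targets, and the acoustic analogue applies the same
difference to semitone modulations.  Positive scores mean the speaker
moved in the instructed direction; the scores' association across
speakers (Pearson r, t with n − 2 df) answers whether articulatory and
acoustic skill are one ability.

# The synthetic phantom and what it does (and does not) emulate

None of these stages can be validated without ground truth, so the
package ships a generative phantom.

## Tract geometry

The air channel is a bent tube in the image plane: a vertical pharyngeal
limb, a horizontal oral limb, a quarter-circle bend joining them, offset
by a half-width (11 mm) on either side of the centerline and closed by
rounded lip and glottis caps.  Five parameters, all dimensionless and
bounded, deform it:

* `tongue_position` (back −1 … front +1): the antisymmetric
  first-derivative lobe of the tongue constriction — a forward/backward
  tilt of the tongue mass along the inner wall.
* `larynx_height` (lowered −1 … raised +1): moves the glottal end of the
  pharyngeal limb, changing centerline length by exactly 15 mm per unit.
  Only pharyngeal points move; the oral limb is untouched.
* `body_scale` (> 0): isotropic scaling about a fixed mid-tract landmark.
* `tongue_shape` (flat −1 … domed +1): a volume-preserving doming of the
  constriction (Mexican-hat profile: the dome rises while the margins
  dip).
* `curvature` (−1 … +1): the bend radius (±25 % per unit).

Two geometric choices deserve explanation because the design was
genuinely open:

* **The scaling origin sits mid-tract (near the velopharyngeal bend),
  not at a cranial landmark.**  Scaling about a point above the tract
  is almost indistinguishable from larynx lowering — both mostly elongate
  the pharynx — and a principal-component analysis cannot attribute
  variance between two nearly collinear modes.  An overall-size mode
  that expands the tract around its middle is equally interpretable and
  is geometrically distinct from the length mode.
* **Tongue position is a fixed antisymmetric field rather than a
  translating bump.**  Translating a Gaussian constriction is linear
  only for displacements well below its width; at realistic amplitudes
  the quadratic remainder behaves like a spurious extra shape mode.  The
  first-derivative field is the linearization of translation, is exactly
  linear in the parameter at any amplitude, and is L2-orthogonal to the
  doming field.

`plant_shape_modes()` draws parameter samples whose realized covariance
is exactly diagonal (whitened normal scores) with standard deviations
calibrated by finite differences so that the five modes contribute
prescribed shares of contour variance — by default the decomposition
observed on the study data (40.7 / 34.0 / 9.3 / 8.2 / 3.4 %).  The
default overall scale (0.12 mm RMS) keeps every mode in its linear
range; the constriction tilt changes wall arc length quadratically, and
at larger amplitudes that term re-appears as a sixth variance component.

## Imaging

Frames are 88 × 110 pixels at 2.5 mm — the in-plane geometry of the
acquisition the chain is designed for — with air dark (10), soft tissue
bright (200), and a cranial arc plus four vertebral bodies brighter
still (255) carrying a smooth sinusoidal intensity texture.  The texture
matters: real T1 images are not piecewise constant, and a registration
metric driven only by edges has a shallow, alias-prone optimum.  The
scene is evaluated analytically at inverse-transformed pixel positions
with 3 × 3 subpixel supersampling, giving partial-volume edges rather
than jagged ones, and Gaussian noise is added per pixel.  Rician noise,
coil bias and motion blur are deliberately not modelled; the downstream
steps are threshold-based and insensitive to the distinction at the
noise levels tested.

Sessions draw per-frame rigid head motion (SD 0.5°, 1 mm), trial-to-trial
articulatory jitter (SD 0.05 on each parameter; within-speaker
variability is a free parameter because no published value exists), and
set `larynx_height = baseline ± modulation_amplitude` for small/large
imitation targets.  The carrier words bead/bard map to tongue positions
+0.8/−0.8.

## Acoustics and ratings

Formants follow the quarter-wavelength resonator: `F_i = (2i−1)c/(4L)`,
`c = 35 000 cm/s`, multiplied by fixed word-perturbation vectors (bard:
F1 × 1.4, F2 × 0.75; bead: F1 × 0.55, F2 × 1.45) that reproduce the
front/back vowel separation qualitatively, plus lognormal measurement
noise of configurable CV.  Because aVTL averages the per-formant length
estimates, the noiseless generator and `compute_avtl()` are exact
inverses — the chain's internal consistency check.  Ratings are built
from a grand mean, fixed effects of condition, f0 and skill group,
normal listener and speaker random effects, residual noise, and clipping
to the slider range (females 145–180 cm, males 155–190 cm, linear between
the printed anchors).

What passing tests on this phantom do **not** show: robustness to
through-plane motion, real coil inhomogeneity, articulatory shapes
outside the bent-tube family, LPC formant-tracking errors (the known
f0/F1 measurement floor is out of scope — measurements are inputs here),
or listeners who do not behave like a linear mixed model.

# Segmentation: parameters and rationale

* **Registration** maximizes normalized cross-correlation over a
  static-structure mask (skull + vertebrae, supplied per subject; the
  phantom provides its ground-truth mask), with multi-start Nelder–Mead
  over rotation and bounds ±10°, ±20 mm.  Both images are pre-smoothed
  with a 1-pixel Gaussian: without it, residual rasterization aliasing
  biases the correlation peak by up to ~1°; with it, planted poses are
  recovered to ≲0.3° and ≲0.25 mm.  The default reference is a single
  representative frame shared across subjects; per-subject references
  are supported.
* **Candidate localization**: pixels whose temporal variance exceeds the
  0.85 quantile (raised to at least 8 × the median variance so flat
  measurement noise cannot flood the mask), restricted to the eroded
  head interior and away from static structures.  The raw variance op
  applies a 1-pixel closing.  The pipeline layer then unions a second
  evidence source — pixels dark in the temporal mean, i.e. the
  always-air channel core, which by definition has *no* variance — and
  applies a 6-pixel closing, hole filling, largest-component selection
  and a 4-pixel dilation.  This widening stands in for the analyst's
  manual adjustment of the variance estimate into a "may sometimes
  contain vocal tract" mask; without it the stable air core would be
  excluded and the extracted region would fragment.
* **Classification**: Otsu's between-class variance maximization on the
  masked histogram (256 bins); a low-contrast flag is raised when the
  class means differ by less than 30 intensity units.
* **Outlines**: marching squares at the 0.5 level of the largest
  air-connected component, sub-pixel by linear interpolation, oriented
  canonically with the start vertex at the anterior-most (lip) boundary
  point.  Components under 10 px are treated as artifacts.

On noiseless frames with planted motion this chain achieves Dice ≥ 0.95
(typically ≥ 0.98) and outline Hausdorff distance within one pixel;
accuracy degrades gracefully with noise (still ≥ 0.97 Dice at SD 10).

# Functional PCA: numerical choices

Curves are resampled to 100 equal-arc-length points (closed outlines are
cut at the lip landmark; open glottis-to-lip polylines are also
supported, but closed outlines are the pipeline default because
segmentation produces closed boundaries and an open trace would need an
arbitrary cut).  x(t) and y(t) are concatenated, so coupled deformations
are a single mode; separate per-coordinate PCAs could not express them.

The inner product is the plain discrete (uniform-weight) one.  A
trapezoid rule differs only in end-point weights, but with uniform
weights the functional eigenproblem coincides *exactly* with the
eigendecomposition of the sample covariance of the stacked coordinates,
which makes the fit verifiable against a brute-force oracle to 1e−8 and
makes eigenvalues interpretable as mm² score variances.  The optional
B-spline stage (default 40 cubic basis functions, second-difference
penalty 0 — i.e. least-squares projection; the basis and smoothing level
are package choices, not established values) acts as a preprocessing
projection; with smoothing disabled the raw grid is used.

Eigenfunction signs are arbitrary, so `orient_components()` fixes them
against canonical deformations generated from the phantom (for the
length component: the raised-larynx derivative, making positive scores
index a shorter tract), and `match_component()` identifies which fitted
component tracks length by cosine similarity — on session data, where
larynx excursions dominate, the length mode is typically fPC1, while in
the five-mode validation mix it is fPC2.  Reconstruction is
`mean + Σ score_k · eigenfunction_k`, warning beyond ±3 SD per component.

Degenerate inputs behave predictably: identical curves give zero
eigenvalues and scores; translation of all curves moves only the mean;
scaling by s multiplies eigenvalues by s² and leaves variance proportions
unchanged.

# Skill scores, grouping and associations

Words and f0 directions are pooled within vocal-tract condition before
medians, giving one score per speaker.  The small-minus-large direction
is used for every measure, with one nuance: for f0 the imitation target
direction is the f0 shift itself (the ±4 f0 targets occur in both
small and large formant conditions), so the f0 score groups takes by the
sign of the f0 target and measures pitch-matching range.  aVTL
modulation is the semitone log-ratio of lengths and therefore carries
the opposite sign of formant modulation; its association with tract
skill is correspondingly negative.  Ranking is within sex (a
within-sex-by-training variant is available), ties break by speaker id,
and exclusion flags are honored before ranking.  Associations report a
one-sided p by default (switchable), matching the reporting convention
of the study this chain follows.

# Perception analysis

Treatment coding uses baseline condition, poor group and female voices
as references.  f0 modulation enters as continuous semitones by default
(a factor version is available).  On the five-condition stimulus set the
f0 main effect is structurally aliased with its vocal-tract interactions
(f0 = 0 exactly when the condition is baseline); the design is full rank
on a complete factorial, and fitters drop the aliased columns otherwise.
Fitting is REML via lmerTest/lme4 with a listener intercept and
per-speaker intercept + f0 and condition slopes; small cohorts that
cannot identify the slope covariances can request an intercepts-only
structure.  Two edge cases are handled explicitly: when the ratings are
an exact function of the fixed effects (zero residual variance) the REML
solution coincides with least squares and is computed that way; and
marginal gradient warnings from lme4's convergence checker (max|grad|
≤ 0.05) are recorded rather than treated as failure.  Condition
contrasts (small vs baseline, large vs baseline, per group and sex) come
from estimated marginal means with Satterthwaite degrees of freedom.

# Problem sizes used in validation

The shipped validation suite runs the five-mode recovery at n = 500
contours, oracle equivalence at 200, segmentation fidelity on 100
noiseless frames across five body plans, end-to-end skill recovery on a
20-speaker cohort at one frame per trial, correlation calibration at the
study's n = 52 with 500 replicates and a 10 000-draw permutation null,
and perceived-height recovery at 80 listeners per sex over 200 stimuli.
These sizes were chosen so each check is statistically decisive at its
tolerance.

# Known limitations

* The phantom is 2-D and piecewise-analytic; it validates the numerics,
  not clinical robustness.
* The aVTL pooling is the plain quarter-wavelength average; regression-
  based pooling across formants exists in the literature and the
  constant c and the formula are exposed for replacement.
* Variance-based localization assumes the articulators actually move
  during the session; a speaker holding one posture throughout would
  need a manually supplied candidate mask.
* The mixed model assumes linear, homoscedastic rating behaviour;
  slider-end clipping is simulated but not modelled in the likelihood
  (negligible at realistic effect sizes, a bias source at extreme ones).
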