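---
title: "A Bayesian observer model of gaze perception with salience priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian observer model of gaze perception with salience priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeprior)
```

## The inference problem

An observer watches a "gazer" fixate a point on a planar surface and must
judge where on that surface the gazer is looking.  Two cues are available:
the directional signal from the gazer's eyes, and — when an image is
projected onto the surface — expectations about which locations in that
image are likely to attract attention (visual salience).  The model treats
the judgment as Bayesian inference over the plane location \(G_{x,y}\):

\[
p(G_{x,y} \mid D, I) \;\propto\; L(G_{x,y} \mid D)\, \cdot\, p(G_{x,y})^{\delta},
\]

where \(D\) is the eye cue (one of 33 fixation directions), \(L\) is an
empirically measured elliptical likelihood, \(p(G_{x,y})\) is a normalized
salience map of the projected image \(I\), and \(\delta\) is a per-subject
weight on the salience cue.  \(\delta = 0\) reduces the model to an
"eyes-only" observer; \(\delta = 1\) is unweighted Bayes' rule.  All maps
live on a discrete working grid over the frame (110 × 147 cells by
default, i.e. the 550 × 733-pixel frame divided by 5) and are renormalized
to sum to 1 after every operation; clicked locations are binned to cells
with a half-open convention (left/top edges inclusive).

## The likelihood: measured, not modelled

The likelihood for each eye direction is a bivariate Gaussian ellipse fit
(`fit_ellipse()`, divide-by-*n* maximum likelihood) to the subject's
repeated judgments on a blank gray surface — 20 clicks per direction across
four gray blocks in the emulated design.  Ellipticity is what a cone of
gaze predicts: projecting an isotropic angular Gaussian of half-width
\(\sigma\) through the eye point onto the plane gives a Gaussian with
tangential s.d. \(\sigma r\) and radial s.d. \(\sigma r^2/L\) (eye–plane
distance \(L\), eye–target distance \(r\)); `cone_ellipse()` implements
this first-order projection and is validated against a Monte-Carlo
ray-tracing oracle in the tests.

Because each ellipse is estimated from only 20 clicks, the raw fits
overfit their training blocks.  To prevent this, the
diagonal of each covariance is multiplied by a factor \(\kappa \ge 1\)
tuned by leave-one-block-out cross-validation (`crossvalidate_kappa()`,
grid 1.0–3.0 by 0.1, ties toward the smaller value).  On simulated
Gaussian observers the CV optimum lands around \(\kappa \approx 1.4\text{–}1.6\)
— not because the noise is heavy-tailed, but because predictive log-score
optimality must compensate the sampling noise of a 15-point covariance
estimate.  Human observers in this paradigm show the same optimum, and it has
a consequence discussed below.  A subject is retained only if the best
cross-validated mean held-out log-likelihood per trial beats chance, defined
as the uniform distribution over the working grid; a uniform-random clicker
is excluded by this rule with probability approaching 1 as trials grow.

## The prior: center-bias-corrected salience

Salience maps of natural images share a strong center bias, and the
measured likelihood already absorbs each subject's own spatial biases.
Using raw maps as priors would double-count that tendency, so each map is
divided by the pixelwise average of all 165 maps (`average_map()`,
`center_correct()`); the corrected map is normalized only when used as a
prior.  The corrected cohort satisfies an exact identity — the pixelwise
mean of all corrected maps is the unit map — which the tests assert to
1e-9.  An epsilon floor (1e-12, applied uniformly before any division,
logarithm or exponentiation) keeps every map strictly positive so that
\(\delta > 1\) cannot create zeros.

The package does not reimplement trained salience models; externally
computed maps can be read from plain-text matrices (`read_map()`).  As a
low-level stand-in for features-only salience it provides
`contrast_salience()`, a two-scale difference-of-Gaussians contrast energy
(edges replicated at the border so the frame itself is not detected as
contrast).

## Fitting the prior weight and comparing models

For each subject, `fit_delta()` maximizes the summed log probability mass
of the clicked cells over \(\delta\).  The objective is concave — it is
\(\sum_t [\delta \log p_t(\text{click}) - \log Z_t(\delta)]\) and each
\(\log Z_t\) is a convex cumulant-style function of \(\delta\) — so a
coarse bracketing grid (step 0.25) followed by golden-section refinement
(`stats::optimize`, tolerance 1e-3) finds the global optimum cheaply.  The
search interval is \([-2, 5]\): negative weights are psychologically
implausible but must be reachable, otherwise the mismatched-prior null
(below) would be biased upward by \(E[\max(0, \text{noise})]\).  Flat
objectives (e.g. uniform priors) return 0 with an `unidentifiable` flag.

`compare_models()` scores each image-block click under the full model and
the eyes-only reduced model and accumulates the log-likelihood ratio in
nats; the primary comparison uses the unweighted prior (\(\delta = 1\)),
which fits no parameters to the image-block data, with `delta = "fit"`
available as the secondary analysis.  The mismatched-prior control
(`mismatch_priors()`) re-scores the same clicks after a seeded derangement
of the image-to-map assignment, so the prior keeps the statistics of real
maps but carries no image-specific information.  Cell mass (not density)
is used throughout; absolute LLR values therefore depend on the working
resolution, but signs and comparisons do not.

## The synthetic cohort: what it emulates

No judgment data are deposited, so the package ships a generator whose
defaults encode the study conditions the analysis assumes:

* **Geometry** — eyes 115 cm from the surface, camera at 160 cm, axis
  height 125 cm; 550 × 733-pixel frame.  The physical frame extent is a free
  parameter; the default 50 × 66.64 cm preserves
  the pixel aspect ratio and comfortably contains the target lattice.
* **Targets** — the origin plus 32 marks in seven rows (5/4/5/4/5/4/5),
  10 cm within-row spacing, even rows offset 5 cm; the vertical row pitch
  is likewise unstated and defaults to 10 cm.
* **Observers** — `make_cohort()` draws a gaze-cone half-width per subject
  (lognormal, median 0.02 rad ≈ 2.3 cm on the plane, CV 20%) plus 1.5 cm
  isotropic motor noise; chosen to put total click scatter near 3 cm,
  the scale human likelihood ellipses show in this task.  One RNG stream per
  subject, derived from the master seed, makes cohorts reproducible and
  order-independent.
* **Salience fields** — `make_salience_field()` builds baseline + Gaussian
  blobs (8 blobs, 5 cm scale, mildly center-concentrated positions, mean
  peak 3× baseline) multiplied by a smooth center-bias envelope (peak 2.5×,
  s.d. 0.3 of the extent).  These reproduce the two statistics the analysis
  relies on: a strongly center-biased cohort average, and image-specific
  structure with enough contrast that \(\delta\) is identifiable from 165
  trials (per-subject s.e. ≈ 0.3).
* **Judgments** — gray-block clicks are drawn from the subject's true
  ellipse, truncated to the frame by resampling; image-block clicks are
  drawn from the discrete posterior with the subject's generative weight
  `delta_true`, using the same center-corrected normalized priors the
  analysis later reconstructs.

What the generator does *not* emulate: photographic stimuli, real salience
algorithms' feature detectors, sequential effects, lapses, or any
correlation between image content and the gazer's true fixation (images
and directions are paired at random, as in the experiment).  Passing tests
therefore certify the pipeline's internal calibration, not the behavior of
human subjects.

### Two generative modes, and why recovery needs the "measured" one

`simulate_exp1()` offers two block-1 modes.  With
`block1_likelihood = "cone"` the posterior uses the subject's true cone
ellipse.  This is the natural forward simulation, but it makes the fitted
\(\delta\) systematically *smaller* than `delta_true`: the analysis
necessarily uses the \(\kappa\)-inflated fitted ellipses, and widening the
likelihood by \(\kappa\) shrinks the apparent prior weight by roughly
\(1/\kappa\) (empirically, cohort mean ≈ 1.1 when `delta_true` = 1.5).
The measured \(\delta\) is, in other words, expressed in units of the
measured likelihood.  With `block1_likelihood = "measured"` the generator
first fits the subject's likelihood model from the just-simulated gray
blocks — exactly as the pipeline will — and samples block-1 clicks from
that measured likelihood.  This is the standard model-true design for
parameter recovery, and it is the faithful reading here because the model's
likelihood is *defined* empirically (the cone merely motivates
ellipticity).  `exp1_recovery_study()` and the reproduction script use the
measured mode; the attenuation in cone mode is a real property worth
knowing about when interpreting fitted prior weights, not an implementation
artifact.

## The viewing-duration experiment

Experiment 2 varies exposure duration (150–2400 ms, crossed with the 33
directions, twice per subject, three practice trials per block excluded
from analysis).  The generative schedule (`exp2_schedule()`) encodes the
hypothesis the analysis is designed to detect: likelihood s.d. multiplied
by \(1 + 30/\sqrt{d}\) (brief glimpses give wide eye-cue readings), and a
prior mixing weight \(\lambda(d) = \text{logis}((\log_2 d - \log_2 600))\)
shifting from the center-bias field toward image-specific corrected
salience as duration grows.  `duration_analysis()` then regresses
salience-at-click on \(\log_2\) duration per subject under four
definitions — the image's own raw map (`full`), the cohort average
(`average`), their ratio (`ratio`), and DoG contrast (`lowlevel`) — and
t-tests the per-subject slopes.  On the default 41-subject cohort the sign
pattern is the one the schedule is built to produce: negative slopes for the full and
average definitions (center bias dominates early), positive for the ratio
(locations more salient than is typical for their position are chosen late).
The log2 predictor is a package choice — duration effects in this task are
naturally multiplicative — and a linear-duration option is provided.  The `lowlevel` definition is a proxy for trained features-only
salience models and is flagged as such in reports.

## Numerical choices

* Working resolution 110 × 147 (a config knob); probability is cell mass at
  cell centers, renormalized per map.
* Gaussian evaluations are windowed at ±4 marginal s.d. (±5 for sampling);
  the excluded tail (< 1e-4) cancels in every within-window mass ratio.
* Covariance fits use divide-by-*n*; near-singular fits get a 1e-6 ridge.
* Ties in the \(\kappa\) grid resolve to the smaller value; the \(\delta\)
  optimum uses concavity as described above.
* Clicks landing outside the frame during simulation are resampled
  (truncation, not clipping), keeping map normalization meaningful.
* Reported problem sizes: the recovery study runs 20 master seeds × 22
  subjects × 825 trials; the duration analysis 41 subjects × 336 trials.

## Known limitations

* Absolute LLR magnitudes are resolution-dependent (cell mass, not
  density); only signs and differences are interpretable across
  resolutions.
* The chance-level exclusion rule is conservative: a widened, truncated
  Gaussian imitates uniformity well, so a uniform clicker is excluded with
  high but not unit probability at 660 gray trials.
* The synthetic salience family is stationary Gaussian-blob texture;
  conclusions about real salience algorithms require supplying real maps.
* Group inference uses one-sample t tests on per-subject estimates,
  as is standard in this paradigm; no hierarchical shrinkage is applied.
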