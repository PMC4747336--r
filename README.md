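# gazeprior

Bayesian modelling of human gaze perception with visual-salience priors.

## The problem

When you judge where another person is looking on a surface, the
direction of their eyes is a noisy cue. If an image is projected on that
surface, you also hold expectations about which locations are likely to
attract their attention. `gazeprior` implements an ideal-observer account
of this judgment and the full analysis pipeline needed to fit and test it:

```
p(G_xy | D, I)  ∝  L(G_xy | D) · p(G_xy)^δ
```

where `G_xy` is the gaze target on the plane, `D` the eye cue (one of 33
fixation directions), `L` an *empirically measured* elliptical likelihood
(a bivariate Gaussian fit to the observer's repeated judgments on a blank
surface, with a cross-validated variance-inflation factor κ), `p(G_xy)` a
normalized salience map of the projected image after division by the
cohort-average map (removing the center bias that the likelihood already
absorbs), and `δ` a per-subject weight on the salience cue. `δ = 0` is an
eyes-only observer; the full-vs-reduced comparison is scored as a
cumulative log-likelihood ratio over trials, with a mismatched-prior
(derangement) control. A second analysis regresses the salience of
clicked locations on log viewing duration under several salience
definitions.

The package is aimed at researchers in visual psychophysics and social
perception who want to fit these models to judgment data (CSV tables of
clicks, plain-text salience maps) or to study the pipeline's calibration
on its built-in synthetic observers.

## Worked example

Simulate a small cohort end to end — salience fields, five-block judgment
experiment, likelihood fits with κ cross-validation, center-corrected
priors, δ fits, matched and mismatched model comparisons:

```r
library(gazeprior)
cfg <- default_config(n_subjects = 5L, n_images = 60L, seed = 42L)
report <- run_exp1_pipeline(cfg, verbose = FALSE)
print(report)
#> Image-block pipeline report (seed 42)
#>   subjects: 5 (0 excluded at chance)
#>   cohort LLR, matched priors   : +33.6 nats
#>   cohort LLR, mismatched priors: -4.9 nats
#>   mean delta, matched   : 1.342 (t(4) = 18.59)
#>   mean delta, mismatched: 0.374

report$subjects[, c("subject", "kappa", "delta", "llr")]
#>   subject kappa    delta      llr
#> 1     S01   1.6 1.183334 5.768462
#> 2     S02   1.5 1.187017 5.962896
#> 3     S03   1.5 1.478601 7.287123
#> 4     S04   1.5 1.532252 8.284555
#> 5     S05   1.6 1.329083 6.251533
```

Reading the output: every simulated observer's cross-validated variance
inflation lands at κ ≈ 1.5–1.6 (the predictive optimum for ellipses
estimated from 20 clicks); the positive cohort LLR (+33.6 nats at the
unweighted δ = 1 comparison) says the salience prior improves the
eyes-only model on every subject, while the deranged-prior control is
negative (−4.9 nats) — a wrong image's salience map only adds noise. The
fitted weights recover the generative δ = 1.5 up to per-subject noise
(s.e. ≈ 0.3 at 165 trials).

The duration experiment is run the same way:

```r
rep2 <- run_exp2_pipeline(default_config(), verbose = FALSE)
rep2$analysis$group   # per-definition mean slope, t, df, p
```

which on the default 41-subject cohort gives negative duration slopes for
the full-map and average-map salience definitions (center bias dominates
brief exposures) and a positive slope for the ratio definition (with more
time, observers choose locations more salient than is typical for their
position).

See the methods vignette (`vignettes/gaze-salience-model.Rmd`) for the
model, the generator's assumptions, and numerical details.

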