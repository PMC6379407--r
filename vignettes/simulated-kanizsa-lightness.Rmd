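---
title: "Simulating attention-dependent lightness of illusory Kanizsa surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating attention-dependent lightness of illusory Kanizsa surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanizsaPSE)
```

## The phenomenon and the experimental logic

Six "pacman" inducers placed at the vertices of a hexagram imply two
overlapping illusory equilateral triangles: the three inducers at the
upright-triangle vertices imply an upright triangle, the other three an
inverted one. When the two inducer triads have opposite contrast polarity
(three black discs at 0 cd/m², three white at 40 cd/m², on a 20 cd/m² gray
background), the display is compatible with two competing surface
arrangements, and which illusory surface an observer attends can change the
lightness they perceive at the very same pixels: filling-in of a surface
bounded by black inducers tends to look *lighter* than the background, and
one bounded by white inducers *darker*.

`kanizsaPSE` turns that experiment into a fully synthetic, end-to-end
pipeline:

1. **Stimuli** (`render_kanizsa()`, `render_matching()`): luminance-calibrated
   rasters of the hexagram display and of the comparison display — an
   equilateral matching triangle (edge 6°) on filtered white noise — at five
   Gaussian blur levels, σ ∈ {0.1, 0.2, 0.5, 0.9, 1.9}°.
2. **Observers** (`make_population()`): a generative psychometric model of
   cued observers with condition-specific points of subjective equality
   (PSEs).
3. **Procedure** (`run_session()`): twenty interleaved 2-down 2-up staircases
   per observer, one per condition (5 blur levels × {homogeneous black,
   homogeneous white, mixed/black-cued, mixed/white-cued}).
4. **Analysis** (`build_pse_table()`, `group_summary()`): maximum-likelihood
   cumulative Gaussian fits per cell, Weber-contrast PSEs, white-minus-black
   difference scores with 95% CIs, JZS paired Bayes factors per blur level,
   slope comparisons, and a classical repeated-measures ANOVA.

All quantities live in Weber contrast percent,
$100\,(L_m - L_b)/L_b$, with $L_b = 20$ cd/m²; the staircase's luminance
levels are the affine re-expression $L_m = L_b(1 + c/100)$.

## Stimulus model

The rendering pipeline works in physical units throughout: positions in
degrees of visual angle, luminance in cd/m², with a display model (40 cm /
1024 px wide, viewed at 58 cm, hence ≈ 25.9 px/°). Images are individual
panels around the figure rather than full screens, which keeps rendering and
tests fast without changing any measurable property of the stimulus.

Decisions the stimulus description left open, and what this package does:

* **Hexagram size.** The inducer circumradius is not a given; we set it to
  $6/\sqrt{3} \approx 3.46°$ so that the implied illusory triangle has edge
  6°, identical to the matching triangle — the two surfaces being compared
  are then size-matched. It is a constructor argument if you want otherwise.
* **Noise model.** "White noise (mean 20 cd/m²)" fixes only the mean; the
  default is per-pixel i.i.d. uniform on [0, 40] cd/m² (mean 20, maximal
  range without clipping), seedable, with a truncated-Gaussian alternative
  (`noise_dist = "gaussian"`).
* **Is the matching triangle itself blurred?** The default blurs the noise
  field and composites the triangle sharp; `blur_triangle = TRUE` filters
  after compositing. The PSE analysis never consumes pixels, so this choice
  affects only exported images.
* **Anti-aliasing.** Pacman and triangle boundaries get sub-pixel coverage by
  4×4 supersampling; the jaw is a 60° wedge whose bisector points at the
  figure center.
* **Blur.** `apply_blur()` is a separable Gaussian convolution with
  σ in degrees, unit-mass kernel (radius 4σ), and constant-extension
  boundaries at the background luminance, so the global mean of figures
  inside the frame is preserved to < 0.1%. `estimate_edge_sigma()` fits a
  Gaussian-CDF profile to a rendered step edge and recovers each σ in the
  blur set to within 5%, which is the QA loop closing the rendering model on
  itself.

Two invariants worth stating because the analysis leans on them: the mixed
display is pixel-identical whichever triangle is cued (the cue lives in the
matching display's orientation only), and swapping inducer polarity maps an
unblurred image L → 40 − L exactly.

## Observer model

The probability of reporting the matching triangle "lighter" than the
attended illusory triangle is a cumulative Gaussian in Weber contrast,

$$\Psi(c) = \gamma + (1 - \gamma - \lambda)\,\Phi\!\big((c - \mu)/\sigma\big),$$

with condition-specific PSE μ, spread σ shared across cue polarity (the
paradigm predicts attention to shift the matching point, not the precision
of the match, so the generative model holds slopes equal across cue — a
claim the slope-comparison analysis can then test), and asymptote rates
γ = λ = 0.02 by default (staircase data barely constrain asymptotes, so
small fixed values are the stable choice).

On mixed trials two surface arrangements compete. With probability
`compliance` (default 0.95) the observer evaluates the cued surface;
otherwise they mis-select the competing one, i.e. μ of the opposite cue is
substituted. Mis-selection — not random guessing — is the default lapse
model because the competing percept is a concrete alternative surface, and
it produces the right signature: lowering compliance pulls the effective
black- and white-cued PSEs toward each other, which is one reason the mixed
effect is expected to be weaker than the homogeneous one. A guessing variant
(`noncompliance_mode = "guess"`) is available; symmetric guessing flattens
the psychometric slope but leaves the PSE in place, so the two lapse models
are empirically distinguishable in the fitted parameters. The simulation
cannot adjudicate whether a human's lapses are attentional mis-selection or
stochastic depth-ordering of the percept itself; it adopts the
attention-driven account as generative truth.

**Group-level defaults.** Measured effect sizes are not available to this
package (reading them off published figures is not a legitimate source), so
the default group PSEs are order-of-magnitude placeholders that encode only
the qualitative structure: homogeneous ±4 Weber% at blur levels 1–4, mixed
±2, the mixed effect reversing sign at the most extreme blur (∓2), and the
homogeneous polarity difference collapsing at the extreme blur with a shared
+3 lighter-bias (heavy blur merges a homogeneous inducer ring; observers
then show a general bias to call the interior lighter). Between-observer
jitter is Normal with SD 2 Weber% per condition; slopes are drawn from a
Normal(3, 1) truncated below at 0.5 Weber%. These were fixed once as
plausible magnitudes for a ±20% contrast matching task and are all
`population_config()` arguments; a configuration violating the sign
structure warns rather than errors, so null and reversed populations can be
explored deliberately.

## Staircase procedure

Each condition runs a transformed up/down track: two consecutive identical
responses move the matching contrast against the response direction (two
"lighter" → darker matching triangle), a move in the direction opposite to
the previous move is a reversal, the step starts at 10 Weber% and halves at
each reversal (so step = 10/2^k after k reversals), and the track ends at
the seventh reversal with the step at 0.078 Weber%. Start levels are uniform
on ±20%. Conventions the experiment's description leaves implicit, fixed
here: the response-run counter resets after every move; the first move
establishes a direction without counting as a reversal; the step is halved
*before* applying the reversal move; levels clip at ±100 Weber% (the
luminance range at a 20 cd/m² background), though clipping does not occur at
default parameters. Sessions interleave all twenty tracks by drawing an
unfinished condition uniformly at random each trial; a session is 600–800
trials and every track terminates (a 2-down 2-up rule always accumulates
reversals on a non-degenerate psychometric function; a hard trial cap guards
the pathological case).

For a symmetric psychometric function the 2-down 2-up rule targets the 50%
point, i.e. the PSE itself. Property tests verify that a deterministic
threshold observer is trapped within four final step sizes of its threshold
across the whole ±20% start range, and that the mean of the last four
reversal levels is an unbiased PSE estimator to within 0.5 Weber% for
Gaussian observers.

## Fitting and group statistics

Fits maximise the Bernoulli likelihood on raw trials rather than least
squares on binned proportions: staircases concentrate trials unevenly
across levels, and the trialwise likelihood constrains the PSE with every
observation. The optimiser works on (μ, log σ) — the log enforcing σ > 0 —
with analytic gradients, BFGS, and five deterministic starts (level
quantiles crossed with spread guesses), so fits are exactly reproducible
with no random restarts. A brute-force grid search over (μ, σ) at 0.05
spacing serves as an independent oracle in the tests; the optimiser matches
its minimum NLL to within 0.01. Cells that cannot be fit (all-identical
responses) are flagged `converged = FALSE` and kept, never silently dropped.

Group statistics mirror the original analysis where it is reproducible at
desk scale: per observer and blur level we take PSE(white-cued) −
PSE(black-cued) (negative = the white-cued surface looked darker), summarise
with mean and Student-t 95% CIs, and test each blur level with a JZS paired
Bayes factor — Cauchy prior on effect size with the default scale
√2/2 ≈ 0.707, evaluated by adaptive quadrature of the Rouder g-mixture to a
relative tolerance of 1e-8. The same machinery compares fitted slopes across
polarity. Two routes to the same Bayes factor (the g-integral and the
noncentral-t/Cauchy mixture) agree to 1e-8, and at t = 0, n = 15 the value
is 0.2624. A full Bayesian 5 × 2 repeated-measures ANOVA (the
model-averaging machinery of packages like JASP) is deliberately out of
scope; the pipeline reports per-blur paired Bayes factors plus a classical
within-observer ANOVA F-table on the difference scores instead. Bayes-factor
magnitudes observed on human data are not reproduction targets here — they
are functions of raw data this package does not have and does not model.

## What the synthetic data can and cannot show

The generator emulates the *statistical structure* of the experiment — the
design (15 observers × 20 conditions), the response model, the adaptive
sampling, between-observer variability, lapses, and the qualitative sign
pattern of the effects. Passing tests therefore demonstrate that the
procedure and analysis are correct and well-calibrated: staircases converge
to the generative PSE, fits recover it with |bias| < 0.5 Weber% and RMSE
< 1.5 Weber% at staircase trial counts, and the analysis reproduces the
configured effect structure in > 90% of replicate experiments.

They do not validate the psychology. Real observers are not stationary
cumulative Gaussians; real filling-in need not be symmetric in polarity;
serial dependencies, learning, and criterion drift are all absent; and the
default effect sizes are placeholders, not measurements. Any conclusion
about perception requires the human data this package deliberately does not
model.

## Problem sizes and numerical choices

The validation suite uses the study-scale design (15 observers, 20 tracks,
seven reversals) and 50 replicate experiments for the stochastic checks;
rendering tests use single panels at ≈ 26 px/° and the five-σ blur set.
Likelihoods clamp Ψ to [1e-9, 1 − 1e-9]; the Bayes-factor quadrature uses
`integrate()` with rel.tol 1e-8; edge-σ fits restrict the profile to a
window around the edge so constant-extension boundary effects stay out of
the fit. All randomness flows from one master seed through
`split_seed()`, so every stage can be rerun in isolation and whole runs are
bit-reproducible (`run_simulation()` is a pure function of its
configuration).

```{r, eval = FALSE}
# the whole pipeline, end to end
res <- run_simulation(run_config(seed = 1), out_dir = "results/experiment")
res$summary$differences
```
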