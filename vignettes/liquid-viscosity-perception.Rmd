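---
title: "Modelling visual viscosity perception with slow-fusion networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling visual viscosity perception with slow-fusion networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Estimating the viscosity of a liquid from a short movie is a hard visual
inference: the same liquid looks very different when poured, stirred,
sprinkled or splashed, and optical appearance (colour, lighting) varies
independently of the mechanics. `liquidperc` implements a desk-scale
modelling pipeline for this problem: a procedural generator of liquid movie
clips whose motion statistics are controlled by a dynamic-viscosity
parameter, a synthetic rating-observer model, a slow-fusion video regression
network trained to estimate viscosity, and a battery of analyses of the
network's internal representation (representational similarity analysis,
unit clustering, artificial lesions, activation maximization, capacity
compression, scene transfer, and centered kernel alignment across network
populations).

Everything runs from a single machine in minutes; the pipeline is the
object of study, not a production vision system.

## The stimulus model

Stimuli form a factorial design: `scene class (10) x viscosity step (16) x
scene variation x optical variation`. Viscosity values are logarithmically
spaced between 0.001 and 10 Pa·s (roughly water to molasses); all labels use
the linear step index 1..16. Each clip is 20 frames of 64 x 64 RGB at a
nominal 30 fps, cut from the end of a 120-step internal simulation so the
onset transient is never seen.

```{r}
library(liquidperc)
design <- make_design(10, 16, 5, 1)   # the 800-clip experimental layout
clips  <- simulate_clipset(design)
```

The simulator is deliberately simple — a 2-D particle/metaball system — but
its design is dictated by what the downstream analyses need:

* **Viscosity enters only through dynamics.** The step index sets a
  geometric ladder of terminal fall speeds (1.3 down to 0.12 px/frame);
  per-frame velocity retention is chosen so gravity balances damping exactly
  at that speed. Cohesion and blob radius grow with viscosity. Optical
  parameters are drawn from a stream that never sees the viscosity step, so
  colour cannot leak label information.
* **Sustained, textured motion.** Emission continues through the rendered
  window and is pulsed (travelling density waves) with per-particle radius
  jitter; a perfectly steady stream would be optically static and carry no
  motion signal. Particles fade in and out instead of appearing or being
  recycled abruptly.
* **Constant moving area.** With sustained emission the steady-state
  particle count scales like rate/speed, which makes mean optical flow
  (area x speed) viscosity-independent; per-scene particle caps pin the
  moving area so mean flow tracks speed.
* **Scene templates.** Ten interaction classes (pour, rain, stir, a
  withdrawn dipper draining, spray, twin-stream pour, drip, jet, sheet fall,
  fountain) with distinct backdrops. A discrete splash event was tried and
  rejected: whether the impact falls inside the 20-frame window depends on
  viscosity, which makes mean flow non-monotone by construction.

Scene variations randomise emitter position and velocity, geometry size and
liquid volume (±10–20%); optical variations randomise a palette (liquid
colour with a guaranteed luminance gap to the background, backdrop colour
and luminance, accent colour) and a small additive rendering-noise level.
The ranges of these nuisance parameters are free design parameters chosen to keep the
liquid visible and the motion statistic's within-condition variance modest.

Under these conditions the per-scene Spearman correlation between viscosity
step and mean optical-flow speed is −0.82 to −0.97 for every template
(measured over 50 random specifications per step). Pooled over all scenes
the correlation is about −0.77, because scenes differ in overall motion
energy; the per-template form is the property the generator is engineered
for.

The controlled reference set (`make_reference_set()`) renders one clip per
scene and step with all nuisance parameters at fixed canonical values.

## The observer model

`simulate_observers()` produces ratings on the 1..16 scale: the true step is
passed through a scene-specific response curve (gain, additive bias, and a
compressive/expansive exponent), then a per-observer constant bias and
trial noise are added, and the result is clipped to the scale. With all
noise terms zero the mean rating equals the true step exactly. Default SDs
(gain 0.3, bias 2.4, log-exponent 0.45, observer bias 1.0, trial noise 2.1)
were calibrated once so that, like the behavioural regime the pipeline
emulates, the physical step explains roughly two thirds of the variance in
variation-averaged mean ratings (R² ≈ 0.68 across seeds) and an individual
observer deviates from the mean observer by about 12% of the scale. These
are configuration knobs, not assertions.

## The slow-fusion network

`build_network(slowfusion_config())` builds the full-size architecture:
three convolutional stages whose parallel temporal pathways fuse with depth
(stage 1: 8-frame windows at stride 4, four pathways; stage 2: fuses
adjacent pathways, 12-frame receptive fields; stage 3: all 20 frames),
followed by a 4096-unit fully connected layer (FC4), dropout 0.5 and a
single linear output. The default optimiser settings are the reference
configuration (learning rate 1.110510e-5, momentum 0.43325, L2 4e-9, 30
epochs); kernel sizes and spatial strides are free parameters exposed in
the configuration. Filter banks are shared across the parallel pathways of a
stage by default — this makes "a unit" well-defined as one filter whose
response concatenates its maps across pathways, giving the 256/64/100 = 420
registered convolutional units; an independent-banks mode is available
(`share_pathway_filters = FALSE`) since the original convention is
ambiguous.

The engine is written in R on BLAS (im2col convolution, hand-derived
backward passes, SGD with momentum). `slowfusion_config_small()` is the
desk-scale preset used by the test suite: 8/16/16 filters, 3 x 3 kernels, a
2x input downsampling and a 64-unit FC4, with optimiser settings re-tuned
for this scale (learning rate 2e-3, momentum 0.9). A study of 1,600 clips
trains for 30 epochs in a few minutes on one CPU and recovers the
generative viscosity with a validation Spearman correlation near 0.9.

```{r}
model <- build_network(slowfusion_config_small(), seed = 1)
model <- sf_train(model, clips, design$viscosity_step,
                  val_ids = which(design$scene_variation == 5),
                  epochs = 30, seed = 1)
predict(model, clips)[1:5]
```

Activation capture (`collect_activations()`) reads the four ReLU layers;
dead units (never active on the probe set) are flagged and excluded from
unit-level analyses. `lesion_units()` returns a copy of the model with the
listed units' ReLU outputs clamped to zero; lesions compose and never
modify the original model.

## The eighteen predictors

`compute_metrics()` evaluates fifteen image-computable metrics — optical
flow speed and its spatial gradient (32 x 32 x 19), their set-level
histograms (shared Freedman–Diaconis bin count), rotationally averaged
power spectra (33 x 20), 3 x 3 local contrast and image gradients
(64 x 64 x 20), HSV saturation and the three CIELAB channels, motion energy
(quadrature spatiotemporal Gabor bank, 128 x 20), dense SIFT-style
descriptors (2048 x 20), GIST (512 x 20) and compact texture statistics
(119 x 20) — plus three high-level predictors (physical step, perceived
mean rating, scene class). Flow uses a pyramidal iterated Lucas–Kanade
tracker evaluated at the output resolution after contrast standardisation,
with speeds outside the container mask zeroed. Bank-dependent
dimensionalities (motion energy, SIFT, texture) depend on bank parameters
that are implementation choices; here they follow from the default bank
configuration and are recorded in `metric_registry()`.

## RSA conventions

Unit-level analyses use Euclidean-distance RDMs (defined even for units
that never fire); layer-level analyses use one-minus-Pearson RDMs of
concatenated layer activation patterns. High-level single-value predictors
always use absolute differences, and the scene predictor the binary
same/different-class map. RDMs are compared by Spearman correlation of
their strict upper triangles with average-rank ties; `rdm_regression()` is
ordinary least squares of the target triangle on the predictor triangles.

Unit tuning profiles (`build_predictor_space()`) are the 18 Spearman
correlations of each unit's RDM with the predictor RDMs; units are
clustered with Louvain communities on a k-nearest-neighbour graph
(k = round(sqrt(n_units)); inverse-distance weights in (0, 1], a design
choice since only the neighbour rule is fixed by convention). Cluster counts are data-dependent. t-SNE embeddings
(`embed_2d()`, `stimulus_embedding()`) are for display only.

`lesion_test()` compares the RMSE change from lesioning a unit set against
a null of 1,000 size-matched uniform draws and reports a z-score.
`activation_maximize()` performs gradient ascent on the input pixels
(default 2,000 iterations, one pyramid level) from the dataset mean clip
plus Gaussian noise, keeping the best input so the final activation never
falls below the seed's; the pooled objective is the sum of the unit's
rectified map (configurable to mean or max; the original pooling is
unstated).

## Capacity, transfer and populations

`capacity_experiment()` freezes everything before FC4 (verified
bit-identical) and retrains heads of decreasing width, ten repeats per
width, keeping the best by validation RMSE on perceived labels;
`retrain_scene_head()` retrains FC4-and-later with a softmax for
scene classification (eight epochs). `population_train()` trains the same
architecture repeatedly with different initial weights and shuffling and
compares layers across networks with linear CKA (cocktail-blank column
centring; invariant to orthogonal transforms and isotropic scaling).
`network_cluster_check()` applies divisive hierarchical clustering
(`cluster::diana`) to 1−CKA distances with elbow and average-silhouette
criteria; "no significant clustering" means the best silhouette stays at or
below 0.25.

`behavior_compare()` reports RMSE (and percent of the 16-step scale:
value/16 x 100, consistent with printed conversions such as 3.75 → 23.4%),
Pearson correlations, and partial correlations in both control conventions,
computed on variation-averaged values by default. `bootstrap_baseline()`
draws ratings with replacement from the pooled empirical distribution
(1,000 draws); per-stimulus permutation is available as an alternative
reading of the resampling scheme.

## Numerical choices and degenerate inputs

* Clip values are stored 8-bit in clip sets (quantisation 1/255, far below
  rendering noise); all computation is double precision.
* Constant feature vectors under the correlation metric yield flagged NA
  entries with a warning; zero-variance decoder columns warn and receive
  zero weight; a zero-spread lesion null or all-zero CKA input is an error.
* The linear decoder estimates the top eigenvalue of the feature covariance
  by power iteration and scales its gradient step by its inverse, so
  full-batch descent is stable at any layer width.
* Spearman ties use average ranks; upper-triangle vectorisation is row-major
  and excludes the diagonal.
* All randomness flows through per-purpose streams derived from integer
  seeds; identical seeds reproduce clips, ratings, weights, nulls and
  embeddings bit-exactly.

## Problem sizes used by the test suite

The packaged checks run a 10 x 16 x 10 study (1,600 clips), train the small
preset for 30 epochs, evaluate the eighteen predictors on the 160 held-out
stimuli (one per scene-step cell), train an 8-network population for five
epochs on a 320-clip subset, and use 150–400 draws for lesion nulls and
bootstrap baselines. These sizes are the package's definition of "desk
scale": large enough for the qualitative findings to be stable, small
enough to run on a laptop core.

## What passing tests do and do not show

The generator emulates the *design* of the original stimulus corpus —
factorial structure, log-spaced viscosity controlling motion statistics,
randomized nuisance optics, scene-dependent observer accuracy — not the
physics or photorealism of a fluid-simulation render farm. Analyses that
pass on synthetic data demonstrate that the pipeline's statistics and
experiments behave correctly and that the qualitative phenomena (depth
trends, capacity compression, population similarity decline) emerge in a
controlled world; they do not certify quantitative agreement with human
observers or with networks trained on the original corpus. Known
limitations: 2-D dynamics (no occlusion-rich 3-D flow), metaball rendering
(no specular highlights or refraction), a single camera viewpoint, and
motion statistics whose absolute scale differs between scene templates
(which is why motion–viscosity monotonicity holds per template but pools
to about −0.77 across templates).
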