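---
title: "Template-free particle picking with an eight-layer convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-free particle picking with an eight-layer convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A cryo-EM micrograph is a single, extremely noisy 2-D exposure containing
many randomly oriented projections of a macromolecule in vitreous ice.
Downstream 3-D reconstruction needs the coordinates of thousands of those
projections ("particles"), and collecting them by hand does not scale.
Template-matching pickers need reference projections and are easily fooled
by ice contamination, carbon edges and overlapping particles. `cryopick`
instead treats picking as a binary image-classification problem: a
convolutional neural network is trained on user-labelled particle and
non-particle boxes, then slid across whole micrographs to score every
position.

## The model

The network has eight layers: an input box, three convolutional layers, three
average-subsampling layers in alternation, and a fully connected scoring
output (C1–S2–C3–S4–C5–S6–output).

* **Activation.** The logistic sigmoid $\sigma(x) = 1/(1+e^{-x})$ is applied
  after every convolution and at the output, keeping every score in $(0,1)$.
  A ReLU option exists for the hidden layers (the output stays sigmoid), but
  sigmoid is the default.
* **Convolutional layer.** Output map $j$ is
  $X^{[l]}_j = \sigma\!\big(\sum_{i \in M_j} X^{[l-1]}_i * W^{[l]}_{ij} +
  B^{[l]}_j\big)$ — a valid, unit-stride, shared-kernel correlation over the
  connected input maps plus a bias. Connectivity is full by default
  ($M_j$ = all input maps); sparse tables are supported in
  `conv_forward()`.
* **Subsampling layer.** A pure $M \times N$ block average,
  $X^{[l]}_{ij} = \frac{1}{MN}\sum_m\sum_n X^{[l-1]}_{iM+m,\,jN+n}$, with no
  learnable parameters and no activation.
* **Output layer.** The final maps are flattened and scored:
  $y = \sigma(w^\top x + b)$.

A configuration is specified by the box side and the six feature-map sides,
exactly the way the benchmark schedules are tabulated; kernel sides
(`in - out + 1`) and pool sizes (`in / out`, which must divide) are derived
and validated by `network_config()`. The four published benchmark schedules
ship as presets:

```{r}
library(cryopick)
preset_config("klh")          # 272-pixel boxes: maps 222/74/54/27/18/9
preset_config("inflammasome") # 112-pixel boxes: maps 98/49/40/20/14/7
```

`preset_config("synthetic64")` is a reduced schedule with the same shape
grammar (64-pixel boxes, maps 56/28/24/12/9/3, kernels 9/5/4, pools 2/2/3,
6/6/12/12/12/12 maps) used by the synthetic experiments below.

## Training

Training minimizes the half mean squared error
$E_N = \frac{1}{2N}\sum_n (t_n - y_n)^2$ with targets $t_n = 1$ for particle
boxes and $0$ for non-particle boxes, by plain gradient descent
$\omega \leftarrow \omega - \frac{\eta}{N}\sum_n \varepsilon_n
\partial\varepsilon_n/\partial\omega$ with learning rate $\eta = 1$ by
default. The gradients are exact reverse-mode derivatives written out by
hand (sigmoid derivative $y(1-y)$, kernel gradients summed over all spatial
applications of the shared weights, pooling gradients spread uniformly with
factor $1/MN$); the test suite audits every parameter of a small network
against central finite differences at relative error $10^{-5}$, and no
automatic-differentiation library is involved.

Every original training box is rotated by 90°, 180° and 270°, quadrupling
the set (`augment_rotations()`). After each epoch the held-out accuracy at
threshold 0.5 is measured (rotation-averaged scoring, ties counted as
positive) and training stops at a target accuracy, 0.95 by default, or at
`max_epochs`. `refresh_training_set()` implements the recursive
training-set optimization loop: verified false positives (relabelled 0) and
missed particles (labelled 1) from new micrographs are appended and
augmented, and the network is retrained.

Two initialization schemes are available. The default draws every weight
and bias uniformly from $[0,1)$. Because all-positive weights start a
three-sigmoid-layer network deep in saturation and make convergence slow, a
symmetric option draws from $[-1/\sqrt{f}, 1/\sqrt{f}]$ with $f$ the
fan-in; the `synthetic64` preset turns it on, the published-schedule
presets keep the uniform default. Updates are full-batch by default;
`batch_size` switches to seeded-shuffle mini-batches.

## Recognition

`pick_particles()` composes the recognition pipeline:

1. **Normalization.** The micrograph is standardized to zero mean and unit
   variance. We standardize per micrograph rather than per box: on
   uniform-statistics micrographs the two are nearly identical, and the
   micrograph-level choice keeps the network exactly translation covariant,
   which the fast scan below exploits. A per-box mode
   (`network_config(normalize = "box")`) is retained.
2. **Raster scan.** Every stride-spaced box position (default stride 4 px,
   boxes fully inside the micrograph) is scored; each box's score is the
   mean of the network output over its four quarter-turn rotations, making
   the score exactly invariant under 90° rotation.
3. **Candidate selection.** A position survives if its score is at or above
   the threshold *and* is a strict maximum within the non-maximum
   suppression radius (Chebyshev distance, default half a box side so two
   particles can overlap by at most half a box). Exact score ties are broken
   by raster order, the top-left position winning.
4. **Pixel-std filter.** Boxes picked in carbon-rich or contaminated areas
   have anomalously high or low pixel standard deviation; candidates are
   kept only within `mean ± k·sd` (default `k = 2`) of the `pixel_std`
   distribution over the micrograph's own candidates, or within an absolute
   range if one is supplied.

Because all layers are translation covariant, the scan runs fully
convolutionally: the first convolution is computed once over the whole
micrograph, and pooling alignment splits scan positions into residue classes
modulo the cumulative pooling factor, with the deeper layers computed once
per class. This is arithmetically identical to scoring every box
independently (the suite checks agreement to $10^{-10}$) but roughly two
orders of magnitude faster. The shared path applies when the stride divides
`micrograph side − box side` on both axes (always true for the sizes used
here); otherwise a per-box fallback runs. Rotation averaging reuses the same
machinery on the four rotations of the micrograph and remaps the score
grids.

Large micrographs are reduced before picking with `bin_micrograph()`
(integer block averaging, e.g. 4× turns 7420×7676 into 1855×1919), mirroring
common practice for big detectors.

## Threshold selection and evaluation

Picks are matched to ground truth greedily in descending score order, each
candidate claiming the nearest unclaimed truth within a tolerance (default a
quarter of the box side, centre distance). Unmatched picks are false
positives, unclaimed truths false negatives. Precision is
$\mathrm{TP}/(\mathrm{TP+FP})$, recall $\mathrm{TP}/(\mathrm{TP+FN})$; when a
denominator is zero the ratio is defined as 1 (no picks means no false
alarms). `pr_curve()` sweeps the score threshold (default 50 evenly spaced
values), and the picking threshold is chosen where
$F_\beta = (1+\beta^2)\,\frac{PR}{\beta^2 P + R}$ peaks with $\beta = 2$,
which weights recall above precision; exact $F_2$ ties resolve to the higher
threshold, favouring precision.

Two implementation notes. The score map and the local-maximum mask do not
depend on the threshold, so `pr_curve()` scans each micrograph once and
sweeps thresholds over the cached scan — identical arithmetic to re-picking
per threshold. And the pixel-std band is estimated once per micrograph from
the full candidate pool and held fixed across the sweep; this keeps the
candidate sets nested so that recall is provably non-increasing in the
threshold, and is also the more stable estimate of the band. A single
`pick_particles()` call at one threshold estimates the band from its own
thresholded candidates instead.

## The synthetic micrograph simulator

`make_templates()` + `render_micrograph()` emulate the noise-tolerance
experiment design so the whole method can be trained and evaluated with no
external data. Templates are smooth projection-like shapes on a 64-pixel box
— an annulus (a ring-like top view), a soft-edged barrel (a side view) and a
seeded asymmetric multi-Gaussian blob — zero outside their support and
scaled to unit variance over it. Particles are placed at rejection-sampled
positions (default 55 per 1024² micrograph, minimum centre separation 80 px)
with continuous random rotations (bilinear resampling via EBImage; the
picker itself only exploits the exact 90° symmetry). Optional elliptical
contaminant patches with scaled noise variance give the pixel-std filter
something to remove (rate defaults to 0).

**SNR definition.** Noise-tolerance experiments are often reported without
pinning down an SNR convention, and alternatives change the scale, so ours
is stated prominently: here
$\mathrm{SNR} = \mathrm{var}(\text{noise-free signal over particle-support
pixels}) / \mathrm{var}(\text{added noise})$, the usual variance-ratio
convention in single-particle work. Noise is pixel-wise independent
zero-mean Gaussian with variance set from the realized signal variance; the
suite verifies the realized ratio within 10% at all six study levels
(0.01, 0.008, 0.005, 0.003, 0.002, 0.001).

What the simulator does **not** model: contrast transfer function
oscillations, structured (coloured) noise, ice-thickness gradients, particle
overlap beyond the separation constraint, and radiation-damage blurring.
Passing the synthetic study therefore demonstrates the machinery —
learning, scanning, selection, evaluation — at realistic variance ratios,
not performance on any particular real specimen.

## The desk-scale noise-tolerance study

The acceptance study in `tests/testthat/test-acceptance.R` runs two
conditions under identical budgets, SNR 0.01 and 0.001: four 1024²
training micrographs of 55 particles each (≈220+220 original boxes,
quadrupled by augmentation), one held-out micrograph for the accuracy
feedback, training with $\eta = 1$, mini-batches of 32, symmetric
initialization, at most 40 epochs with the stop target set at held-out box
accuracy 0.99 (box-level 95% still leaves too many high-scoring noise
windows at scan scale; training to 0.99 is the workflow's
"repeat until satisfactory" loop condensed into one number). Evaluation
scans three fresh micrographs at stride 4 and matches at tolerance
box/4 = 16 px. At SNR 0.01 the $F_2$-selected threshold yields precision
and recall of at least 0.8; at SNR 0.001 the same budget fails to learn
and the precision-recall area collapses, reproducing the qualitative
degradation of the original noise-tolerance experiment.

## Numerical and design choices

* Double precision throughout; the gradient-check tolerance assumes it.
* "Convolution" is implemented as cross-correlation (no kernel flip); with
  learned kernels the conventions are equivalent up to kernel reindexing.
* One bias per output feature map by default; a per-layer shared bias
  (`bias = "layer"`) is available, in which case its gradient accumulates
  over the layer's maps.
* Kernel and pool sizes are never free parameters: they are forced by the
  map-size schedule and validated (exact divisibility for pools).
* Coordinates are 0-based, origin top-left, y downward, everywhere inside
  the package; the EMAN2 bottom-left convention is produced only at the
  box-file boundary (`write_box_file()`/`read_box_file()`).
* Degenerate inputs have defined behaviour rather than surprises: empty
  candidate lists write empty box files; the pixel-std filter is a no-op
  below two candidates; zero-denominator precision/recall are 1; saturated
  sigmoids flush to exactly 0/1 in floating point.
* Determinism: every stochastic step (initialization, placement, harvest,
  shuffling) consumes an explicit integer seed, and identical seeds give
  bit-identical results.

## Known limitations

* The scan reports coordinates on the stride grid without sub-stride
  refinement; localization error is bounded by stride/2 plus the matcher's
  tolerance.
* Full-batch training with $\eta = 1$ from the uniform $[0,1)$
  initialization converges very slowly on deep sigmoid stacks; the
  symmetric-initialization and mini-batch options exist precisely because
  of this, and the experiments use them.
* The simulator's white-noise assumption makes the synthetic task somewhat
  easier than real micrographs at equal SNR; conclusions transfer
  qualitatively, not numerically.
* No GPU path and no STAR/RELION coordinate export.
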