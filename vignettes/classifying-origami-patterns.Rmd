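---
title: "Classifying nanoscale patterns in localization microscopy data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying nanoscale patterns in localization microscopy data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-molecule localization microscopy (SMLM) — and DNA-PAINT in
particular — does not produce images. It produces a table: one row per
detected emission event, with a sub-pixel position, a photon count, a PSF
width, a localization precision. A super-resolution "image" is only ever a
2D histogram of those positions. When the sample is a field of DNA-origami
nanostructures, each carrying a designed pattern of docking sites (a digit,
a grid), the analysis question becomes: *given the localizations of one
picked structure, which design is it?* Historically that classification was
done by eye, structure by structure. This package automates it with a small
multilayer perceptron (MLP) trained on rendered pick images, and closes the
loop by exporting the classified localizations per class in the standard
SMLM HDF5+YAML dialect, so downstream tools can keep working with them.

The pipeline is deliberately simple and fully scriptable:

1. **Load** a localization table (`read_locs()`), with circular **picks**
   grouping the localizations of each candidate structure (`read_picks()`,
   or a `group` column written by an upstream annotation step).
2. **Render** each pick into a square, oversampled 2D-histogram grayscale
   image (`render_pick()`), optionally expanding the training set by rigid
   **rotations** of the localization coordinates (`augment_set()`).
3. **Train** an MLP with up to three hidden layers and a softmax output
   (`mlp_train()`, orchestrated by `run_training()`), evaluated with a
   learning curve and a confusion matrix on a held-out 30% of structures.
4. **Classify and export** new datasets pick-by-pick with a saved model
   (`classify_dataset()`, `export_by_class()`).

A built-in DNA-PAINT simulator (`simulate_dataset()`) supplies ground-truth
datasets for all of it.

## Rendering

A pick's localizations are binned on a subpixel lattice: localization
$(x, y)$ falls into bin $(\lfloor (x - x_0)\,o \rfloor, \lfloor (y - y_0)\,o
\rfloor)$, where $o$ is the **oversampling** (subpixels per camera pixel)
and $(x_0, y_0)$ places the chosen center on the image midpoint. Bins are
half-open and binning uses `floor`, so with normalization off the pixel sum
equals the number of in-bounds localizations exactly — a conservation law
the test suite checks against 1,000 random picks. Localizations falling
outside the image are dropped and counted, never silently lost.

Two centering modes exist. `center_of_mass` (the default) centers the image
on the localization centroid, which makes the rendered image invariant to
imperfect pick placement — translating the localizations and the pick
together yields a bit-identical image. `pick_center` uses the pick circle's
center and is appropriate when the centroid is unreliable (heavy uneven
background).

Per-image `max_to_one` normalization (the default) divides by the brightest
bin so classifier inputs are scale-free: localization counts per structure
vary with labeling and imaging time, and absolute counts should not drive
the class decision.

The default oversampling of 13 subpixels per 130-nm camera pixel makes one
subpixel ≈ 10 nm, about twice the default simulated localization precision
(5 nm): finer bins would mostly resolve noise, coarser bins blur the 20-nm
site lattice. The default image size of 20 subpixels covers the default
1.5-px pick (`image_size_for_pick()` rounds `diameter × oversampling` up to
the next even integer).

### Rotation augmentation

Augmentation rotates the *localization coordinates* rigidly about the
render center and re-bins, rather than interpolating rendered images. At
the histogram level the two are equivalent, but coordinate rotation is
exact and interpolation-free; the angle-0 copy is bin-identical to the
plain render, which the tests assert. Angles are the $n$ equal steps
$2\pi k / n$.

Augmentation is **off by default** (`n_angles = 1`). The reason is worth
spelling out because it is a property of the data, not of the method:
rotation augmentation teaches the classifier rotation invariance, and that
is only useful when structure orientations actually vary. The digit
patterns are *not* separable under rotation — our digit-2 mask is exactly
180°-symmetric, and rotated digit-2 renders approach digit-3 — so
augmenting a co-oriented training set manufactures class overlap that the
test data never exhibit, and measurably lowers held-out accuracy. On real
surfaces, origami adsorb at arbitrary in-plane orientations; there
augmentation is essential, and the simulator's `random_orientation = TRUE`
mode reproduces that regime (expect a lower accuracy ceiling: the task is
genuinely harder, and some rotated-class overlap is irreducible for a
pixel-space MLP). Enable augmentation whenever orientations vary:

```{r}
run_training(class_files, n_angles = 8L, ...)
```

## The classifier

The MLP is implemented from scratch: fully connected layers (1–3 hidden,
enforced), hidden activation ReLU by default (logistic and tanh
available), softmax output, multinomial cross-entropy loss, exact
backpropagation, mini-batch training with Adam
($\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$) or plain SGD.
Defaults — learning rate $10^{-3}$, batch 32, at most 200 epochs, L2
penalty $10^{-4}$, early-stopping patience 10 and tolerance $10^{-4}$ —
mirror the common defaults of mainstream MLP implementations so behavior
is comparable out of the box.

Weights initialize uniformly on $(-1, 1)/\sqrt{\text{fan-in}}$, biases at
zero; everything is seeded, and training is a pure function of data,
architecture and config — reruns are bit-identical, which the tests check.

Numerical choices worth knowing:

* probabilities are clipped at $10^{-15}$ inside the loss so a confident
  wrong prediction cannot produce $-\log 0$;
* `mlp_predict()` breaks probability ties toward the lowest class index,
  for determinism;
* early stopping watches the loss on an internal seeded 10% validation
  split of the training images (`validation_fraction`); the parameters of
  the best validation epoch are restored. With `validation_fraction = 0`
  the training loss is watched instead. The split is random, not
  stratified: at training scale every class is comfortably represented;
* backpropagation is verified against central finite differences
  ($h = 10^{-6}$, relative error $\le 10^{-5}$) across all three depths
  and all three activations. Two caveats make that oracle honest: biases
  are drawn nonzero in the check, because a ReLU unit whose inputs are all
  dead and whose bias is exactly zero sits precisely on the
  non-differentiable kink $z = 0$, where finite differences are invalid;
  and near-zero gradients are compared with an absolute floor of
  $10^{-4}$ in the denominator, since central differences carry rounding
  noise of order $10^{-10}$.

The model bundle (`save_model()`) is a single HDF5 container: float64
weight and bias datasets `W0…Wk`, `b0…bk`, the training history, and a YAML
header with the layer sizes, activation, label map and — crucially — the
frozen render configuration. `classify_dataset()` refuses a model whose
render settings disagree with its input size: a silent train/predict
rendering mismatch is the most likely user error, and it would fail
quietly otherwise.

## The training workflow

`run_training()` assembles labeled picksets from per-class grouped
localization files (classes indexed in sorted-name order), splits 70/30,
augments the training side only, renders, trains, and evaluates on the
untouched test structures. Two details are deliberate:

* **The split happens before augmentation, at structure level.** Rotated
  copies of one structure are near-duplicates; letting them straddle the
  split would leak training information into the test set and inflate
  accuracy. The stricter reading costs nothing and is the only defensible
  one.
* **The split is stratified**, with per-class test counts of
  `round(0.3 × class size)` (at least 1, at most size − 1): unstratified
  splits can starve rare classes at demonstration scale.

The report carries the learning curve (per-epoch training and validation
loss), the C×C confusion matrix (rows true, columns predicted), per-class
precision/recall and overall accuracy, all serialized as YAML/CSV plus a
PNG learning curve.

## Inference and export

`classify_dataset()` renders every pick with the model's frozen settings
and classifies it. Two guard rails, absent from the original interactive
workflow but necessary headless: picks with fewer than `min_locs`
localizations (default 10) are reported `unclassified:too_few_locs`, and
winning probabilities below `min_probability` (default 0.5) become
`unclassified:low_confidence` — softmax argmax on a near-empty pick is
noise and would silently pollute exports. Lowering `min_probability` never
decreases the number of classified picks (a monotonicity the tests check).

`export_by_class()` writes one standard localization file per class — the
pick is atomic, a structure is exported whole — with the `group` column
renumbered per file and provenance recording the thresholds. Every
localization of every processed pick lands in exactly one output file;
exported files re-read cleanly and re-classify to the same classes.

## The simulator

`simulate_dataset()` emulates DNA-PAINT imaging of surface-immobilized
origami just far enough to exercise every downstream module with known
ground truth:

* binding-site patterns: digits 1–3 as lit cells of fixed 3×5 masks at
  20 nm pitch (the masks are this package's own designs, chosen to differ
  pairwise in ≥ 3 sites), and the classic 20-nm grid (4×3 lattice);
* per structure, each site survives with probability
  `labeling_efficiency` (default 0.8), and a surviving site emits
  Poisson(`mean_events_per_site` = 30) localizations with isotropic
  Gaussian noise of `precision_nm` = 5 nm;
* structures sit on a jittered grid (spacing 3 pick diameters, jitter ≤
  0.5, so picks cannot overlap); uniform background localizations are
  added at 0.5 /µm²; frames are uniform over a 10,000-frame movie;
* outputs are the standard HDF5+YAML localization file (0-based `group`
  ids, background as `NA`), a pick YAML, and a `truth.csv`.

Defaults are typical DNA-PAINT scales (130-nm pixels, 5-nm precision) and
are the package's benchmark conditions.

What the simulator does **not** emulate — and therefore what passing tests
do *not* demonstrate about real data:

* **blinking kinetics.** Binding events are collapsed to a Poisson count
  per site; there is no bright/dark time structure, no multiple
  localizations per binding event, no photobleaching. Classification
  consumes only positional histograms, so kinetics add nothing here, but
  any time-domain analysis would find these files unrealistic;
* **orientation, by default.** All structures are co-oriented unless
  `random_orientation = TRUE`; real origami are not. The default keeps the
  four classes linearly separable in rendered-image space, which is the
  premise of the end-to-end accuracy benchmark; real-data accuracy with
  random orientations and augmentation will be lower;
* drift, camera noise, PSF astigmatism, sample tilt, partial structures,
  aggregates. The ancillary columns (photons, PSF widths, background,
  reported precision) are drawn from plausible fixed distributions and are
  format filler, not physics.

## Problem sizes and tolerances

The end-to-end benchmark in the tests and the acceptance script uses the
four default patterns × 200 structures (≈ 190,000 localizations), a single
hidden layer of 100 units, and the default 70/30 split — small enough to
run in well under a minute on one core, large enough that held-out
accuracy is a stable ≈ 0.95–0.98 across seeds, with the shuffled-label
control at chance (0.25 for four balanced classes). Unit tests use far
smaller instances (tens of structures) plus exact identities: histogram
conservation, rotation involution to $10^{-9}$ px, split arithmetic,
byte-identical reruns under a fixed seed.

## Known limitations

* One global pick diameter per pick set (the upstream convention); no
  non-circular picks, no automatic pick finding.
* The MLP sees raw pixels; there is no convolutional architecture, no
  learned rotation invariance beyond what augmentation provides.
* Rendering is plain 2D histogramming — no Gaussian or precision-weighted
  rendering, no 3D.
* The HDF5 dialect is the single-table `locs` convention with a YAML
  sidecar; other localization formats (CSV dialects, TIFF stacks) are out
  of scope.
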