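---
title: "Keyframe summarization and lesion classification for video laryngoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyframe summarization and lesion classification for video laryngoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Video laryngoscopy records the vocal folds at about 25 frames per second for
tens of seconds per patient. Consecutive frames are almost always nearly
identical: the scope drifts slightly, illumination flickers, the sensor adds
noise, but the content barely changes. The clinically informative moments —
a new view after the scope moves, a lesion coming into frame — are rare and
abrupt. Processing or archiving every frame wastes memory and compute, and
burdens downstream classifiers with redundant data.

`endokey` implements the summarize-then-classify pipeline for this setting:

1. compute the structural similarity index (SSIM) between every pair of
   consecutive frames;
2. keep a frame as a **keyframe** when its SSIM to its predecessor falls
   strictly below a threshold (plus the first frame, which seeds every
   summary);
3. export the keyframes with a dataset manifest, split them into
   training/validation sets, and classify them (healthy vocal folds /
   nodule / polyp) with a dual-backbone feature-fusion convolutional
   network.

## SSIM

For two grayscale windows $x, y$ the similarity is

$$\mathrm{SSIM}(x,y) =
\frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
     {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)},$$

with window-weighted means $\mu$, variances $\sigma^2$ and covariance
$\sigma_{xy}$, and stabilizers $C_1 = (K_1 L)^2$, $C_2 = (K_2 L)^2$ on
dynamic range $L$. The frame score is the mean over all local windows.
Defaults follow the reference configuration of the original formulation:
an $11{\times}11$ Gaussian window with $\sigma = 1.5$, $K_1 = 0.01$,
$K_2 = 0.03$, $L = 255$. Design choices worth knowing:

* **Valid-window convention.** Only windows fully inside the image are
  evaluated (no padding), so the SSIM map is smaller than the image by
  `window_size - 1` per axis. Padding would manufacture artificial
  similarity at the borders.
* **Grayscale.** RGB frames are reduced with BT.601 luma weights
  (0.299/0.587/0.114) before comparison; a per-channel mode would triple the
  cost for little benefit on endoscopic material, where luminance carries
  the structure.
* **Range.** The score is 1 exactly for identical frames and lies in
  $[-1, 1]$. It is *not* clamped to $[0, 1]$: anti-correlated structure
  (e.g. two independent noise fields) legitimately produces slightly
  negative scores, and the thresholding step never sees such pairs in
  practice because consecutive endoscopic frames are strongly correlated.
* A `"global"` mode (one uniform window spanning the image) is available
  for small test images and property checks; the windowed mode is the
  default and the one used by the pipeline.

## Keyframe selection

A frame $i \ge 2$ is a keyframe iff
$\mathrm{SSIM}(f_{i-1}, f_i) < t$ for the chosen threshold $t$; frame 1 is
always kept (otherwise a constant clip would produce an empty summary).
Ties are not keyframes ("below the threshold" is strict). Comparison is
against the immediately preceding *raw* frame; an optional
`anchor = "last_keyframe"` mode compares against the most recent keyframe
instead, which accumulates slow drift until it crosses the threshold — a
different semantics, provided for experimentation.

Because the comparison for each transition does not depend on the
threshold, selections are nested: $t_1 \le t_2$ implies
$\mathrm{keyframes}(t_1) \subseteq \mathrm{keyframes}(t_2)$, so keyframe
counts grow monotonically with the threshold. `threshold_sweep()` exploits
this by computing each clip's SSIM trace once and reusing it for every
threshold; the default sweep is $t \in \{0.90, 0.95, 0.98\}$, thresholds
expressed as fractions ("90%" is 0.90). Frame indices are 1-based
throughout, following R convention.

## The synthetic study conditions

Patient recordings are private, so the package ships a generator that
reproduces the *statistical contract* the pipeline consumes, not the
anatomy. A clip is a static scene — radial illumination gradient, a
band-limited sinusoidal texture field, and a class-specific lesion
signature — observed through a slowly drifting sub-pixel camera offset with
brightness flicker and Gaussian sensor noise. At each ground-truth **event**
index the camera jumps by a quarter of the frame and the texture is
resampled: genuinely new content.

The default magnitudes were fixed by a one-time calibration sweep and then
frozen: drift 0.08 px/frame, noise 0.3 intensity units, flicker sd 0.002.
Under these defaults, non-event transitions keep consecutive SSIM above
0.98 and event transitions fall below 0.90 for every seed tested; the test
suite re-asserts this empirically over seeded clips rather than trusting
the constants, and scene-cut recovery at threshold 0.90 is exact (frame 1
plus exactly the event indices).

Lesion signatures follow the clinical morphology in caricature: nodules are
two small blobs placed symmetrically about the midline at mid-height
(bilateral, symmetric); a polyp is one larger unilateral blob; healthy
frames have none. Lesion amplitude is the `contrast` parameter (default 80
intensity units, used by both the video and still-image generators);
`contrast = 0` erases the class signal entirely, giving a chance-level
control. At the default contrast the three classes are linearly separable
on 8×8 mean-pooled patches — the suite verifies this with an LDA baseline —
so a classifier that fails there is broken, not under-informed.

What the generator does **not** emulate: specular highlights, gag-reflex
motion blur, interlacing, compression artifacts, anatomical variation.
Passing tests demonstrate the pipeline's correctness and learnability under
controlled conditions; they say nothing about diagnostic performance on
patient data.

## The fusion classifier

Two convolutional backbones process the same standardized input frame;
their globally average-pooled feature vectors are concatenated (the fused
width is the sum of the branch widths) and passed through a small fully
connected head with dropout (default rate 0.3) and a softmax output over
the three classes. The built-in backbones, `"tiny"` (widths 8/12/16/24, 24
features) and `"tiny_wide"` (12/16/24/32, 32 features), are 21-layer stacks
of 3×3 convolutions, ReLU, and 2×2 average pooling that build with no
downloads and train on one CPU in minutes; the wider branch plays the
"global context" role opposite the narrower "fine detail" branch.

Transfer modes mirror the two standard scenarios:

* **frozen** — every backbone layer is non-trainable; only the head trains.
* **fine_tune_last_k** — exactly the last *k* entries of each backbone's
  flat layer list are unfrozen (default *k* = 20), plus the head. "Layer"
  means an entry of the layer list as the framework exposes it, including
  parameter-free ReLU/pooling entries; `layer_trainability()` prints the
  walk so the choice is auditable, and *k* larger than the backbone depth
  is a configuration error.

Training uses the fixed protocol applied to every compared run: Adam with
learning rate 0.001, batch size 32, at most 30 epochs, early stopping on
validation loss with patience 5 and best-weights restoration. Inputs are
per-image standardized (zero mean, unit variance) — the branches' standard
preprocessing step, which removes global illumination differences before
the backbones see the frame. All randomness (shuffling, dropout,
initialization) is seed-controlled; the same seed reproduces the same
history on the same machine.

The engine itself (im2col convolution, average pooling, global average
pooling, dense layers, inverted dropout, softmax/cross-entropy, Adam) is a
deliberately small pure-R implementation sized for desk-scale experiments;
its gradients are validated against numerical differentiation in
development and its training behaviour (frozen checksums, last-k-only
updates, early stopping, seeded reproducibility) is covered by the suite.

## Evaluation

`metric_report()` bundles the confusion matrix (rows = true, columns =
predicted) with one-vs-rest per-class precision, recall and F1, their
unweighted macro averages, accuracy, the Matthews correlation coefficient,
and optional one-vs-rest ROC AUC per class (midrank Mann–Whitney statistic,
equivalent to trapezoidal ROC area). Conventions:

* Standard definitions are used: precision $= TP/(TP+FP)$, recall
  $= TP/(TP+FN)$. (Published write-ups occasionally transpose the two
  denominators in print; per-class tables labeled "precision"/"recall" are
  only consistent with the standard forms, which is what this module
  computes.)
* Zero denominators (a class never predicted, a degenerate fold) yield 0
  with a warning rather than NaN.
* MCC for two classes is the familiar binary formula; for more classes the
  standard multiclass generalization over the full confusion matrix, which
  reduces exactly to the binary form at $2{\times}2$ — the only
  self-consistent way to report one MCC per three-class model.
* Values are stored on the 0–1 scale; the print method renders 0–100 when
  asked.

`cross_validate()` performs stratified k-fold partitioning (default k = 5,
deterministic given a seed; stratification relaxes with a warning when a
class has fewer members than folds) and aggregates per-class metrics as
mean ± sample standard deviation across folds.

## Splits and leakage

The frame-level stratified 80/20 split is the default: within each class a
`val_fraction` share of *frames* is drawn at random, exact to within one
record per stratum and reproducible under a seed. Frame-level splitting can
place frames of one patient on both sides — a real leakage concern for
drift-heavy video, where adjacent frames are near-duplicates — so
`group_by_patient = TRUE` assigns whole patients to a split instead,
trading exactness of the ratio for safety. Both are first-class; the
frame-level default matches the common practice the pipeline reproduces,
and the grouped option is the recommended setting for honest generalization
estimates.

## Problem sizes and numerical choices

The suite and the acceptance script run entirely on generated data at desk
scale, chosen as the package's own study conditions: 64×64 clips of 12–50
frames for summarization checks (20–50 seeded clips per property), 32×32
images for classification, 20 videos per class (roughly 80 keyframes per
class) for the end-to-end run, and a 120-image contrast-free control.
Variances in the SSIM moments are clamped at zero to absorb floating-point
rounding; probability rows are clamped at $10^{-12}$ inside the
cross-entropy; exact prediction ties break toward the lower class index.
Degenerate inputs (empty manifests, single-frame clips, absent classes,
all-one-class predictions) follow the documented conventions rather than
erroring where a convention exists.

## Known limitations

* Container video (.mp4) is not decoded; the package reads directories of
  image frames (PNG natively, TIFF optionally) in lexicographic order, and
  the exporter zero-pads indices so that order is temporal. Decode
  container video with external tooling first.
* The built-in backbones are deliberately small and randomly initialized;
  no pretrained weights ship with the package, and headline accuracies from
  pretrained-backbone studies on patient data are out of reach (and out of
  scope) by construction.
* The SSIM threshold is global and fixed per run; adaptive thresholds are
  future work.
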