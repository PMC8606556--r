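---
title: "Topology-preserving graph convolution for retinal artery/vein classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-preserving graph convolution for retinal artery/vein classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Retinal fundus photographs show the only vasculature visible to
non-invasive imaging, and several clinical biomarkers (most prominently the
arteriolar-to-venular ratio) require each vessel pixel to be labeled artery
or vein.  Convolutional pixel classifiers do this well locally but exhibit
two characteristic topological failures: a single vessel segment receives
multiple class assignments, and thin or low-contrast vessels come out
fragmented.  Both failures are failures of *long-range* reasoning — a
convolution sees a fixed receptive field, while the correct label of a pixel
often depends on the vessel tree it belongs to.

`vesseltopo` addresses this by re-expressing the image as a graph whose
edges follow the segmented vasculature, classifying the graph nodes with a
spectral graph convolutional network (GCN), and fusing the pixel-wise and
node-wise predictions.

## The model

### Pixel classifier and representative features

The backbone is an encoder–decoder ("U-Net" style) pixel classifier whose
final stage is exactly one 1×1 convolution from `H` hidden channels to the
four classes *(background, artery, crossing/uncertain, vein)* followed by a
per-pixel softmax.  The tensor entering that 1×1 classifier is the
*representative CNN feature map*: it is the most compressed description of
each pixel that still linearly determines the class probabilities, which
makes it the natural node feature for the graph stage.  `extract_features()`
returns exactly this tensor together with the probabilities, and the test
suite asserts the internal-consistency oracle (pushing the returned features
through the model's own 1×1 head reproduces the returned probabilities to
machine precision).

### Graph construction

Every pixel of the `P × Q` raster is a node (`N = P·Q`, row-major 0-based
ids).  The class-probability map is binarized by *argmax ∉ background* —
the natural multi-class threshold for softmax outputs — optionally dilated
by a lattice Euclidean disk of radius `r`, and an undirected edge joins two
pixels iff they are 8-neighbours and both foreground.  Background pixels
remain **isolated nodes**: they keep their features, are reachable by the
classifier through their self-loop, and are exactly what allows the GCN to
re-classify pixels that the segmentation missed (broken vessels).  An
ablation flag (`keep_isolated = FALSE`) drops them and reindexes.

Node features are the concatenation of the `H` CNN features and the `CH = 3`
image channels (`H + CH` columns; with the published `H = 64` that is 67),
with `"cnn"` and `"rgb"` subsets available for ablation.  Dilated-but-
background pixels read their features from the same pixel-aligned rasters —
features exist at every pixel, so no resampling or imputation is needed.

### Spectral graph convolution

With adjacency `A`, degrees `D`, and normalized Laplacian
`L = I − D^(−1/2) A D^(−1/2)`, a spectral filter is
`g_θ ⋆ x = U g_θ U^T x` in the Laplacian eigenbasis `U`.  The package
implements the two standard truncations:

* **Chebyshev filter** (`cheb_layer()`): `Σ_{k≤K} T_k(L̂) X θ_k` with
  `T_k = 2 L̂ T_{k−1} − T_{k−2}`, `L̂ = (2/λ_max) L − I`.  The exact spectral
  form is implemented only as a test oracle (dense eigendecomposition on
  ≤ 20-node graphs) — never as a production path.
* **First-order layer** (`gcn_layer()`): `Y = S X Θ` with the renormalized
  propagation matrix `S = D̂^(−1/2) Â D̂^(−1/2)`, `Â = A + I`.  Adding the
  self-loop before normalizing bounds the spectrum of `S` in `[−1, 1]`
  (asserted on random graphs), which stabilises deep stacking.

For an isolated node, `S` has row `e_i`, so its output is `x_i Θ`: isolated
nodes are classified from their features alone, exactly the mechanism that
repairs gaps.  `first_order_identity_check()` verifies numerically that the
K = 1 Chebyshev filter with `θ = θ'_0 = −θ'_1` collapses to the
single-parameter form.

The classifier (`gcn_forward()`) is two such layers:
`softmax(S · dropout(relu(S X Θ1)) · Θ2)`, hidden width `H' = 32` by
default.  The activation is a rectifier and the dropout rate defaults to
0.5; neither is pinned by the published description, so both follow the
conventions of the GCN literature and are configurable.

### Fusion

Two fusion rules combine the CNN probability map and the GCN node
probabilities:

* **Agreement voting** — a pixel gets a class only when both argmaxes agree;
  disagreements get the no-assignment (background) label.  Per vessel class
  this is exactly the intersection of the two assignment sets (a tested
  property).
* **Weighted averaging** — `fused_i = w_CNN p_CNN,i + w_GCN p_GCN,i`
  per class, then a strict 50% threshold; if several classes pass, the
  maximum wins; if none does, background.  The strict comparison avoids
  double assertion at an exact 0.5/0.5 tie.

**Which fusion when?**  Under the package's default evaluation support (all
ground-truth artery/vein pixels, with unassigned pixels counted as errors of
their true class) agreement fusion can *never* exceed the CNN's accuracy:
its correct set is the intersection of the two sources' correct sets, hence
a subset of the CNN's.  Agreement fusion increases accuracy only under a
support that excludes unassigned pixels (`eval_set = "pred_and_gt"`), which
is presumably closer to how headline numbers are usually computed — the
literature rarely states its support, which is why `evaluate_av()` makes it
explicit and reports it with every metric.  On the gt-support convention the
package's end-to-end test therefore gates the *weighted* variant
(`w_CNN = 0.2, w_GCN = 0.8`, the strongest weighted setting in the
published ablation), while the agreement variant is always computed and
reported alongside.

## Evaluation metrics and topology diagnostics

`evaluate_av()` treats artery as the positive class and vein as negative:
sensitivity is artery recall, specificity vein recall, accuracy their
prevalence-weighted combination (an asserted identity).  Crossing/uncertain
pixels are excluded from the support.

`topology_diagnostics()` quantifies the two motivating failure modes:
`multiclass_segment_count` counts ground-truth single-class vessel segments
(runs between branch points, computed per class so a perfect prediction
always scores 0) containing more than one predicted A/V class, and
`fragmentation_ratio` is the predicted-to-true ratio of 8-connected vessel
component counts (1 ideal, larger = more broken).

## The synthetic world

`generate_labeled_image()` draws each vessel tree as a biased random walk
from an image-margin root with stochastic branching (branch probability
0.04 per step, at most 8 walkers per tree), rasterised with disk brushes of
radius 1–2.5 px; step length 0.7 px guarantees each tree is one 8-connected
component (asserted against a flood-fill oracle).  Overlap of artery and
vein trees is labeled crossing/uncertain pixel-wise, matching how public
A/V datasets annotate crossings.  Colors are fundus-like (reddish
background 0.72/0.45/0.30; arteries brighter 0.93/0.35/0.30; veins darker
0.45/0.12/0.15) with i.i.d. Gaussian RGB noise, σ = 0.04 — enough that a
trained classifier is required, while `noise_sd = 0` with disjoint means
gives the easy regime in which color alone separates the classes (used by
the RGB-only ablation test).  All randomness flows from one integer seed
through one owned generator; no global random state leaks.

What the generator does **not** emulate: optic disc and fovea, vessel
caliber statistics and tortuosity of real retinas, illumination gradients,
camera noise, or annotation ambiguity.  A green end-to-end test therefore
establishes that the machinery — feature extraction, graph construction,
spectral propagation, training, fusion — is implemented correctly and that
the topology-repair mechanism works in a controlled world; it does not
establish clinical-grade accuracy on real fundus images.

`corrupt_mask()` simulates segmentation errors by erasing short foreground
runs.  A candidate break site (an interior vessel pixel) is accepted only
if erasing a disk of diameter `gap_length` around it increases the local
8-component count in a surrounding window, so "a break severs the vessel"
is part of the operation's contract rather than a seed-dependent accident.
Foreground is only ever removed.

## Numerical and design choices

* **Schedules.**  The published recipe is GPU-scale: the CNN trains 20k
  epochs at learning rate 2e-5 (halved every 10k), the GCN 200 epochs at
  0.003.  Those remain the config defaults.  The printed GCN decay wording
  is garbled in the source text; it is read as "to 1/100th every 30
  epochs", kept configurable.  At desk scale that decay freezes Adam about
  30 epochs in while the loss is still clearly falling, so the bundled
  pipeline profile uses 0.01 decayed ×0.1 every 60 epochs, and a CNN
  profile of a few dozen epochs at 1e-3–2e-3.  This is a deliberate
  desk-scale deviation, not a claim about the original training.
* **"Epoch"** means one pass over the training set with one full-image
  (CNN) or full-graph (GCN) Adam step per item; the source is silent on
  batching.  Adam uses β1 = 0.9, β2 = 0.999, ε = 1e-8 everywhere.
* **Class imbalance.**  Cross-entropy is unweighted (nothing else is
  stated); per-class weighting was considered and left out to keep the
  training contract minimal.  The GCN loss includes all nodes by default —
  background nodes carry the background label — with `loss_nodes =
  "vessel"` as the documented alternative, since the source does not state
  whether isolated nodes contribute to the loss.
* **Ties.**  Argmax ties break toward the lowest class index everywhere
  (binarization, label maps, fusion), so an exact tie with background stays
  background.
* **Degree-0 nodes in the Chebyshev path** use `D^(−1/2) = 0`, making the
  unnormalized-Laplacian act as the identity on them; the first-order path
  handles them through the self-loop instead.  The strict first-order
  identity check refuses graphs with isolated nodes because `D` is
  singular there.
* **Sparse throughout.**  Adjacency and propagation matrices are stored
  sparse (`Matrix`); dense `N × N` objects appear only inside test oracles
  on tiny graphs.  For a real 584 × 565 fundus image `N ≈ 330k`, which a
  dense matrix could not hold.
* **Graphs from predicted or true masks.**  Whether training graphs use the
  CNN-predicted or the ground-truth segmentation is not stated in the
  source; the package supports both (`mask_source`), defaulting to the
  predicted mask, which matches the stated pipeline order.
* **Serialization.**  Checkpoints and feature maps use R's gzip-compressed
  native container (RDS); edge lists are also exported as two-column CSV;
  images and label maps are 8-bit PNG in the artery = red, vein = blue,
  crossing/uncertain = green dialect (white accepted on read).  Manifests
  record the stage, seed, and a path-independent config hash so identical
  runs produce identical manifests.

## Known limitations

* The backbone is a deliberately small pure-R re-implementation (verified
  by finite-difference gradient checks); it is suitable for desk-scale
  experiments and method development, not for training on full-resolution
  clinical datasets.
* The published headline accuracies were obtained on external fundus
  datasets after GPU-scale training and are out of scope here; nothing in
  this package claims to reproduce them.
* Rotation augmentation is restricted to 90° multiples on square canvases.
* The AV-dataset directory reader accepts PNG only.
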