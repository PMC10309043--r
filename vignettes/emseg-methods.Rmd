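---
title: "Methods: semi-automatic EM membrane segmentation with emseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic EM membrane segmentation with emseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`emseg` implements the desk-scale semi-automatic reconstruction loop for
volume electron microscopy: build training data from partial annotations,
train a 2D membrane classifier, predict tile-by-tile over a stored
volume, and expand the semantic prediction into per-section instances.
This vignette records the models, the parameters that matter, and the
design choices made where the design was genuinely open.

## Ground-truth construction

**Grayscale stretching.** EM sections vary in contrast; each source image
is linearly stretched so that its low/high percentile anchors (defaults:
1st and 99th percentile gray values) map to 0 and 255, values outside
clamping. The fitted anchor gray values are persisted in the dataset
manifest, and inference applies the *same* correction — a mismatch here
is a classic silent failure mode for tiled prediction. Constant images
are passed through unchanged.

**Saturated regions and the chessboard criterion.** Annotation is
expensive, so label images are usually only partially painted. A pixel is
*saturated* when it carries a label; training patches may only come from
regions where every contiguous pixel is saturated, but those regions can
have any shape. For a square patch of side $s$ centered at $c$, full
annotation is equivalent to a Chebyshev (chessboard, $L_\infty$)
distance condition on the distance transform $d(\cdot)$ from labeled
pixels to the nearest unlabeled pixel (the image border counts as
unlabeled, so patches can never sample outside the image):

* odd $s$: the patch is the Chebyshev ball of radius $(s-1)/2$, so the
  exact criterion is $d(c) \ge \lceil s/2 \rceil$;
* even $s$: the patch (rows $c-s/2+1$ … $c+s/2$ under this package's
  convention) is the radius-$s/2$ neighbourhood of the $2 \times 2$
  pixel block anchored at $c$, so the exact criterion is
  $\min d \ge s/2$ over that block.

Both criteria are exact in both directions (no valid center is missed,
no returned center admits an unlabeled pixel); the test suite checks
them against an $O(n^2)$ brute-force oracle. The distance transform is a
two-pass chamfer with unit weights, which is exact for $L_\infty$.

**Rotation-aware extraction.** Rotation proved the most valuable
augmentation for membrane detection, so each patch draw samples a
continuous-uniform angle in $[0°, 360°)$. The order of operations is
rotate-then-measure: the full EM image (bilinear) and label image
(nearest-neighbour, rotation void filled with the unlabeled sentinel)
are rotated about the image center, the saturated mask and the distance
criterion are recomputed on the *rotated* labels, and a center is drawn
uniformly among the valid pixels. This guarantees saturation for
arbitrary angles without inflating the distance criterion by $\sqrt 2$.
Centers are drawn uniformly (not on a grid); sampling is the simplest
scheme consistent with the distance criterion, and patch provenance
(source, angle, center, augmentations) is recorded per patch. If a drawn
angle admits no valid center the angle is resampled, up to a bounded
number of retries, after which the build fails with an explicit
"insufficient saturated annotation" error.

**Photometric augmentations.** Flips apply to the EM/label pair
identically; Gaussian blur, motion blur and histogram equalization apply
to the EM patch only, since labels are categorical and must stay crisp.
Parameters are deliberately mild perturbations that do not destroy
membranes: Gaussian $\sigma \sim U[0.5, 2]$ px, linear motion-blur
kernels with odd length in $[3, 15]$ px and uniform orientation. Each
configured augmentation fires independently with probability 0.5 per
patch. The train/validation split is 90/10 by patch, seeded; the whole
dataset is a pure function of (inputs, configuration, seed).

**Label conversions.** Filled-in instance annotations convert to
membrane ground truth by per-instance erosion with a Euclidean disk
$\{(dx, dy): dx^2 + dy^2 \le r^2\}$ of user-chosen radius $r \ge 1$; the
eroded-away pixels become membrane class, so two abutting cells share a
$2r$-wide band. Erosion acts against the image edge as well, so an
instance filling the image acquires an $r$-pixel frame; an instance
consumed entirely by the erosion becomes pure membrane with a warning,
not an error. Background (extracellular space) is either folded into the
membrane class (`fill_ecs`; with three classes only where it lies within
$r$ of two distinct instances) or kept as a third "other" class — useful
when regions exterior to the specimen must be labeled explicitly to
prevent merge errors with the outside. Membrane masks thin to 1-pixel
skeletons by Guo–Hall thinning, which preserves the 8-connected
component structure; 8-connectivity is the package-wide convention for
masks and skeletons.

## The segmentation network

The classifier is a standard 2D U-net: per level two 3×3 convolutions
with ReLU, 2×2 max pooling on the contracting path, nearest-neighbour 2×
upsampling + 3×3 convolution + skip concatenation on the expanding path,
and a 1×1 softmax head over 2 or 3 classes. Defaults are depth 3 and 16
base channels — small enough for CPU desk-scale work; the tests and the
acceptance script use even smaller instances (depth 1–2, 2–8 channels)
because the synthetic task is easy and the suite must stay fast.
Patch sides are multiples of 128, which keeps every feature map size
integral for depths up to 7 and makes prediction on 1,024×1,024 tiles a
valid fully-convolutional operation.

Training minimizes per-pixel cross-entropy (optional inverse-frequency
class weights, normalized to mean 1 — EM datasets are typically ~75%
intracellular) with momentum SGD (lr 0.01, momentum 0.9). Momentum SGD
is the default so that a single update step has the closed form
$\Delta w = -\eta \, m_g \, g$ with group multiplier $m_g$, which makes
the leaky-freeze contract directly testable; Adam is available by flag.
The forward/backward passes are authored in R over Rcpp convolution and
pooling kernels, and the backward pass is verified against numerical
differentiation in the test suite. Training is deterministic given the
seed (single-threaded).

**Transfer-learning schedules.** `scratch`/`continuous` train all
parameters (continuous learning = retraining a pretrained net with no
modification); `freeze_last` trains only the head; `freeze_encoder`
fixes the contracting path (the bottleneck is grouped with the encoder);
`leaky_freeze` trains the encoder at `leaky_factor` (default 0.1) times
the decoder's learning rate; `episodic` interleaves batches from two or
more datasets at a configurable ratio (default 1:1) to counter
catastrophic forgetting. ONNX export (opset 13, NCHW, float32; Conv,
Relu, MaxPool, Resize-nearest, Concat, Softmax) preserves architecture
and weights; import reconstructs a model usable for both inference and
continued training, and rejects graphs outside this documented topology
with an error naming the unsupported operator. The protobuf subset
reader/writer is part of the package; its round trip is verified to
forward agreement within $10^{-4}$ (observed: $\sim 4 \times 10^{-8}$,
the float32 quantization floor).

## Tile volumes and chunked inference

Volumes are directories of fixed-size PNG tiles (default 1,024×1,024;
always a multiple of 128) with a JSON-syntax `.vsvi` descriptor — the
text-file contract under which the VAST annotation tool mounts tiled
image stacks. The descriptor records the naming scheme
(`mip%d/z%05d/r%03d_c%03d.png` by default; configurable, so dialect
compatibility is configuration rather than code), extents, voxel size,
mip range, pixel type and value semantics. The exact key names of other
tools' descriptor dialects are not standardized; this package's schema
is its own documented dialect, validated strictly, and round-trips
losslessly. Coordinates are 0-based (z section, y row, x column) with
half-open ROIs. Edge tiles are zero-padded so every tile file has
identical dimensions; tiles are flushed as written, keeping the memory
contract at one chunk plus the model. Mip level $m$ stores the volume
downsampled $2^m$-fold in x/y only — 2×2 block means for grayscale,
stride-2 nearest subsampling for labels (averaging ids is meaningless).
Label volumes pack integer ids into 24-bit RGB PNGs; probability tiles
quantize $[0,1]$ to 8-bit.

Traversal mirrors the viewer's caching: chunks of 16 sections by one
tile footprint, ordered z-innermost, then x, then y; the chunks
partition any ROI exactly (property-tested on random ROIs). Prediction
applies the dataset's stored grayscale correction, then the model, to
every section of every tile. Tiles are predicted independently with no
overlap or blending — the conformance-first choice matching per-tile
evaluation; consequently tile borders can show seam artifacts with small
networks, and an overlap-and-crop mode is deliberately out of scope
here. Because *all* prediction modes (whole volume, boxed ROI, anchor
cubes) evaluate the same volume-aligned tile grid, overlapping outputs
agree bit-exactly, and reruns are bit-identical; `--resume` skips tiles
whose files already exist. Anchor mode clips cubes at volume edges and
flags the clipping; categorical maps are per-pixel argmaxes with ties
broken toward the lower class index.

## Instance expansion and scoring

Membrane probabilities become instances by watershed region growing:
regional minima shallower than `h` (default 0.1) are suppressed by
geodesic reconstruction-by-erosion, the suppressed landscape is
thresholded (default 0.5) and its connected components become seeds, and
Meyer flooding of the *original* probability landscape grows each seed
until basins meet. Pixels where two basins meet keep id 0 — matching
paint-until-border semantics — and instances smaller than `min_area`
merge into the neighbour with the lowest probability barrier. An
all-membrane input yields an empty map; an all-zero landscape yields one
instance. The defaults (`threshold` 0.5, `h` 0.1) were chosen once as
the natural midpoint and a mild suppression depth; the upstream
reference implementation for this step is described as a proof of
concept without printed parameters. `seeded_fill()` is the single-click
counterpart: the 8-connected non-membrane component containing the
seed, which demonstrably leaks through a 1-pixel membrane break — the
merge-error failure mode.

Variation of information between two instance maps is
$VI = H(A|B) + H(B|A)$ in bits from the pixel-wise contingency table;
the two conditional terms are reported separately as merge/split error
components. Pixels with id 0 in either map are excluded from the
contingency table — the masking convention is this package's documented
choice (the upstream masking convention is unprinted), and it is what
makes the conversion round trip meaningful: membrane-band pixels, which
belong to no instance, are not scored. Whether to score per 2D section
or over 3D volumes is likewise unprinted upstream; scoring here is per
section, consistent with the package's 2D scope.

## Synthetic fixtures and what they show

`generate_mosaic()` renders Voronoi cell mosaics: seeded random centers,
nearest-center instance ids, membrane ground truth derived *through*
`instance_to_membrane()` (so the self-consistency of the two ground
truths is exact by construction), gray levels 165/60 for
intracellular/membrane, Gaussian texture noise (sd 10), blur σ 1.
Defaults are 256² images with 12 cells and nominal membrane width 3 px,
realized as erosion radius ⌈3/2⌉ = 2 (the conversion produces
even-width inter-cell bands). Voronoi mosaics are the minimal texture
with cell-like topology; optional membrane gaps (deleted boundary
disks) create controlled merge-error conditions. `generate_volume()`
stacks per-section mosaics whose cell centers drift linearly with a
per-cell random velocity (coherent across z; drift 0 reproduces
identical sections; the texture noise field is intentionally frozen
across z).

What the fixtures do *not* emulate: organelle ultrastructure and
intracellular texture, staining gradients, section artifacts
(folds, knife marks), anisotropic z statistics, and membranes whose
appearance varies with orientation. Passing tests therefore demonstrate
the *mechanics* — saturation guarantees, storage contracts, training
dynamics, mode consistency, metric correctness — not segmentation
accuracy on real EM, which is data-bound. Quantities like the 97%-range
validation accuracies reached on these mosaics are properties of the
synthetic task, not forecasts for tissue.

## Experiment harnesses and problem sizes

`transfer_experiment()` pretrains a depth-1, 4-channel U-net on 40
patches of a domain-A mosaic, then per seed fine-tunes (continuous
learning) on 30 patches from three domain-B images — brighter/noisier
mosaics, mimicking a related-but-different specimen — against an
identical scratch network, recording the first epoch at which balanced
validation accuracy reaches 0.85. Balanced accuracy is used because
plain accuracy is dominated by the ~90% intracellular class. Across
seeds, fine-tuning typically reaches threshold at epoch 0–1 versus 2–5
from scratch. `augmentation_benchmark()` trains one network per
augmentation variant and reports the mean test variation of information
over held-out mosaics, with standard errors over test images and over
reseeded retrainings.

Problem sizes throughout the tests and the acceptance script — 256²
mosaics, 40–60 patches of 128², depth-1/2 networks with 2–8 base
channels, 6–10 epochs, 200 oracle masks, 1,000 saturation draws — are
the package's chosen desk-scale defaults: large enough for every
contract to be exercised meaningfully, small enough that the whole suite
runs in minutes on one CPU core.

## Known limitations

* Purely 2D: no 3D network, no cross-section instance agglomeration —
  per-section instances are the designed endpoint, feeding external
  agglomeration tools.
* No live connection to a running annotation tool; interoperability is
  file-based (tile trees + `.vsvi`), honouring the same chunking
  contract.
* No-overlap tiled inference can seam at tile borders with small
  receptive fields.
* The ONNX importer accepts exactly the documented U-net topology, not
  arbitrary graphs.
* The native CPU training loop is intended for desk-scale fine-tuning
  and method work, not for terabyte-scale production training.
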