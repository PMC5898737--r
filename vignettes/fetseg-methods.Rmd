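---
title: "Automated FET-PET lesion segmentation with a volumetric U-Net: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated FET-PET lesion segmentation with a volumetric U-Net: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fetseg)
```

## The problem

O-(2-[18F]fluoroethyl)-L-tyrosine (18F-FET) is an amino-acid PET tracer
with low uptake in normal brain, which makes it well suited to imaging
gliomas: the tumor stands out against a quiet background, interrupted
only by a few physiologic structures (venous sinuses, peri-orbital fat)
and reconstruction artifacts at the field-of-view border. Delineating
the biological tumor volume (BTV) on these images matters for biopsy
targeting, radiotherapy planning and response monitoring, but manual
delineation is slow and observer-dependent, and plain intensity
thresholds ignore spatial context.

`fetseg` implements a fully automated two-step procedure on 3D volumes:

1. **Detection** — a 3-level volumetric U-Net produces a foreground
   probability map from the preprocessed 20–40 min summation image, and
   its thresholded mask localizes the lesion.
2. **Segmentation** — the predicted mask is refined by a morphological
   dilation (3×3×3 cube) followed by an adaptive threshold at 1.3 times
   a subject-specific background estimate, obtained by reflecting the
   predicted mask across the mid-sagittal plane ("hemispheric swap")
   and averaging the activity under the reflection.

The refinement mirrors the construction of the reference segmentation,
where the threshold is 1.3 times the mean of a 10 cm³ spherical VOI in
the contralateral hemisphere.

## Reference (ground-truth) segmentation

For each subject the reference mask T is produced semi-automatically on
the 20–40 min summation image at native resolution:

* a generous envelope around the lesion (in clinical practice drawn by
  hand; here emulated by dilating the simulated lesion support with a
  Euclidean ball of 10 mm),
* a background estimate: mean activity of a 10 cm³ sphere
  (radius $(3V/4\pi)^{1/3} \approx 13.37$ mm, about 1,250 voxels at
  2 mm spacing) centred at the centroid of the contralateral
  hemisphere's brain support,
* $T = \{\,v \in \text{envelope} : I(v) \ge 1.3 \times \text{background}\,\}$.

Two choices the procedure leaves open were fixed as follows. The
comparison is *inclusive* (≥), which keeps a uniform lesion at exactly
2× background entirely above a 1.3× cut. The background sphere is
placed deterministically at the contralateral support centroid rather
than by eye; this makes the reference reproducible and testable, at the
cost of ignoring operator judgement about avoiding sinuses — on the
phantoms the sinuses are midline structures and contribute to both
hemispheres symmetrically, so the bias is shared.

Note that T is *not* the simulated ("biological") lesion support: T is
a thresholded BTV, exactly as in the clinical procedure, and the two
differ systematically at the blurred lesion rim. The package keeps both
notions distinct (`truthLesion` on the phantom; `semiAutoSegment`'s
output for training and evaluation).

## The synthetic cohort

No patient volumes ship with the package; a parametric phantom
(`phantomSpec`, `generateSubject`, `generateCohort`) emulates the
statistical structure of a spatially normalized dynamic FET-PET study
on the MNI-like 2 mm grid (91×109×91):

* an ellipsoidal brain support at uniform background uptake (1.0 a.u.),
* 2–4 midline/posterior tubular "sinus" structures at 1.5–2.0×
  background, symmetric peri-orbital fat blobs, and a thin peri-cranial
  rim at 1.3× background,
* one lesion per positive subject: a union of 1–3 overlapping
  ellipsoids (component radius uniform in 8–25 mm) placed in a single
  hemisphere, at a contrast uniform in 2–4× background, modulated by a
  smooth heterogeneity field (relative sd 0.2),
* a linear per-frame trend of lesion activity (slope uniform in
  −0.03…+0.05 per frame) across 10 frames of 5 min,
* each frame blurred with an isotropic Gaussian of FWHM 5 mm (the
  reconstruction post-filter that dominates the texture of the real
  images) and degraded with additive Gaussian noise of sd 0.05×
  background.

No quantitative SUV distribution is prescribed for this kind of
acquisition, so the contrast, noise and heterogeneity levels are
stand-ins chosen once to keep the 1.3×-background threshold regime
non-degenerate (a lesion must exceed the threshold or the reference
segmentation collapses); the lower contrast bound of 2 sits safely above 1.3 while
still producing partial-volume losses at the rim after the 5 mm blur.

What the phantom does *not* emulate: anatomically realistic uptake
topography, OSEM reconstruction noise correlations (the noise here is
additive Gaussian, post-filter), scanner-specific resolution, multiple
lesions, or misregistration between subjects. Passing tests on phantoms
therefore demonstrate that the pipeline's machinery is correct and that
the two-step procedure behaves as described under controlled
conditions — not that the same accuracy transfers to patient data.

## Preprocessing

In pipeline order: frame summation (20–40 min, frames 5–8) → reference
segmentation at native resolution → trilinear resize of the summation
image to the network grid (64×64×40 by default; masks are resized
nearest-neighbour and re-binarized, because interpolated masks are no
longer binary) → gradient-magnitude contour enhancement
($I \mapsto I + \lVert\nabla I\rVert$, central differences) →
z-normalization. Whether the enhancement precedes or follows the
resize is an open choice; enhancing *after* resizing was chosen because the enhancement is a network-input concern and this
keeps the reference segmentation independent of the network grid.

Training-set augmentation draws one random affine per subject and epoch
(rotation ±30° about a random grid axis, per-axis translation ±0.1 of
the axis length, shear ±10° in a random axis pair, isotropic zoom
0.85–1.15), composed zoom → shear → rotate → translate about the volume
centre, applied identically to image (trilinear, out-of-field filled
with the volume minimum) and mask (nearest-neighbour, filled with 0).
Augmenting on the fly rather than pre-expanding the dataset is
equivalent in expectation and keeps memory flat.

The 70/30 split is a uniform random partition with
$|\text{train}| = \text{round}(0.7\,n)$ (37 subjects → 26/11).

## Network and training

The U-Net (`unetConfig`, `buildUnet`) has three resolution levels:

* encoder: per level, two same-padded 3×3×3 convolutions + ReLU, then
  2×2×2 max-pooling with stride 2; channels double from 16 (16→32→64);
* decoder: per level, 2× nearest-neighbour upsampling followed by a
  3×3×3 "up-convolution" halving the channels, concatenation with the
  matching encoder feature map, then two 3×3×3 convolutions + ReLU;
* head: a 1×1×1 convolution to one channel with a sigmoid.

This configuration has exactly 387,889 trainable parameters and 11
convolution layers under the convention that counts the ten block
convolutions plus the head (up-convolutions belong to the upsampling
step). The architecture is pinned to this parameter count, which
resolves several otherwise-open choices: same-padding (padding 1),
because larger padding grows feature maps and breaks skip
concatenation; a single sigmoid output channel, because a two-channel
head would give 387,906 parameters; and no batch normalization, which
would likewise change the count. Weights
are initialized with the fan-in-scaled uniform scheme
($\pm\sqrt{6/(k^3 c_{in})}$), biases at zero, seeded.

Training (`trainUnet`) minimizes minus the *soft* Dice coefficient

$$\mathcal{L} = -\frac{2\sum_v p_v t_v + s}{\sum_v p_v + \sum_v t_v + s},
\qquad s = 10^{-6},$$

with Adam (learning rate $10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$),
batch size 5, up to 150 epochs, final-epoch weights retained (no early
stopping). Per-sample losses are averaged within a batch. The recorded
per-epoch validation Dice is the *hard* Dice at probability threshold
0.5 (soft Dice is logged alongside, since a learning curve alone does
not reveal which convention produced it). All network primitives (direct
same-padded 3D convolution, pooling, upsampling, and their backward
passes) are implemented in C++ within the package and verified against
finite differences; training is single-threaded and bit-reproducible
for a fixed seed on one platform.

## Post-processing

`refineMask` computes
$\text{dilate}(P) \cap \{\,I \ge 1.3 \times \overline{I}(\text{mirror}(P))\,\}$,
with three deliberate choices where the procedure is otherwise
ambiguous: the background mean uses the *un-dilated* prediction (the
swap is described as "of the predicted mask"); the threshold is applied
to the raw resized summation intensity, not the z-normalized network
input (z-scores can be negative, making a multiplicative 1.3× threshold
meaningless, and the reference procedure also thresholds raw activity);
and since the refined mask is an intersection, the order of dilation
and thresholding is immaterial.

## Evaluation

`dsc`, `confusionCounts` and `voxelMetrics` implement
$DSC = 2|P\cap T|/(|P|+|T|)$ (defined as 1 when both masks are empty)
and Se, Sp, PPV, NPV with 95% Wald intervals
$p \pm 1.96\sqrt{p(1-p)/n}$ clipped to [0,1], each with its own
denominator as $n$. Wald is the convention adopted here: on the reference confusion counts
it yields the PPV interval 76.9–78.3%, which neither the exact-binomial
nor the Wilson interval does. Cohort Dice is reported both pooled
($2TP/(2TP+FP+FN)$ over summed counts) and as a per-subject mean — the
two differ, and cohort-level summaries in the clinical literature are
typically per-subject aggregates. Lesion-level detection labels 26-connected components of
the prediction; a lesion counts as detected on ≥1 voxel of overlap, and
components overlapping no lesion are false positives — the simplest
rule consistent with reporting "no false positive".

## Numerical choices and degenerate inputs

* Resampling is cell-centred (align-corners-false), which makes
  resizing to the same shape the exact identity and preserves constant
  volumes exactly; mask resampling is nearest-neighbour + re-binarize.
* Mirroring is about the grid midline of the left-right (first) axis,
  $i \mapsto n-1-i$, an exact involution; phantoms are generated
  midline-symmetric so the swap samples homologous tissue exactly.
* Frame windows are half-open $[start, end)$ minutes and must align
  with frame boundaries; the default 20–40 min window sums frames 5–8.
* Max-pooling ties resolve to the first voxel in scan order;
  `semiAutoSegment` flags an empty result on the output instead of
  raising; `voxelMetrics` flags a zero-denominator metric as undefined
  and still returns the others; an empty predicted mask skips
  refinement (there is nothing to mirror).
* Gaussian blur uses a separable kernel truncated at 3.5σ with
  reflecting boundaries.

## Scaled experiment sizes

The package's own end-to-end experiments run the full pipeline at
reduced scale so that they complete on a single CPU: the standard
cohort experiment used in the acceptance suite generates 20 phantom
subjects (14 train / 6 validation), trains at a 32×32×24 network grid
for 25 epochs without augmentation, and evaluates detection and
segmentation on the validation subjects. Augmentation is omitted at
this scale because regularization against overfitting a 14-subject
phantom cohort is not the property under test and it roughly doubles
the epochs needed to converge; the full-scale defaults
(64×64×40, 150 epochs, augmentation on) remain the package defaults.
Determinism is exercised with an even smaller configuration (6
small-grid subjects, 2 epochs) where byte-identical reports are
asserted across two runs.

## Known limitations

* The phantom's simplifications listed above; in particular additive
  Gaussian noise understates the spatial noise correlation of iterative
  PET reconstruction.
* The emulated manual envelope is derived from the simulated lesion, so
  reference masks on phantoms inherit none of the inter-observer
  variability of clinical delineation.
* Training on CPU restricts practical problem sizes; the implementation
  is exact but not fast on full-resolution cohorts.
* Single-lesion subjects only; the detection stage handles multiple
  components, but the generator never produces multi-focal disease.
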