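---
title: "Tracing weak neurite fibers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing weak neurite fibers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains what NeuriteTrace computes, the assumptions behind
each stage, and the design decisions taken where more than one reasonable
choice existed. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

Single-neuron light-microscopy volumes contain fibers spanning two orders of
magnitude in brightness. Dim fibers — mostly axons, with raw 8-bit
intensities below ~20 — sit barely above the noise floor, and both classical
tracers and plainly trained segmentation networks miss them
disproportionately. The package combines an image transform that lifts weak
signal without damaging bright-fiber contrast, and a training-time loss
re-weighting that focuses the network on exactly the foreground it currently
misses.

## Derivative-truncated gamma transform

With intensities normalized to $[0,1]$ by the dtype maximum (so raw 20 is
always $20/255$), the plain gamma transform $g(x)=x^\gamma$, $\gamma<1$,
amplifies weak values but has derivative $\gamma x^{\gamma-1}<1$ for
$x$ above the point where the derivative crosses 1. Contrast between two
bright values is therefore compressed, which shows up as a diffuse halo
around bright tubes. The truncated transform keeps the gamma curve only
where its slope is $\ge 1$:

$$\hat g(x) = \begin{cases} x^\gamma & x \le \delta\\
x - \delta + \delta^\gamma & x > \delta\end{cases},
\qquad \delta = \gamma^{1/(1-\gamma)},$$

and $\delta$ is precisely the root of $\gamma\delta^{\gamma-1}=1$
(`truncationPoint()`, closed form, checked to $10^{-10}$ in the tests;
$\gamma=0.5 \Rightarrow \delta=0.25$ exactly). The two pieces meet
continuously at $\delta$ and the slope is $\ge 1$ everywhere, so any
contrast present in the input is preserved or amplified — the anti-halo
property, asserted on a $10^{-3}$ grid.

**Standardization.** The transform maximum is $\hat g(1)=1-\delta+
\delta^\gamma \ge 1$; `standardizeRange()` divides by this constant so the
output range is again $[0,1]$. A per-volume min–max rescale would also land
in $[0,1]$ but would make the transform data dependent and destroy the exact
unit slope; dividing by the fixed $\hat g(1)$ keeps the transform a pure
pointwise function. `gamma = 1` bypasses everything and returns the input
bit-for-bit.

**Default $\gamma = 0.4$.** The transform is illustrated and exercised
throughout at 0.4, which puts $\delta \approx 0.217$ — weak fibers
($<20/255 \approx 0.078$) are deep inside the amplified region while the
strong-fiber range is untouched. The exponent is exposed everywhere a
transform is applied; the same value must be used at training and inference
time, and the pipeline applies it to both.

## Labels from SWC reconstructions

Expert reconstructions are SWC trees whose nodes can be several voxels
apart, so label generation first resamples every parent→child segment at
1-voxel spacing (endpoints included, so consecutive points on a segment are
never more than a voxel apart), then stamps each rounded point with a fixed
3×3×1-voxel (x, y, z) box, and finally overlays an 18×18×6 cuboid at the
soma. The same cuboid is painted into the *image* at a configured intensity
(default: the image maximum), because manual annotations carry no soma
segmentation and a consistent artificial soma appearance is less ambiguous
than the natural variability of somata. An ellipsoidal soma with the same
semi-axes is available (`somaShape = "ellipsoid"`); the cuboid is the
default.

Numerical conventions, fixed once to avoid silent transposes:

* SWC coordinates are voxel units, 0-based, voxel centers at integers;
  volumes are R arrays of dim `c(x, y, z)` (x fastest, matching R's
  column-major layout), and all user-facing sizes are quoted (x, y, z).
* The even-sized soma cuboid cannot be centered on a voxel; it is anchored
  as the floor-centered half-open range $[c-s/2,\,c+s/2)$ per axis, which
  contains exactly $s$ voxels when unclipped (1944 for 18×18×6) and clips
  deterministically at volume borders (243 voxels for a corner soma).
* Node radii are read and written for I/O fidelity but ignored by label
  generation — the uniform fiber width deliberately over-covers thin axons
  because annotation coordinates carry small shifts relative to the signal.

## Segmentation network and training

The network is a compact vanilla 3D U-Net: per level two 3×3×3 convolutions,
each followed by instance normalization and ReLU; 2×2×2 max pooling between
levels; nearest-neighbour ×2 upsampling followed by a 3×3×3 convolution and
skip concatenation on the way up. Upsample-then-convolve was chosen over a
transposed convolution: both are standard in vanilla U-Nets, and the former
avoids checkerboard artifacts and keeps the hand-written backward pass
simple. Two 1×1×1 heads emit 2-channel logits — one on the final block, one
on the preceding (half-resolution) block for deep supervision, where the
label is max-pooled so 1-voxel fibers survive downsampling. Head weights are
1.0 (final) and 0.5 (auxiliary); the per-head loss is soft Dice plus
cross-entropy.

The full-scale profile is the reference training recipe: Nesterov SGD,
learning rate 0.01, momentum 0.99, weight decay 3e-5, 15 200 iterations,
160×160×128 crops, flip/gamma/noise/resize augmentations. Choices the
recipe leaves open, fixed here: polynomial learning-rate decay with power
0.9 (the conventional schedule for this optimizer family), batch size 1
(instance normalization makes batch statistics irrelevant), 4 levels and 16
base channels at full scale, and augmentation parameters (flip p=0.5 per
axis, gamma jitter in [0.7, 1.4] p=0.3, noise σ up to 0.05 p=0.3, resize
[0.8, 1.2] p=0.2 with nearest-neighbour resampling so labels stay binary).

**False-negative mining.** Each iteration, the foreground probability $P$ of
the final head defines $FN = F \cap \{P<0.5\}$; the weight map is $w_{FN}$
(default 1.5) on $FN$ and 1 elsewhere; the weighted cross-entropy is
$\frac1N\sum w\,\ell$ with $N$ the total voxel count (not $\sum w$, so
up-weighting strictly increases the penalty on missed foreground). The mask
is recomputed on the fly and treated as a constant in the backward pass — no
gradient flows through its construction, which also means the loss is
intentionally discontinuous in the parameters at the $P=0.5$ boundary.
Dice is left unweighted by default: it is a set-overlap measure, not a
per-voxel loss; a weighted-Dice variant sits behind
`trainConfig(weighted_dice = TRUE)`. Only false negatives are ever
up-weighted because partially annotated images contain true-but-unlabeled
fibers; punishing apparent false positives harder would teach the network to
suppress exactly the fibers the method wants to recover. With
$w_{FN}=1$ (or `fnm = FALSE`) training reduces bit-for-bit to the
unweighted baseline, which the tests assert.

**Implementation.** The network, loss and optimizer are implemented natively
(R with C++ kernels): 3×3×3 convolutions run as 27 shifted BLAS GEMMs with
explicit boundary corrections, verified against an im2col reference to
$10^{-12}$, and every backward pass is the exact adjoint, verified by central
finite differences (relative error $<10^{-4}$ at $\varepsilon=10^{-6}$,
checked with mining disabled since the mined loss is discontinuous by
design). Training is deterministic given the config seed.

**Tiled inference.** Whole volumes are segmented in overlapping tiles; each
tile contributes its central region (interior margins of `overlap/2` are
discarded) and remaining overlaps are averaged. With normalization disabled
and overlap at least the receptive-field diameter, tiled equals single-pass
prediction to $10^{-6}$ (tested); with instance normalization the
per-window statistics necessarily differ, so tiling is only approximately
seam-free — an inherent property of instance-normalized networks, not a
defect of the tiling.

## Fusion and tracing

The probability map is fused with the *original* (un-enhanced) image,
$\hat x = \alpha x + (1-\alpha)p$ with $\alpha = 0.8$: the image dominates,
but confidently segmented dim fibers are lifted by up to $0.2$ — enough to
cross tracing thresholds — and a soma that the network disconnects is
rescued by its image intensity. Fusion happens on the normalized $[0,1]$
scale throughout.

The built-in tracer is deliberately simple: threshold the fused volume
(default 0.1, i.e. just above what fused background can reach but below any
confidently segmented fiber), keep the 26-connected component containing the
soma (erroring with "disconnected soma" if the soma voxel itself is below
threshold), thin it to a ~1-voxel skeleton by sequential simple-point
removal (endpoints preserved, the soma voxel protected; sequential removal
guarantees topology preservation at the cost of slight scan-order
asymmetry), build the 26-adjacency voxel graph with Euclidean edge weights,
take the shortest-path spanning tree from the soma, and prune terminal twigs
shorter than 2 voxels (skeleton fuzz from 3-voxel-wide label tubes). The
result is always a single-rooted acyclic SWC. Fused volumes can be written
to TIFF for external tracers where a production tracer is preferred.

## Evaluation metrics

Both trees are resampled to 1-voxel spacing before any metric, so "points"
approximates "voxels"; `resample = FALSE` gives raw-node behavior. For
point sets $A$ (gold) and $B$ (reconstruction):

* **SD12** = mean nearest-point distance $A \to B$ (recall-like), **SD21**
  the reverse (precision-like), **SD** their average.
* **SSD** restricts the mean to distances $> 2$ voxels and returns 0 when
  none exceeds the threshold (no substantial discrepancy — not `NaN`).
* **PDS** is the fraction of points with nearest distance $> 2$ voxels; the
  bidirectional value averages the two directional fractions, the same
  convention as SD and SSD.
* **Intensity-stratified recall**: a gold point is traced iff a
  reconstruction point lies within the match radius (default 2 voxels,
  chosen to agree with the SSD/PDS threshold; the choice is ours — no
  canonical value exists); recall is reported per intensity bin of the image
  value at the gold point, and *weak recall* pools bins below $20/255$.
* **Self-crossing count**: pairs of nodes closer than 1 voxel after
  excluding nodes within 50 voxels of the soma and pairs related within 10
  generations (shared ancestor horizon). The raw pair count is reported;
  batch mode averages across neurons.

All distance metrics are verified against $O(NM)$ brute-force oracles on
hundreds of random instances, and the directional semantics are pinned by a
nested-pruning monotonicity test (pruning the reconstruction can only raise
SD12 and, for a pruned copy, keeps SD21 at zero).

## The synthetic phantom generator

Real single-neuron volumes cannot ship with a package, so the generator
produces what the pipeline needs to be falsifiable: seeded scenes with

* sparse branching tubular fibers (~1.0–1.3-voxel radius) grown as random
  walks with turning angle capped at 30° per unit step — tortuous but not
  self-folding — sprouting from the soma or (p = 0.35) from an existing
  fiber;
* a bimodal peak-intensity split: weak fibers uniform in [0.04, 0.075]
  (below the 20/255 threshold), strong in [0.25, 0.9];
* Gaussian tube profiles with $\sigma = r/1.5$ truncated at $3\sigma$
  (smooth sub-voxel fibers, as in light microscopy), combined by maximum;
* background mean 0.01, additive Gaussian noise $\sigma = 0.01$, a bright
  ellipsoidal soma, and oval plaque artifacts (smooth ellipsoidal intensity
  bumps placed with a minimum-separation rule so they form distinct blobs);
* partial labels: each fiber is dropped from the annotation with probability
  `unlabeled_fraction` (default 0.2), descendants dropped with it, so the
  labeled tree is always a connected subtree containing the soma.

Determinism is a contract: identical configurations (including the seed)
produce byte-identical images and SWC files, and one frozen node count is
kept as a regression fixture. The defaults were chosen once to make weak
fibers genuinely hard (near the noise floor) while keeping every gold node
above background pre-noise, and are not tuned per experiment.

What the phantoms do **not** emulate: realistic optics (no PSF, no
anisotropic z-blur by default, though the blur hook exists), non-Gaussian
sensor noise, densely packed multi-neuron fields, intensity falloff along a
fiber, and annotation coordinate shifts. Passing tests on phantoms therefore
demonstrate the correctness and the qualitative behavior of the machinery —
that mining raises weak-fiber recall, that the pipeline reconstructs the
morphology — not performance on real brains.

## Benchmark problem sizes

The test suite and the acceptance script run everything at a *tiny profile*
chosen as the package's CPU-scale study size: 64×64×32-voxel scenes with 20
fibers (weak fraction 0.5 in the benchmark), a 2-level / 8-channel network,
32³ crops, 200 training iterations, weights $w_{FN} \in \{1.0, 1.5\}$ × 3
seeds in the test benchmark (2 seeds in the acceptance script, which also
traces three held-out scenes). The benchmark asserts direction, not
magnitude: median weak-fiber voxel recall with mining at least that of the
unweighted baseline, training loss decreasing, and end-to-end SD to gold
under 5 voxels on at least 3 of 4 held-out scenes.

## Known limitations

* The fixed 3×3×1 fiber width can bridge adjacent axons in dense arbors;
  radius-aware labels are a natural extension once annotation shifts are
  corrected.
* The built-in tracer is a stand-in: it has no gap-bridging, so fibers the
  segmentation leaves disconnected from the soma component are lost
  (mitigated, by design, through fusion with the image).
* Instance normalization makes tiled inference only approximately equal to
  whole-volume inference (see above).
* The native training loop is single-threaded double precision; it is sized
  for the tiny profile and for method study, not for full-scale training,
  where the same architecture and loss would be run on GPU tooling.
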