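---
title: "Methods: the cardioseg segmentation pipeline"
author: "cardioseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cardioseg segmentation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardioseg)
```

# Overview

cardioseg segments short-axis cardiac cine-MRI into background, right
atrium, left atrium and aorta. The pipeline has four stages — region-of-
interest (ROI) detection, an attention-augmented encoder–decoder network,
conditional-random-field (CRF) boundary refinement, and six-metric
evaluation — plus a synthetic phantom generator that stands in for
clinical data everywhere in development and testing. This vignette is the
package's own account of the science in each stage: the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not demonstrate.

# The phantom generator

A cine study is emulated as two pulsating, circular "atria" and one
static circular "aorta" on a uniform background, sampled at the geometry
of clinical acquisitions: 235–263 pixels per side and 28–40 frames per
cardiac cycle (both drawn per phantom unless overridden). Chamber radii
follow one full sinusoid over the cycle,
$r_k(t) = \bar r_k \,(1 + a \sin 2\pi (t-1)/T)$, with pulsation amplitude
$a = 0.2$ by default; the aorta radius is constant, matching its
near-static appearance within a slice. Noise-free tissue intensities are
plateaus (background 0.2, right atrium 0.5, left atrium 0.7, aorta 0.9,
arbitrary units) with additive i.i.d. Gaussian noise of
$\sigma = 0.05$ — a contrast-to-noise ratio of at least 6 between
adjacent classes, comfortable but not trivial. Masks always trace the
noiseless geometry exactly, so ground truth is analytic.

What the phantom deliberately reproduces is the *statistical structure
the pipeline exploits*: temporal intensity variation concentrated at
moving chamber rims, a circular near-static aorta, and
radiometrically distinct tissues. What it does not reproduce: MR physics
(coil bias fields, Rician noise), anatomical shape variability,
myocardium/blood-pool contrast inversion, through-plane motion, or
pathology. Passing the synthetic benchmarks therefore demonstrates that
the implementation is correct and the pipeline's logic is sound under
its stated assumptions — not that the trained toy model transfers to
clinical images.

All randomness is seeded; a fixed `PhantomSpec` yields byte-identical
output.

# ROI detection

**Temporal standard-deviation filter.** The per-pixel population standard
deviation over the $T$ frames highlights the moving cardiac region.
Population (divide by $T$) rather than sample normalization is used so
tiny closed-form cases are exact (a pixel alternating 0, 1 has standard
deviation exactly 0.5). The filter is temporal-only; a spatiotemporal
window would blur the localization it exists to provide.

**Detection gate.** Before any circle search, the std-dev map must show
actual motion signal: the ratio of its 99.9th percentile to its median
must exceed `minSignalRatio` (default 2). On a structure-free noise
sequence every pixel sits at the noise floor and the ratio hovers near 1,
so detection aborts with "ROI not found" instead of returning a spurious
circle — circle voting alone cannot make this distinction, because dense
noise edges can support substantial accidental circles.

**Canny chain.** Gaussian smoothing (truncated at $3\sigma$, renormalized,
default $\sigma = 1.5$ px), Sobel gradients with the canonical kernel
pair, gradient magnitude $\sqrt{G_x^2+G_y^2}$, and the direction
$\theta = \operatorname{atan2}(G_y, G_x)$ quantized to the eight compass
angles. Some texts print the transposed form
$\arctan(G_x/G_y)$; we implement the conventional form and expose the
other behind `direction = "printed"` — for quantized directions the two
differ only by a relabelling, and the conventional form is what makes
"compare the two neighbours along the gradient" thin edges across, not
along, a boundary. Non-maximum suppression keeps a pixel when its
magnitude is $\ge$ both neighbours along its quantized direction
(plateaus survive; opposite directions share a neighbour pair).
Hysteresis marks responses above $T_1$ strong and those in $(T_2, T_1]$
weak, keeping weak pixels 8-connected (transitively) to a strong pixel —
implemented as a BFS flood fill, and tested against an independent
iterative-dilation oracle. Defaults: $T_1$ by Otsu's method on the
positive suppressed magnitudes, $T_2 = T_1/2$ (the conventional 2:1
ratio). All convolutions reflect-pad borders, so constant images pass
through unchanged.

**Which image is edge-detected.** The chain runs on the *temporal-mean*
image, not on the std-dev map. The reason is physical: the aorta is the
near-static structure, so it is invisible in a variance map — only the
pulsating chamber rims appear there. The mean image averages the noise
down by $\sqrt T$ and shows the aortic rim as a clean circle. The std-dev
map still contributes twice: as the detection gate above, and as the
evidence used to *select* the aorta among circle candidates.

**Hough transform and aorta selection.** Every edge pixel votes for all
centres at each radius in the aortic search range (default 8–25 px); the
accumulator is deduplicated greedily (centres closer than half the larger
radius collapse). A candidate counts only if its votes cover at least
`minVoteFrac` (default 0.25 — a quarter) of its circumference. Among
eligible candidates the one with the *lowest mean interior temporal
standard deviation* is chosen: chamber circles contain their own
pulsating rim and score high, the aorta's interior sits at the noise
floor. We use this relative comparison rather than an absolute "below the
map median" rule because the aorta interior and the background are
statistically indistinguishable (both are noise-floor), making an
absolute threshold a coin flip; the relative rule encodes the same
intent — the most static circular structure — robustly. A 128 × 128
window is centred on the winner, clamped at image borders, and the crop
is z-scored per sequence (zero mean, unit standard deviation).

Coordinates throughout are 1-based (row, col) with inclusive windows, the
R array idiom.

# The segmentation network

**Encoder.** Five levels; level $\ell$ applies two 3 × 3 convolutions
with ReLU and an additive residual shortcut (a 1 × 1 projection aligns
channel counts, which always differ across a level), then 2 × 2 max
pooling (omitted after the deepest level). Channel widths double per
level from `baseChannels`; the classic configuration is 64→1024 with a
128 × 128 input, giving an 8 × 8 × 1024 bottleneck. Inputs must be
divisible by 16; the constraint is checked by name.

**LRSAR block.** Dense non-local attention at the bottleneck would cost
$\Theta((HW)^2 C)$. The low-rank self-attention reconstruction block
instead builds $s$ rank-one attention maps. For each $i \le s$
(default $s = 4$):

* global average pooling slices the bottleneck $X \in \mathbb R^{H\times
  W\times C}$ along height, width and channel into three 1-d profiles;
* an independent fully connected layer plus sigmoid per axis and per $i$
  yields factors $Q_i \in (0,1)^H$, $K_i \in (0,1)^W$,
  $V_i \in (0,1)^C$ (pooling is parameter-free and shared; the FC
  parameters are what differ between the $s$ triples);
* the spatial map $A_i = \operatorname{softmax}(Q_i \otimes K_i)$ is
  normalized over all $H\cdot W$ entries, so each map sums to 1 and is a
  single spatial attention distribution. A row-wise softmax variant is
  available (`softmaxAxis = "row"`) for comparison;
* the rank-one tensor $A_i \otimes V_i$ is projected by a 1 × 1
  convolution to give the attention increment $\mathrm{attn}_i$.

Recombination uses learnable weights $\lambda_i$ (initialized to $1/s$):
$Y = X + \sum_i \lambda_i\,\mathrm{attn}_i$. The alternative literal
reading $Y = \sum_i \lambda_i (X + \mathrm{attn}_i)$ scales $X$ by
$\sum_i \lambda_i$ and so breaks the residual identity at
$\lambda = 0$; it is kept behind `mode = "literal"`, with the residual
form the default precisely to preserve that identity. The block sits at
the bottleneck only, where the spatial dimension is smallest and the FC
factor layers stay cheap.

**Complexity accounting.** `lrsarMacs()` and `denseAttentionMacs()` count
the construction and application of the attention maps themselves —
outer product, softmax, rank-one reconstruction, weighted accumulation
($\Theta(s H W C)$) versus pairwise similarities, softmax and value
aggregation ($\Theta((HW)^2 C)$). Linear embeddings present in both
designs (GAP/FC factor generation here; the $\theta,\phi,g$ and output
projections of a dense block) are excluded from both counts, as they are
common cost. Under this accounting the dense/LRSAR ratio grows linearly
in $H W$: 16× from an 8 × 8 to a 32 × 32 map.

**Decoder.** Four stages of 2 × 2 transposed-convolution upsampling, skip
concatenation with the matching encoder feature, and one 3 × 3
convolution + ReLU; a final 1 × 1 convolution produces $K = 4$ logits and
a per-pixel softmax the probability map, at the input resolution.

**Implementation.** The forward and backward passes are written directly
in R: convolutions are im2col matrix products (so the arithmetic runs in
BLAS), pooling uses explicit corner maxima with first-maximum tie
routing, and every layer's gradient is hand-derived. The full Jacobian
chain is verified in the test suite against central finite differences at
relative error below $10^{-3}$ (with the loss computed via log-sum-exp,
agreement is near machine precision; the softmax saturates on confident
pixels, which is why cross-entropy is evaluated from the logits rather
than the clipped probabilities).

**Training.** Loss is cross-entropy plus soft Dice averaged over the
three foreground classes (smoothing constant 1 in numerator and
denominator); optimizer is Adam at learning rate $10^{-3}$ with
mini-batches of 4 accumulated sample-by-sample. Shuffling and
augmentation (optional horizontal/vertical flips and nearest-neighbour
rotations up to ±15°, train-time only, off by default in the standard
run) draw from a seeded RNG, so a fixed seed reproduces the loss
trajectory bit-for-bit on a given BLAS. Training aborts with a
diagnostic on empty datasets or non-finite loss; a checkpoint of the
best-validation model can be written each epoch.

**The standard small run.** The package's reference experiment generates
25 phantoms at generator defaults, detects each ROI, crops 128 × 128,
box-downsamples 2× to 64 × 64 (the package's training resolution — it
quarters the arithmetic at no cost to the phantom's structure sizes,
which remain 5–25 px), and keeps 4 evenly spaced frames per phantom: 100
crops, split 80/20 *by phantom* so no cardiac cycle leaks across the
split. The network uses `baseChannels = 8` and trains for 12 epochs.
These sizes are chosen so the whole experiment, including the plain
U-Net ablation under the identical budget, runs in a few minutes on one
CPU core; on this easy, radiometrically separable task both variants
reach validation Dice far above the 0.80 working threshold, so the run
validates the training machinery rather than ranking the architectures —
ranking them requires a task hard enough to separate them, which the
phantom intentionally is not.

# CRF refinement

The network's probability map is refined by a conditional random field
over the pixel grid with energy

$$E(y) = -\sum_i \log p_i(y_i) \;+\; \sum_{(i,j)\in\mathcal N}
w\,e^{-(I_i-I_j)^2/\sigma_I^2}\,[y_i \ne y_j],$$

i.e. unary state potentials from the network and contrast-modulated
Potts transition potentials over a 4- or 8-neighbourhood (default 8).
Defaults: pairwise weight $w = 2$, intensity scale $\sigma_I = 0.5$ (in
the z-scored image's units), 10 mean-field iterations. Exact inference
on a grid CRF is intractable, so we use mean-field updates — each sweep
recomputes every pixel's label distribution from its neighbours' current
distributions — which converge to a fixed point on our fixtures within a
few iterations (doubling the iteration count changes no labels). The
partition function is never computed: inference and the exported
`crfEnergy()` both work with unnormalized potentials. With
$w = 0$ the refinement reduces exactly to the per-pixel argmax (ties
resolve to the lowest class index). A fully connected (dense) CRF is out
of scope; the grid neighbourhood is the minimal model that expresses
"boundaries should follow intensity edges".

`perturbMaskProbs()` provides the benchmark fixture: boundary pixels of a
ground-truth mask flip to a neighbour's label with a set rate, and the
map assigns the chosen label a set confidence. On such fixtures
refinement lowers the CRF energy relative to the argmax labelling and
raises mean foreground Dice; both properties are asserted over 20 seeds
in the acceptance suite. Mean-field does not carry a general
energy-descent guarantee — the energy check is an empirical property of
these operating conditions, which is exactly why it is tested rather
than assumed.

# Evaluation metrics

From one-vs-rest confusion counts per class: accuracy $(TP+TN)/N$,
precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, F1 (harmonic mean), IoU
$TP/(TP+FP+FN)$ and Dice $2TP/(2TP+FP+FN)$ — the count forms of the set
expressions $|I_1\cap I_2|/|I_1\cup I_2|$ and
$2|I_1\cap I_2|/(|I_1|+|I_2|)$, with $\mathrm{DSC} = 2\,\mathrm{IoU} /
(1+\mathrm{IoU})$ holding exactly per class (not for macro averages,
which average the two metrics separately). Zero-denominator convention:
a class absent from both prediction and reference scores 1, otherwise 0.
Macro averaging excludes the background class by default (the
segmentation-community convention); `macro = "all"` includes it, since
published tables do not always say which was used.

# Reproducibility and limitations

Every stochastic step — phantom noise, weight initialization, shuffling,
augmentation, fixture corruption — draws from an explicitly seeded RNG,
and derived seeds stay below $2^{31}$. The pipeline persists every
intermediate artifact (std-dev map, ROI JSON, refined masks, metrics
CSV) plus a manifest with a config hash, package version, seed and
per-stage timings, so any run is restartable and auditable.

Known limitations: single 2-D slice sequences only (no 3-D slice-stack
ROI propagation); the network's FC attention factors fix the input side
at construction; training is single-threaded CPU and sized for the
phantom benchmark, not clinical-scale data; the phantom's simplicity
means synthetic Dice values substantially overstate what any model would
achieve on real cine-MRI; and bit-exact reproducibility holds per BLAS
build, not across different linear-algebra libraries.
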