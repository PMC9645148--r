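# cardioseg

Semantic segmentation of short-axis cardiac cine-MRI in R: automatic
localization of the heart, pixel-wise labelling of the right atrium, left
atrium and aorta with an attention-augmented encoder–decoder network, and
conditional-random-field boundary refinement — plus a synthetic
beating-heart phantom generator so the entire pipeline can be developed,
trained and validated without patient data.

The package is aimed at medical-image-analysis researchers who want a
fully inspectable, CPU-only reference implementation of this pipeline:
every stage, from the Canny edge detector to the network's backward pass,
is ordinary R code operating on plain arrays.

## The pipeline

For a cine sequence (an `H x W x T` intensity stack covering one cardiac
cycle, typically 28–40 frames at 235–263 pixels per side):

1. **ROI detection.** A temporal standard-deviation filter
   `sd(x_ij) over t` highlights moving cardiac tissue. The four-step Canny
   detector (Gaussian smoothing; Sobel gradients
   `G = sqrt(Gx^2 + Gy^2)`, `theta = atan2(Gy, Gx)` quantized to eight
   directions; non-maximum suppression; double-threshold hysteresis with
   `T1 : T2 = 2 : 1`) extracts edges from the temporal-mean image, and a
   Hough circle transform proposes circular structures. The aorta — the
   near-static circle — is chosen by minimal interior temporal variance,
   and a 128 × 128 window is cropped around it and z-scored.
2. **ESA-UNet.** A five-level residual U-Net whose bottleneck carries a
   low-rank self-attention reconstruction (LRSAR) block: the bottleneck
   tensor `X (H x W x C)` is pooled along each axis into 1-d factors
   `Q_i (H)`, `K_i (W)`, `V_i (C)` (GAP → FC → sigmoid, independent
   parameters per `i`); each rank-one spatial attention map
   `A_i = softmax(Q_i ⊗ K_i)` is expanded to `A_i ⊗ V_i`, projected by a
   1 × 1 convolution, and the `s = 4` terms recombine through learnable
   weights: `Y = X + Σ_i λ_i attn_i`. Building and applying these maps
   costs `Θ(s·H·W·C)` multiply–adds versus `Θ((H·W)^2·C)` for dense
   non-local attention — a ~16× advantage at an 8 × 8 × 1024 bottleneck.
3. **CRF refinement.** A Potts grid CRF with unary `-log p` and pairwise
   `w · exp(-(ΔI)^2 / σ_I^2)` potentials, solved by mean-field iteration,
   snaps label boundaries to intensity edges.
4. **Evaluation.** Accuracy, precision, recall, F1, IoU and DSC per class
   and macro-averaged, with `DSC = 2·IoU / (1 + IoU)` holding exactly.

## Worked example

```r
library(cardioseg)

spec <- phantomSpec(seed = 3)       # a synthetic cine study
cine <- generatePhantom(spec)
roi  <- detectROI(cine)
roi
#> ROIResult: centre (82.0, 133.0), radius 12.0 px, 31 votes
#>   crop window: 128 x 128 at origin (18, 69)
spec@aortaCenter                    # ground truth: (82.28, 133.10)
```

The detector recovers the aortic centre to sub-pixel accuracy. Continuing
with CRF refinement of a deliberately boundary-corrupted probability map:

```r
crop <- cropAndNormalize(cine, roi)
ref  <- masks(crop)[, , 1]
probs   <- perturbMaskProbs(ref, flipRate = 0.3, confidence = 0.7, seed = 9)
refined <- crfRefine(probs, frames(crop)[, , 1], crfConfig(pairwiseWeight = 2))
rbind(argmax  = computeMetrics(confusionCounts(probsToMask(probs), ref))[5, -1],
      refined = computeMetrics(confusionCounts(refined, ref))[5, -1])
#>            acc    pre     re     f1    iou    dsc
#> argmax  0.9992 0.9958 0.9917 0.9937 0.9875 0.9937
#> refined 1.0000 0.9998 1.0000 0.9999 0.9998 0.9999
```

The macro rows show the six metrics over the three foreground structures:
the CRF repairs essentially all the injected boundary noise.

Training the network end to end on phantom crops (a few minutes on one
CPU core):

```r
run <- standardSmallRun(seed = 1)   # 80 train / 20 val crops, 12 epochs
run$valDSC
#> 0.9924019
```

`demoRun(seed = 0)` wraps the whole flow — generate, train, segment,
refine, evaluate — and writes a Markdown summary; a command-line front
end with `phantom`, `roi`, `train`, `predict`, `refine`, `eval` and
`demo` subcommands is installed at `inst/scripts/cardioseg`.

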