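# irseg

Segmentation of small, low-contrast moving targets in mid-infrared
monitoring video — the all-weather imaging used for long-range outdoor
surveillance of open terrain, where a grazing flock or a few people cover
only tens of pixels per frame and *dwell* in place for long stretches.

Classic per-pixel Gaussian-mixture background subtraction fails in exactly
this regime: a dwelling target's interior intensity is slowly absorbed into
the background model, carving false-negative cavities ("stay-holes") into
the detections. `irseg` implements a hybrid method that attacks the problem
from both sides:

* **ITF-GMM** — a per-pixel mixture background model whose update is driven
  by image temporal features. Inside a fixed region of interest built from
  early detections, the learning rate follows the structural similarity of
  consecutive frames, `alpha = (1 - SSIM)/80` (near-identical frames freeze
  the model, so dwelling targets stop being absorbed), and each pixel's
  component count tracks the surviving peaks of a rolling 256-bin temporal
  intensity histogram (peaks closer than 30 bins merge; the count is
  clamped to [1, 5]; outside the ROI it is pinned at 2).
  The underlying mixture follows the standard formulation: match rule
  `|m - mu| <= 2.5 sigma` in `omega/sigma^2` rank order, exponential
  weight/mean/variance updates at rate `alpha`, and background =
  the minimal component prefix whose cumulative weight reaches `T` (0.7).
* **Con-UNet** — a compact encoder–decoder pixel classifier in which every
  2×2 max-pool of the baseline UNet is replaced by a 3×3 stride-2
  reflect-padded convolution, preserving the spatial detail that
  tens-of-pixels targets cannot spare; nearest-×2 + 2×2-conv upsampling,
  skip concatenations, sigmoid output, trained with Adam on binary
  cross-entropy. The network, its gradients and the optimizer are
  implemented directly in R (C++ im2col, BLAS matrix products) and verified
  against finite differences in the test suite.
* **Fusion** — the two binary masks are combined pixelwise (bitwise OR by
  default) and refined morphologically (open 3×3, close 5×5), so the
  network fills the background model's stay-holes while motion evidence
  suppresses appearance hallucinations.
* **Scoring** — precision / accuracy / IOU / recall (micro-averaged over
  frames) plus the no-reference sharpness measures Brenner, Roberts and
  SMD2 with their relative-difference comparison.

Because the kind of data this targets is rarely shareable, the package
ships a seeded synthetic-scene generator (smooth drifting background,
small bright dwelling targets, optional flock clustering and oscillating
clutter, Gaussian sensor noise) with exact ground-truth masks, including a
packaged `stay_hole_benchmark()` on which a plain mixture model demonstrably
loses flock interiors.

## Worked example

The ablation at the heart of the method — plain mixture model, then the
SSIM-scheduled learning rate, then the histogram-driven component counts —
on the packaged stay-hole benchmark:

```r
library(irseg)

bm <- stay_hole_benchmark(seed = 1)   # 320 frames, 120 x 160, 4 dwelling targets
recall_of <- function(run) {
  post <- setdiff(seq_along(run$masks), run$warmup)
  segmentation_metrics(run$masks[post], bm$masks[post])$recall
}
recall_of(itf_gmm(bm$frames, itf_config(adapt_lr = FALSE, adapt_k = FALSE)))
#> [1] 0.7650251
recall_of(itf_gmm(bm$frames, itf_config(adapt_lr = TRUE,  adapt_k = FALSE)))
#> [1] 0.8131835
recall_of(itf_gmm(bm$frames, itf_config(adapt_lr = TRUE,  adapt_k = TRUE)))
#> [1] 0.9547264
```

Each adaptive feature recovers more of the dwelling targets' interiors:
freezing the in-ROI learning rate while the flock dwells slows background
absorption, and adapting the per-pixel component count concentrates weight
in the true background mode so target intensities stay foreground.

Model complexity of the network pair, counted as multiply+add per
multiply-accumulate at the 256×256 network input:

```r
count_flops(unet_reference_spec("unet"))      # max-pooling baseline
#> [1] 61.36686
count_flops(unet_reference_spec("conunet"))   # stride-2 convolutions
#> [1] 64.08477
```

The full pipeline at desk scale — train a scaled Con-UNet on 32 generated
pairs, run ITF-GMM on a stay-hole-regime scene, fuse and score (about
12 minutes on one CPU):

```r
res <- run_e2e_benchmark(seed = 1)
round(unlist(res[c("precision", "iou", "recall")]), 4)
#> precision       iou    recall
#>    0.9125    0.9053    0.9913
```

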