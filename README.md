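# blockcount

Plant counting from dot-annotated field images by **blockwise
classification of count intervals**, with a fully convolutional counter,
redundant-patch decoding, a seeded synthetic-scene generator, and the
standard counting metrics.

## The problem

High-throughput phenotyping of transplanted rice (and similar row crops)
needs per-image plant counts from fixed field cameras. The cheapest usable
supervision is a dot per plant root. The standard route — smooth the dots
into a density map and regress it — struggles with the extreme imbalance
of local counts: most patches contain nothing, a few contain many plants.
This package implements the counting-by-classification alternative for
people who want a self-contained, CPU-scale, fully inspectable
implementation: R users in plant phenotyping, and anyone studying
quantization-based counting itself.

## The method

For an image with dot map $P$:

1. **Density**: $D_i = \sum_{p\in P}\mathcal N(i; p, \sigma^2)$ with
   $\sigma = 4$ px, per-dot truncated and renormalized so
   $\sum_i D_i = |P|$ exactly.
2. **Counts**: $N(b_j) = \sum_{k\in b_j} D_k$ over 32×32 patches at
   stride 8 (overlapping, "redundant").
3. **Classes**: $C(b_j) = 0$ if $N = 0$, else
   $\max(\lfloor(\ln N - q)/s\rfloor + 2, 1)$ capped at $c_{\max}$, with
   $s = 0.1$, $q = -2$ (natural log). A CNN — staged backbone tapped at
   strides 8/16/32, multilayer fusion down to stride 8, average-pooling
   head — predicts $C$ for every patch with cross-entropy; an $\ell_1$
   count-regression head is included as the ablation baseline.
4. **Decode**: class → interval midpoint
   ($N_t(C)=e^{q+(C-2)s}$, 0 for $C\le1$); overlapping patch counts are
   spread per-pixel and averaged by coverage $T(x,y)$ (*deredundancy*);
   the image count is the sum of the decoded pixel map. The roundtrip
   decode error is bounded by $(e^{s}-1)/2 \approx 5.26\%$ per patch.

The network layers and backpropagation are implemented directly on base R
matrix algebra (im2col + BLAS); no deep-learning framework is required.

## Worked example

Encode a synthetic scene and decode it back:

```r
library(blockcount)
sc <- render_scene(scene_spec(size = 256, n_plants = 50,
                              plant_radius = c(6, 14),
                              border_margin = 52, seed = 11))
qs <- quantizer_spec(s = 0.1, q = -2, c_max = 60)
enc <- encode_image(sc$annotation, c(256, 256), spec = qs)
sum(enc$density)
#> [1] 50
enc$counts
#> Count map: 29 x 29 patches (block 32, stride 8) over a 256 x 256 image; sum = 800.0000
```

The density map integrates to the plant count exactly, and the overlapping
count map holds 16× the total (each interior pixel is covered by 16
patches). Rig a model to emit the ground-truth class map and the decode
path recovers the count to within the quantization bound:

```r
rig <- rigged_counter(function(img)
  encode_image(sc$annotation, dim(img)[1:2], spec = qs)$classes$values,
  quantizer = qs)
predict(rig, sc$image)
#> Prediction 'image': total count 50.48 (50) over a 256 x 256 pixel map
```

Train the two learning targets under identical conditions and compare:

```r
bench <- synthetic_benchmark(seed = 1)   # ~4 min on one CPU
bench$classification$metrics
#> Counting metrics over 16 image(s):
#>   MAE     1.700
#>   RMSE    2.150
#>   rMAE    4.947 %
#>   R2     0.9834
bench$regression$metrics
#> Counting metrics over 16 image(s):
#>   MAE     5.300
#>   RMSE    6.194
#>   rMAE   18.458 %
#>   R2     0.9339
```

On 16 held-out scenes the count-interval classifier reaches ~5% relative
error; the same network trained as an $\ell_1$ count regressor is several
times worse — the scaled-down analogue of the classification-vs-regression
comparison this method is built on.

A thin command-line wrapper covers the same pipeline from a shell
(`inst/cli/blockcount.R`): `synth`, `encode`, `train`, `infer`, `eval`.

## Package layout

* `R/codec.R` — dots → density → counts → classes and back (the learning
  target mathematics)
* `R/nn.R`, `R/network.R` — layers with backprop; backbone, fusion,
  redundant head
* `R/training.R`, `R/benchmark.R` — `blockcount()` fitting function,
  losses, scaled benchmark
* `R/inference.R`, `R/evaluation.R` — whole-image prediction and metrics
* `R/synthetic.R` — seeded paddy-scene generator
* `vignettes/blockwise-counting.Rmd` — model details, design decisions,
  limitations
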