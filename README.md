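# dkmseg

Tissue-class segmentation of 2-D grayscale brain-MRI slices by k-means
clustering with **density-based initialization**, alongside the two
baselines it is meant to be compared against: traditionally
(randomly) initialized k-means and flat-kernel mean-shift mode seeking.
Because clinical scans usually come without per-pixel ground truth, the
package also ships a **synthetic brain-phantom generator** with known
labels and an **error-rate evaluator** with optimal label matching, so
the three-way comparison can be run end to end on verifiable data.

It is aimed at image-analysis researchers who want a small, fully
reproducible harness for studying how the choice of initial cluster
centers affects intensity-based MRI segmentation.

## The method

A grayscale slice is flattened into a dataset `Y = {x_1, …, x_n}` of
pixel intensities (optionally augmented with scaled pixel coordinates).
k-means partitions `Y` into `K` classes — for a brain MR slice typically
background, soft tissue, fat and bone — by minimizing the within-cluster
objective

```
H = Σ_h Σ_{i ∈ c_h} d(x_i, c_h),      d = squared Euclidean distance,
```

via Lloyd's iteration: assign every pixel to its nearest center, move
each center `c_h` to the mean of its members `c_h = (1/n_h) Σ x_i^h`,
repeat. `H` never increases, but the final partition depends strongly on
the initial centers; random initialization can start two centers inside
one tissue class and merge two others.

The density-based initialization instead picks the `K` initial centers
as *data objects of high local density, far from denser points*
(a density-peaks criterion): each point's density is the number of
points within a radius `r` of it (cut-off kernel; `r` defaults to the
2% quantile of the positive pairwise distances), its separation is the
distance to the nearest strictly denser point, and the `K` points with
the largest `density × separation` products become the initial centers.
For quantized intensities the computation collapses duplicate values
onto the intensity histogram, which makes it exact and fast even for
512 × 512 slices. The selection is fully deterministic.

Mean shift is provided as the standard nonparametric comparator: every
intensity value climbs to the mode of the flat-kernel density estimate
(bandwidth defaults to 15% of the intensity range), and pixels inherit
the mode their value converged to.

Segmentation quality is the **error rate**: the fraction of pixels whose
predicted label disagrees with the ground truth *after* the
prediction-to-truth label mapping that maximizes agreement (an exact
solution of the assignment problem; surplus prediction labels map
many-to-one by majority).

## Worked example

```r
library(dkmseg)

ph <- generatePhantom(PhantomSpec(256L, noiseSigma = 0.08, seed = 7L))
ph
#> Phantom
#>   GrayImage 256 x 256 (8-bit source), range [0, 1]
#>   LabelImage 256 x 256, 4 labels: {0, 1, 2, 3}
#>   PhantomSpec 256x256, K=4, layout=concentric, noise=0.08, bias=0, seed=7
#>     means:      0.05 0.35 0.65 0.95
#>     fractions:  0.40 0.25 0.20 0.15

seg <- segmentImage(phantomImage(ph), method = "kmeans-density", k = 4)
seg$model
#> ClusterModel K=4, n=65536, 4 iteration(s), converged, H=277.62
round(sort(centers(seg$model)[, 1]), 3)
#> [1] 0.060 0.347 0.644 0.935

evaluateSegmentation(seg$labels, truthLabels(ph),
                     phantomId = "demo", method = "kmeans-density")
#> EvalReport [demo | kmeans-density] error rate 0.0458 (4.6%), runtime NA s
```

The phantom has four tissue classes with intensity means 0.05 / 0.35 /
0.65 / 0.95 blurred by Gaussian noise (sd 0.08). Density-initialized
k-means converges in 4 iterations to centers close to the class means
and misclassifies 4.6% of pixels, almost all of them in the overlap of
neighboring class histograms.

The three-way comparison over a reproducible phantom suite:

```r
cmp <- runComparison(phantomSuite("noisy_comparison"), k = 4, seed = 1)
round(100 * cmp$meanErrorRates, 2)
#>         kmeans kmeans-density      meanshift
#>           4.41           4.38           4.99
```

## Command line

```sh
inst/cli/dkmseg phantom --preset paper_comparison --out phantoms/
inst/cli/dkmseg segment --method kmeans-density --k 4 \
    --input scan.png --output scan_labels.png
inst/cli/dkmseg eval --pred scan_labels.png --truth truth.png
inst/cli/dkmseg compare --preset noisy_comparison --k 4 --seed 1 \
    --out report.json --csv report.csv
```

All randomness flows from `--seed`; seeded runs are bit-reproducible.

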