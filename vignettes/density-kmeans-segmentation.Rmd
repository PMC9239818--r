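---
title: "Density-initialized k-means segmentation of brain MRI: methods and design"
author: "dkmseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-initialized k-means segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkmseg)
```

## The problem

Intensity-based tissue segmentation of a 2-D brain MR slice is a
clustering problem: the `n` pixel intensities are partitioned into `K`
classes (background, soft tissue, fat, bone being the canonical four),
and each pixel inherits the label of its cluster. k-means solves this by
minimizing the within-cluster objective

$$H \;=\; \sum_{h=1}^{K} \sum_{i \in c_h} d(x_i, c_h),$$

with $d$ the squared Euclidean distance, by Lloyd's alternation of
nearest-center assignment and per-cluster mean update. Lloyd's iteration
descends on $H$ but converges only to a local optimum determined by the
initial centers. This package studies one remedy — choosing initial
centers as *data objects of high local density* — against the two usual
baselines, random initialization and mean shift.

## The clustering core

* **Metric.** $H$ uses squared Euclidean distance by default because the
  mean update $c_h = \frac{1}{n_h}\sum_i x_i^h$ is the exact minimizer
  of the squared form only; plain Euclidean is available for reporting.
* **Convergence.** Iteration stops when the assignment reaches a fixed
  point, when the absolute decrease of $H$ falls to `tol` (default
  `1e-6`), or at `maxIter` (default 100). The trace of $H$ recorded
  after every assignment step is non-increasing by construction and is
  asserted on every run in the test suite.
* **Empty clusters.** A cluster that loses all members is re-seeded at
  the point farthest from its assigned center. `K` is never silently
  reduced — for a tissue-class model, losing a class is a wrong answer,
  not a convenience.
* **Tie-breaking.** Every arg-min (assignment, peak ranking, mode
  merging) resolves ties toward the lowest index. This is what makes
  whole runs bit-reproducible.
* **Feature space.** Intensity-only by default, matching the objective
  above literally. `spatialWeight > 0` appends scaled `(row, col)`
  coordinates for users who want position information in the features;
  it is off by default so the three methods compare on the same footing.

## Density-peaks initialization

"High local density" needs an estimator; we use the minimal one that
satisfies both requirements of the idea — centers in dense regions, and
never two centers in the *same* dense region:

* density of point $i$ = number of points within radius $r$ of it
  (cut-off kernel, self included; a Gaussian kernel is available),
* separation of point $i$ = distance to the nearest *strictly denser*
  point (the densest point takes the maximum pairwise distance),
* the `K` points with the largest density × separation products become
  the centers, skipping candidates within $r$ of an already chosen one
  unless `K` forces otherwise.

The radius defaults to the 2% quantile of the **positive** pairwise
distances. Quantized images concentrate a large share of pairs at
distance exactly zero, so a quantile over all pairs would collapse to
zero there; restricting to positive distances keeps the radius strictly
positive for any non-degenerate data, and for continuous data the two
definitions coincide. All points identical falls back to an epsilon of
`1e-6`. The quantile is computed exactly (duplicate-collapsed) up to 512
unique values and otherwise estimated from a fixed-seed subsample of
2000 points, which stays within a few percent of the exact value.

Two numerical details matter. First, duplicate feature values are
collapsed to unique values with multiplicity weights before the
pairwise pass — for 8-bit intensities that is at most 256 unique values
regardless of image size, which is why initialization costs essentially
nothing on a 512 × 512 slice, and the collapse is *exact*, not an
approximation (the suite checks it against the direct per-pixel
computation). Second, pairwise distances are computed in the direct
$|x_i-x_j|$ form rather than the faster cross-product identity: the
radius routinely falls exactly on an observed distance, where a one-ulp
error flips neighborhood counts.

## Mean-shift baseline

Flat (uniform) kernel; seeds are the unique intensity values, iterated
with multiplicity weights until the displacement drops below
`1e-4 × bandwidth` or 300 iterations; converged positions within
`bandwidth/2` of an earlier mode merge into it, in index order. The
bandwidth defaults to 15% of the intensity range — a documented
constant, not an estimate; it yields one mode per tissue class on the
default four-class phantoms. Mode count is checked to be non-increasing
in bandwidth over a sweep. Mean shift finds its own number of modes, so
for error-rate comparison surplus modes are allowed to map many-to-one
onto truth classes by the same matching used for k-means; without that
the comparison would be ill-defined.

## Error rate and label matching

Cluster indices are arbitrary, so the error rate is computed after the
prediction-to-truth label mapping that maximizes agreement: an exact
solution of the assignment problem on the contingency table, injective
when the prediction has at most as many labels as the truth, by
exhaustive enumeration over injective maps (exact and instant for the
K ≤ 8 this tool operates in). When the prediction has more labels,
majority mapping per prediction label is optimal under the many-to-one
relaxation and is used instead. A majority-vote mapping is also
available explicitly as a cheaper alternative. Runtimes are recorded
around the segmentation call only and are never asserted — they depend
on hardware and are reported for orientation.

## The phantom generator

Clinical scans come without per-pixel truth, so the package generates
its own: four tissue classes with intensity means 0.05 / 0.35 / 0.65 /
0.95 and area fractions 0.40 / 0.25 / 0.20 / 0.15 (background largest,
innermost class smallest), laid out either as nested rings around the
image center (`concentric`, brain-like) or as random smoothed regions
(`blobs`, thresholded from a seeded sum of low-frequency cosine waves).
Class areas are cut at quantiles of the layout field, so empirical
fractions match the request to within a pixel. On top of the class
means: an optional multiplicative low-order cosine bias field
(peak-to-peak `biasAmplitude`, default 0 — inhomogeneity is not part of
the baseline study conditions), additive Gaussian noise of sd
`noiseSigma`, clipping to [0, 1], and quantization to the 8-bit grid
`round(255x)/255`. The quantization mirrors the PNG-derived slices the
tool ingests and is what makes the histogram collapse in the
initialization exact. One seeded generator per phantom; the seed is
recorded in the spec.

Intensities are processed in normalized [0, 1] throughout (files are
scaled by their container bit-depth maximum on read, never min-max), so
`noiseSigma`, `densityRadius` and `bandwidth` mean the same thing for
8- and 16-bit inputs.

**Study conditions.** The `paper_comparison` preset fixes two 256 × 256
and two 512 × 512 phantoms (noise sd 0.05) — the image sizes of the
runtime comparison. The `noisy_comparison` preset fixes twenty 128 × 128
phantoms at noise sd 0.08: with adjacent class means 0.30 apart that
puts the half-gap at about 1.9 sd, so neighboring class histograms
overlap visibly and no method can be exact. The 128 × 128 size keeps the
twenty-phantom, three-method comparison cheap while leaving more than
2,400 pixels in the smallest class. Both presets use fixed per-phantom
seeds, so they are reproducible across machines.

## What the synthetic comparison shows — and what it does not

On zero-noise phantoms every class is a single intensity value, so a
correct `K`-cluster segmentation must reach error 0; both
density-initialized k-means and mean shift do, and this is used as an
end-to-end oracle. On the noisy suite the comparison reproduces the
expected *ordering* — density initialization no worse on average than
random initialization, with mean shift bracketed by the k-means
variants — as a statistical property. The absolute error rates on
phantoms (about 4–5%) are not comparable to error rates on clinical
scans, where partial-volume effects, field inhomogeneity and anatomy
make classes far less separable; with 1-D well-separated intensities
and tens of thousands of pixels, random initialization also recovers
far more often than folklore suggests, which is why the margin between
the two initializations is small here. The phantoms model none of:
partial-volume mixing, 3-D structure, spatially correlated noise, or
BOLD time series. Passing the suite therefore validates the
*algorithms and their implementation*, not clinical performance.

## Degenerate inputs and numerical choices

* Constant images: mean shift returns one mode; `autoRadius` and
  `autoBandwidth` fall back to epsilons; k-means with `K > 1` relies on
  the empty-cluster policy.
* `K` larger than the number of distinct values is rejected up front.
* Assignment ties, equal density peaks and coincident modes all resolve
  to the lowest index; two runs of any seeded pipeline are
  byte-identical (asserted in the suite by hashing CLI outputs).
* `tol` is absolute, not relative: at image scale ($H \sim 10^2$) the
  default `1e-6` effectively means "run to the assignment fixed point",
  which it almost always reaches in well under the 100-iteration cap.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated
data: 200 random Lloyd-descent instances (n ≤ 500, K ≤ 6), exact-DP
cross-checks on 1-D datasets with n ≤ 12, one zero-noise 256 × 256
recovery per method, the 20-phantom 128 × 128 noisy comparison, 500
label-matching instances against the exhaustive permutation optimum,
100 density-oracle instances, and mean-shift mode checks against a
dense-grid KDE search. These sizes were chosen so the whole suite runs
in well under a minute on one core while still exercising every code
path at meaningful scale.
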