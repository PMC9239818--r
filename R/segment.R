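## End-user segmentation entry point shared by the R API and the CLI.

#' Segment a grayscale image
#'
#' Flattens the image into a feature dataset (intensity-only by default,
#' optionally with scaled spatial coordinates), runs the requested
#' method, and maps the per-pixel assignment back into a label image.
#'
#' @param image a [GrayImage-class] (or numeric matrix in \[0, 1\]).
#' @param method `"kmeans"` (initialization set by `init`),
#'   `"kmeans-density"` (density-peaks initialization), or
#'   `"meanshift"`.
#' @param k number of clusters for the k-means variants.
#' @param init for `method = "kmeans"`: `"density"` or `"random"`.
#' @param densityRadius density radius, or `NULL`/`"auto"` for
#'   [autoRadius()].
#' @param bandwidth mean-shift bandwidth, or `NULL`/`"auto"` for
#'   [autoBandwidth()].
#' @param spatialWeight weight of appended spatial coordinates
#'   (default 0: intensity-only, see [asDataset()]).
#' @param maxIter,tol Lloyd iteration controls.
#' @param seed seed for random initialization (the only randomness; all
#'   other paths are deterministic).
#' @return list with `labels` (a [LabelImage-class]) and `model` (a
#'   [ClusterModel-class] or [MeanShiftResult-class]).
#' @export
segmentImage <- function(image, method = c("kmeans", "kmeans-density",
                                           "meanshift"),
                         k = 4L, init = c("density", "random"),
                         densityRadius = NULL, bandwidth = NULL,
                         spatialWeight = 0, maxIter = 100L, tol = 1e-6,
                         seed = 1L) {
  method <- match.arg(method)
  init <- match.arg(init)
  if (method != "meanshift") {
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop("invalid parameter k: must be >= 1")
  }
  if (identical(densityRadius, "auto")) densityRadius <- NULL
  if (identical(bandwidth, "auto")) bandwidth <- NULL
  X <- asDataset(image, spatialWeight = spatialWeight)
  shape <- attr(X, "imageShape")
  if (method == "meanshift") {
    model <- meanShiftSegment(X, bandwidth = bandwidth)
  } else {
    useDensity <- method == "kmeans-density" || init == "density"
    initC <- if (useDensity)
      selectInitialCenters(X, k, radius = densityRadius)
    else
      randomInitialCenters(X, k, seed = seed)
    model <- runKmeans(X, initC, maxIter = maxIter, tol = tol)
  }
  list(labels = labelsFromAssignment(clusterAssignment(model), shape),
       model = model)
}
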