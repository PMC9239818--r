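#' @import methods
NULL

## Central data objects. Rasters follow the (row, col) convention, 0-based
## labels, row-major flattening when converted to a feature dataset; the
## label/pixel correspondence of every downstream report depends on it.

#' GrayImage: a 2-D raster of normalized intensities
#'
#' A matrix subclass holding a single-channel image with all values in
#' \[0, 1\]. Images read from 8- or 16-bit containers are normalized by the
#' container bit-depth maximum (e.g. 8-bit / 255), never by per-image
#' min-max, so noise levels and kernel bandwidths keep their meaning
#' across images.
#'
#' @slot .Data numeric matrix (height x width) of intensities in \[0, 1\].
#' @slot bitDepth integer; bit depth of the source container (8 or 16).
#' @export
setClass("GrayImage",
  contains = "matrix",
  representation(bitDepth = "integer"),
  prototype(bitDepth = 8L)
)

setValidity("GrayImage", function(object) {
  px <- object@.Data
  if (length(px) == 0L || any(dim(px) < 1L))
    return("image must have positive dimensions")
  if (!is.numeric(px) || anyNA(px) || any(!is.finite(px)))
    return("pixel values must be finite numbers")
  if (min(px) < 0 || max(px) > 1)
    return("pixel values must lie in [0, 1]")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  TRUE
})

#' LabelImage: a per-pixel integer class map
#'
#' A matrix subclass holding nonnegative integer labels (prediction or
#' ground truth), 0-based.
#'
#' @slot .Data integer matrix of labels, all >= 0.
#' @export
setClass("LabelImage", contains = "matrix")

setValidity("LabelImage", function(object) {
  lb <- object@.Data
  if (length(lb) == 0L || any(dim(lb) < 1L))
    return("label image must have positive dimensions")
  if (!is.integer(lb) || anyNA(lb))
    return("labels must be integers with no NA")
  if (min(lb) < 0L)
    return("labels must be nonnegative")
  TRUE
})

#' PhantomSpec: parameters of a synthetic brain phantom
#'
#' Describes a synthetic grayscale image with known per-pixel tissue
#' classes: geometry, per-class intensity means and area fractions,
#' additive Gaussian noise, an optional multiplicative low-frequency bias
#' field, and the RNG seed, which is recorded for provenance.
#'
#' @slot width,height image size in pixels.
#' @slot nClasses number of tissue classes K (including background).
#' @slot classMeans K intensity means in \[0, 1\], strictly increasing.
#' @slot classFractions K area fractions, all > 0, summing to 1.
#' @slot noiseSigma additive Gaussian noise sd, intensity units, >= 0.
#' @slot biasAmplitude peak-to-peak multiplicative bias-field amplitude
#'   (0 disables the bias field).
#' @slot layout `"concentric"` (classes nested as rings around the image
#'   center, brain-like) or `"blobs"` (random smoothed regions).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(
    width = "integer", height = "integer", nClasses = "integer",
    classMeans = "numeric", classFractions = "numeric",
    noiseSigma = "numeric", biasAmplitude = "numeric",
    layout = "character", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (object@width < 1L || object@height < 1L)
    return("width and height must be positive")
  K <- object@nClasses
  if (K < 2L)
    return("n_classes must be >= 2")
  if (length(object@classMeans) != K)
    return("class_means must have length n_classes")
  if (any(diff(object@classMeans) <= 0))
    return("class_means must be strictly increasing")
  if (min(object@classMeans) < 0 || max(object@classMeans) > 1)
    return("class_means must lie in [0, 1]")
  if (length(object@classFractions) != K)
    return("class_fractions must have length n_classes")
  if (any(object@classFractions <= 0))
    return("class_fractions must all be > 0")
  if (abs(sum(object@classFractions) - 1) > 1e-9)
    return("class_fractions must sum to 1 (tolerance 1e-9)")
  if (object@noiseSigma < 0)
    return("noise_sigma must be >= 0")
  if (object@biasAmplitude < 0)
    return("bias_amplitude must be >= 0")
  if (!object@layout %in% c("concentric", "blobs"))
    return("layout must be 'concentric' or 'blobs'")
  TRUE
})

#' Phantom: a synthetic image together with its ground truth
#'
#' @slot image a [GrayImage-class].
#' @slot truth a [LabelImage-class] of the same dimensions.
#' @slot spec the [PhantomSpec-class] that generated it.
#' @export
setClass("Phantom",
  representation(image = "GrayImage", truth = "LabelImage",
                 spec = "PhantomSpec")
)

setValidity("Phantom", function(object) {
  if (!identical(dim(object@image@.Data), dim(object@truth@.Data)))
    return("image and truth must have identical dimensions")
  TRUE
})

#' ClusterModel: the result of a k-means run
#'
#' Holds the K cluster centers, the per-point assignment, the per-iteration
#' trace of the within-cluster objective H, cluster sizes, and convergence
#' information. The objective trace is non-increasing (Lloyd descent).
#'
#' @slot centers K x d numeric matrix of cluster centers.
#' @slot assignment integer vector, per-point cluster index in 1..K.
#' @slot objectiveTrace numeric; H after each iteration's assignment step.
#' @slot nPerCluster integer vector of cluster sizes, summing to n.
#' @slot converged logical flag.
#' @slot iterations iteration count.
#' @slot metric distance metric used ("sqeuclidean" or "euclidean").
#' @export
setClass("ClusterModel",
  representation(
    centers = "matrix", assignment = "integer",
    objectiveTrace = "numeric", nPerCluster = "integer",
    converged = "logical", iterations = "integer", metric = "character"
  )
)

setValidity("ClusterModel", function(object) {
  K <- nrow(object@centers)
  if (K < 1L) return("at least one center required")
  if (length(object@assignment) &&
      (min(object@assignment) < 1L || max(object@assignment) > K))
    return("assignment indices must lie in 1..K")
  if (sum(object@nPerCluster) != length(object@assignment))
    return("n_per_cluster must sum to n")
  tr <- object@objectiveTrace
  if (length(tr) > 1L && any(diff(tr) > 1e-8 * max(1, tr[1L])))
    return("objective trace must be non-increasing")
  TRUE
})

#' MeanShiftResult: modes and assignment from mean-shift segmentation
#'
#' @slot modes m x d numeric matrix of converged mode positions.
#' @slot assignment integer vector, per-point mode index in 1..m.
#' @slot bandwidth flat-kernel bandwidth used.
#' @slot iterations integer vector of per-seed convergence counts.
#' @export
setClass("MeanShiftResult",
  representation(modes = "matrix", assignment = "integer",
                 bandwidth = "numeric", iterations = "integer")
)

setValidity("MeanShiftResult", function(object) {
  if (nrow(object@modes) < 1L) return("at least one mode required")
  if (length(object@assignment) &&
      max(object@assignment) > nrow(object@modes))
    return("assignment indices must not exceed the number of modes")
  if (object@bandwidth <= 0) return("bandwidth must be positive")
  TRUE
})

#' EvalReport: error rate, matching and runtime for one segmentation
#'
#' @slot phantomId identifier of the evaluated image.
#' @slot method method label ("kmeans", "kmeans-density", "meanshift").
#' @slot params named list of method parameters.
#' @slot errorRate fraction in \[0, 1\] of pixels misclassified after
#'   optimal prediction-to-truth label matching.
#' @slot matching integer vector mapping prediction labels (names, 0-based)
#'   to truth labels (values, 0-based).
#' @slot confusion contingency table, truth x prediction, entries sum to n.
#' @slot runtimeSeconds wall-clock seconds of the segmentation call only
#'   (informational; hardware-dependent, never asserted).
#' @slot seed seed used by the method (NA when the method uses none).
#' @export
setClass("EvalReport",
  representation(
    phantomId = "character", method = "character", params = "list",
    errorRate = "numeric", matching = "integer", confusion = "matrix",
    runtimeSeconds = "numeric", seed = "integer"
  )
)

setValidity("EvalReport", function(object) {
  if (object@errorRate < 0 || object@errorRate > 1)
    return("error rate must lie in [0, 1]")
  TRUE
})

## show methods ------------------------------------------------------------

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@.Data)
  cat(sprintf("GrayImage %d x %d (%d-bit source), range [%.4g, %.4g]\n",
              d[1L], d[2L], object@bitDepth,
              min(object@.Data), max(object@.Data)))
})

setMethod("show", "LabelImage", function(object) {
  d <- dim(object@.Data)
  u <- sort(unique(as.vector(object@.Data)))
  cat(sprintf("LabelImage %d x %d, %d labels: {%s}\n", d[1L], d[2L],
              length(u), paste(utils::head(u, 8L), collapse = ", ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %dx%d, K=%d, layout=%s, noise=%.3g, bias=%.3g, seed=%d\n",
    object@width, object@height, object@nClasses, object@layout,
    object@noiseSigma, object@biasAmplitude, object@seed))
  cat("  means:     ", paste(format(object@classMeans), collapse = " "), "\n")
  cat("  fractions: ", paste(format(object@classFractions), collapse = " "),
      "\n")
})

setMethod("show", "Phantom", function(object) {
  cat("Phantom\n  ")
  show(object@image)
  cat("  ")
  show(object@truth)
  cat("  ")
  show(object@spec)
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf(
    "ClusterModel K=%d, n=%d, %d iteration(s), %sconverged, H=%.6g\n",
    nrow(object@centers), length(object@assignment), object@iterations,
    if (object@converged) "" else "NOT ", utils::tail(object@objectiveTrace, 1L)))
})

setMethod("show", "MeanShiftResult", function(object) {
  cat(sprintf("MeanShiftResult: %d mode(s), bandwidth=%.4g, n=%d\n",
              nrow(object@modes), object@bandwidth,
              length(object@assignment)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport [%s | %s] error rate %.4f (%.1f%%), runtime %.3f s\n",
    object@phantomId, object@method, object@errorRate,
    100 * object@errorRate, object@runtimeSeconds))
})
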