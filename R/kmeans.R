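## k-means machinery: distance, objective H, assignment, center update,
## Lloyd iteration. Independent of how initial centers are chosen.
##
## The objective is H = sum_h sum_{i in c_h} d(x_i, c_h), with d the
## squared Euclidean distance by default (the mean update of the center
## step is only optimal for the squared form); plain Euclidean is
## available for the general form of H.
##
## Tie-breaking everywhere is "lowest index wins", which makes runs
## bit-reproducible.

asFeatureMatrix <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 1L)
  else { m <- as.matrix(x); storage.mode(m) <- "double"; m }
}

#' Distance between two feature vectors
#'
#' @param a,b numeric vectors of equal length.
#' @param metric `"sqeuclidean"` (default) or `"euclidean"`.
#' @return nonnegative scalar.
#' @export
featureDistance <- function(a, b, metric = c("sqeuclidean", "euclidean")) {
  metric <- match.arg(metric)
  if (length(a) != length(b))
    stop("dimension mismatch: ", length(a), " vs ", length(b))
  d2 <- sum((a - b)^2)
  if (metric == "sqeuclidean") d2 else sqrt(d2)
}

# n x K matrix of squared Euclidean distances from rows of X to rows of C.
crossDist2 <- function(X, C) {
  D <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * tcrossprod(X, C)
  D[D < 0] <- 0   # numerical noise
  D
}

#' Assign each point to its nearest center
#'
#' Ties are broken toward the lowest center index, deterministically.
#'
#' @param data n x d feature matrix (or numeric vector for d = 1).
#' @param centers K x d matrix of centers.
#' @param metric distance metric; the arg-min is identical for
#'   `"sqeuclidean"` and `"euclidean"`.
#' @return integer vector of cluster indices in 1..K.
#' @export
assignPoints <- function(data, centers,
                         metric = c("sqeuclidean", "euclidean")) {
  match.arg(metric)
  X <- asFeatureMatrix(data)
  C <- asFeatureMatrix(centers)
  if (nrow(C) < 1L) stop("at least one center is required")
  if (ncol(X) != ncol(C))
    stop("dimension mismatch between data and centers")
  D <- crossDist2(X, C)
  max.col(-D, ties.method = "first")
}

#' Within-cluster objective H
#'
#' `H = sum_h sum_{i in c_h} d(x_i, c_h)`: the sum over clusters of
#' distances between member points and their cluster center. Smaller H
#' means more compact clustering; H = 0 iff every point coincides with
#' its center.
#'
#' @param data n x d feature matrix.
#' @param centers K x d matrix of centers.
#' @param assignment integer vector in 1..K covering all points.
#' @param metric `"sqeuclidean"` (default) or `"euclidean"`.
#' @return nonnegative scalar.
#' @export
computeObjective <- function(data, centers, assignment,
                             metric = c("sqeuclidean", "euclidean")) {
  metric <- match.arg(metric)
  X <- asFeatureMatrix(data)
  C <- asFeatureMatrix(centers)
  assignment <- as.integer(assignment)
  if (length(assignment) != nrow(X))
    stop("assignment must cover all points")
  if (min(assignment) < 1L || max(assignment) > nrow(C))
    stop("assignment indices out of range")
  d2 <- rowSums((X - C[assignment, , drop = FALSE])^2)
  if (metric == "sqeuclidean") sum(d2) else sum(sqrt(d2))
}

#' Recompute centers as per-cluster means
#'
#' Each nonempty cluster's center becomes the arithmetic mean of its
#' members (the H-minimizing update for squared Euclidean distance).
#' An empty cluster is re-seeded at the point with maximal distance to
#' its currently assigned center (farthest-point policy); K is never
#' silently dropped.
#'
#' @param data n x d feature matrix.
#' @param assignment integer vector in 1..K.
#' @param K number of clusters (defaults to `max(assignment)`).
#' @return K x d matrix of updated centers; the `"reassigned"` attribute
#'   carries the assignment after any empty-cluster re-seeding.
#' @export
updateCenters <- function(data, assignment, K = max(assignment)) {
  X <- asFeatureMatrix(data)
  assignment <- as.integer(assignment)
  K <- as.integer(K)
  sums <- rowsum(X, assignment)
  counts <- tabulate(assignment, nbins = K)
  C <- matrix(0, nrow = K, ncol = ncol(X))
  C[as.integer(rownames(sums)), ] <- sums / counts[counts > 0L]
  empty <- which(counts == 0L)
  if (length(empty)) {
    for (k in empty) {
      d2 <- rowSums((X - C[assignment, , drop = FALSE])^2)
      far <- which.max(d2)            # lowest index on ties
      donor <- assignment[far]
      assignment[far] <- k
      # recompute the means of the re-seeded cluster and the donor
      for (kk in c(k, donor)) {
        memb <- assignment == kk
        if (any(memb)) C[kk, ] <- colMeans(X[memb, , drop = FALSE])
      }
    }
  }
  attr(C, "reassigned") <- assignment
  C
}

#' Run Lloyd's k-means from given initial centers
#'
#' Alternates nearest-center assignment and per-cluster mean update until
#' the decrease in H is at most `tol`, the assignment stops changing, or
#' `maxIter` is reached. The objective trace (H after each assignment
#' step) is non-increasing; the run is fully deterministic given the
#' initial centers.
#'
#' @param data n x d feature matrix (or numeric vector for d = 1).
#' @param initCenters K x d matrix (or length-K vector) of initial
#'   centers, 1 <= K <= n.
#' @param maxIter maximum number of iterations (default 100).
#' @param tol absolute tolerance on the decrease of H (default 1e-6).
#' @param metric distance metric for H ("sqeuclidean" default).
#' @return a [ClusterModel-class].
#' @export
runKmeans <- function(data, initCenters, maxIter = 100L, tol = 1e-6,
                      metric = c("sqeuclidean", "euclidean")) {
  metric <- match.arg(metric)
  X <- asFeatureMatrix(data)
  C <- asFeatureMatrix(initCenters)
  n <- nrow(X); K <- nrow(C)
  if (any(!is.finite(X))) stop("non-finite values in data")
  if (K < 1L || K > n) stop("K must satisfy 1 <= K <= n (K=", K,
                            ", n=", n, ")")
  if (tol < 0) stop("tol must be >= 0")
  ## `iter` counts center-update steps; the trace records H after each
  ## assignment step (including the final pass that detects a fixed
  ## point), so its last entry is the H of the returned model.
  trace <- numeric(0)
  assign_prev <- NULL
  assign_cur <- NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    assign_cur <- assignPoints(X, C)
    H <- computeObjective(X, C, assign_cur, metric = metric)
    trace <- c(trace, H)
    if (!is.null(assign_prev) && identical(assign_cur, assign_prev)) {
      converged <- TRUE
      break
    }
    if (length(trace) > 1L &&
        (trace[length(trace) - 1L] - H) <= tol) {
      converged <- TRUE
      break
    }
    if (iter >= maxIter) break
    C <- updateCenters(X, assign_cur, K = K)
    assign_prev <- attr(C, "reassigned")
    iter <- iter + 1L
  }
  new("ClusterModel",
      centers = unname(C[, , drop = FALSE]),
      assignment = as.integer(assign_cur),
      objectiveTrace = trace,
      nPerCluster = tabulate(assign_cur, nbins = K),
      converged = converged,
      iterations = iter,
      metric = metric)
}

#' Sample K distinct data points as random initial centers
#'
#' The traditional initialization: K distinct points (indices) drawn
#' uniformly at random, seeded. Points drawn this way can still carry
#' equal or nearly equal feature values — the known weakness of random
#' initialization that density-based selection avoids.
#'
#' @param data n x d feature matrix.
#' @param K number of centers.
#' @param seed integer RNG seed; the only source of randomness.
#' @return K x d matrix of centers.
#' @export
randomInitialCenters <- function(data, K, seed) {
  X <- asFeatureMatrix(data)
  K <- as.integer(K)
  if (K > nrow(X))
    stop("K exceeds the number of points (", nrow(X), ")")
  idx <- withLocalSeed(as.integer(seed), sample.int(nrow(X), K))
  X[idx, , drop = FALSE]
}

# Run expr under a seed without touching the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Serialize a ClusterModel to a JSON document
#'
#' @param model a [ClusterModel-class].
#' @param path optional output path; when NULL the JSON string is
#'   returned.
#' @export
modelToJSON <- function(model, path = NULL) {
  stopifnot(is(model, "ClusterModel"))
  doc <- list(
    centers = unname(apply(model@centers, 1L, as.numeric,
                           simplify = FALSE)),
    objective_trace = model@objectiveTrace,
    n_per_cluster = model@nPerCluster,
    iterations = model@iterations,
    converged = model@converged,
    metric = model@metric
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
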