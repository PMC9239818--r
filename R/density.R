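## Density-based choice of initial cluster centers.
##
## Local density of a point is the cut-off-kernel count of points within
## a radius of it; each point's separation is its distance to the nearest
## point of strictly higher density (the global density maximum gets the
## maximum pairwise distance). Initial centers are actual data objects
## ranked by the product density x separation, so they sit in dense
## regions AND away from one another — a density-peaks selection. A
## Gaussian kernel is available as an option.
##
## For intensity-only pixel data, duplicate feature values are collapsed
## to unique values with multiplicity weights before the O(u^2) pairwise
## pass. For 8-bit-quantized images u <= 256 whatever the image size,
## which is what makes the selection fast on 512 x 512 slices; the
## collapse is exact, not an approximation (verified against the direct
## per-point computation in the test suite).

# Collapse rows of X to unique rows + weights; map[i] = unique row of i.
collapseWeights <- function(X) {
  if (ncol(X) == 1L) {
    u <- sort(unique(X[, 1L]))
    map <- match(X[, 1L], u)
    list(U = matrix(u, ncol = 1L), w = tabulate(map, length(u)), map = map)
  } else {
    key <- apply(X, 1L, paste, collapse = "\r")
    u <- !duplicated(key)
    U <- X[u, , drop = FALSE]
    map <- match(key, key[u])
    list(U = U, w = tabulate(map, nrow(U)), map = map)
  }
}

#' Local density and separation of every point
#'
#' Computes, on the clustering feature space, each point's local density
#' (number of points within `radius`, cut-off kernel, self included) and
#' its separation: the Euclidean distance to the nearest point of
#' strictly higher density. The density maximum, having no denser
#' neighbor, gets the maximum pairwise distance of the dataset.
#'
#' @param data n x d feature matrix (or numeric vector for d = 1).
#' @param radius neighborhood radius in feature units, > 0.
#' @param kernel `"cutoff"` (default; integer counts) or `"gaussian"`
#'   (`sum exp(-(d/radius)^2)`, a smooth alternative).
#' @return list with per-point numeric vectors `density` and
#'   `separation`, and the `radius` used.
#' @export
localDensity <- function(data, radius, kernel = c("cutoff", "gaussian")) {
  kernel <- match.arg(kernel)
  if (radius <= 0) stop("radius must be > 0")
  X <- asFeatureMatrix(data)
  cw <- collapseWeights(X)
  U <- cw$U; w <- cw$w
  u <- nrow(U)
  if (u == 1L) {
    n <- nrow(X)
    return(list(density = rep(as.numeric(n), n),
                separation = rep(0, n), radius = radius))
  }
  # direct |x_i - x_j| arithmetic: the radius cutoff routinely falls
  # exactly on a pairwise distance for quantized intensities, where the
  # faster cross-product identity is one ulp off
  D <- as.matrix(stats::dist(U))
  dens <- if (kernel == "cutoff") {
    as.vector((D <= radius) %*% w)
  } else {
    as.vector(exp(-(D / radius)^2) %*% w)
  }
  # separation: distance to nearest strictly denser unique value
  sep <- numeric(u)
  maxD <- max(D)
  for (i in seq_len(u)) {
    higher <- dens > dens[i]
    sep[i] <- if (any(higher)) min(D[i, higher]) else maxD
  }
  list(density = dens[cw$map], separation = sep[cw$map], radius = radius)
}

#' Select K initial cluster centers by density peaks
#'
#' Returns K actual data points ranked by the product
#' `density x separation`, descending (ties broken toward the lowest
#' point index). No two returned centers lie within `radius` of each
#' other unless K exceeds the number of separated peaks, in which case
#' the remaining slots are filled by score order. The selection contains
#' no randomness: identical input gives identical centers.
#'
#' @param data n x d feature matrix.
#' @param K number of centers, 1 <= K <= number of distinct points.
#' @param radius density radius; `NULL` (default) uses [autoRadius()].
#' @param kernel density kernel, see [localDensity()].
#' @return K x d matrix of centers (rows are members of the dataset).
#' @export
selectInitialCenters <- function(data, K, radius = NULL,
                                 kernel = c("cutoff", "gaussian")) {
  kernel <- match.arg(kernel)
  X <- asFeatureMatrix(data)
  K <- as.integer(K)
  cw <- collapseWeights(X)
  if (K < 1L || K > nrow(cw$U))
    stop("K must satisfy 1 <= K <= number of distinct points (",
         nrow(cw$U), ")")
  if (is.null(radius)) radius <- autoRadius(X)
  prof <- localDensity(X, radius, kernel = kernel)
  score <- prof$density * prof$separation
  # work on unique points: first occurrence index represents each value
  firstIdx <- which(!duplicated(cw$map))
  firstIdx <- firstIdx[order(cw$map[firstIdx])]
  uScore <- score[firstIdx]
  ord <- order(-uScore, firstIdx)          # ties -> lowest point index
  chosen <- integer(0)
  U <- cw$U
  for (i in ord) {
    if (length(chosen) == K) break
    if (length(chosen)) {
      d2 <- rowSums((U[chosen, , drop = FALSE] -
                     matrix(U[i, ], nrow = length(chosen),
                            ncol = ncol(U), byrow = TRUE))^2)
      if (min(sqrt(d2)) <= radius) next    # too close to a chosen peak
    }
    chosen <- c(chosen, i)
  }
  if (length(chosen) < K) {                # forced: fill by score order
    for (i in ord) {
      if (length(chosen) == K) break
      if (!i %in% chosen) chosen <- c(chosen, i)
    }
  }
  U[chosen, , drop = FALSE]
}

#' Data-driven density radius
#'
#' Returns the 2% quantile (by default) of the positive pairwise
#' Euclidean distances of the dataset. The quantile is exact whenever
#' collapsing duplicates leaves at most `exactLimit` unique values (the
#' usual case for quantized image intensities); otherwise it is
#' estimated from a fixed-seed subsample of the points. Strictly
#' positive for non-degenerate data; when all points are identical a
#' documented epsilon (1e-6) is returned.
#'
#' @param data n x d feature matrix, n >= 2.
#' @param quantile quantile of the positive pairwise-distance
#'   distribution (default 0.02).
#' @param exactLimit maximum number of unique values for the exact
#'   weighted computation (default 512).
#' @param subsample subsample size for the estimate beyond that
#'   (default 2000, fixed internal seed).
#' @return positive scalar radius.
#' @export
autoRadius <- function(data, quantile = 0.02, exactLimit = 512L,
                       subsample = 2000L) {
  X <- asFeatureMatrix(data)
  if (nrow(X) < 2L) stop("need at least 2 points")
  eps <- 1e-6
  cw <- collapseWeights(X)
  if (nrow(cw$U) == 1L) return(eps)
  if (nrow(cw$U) <= exactLimit) {
    # exact weighted quantile over all positive pairs of original points
    D <- sqrt(crossDist2(cw$U, cw$U))
    w <- as.numeric(cw$w)
    W <- outer(w, w)
    keep <- upper.tri(D)
    dv <- D[keep]; wv <- W[keep]
    ord <- order(dv)
    dv <- dv[ord]; wv <- wv[ord]
    pos <- dv > 0
    dv <- dv[pos]; wv <- wv[pos]
    cum <- cumsum(wv) / sum(wv)
    r <- dv[which(cum >= quantile)[1L]]
  } else {
    idx <- withLocalSeed(853707L, sample.int(nrow(X), subsample))
    dv <- as.vector(stats::dist(X[idx, , drop = FALSE]))
    dv <- dv[dv > 0]
    if (!length(dv)) return(eps)
    r <- as.numeric(stats::quantile(dv, quantile, type = 1L))
  }
  max(r, eps)
}

#' Density-initialized k-means (the improved algorithm)
#'
#' Convenience wrapper: choose K initial centers by density peaks, then
#' run Lloyd's iteration from them. Deterministic end to end.
#'
#' @inheritParams runKmeans
#' @inheritParams selectInitialCenters
#' @return a [ClusterModel-class].
#' @export
densityKmeans <- function(data, K, radius = NULL, maxIter = 100L,
                          tol = 1e-6,
                          metric = c("sqeuclidean", "euclidean")) {
  init <- selectInitialCenters(data, K, radius = radius)
  runKmeans(data, init, maxIter = maxIter, tol = tol,
            metric = match.arg(metric))
}
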