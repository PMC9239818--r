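## Flat-kernel mean-shift mode seeking, the comparator algorithm.
##
## Seeds are the unique feature values (for quantized image intensities,
## the nonzero histogram bins), iterated with multiplicity weights:
## m(x) <- weighted mean of points within the bandwidth of x. Converged
## positions within the merge tolerance are merged in index order, which
## makes the result reproducible bit for bit.

#' Mean-shift segmentation
#'
#' Each seed moves to the (multiplicity-weighted) mean of the points
#' within `bandwidth` of it until the displacement falls below
#' `1e-4 * bandwidth` or 300 iterations. Converged positions within
#' `mergeTol` of an earlier mode are merged into it; every point is
#' assigned to the mode its own value converged to.
#'
#' @param data n x d feature matrix (or numeric vector).
#' @param bandwidth flat-kernel radius, > 0; `NULL` uses
#'   [autoBandwidth()].
#' @param mergeTol mode merge tolerance (default `bandwidth / 2`).
#' @param maxIter per-seed iteration cap (default 300).
#' @return a [MeanShiftResult-class].
#' @export
meanShiftSegment <- function(data, bandwidth = NULL, mergeTol = NULL,
                             maxIter = 300L) {
  X <- asFeatureMatrix(data)
  if (is.null(bandwidth)) bandwidth <- autoBandwidth(X)
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(mergeTol)) mergeTol <- bandwidth / 2
  cw <- collapseWeights(X)
  U <- cw$U; w <- as.numeric(cw$w)
  u <- nrow(U)
  tolMove2 <- (1e-4 * bandwidth)^2
  bw2 <- bandwidth^2
  pos <- U
  iters <- integer(u)
  for (s in seq_len(u)) {
    x <- pos[s, ]
    for (it in seq_len(maxIter)) {
      d2 <- rowSums((U - matrix(x, nrow = u, ncol = ncol(U),
                                byrow = TRUE))^2)
      inb <- d2 <= bw2
      m <- colSums(U[inb, , drop = FALSE] * w[inb]) / sum(w[inb])
      moved2 <- sum((m - x)^2)
      x <- m
      if (moved2 < tolMove2) break
    }
    pos[s, ] <- x
    iters[s] <- it
  }
  # merge converged positions in seed-index order
  modeList <- matrix(numeric(0), ncol = ncol(U))
  seedMode <- integer(u)
  for (s in seq_len(u)) {
    if (nrow(modeList)) {
      d2 <- rowSums((modeList - matrix(pos[s, ], nrow = nrow(modeList),
                                       ncol = ncol(U), byrow = TRUE))^2)
      j <- which(d2 <= mergeTol^2)
      if (length(j)) { seedMode[s] <- j[1L]; next }
    }
    modeList <- rbind(modeList, pos[s, ])
    seedMode[s] <- nrow(modeList)
  }
  new("MeanShiftResult",
      modes = unname(modeList),
      assignment = seedMode[cw$map],
      bandwidth = bandwidth,
      iterations = iters)
}

#' Default mean-shift bandwidth
#'
#' 15% of the intensity range of the data (a documented constant,
#' overridable wherever a bandwidth is accepted); for multivariate
#' features, 15% of the largest per-dimension range. Degenerate data
#' (zero range) falls back to an epsilon of 1e-6.
#'
#' @param data n x d feature matrix, n >= 2.
#' @return positive scalar bandwidth.
#' @export
autoBandwidth <- function(data) {
  X <- asFeatureMatrix(data)
  if (nrow(X) < 2L) stop("need at least 2 points")
  rng <- max(apply(X, 2L, function(v) diff(range(v))))
  if (rng <= 0) 1e-6 else 0.15 * rng
}
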