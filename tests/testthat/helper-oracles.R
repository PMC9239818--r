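# Independent oracles, deliberately written as plain brute force /
# dynamic programming so they share no code with the implementation.

# Exact 1-D k-means by dynamic programming over the sorted data:
# optimal within-cluster sum of squares for exactly K contiguous
# segments of the sorted values.
dpKmeans1D <- function(x, K) {
  x <- sort(x)
  n <- length(x)
  s1 <- cumsum(x)
  s2 <- cumsum(x^2)
  sse <- function(i, j) { # SSE of x[i..j]
    s <- s1[j] - if (i > 1) s1[i - 1] else 0
    q <- s2[j] - if (i > 1) s2[i - 1] else 0
    q - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, nrow = K, ncol = n)
  for (j in seq_len(n)) D[1, j] <- sse(1, j)
  if (K > 1) {
    for (k in 2:K) {
      for (j in k:n) {
        best <- Inf
        for (i in k:j) {
          v <- D[k - 1, i - 1] + sse(i, j)
          if (v < best) best <- v
        }
        D[k, j] <- best
      }
    }
  }
  max(D[K, n], 0)
}

# Objective H by an explicit double loop over clusters and members.
bruteObjective <- function(X, C, assignment, metric = "sqeuclidean") {
  X <- as.matrix(X); C <- as.matrix(C)
  H <- 0
  for (h in seq_len(nrow(C))) {
    for (i in which(assignment == h)) {
      d2 <- sum((X[i, ] - C[h, ])^2)
      H <- H + if (metric == "sqeuclidean") d2 else sqrt(d2)
    }
  }
  H
}

# Exhaustive nearest-center search, lowest index on ties.
bruteAssign <- function(X, C) {
  X <- as.matrix(X); C <- as.matrix(C)
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    best <- Inf; bj <- 0L
    for (j in seq_len(nrow(C))) {
      d2 <- sum((X[i, ] - C[j, ])^2)
      if (d2 < best) { best <- d2; bj <- j }
    }
    out[i] <- bj
  }
  out
}

# O(n^2) pairwise cut-off density and separation, per point.
bruteDensity <- function(X, radius) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- unname(as.matrix(stats::dist(X)))
  dens <- rowSums(D <= radius)   # self included (diagonal is 0)
  sep <- numeric(n)
  maxD <- max(D)
  for (i in seq_len(n)) {
    higher <- dens > dens[i]
    sep[i] <- if (any(higher)) min(D[i, higher]) else maxD
  }
  list(density = dens, separation = sep)
}

# Maximum agreement over every permutation of truth labels.
bruteBestAgreement <- function(pred, truth) {
  pv <- as.vector(pred); tv <- as.vector(truth)
  pl <- sort(unique(pv)); tl <- sort(unique(tv))
  stopifnot(length(pl) <= length(tl))
  idx <- seq_along(tl)
  perms <- matrix(idx, nrow = 1)
  if (length(tl) > 1) {
    perms <- as.matrix(expand.grid(rep(list(idx), length(tl))))
    perms <- perms[apply(perms, 1, function(r) !anyDuplicated(r)), ,
                   drop = FALSE]
  }
  best <- -1L
  for (r in seq_len(nrow(perms))) {
    map <- tl[perms[r, seq_along(pl)]]
    best <- max(best, sum(map[match(pv, pl)] == tv))
  }
  best
}

# Flat-kernel KDE local maxima by dense grid search; plateaus (the KDE
# is piecewise constant) are reduced to their midpoints.
gridKdeModes <- function(x, bandwidth, step = 1e-4) {
  grid <- seq(min(x) - bandwidth, max(x) + bandwidth, by = step)
  dens <- vapply(grid, function(g) sum(abs(x - g) <= bandwidth),
                 numeric(1))
  r <- rle(dens)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mids <- numeric(0)
  for (p in seq_along(r$values)) {
    leftOK <- p == 1 || r$values[p - 1] < r$values[p]
    rightOK <- p == length(r$values) || r$values[p + 1] < r$values[p]
    if (leftOK && rightOK)
      mids <- c(mids, (grid[starts[p]] + grid[ends[p]]) / 2)
  }
  mids
}

# Symmetric 1-D mixture: blobs of points laid out symmetrically around
# their centers, so blob centers are exact flat-kernel fixed points.
symmetricMixture <- function(centers, halfwidth = 0.01, m = 10L) {
  offs <- seq(-halfwidth, halfwidth, length.out = 2L * m + 1L)
  as.vector(outer(offs, centers, `+`))
}

makePhantom <- function(size = 64L, noise = 0, seed = 1L, ...) {
  generatePhantom(PhantomSpec(size, noiseSigma = noise, seed = seed, ...))
}
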