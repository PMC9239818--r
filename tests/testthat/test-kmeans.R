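test_that("featureDistance matches closed forms and rejects mismatch", {
  expect_identical(featureDistance(0, 0), 0)
  expect_identical(featureDistance(0, 3), 9)
  expect_identical(featureDistance(c(1, 2), c(4, 6)), 25)
  expect_identical(featureDistance(c(1, 2), c(4, 6), "euclidean"), 5)
  expect_equal(featureDistance(c(1, 2), c(4, 6)),
               featureDistance(c(4, 6), c(1, 2)))
  expect_error(featureDistance(1, c(1, 2)), "dimension mismatch")
})

test_that("computeObjective matches hand values and a brute-force double loop", {
  expect_identical(computeObjective(5, matrix(5), 1L), 0)
  expect_identical(computeObjective(c(0, 2), matrix(1), c(1L, 1L)), 2)
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rnorm(40), ncol = 2)
    C <- matrix(rnorm(6), ncol = 2)
    a <- sample(1:3, 20, replace = TRUE)
    for (metric in c("sqeuclidean", "euclidean")) {
      expect_equal(computeObjective(X, C, a, metric = metric),
                   bruteObjective(X, C, a, metric = metric),
                   tolerance = 1e-12)
    }
  }
  expect_error(computeObjective(c(0, 2), matrix(1), 1L), "cover all")
})

test_that("assignPoints picks the nearest center, lowest index on ties", {
  expect_identical(assignPoints(0.9, matrix(c(0, 1))), 2L)
  expect_identical(assignPoints(0.5, matrix(c(0, 1))), 1L)  # exact tie
  set.seed(12)
  X <- matrix(runif(200), ncol = 2)
  C <- matrix(runif(8), ncol = 2)
  expect_identical(assignPoints(X, C), bruteAssign(X, C))
  expect_error(assignPoints(X, matrix(numeric(0), ncol = 2)),
               "at least one center")
})

test_that("updateCenters takes per-cluster means and re-seeds empty clusters", {
  C <- updateCenters(c(1, 3), c(1L, 1L))
  expect_equal(C[1, 1], 2)
  expect_equal(updateCenters(7, 1L)[1, 1], 7)
  # cluster 2 empty: re-seeded at the point farthest from its center
  C <- updateCenters(c(0, 0.1, 10), rep(1L, 3), K = 2L)
  expect_equal(C[2, 1], 10)                 # farthest point
  expect_equal(C[1, 1], 0.05)               # donor mean recomputed
  expect_identical(attr(C, "reassigned"), c(1L, 1L, 2L))
})

test_that("runKmeans converges on fixed points and on the 4-point instance", {
  # data exactly K distinct repeated values, init = those values
  m <- runKmeans(rep(c(1, 5, 9), each = 4), matrix(c(1, 5, 9)))
  expect_true(m@converged)
  expect_identical(m@iterations, 1L)
  expect_equal(tail(objectiveTrace(m), 1), 0)
  # enumerable instance: the optimal 2-partition of {0, .1, .9, 1}
  m2 <- runKmeans(c(0, 0.1, 0.9, 1.0), matrix(c(0.1, 0.8)))
  expect_equal(sort(centers(m2)[, 1]), c(0.05, 0.95))
  expect_equal(tail(objectiveTrace(m2), 1), 0.01, tolerance = 1e-12)
  expect_error(runKmeans(c(1, 2), matrix(1:3)), "1 <= K <= n")
  expect_error(runKmeans(c(1, NA), matrix(1)), "non-finite")
})

test_that("Lloyd iteration never increases H and is idempotent at a fixed point", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(20:80, 1)
    K <- sample(2:5, 1)
    X <- matrix(runif(n * 2), ncol = 2)
    m <- runKmeans(X, randomInitialCenters(X, K, seed = rep))
    expect_true(all(diff(objectiveTrace(m)) <= 1e-12))
    expect_true(m@iterations <= 100L)
    expect_identical(sum(m@nPerCluster), n)
    # one further iteration changes nothing once converged
    if (m@converged) {
      a2 <- assignPoints(X, centers(m))
      expect_identical(a2, clusterAssignment(m))
      C2 <- updateCenters(X, a2, K = K)
      expect_equal(unname(C2[, ]), centers(m), tolerance = 1e-12)
    }
  }
})

test_that("permuting initial centers permutes labels and leaves H unchanged", {
  set.seed(14)
  X <- matrix(runif(120), ncol = 2)
  C <- randomInitialCenters(X, 4, seed = 7)
  perm <- c(3L, 1L, 4L, 2L)
  m1 <- runKmeans(X, C)
  m2 <- runKmeans(X, C[perm, ])
  expect_equal(tail(objectiveTrace(m1), 1), tail(objectiveTrace(m2), 1),
               tolerance = 1e-12)
  # label correspondence: m2's cluster j is m1's cluster perm[j]
  expect_identical(perm[clusterAssignment(m2)], clusterAssignment(m1))
  expect_equal(centers(m2)[order(perm), ], centers(m1),
               tolerance = 1e-12)
})

test_that("best-of-all-inits matches the exact 1-D DP optimum on small data", {
  set.seed(15)
  for (rep in 1:8) {
    n <- sample(5:10, 1)
    K <- sample(2:3, 1)
    x <- round(runif(n), 3)
    u <- unique(x)
    best <- Inf
    for (comb in asplit(combn(u, K), 2)) {
      m <- runKmeans(x, matrix(comb), tol = 0)
      best <- min(best, tail(objectiveTrace(m), 1))
    }
    expect_equal(best, dpKmeans1D(x, K), tolerance = 1e-9)
  }
})

test_that("ClusterModel serializes to JSON with its trace and config", {
  m <- runKmeans(c(0, 0.1, 0.9, 1.0), matrix(c(0.1, 0.8)))
  js <- jsonlite::fromJSON(modelToJSON(m))
  expect_equal(js$iterations, m@iterations)
  expect_equal(js$objective_trace, objectiveTrace(m))
  expect_equal(js$metric, "sqeuclidean")
  expect_true(js$converged)
})
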