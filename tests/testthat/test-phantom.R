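test_that("PhantomSpec validity names the violated invariant", {
  expect_error(PhantomSpec(nClasses = 1L, classMeans = 0.5,
                           classFractions = 1), "n_classes")
  expect_error(PhantomSpec(classMeans = c(0.9, 0.5, 0.3, 0.1)),
               "strictly increasing")
  expect_error(PhantomSpec(classFractions = c(0.5, 0.5, 0.25, -0.25)),
               "> 0")
  expect_error(PhantomSpec(classFractions = c(0.3, 0.3, 0.3, 0.2)),
               "sum to 1")
  expect_error(PhantomSpec(noiseSigma = -0.1), "noise_sigma")
  expect_error(PhantomSpec(biasAmplitude = -1), "bias_amplitude")
})

test_that("zero-noise zero-bias phantoms are exactly K-valued", {
  for (layout in c("concentric", "blobs")) {
    ph <- makePhantom(48L, noise = 0, layout = layout)
    expect_identical(length(unique(as.vector(pixelData(ph)))), 4L)
    expect_identical(sort(unique(as.vector(labelData(truthLabels(ph))))),
                     0:3)
  }
})

test_that("phantom generation is deterministic given the seed", {
  spec <- PhantomSpec(32L, noiseSigma = 0.05, seed = 9L)
  p1 <- generatePhantom(spec)
  p2 <- generatePhantom(spec)
  expect_identical(pixelData(p1), pixelData(p2))
  expect_identical(labelData(truthLabels(p1)), labelData(truthLabels(p2)))
  p3 <- generatePhantom(PhantomSpec(32L, noiseSigma = 0.05, seed = 10L))
  expect_false(identical(pixelData(p1), pixelData(p3)))
})

test_that("empirical class areas and intensity means match the spec", {
  for (layout in c("concentric", "blobs")) {
    ph <- generatePhantom(PhantomSpec(128L, noiseSigma = 0.05,
                                      layout = layout, seed = 1L))
    truth <- labelData(truthLabels(ph))
    frac <- tabulate(as.vector(truth) + 1L, 4L) / length(truth)
    expect_true(all(abs(frac - c(0.40, 0.25, 0.20, 0.15)) < 0.05))
    px <- pixelData(ph)
    means <- phantomSpec(ph)@classMeans
    for (k in 0:3) {
      mask <- truth == k
      expect_gt(sum(mask), 1e3)
      # noise is clipped at [0,1], so allow a small clipping bias at the
      # extreme classes on top of the sd/sqrt(n) sampling error
      expect_lt(abs(mean(px[mask]) - means[k + 1]), 0.01)
    }
  }
})

test_that("the bias field modulates intensities multiplicatively", {
  ph <- generatePhantom(PhantomSpec(64L, noiseSigma = 0,
                                    biasAmplitude = 0.2, seed = 1L))
  px <- pixelData(ph)
  truth <- labelData(truthLabels(ph))
  # within one class, bias spreads the (otherwise constant) intensity
  spread <- diff(range(px[truth == 1]))
  expect_gt(spread, 0.01)
  expect_lt(spread, 0.35 * 0.2 + 0.01)   # bounded by mean * amplitude
})

test_that("phantomSuite presets have the registered sizes and labels", {
  suite <- phantomSuite("paper_comparison")
  dims <- vapply(suite, function(p) nrow(pixelData(p)), numeric(1))
  expect_identical(unname(dims), c(256, 256, 512, 512))
  tiny <- phantomSuite("tiny")
  expect_true(all(vapply(tiny, function(p) nrow(pixelData(p)) <= 32,
                         logical(1))))
  for (p in c(suite, tiny))
    expect_identical(sort(unique(as.vector(labelData(truthLabels(p))))),
                     0:3)
  expect_error(phantomSuite("nope"))
  # reproducible across calls
  s2 <- phantomSuite("paper_comparison")
  expect_identical(pixelData(suite[[1]]), pixelData(s2[[1]]))
})

test_that("more noise never helps segmentation, on average over seeds", {
  sigmas <- c(0.02, 0.08, 0.15)
  for (method in c("kmeans-density", "meanshift")) {
    meanErr <- vapply(sigmas, function(s) {
      errs <- vapply(1:10, function(seed) {
        ph <- makePhantom(48L, noise = s, seed = seed)
        seg <- segmentImage(phantomImage(ph), method = method, k = 4)
        errorRate(seg$labels, truthLabels(ph))
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    expect_true(all(diff(meanErr) >= 0),
                info = paste(method, paste(round(meanErr, 4),
                                           collapse = " ")))
  }
})
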