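test_that("PGM round-trips 8- and 16-bit images exactly", {
  set.seed(51)
  for (depth in c(8L, 16L)) {
    maxv <- 2^depth - 1
    raw <- matrix(sample(0:maxv, 15 * 9, replace = TRUE), 9, 15)
    img <- GrayImage(raw / maxv, bitDepth = depth)
    path <- tempfile(fileext = ".pgm")
    writeImage(img, path)
    back <- readImage(path)
    expect_equal(pixelData(back), pixelData(img), tolerance = 1e-12)
    expect_identical(back@bitDepth, depth)
  }
})

test_that("PNG grayscale round-trips and normalization follows bit depth", {
  # constant-255 8-bit image reads as all 1.0
  p <- tempfile(fileext = ".png")
  png::writePNG(matrix(1, 4, 4), p)
  img <- readImage(p)
  expect_true(all(pixelData(img) == 1))
  expect_identical(img@bitDepth, 8L)
  # random 8-bit image: write then read is the identity
  set.seed(52)
  raw <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  p2 <- tempfile(fileext = ".png")
  writeImage(GrayImage(raw / 255), p2)
  expect_equal(pixelData(readImage(p2)), raw / 255, tolerance = 1e-12)
})

test_that("RGB input and missing files are rejected with clear errors", {
  p <- tempfile(fileext = ".png")
  png::writePNG(array(runif(27), dim = c(3, 3, 3)), p)
  expect_error(readImage(p), "RGB")
  expect_error(readImage("no/such/file.png"), "not found")
  expect_error(readImage(tempfile(fileext = ".bmp")), "not found")
})

test_that("labels are stored verbatim in PNG, PGM and NIfTI containers", {
  set.seed(53)
  lb <- LabelImage(matrix(sample(0:3, 30, replace = TRUE), 5, 6))
  for (ext in c(".png", ".pgm", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    writeLabels(lb, path)
    back <- readLabels(path)
    expect_identical(labelData(back), labelData(lb))
  }
  # distinct byte values of the PNG are exactly the labels used
  p <- tempfile(fileext = ".png")
  writeLabels(lb, p)
  expect_identical(sort(unique(as.vector(labelData(readLabels(p))))),
                   sort(unique(as.vector(labelData(lb)))))
  expect_error(writeLabels(matrix(300L, 2, 2), tempfile(fileext = ".png")),
               "256 labels")
})

test_that("NIfTI slices re-import with identical shape and values", {
  ph <- makePhantom(16L, noise = 0.05, seed = 6L)
  path <- tempfile(fileext = ".nii.gz")
  writeImage(phantomImage(ph), path)
  back <- readImage(path)
  expect_identical(dim(pixelData(back)), dim(pixelData(ph)))
  expect_equal(pixelData(back), pixelData(ph), tolerance = 1e-12)
})

test_that("asDataset flattens row-major and labelsFromAssignment inverts it", {
  px <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), nrow = 2, byrow = TRUE)
  X <- asDataset(px)
  expect_identical(X[, 1], c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  lb <- labelsFromAssignment(1:6, c(2L, 3L))
  expect_identical(labelData(lb)[1, ], 0:2)
  expect_identical(labelData(lb)[2, ], 3:5)
  # spatial features are scaled to [0, w) x [0, h) by the weight
  Xs <- asDataset(px, spatialWeight = 0.5)
  expect_identical(ncol(Xs), 3L)
  expect_equal(max(Xs[, 2]), 0.5 * 1 / 2)
})

test_that("cliMain segments an image end to end and validates arguments", {
  dir <- tempfile(); dir.create(dir)
  ph <- makePhantom(32L, noise = 0.05, seed = 7L)
  imgPath <- file.path(dir, "a.png")
  writeImage(phantomImage(ph), imgPath)
  outPath <- file.path(dir, "a_labels.png")
  code <- cliMain(c("segment", "--method", "kmeans-density", "--k", "4",
                    "--input", imgPath, "--output", outPath))
  expect_identical(code, 0L)
  expect_true(file.exists(outPath))
  labels <- readLabels(outPath)
  expect_identical(dim(labelData(labels)), c(32L, 32L))
  expect_lt(errorRate(labels, truthLabels(ph)), 0.2)
  # invalid parameter: nonzero exit, message names it, no stack trace
  expect_message(
    bad <- cliMain(c("segment", "--k", "0", "--input", imgPath,
                     "--output", outPath)),
    "invalid parameter k")
  expect_identical(bad, 1L)
  expect_message(bad2 <- cliMain(c("frobnicate")), "unknown command")
  expect_identical(bad2, 1L)
})

test_that("cliMain phantom/eval/compare subcommands interoperate", {
  dir <- tempfile(); dir.create(dir)
  expect_identical(cliMain(c("phantom", "--size", "24", "--noise", "0.05",
                             "--seed", "3", "--out", dir)), 0L)
  img <- list.files(dir, pattern = "_image", full.names = TRUE)
  truth <- list.files(dir, pattern = "_truth", full.names = TRUE)
  expect_identical(length(img), 1L)
  pred <- file.path(dir, "pred.png")
  expect_identical(cliMain(c("segment", "--input", img, "--output", pred,
                             "--k", "4")), 0L)
  evalOut <- file.path(dir, "eval.json")
  expect_output(
    code <- cliMain(c("eval", "--pred", pred, "--truth", truth,
                      "--out", evalOut)),
    "error_rate")
  expect_identical(code, 0L)
  ev <- jsonlite::read_json(evalOut)
  expect_true(ev$error_rate >= 0 && ev$error_rate <= 1)
  # compare on the tiny preset writes a schema-conformant report
  rep <- file.path(dir, "report.json")
  expect_output(
    code2 <- cliMain(c("compare", "--preset", "tiny", "--k", "4",
                       "--seed", "1", "--out", rep)),
    "mean_error_rate")
  expect_identical(code2, 0L)
  doc <- readComparisonJSON(rep)
  expect_identical(length(doc$cells), 6L)
  expect_true(all(c("phantom_id", "method", "error_rate",
                    "runtime_seconds", "seed") %in%
                  names(doc$cells[[1]])))
})

test_that("a YAML config is merged under explicit flags", {
  dir <- tempfile(); dir.create(dir)
  ph <- makePhantom(24L, noise = 0.05, seed = 8L)
  imgPath <- file.path(dir, "b.png")
  writeImage(phantomImage(ph), imgPath)
  cfg <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(method = "kmeans-density", k = 4,
                        output = file.path(dir, "from_cfg.png")), cfg)
  expect_identical(cliMain(c("segment", "--input", imgPath,
                             "--config", cfg)), 0L)
  expect_true(file.exists(file.path(dir, "from_cfg.png")))
  # explicit flag wins over the config value
  out2 <- file.path(dir, "explicit.png")
  expect_identical(cliMain(c("segment", "--input", imgPath,
                             "--output", out2, "--config", cfg)), 0L)
  expect_true(file.exists(out2))
})
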