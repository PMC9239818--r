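## Synthetic brain phantoms: grayscale images with known per-pixel tissue
## labels, standing in for clinical MRI slices. The default four classes
## emulate the tissue decomposition a brain MR slice clusters into —
## regional background, soft tissue, fat, bone — with well-separated
## intensity means.

#' Construct a PhantomSpec
#'
#' @param width,height image size in pixels.
#' @param nClasses number of tissue classes K (>= 2), including
#'   background.
#' @param classMeans K strictly increasing intensity means in \[0, 1\].
#' @param classFractions K positive area fractions summing to 1. Default:
#'   background largest, innermost tissue smallest.
#' @param noiseSigma additive Gaussian noise sd in intensity units.
#' @param biasAmplitude peak-to-peak amplitude of the multiplicative
#'   low-frequency bias field (0 disables; default 0).
#' @param layout `"concentric"` (nested rings, brain-like) or `"blobs"`
#'   (random smoothed regions).
#' @param seed integer RNG seed, recorded in the spec for provenance.
#' @return a validated [PhantomSpec-class].
#' @export
PhantomSpec <- function(width = 256L, height = width, nClasses = 4L,
                        classMeans = c(0.05, 0.35, 0.65, 0.95),
                        classFractions = c(0.40, 0.25, 0.20, 0.15),
                        noiseSigma = 0, biasAmplitude = 0,
                        layout = c("concentric", "blobs"), seed = 1L) {
  new("PhantomSpec",
      width = as.integer(width), height = as.integer(height),
      nClasses = as.integer(nClasses),
      classMeans = as.numeric(classMeans),
      classFractions = as.numeric(classFractions),
      noiseSigma = as.numeric(noiseSigma),
      biasAmplitude = as.numeric(biasAmplitude),
      layout = match.arg(layout), seed = as.integer(seed))
}

# Truth map with class areas matching the requested fractions to within
# one pixel: pixels are ranked by a scalar field (radial distance for
# `concentric`, a smooth random field for `blobs`) and cut at the
# cumulative-fraction quantiles.
phantomTruth <- function(spec) {
  h <- spec@height; w <- spec@width; K <- spec@nClasses
  rows <- matrix(seq_len(h), nrow = h, ncol = w)
  cols <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  if (spec@layout == "concentric") {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    # normalized elliptical radius; class 0 outermost, class K-1 central
    field <- sqrt(((rows - cy) / h)^2 + ((cols - cx) / w)^2)
  } else {
    # smooth random field: sum of seeded low-frequency cosine waves
    nw <- 12L
    amp <- stats::runif(nw, 0.3, 1)
    fr <- stats::runif(nw, 1, 4)
    fc <- stats::runif(nw, 1, 4)
    ph <- stats::runif(nw, 0, 2 * pi)
    th <- stats::runif(nw, 0, pi)
    field <- matrix(0, h, w)
    for (i in seq_len(nw)) {
      field <- field + amp[i] *
        cos(2 * pi * (fr[i] * cos(th[i]) * rows / h +
                      fc[i] * sin(th[i]) * cols / w) + ph[i])
    }
  }
  v <- as.vector(field)
  # class k occupies a quantile band of the field; for concentric the
  # bands run from the center outward with class K-1 innermost and the
  # background class 0 at the rim, so the band fractions are reversed
  # before cutting and the labels flipped after
  frac <- if (spec@layout == "concentric") rev(spec@classFractions)
          else spec@classFractions
  cuts <- stats::quantile(v, cumsum(frac)[-K], type = 1L)
  lab <- findInterval(v, cuts, left.open = TRUE)
  if (spec@layout == "concentric") lab <- (K - 1L) - lab
  matrix(as.integer(lab), h, w)
}

#' Generate a synthetic phantom
#'
#' Pixel values are `classMeans[truth] * bias + noise`, clipped to
#' \[0, 1\] and quantized to the 8-bit intensity grid (`round(255 x)/255`),
#' matching what the tool sees when it ingests PNG-derived MRI slices.
#' Deterministic given the seed in the spec; the empirical area fraction
#' of every class matches the requested fraction to within one pixel.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [Phantom-class] carrying the image, the ground-truth
#'   label map, and the spec.
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  withLocalSeed(spec@seed, {
    truth <- phantomTruth(spec)
    h <- spec@height; w <- spec@width
    px <- matrix(spec@classMeans[truth + 1L], h, w)
    if (spec@biasAmplitude > 0) {
      rows <- matrix(seq_len(h) - 1L, nrow = h, ncol = w)
      cols <- matrix(seq_len(w) - 1L, nrow = h, ncol = w, byrow = TRUE)
      bias <- 1 + (spec@biasAmplitude / 2) *
        cos(pi * rows / max(h - 1L, 1L)) * cos(pi * cols / max(w - 1L, 1L))
      px <- px * bias
    }
    if (spec@noiseSigma > 0)
      px <- px + matrix(stats::rnorm(h * w, 0, spec@noiseSigma), h, w)
    px[px < 0] <- 0; px[px > 1] <- 1
    px <- round(px * 255) / 255
    new("Phantom", image = GrayImage(px, bitDepth = 8L),
        truth = LabelImage(truth), spec = spec)
  })
}

#' Registered phantom suites
#'
#' Named presets with fixed seeds, reproducible across runs:
#' \describe{
#'   \item{`paper_comparison`}{two 256 x 256 and two 512 x 512
#'     four-class concentric phantoms, noise sd 0.05 — the image sizes
#'     of the runtime/error-rate comparison.}
#'   \item{`noisy_comparison`}{twenty 128 x 128 four-class phantoms with
#'     noise sd 0.08 (adjacent class histograms visibly overlap), seeds
#'     `base+1 .. base+20` — the error-rate ordering study.}
#'   \item{`tiny`}{two phantoms of at most 32 x 32 for unit tests.}
#' }
#'
#' @param preset preset name.
#' @param baseSeed offset added to every phantom seed (default 100).
#' @return a named list of [Phantom-class] objects.
#' @export
phantomSuite <- function(preset = c("paper_comparison", "noisy_comparison",
                                    "tiny"),
                         baseSeed = 100L) {
  preset <- match.arg(preset)
  baseSeed <- as.integer(baseSeed)
  specs <- switch(preset,
    paper_comparison = list(
      img256_1 = PhantomSpec(256L, noiseSigma = 0.05, seed = baseSeed + 1L),
      img256_2 = PhantomSpec(256L, noiseSigma = 0.05, layout = "blobs",
                             seed = baseSeed + 2L),
      img512_1 = PhantomSpec(512L, noiseSigma = 0.05, seed = baseSeed + 3L),
      img512_2 = PhantomSpec(512L, noiseSigma = 0.05, layout = "blobs",
                             seed = baseSeed + 4L)
    ),
    noisy_comparison = {
      s <- lapply(seq_len(20L), function(i)
        PhantomSpec(128L, noiseSigma = 0.08, seed = baseSeed + i))
      names(s) <- sprintf("noisy_%02d", seq_len(20L))
      s
    },
    tiny = list(
      tiny_concentric = PhantomSpec(32L, noiseSigma = 0.02,
                                    seed = baseSeed + 1L),
      tiny_blobs = PhantomSpec(24L, noiseSigma = 0.02, layout = "blobs",
                               seed = baseSeed + 2L)
    )
  )
  lapply(specs, generatePhantom)
}

#' Write a phantom's image and truth to disk
#'
#' @param phantom a [Phantom-class].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param format `"png"`, `"pgm"`, or `"nii.gz"`.
#' @return character vector of the two paths written, invisibly.
#' @export
writePhantom <- function(phantom, dir, name = "phantom",
                         format = c("png", "pgm", "nii.gz")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imgPath <- file.path(dir, paste0(name, "_image.", format))
  lblPath <- file.path(dir, paste0(name, "_truth.", format))
  writeImage(phantom@image, imgPath)
  writeLabels(phantom@truth, lblPath)
  invisible(c(image = imgPath, truth = lblPath))
}
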