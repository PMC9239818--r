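## Image I/O: PNG (8/16-bit grayscale, via the png package), PGM (P2/P5,
## minimal reader/writer), NIfTI-1 (via RNifti, slice-wise).
## Convention everywhere: (row, col), 0-based labels, row-major flattening.

#' Construct a GrayImage from a numeric matrix
#'
#' @param pixels numeric matrix of intensities in \[0, 1\] (height x width).
#' @param bitDepth source container bit depth (8 or 16).
#' @return a [GrayImage-class].
#' @export
GrayImage <- function(pixels, bitDepth = 8L) {
  new("GrayImage", as.matrix(pixels), bitDepth = as.integer(bitDepth))
}

#' Construct a LabelImage from an integer matrix
#'
#' @param labels matrix of nonnegative integer labels.
#' @return a [LabelImage-class].
#' @export
LabelImage <- function(labels) {
  m <- as.matrix(labels)
  storage.mode(m) <- "integer"
  new("LabelImage", m)
}

#' Number of distinct labels in a LabelImage
#' @param object a [LabelImage-class].
#' @export
nLabels <- function(object) {
  stopifnot(is(object, "LabelImage"))
  length(unique(as.vector(object@.Data)))
}

fileExt <- function(path) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

#' Read a grayscale image
#'
#' Supported formats: PNG (8- or 16-bit grayscale), PGM (ASCII `P2` or
#' binary `P5`), and NIfTI-1 (`.nii` / `.nii.gz`; a `slice` index is
#' required for volumes with more than one slice). Intensities are
#' normalized to \[0, 1\] by dividing by the container bit-depth maximum
#' (8-bit: 255; 16-bit: 65535). RGB / multichannel input is rejected.
#'
#' @param path file path.
#' @param slice slice index (1-based) along `sliceAxis`, for NIfTI volumes.
#' @param sliceAxis axis along which slices are taken (default: last).
#' @return a [GrayImage-class]. For NIfTI input the slice axis and index
#'   are recorded in the `"provenance"` attribute.
#' @export
readImage <- function(path, slice = NULL, sliceAxis = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path)
  ext <- fileExt(path)
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) {
      if (dim(px)[3L] == 2L) {
        px <- px[, , 1L]              # gray + alpha: drop alpha
      } else {
        stop("RGB/multichannel PNG input is not supported: ", path)
      }
    }
    # png::readPNG already divides by the bit-depth maximum
    bits <- pngBitDepth(path)
    GrayImage(px, bitDepth = bits)
  } else if (ext %in% c("pgm", "ppm")) {
    if (ext == "ppm") stop("color PPM input is not supported: ", path)
    readPGM(path)
  } else if (ext %in% c("nii", "nii.gz")) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    d <- dim(arr)
    if (length(d) > 2L && any(d[-(1:2)] > 1L)) {
      if (is.null(sliceAxis)) sliceAxis <- length(d)
      if (is.null(slice))
        stop("a slice index is required for NIfTI volumes (",
             paste(d, collapse = "x"), ")")
      if (slice < 1L || slice > d[sliceAxis])
        stop("slice index ", slice, " out of range 1..", d[sliceAxis])
      idx <- rep(list(quote(expr = )), length(d))
      idx[[sliceAxis]] <- slice
      arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    }
    arr <- array(arr, dim = dim(arr)[1:2])
    rng <- range(arr)
    bits <- if (rng[2L] > 255) 16L else 8L
    px <- arr / (2^bits - 1)
    px[px < 0] <- 0; px[px > 1] <- 1
    img <- GrayImage(px, bitDepth = bits)
    attr(img, "provenance") <- list(path = path, sliceAxis = sliceAxis,
                                    slice = slice)
    img
  } else {
    stop("unsupported image format: .", ext)
  }
}

# Bit depth from the PNG IHDR chunk (byte 25 of the file).
pngBitDepth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  as.integer(hdr[25L])
}

#' Write a grayscale image
#'
#' PNG and PGM output quantize the \[0, 1\] intensities to the container
#' bit depth; NIfTI output stores the 0..max integer grid as a
#' single-slice volume.
#'
#' @param image a [GrayImage-class] (or numeric matrix in \[0, 1\]).
#' @param path output path; format chosen by extension
#'   (.png, .pgm, .nii, .nii.gz).
#' @param bitDepth output bit depth (defaults to the image's source depth).
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path, bitDepth = NULL) {
  if (is(image, "GrayImage")) {
    if (is.null(bitDepth)) bitDepth <- image@bitDepth
    px <- image@.Data
  } else {
    if (is.null(bitDepth)) bitDepth <- 8L
    px <- as.matrix(image)
  }
  maxv <- 2^bitDepth - 1
  ext <- fileExt(path)
  if (ext == "png") {
    png::writePNG(px, path, dpi = NULL)    # png quantizes to 8-bit
  } else if (ext == "pgm") {
    writePGM(round(px * maxv), path, maxval = maxv)
  } else if (ext %in% c("nii", "nii.gz")) {
    arr <- array(as.integer(round(px * maxv)), dim = c(dim(px), 1L))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

## -- PGM (P2 ASCII / P5 binary); no installed package reads PGM ----------

readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic ", magic, "): ", path)
  tokens <- character(0)
  buf <- character(0)
  # header tokens: width height maxval, '#' starts a comment
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[ \t\r\n]", ch)) {
      if (length(buf)) { tokens <- c(tokens, paste(buf, collapse = "")) }
      buf <- character(0)
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tokens[1L]); h <- as.integer(tokens[2L])
  maxval <- as.integer(tokens[3L])
  n <- w * h
  if (magic == "P5") {
    if (maxval > 255) {
      v <- readBin(con, "integer", n, size = 2L, signed = FALSE,
                   endian = "big")
    } else {
      v <- as.integer(readBin(con, "raw", n))
    }
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(v) != n) stop("truncated PGM pixel data")
  px <- matrix(v / maxval, nrow = h, ncol = w, byrow = TRUE)
  GrayImage(px, bitDepth = if (maxval > 255) 16L else 8L)
}

writePGM <- function(values, path, maxval = 255L) {
  v <- as.integer(round(values))
  h <- nrow(values); w <- ncol(values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n%d\n", w, h, as.integer(maxval))),
           con)
  vv <- as.integer(as.vector(t(values)))   # row-major pixel stream
  if (maxval > 255) {
    # big-endian 16-bit, packed by hand (writeBin size=2 is signed)
    writeBin(as.raw(rbind(vv %/% 256L, vv %% 256L)), con)
  } else {
    writeBin(as.raw(vv), con)
  }
  invisible(path)
}

#' Write a label image
#'
#' Label integers are stored verbatim (no intensity scaling): 8-bit PNG
#' or PGM for up to 256 labels, NIfTI for any count.
#'
#' @param labels a [LabelImage-class] (or integer matrix).
#' @param path output path (.png, .pgm, .nii, .nii.gz).
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path) {
  lb <- if (is(labels, "LabelImage")) labels@.Data else {
    m <- as.matrix(labels); storage.mode(m) <- "integer"; m
  }
  ext <- fileExt(path)
  if (ext %in% c("png", "pgm")) {
    if (max(lb) > 255L)
      stop("more than 256 labels cannot be stored in 8-bit ", ext,
           "; use NIfTI output")
    if (ext == "png") png::writePNG(lb / 255, path, dpi = NULL)
    else writePGM(lb, path, maxval = 255L)
  } else if (ext %in% c("nii", "nii.gz")) {
    arr <- array(lb, dim = c(dim(lb), 1L))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  } else {
    stop("unsupported label format: .", ext)
  }
  invisible(path)
}

#' Read a label image written by [writeLabels()]
#'
#' @param path input path (.png, .pgm, .nii, .nii.gz).
#' @return a [LabelImage-class].
#' @export
readLabels <- function(path) {
  ext <- fileExt(path)
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) stop("label PNG must be single-channel")
    LabelImage(round(px * 255))
  } else if (ext == "pgm") {
    img <- readPGM(path)
    LabelImage(round(img@.Data * (2^img@bitDepth - 1)))
  } else if (ext %in% c("nii", "nii.gz")) {
    arr <- as.array(RNifti::readNifti(path))
    LabelImage(array(arr, dim = dim(arr)[1:2]))
  } else {
    stop("unsupported label format: .", ext)
  }
}

#' Flatten an image into a clustering dataset
#'
#' Pixels are flattened in row-major order (row 1 left to right, then
#' row 2, ...) into an n x d feature matrix. By default features are
#' intensity only (d = 1); a positive `spatialWeight` w appends scaled
#' pixel coordinates (w * row/height, w * col/width), injecting the
#' position information that intensity-only k-means ignores.
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param spatialWeight nonnegative weight of the spatial coordinates
#'   (default 0: intensity-only features).
#' @return numeric matrix with n = height*width rows and an
#'   `"imageShape"` attribute c(height, width) for mapping back.
#' @export
asDataset <- function(image, spatialWeight = 0) {
  px <- if (is(image, "GrayImage")) image@.Data else as.matrix(image)
  h <- nrow(px); w <- ncol(px)
  intens <- as.vector(t(px))
  if (spatialWeight > 0) {
    rows <- rep(seq_len(h) - 1L, each = w)
    cols <- rep(seq_len(w) - 1L, times = h)
    X <- cbind(intensity = intens,
               row = spatialWeight * rows / h,
               col = spatialWeight * cols / w)
  } else {
    X <- matrix(intens, ncol = 1L, dimnames = list(NULL, "intensity"))
  }
  attr(X, "imageShape") <- c(h, w)
  X
}

#' Reshape a per-pixel assignment back into a LabelImage
#'
#' Inverse of the row-major flattening of [asDataset()]. Cluster indices
#' (1-based) become 0-based image labels.
#'
#' @param assignment integer vector of length height*width (1-based).
#' @param shape c(height, width).
#' @return a [LabelImage-class].
#' @export
labelsFromAssignment <- function(assignment, shape) {
  h <- shape[1L]; w <- shape[2L]
  stopifnot(length(assignment) == h * w)
  LabelImage(matrix(as.integer(assignment) - 1L, nrow = h, ncol = w,
                    byrow = TRUE))
}
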