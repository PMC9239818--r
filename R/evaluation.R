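## Segmentation error rate with optimal label matching, and the
## comparison harness.
##
## Cluster indices are arbitrary, so before counting disagreements the
## prediction labels are mapped to truth labels by the correspondence
## that maximizes total agreement: an exact solution of the assignment
## problem on the contingency table (injective when the prediction has
## at most as many labels as the truth; surplus prediction labels map
## many-to-one by majority). A majority-vote mapping is available as a
## faster option.

labelMatrixOf <- function(x) {
  if (is(x, "LabelImage")) x@.Data
  else if (is(x, "Phantom")) x@truth@.Data
  else { m <- as.matrix(x); storage.mode(m) <- "integer"; m }
}

# All permutations of 1..n, one per row (n <= 8 guarded by caller).
permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutationsOf(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

# Exact maximum-agreement injective assignment of rows (pred) to columns
# (truth) of a contingency table; enumeration over injective maps.
bestInjectiveMap <- function(tab) {
  np <- nrow(tab); nt <- ncol(tab)
  stopifnot(np <= nt)
  if (nt > 8L)
    stop("exact label matching supports at most 8 labels on the larger ",
         "side; got ", nt)
  perms <- permutationsOf(nt)
  best <- -1L; bestMap <- NULL
  for (r in seq_len(nrow(perms))) {
    map <- perms[r, seq_len(np)]
    agree <- sum(tab[cbind(seq_len(np), map)])
    if (agree > best) { best <- agree; bestMap <- map }
  }
  list(map = bestMap, agreement = best)
}

#' Optimal prediction-to-truth label matching
#'
#' Returns the mapping of prediction labels to truth labels that
#' maximizes the number of agreeing pixels. When the prediction has at
#' most as many labels as the truth the mapping is injective (exact
#' assignment-problem solution); when it has more, surplus labels are
#' allowed to map many-to-one and each prediction label takes its
#' majority truth label, which is optimal under that relaxation.
#'
#' @param pred,truth [LabelImage-class] objects (or integer matrices) of
#'   equal shape.
#' @param method `"optimal"` (default) or `"majority"` (each prediction
#'   label mapped to its majority truth label regardless of counts).
#' @return named integer vector: names are prediction labels, values the
#'   matched truth labels (both 0-based); the `"agreement"` attribute
#'   holds the matched agreement count.
#' @export
matchLabels <- function(pred, truth, method = c("optimal", "majority")) {
  method <- match.arg(method)
  P <- labelMatrixOf(pred); T <- labelMatrixOf(truth)
  if (!identical(dim(P), dim(T)))
    stop("shape mismatch: ", paste(dim(P), collapse = "x"), " vs ",
         paste(dim(T), collapse = "x"))
  pl <- sort(unique(as.vector(P))); tl <- sort(unique(as.vector(T)))
  tab <- table(factor(as.vector(P), levels = pl),
               factor(as.vector(T), levels = tl))
  tab <- matrix(as.integer(tab), nrow = length(pl),
                dimnames = list(pl, tl))
  if (method == "majority" || length(pl) > length(tl)) {
    mapIdx <- max.col(tab, ties.method = "first")
    agree <- sum(tab[cbind(seq_len(nrow(tab)), mapIdx)])
  } else {
    sol <- bestInjectiveMap(tab)
    mapIdx <- sol$map
    agree <- sol$agreement
  }
  out <- tl[mapIdx]
  names(out) <- pl
  attr(out, "agreement") <- as.integer(agree)
  out
}

#' Segmentation error rate
#'
#' Fraction of pixels whose predicted label disagrees with the ground
#' truth after the optimal prediction-to-truth label matching:
#' `1 - agreement / n`. Zero iff the prediction is a relabeling of the
#' truth; invariant under any relabeling of either argument.
#'
#' @inheritParams matchLabels
#' @return a fraction in \[0, 1\].
#' @export
errorRate <- function(pred, truth, method = c("optimal", "majority")) {
  P <- labelMatrixOf(pred); T <- labelMatrixOf(truth)
  if (!identical(dim(P), dim(T)))
    stop("shape mismatch: ", paste(dim(P), collapse = "x"), " vs ",
         paste(dim(T), collapse = "x"))
  m <- matchLabels(P, T, method = match.arg(method))
  1 - attr(m, "agreement") / length(P)
}

#' Evaluate one segmentation against ground truth
#'
#' @param pred a [LabelImage-class] prediction.
#' @param truth the ground-truth [LabelImage-class].
#' @param phantomId identifier for the report.
#' @param method method label for the report.
#' @param params named list of method parameters.
#' @param runtimeSeconds wall-clock seconds of the segmentation call
#'   (informational only; hardware-dependent).
#' @param seed seed the method used (NA if none).
#' @return an [EvalReport-class].
#' @export
evaluateSegmentation <- function(pred, truth, phantomId = "image",
                                 method = "unknown", params = list(),
                                 runtimeSeconds = NA_real_,
                                 seed = NA_integer_) {
  P <- labelMatrixOf(pred); T <- labelMatrixOf(truth)
  m <- matchLabels(P, T)
  tl <- sort(unique(as.vector(T))); pl <- sort(unique(as.vector(P)))
  conf <- table(factor(as.vector(T), levels = tl),
                factor(as.vector(P), levels = pl))
  conf <- matrix(as.integer(conf), nrow = length(tl),
                 dimnames = list(truth = tl, pred = pl))
  new("EvalReport",
      phantomId = as.character(phantomId), method = as.character(method),
      params = params,
      errorRate = 1 - attr(m, "agreement") / length(P),
      matching = as.integer(m), confusion = conf,
      runtimeSeconds = as.numeric(runtimeSeconds),
      seed = as.integer(seed))
}

#' Run the three-way method comparison on a phantom suite
#'
#' Segments every phantom with every configured method, evaluates each
#' result against the phantom's ground truth, and aggregates mean error
#' rates per method. Runtimes are recorded (wall-clock around the
#' segmentation call only) but are informational: they are
#' hardware-dependent and never asserted. A method failure on one
#' phantom aborts that cell only and is recorded in the aggregate.
#'
#' @param phantoms list of [Phantom-class] objects (e.g. from
#'   [phantomSuite()]).
#' @param methods list of method configurations, each a named list with
#'   at least `method` (`"kmeans"`, `"kmeans-density"`, `"meanshift"`);
#'   see [segmentImage()] for the remaining fields. Default: the
#'   three-way comparison with K = 4.
#' @param k number of clusters for the default method set.
#' @param seed base seed for random initialization (incremented per
#'   phantom so restarts differ across images).
#' @return list with `reports` (one [EvalReport-class] per cell),
#'   `summary` (data.frame: one row per cell), and `meanErrorRates`
#'   (named per-method means).
#' @export
runComparison <- function(phantoms, methods = NULL, k = 4L, seed = 1L) {
  if (!length(phantoms)) stop("at least one phantom is required")
  if (is.null(methods)) {
    methods <- list(
      list(method = "kmeans", k = k, init = "random"),
      list(method = "kmeans-density", k = k),
      list(method = "meanshift")
    )
  }
  if (is.null(names(phantoms)))
    names(phantoms) <- sprintf("phantom_%02d", seq_along(phantoms))
  reports <- list()
  rows <- list()
  for (pi in seq_along(phantoms)) {
    ph <- phantoms[[pi]]
    pid <- names(phantoms)[pi]
    for (cfg in methods) {
      cfgSeed <- as.integer(seed) + pi - 1L
      rep <- tryCatch({
        t0 <- proc.time()[["elapsed"]]
        seg <- segmentImage(ph@image, method = cfg$method,
                            k = cfg$k %||% k,
                            init = cfg$init %||% "density",
                            densityRadius = cfg$densityRadius,
                            bandwidth = cfg$bandwidth,
                            spatialWeight = cfg$spatialWeight %||% 0,
                            seed = cfgSeed)
        rt <- proc.time()[["elapsed"]] - t0
        evaluateSegmentation(seg$labels, ph@truth, phantomId = pid,
                             method = methodLabel(cfg),
                             params = cfg, runtimeSeconds = rt,
                             seed = cfgSeed)
      }, error = function(e) {
        new("EvalReport", phantomId = pid, method = methodLabel(cfg),
            params = c(cfg, list(error = conditionMessage(e))),
            errorRate = NA_real_, matching = integer(0),
            confusion = matrix(0L, 1L, 1L),
            runtimeSeconds = NA_real_, seed = cfgSeed)
      })
      reports[[length(reports) + 1L]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        phantom_id = pid, method = rep@method,
        error_rate = rep@errorRate,
        runtime_seconds = round(rep@runtimeSeconds, 3L),
        seed = rep@seed, stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  meanErr <- tapply(summary$error_rate, summary$method, mean,
                    na.rm = TRUE)
  list(reports = reports, summary = summary,
       meanErrorRates = meanErr[unique(summary$method)])
}

methodLabel <- function(cfg) {
  if (cfg$method == "kmeans" && identical(cfg$init %||% "density",
                                          "random")) "kmeans"
  else if (cfg$method %in% c("kmeans", "kmeans-density")) "kmeans-density"
  else cfg$method
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a comparison report as JSON
#'
#' The JSON schema per cell is `{phantom_id, method, params, error_rate,
#' confusion, runtime_seconds, seed}`; the round-trip through
#' [readComparisonJSON()] is lossless for these fields. A companion CSV
#' of the summary table can be written alongside.
#'
#' @param comparison result of [runComparison()].
#' @param path output JSON path.
#' @param csvPath optional path for the aggregate CSV (one row per
#'   phantom x method cell).
#' @return `path`, invisibly.
#' @export
writeComparisonJSON <- function(comparison, path, csvPath = NULL) {
  cells <- lapply(comparison$reports, function(r) {
    list(phantom_id = r@phantomId, method = r@method,
         params = r@params[!vapply(r@params, is.null, logical(1))],
         error_rate = r@errorRate,
         confusion = apply(r@confusion, 1L, as.integer,
                           simplify = FALSE),
         runtime_seconds = r@runtimeSeconds, seed = r@seed)
  })
  doc <- list(cells = cells,
              mean_error_rates = as.list(comparison$meanErrorRates))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csvPath))
    utils::write.csv(comparison$summary, csvPath, row.names = FALSE)
  invisible(path)
}

#' @rdname writeComparisonJSON
#' @export
readComparisonJSON <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
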