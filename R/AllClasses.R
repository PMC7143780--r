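#' @import methods
#' @importFrom stats rnorm rbinom runif hclust cutree as.dist setNames
#' @importFrom utils read.csv write.csv
#' @useDynLib growthwarp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.VALID_SCALES    <- c("linear", "log")
.VALID_INITCONC  <- c("low", "high", "unknown")

#' GrowthCurve: one optical-density time series
#'
#' A single bacterial growth curve: strictly increasing time points (hours)
#' and OD600 readings of equal length, on either a linear or a logarithmic
#' scale, together with its metadata labels (strain, growth medium, initial
#' inoculum class).
#'
#' @slot curveId unique curve identifier.
#' @slot times numeric, strictly increasing time points in hours, all >= 0.
#' @slot values numeric OD600 readings, same length as `times` (>= 2 points).
#' @slot scale `"linear"` or `"log"`.
#' @slot strain strain label.
#' @slot medium growth-medium label (e.g. `"LB"`, `"MAA"`, `"M63"`).
#' @slot initConc initial-concentration class: `"low"`, `"high"` or
#'   `"unknown"`.
#'
#' @seealso [growthCurve()] for the user-facing constructor,
#'   [logTransform()], [thinToInterval()].
#' @exportClass GrowthCurve
setClass("GrowthCurve",
  representation(
    curveId  = "character",
    times    = "numeric",
    values   = "numeric",
    scale    = "character",
    strain   = "character",
    medium   = "character",
    initConc = "character"
  ),
  prototype(scale = "linear", strain = "unknown", medium = "unknown",
            initConc = "unknown")
)

setValidity("GrowthCurve", function(object) {
  msg <- character()
  if (length(object@curveId) != 1L || is.na(object@curveId) ||
      !nzchar(object@curveId))
    msg <- c(msg, "curveId must be a single non-empty string")
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) < 2L)
    msg <- c(msg, "a curve needs at least 2 points")
  if (anyNA(object@times) || anyNA(object@values))
    msg <- c(msg, "times and values must be free of missing values")
  else {
    if (any(object@times < 0))
      msg <- c(msg, "all times must be >= 0")
    if (length(object@times) >= 2L && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
  }
  if (length(object@scale) != 1L || !object@scale %in% .VALID_SCALES)
    msg <- c(msg, "scale must be 'linear' or 'log'")
  else if (object@scale == "linear" && !anyNA(object@values) &&
           any(object@values < 0))
    msg <- c(msg, "linear-scale OD values must be non-negative")
  if (length(object@initConc) != 1L ||
      !object@initConc %in% .VALID_INITCONC)
    msg <- c(msg, "initConc must be 'low', 'high' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' Construct a GrowthCurve
#'
#' @param curveId unique identifier.
#' @param times strictly increasing time points (hours).
#' @param values OD600 readings, same length as `times`.
#' @param scale `"linear"` (raw OD) or `"log"` (log-transformed OD).
#' @param strain,medium,initConc metadata labels; `initConc` must be one of
#'   `"low"`, `"high"`, `"unknown"`.
#' @return a [GrowthCurve-class] object.
#' @examples
#' gc <- growthCurve("w1", times = 0:5, values = c(.01, .02, .05, .2, .6, .9),
#'                   medium = "LB")
#' gc
#' @export
growthCurve <- function(curveId, times, values, scale = "linear",
                        strain = "unknown", medium = "unknown",
                        initConc = "unknown") {
  new("GrowthCurve", curveId = as.character(curveId),
      times = as.numeric(times), values = as.numeric(values),
      scale = scale, strain = as.character(strain),
      medium = as.character(medium), initConc = as.character(initConc))
}

#' GrowthDataset: an ordered collection of growth curves
#'
#' Holds the curves of one experiment. Curve ids are unique and all curves
#' share one scale (linear or log); mixed-scale collections are rejected so
#' that pairwise distances are always computed on commensurable values.
#'
#' @slot curves list of [GrowthCurve-class] objects.
#' @seealso [growthDataset()], [readGrowthTable()], [simulateDataset()].
#' @exportClass GrowthDataset
setClass("GrowthDataset", representation(curves = "list"))

setValidity("GrowthDataset", function(object) {
  msg <- character()
  if (!all(vapply(object@curves, is, logical(1), "GrowthCurve")))
    msg <- c(msg, "all elements must be GrowthCurve objects")
  else {
    ids <- vapply(object@curves, function(x) x@curveId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate curve ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    scales <- unique(vapply(object@curves, function(x) x@scale, character(1)))
    if (length(scales) > 1L)
      msg <- c(msg, "all curves must share one scale (mixed linear/log)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GrowthDataset
#'
#' @param curves list of [GrowthCurve-class] objects with unique ids and a
#'   common scale.
#' @return a [GrowthDataset-class] object.
#' @export
growthDataset <- function(curves) {
  new("GrowthDataset", curves = unname(curves))
}

#' WarpDistanceMatrix: pairwise warping distances over a dataset
#'
#' A symmetric, zero-diagonal matrix of non-negative pairwise distances
#' between growth curves, tagged with the distance it holds: pure DTW
#' (`kind = "dtw"`), pure derivative DTW (`kind = "ddtw"`), or the
#' alpha-weighted combination `(1 - alpha) * DTW + alpha * DDTW`
#' (`kind = "combined"`, `alpha` recorded).
#'
#' @slot values square numeric matrix with curve ids as dimnames.
#' @slot kind one of `"dtw"`, `"ddtw"`, `"combined"`.
#' @slot alpha the weight that produced a combined matrix; `NA` for the pure
#'   matrices.
#' @seealso [pairwiseMatrices()], [combineMatrices()].
#' @exportClass WarpDistanceMatrix
setClass("WarpDistanceMatrix",
  representation(values = "matrix", kind = "character", alpha = "numeric"))

setValidity("WarpDistanceMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)) ||
      !identical(rownames(v), colnames(v)))
    msg <- c(msg, "matrix needs identical row/column id names")
  else if (anyDuplicated(rownames(v)))
    msg <- c(msg, "curve ids must be unique")
  if (anyNA(v)) msg <- c(msg, "distances must not be missing")
  else {
    if (any(v < 0)) msg <- c(msg, "distances must be non-negative")
    if (nrow(v) == ncol(v)) {
      if (any(abs(v - t(v)) > 1e-8 * (1 + max(abs(v)))))
        msg <- c(msg, "matrix must be symmetric")
      if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
    }
  }
  if (length(object@kind) != 1L ||
      !object@kind %in% c("dtw", "ddtw", "combined"))
    msg <- c(msg, "kind must be 'dtw', 'ddtw' or 'combined'")
  else if (object@kind == "combined" &&
           (length(object@alpha) != 1L || is.na(object@alpha) ||
            object@alpha < 0 || object@alpha > 1))
    msg <- c(msg, "a combined matrix needs alpha in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GrowthGridResult: benchmark scores over the alpha-by-N grid
#'
#' One row per (alpha, N) cell of the model-selection grid, holding the four
#' goodness-of-clustering statistics and the majority-vote error count for
#' the Ward partition obtained at that cell.
#'
#' @slot grid data.frame with columns `alpha`, `n_clusters`, `ari`, `ami`,
#'   `v`, `h`, `c`, `sc`, `errors`.
#' @slot alphaGrid the alpha values scanned.
#' @slot nRange the cluster counts scanned.
#' @slot nCurves number of curves the grid was computed on.
#' @seealso [gridSearch()], [bestByBenchmark()], [minErrorProfile()],
#'   [selectByErrorKnee()].
#' @exportClass GrowthGridResult
setClass("GrowthGridResult",
  representation(grid = "data.frame", alphaGrid = "numeric",
                 nRange = "integer", nCurves = "integer"))

setValidity("GrowthGridResult", function(object) {
  msg <- character()
  need <- c("alpha", "n_clusters", "ari", "ami", "v", "h", "c", "sc", "errors")
  if (!all(need %in% names(object@grid)))
    msg <- c(msg, paste("grid must have columns:", paste(need, collapse = ", ")))
  else if (nrow(object@grid) !=
           length(object@alphaGrid) * length(object@nRange))
    msg <- c(msg, "grid must have one row per (alpha, N) cell")
  if (length(msg)) msg else TRUE
})
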