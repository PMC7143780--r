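#' Dynamic time warping distance between two value sequences
#'
#' Accumulated cost of the optimal monotone alignment (warping path) between
#' `x` and `y` under the classic three-predecessor recurrence
#' `G(i,j) = d(x_i, y_j) + min(G(i-1,j), G(i,j-1), G(i-1,j-1))` with local
#' cost `d(a, b) = |a - b|` and no windowing constraint. The distance is the
#' bottom-right entry `G(n, m)`, so sequences of unequal length compare
#' directly. Time stamps play no role: warping is index-based, which is why
#' curves must first be brought to a common sampling interval (see
#' [thinToInterval()]).
#'
#' @param x,y numeric sequences (length >= 1).
#' @param returnMatrix if `TRUE`, also return the full accumulated-cost
#'   matrix.
#' @return the non-negative DTW distance, or (with `returnMatrix = TRUE`) a
#'   list with `distance` and the `n x m` `costMatrix`.
#' @examples
#' dtwDistance(c(1, 2, 3), c(1, 2, 3))   # 0
#' dtwDistance(c(1, 2), c(1, 2, 2))      # 0: the repeated 2 is absorbed
#' @seealso [ddtwDistance()], [combinedDistance()], [pairwiseMatrices()]
#' @export
dtwDistance <- function(x, y, returnMatrix = FALSE) {
  if (length(x) < 1L || length(y) < 1L)
    stop("dtw needs non-empty sequences")
  if (anyNA(x) || anyNA(y)) stop("sequences must be free of missing values")
  x <- as.numeric(x); y <- as.numeric(y)
  if (!returnMatrix) return(.dtw_distance_cpp(x, y))
  G <- .dtw_cost_matrix_cpp(x, y)
  list(distance = G[length(x), length(y)], costMatrix = G)
}

#' First forward-difference of a sequence
#'
#' `out[i] = x[i+1] - x[i]`, the derivative estimate DDTW operates on.
#'
#' @param x numeric sequence of length >= 2.
#' @return numeric sequence of length `length(x) - 1`.
#' @export
firstDerivative <- function(x) {
  if (length(x) < 2L) stop("first derivative needs at least 2 points")
  diff(as.numeric(x))
}

#' Derivative dynamic time warping distance
#'
#' DTW applied to the first forward differences of the two sequences:
#' `ddtw(x, y) = dtw(x', y')`. Because differencing removes any constant
#' offset, DDTW is exactly invariant to vertical shifts and responds to the
#' shape (slope) of a growth curve — its growth rate — rather than to its
#' absolute OD level.
#'
#' @param x,y numeric sequences (length >= 2).
#' @return the non-negative DDTW distance.
#' @examples
#' ddtwDistance(c(0, 1, 2), c(10, 11, 12))  # 0: same slopes
#' @export
ddtwDistance <- function(x, y) {
  dtwDistance(firstDerivative(x), firstDerivative(y))
}

#' Alpha-weighted combination of DTW and DDTW
#'
#' `(1 - alpha) * dtw(x, y) + alpha * ddtw(x, y)` with `alpha` in `[0, 1]`.
#' The raw (unnormalised) DTW and DDTW values are combined; the two are
#' typically of different orders of magnitude, which the fine alpha grid of
#' the model-selection step compensates for.
#'
#' @param x,y numeric sequences (length >= 2).
#' @param alpha weight of the derivative distance, in `[0, 1]`; 0 gives pure
#'   DTW, 1 pure DDTW.
#' @return the non-negative combined distance.
#' @export
combinedDistance <- function(x, y, alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  (1 - alpha) * dtwDistance(x, y) + alpha * ddtwDistance(x, y)
}

#' Pairwise DTW and DDTW matrices over a dataset
#'
#' Computes the two symmetric pairwise matrices once; every alpha on the
#' model-selection grid then only needs the cheap element-wise combination
#' [combineMatrices()], never a recomputation of the warping itself.
#'
#' @param ds a [GrowthDataset-class]; all curves length >= 2 on one scale.
#' @return list with elements `dtw` and `ddtw`, each a
#'   [WarpDistanceMatrix-class].
#' @export
pairwiseMatrices <- function(ds) {
  stopifnot(is(ds, "GrowthDataset"))
  if (length(ds) < 2L) stop("need at least 2 curves")
  ids <- curveIds(ds)
  vals <- lapply(ds@curves, function(g) g@values)
  if (any(vapply(vals, length, integer(1)) < 2L))
    stop("all curves must have length >= 2")
  M1 <- .dtw_pairwise_cpp(vals)
  M2 <- .dtw_pairwise_cpp(lapply(vals, diff))
  dimnames(M1) <- dimnames(M2) <- list(ids, ids)
  list(dtw  = new("WarpDistanceMatrix", values = M1, kind = "dtw",
                  alpha = NA_real_),
       ddtw = new("WarpDistanceMatrix", values = M2, kind = "ddtw",
                  alpha = NA_real_))
}

#' Combine DTW and DDTW matrices at a given alpha
#'
#' Element-wise `(1 - alpha) * M_dtw + alpha * M_ddtw`; the alpha is recorded
#' on the result.
#'
#' @param mDtw,mDdtw [WarpDistanceMatrix-class] objects of kind `"dtw"` and
#'   `"ddtw"` with identical ids.
#' @param alpha weight in `[0, 1]`.
#' @return a [WarpDistanceMatrix-class] of kind `"combined"`.
#' @export
combineMatrices <- function(mDtw, mDdtw, alpha) {
  stopifnot(is(mDtw, "WarpDistanceMatrix"), is(mDdtw, "WarpDistanceMatrix"))
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  if (!identical(rownames(mDtw@values), rownames(mDdtw@values)))
    stop("matrices have mismatched curve ids")
  new("WarpDistanceMatrix",
      values = (1 - alpha) * mDtw@values + alpha * mDdtw@values,
      kind = "combined", alpha = alpha)
}

#' Accessors for WarpDistanceMatrix
#'
#' `distValues()` returns the plain numeric matrix, `distAlpha()` the alpha
#' that produced a combined matrix (`NA` for pure DTW/DDTW), `distKind()`
#' the tag, and `curveIds()` the ids.
#'
#' @param x a [WarpDistanceMatrix-class].
#' @rdname distValues
#' @export
setMethod("distValues", "WarpDistanceMatrix", function(x) x@values)

#' @rdname distValues
setMethod("distAlpha", "WarpDistanceMatrix", function(x) x@alpha)

#' @rdname distValues
setMethod("distKind", "WarpDistanceMatrix", function(x) x@kind)

#' @rdname curveIds
setMethod("curveIds", "WarpDistanceMatrix", function(x) rownames(x@values))

setMethod("show", "WarpDistanceMatrix", function(object) {
  cat(sprintf("WarpDistanceMatrix: %d x %d, kind=%s",
              nrow(object@values), ncol(object@values), object@kind))
  if (object@kind == "combined") cat(sprintf(" (alpha=%g)", object@alpha))
  cat("\n")
})

#' Read and write distance matrices
#'
#' Tab-delimited square matrix with an id header row and id first column,
#' preceded by a comment line `# alpha=<value>` recording the weight
#' (`dtw_only` / `ddtw_only` for the pure matrices).
#'
#' @param x a [WarpDistanceMatrix-class].
#' @param path file path.
#' @return `writeDistanceMatrix` invisibly returns `path`;
#'   `readDistanceMatrix` returns the matrix object.
#' @rdname distanceMatrixIO
#' @export
writeDistanceMatrix <- function(x, path) {
  stopifnot(is(x, "WarpDistanceMatrix"))
  tag <- switch(x@kind, dtw = "dtw_only", ddtw = "ddtw_only",
                format(x@alpha, digits = 15))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# alpha=%s", tag), con)
  writeLines(paste(c("id", colnames(x@values)), collapse = "\t"), con)
  for (i in seq_len(nrow(x@values)))
    writeLines(paste(c(rownames(x@values)[i],
                       format(x@values[i, ], digits = 15, trim = TRUE,
                              scientific = FALSE)), collapse = "\t"), con)
  invisible(path)
}

#' @rdname distanceMatrixIO
#' @export
readDistanceMatrix <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# alpha=", lines[1L]))
    stop("missing '# alpha=' comment line")
  tag <- sub("^# alpha=", "", lines[1L])
  tab <- read.delim(text = lines[-1L], check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (tag == "dtw_only")
    new("WarpDistanceMatrix", values = m, kind = "dtw", alpha = NA_real_)
  else if (tag == "ddtw_only")
    new("WarpDistanceMatrix", values = m, kind = "ddtw", alpha = NA_real_)
  else
    new("WarpDistanceMatrix", values = m, kind = "combined",
        alpha = as.numeric(tag))
}
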