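#' Curve ids of a dataset or curve
#'
#' @param x a [GrowthCurve-class] or [GrowthDataset-class].
#' @return character vector of curve identifiers.
#' @rdname curveIds
#' @export
setMethod("curveIds", "GrowthCurve", function(x) x@curveId)

#' @rdname curveIds
setMethod("curveIds", "GrowthDataset",
  function(x) vapply(x@curves, function(g) g@curveId, character(1)))

#' Metadata label accessors
#'
#' `media()`, `strains()` and `initConcs()` return the per-curve labels,
#' named by curve id; `curveScale()` returns the common scale of the
#' dataset's curves (`"linear"` or `"log"`).
#'
#' @param x a [GrowthDataset-class].
#' @return named character vector (or a single string for `curveScale`).
#' @rdname media
#' @export
setMethod("media", "GrowthDataset", function(x)
  setNames(vapply(x@curves, function(g) g@medium, character(1)), curveIds(x)))

#' @rdname media
setMethod("strains", "GrowthDataset", function(x)
  setNames(vapply(x@curves, function(g) g@strain, character(1)), curveIds(x)))

#' @rdname media
setMethod("initConcs", "GrowthDataset", function(x)
  setNames(vapply(x@curves, function(g) g@initConc, character(1)), curveIds(x)))

#' @rdname media
setMethod("curveScale", "GrowthDataset", function(x) {
  if (length(x@curves) == 0L) return(NA_character_)
  x@curves[[1L]]@scale
})

#' @rdname media
setMethod("curveScale", "GrowthCurve", function(x) x@scale)

#' @describeIn GrowthDataset number of curves.
#' @param x a GrowthDataset.
#' @export
setMethod("length", "GrowthDataset", function(x) length(x@curves))

#' @describeIn GrowthDataset extract one curve by position or id.
#' @param i index or curve id.
#' @export
setMethod("[[", "GrowthDataset", function(x, i) {
  if (is.character(i)) {
    k <- match(i, curveIds(x))
    if (is.na(k)) stop("no curve with id '", i, "'")
    i <- k
  }
  x@curves[[i]]
})

#' @describeIn GrowthDataset subset to a new dataset.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GrowthDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    k <- match(i, curveIds(x))
    if (anyNA(k)) stop("unknown curve id(s): ",
                       paste(i[is.na(k)], collapse = ", "))
    i <- k
  }
  growthDataset(x@curves[i])
})

setMethod("show", "GrowthCurve", function(object) {
  cat(sprintf("GrowthCurve '%s': %d points, %.2g-%.2g h, scale=%s\n",
              object@curveId, length(object@times), min(object@times),
              max(object@times), object@scale))
  cat(sprintf("  strain=%s medium=%s init_conc=%s\n",
              object@strain, object@medium, object@initConc))
})

setMethod("show", "GrowthDataset", function(object) {
  n <- length(object)
  cat(sprintf("GrowthDataset: %d curve%s", n, if (n == 1) "" else "s"))
  if (n > 0) {
    lens <- vapply(object@curves, function(g) length(g@times), integer(1))
    cat(sprintf(" (scale=%s, lengths %d-%d)", curveScale(object),
                min(lens), max(lens)))
    tab <- table(media(object))
    cat("\n  media: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "))
  }
  cat("\n")
})

# ---- reading & writing -----------------------------------------------------

.read_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("curve_id", "strain", "medium", "init_conc")
  if (!all(need %in% names(md)))
    stop("malformed metadata header: need columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(md$curve_id))
    stop("duplicate curve_id in metadata file")
  bad <- setdiff(unique(md$init_conc), .VALID_INITCONC)
  if (length(bad))
    stop("invalid init_conc value(s): ", paste(bad, collapse = ", "))
  md
}

#' Read a growth-curve table
#'
#' Reads OD600 growth curves from a delimited text file in either long layout
#' (columns `curve_id`, `time_h`, `od`) or wide layout (first column `time_h`,
#' one column per curve, named by curve id), with an optional metadata table
#' (`curve_id`, `strain`, `medium`, `init_conc`) attaching labels. Readings
#' that are missing (empty/NA) are dropped point-wise; a curve retaining fewer
#' than two points is rejected with a warning; curves without metadata get
#' label `"unknown"`.
#'
#' @param path path to the curve table (CSV, header required).
#' @param layout `"long"` or `"wide"`.
#' @param metadataPath optional path to the metadata CSV.
#' @return a [GrowthDataset-class] on the linear OD scale.
#' @seealso [writeGrowthTable()], [logTransform()], [thinToInterval()]
#' @export
readGrowthTable <- function(path, layout = c("long", "wide"),
                            metadataPath = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)

  series <- list()  # id -> list(times, values)
  if (layout == "long") {
    need <- c("curve_id", "time_h", "od")
    if (!all(need %in% names(raw)))
      stop("malformed header for long layout: need columns ",
           paste(need, collapse = ", "))
    for (id in unique(raw$curve_id)) {
      rows <- raw[raw$curve_id == id, , drop = FALSE]
      keep <- !is.na(rows$od) & !is.na(rows$time_h)
      rows <- rows[keep, , drop = FALSE]
      rows <- rows[order(rows$time_h), , drop = FALSE]
      if (anyDuplicated(rows$time_h))
        stop("curve '", id, "' has duplicate time points")
      series[[as.character(id)]] <- list(times = rows$time_h, values = rows$od)
    }
  } else {
    if (names(raw)[1L] != "time_h")
      stop("malformed header for wide layout: first column must be time_h")
    ids <- names(raw)[-1L]
    if (length(ids) == 0L) stop("wide layout needs at least one curve column")
    if (anyDuplicated(ids)) stop("duplicate curve_id column in wide table")
    if (anyDuplicated(raw$time_h[!is.na(raw$time_h)]))
      stop("wide table has duplicate time points")
    ord <- order(raw$time_h)
    raw <- raw[ord, , drop = FALSE]
    for (id in ids) {
      keep <- !is.na(raw[[id]]) & !is.na(raw$time_h)
      series[[id]] <- list(times = raw$time_h[keep], values = raw[[id]][keep])
    }
  }

  md <- if (!is.null(metadataPath)) .read_metadata(metadataPath) else NULL
  curves <- list()
  for (id in names(series)) {
    s <- series[[id]]
    if (length(s$times) < 2L) {
      warning("curve '", id, "' rejected: fewer than 2 retained points")
      next
    }
    strain <- medium <- initc <- "unknown"
    if (!is.null(md)) {
      k <- match(id, md$curve_id)
      if (!is.na(k)) {
        strain <- md$strain[k]; medium <- md$medium[k]; initc <- md$init_conc[k]
      }
    }
    curves[[id]] <- growthCurve(id, s$times, s$values, scale = "linear",
                                strain = strain, medium = medium,
                                initConc = initc)
  }
  growthDataset(curves)
}

#' Write a growth-curve table
#'
#' Inverse of [readGrowthTable()]: writes the curves in long or wide layout
#' and, optionally, the metadata table. In wide layout curves are aligned on
#' the union of their time points, with empty cells where a curve has no
#' reading.
#'
#' @param ds a [GrowthDataset-class].
#' @param path output CSV path.
#' @param layout `"long"` or `"wide"`.
#' @param metadataPath optional path for the metadata CSV.
#' @return invisibly, `path`.
#' @export
writeGrowthTable <- function(ds, path, layout = c("long", "wide"),
                             metadataPath = NULL) {
  layout <- match.arg(layout)
  ids <- curveIds(ds)
  if (layout == "long") {
    df <- do.call(rbind, lapply(ds@curves, function(g)
      data.frame(curve_id = g@curveId, time_h = g@times, od = g@values)))
    if (is.null(df)) df <- data.frame(curve_id = character(),
                                      time_h = numeric(), od = numeric())
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    times <- sort(unique(unlist(lapply(ds@curves, function(g) g@times))))
    df <- data.frame(time_h = times)
    for (g in ds@curves)
      df[[g@curveId]] <- g@values[match(times, g@times)]
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  }
  if (!is.null(metadataPath)) {
    md <- data.frame(curve_id = ids, strain = unname(strains(ds)),
                     medium = unname(media(ds)),
                     init_conc = unname(initConcs(ds)))
    write.csv(md, metadataPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# ---- preprocessing ---------------------------------------------------------

#' Log-transform OD readings
#'
#' Converts a linear-scale curve to a logarithmic scale, reflecting the
#' multiplicative nature of binary-fission growth. Values at or below
#' `floorEpsilon` are floored at `floorEpsilon` before taking the logarithm,
#' so zero or near-blank readings survive as finite values instead of being
#' dropped.
#'
#' Downstream cluster partitions are invariant to the choice of `base`:
#' changing base rescales every log curve, hence every DTW/DDTW distance, by
#' one positive constant, which Ward's linkage ignores.
#'
#' @param x a [GrowthCurve-class] or [GrowthDataset-class] on the linear scale.
#' @param base logarithm base (default 10, the OD convention).
#' @param floorEpsilon positive floor applied before the log (default 1e-3).
#' @return the transformed object with `scale == "log"`.
#' @rdname logTransform
#' @export
setMethod("logTransform", "GrowthCurve", function(x, base = 10,
                                                  floorEpsilon = 1e-3) {
  if (x@scale != "linear")
    stop("curve '", x@curveId, "' is already on the log scale")
  if (base <= 0 || base == 1) stop("base must be positive and != 1")
  if (floorEpsilon <= 0) stop("floorEpsilon must be positive")
  v <- pmax(x@values, floorEpsilon)
  initialize(x, values = log(v, base = base), scale = "log")
})

#' @rdname logTransform
setMethod("logTransform", "GrowthDataset", function(x, base = 10,
                                                    floorEpsilon = 1e-3) {
  growthDataset(lapply(x@curves, logTransform, base = base,
                       floorEpsilon = floorEpsilon))
})

#' Thin a curve to a coarser sampling interval
#'
#' Reduces a densely sampled curve to one reading per `interval` hours, so
#' that curves recorded at different cadences (e.g. 30 min in rich medium,
#' 1 h in minimal media) become comparable index-by-index. A reading is
#' assigned to grid point `k * interval` when its time is within
#' `interval / 10` of it; among several candidates the nearest wins, with the
#' earlier time on ties. Thinning is idempotent: a curve already on the grid
#' is returned unchanged.
#'
#' @param x a [GrowthCurve-class] or [GrowthDataset-class].
#' @param interval target sampling interval in hours; must be no smaller than
#'   the curve's native spacing.
#' @return the thinned object.
#' @rdname thinToInterval
#' @export
setMethod("thinToInterval", "GrowthCurve", function(x, interval) {
  if (interval <= 0) stop("interval must be positive")
  if (min(diff(x@times)) > interval * (1 + 1e-9))
    stop("curve '", x@curveId, "': native spacing exceeds target interval")
  tol <- interval / 10
  kmax <- floor((max(x@times) + tol) / interval)
  keep <- integer(0)
  for (k in 0:kmax) {
    off <- abs(x@times - k * interval)
    cand <- which(off <= tol + 1e-12)
    if (length(cand)) {
      # nearest to the grid point; earlier time wins ties
      best <- cand[order(off[cand], x@times[cand])][1L]
      keep <- c(keep, best)
    }
  }
  keep <- unique(keep)
  if (length(keep) < 2L)
    stop("curve '", x@curveId, "': fewer than 2 points survive thinning")
  initialize(x, times = x@times[keep], values = x@values[keep])
})

#' @rdname thinToInterval
setMethod("thinToInterval", "GrowthDataset", function(x, interval) {
  growthDataset(lapply(x@curves, thinToInterval, interval = interval))
})

#' Validate a growth-curve collection
#'
#' Reporting-only inspection of a dataset (or plain list of curves): curve
#' counts per medium, range of curve lengths, the set of sampling intervals
#' present, and any invariant violations (e.g. mixed linear/log scales).
#' Never mutates its input.
#'
#' @param ds a [GrowthDataset-class] or a list of [GrowthCurve-class].
#' @return a list with elements `nCurves`, `perMedium` (named integer),
#'   `lengthRange`, `intervals`, `violations` (character vector, empty when
#'   clean).
#' @export
validateDataset <- function(ds) {
  curves <- if (is(ds, "GrowthDataset")) ds@curves else ds
  violations <- character()
  if (length(curves) == 0L)
    return(list(nCurves = 0L, perMedium = integer(0),
                lengthRange = c(NA_integer_, NA_integer_),
                intervals = numeric(0), violations = violations))
  ids <- vapply(curves, function(g) g@curveId, character(1))
  if (anyDuplicated(ids))
    violations <- c(violations, "duplicate curve ids")
  scales <- unique(vapply(curves, function(g) g@scale, character(1)))
  if (length(scales) > 1L)
    violations <- c(violations, "mixed scales (linear and log)")
  lens <- vapply(curves, function(g) length(g@times), integer(1))
  if (any(lens < 2L))
    violations <- c(violations, "curve(s) with fewer than 2 points")
  meds <- vapply(curves, function(g) g@medium, character(1))
  tab <- table(meds)
  ivals <- sort(unique(round(unlist(lapply(curves,
                                           function(g) diff(g@times))), 6)))
  list(nCurves = length(curves),
       perMedium = setNames(as.integer(tab), names(tab)),
       lengthRange = range(lens),
       intervals = ivals,
       violations = violations)
}
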