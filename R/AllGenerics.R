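#' @rdname curveIds
#' @export
setGeneric("curveIds", function(x) standardGeneric("curveIds"))

#' @rdname logTransform
#' @export
setGeneric("logTransform",
  function(x, base = 10, floorEpsilon = 1e-3) standardGeneric("logTransform"))

#' @rdname thinToInterval
#' @export
setGeneric("thinToInterval",
  function(x, interval) standardGeneric("thinToInterval"))

#' @rdname media
#' @export
setGeneric("media", function(x) standardGeneric("media"))

#' @rdname media
#' @export
setGeneric("strains", function(x) standardGeneric("strains"))

#' @rdname media
#' @export
setGeneric("initConcs", function(x) standardGeneric("initConcs"))

#' @rdname media
#' @export
setGeneric("curveScale", function(x) standardGeneric("curveScale"))

#' @rdname distValues
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))

#' @rdname distValues
#' @export
setGeneric("distAlpha", function(x) standardGeneric("distAlpha"))

#' @rdname distValues
#' @export
setGeneric("distKind", function(x) standardGeneric("distKind"))

#' Score table of a grid result
#'
#' The per-cell data.frame of a [GrowthGridResult-class]: one row per
#' (alpha, N) combination with columns `alpha`, `n_clusters`, `ari`, `ami`,
#' `v`, `h`, `c`, `sc`, `errors`.
#'
#' @param x a [GrowthGridResult-class].
#' @return a data.frame.
#' @rdname gridScores
#' @export
setGeneric("gridScores", function(x) standardGeneric("gridScores"))
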