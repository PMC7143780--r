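#' Majority-vote error count of a clustering
#'
#' The simple benchmark used for model selection: within each cluster the
#' medium of the majority is taken as the truth, and every curve of any
#' other medium in that cluster is an error. Note that one medium may
#' legitimately occupy several clusters — errors are counted per cluster,
#' never by forcing one cluster per medium. Fewer errors mean better
#' clustering.
#'
#' Majority ties within a cluster go to the medium with the larger
#' dataset-wide count, remaining ties break lexicographically, so the count
#' is deterministic.
#'
#' @param assignment named integer vector, curve id -> cluster.
#' @param labels named character vector, curve id -> medium; every assigned
#'   id must be labelled.
#' @return list with `perCluster` (data.frame: `cluster`, `size`,
#'   `majority`, `errors`), `perMedium` (named integer vector attributing
#'   each error to the erring curve's own medium), and `total`.
#' @export
errorCount <- function(assignment, labels) {
  ids <- names(assignment)
  if (is.null(ids)) stop("assignment must be named by curve id")
  lab <- labels[ids]
  if (anyNA(lab)) stop("missing medium label for: ",
                       paste(ids[is.na(lab)], collapse = ", "))
  lab <- as.character(lab)
  globalCount <- table(lab)
  clusters <- sort(unique(assignment))
  media <- sort(unique(lab))
  perMedium <- setNames(integer(length(media)), media)
  rows <- lapply(clusters, function(cl) {
    inCl <- lab[assignment == cl]
    cnt <- table(inCl)
    top <- max(cnt)
    cand <- names(cnt)[cnt == top]
    if (length(cand) > 1L) {  # larger dataset-wide medium wins, then name
      g <- as.numeric(globalCount[cand])
      cand <- cand[order(-g, cand)]
    }
    maj <- cand[1L]
    err <- inCl[inCl != maj]
    data.frame(cluster = cl, size = length(inCl), majority = maj,
               errors = length(err), stringsAsFactors = FALSE)
  })
  for (cl in clusters) {
    inCl <- lab[assignment == cl]
    maj <- rows[[match(cl, clusters)]]$majority
    errTab <- table(inCl[inCl != maj])
    perMedium[names(errTab)] <- perMedium[names(errTab)] + as.integer(errTab)
  }
  perCluster <- do.call(rbind, rows)
  list(perCluster = perCluster, perMedium = perMedium,
       total = sum(perCluster$errors))
}

#' Grid search over the alpha weight and the cluster count
#'
#' Evaluates every (alpha, N) combination: the pairwise DTW and DDTW
#' matrices are computed once; for each alpha the two are combined
#' element-wise and clustered with one Ward linkage; each N is then a cut of
#' that dendrogram, scored with the four benchmarks and the majority-vote
#' error count.
#'
#' Defaults follow the study design: alpha from 0 to 1 in steps of 0.01
#' (101 values) and N from 2 to 28 (27 values).
#'
#' @param ds a preprocessed [GrowthDataset-class] (log scale, common
#'   sampling interval).
#' @param labels named character vector, curve id -> medium; defaults to the
#'   dataset's medium labels.
#' @param alphaGrid numeric vector of weights in `[0, 1]`.
#' @param nRange integer vector of cluster counts in
#'   `[2, length(ds)]`.
#' @return a [GrowthGridResult-class].
#' @export
gridSearch <- function(ds, labels = media(ds),
                       alphaGrid = seq(0, 1, by = 0.01), nRange = 2:28) {
  stopifnot(is(ds, "GrowthDataset"))
  if (any(alphaGrid < 0 | alphaGrid > 1)) stop("alphaGrid must lie in [0, 1]")
  nRange <- as.integer(nRange)
  if (any(nRange < 2L) || any(nRange > length(ds)))
    stop("nRange must lie in [2, number of curves]")
  mats <- pairwiseMatrices(ds)
  rows <- vector("list", length(alphaGrid) * length(nRange))
  k <- 0L
  for (alpha in alphaGrid) {
    Dc <- combineMatrices(mats$dtw, mats$ddtw, alpha)
    hc <- wardLinkage(Dc)
    for (N in nRange) {
      cl <- cutToClusters(hc, N)
      sc <- scoreAll(Dc, cl, labels)
      err <- errorCount(cl, labels)$total
      k <- k + 1L
      rows[[k]] <- data.frame(alpha = alpha, n_clusters = N,
                              ari = sc[["ari"]], ami = sc[["ami"]],
                              v = sc[["v"]], h = sc[["h"]], c = sc[["c"]],
                              sc = sc[["sc"]], errors = err)
    }
  }
  new("GrowthGridResult", grid = do.call(rbind, rows),
      alphaGrid = as.numeric(alphaGrid), nRange = nRange,
      nCurves = length(ds))
}

#' @rdname gridScores
#' @export
setMethod("gridScores", "GrowthGridResult", function(x) x@grid)

setMethod("show", "GrowthGridResult", function(object) {
  cat(sprintf(
    "GrowthGridResult: %d alpha x %d N cells over %d curves (min errors %d)\n",
    length(object@alphaGrid), length(object@nRange), object@nCurves,
    min(object@grid$errors)))
})

#' Best grid cell by a statistical benchmark
#'
#' The (alpha, N) cell maximizing the chosen benchmark; ties go to the
#' smallest N, then the smallest alpha.
#'
#' @param grid a [GrowthGridResult-class].
#' @param which one of `"ari"`, `"ami"`, `"v"`, `"sc"`.
#' @return list with `alpha`, `n_clusters` and `score`.
#' @export
bestByBenchmark <- function(grid, which = c("ari", "ami", "v", "sc")) {
  which <- match.arg(which)
  g <- gridScores(grid)
  if (nrow(g) == 0L) stop("empty grid")
  best <- max(g[[which]])
  cand <- g[g[[which]] == best, , drop = FALSE]
  cand <- cand[order(cand$n_clusters, cand$alpha), , drop = FALSE]
  list(alpha = cand$alpha[1L], n_clusters = cand$n_clusters[1L],
       score = best)
}

#' Per-N minimum of the error count over alpha
#'
#' For each cluster count N on the grid, the minimum majority-vote error
#' count over the alpha grid and the largest alpha attaining it (the
#' largest-alpha convention matches how a constant-alpha plateau across N is
#' read off this profile).
#'
#' @param grid a [GrowthGridResult-class] covering at least 2 values of N.
#' @return data.frame with columns `n_clusters`, `min_errors`, `alpha` —
#'   one row per N, no gaps.
#' @export
minErrorProfile <- function(grid) {
  g <- gridScores(grid)
  ns <- sort(unique(g$n_clusters))
  if (length(ns) < 2L) stop("profile needs at least 2 values of N")
  rows <- lapply(ns, function(N) {
    sub <- g[g$n_clusters == N, , drop = FALSE]
    e <- min(sub$errors)
    data.frame(n_clusters = N, min_errors = e,
               alpha = max(sub$alpha[sub$errors == e]))
  })
  do.call(rbind, rows)
}

#' Knee-based selection of (alpha, N) on the error profile
#'
#' Operationalises "the errors decreased most significantly" as the largest
#' single-step drop of the per-N minimum error profile: the selected N is
#' the value immediately after that drop (ties to the smallest N), avoiding
#' the over-clustering that chasing the global error minimum at large N
#' produces. The selected alpha is the largest alpha attaining the minimum
#' at the selected N.
#'
#' @param profile output of [minErrorProfile()] over at least 3 consecutive
#'   N values.
#' @return list with `alpha`, `n_clusters` and `errors` (the achieved
#'   minimum at the selected N).
#' @export
selectByErrorKnee <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("n_clusters", "min_errors", "alpha") %in% names(profile)))
  profile <- profile[order(profile$n_clusters), , drop = FALSE]
  if (nrow(profile) < 3L) stop("need a profile over at least 3 values of N")
  drops <- -diff(profile$min_errors)   # e(N-1) - e(N) for each step
  maxDrop <- max(drops)
  if (maxDrop < 0)
    stop("no knee: the error profile is monotone increasing")
  if (maxDrop == 0)
    warning("flat error profile: selecting the smallest N after a zero drop")
  k <- which(drops == maxDrop)[1L]
  sel <- profile[k + 1L, ]
  list(alpha = sel$alpha, n_clusters = sel$n_clusters,
       errors = sel$min_errors)
}

#' Largest alpha per N at a given error level
#'
#' Diagnostic for reading an alpha plateau off the grid: for each N, the
#' largest alpha whose error count is at most `E` (NA where no alpha
#' attains it). A constant, maximal alpha over a range of N supports the
#' chosen cluster count.
#'
#' @param grid a [GrowthGridResult-class].
#' @param E non-negative integer error budget.
#' @return data.frame with columns `n_clusters`, `alpha` (NA where `E` is
#'   unattainable at that N).
#' @export
alphaProfileAtErrorLevel <- function(grid, E) {
  if (length(E) != 1L || is.na(E) || E < 0) stop("E must be a non-negative integer")
  g <- gridScores(grid)
  ns <- sort(unique(g$n_clusters))
  rows <- lapply(ns, function(N) {
    sub <- g[g$n_clusters == N & g$errors <= E, , drop = FALSE]
    data.frame(n_clusters = N,
               alpha = if (nrow(sub)) max(sub$alpha) else NA_real_)
  })
  do.call(rbind, rows)
}
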