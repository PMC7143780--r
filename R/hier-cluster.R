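#' Ward agglomerative clustering of a distance matrix
#'
#' Bottom-up clustering with Ward's minimum-variance criterion on a
#' precomputed dissimilarity matrix. At each step the pair of active clusters
#' with minimal Ward dissimilarity is merged, and dissimilarities to the new
#' cluster are updated by the Lance-Williams recurrence
#' `d(k,l) = ((n_i + n_l) d(i,l) + (n_j + n_l) d(j,l) - n_l d(i,j)) /
#' (n_i + n_j + n_l)` applied to the stored values (no squaring or square
#' root). Treating a warping dissimilarity as a squared-Euclidean surrogate
#' in this recurrence is the convention of the standard hierarchical
#' clustering stacks; it is a known theoretical caveat, documented rather
#' than hidden.
#'
#' One linkage pass serves every cut: compute the dendrogram once, then call
#' [cutToClusters()] for each N.
#'
#' @param D a [WarpDistanceMatrix-class] or a symmetric numeric matrix with
#'   zero diagonal and id dimnames.
#' @return an object of class [stats::hclust] with curve ids as labels.
#'   Merge heights are non-decreasing for Ward on a valid dissimilarity; a
#'   violation triggers a warning, not an error.
#' @examples
#' D <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' hc <- wardLinkage(D)
#' hc$height  # 1, then 13 by the Lance-Williams update
#' @export
wardLinkage <- function(D) {
  m <- if (is(D, "WarpDistanceMatrix")) distValues(D) else as.matrix(D)
  if (nrow(m) != ncol(m) || nrow(m) < 2L)
    stop("need a square matrix of dimension >= 2")
  if (anyNA(m) || any(m < 0)) stop("distances must be non-negative")
  if (any(abs(m - t(m)) > 1e-8 * (1 + max(abs(m)))))
    stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("diagonal must be zero")
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("c", seq_len(nrow(m)))
  hc <- hclust(as.dist(m), method = "ward.D")
  if (any(diff(hc$height) < -1e-8 * (1 + max(hc$height))))
    warning("non-monotone merge heights: the dissimilarity is not Ward-compatible")
  hc
}

#' Cut a dendrogram into N flat clusters
#'
#' Undoes the last `N - 1` merges of a Ward dendrogram and relabels the
#' resulting groups 1..N in order of first leaf appearance, so labels are
#' stable and deterministic.
#'
#' @param hc an [stats::hclust] object from [wardLinkage()].
#' @param N number of clusters, `2 <= N <=` number of leaves.
#' @return named integer vector mapping curve id to cluster index in 1..N.
#' @export
cutToClusters <- function(hc, N) {
  stopifnot(inherits(hc, "hclust"))
  nLeaves <- length(hc$labels)
  if (length(N) != 1L || is.na(N) || N != round(N) || N < 2 || N > nLeaves)
    stop("N must be an integer in [2, number of leaves]")
  cl <- cutree(hc, k = N)
  # relabel 1..N by first appearance in input order
  relab <- match(cl, unique(cl))
  setNames(as.integer(relab), names(cl))
}
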