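#' Cluster-by-category contingency table
#'
#' Cross-tabulates a flat clustering against external category labels
#' (typically the growth medium). Rows are clusters, columns categories;
#' entry (j, i) counts the curves of cluster j carrying category i. The row
#' and column marginals and the grand total are what the chance-corrected
#' agreement indices operate on.
#'
#' @param assignment named integer vector (curve id -> cluster index), as
#'   returned by [cutToClusters()].
#' @param labels named character vector (curve id -> category); every
#'   assigned id must be labelled.
#' @return an integer matrix of class `table` with dimnames
#'   `cluster`/`category`.
#' @export
contingencyTable <- function(assignment, labels) {
  ids <- names(assignment)
  if (is.null(ids)) stop("assignment must be named by curve id")
  lab <- labels[ids]
  if (anyNA(lab) || (!is.null(names(labels)) && any(!ids %in% names(labels))))
    stop("missing category label for: ",
         paste(ids[is.na(lab)], collapse = ", "))
  table(cluster = factor(assignment), category = factor(lab))
}

.as_count_matrix <- function(ct) {
  m <- as.matrix(unclass(ct))
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  m
}

# TRUE when the two partitions encoded by the table are identical up to
# relabelling: each row and each column has exactly one non-zero entry.
.identical_partitions <- function(m) {
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  all(rowSums(m > 0) == 1) && all(colSums(m > 0) == 1)
}

.entropy <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Silhouette analysis on a precomputed distance matrix
#'
#' For each curve i, `a(i)` is the mean distance to the other members of its
#' own cluster and `b(i)` the smallest mean distance to any other cluster;
#' the silhouette is `1 - a/b` when `a < b`, `0` when `a = b`, and
#' `b/a - 1` when `a > b`, always in `[-1, 1]`. Members of singleton
#' clusters, for which `a(i)` is undefined, get silhouette 0 by convention,
#' so the coefficient stays defined for every cut. The silhouette
#' coefficient SC is the mean over all curves.
#'
#' @param D a [WarpDistanceMatrix-class] or symmetric numeric matrix whose
#'   ids cover the assignment.
#' @param assignment named integer vector (curve id -> cluster), N >= 2
#'   clusters.
#' @return list with `widths` (data.frame: `curve_id`, `cluster`, `a`, `b`,
#'   `s`) and `sc`, the mean silhouette.
#' @export
silhouetteScore <- function(D, assignment) {
  m <- if (is(D, "WarpDistanceMatrix")) distValues(D) else as.matrix(D)
  ids <- names(assignment)
  if (is.null(ids)) stop("assignment must be named by curve id")
  if (!all(ids %in% rownames(m))) stop("distance matrix does not cover all ids")
  m <- m[ids, ids, drop = FALSE]
  cl <- as.integer(factor(assignment))
  N <- max(cl)
  if (N < 2L) stop("silhouette needs at least 2 clusters")
  n <- length(cl)
  Z <- matrix(0, n, N); Z[cbind(seq_len(n), cl)] <- 1
  sizes <- colSums(Z)
  S <- m %*% Z                       # total distance from i to each cluster
  own <- S[cbind(seq_len(n), cl)]
  a <- ifelse(sizes[cl] > 1, own / (sizes[cl] - 1), NA_real_)
  meanOther <- sweep(S, 2, sizes, "/")
  meanOther[cbind(seq_len(n), cl)] <- Inf
  b <- apply(meanOther, 1, min)
  s <- numeric(n)
  single <- is.na(a)
  gt <- !single & a > b
  lt <- !single & a < b
  s[lt] <- 1 - a[lt] / b[lt]
  s[gt] <- b[gt] / a[gt] - 1
  # a == b (and singletons) stay 0
  list(widths = data.frame(curve_id = ids, cluster = assignment,
                           a = a, b = b, s = s, row.names = NULL),
       sc = mean(s))
}

#' Adjusted Rand index from a contingency table
#'
#' Pair-counting agreement between the clustering and the categories,
#' corrected for chance:
#' `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)` and
#' `max = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. Returns 1 when numerator
#' equals denominator (identical partitions) and 0 when the denominator is 0.
#'
#' @param ct contingency table (see [contingencyTable()]), grand total >= 2.
#' @return a real number <= 1; approximately 0 for random labellings.
#' @export
adjustedRandIndex <- function(ct) {
  m <- .as_count_matrix(ct)
  n <- sum(m)
  if (n < 2) stop("need a table with at least 2 items")
  sij <- sum(choose(m, 2))
  sa <- sum(choose(rowSums(m), 2))
  sb <- sum(choose(colSums(m), 2))
  expected <- sa * sb / choose(n, 2)
  num <- sij - expected
  den <- (sa + sb) / 2 - expected
  tol <- 1e-12 * (1 + abs(den))
  if (abs(num - den) <= tol) return(1)
  if (abs(den) <= tol) return(0)
  num / den
}

# Expected mutual information under the fixed-marginals permutation
# (generalized hypergeometric) model; natural log.
.expected_mi <- function(a, b, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
            lgamma(n - bj + 1) - lgn - lgamma(nij + 1) -
            lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
            lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * exp(lp))
    }
  }
  emi
}

#' Adjusted mutual information from a contingency table
#'
#' `AMI = (MI - E[MI]) / (max(H(C), H(G)) - E[MI])`, where MI is the mutual
#' information between the cluster and category partitions, H their
#' entropies (natural log), and E[MI] the expectation of MI over all tables
#' with the same marginals under the permutation model. Identical partitions
#' give exactly 1; a degenerate denominator (e.g. one partition in a single
#' cluster) gives 0.
#'
#' @param ct contingency table, grand total >= 2.
#' @return a real number <= 1; approximately 0 for random labellings.
#' @export
adjustedMutualInformation <- function(ct) {
  m <- .as_count_matrix(ct)
  n <- sum(m)
  if (n < 2) stop("need a table with at least 2 items")
  if (.identical_partitions(m)) return(1)
  a <- rowSums(m); b <- colSums(m)
  nz <- m > 0
  mi <- sum((m[nz] / n) * log(n * m[nz] /
                              (outer(a, b)[nz])))
  hC <- .entropy(a); hG <- .entropy(b)
  emi <- .expected_mi(a[a > 0], b[b > 0], n)
  den <- max(hC, hG) - emi
  if (abs(den) <= 1e-12) return(0)
  (mi - emi) / den
}

#' V-measure: homogeneity, completeness and their harmonic mean
#'
#' Homogeneity `h = 1 - H(category|cluster) / H(category)` is 1 when every
#' cluster contains a single category; completeness
#' `c = 1 - H(cluster|category) / H(cluster)` is 1 when every category lands
#' in a single cluster; `V = 2hc / (h + c)`. When the reference entropy is 0
#' the corresponding component is 1 by convention; when `h + c = 0`, V is 0.
#'
#' @param ct contingency table, grand total >= 1.
#' @return named numeric vector `c(h = , c = , v = )`, all in `[0, 1]`.
#' @export
vMeasure <- function(ct) {
  m <- .as_count_matrix(ct)
  n <- sum(m)
  if (n < 1) stop("empty contingency table")
  a <- rowSums(m)  # clusters
  b <- colSums(m)  # categories
  hCat <- .entropy(b)
  hClu <- .entropy(a)
  nz <- m > 0
  # H(category | cluster) and H(cluster | category)
  hCatGivenClu <- -sum((m[nz] / n) * log(m[nz] / a[row(m)[nz]]))
  hCluGivenCat <- -sum((m[nz] / n) * log(m[nz] / b[col(m)[nz]]))
  h <- if (hCat == 0) 1 else 1 - hCatGivenClu / hCat
  cc <- if (hClu == 0) 1 else 1 - hCluGivenCat / hClu
  v <- if (h + cc == 0) 0 else 2 * h * cc / (h + cc)
  c(h = h, c = cc, v = v)
}

#' All four goodness-of-clustering statistics at once
#'
#' Computes the internal benchmark (silhouette coefficient, from the
#' distance matrix) and the three external benchmarks (ARI, AMI, V-measure,
#' from the cluster-vs-category contingency table) for one partition. All
#' four increase towards 1 as the clustering agrees better with the
#' categories / the metric structure.
#'
#' @param D distance matrix covering the assignment (see
#'   [silhouetteScore()]).
#' @param assignment named integer vector, curve id -> cluster.
#' @param labels named character vector, curve id -> category.
#' @return named numeric vector with elements `ari`, `ami`, `v`, `h`, `c`,
#'   `sc`.
#' @export
scoreAll <- function(D, assignment, labels) {
  ct <- contingencyTable(assignment, labels)
  vm <- vMeasure(ct)
  c(ari = adjustedRandIndex(ct),
    ami = adjustedMutualInformation(ct),
    v = unname(vm["v"]), h = unname(vm["h"]), c = unname(vm["c"]),
    sc = silhouetteScore(D, assignment)$sc)
}
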