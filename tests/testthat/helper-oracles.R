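# Independent oracles used by the unit and acceptance tests. These never call
# the package's own DP / closed-form code paths.

# Minimum warping-path cost by explicit enumeration of all monotone paths
# from (1,1) to (n,m) with steps (1,0), (0,1), (1,1); local cost |a-b|.
# Branch-and-bound pruning is sound because local costs are non-negative.
dtw_path_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + abs(x[i] - y[j])
    if (acc >= best) return(invisible(NULL))
    if (i == n && j == m) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

# Expected mutual information under the fixed-marginals permutation model,
# computed by enumerating every admissible cell count weighted by dhyper().
emi_hyper_oracle <- function(rowMarg, colMarg, n) {
  emi <- 0
  for (ai in rowMarg) {
    for (bj in colMarg) {
      for (nij in max(1, ai + bj - n):min(ai, bj)) {
        if (nij < 1) next
        p <- stats::dhyper(nij, ai, n - ai, bj)
        emi <- emi + p * (nij / n) * log(n * nij / (ai * bj))
      }
    }
  }
  emi
}

# AMI recomputed from a plain count matrix using the enumeration E[MI].
ami_oracle <- function(m) {
  n <- sum(m)
  a <- rowSums(m); b <- colSums(m)
  nz <- m > 0
  mi <- sum((m[nz] / n) * log(n * m[nz] / outer(a, b)[nz]))
  ent <- function(x) { p <- x[x > 0] / n; -sum(p * log(p)) }
  emi <- emi_hyper_oracle(a[a > 0], b[b > 0], n)
  den <- max(ent(a), ent(b)) - emi
  if (abs(den) < 1e-12) return(0)
  (mi - emi) / den
}

# Reference ARI/AMI/V from scikit-learn for a list of label/cluster pairs.
# Returns a data.frame(ari, ami, v) or NULL if python is unavailable.
sklearn_reference <- function(cases) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  script <- tempfile(fileext = ".py")
  jsonlite::write_json(
    lapply(cases, function(cs)
      list(labels = as.integer(factor(cs$labels)),
           clusters = as.integer(cs$clusters))),
    infile)
  writeLines(c(
    "import sys, json",
    "from sklearn.metrics import adjusted_rand_score, \\",
    "    adjusted_mutual_info_score, homogeneity_completeness_v_measure",
    "cases = json.load(open(sys.argv[1]))",
    "out = []",
    "for cs in cases:",
    "    lab, clu = cs['labels'], cs['clusters']",
    "    h, c, v = homogeneity_completeness_v_measure(lab, clu)",
    "    out.append({'ari': adjusted_rand_score(lab, clu),",
    "                'ami': adjusted_mutual_info_score(lab, clu,",
    "                                                  average_method='max'),",
    "                'v': v})",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  status <- system2(py, c(script, infile, outfile), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0L || !file.exists(outfile)) return(NULL)
  res <- jsonlite::fromJSON(outfile)
  as.data.frame(res)
}
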