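# identical-partition tables short-circuit to 1; everything else goes through
# the closed form, which the enumeration oracle checks below
.row_col_identical <- function(m) {
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  all(rowSums(m > 0) == 1) && all(colSums(m > 0) == 1)
}

.as_table_perm <- function(ct) {
  m <- unclass(ct)
  as.table(m[sample(nrow(m)), sample(ncol(m)), drop = FALSE])
}

test_that("contingency table cross-tabulates clusters and categories", {
  asg <- named_assignment(c("a", "b", "c", "d"), c(1, 1, 2, 2))
  lab <- c(a = "LB", b = "LB", c = "M63", d = "M63")
  ct <- contingencyTable(asg, lab)
  expect_equal(as.vector(unclass(ct)), c(2L, 0L, 0L, 2L))
  expect_equal(sum(ct), 4L)

  one <- contingencyTable(asg, c(a = "LB", b = "LB", c = "LB", d = "LB"))
  expect_equal(dim(one), c(2L, 1L))
  expect_equal(sum(one), 4L)

  expect_error(contingencyTable(asg, lab[1:3]), "missing")
})

test_that("silhouette follows the piecewise definition and its conventions", {
  D <- matrix(c(0, 0, 5, 5,
                0, 0, 5, 5,
                5, 5, 0, 0,
                5, 5, 0, 0), 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  asg <- named_assignment(letters[1:4], c(1, 1, 2, 2))
  res <- silhouetteScore(D, asg)
  expect_equal(res$widths$s, rep(1, 4))   # a = 0 < b = 5
  expect_equal(res$sc, 1)

  # a == b: middle branch gives exactly 0
  Dflat <- matrix(3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Dflat) <- 0
  expect_equal(silhouetteScore(Dflat, asg)$widths$s, rep(0, 4))

  # singleton cluster scores 0 by convention
  asg3 <- named_assignment(letters[1:4], c(1, 1, 2, 3))
  res3 <- silhouetteScore(D, asg3)
  expect_equal(res3$widths$s[3:4], c(0, 0))

  # always within [-1, 1]
  set.seed(5)
  for (i in 1:10) {
    n <- 12
    M <- matrix(runif(n * n, 0, 4), n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(paste0("s", 1:n), paste0("s", 1:n))
    asgr <- named_assignment(paste0("s", 1:n), sample(1:3, n, replace = TRUE))
    if (length(unique(asgr)) < 2) next
    s <- silhouetteScore(M, asgr)$widths$s
    expect_true(all(s >= -1 & s <= 1))
  }
  expect_error(silhouetteScore(D, named_assignment(letters[1:4], rep(1, 4))),
               "2 clusters")
})

test_that("adjusted Rand index matches hand-derived values", {
  perfect <- contingencyTable(named_assignment(letters[1:4], c(1, 1, 2, 2)),
                              setNames(c("A", "A", "B", "B"), letters[1:4]))
  expect_equal(adjustedRandIndex(perfect), 1)

  # one partition a single cluster: index equals its expectation -> 0
  single <- contingencyTable(named_assignment(letters[1:5], rep(1, 5)),
                             setNames(c("A", "A", "B", "B", "B"), letters[1:5]))
  expect_equal(adjustedRandIndex(single), 0)

  # labels (A,A,B,B,B), clusters ({1,2,3},{4,5}): (2 - 1.6)/(4 - 1.6) = 1/6
  ct <- contingencyTable(named_assignment(letters[1:5], c(1, 1, 1, 2, 2)),
                         setNames(c("A", "A", "B", "B", "B"), letters[1:5]))
  expect_equal(adjustedRandIndex(ct), 1 / 6)
})

test_that("AMI agrees with the hypergeometric enumeration oracle on all small 2x2 tables", {
  for (n in 2:8) {
    for (a1 in 0:n) {
      for (b1 in 0:n) {
        for (n11 in max(0, a1 + b1 - n):min(a1, b1)) {
          m <- matrix(c(n11, a1 - n11, b1 - n11, n - a1 - b1 + n11), 2,
                      byrow = TRUE)
          if (any(m < 0)) next
          if (.row_col_identical(m)) next  # short-circuits to exactly 1
          expect_equal(adjustedMutualInformation(as.table(m)),
                       ami_oracle(m), tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("AMI endpoints: identical partitions give 1, a single cluster gives 0", {
  ids <- paste0("s", 1:6)
  lab <- setNames(rep(c("A", "B", "C"), each = 2), ids)
  same <- contingencyTable(named_assignment(ids, rep(1:3, each = 2)), lab)
  expect_equal(adjustedMutualInformation(same), 1)
  lump <- contingencyTable(named_assignment(ids, rep(1, 6)), lab)
  expect_equal(adjustedMutualInformation(lump), 0)
})

test_that("V-measure separates homogeneity from completeness", {
  ids <- paste0("s", 1:4)
  lab <- setNames(c("A", "A", "B", "B"), ids)
  same <- contingencyTable(named_assignment(ids, c(1, 1, 2, 2)), lab)
  expect_equal(unname(vMeasure(same)), c(1, 1, 1))

  # interleaved: within each cluster the categories split 50/50
  inter <- contingencyTable(named_assignment(ids, c(1, 2, 1, 2)), lab)
  expect_equal(unname(vMeasure(inter)), c(0, 0, 0))

  # pure clusters but one category split over two clusters
  ids6 <- paste0("s", 1:6)
  lab6 <- setNames(c("A", "A", "A", "A", "B", "B"), ids6)
  split <- contingencyTable(named_assignment(ids6, c(1, 1, 2, 2, 3, 3)), lab6)
  vm <- vMeasure(split)
  expect_equal(unname(vm["h"]), 1)
  expect_lt(vm["c"], 1)
  expect_gt(vm["v"], 0)
  expect_lt(vm["v"], 1)
})

test_that("indices are invariant to relabelling clusters and categories", {
  set.seed(17)
  ids <- paste0("s", 1:20)
  for (i in 1:10) {
    asg <- named_assignment(ids, sample(1:4, 20, replace = TRUE))
    lab <- setNames(sample(c("x", "y", "z"), 20, replace = TRUE), ids)
    if (length(unique(asg)) < 2 || length(unique(lab)) < 2) next
    ct <- contingencyTable(asg, lab)
    m <- .as_table_perm(ct)
    expect_equal(adjustedRandIndex(ct), adjustedRandIndex(m))
    expect_equal(adjustedMutualInformation(ct),
                 adjustedMutualInformation(m), tolerance = 1e-12)
    expect_equal(vMeasure(ct), vMeasure(m), tolerance = 1e-12)
  }
})

test_that("scoreAll is consistent with its constituents and near 0 for random labels", {
  ds <- logTransform(toy_dataset())
  D <- combineMatrices(pairwiseMatrices(ds)$dtw,
                       pairwiseMatrices(ds)$ddtw, 0.5)
  asg <- cutToClusters(wardLinkage(D), 2)
  lab <- media(ds)
  sc <- scoreAll(D, asg, lab)
  ct <- contingencyTable(asg, lab)
  expect_equal(sc[["ari"]], adjustedRandIndex(ct))
  expect_equal(sc[["ami"]], adjustedMutualInformation(ct))
  expect_equal(sc[["v"]], unname(vMeasure(ct)["v"]))
  expect_equal(sc[["sc"]], silhouetteScore(D, asg)$sc)
  # perfect media-aligned partition
  expect_equal(unname(sc[c("ari", "ami", "v")]), c(1, 1, 1))

  # Monte Carlo: random labellings have chance-level ARI and AMI
  set.seed(23)
  n <- 60
  ids <- paste0("s", 1:n)
  asgr <- named_assignment(ids, rep(1:4, length.out = n))
  draws <- replicate(200, {
    lr <- setNames(sample(rep(c("A", "B", "C"), each = n / 3)), ids)
    ctr <- contingencyTable(asgr, lr)
    c(adjustedRandIndex(ctr), adjustedMutualInformation(ctr))
  })
  for (k in 1:2) {
    m <- mean(draws[k, ]); se <- sd(draws[k, ]) / sqrt(ncol(draws))
    expect_lt(abs(m), 3 * se + 1e-3)
  }
})
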