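test_that("majority-vote errors follow the per-cluster rule", {
  # one cluster, LB majority: the 2 MAA curves are the errors
  ids <- paste0("s", 1:12)
  lab <- setNames(c(rep("LB", 10), rep("MAA", 2)), ids)
  err <- errorCount(named_assignment(ids, rep(1, 12)), lab)
  expect_equal(err$total, 2L)
  expect_equal(err$perMedium[["MAA"]], 2L)
  expect_equal(err$perMedium[["LB"]], 0L)
  expect_equal(err$perCluster$majority, "LB")

  # media-pure clustering has zero errors at any N
  lab2 <- setNames(rep(c("LB", "M63"), each = 4), paste0("c", 1:8))
  pure <- errorCount(named_assignment(paste0("c", 1:8), rep(1:2, each = 4)),
                     lab2)
  expect_equal(pure$total, 0L)

  expect_error(errorCount(named_assignment("x", 1), c(y = "LB")), "missing")
})

test_that("a medium split across clusters only errs where it is the minority", {
  # 346 M63 curves: 300 land in a cluster whose majority is M63, 46 in a
  # cluster dominated by MAA -> exactly 46 errors, all attributed to M63
  n_m63 <- 346; n_maj <- 300
  ids <- c(paste0("m63_", 1:n_m63), paste0("maa_", 1:333), paste0("lb_", 1:336))
  lab <- setNames(c(rep("M63", n_m63), rep("MAA", 333), rep("LB", 336)), ids)
  asg <- named_assignment(ids, c(rep(2, n_maj), rep(3, n_m63 - n_maj),
                                 rep(3, 333), rep(1, 336)))
  err <- errorCount(asg, lab)
  expect_equal(err$total, 46L)
  expect_equal(err$perMedium[["M63"]], 46L)
  expect_equal(err$perMedium[["MAA"]], 0L)
  expect_equal(
    err$perCluster$majority[match(c(1, 2, 3), err$perCluster$cluster)],
    c("LB", "M63", "MAA"))
})

test_that("error totals are invariant to cluster relabelling and hit the extremes", {
  set.seed(31)
  ids <- paste0("s", 1:30)
  lab <- setNames(sample(c("LB", "MAA", "M63"), 30, replace = TRUE), ids)
  asg <- named_assignment(ids, sample(1:5, 30, replace = TRUE))
  relab <- setNames(sample(1:5)[asg], ids)
  expect_equal(errorCount(asg, lab)$total, errorCount(relab, lab)$total)
  # one big cluster: n minus the largest medium count
  expect_equal(errorCount(named_assignment(ids, rep(1, 30)), lab)$total,
               30L - max(table(lab)))
  # all singletons: zero errors
  expect_equal(errorCount(named_assignment(ids, 1:30), lab)$total, 0L)
})

test_that("majority ties break by dataset-wide medium count, then name", {
  ids <- paste0("s", 1:7)
  # cluster 1 is tied LB/MAA 2:2; MAA has the larger dataset-wide count
  lab <- setNames(c("LB", "LB", "MAA", "MAA", "MAA", "AAA", "AAA"), ids)
  asg <- named_assignment(ids, c(1, 1, 1, 1, 2, 2, 2))
  err <- errorCount(asg, lab)
  expect_equal(err$perCluster$majority[1], "MAA")
  # dataset-wide tie: lexicographically smaller name wins
  lab2 <- setNames(c("B", "B", "A", "A", "C", "C"), paste0("t", 1:6))
  err2 <- errorCount(named_assignment(paste0("t", 1:6), c(1, 1, 1, 1, 2, 2)),
                     lab2)
  expect_equal(err2$perCluster$majority[1], "A")
})

test_that("a single-cell grid equals running the stages by hand", {
  ds <- separable_dataset(4) |> thinToInterval(1)
  g <- gridSearch(ds, alphaGrid = 0.5, nRange = 3L)
  expect_equal(nrow(gridScores(g)), 1L)
  m <- pairwiseMatrices(ds)
  D <- combineMatrices(m$dtw, m$ddtw, 0.5)
  cl <- cutToClusters(wardLinkage(D), 3)
  sc <- scoreAll(D, cl, media(ds))
  row <- gridScores(g)[1, ]
  expect_equal(row$ari, sc[["ari"]])
  expect_equal(row$sc, sc[["sc"]])
  expect_equal(row$errors, errorCount(cl, media(ds))$total)
})

test_that("the grid has one row per (alpha, N) cell and handles degenerate data", {
  ds <- separable_dataset(3) |> thinToInterval(1)
  g <- gridSearch(ds, alphaGrid = seq(0, 1, 0.25), nRange = 2:5)
  expect_equal(nrow(gridScores(g)), 5L * 4L)
  expect_equal(unique(gridScores(g)$alpha), seq(0, 1, 0.25))

  # identical curves: all distances zero, still no crash
  gc <- function(id, med) growthCurve(id, 0:4, c(1, 1, 2, 3, 3),
                                      scale = "log", medium = med)
  flat <- growthDataset(list(gc("u", "LB"), gc("v", "LB"), gc("w", "M63"),
                             gc("x", "M63")))
  gf <- gridSearch(flat, alphaGrid = c(0, 1), nRange = 2:3)
  expect_true(all(is.finite(gf@grid$errors)))
  # errors = n - max medium count when structure is absent is not guaranteed
  # per cell, but the totals stay within [0, n - N]
  expect_true(all(gf@grid$errors >= 0 &
                  gf@grid$errors <= 4 - gf@grid$n_clusters))
})

test_that("grid range preconditions are enforced", {
  ds <- separable_dataset(3)
  expect_error(gridSearch(ds, alphaGrid = c(0, 1.5), nRange = 2:3), "alpha")
  expect_error(gridSearch(ds, alphaGrid = 0.5, nRange = 1:3), "nRange")
  expect_error(gridSearch(ds, alphaGrid = 0.5, nRange = 2:100), "nRange")
})

test_that("bestByBenchmark maximizes with smallest-N, smallest-alpha ties", {
  df <- expand.grid(alpha = c(0, 0.5, 1), n_clusters = 2:4)
  df$ari <- c(0.2, 0.9, 0.4, 0.1, 0.9, 0.3, 0.5, 0.2, 0.1)
  g <- manual_grid(df)
  best <- bestByBenchmark(g, "ari")
  expect_equal(best$n_clusters, 2L)   # tie at 0.9 between N=2 and N=3
  expect_equal(best$alpha, 0.5)
  expect_equal(best$score, 0.9)
})

test_that("the min-error profile reports every N with the largest attaining alpha", {
  df <- expand.grid(alpha = c(0.1, 0.6, 0.9), n_clusters = 2:4)
  df$errors <- c(10, 10, 10, 7, 5, 5, 4, 4, 4)  # row-major over alpha per N
  g <- manual_grid(df)
  prof <- minErrorProfile(g)
  expect_equal(prof$n_clusters, 2:4)
  expect_equal(prof$min_errors, c(10, 5, 4))
  # alpha-independent rows report the maximum grid alpha
  expect_equal(prof$alpha, c(0.9, 0.9, 0.9))

  df2 <- df; df2$errors <- c(10, 9, 10, 7, 11, 5, 4, 4, 4)
  prof2 <- minErrorProfile(manual_grid(df2))
  expect_equal(prof2$min_errors, c(9, 5, 4))
  expect_equal(prof2$alpha[1:2], c(0.6, 0.9))
})

test_that("knee selection finds the largest single-step error drop", {
  prof <- data.frame(n_clusters = 2:8,
                     min_errors = c(40, 38, 36, 35, 11, 10, 10),
                     alpha = c(0.5, 0.5, 0.6, 0.7, 0.78, 0.8, 0.8))
  sel <- selectByErrorKnee(prof)
  expect_equal(sel$n_clusters, 6L)      # the 35 -> 11 step
  expect_equal(sel$errors, 11)
  expect_equal(sel$alpha, 0.78)

  # two equal maximal drops: the smaller N wins
  prof2 <- data.frame(n_clusters = 2:5, min_errors = c(20, 10, 10, 0),
                      alpha = 1)
  expect_equal(selectByErrorKnee(prof2)$n_clusters, 3L)

  # flat profile: warning, smallest N after the zero drop
  prof3 <- data.frame(n_clusters = 2:4, min_errors = c(5, 5, 5), alpha = 1)
  expect_warning(sel3 <- selectByErrorKnee(prof3), "flat")
  expect_equal(sel3$n_clusters, 3L)

  # monotone increasing profile has no knee
  prof4 <- data.frame(n_clusters = 2:4, min_errors = c(1, 2, 3), alpha = 1)
  expect_error(selectByErrorKnee(prof4), "no knee")
  expect_error(selectByErrorKnee(prof4[1:2, ]), "at least 3")
})

test_that("the alpha profile at an error level supports the plateau diagnostic", {
  df <- expand.grid(alpha = c(0.2, 0.8), n_clusters = 2:4)
  df$errors <- c(20, 25, 11, 11, 3, 11)
  g <- manual_grid(df)
  prof <- alphaProfileAtErrorLevel(g, 11)
  expect_equal(prof$n_clusters, 2:4)
  expect_equal(prof$alpha, c(NA, 0.8, 0.8))
  # below the global minimum nothing is attainable
  expect_true(all(is.na(alphaProfileAtErrorLevel(g, 2)$alpha)))
  # a budget of n is attained by every N at the maximum grid alpha
  expect_equal(alphaProfileAtErrorLevel(g, 1000)$alpha, rep(0.8, 3))
  expect_error(alphaProfileAtErrorLevel(g, -1), "non-negative")
})

test_that("well-separated media are recovered with zero errors at N = 3", {
  ds <- thinToInterval(simulateDataset(presetArchetypes(), c(6, 6, 6),
                                       seed = 77), 1)
  g <- gridSearch(ds, alphaGrid = seq(0, 1, 0.1), nRange = 2:6)
  sub <- gridScores(g)
  at3 <- sub[sub$n_clusters == 3 & sub$errors == 0, , drop = FALSE]
  expect_gt(nrow(at3), 0)            # a nonempty alpha range achieves 0 errors
  expect_true(all(at3$ari == 1))
  best <- bestByBenchmark(g, "ari")
  expect_equal(best$n_clusters, 3L)
})
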