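.pipe_log <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, sprintf(fmt, ...)))
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Default configuration for the full analysis
#'
#' Returns the configuration list [runFullAnalysis()] consumes, with the
#' study-design defaults: log base 10, OD floor 1e-3, thinning to 1 h,
#' alpha from 0 to 1 in steps of 0.01, N from 2 to 28 (capped at the
#' dataset size). Supply either `input` (paths to a curve table and
#' optional metadata) or `simulate` (parameters for
#' [simulateDataset()] with [presetArchetypes()]).
#'
#' @param ... named fields overriding the defaults.
#' @return a named list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    input = NULL,                       # list(path, layout, metadataPath)
    simulate = list(nPerMedium = c(50, 50, 50), contrast = 1,
                    initMix = 0.5, noiseSd = 0.05),
    logBase = 10,
    floorEpsilon = 1e-3,
    targetInterval = 1,
    alpha = list(start = 0, stop = 1, step = 0.01),
    nRange = c(2, 28),
    seed = 1L,
    outDir = NULL,
    verbose = TRUE)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

.validate_config <- function(cfg) {
  a <- cfg$alpha
  if (!is.list(a) || any(!c("start", "stop", "step") %in% names(a)))
    stop("alpha must be a list(start, stop, step)")
  if (a$start < 0 || a$stop > 1 || a$start > a$stop || a$step <= 0)
    stop("alpha grid must lie within [0, 1] with a positive step")
  if (length(cfg$nRange) != 2 || cfg$nRange[1] < 2 ||
      cfg$nRange[1] > cfg$nRange[2])
    stop("nRange must be c(min, max) with min >= 2")
  if (is.null(cfg$input) && is.null(cfg$simulate))
    stop("config needs either an input block or a simulate block")
  if (!is.null(cfg$input) && !file.exists(cfg$input$path))
    stop("input file not found: ", cfg$input$path)
  if (!is.null(cfg$simulate)) {
    n <- sum(cfg$simulate$nPerMedium)
    if (cfg$nRange[2] > n)
      stop(sprintf("nRange max (%d) exceeds dataset size (%d)",
                   cfg$nRange[2], n))
  }
  invisible(cfg)
}

#' Run the full growth-curve clustering analysis
#'
#' Chains every stage end-to-end: acquire curves (read a table or simulate),
#' preprocess (log conversion for linear input, thinning to a common
#' interval), compute the pairwise DTW/DDTW matrices once, evaluate the
#' alpha-by-N grid with all four benchmarks and the majority-vote error
#' count, pick the best cell per statistical benchmark and the knee of the
#' error profile, and write every intermediate artifact to `outDir`. The
#' run is deterministic given the config (all randomness flows from
#' `config$seed`): a rerun writes byte-identical tables.
#'
#' @param config configuration list, see [defaultRunConfig()].
#' @return (invisibly) the run report: selected (alpha, N) per criterion,
#'   achieved error count and accuracy, the per-cluster majority table, and
#'   the file manifest. Also written to `report.json`.
#' @export
runFullAnalysis <- function(config = defaultRunConfig()) {
  cfg <- .stage("config", .validate_config(config))
  verbose <- isTRUE(cfg$verbose)
  outDir <- cfg$outDir
  if (is.null(outDir)) outDir <- tempfile("growthwarp_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  emit <- function(name) {
    manifest <<- c(manifest, name)
    file.path(outDir, name)
  }

  ds <- .stage("acquire", {
    if (!is.null(cfg$input)) {
      .pipe_log(verbose, "acquire", "reading %s", cfg$input$path)
      raw <- readGrowthTable(cfg$input$path,
                             layout = if (is.null(cfg$input$layout)) "long"
                                      else cfg$input$layout,
                             metadataPath = cfg$input$metadataPath)
      logTransform(raw, base = cfg$logBase, floorEpsilon = cfg$floorEpsilon)
    } else {
      s <- cfg$simulate
      .pipe_log(verbose, "acquire", "simulating %s curves",
                paste(s$nPerMedium, collapse = "+"))
      arch <- presetArchetypes(
        contrast = if (is.null(s$contrast)) 1 else s$contrast,
        noiseSd = if (is.null(s$noiseSd)) 0.05 else s$noiseSd)
      simulateDataset(arch, s$nPerMedium,
                      initMix = if (is.null(s$initMix)) 0.5 else s$initMix,
                      seed = cfg$seed)
    }
  })

  ds <- .stage("preprocess", {
    if (cfg$nRange[2] > length(ds))
      stop(sprintf("nRange max (%d) exceeds dataset size (%d)",
                   cfg$nRange[2], length(ds)))
    thinToInterval(ds, cfg$targetInterval)
  })
  .stage("preprocess", {
    writeGrowthTable(ds, emit("curves.csv"), layout = "long",
                     metadataPath = emit("metadata.csv"))
  })

  mats <- .stage("distance", {
    .pipe_log(verbose, "distance", "DTW/DDTW over %d curves", length(ds))
    m <- pairwiseMatrices(ds)
    writeDistanceMatrix(m$dtw, emit("dtw.tsv"))
    writeDistanceMatrix(m$ddtw, emit("ddtw.tsv"))
    m
  })

  grid <- .stage("grid", {
    alphaGrid <- seq(cfg$alpha$start, cfg$alpha$stop, by = cfg$alpha$step)
    nRange <- seq(cfg$nRange[1], cfg$nRange[2])
    .pipe_log(verbose, "grid", "%d alpha x %d N cells",
              length(alphaGrid), length(nRange))
    g <- gridSearch(ds, alphaGrid = alphaGrid, nRange = nRange)
    write.csv(gridScores(g), emit("grid.csv"), row.names = FALSE,
              quote = FALSE)
    g
  })

  report <- .stage("select", {
    bench <- lapply(c(ari = "ari", ami = "ami", v = "v", sc = "sc"),
                    function(w) bestByBenchmark(grid, w))
    profile <- minErrorProfile(grid)
    knee <- selectByErrorKnee(profile)
    .pipe_log(verbose, "select", "knee at N=%d, alpha=%.2f, %d errors",
              knee$n_clusters, knee$alpha, knee$errors)
    D <- combineMatrices(mats$dtw, mats$ddtw, knee$alpha)
    cl <- cutToClusters(wardLinkage(D), knee$n_clusters)
    err <- errorCount(cl, media(ds))
    write.csv(data.frame(curve_id = names(cl), cluster = unname(cl)),
              emit("assignment.csv"), row.names = FALSE, quote = FALSE)
    n <- length(ds)
    list(n_curves = n,
         selection = list(alpha = knee$alpha, n_clusters = knee$n_clusters,
                          errors = knee$errors,
                          accuracy_percent = round(100 * (n - knee$errors) / n)),
         best_by_benchmark = bench,
         error_profile = profile,
         majority_table = err$perCluster,
         per_medium_errors = as.list(err$perMedium),
         manifest = manifest)
  })

  .stage("report", {
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })
  report$manifest <- c(report$manifest, "report.json")
  report$outDir <- outDir
  invisible(report)
}
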