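# Small in-code fixtures shared across test files.

# Dataset of hand-written curves with medium labels.
toy_dataset <- function(scale = "linear") {
  mk <- function(id, values, medium)
    growthCurve(id, times = seq(0, length(values) - 1), values = values,
                scale = scale, medium = medium)
  growthDataset(list(
    mk("a1", c(0.01, 0.02, 0.08, 0.40, 0.90, 1.00), "LB"),
    mk("a2", c(0.01, 0.03, 0.09, 0.45, 0.95, 1.05), "LB"),
    mk("b1", c(0.01, 0.01, 0.02, 0.05, 0.15, 0.40), "M63"),
    mk("b2", c(0.01, 0.01, 0.02, 0.06, 0.17, 0.45), "M63")))
}

# Named cluster assignment from an unnamed vector of ids + clusters.
named_assignment <- function(ids, clusters) {
  stats::setNames(as.integer(clusters), ids)
}

# A GrowthGridResult built directly from a score table (for the selection
# operations, which only read the table).
manual_grid <- function(df) {
  alphaGrid <- sort(unique(df$alpha))
  nRange <- sort(unique(df$n_clusters))
  for (col in c("ari", "ami", "v", "h", "c", "sc", "errors"))
    if (is.null(df[[col]])) df[[col]] <- 0
  methods::new("GrowthGridResult", grid = df, alphaGrid = alphaGrid,
               nRange = as.integer(nRange), nCurves = 0L)
}

# Noiseless, jitter-free three-medium dataset: every curve of one medium is
# identical, media are well separated.
separable_dataset <- function(nPer = 4, seed = 1) {
  simulateDataset(presetArchetypes(contrast = 1, noiseSd = 0),
                  rep(nPer, 3), initMix = 1, seed = seed,
                  jitterRel = c(lag = 0, mu = 0, amplitude = 0, duration = 0),
                  baselineSd = 0)
}
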