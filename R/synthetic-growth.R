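#' Medium archetype for the growth-curve simulator
#'
#' Parameter bundle describing how a growth medium shapes a curve, in log-OD
#' units: a modified Gompertz sigmoid
#' `L(t) = L0 + A * exp(-exp((mu * e / A) * (lambda - t) + 1))`
#' with lag `lambda` (h), maximum specific growth proxy `mu` (log-OD/h) and
#' amplitude `A` (log-OD span from baseline `L0` to the plateau), sampled on
#' a regular grid of `interval` hours over `duration` hours, with additive
#' Gaussian noise of sd `noiseSd` and an optional linear death-phase decline
#' of slope `deathSlope` after the plateau is reached.
#'
#' @param name medium label.
#' @param lag lag time `lambda` in hours, >= 0.
#' @param mu maximum growth-rate proxy in log-OD per hour, > 0.
#' @param amplitude plateau minus baseline in log-OD, > 0.
#' @param baseline log-OD at inoculation.
#' @param duration record length in hours; `duration / interval >= 4`.
#' @param interval sampling interval in hours.
#' @param noiseSd additive noise sd in log-OD units.
#' @param deathSlope optional post-plateau decline, log-OD per hour (0 = off).
#' @return a `mediumArchetype` list.
#' @seealso [presetArchetypes()], [simulateCurve()], [simulateDataset()]
#' @export
mediumArchetype <- function(name, lag, mu, amplitude, baseline, duration,
                            interval, noiseSd = 0, deathSlope = 0) {
  if (lag < 0) stop("lag must be >= 0")
  if (mu <= 0) stop("mu must be > 0")
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (duration / interval < 4) stop("need duration/interval >= 4 points")
  if (noiseSd < 0 || deathSlope < 0) stop("noiseSd and deathSlope must be >= 0")
  structure(list(name = as.character(name), lag = lag, mu = mu,
                 amplitude = amplitude, baseline = baseline,
                 duration = duration, interval = interval,
                 noiseSd = noiseSd, deathSlope = deathSlope),
            class = "mediumArchetype")
}

#' Preset medium archetypes: rich, supplemented and minimal
#'
#' Three archetypes mirroring the qualitative ordering of a rich complete
#' medium (LB-like: short lag, fast growth, short record at 30-min
#' sampling), a minimal medium supplemented with amino acids (MAA-like:
#' intermediate) and a minimal medium (M63-like: long lag, slow growth,
#' long record at 1-h sampling). A single `contrast` scalar interpolates
#' the lag, rate, amplitude and record duration between the three presets
#' (`contrast = 1`) and their common mean (`contrast = 0`, media
#' indistinguishable); sampling intervals and noise are untouched.
#'
#' @param contrast separability scalar in `[0, 1]` (and beyond 1 to
#'   exaggerate).
#' @param noiseSd noise sd applied to all three archetypes.
#' @return named list of three `mediumArchetype`s: `LB`, `MAA`, `M63`.
#' @export
presetArchetypes <- function(contrast = 1, noiseSd = 0.05) {
  base <- list(
    LB  = list(lag = 1.5, mu = 0.90, amplitude = 2.2, duration = 24,
               interval = 0.5),
    MAA = list(lag = 3.5, mu = 0.45, amplitude = 1.9, duration = 36,
               interval = 1),
    M63 = list(lag = 7.0, mu = 0.25, amplitude = 1.6, duration = 48,
               interval = 1))
  fields <- c("lag", "mu", "amplitude", "duration")
  means <- vapply(fields, function(f)
    mean(vapply(base, `[[`, numeric(1), f)), numeric(1))
  out <- lapply(names(base), function(nm) {
    p <- base[[nm]]
    for (f in fields) p[[f]] <- means[[f]] + contrast * (p[[f]] - means[[f]])
    mediumArchetype(nm, lag = p$lag, mu = p$mu, amplitude = p$amplitude,
                    baseline = -2, duration = p$duration,
                    interval = p$interval, noiseSd = noiseSd)
  })
  setNames(out, names(base))
}

.gompertz_log_od <- function(t, lag, mu, A, L0) {
  L0 + A * exp(-exp((mu * exp(1) / A) * (lag - t) + 1))
}

#' Simulate one growth curve from a medium archetype
#'
#' Deterministic for a fixed seed. A positive `initShift` models a denser
#' inoculum: it raises the baseline by `initShift` log-OD and shortens the
#' apparent lag by `initShift / mu` hours (the time the culture would have
#' needed to grow that extra span), floored at zero.
#'
#' @param arch a [mediumArchetype()].
#' @param initShift log-OD offset of the initial density (default 0).
#' @param seed integer seed for the noise.
#' @param curveId,strain,initConc labels attached to the curve.
#' @return a log-scale [GrowthCurve-class] on the archetype's time grid.
#' @export
simulateCurve <- function(arch, initShift = 0, seed = 1L,
                          curveId = arch$name, strain = "unknown",
                          initConc = "unknown") {
  if (!inherits(arch, "mediumArchetype")) stop("arch must be a mediumArchetype")
  times <- seq(0, arch$duration, by = arch$interval)
  lag <- max(0, arch$lag - initShift / arch$mu)
  L0 <- arch$baseline + initShift
  vals <- .gompertz_log_od(times, lag, arch$mu, arch$amplitude, L0)
  if (arch$deathSlope > 0) {
    tPlateau <- lag + 1.5 * arch$amplitude / arch$mu
    vals <- vals - arch$deathSlope * pmax(0, times - tPlateau)
  }
  if (arch$noiseSd > 0) {
    set.seed(as.integer(seed))
    vals <- vals + rnorm(length(vals), 0, arch$noiseSd)
  }
  growthCurve(curveId, times, vals, scale = "log", strain = strain,
              medium = arch$name, initConc = initConc)
}

#' Simulate a labelled multi-medium growth dataset
#'
#' Draws `nPerMedium[k]` curves from archetype `k`, jittering the archetype
#' parameters per curve (relative sds in `jitterRel`, additive sd
#' `baselineSd` on the baseline) so replicate curves differ in rate, lag,
#' plateau and record length, as biological repeats do. A fraction
#' `initMix` of each medium's curves starts from the low inoculum
#' (`init_conc = "low"`, no shift); the rest start denser
#' (`init_conc = "high"`, shift `initShiftHigh` log-OD, shorter apparent
#' lag). Strain labels cycle through `nStrains` synthetic strain names.
#' Fully reproducible per seed.
#'
#' @param archetypes list of [mediumArchetype()]s.
#' @param nPerMedium integer vector, one count (>= 1) per archetype.
#' @param initMix fraction of curves at the low initial density.
#' @param seed integer seed governing all randomness.
#' @param jitterRel named numeric: relative sd of per-curve jitter on
#'   `lag`, `mu`, `amplitude`, `duration`.
#' @param baselineSd additive sd on the baseline (log-OD).
#' @param initShiftHigh log-OD offset of the high-inoculum class.
#' @param nStrains number of synthetic strain labels to cycle through.
#' @return a log-scale [GrowthDataset-class] with medium, strain and
#'   init_conc labels.
#' @export
simulateDataset <- function(archetypes, nPerMedium, initMix = 0.5, seed = 1L,
                            jitterRel = c(lag = 0.10, mu = 0.10,
                                          amplitude = 0.05, duration = 0.05),
                            baselineSd = 0.05, initShiftHigh = 0.4,
                            nStrains = 28L) {
  if (length(archetypes) != length(nPerMedium))
    stop("archetypes and nPerMedium must have equal length")
  if (any(nPerMedium < 1)) stop("counts must be >= 1")
  if (initMix < 0 || initMix > 1) stop("initMix must lie in [0, 1]")
  set.seed(as.integer(seed))
  strainPool <- sprintf("strain%02d", seq_len(nStrains))
  curves <- list()
  for (k in seq_along(archetypes)) {
    arch <- archetypes[[k]]
    if (!inherits(arch, "mediumArchetype"))
      stop("archetypes must be mediumArchetype objects")
    n <- nPerMedium[k]
    # draw all per-curve randomness up front, then build deterministically
    jit <- function(field) {
      rel <- if (field %in% names(jitterRel)) jitterRel[[field]] else 0
      pmax(arch[[field]] * (1 + rnorm(n, 0, rel)), arch[[field]] * 0.2)
    }
    lag <- pmax(arch$lag * (1 + rnorm(n, 0, jitterRel[["lag"]])), 0)
    mu <- jit("mu"); amp <- jit("amplitude"); dur <- jit("duration")
    L0 <- arch$baseline + rnorm(n, 0, baselineSd)
    low <- runif(n) < initMix
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    strain <- sample(strainPool, n, replace = TRUE)
    for (i in seq_len(n)) {
      a <- mediumArchetype(arch$name, lag = lag[i], mu = mu[i],
                           amplitude = amp[i], baseline = L0[i],
                           duration = max(dur[i], 4 * arch$interval),
                           interval = arch$interval, noiseSd = arch$noiseSd,
                           deathSlope = arch$deathSlope)
      id <- sprintf("%s_%03d", arch$name, i)
      curves[[id]] <- simulateCurve(
        a, initShift = if (low[i]) 0 else initShiftHigh, seed = seeds[i],
        curveId = id, strain = strain[i],
        initConc = if (low[i]) "low" else "high")
    }
  }
  growthDataset(curves)
}
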