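#' @include AllClasses.R
NULL

#' Default frequency bands
#'
#' The five analysis bands: Alpha 8-13, Beta 13-30, LowG 30-55,
#' MidG 65-115 and HigG 125-230 Hz. The 55-65 and 115-125 Hz gaps avoid
#' mains noise at 60 Hz and its second harmonic.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
defaultBands <- function() {
  list(Alpha = c(8, 13), Beta = c(13, 30), LowG = c(30, 55),
       MidG = c(65, 115), HigG = c(125, 230))
}

#' Construct an analysis configuration
#'
#' All arguments have the study defaults; see [AnalysisConfig-class] for
#' their meaning. Windows are closed on the left and open on the right.
#'
#' @param epochWindowMs epoching window (default -1000..1000 ms).
#' @param analysisWindowMs analysis crop (default -150..500 ms).
#' @param baselineWindowMs baseline window (default -150..-10 ms).
#' @param bands named list of band edges in Hz.
#' @param timeBandpassHz,tfrBandpassHz FIR band edges for the time-domain
#'   (1-30 Hz) and time-frequency (1-230 Hz) branches.
#' @param nPermutations Monte Carlo permutations (default 1000).
#' @param alphaCluster cluster significance level (default 0.05).
#' @param alphaForming cluster-forming (sample-level) alpha (default 0.05).
#' @param waveletCycles Morlet cycles (default 7).
#' @param tfrTimeStepMs TFR output grid step (default 20 ms).
#' @param adjacencyMaxDistMm electrode adjacency radius (default 15 mm).
#' @param logBase `"db10"` (true decibels, default) or `"natural"`.
#' @param baselineStat `"geometric"` (default) or `"arithmetic"` baseline
#'   mean of power; geometric centres the null distribution of
#'   stochastic log power at 0 (see the methods vignette).
#' @param clusterStat cluster-level statistic, `"mass"` (default) or
#'   `"size"`.
#' @param nullMethod how the max-cluster-statistic null is sampled:
#'   `"shift"` (default) re-normalizes each trial against a randomly
#'   time-shifted analysis/baseline window - a stationarity-based
#'   surrogate that needs no symmetry assumption and is calibrated for
#'   skewed log power; `"bootstrap"` resamples trials with replacement
#'   after per-cell centering (conservative at small n); `"signflip"`
#'   flips each trial's sign with probability 1/2, exact only when
#'   normalized power is symmetric about 0 - log power is left-skewed,
#'   so with few trials the sign-flip null is anticonservative for
#'   positive (ERS) clusters (see the methods vignette and
#'   [permutationTest()]).
#' @param carEnabled apply per-grid common average reference (default
#'   `FALSE`). The source study re-referenced only grids showing
#'   significant common noise; enable this when the data carry shared
#'   noise (e.g. mains pickup). On clean data, CAR folds an attenuated
#'   copy of focal responses into every channel of the grid and
#'   de-localises the cluster maps.
#' @param rngSeed permutation RNG seed.
#' @return An [AnalysisConfig-class].
#' @examples
#' cfg <- analysisConfig(nPermutations = 500)
#' cfg
#' @export
analysisConfig <- function(epochWindowMs = c(-1000, 1000),
                           analysisWindowMs = c(-150, 500),
                           baselineWindowMs = c(-150, -10),
                           bands = defaultBands(),
                           timeBandpassHz = c(1, 30),
                           tfrBandpassHz = c(1, 230),
                           nPermutations = 1000,
                           alphaCluster = 0.05,
                           alphaForming = 0.05,
                           waveletCycles = 7,
                           tfrTimeStepMs = 20,
                           adjacencyMaxDistMm = 15,
                           logBase = "db10",
                           baselineStat = "geometric",
                           clusterStat = "mass",
                           nullMethod = "shift",
                           carEnabled = FALSE,
                           rngSeed = 1L) {
  new("AnalysisConfig",
      epochWindowMs = as.numeric(epochWindowMs),
      analysisWindowMs = as.numeric(analysisWindowMs),
      baselineWindowMs = as.numeric(baselineWindowMs),
      bands = bands,
      timeBandpassHz = as.numeric(timeBandpassHz),
      tfrBandpassHz = as.numeric(tfrBandpassHz),
      nPermutations = as.integer(nPermutations),
      alphaCluster = as.numeric(alphaCluster),
      alphaForming = as.numeric(alphaForming),
      waveletCycles = as.numeric(waveletCycles),
      tfrTimeStepMs = as.numeric(tfrTimeStepMs),
      adjacencyMaxDistMm = as.numeric(adjacencyMaxDistMm),
      logBase = logBase, baselineStat = baselineStat,
      clusterStat = clusterStat, nullMethod = nullMethod,
      carEnabled = carEnabled,
      rngSeed = as.integer(rngSeed))
}

#' Default evoked components of the synthetic generator
#'
#' The four long-latency somatosensory components injected at each
#' finger's cortical site: N40 (38 ms), P100 (108 ms), N140 (138 ms) and
#' P200 (186 ms), modelled as Gaussian-windowed monophasic atoms of 30 ms
#' width (FWHM).
#'
#' @return `data.frame` with columns `label`, `latency_ms`,
#'   `amplitude_uv`, `width_ms`, `polarity`.
#' @export
defaultErpComponents <- function() {
  data.frame(
    label = c("N40", "P100", "N140", "P200"),
    latency_ms = c(38, 108, 138, 186),
    amplitude_uv = c(20, 15, 12, 10),
    width_ms = c(30, 30, 30, 30),
    polarity = c(-1, 1, -1, 1))
}

#' Construct a synthetic session configuration
#'
#' Defaults reproduce the study design: per set, each of the five fingers
#' is vibrated ten times in random order for 100-500 ms with a 1-1.4 s
#' inter-stimulation interval; recording at 500 Hz from an 8 x 8 grid at
#' 10 mm pitch; contralateral events receive post-central evoked
#' components, a 65-115 Hz synchronisation burst and alpha/beta
#' desynchronisation at finger-specific sites laid out latero-medially.
#' See [SimConfig-class] for slot meanings.
#'
#' @param nSets stimulation sets (default 6).
#' @param trialsPerFinger trials per finger per set (default 10).
#' @param stimDurationRangeMs vibration duration range (default 100-500).
#' @param isiRangeMs offset-to-onset interval range (default 1000-1400).
#' @param fs sampling rate (default 500 Hz).
#' @param gridShape grid rows x cols (default `c(8, 8)`).
#' @param gridPitchMm inter-contact distance (default 10 mm).
#' @param fingerSites five target electrode labels, thumb first; default:
#'   five consecutive electrodes along the grid's x (latero-medial) axis.
#' @param erpComponents see [defaultErpComponents()].
#' @param ersBandHz,ersOnsetMs,ersDurationMs,ersAmpUv mid-gamma burst
#'   parameters (defaults 65-115 Hz, 30 ms onset, 150 ms duration, 5 uV
#'   RMS).
#' @param erdBandHz,erdAttenuation,erdWindowMs desynchronisation
#'   parameters (defaults 8-30 Hz, 0.5, 150-600 ms).
#' @param spatialSigmaMm Gaussian spatial falloff (default 8 mm).
#' @param backgroundExponent,backgroundRmsUv 1/f^exponent background
#'   (defaults 2 and 20 uV).
#' @param interictalRateHz,lineNoise60Uv optional artefacts (default off).
#' @param onsetLatencyOffsetMs constant stimulator latency (default 0).
#' @param hands `"CL"`, `"IL"` or both (cycled over sets; default CL).
#' @param task task code, `"s"` or `"sm"`.
#' @param ilResponse inject a weak delayed response for IL events.
#' @param seed RNG seed.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(nSets = 1, seed = 7)
#' cfg
#' @export
simConfig <- function(nSets = 6, trialsPerFinger = 10,
                      stimDurationRangeMs = c(100, 500),
                      isiRangeMs = c(1000, 1400), fs = 500,
                      gridShape = c(8, 8), gridPitchMm = 10,
                      fingerSites = NULL,
                      erpComponents = defaultErpComponents(),
                      ersBandHz = c(65, 115), ersOnsetMs = 30,
                      ersDurationMs = 150, ersAmpUv = 5,
                      erdBandHz = c(8, 30), erdAttenuation = 0.5,
                      erdWindowMs = c(150, 600), spatialSigmaMm = 8,
                      backgroundExponent = 2, backgroundRmsUv = 20,
                      interictalRateHz = 0, lineNoise60Uv = 0,
                      onsetLatencyOffsetMs = 0, hands = "CL", task = "s",
                      ilResponse = FALSE, seed = 1L) {
  gridShape <- as.integer(gridShape)
  if (is.null(fingerSites)) {
    # middle row, five consecutive columns: a latero-medial line along +x
    row <- max(1L, gridShape[1] %/% 2L)
    col0 <- (gridShape[2] - 5L) %/% 2L + 1L
    if (gridShape[2] < 5L)
      stop("grid too small for the default finger sites; supply fingerSites")
    idx <- (row - 1L) * gridShape[2] + col0 + 0:4
    fingerSites <- sprintf("e%02d", idx)
  }
  new("SimConfig", nSets = as.integer(nSets),
      trialsPerFinger = as.integer(trialsPerFinger),
      stimDurationRangeMs = as.numeric(stimDurationRangeMs),
      isiRangeMs = as.numeric(isiRangeMs), fs = as.numeric(fs),
      gridShape = gridShape, gridPitchMm = as.numeric(gridPitchMm),
      fingerSites = fingerSites, erpComponents = erpComponents,
      ersBandHz = as.numeric(ersBandHz), ersOnsetMs = as.numeric(ersOnsetMs),
      ersDurationMs = as.numeric(ersDurationMs),
      ersAmpUv = as.numeric(ersAmpUv), erdBandHz = as.numeric(erdBandHz),
      erdAttenuation = as.numeric(erdAttenuation),
      erdWindowMs = as.numeric(erdWindowMs),
      spatialSigmaMm = as.numeric(spatialSigmaMm),
      backgroundExponent = as.numeric(backgroundExponent),
      backgroundRmsUv = as.numeric(backgroundRmsUv),
      interictalRateHz = as.numeric(interictalRateHz),
      lineNoise60Uv = as.numeric(lineNoise60Uv),
      onsetLatencyOffsetMs = as.numeric(onsetLatencyOffsetMs),
      hands = hands, task = task, ilResponse = ilResponse,
      seed = as.integer(seed))
}
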