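#' Multi-channel ECoG recording
#'
#' Continuous multi-channel cortical signal, channels in rows, samples in
#' columns, in microvolts. Channel labels are carried as the row names of
#' `data`.
#'
#' @slot data numeric matrix, channels x samples (microvolts), with unique
#'   row names.
#' @slot fs sampling rate in Hz.
#' @slot startTime offset of the first sample in seconds (default 0).
#' @export
setClass("EcogRecording",
  representation(data = "matrix", fs = "numeric", startTime = "numeric"),
  prototype(startTime = 0),
  validity = function(object) {
    msg <- character()
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    nm <- rownames(object@data)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "data must have unique, non-empty channel row names")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "all samples must be finite")
    if (length(object@startTime) != 1L || !is.finite(object@startTime))
      msg <- c(msg, "startTime must be a single finite number")
    if (length(msg)) msg else TRUE
  })

#' Epoched trials
#'
#' Trials cut around stimulus onsets: a trial x channel x time array with a
#' time axis in milliseconds relative to onset and one label row per trial.
#'
#' @slot data numeric array, trial x channel x time.
#' @slot timeMs time axis (ms relative to stimulus onset), strictly
#'   increasing and containing 0.
#' @slot labels `data.frame` with one row per trial (`finger`, `hand`,
#'   `task`, `onset_ms`).
#' @slot fs sampling rate in Hz.
#' @export
setClass("TrialTensor",
  representation(data = "array", timeMs = "numeric", labels = "data.frame",
                 fs = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L)
      msg <- c(msg, "data must be a 3-D trial x channel x time array")
    else {
      if (length(object@timeMs) != d[3])
        msg <- c(msg, "timeMs length must match the time dimension")
      if (nrow(object@labels) != d[1])
        msg <- c(msg, "label count must equal trial count")
      if (is.null(dimnames(object@data)[[2]]))
        msg <- c(msg, "channel dimension must be named")
    }
    if (any(diff(object@timeMs) <= 0))
      msg <- c(msg, "time axis must be strictly increasing")
    if (!any(object@timeMs == 0))
      msg <- c(msg, "time axis must contain 0")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "all values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Time-frequency power tensor
#'
#' Morlet wavelet power, trial x channel x frequency x time. Raw power is
#' in microvolts squared; after [baselineNormalize()] values are
#' log-ratios to baseline (dB by default).
#'
#' @slot power numeric 4-D array, trial x channel x frequency x time.
#' @slot freqsHz analysis frequencies (1 Hz-spaced by default).
#' @slot timeMs output time grid (ms relative to onset).
#' @slot labels per-trial labels, as in [TrialTensor-class].
#' @slot fs sampling rate of the source signal in Hz.
#' @slot normalized `TRUE` after baseline normalisation.
#' @slot logBase `"none"` for raw power, else `"db10"` or `"natural"`.
#' @export
setClass("TFRTensor",
  representation(power = "array", freqsHz = "numeric", timeMs = "numeric",
                 labels = "data.frame", fs = "numeric",
                 normalized = "logical", logBase = "character"),
  prototype(normalized = FALSE, logBase = "none"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@power)
    if (length(d) != 4L)
      msg <- c(msg, "power must be 4-D: trial x channel x frequency x time")
    else {
      if (length(object@freqsHz) != d[3])
        msg <- c(msg, "freqsHz length must match frequency dimension")
      if (length(object@timeMs) != d[4])
        msg <- c(msg, "timeMs length must match time dimension")
      if (nrow(object@labels) != d[1])
        msg <- c(msg, "label count must equal trial count")
      if (is.null(dimnames(object@power)[[2]]))
        msg <- c(msg, "channel dimension must be named")
    }
    if (!object@normalized && any(object@power < 0))
      msg <- c(msg, "raw power must be non-negative")
    if (!object@logBase %in% c("none", "db10", "natural"))
      msg <- c(msg, "logBase must be one of none, db10, natural")
    if (length(msg)) msg else TRUE
  })

#' Trial-averaged evoked response
#'
#' Mean over trials of one group (e.g. one finger within one condition),
#' channels x time.
#'
#' @slot data numeric matrix, channel x time (microvolts), with channel
#'   row names.
#' @slot timeMs time axis (ms relative to onset).
#' @slot nTrials number of trials averaged.
#' @slot fs sampling rate in Hz.
#' @slot group named list identifying the group (e.g. `finger`, `hand`).
#' @export
setClass("Evoked",
  representation(data = "matrix", timeMs = "numeric", nTrials = "integer",
                 fs = "numeric", group = "list"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@data) != length(object@timeMs))
      msg <- c(msg, "timeMs length must match time dimension")
    if (is.null(rownames(object@data)))
      msg <- c(msg, "data must have channel row names")
    if (object@nTrials < 1L)
      msg <- c(msg, "nTrials must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Cluster-based permutation test result
#'
#' Connected suprathreshold channel x frequency x time clusters for one
#' (condition, band, finger) map, with Monte Carlo p-values from the
#' max-|cluster mass| sign-flip permutation null.
#'
#' @slot table `data.frame`, one row per cluster: `id`, `sign` (+1 ERS,
#'   -1 ERD), `size`, `mass`, `onset_ms`, `p_value`, `significant`.
#' @slot members list (parallel to `table`) of `data.frame`s of member
#'   cells (`channel`, `freq_hz`, `time_ms`, `t`).
#' @slot band band name; @slot condition condition label (e.g. `"CLs"`);
#'   @slot finger finger index.
#' @slot nPermutations,formingThreshold,alpha test parameters.
#' @slot permMaxMass the permutation null sample of max |cluster mass|.
#' @export
setClass("ClusterResult",
  representation(table = "data.frame", members = "list", band = "character",
                 condition = "character", finger = "integer",
                 nPermutations = "integer", formingThreshold = "numeric",
                 alpha = "numeric", permMaxMass = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@members) != nrow(object@table))
      msg <- c(msg, "members must parallel the cluster table")
    if (nrow(object@table) &&
        any(object@table$p_value < 0 | object@table$p_value > 1))
      msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Somatotopic finger map
#'
#' Power-weighted centroids of the primary significant cluster of each
#' finger, with overall map span and latero-medial order score.
#'
#' @slot centroids `data.frame`: `finger`, `x`, `y`, `z` (mm), `p_value`,
#'   `cluster_id`, `mapped`.
#' @slot spanMm maximum pairwise centroid distance (mm; `NA` if < 2 mapped).
#' @slot orderScore Spearman correlation of finger index with the
#'   latero-medial projection (`NA` if < 2 mapped).
#' @slot axis latero-medial unit vector used for the projection.
#' @slot weights list, per mapped finger, of the per-electrode weight table.
#' @export
setClass("FingerMap",
  representation(centroids = "data.frame", spanMm = "numeric",
                 orderScore = "numeric", axis = "numeric", weights = "list"),
  validity = function(object) {
    if (length(object@axis) != 3L) "axis must be a length-3 vector" else TRUE
  })

#' Analysis configuration
#'
#' All tunable parameters of the mapping pipeline, with the study defaults.
#' Use [analysisConfig()] to construct.
#'
#' @slot epochWindowMs,analysisWindowMs,baselineWindowMs time windows in
#'   ms relative to onset, closed on the left, open on the right.
#' @slot bands named list of `c(lo, hi)` band edges in Hz.
#' @slot timeBandpassHz,tfrBandpassHz FIR band edges for the time-domain
#'   and time-frequency branches.
#' @slot nPermutations,alphaCluster,alphaForming permutation test control.
#' @slot waveletCycles,tfrTimeStepMs Morlet cycles and output grid step.
#' @slot adjacencyMaxDistMm electrode neighbourhood radius.
#' @slot logBase `"db10"` or `"natural"`; @slot baselineStat
#'   `"geometric"` or `"arithmetic"` baseline mean of power.
#' @slot clusterStat `"mass"` or `"size"`.
#' @slot nullMethod how the max-cluster-statistic null is sampled:
#'   `"shift"` (time-shift surrogate, default), `"bootstrap"` (centered
#'   bootstrap-t) or `"signflip"` (classical sign-flip, exact only for
#'   symmetric normalized power). See [permutationTest()].
#' @slot carEnabled apply per-grid common average reference.
#' @slot rngSeed seed for the permutation RNG.
#' @export
setClass("AnalysisConfig",
  representation(epochWindowMs = "numeric", analysisWindowMs = "numeric",
                 baselineWindowMs = "numeric", bands = "list",
                 timeBandpassHz = "numeric", tfrBandpassHz = "numeric",
                 nPermutations = "integer", alphaCluster = "numeric",
                 alphaForming = "numeric", waveletCycles = "numeric",
                 tfrTimeStepMs = "numeric", adjacencyMaxDistMm = "numeric",
                 logBase = "character", baselineStat = "character",
                 clusterStat = "character", nullMethod = "character",
                 carEnabled = "logical", rngSeed = "integer"),
  validity = function(object) {
    msg <- character()
    win2 <- function(w) length(w) == 2L && all(is.finite(w)) && w[1] < w[2]
    for (nm in c("epochWindowMs", "analysisWindowMs", "baselineWindowMs",
                 "timeBandpassHz", "tfrBandpassHz"))
      if (!win2(slot(object, nm)))
        msg <- c(msg, sprintf("%s must be an ordered pair", nm))
    for (b in names(object@bands)) {
      e <- object@bands[[b]]
      if (!win2(e) || any(e <= 0))
        msg <- c(msg, sprintf("band %s edges must be positive and ordered", b))
    }
    if (object@nPermutations < 100L)
      msg <- c(msg, "nPermutations must be >= 100")
    if (!object@logBase %in% c("db10", "natural"))
      msg <- c(msg, "logBase must be db10 or natural")
    if (!object@baselineStat %in% c("geometric", "arithmetic"))
      msg <- c(msg, "baselineStat must be geometric or arithmetic")
    if (!object@clusterStat %in% c("mass", "size"))
      msg <- c(msg, "clusterStat must be mass or size")
    if (!object@nullMethod %in% c("shift", "bootstrap", "signflip"))
      msg <- c(msg, "nullMethod must be shift, bootstrap or signflip")
    if (length(msg)) msg else TRUE
  })

#' Synthetic session configuration
#'
#' Parameters of the simulated vibrotactile ECoG session; defaults follow
#' the study design (randomised single-finger 200 Hz vibration, 100-500 ms
#' duration, 1-1.4 s inter-stimulation interval, 10 trials per finger per
#' set, 8 x 8 grid at 10 mm pitch recorded at 500 Hz). Use [simConfig()].
#'
#' @slot nSets number of stimulation sets (50 trials each).
#' @slot trialsPerFinger trials per finger per set.
#' @slot stimDurationRangeMs,isiRangeMs uniform ranges for vibration
#'   duration and offset-to-onset inter-stimulation interval.
#' @slot fs sampling rate (Hz).
#' @slot gridShape `c(rows, cols)`; @slot gridPitchMm inter-contact
#'   distance in mm.
#' @slot fingerSites labels of the five target electrodes, thumb first,
#'   on a latero-medial line.
#' @slot erpComponents `data.frame` (`label`, `latency_ms`,
#'   `amplitude_uv`, `width_ms`, `polarity`) of evoked components.
#' @slot ersBandHz,ersOnsetMs,ersDurationMs,ersAmpUv mid-gamma burst:
#'   band, onset after stimulus, duration, RMS amplitude in microvolts.
#' @slot erdBandHz,erdAttenuation,erdWindowMs alpha/beta desynchronisation:
#'   band, fractional attenuation of band amplitude, window.
#' @slot spatialSigmaMm Gaussian spatial falloff of all injected responses.
#' @slot backgroundExponent,backgroundRmsUv 1/f^exponent background and
#'   its per-channel RMS.
#' @slot interictalRateHz rate of random biphasic interictal transients
#'   (default 0 = off); @slot lineNoise60Uv amplitude of a shared 60 Hz
#'   sinusoid (default 0 = off).
#' @slot onsetLatencyOffsetMs constant stimulator latency added to every
#'   injected response (default 0).
#' @slot hands hand(s) stimulated, cycled over sets; @slot task task code.
#' @slot ilResponse if `TRUE`, ipsilateral events receive a weak delayed
#'   response (demonstration only; default `FALSE`, i.e. none).
#' @slot seed RNG seed.
#' @export
setClass("SimConfig",
  representation(nSets = "integer", trialsPerFinger = "integer",
                 stimDurationRangeMs = "numeric", isiRangeMs = "numeric",
                 fs = "numeric", gridShape = "integer",
                 gridPitchMm = "numeric", fingerSites = "character",
                 erpComponents = "data.frame", ersBandHz = "numeric",
                 ersOnsetMs = "numeric", ersDurationMs = "numeric",
                 ersAmpUv = "numeric", erdBandHz = "numeric",
                 erdAttenuation = "numeric", erdWindowMs = "numeric",
                 spatialSigmaMm = "numeric", backgroundExponent = "numeric",
                 backgroundRmsUv = "numeric", interictalRateHz = "numeric",
                 lineNoise60Uv = "numeric", onsetLatencyOffsetMs = "numeric",
                 hands = "character", task = "character",
                 ilResponse = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSets < 1L || object@trialsPerFinger < 1L)
      msg <- c(msg, "nSets and trialsPerFinger must be >= 1")
    rng <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] < r[2]
    if (!rng(object@stimDurationRangeMs) || object@stimDurationRangeMs[1] <= 0)
      msg <- c(msg, "stimDurationRangeMs must be a positive ordered pair")
    if (!rng(object@isiRangeMs) || object@isiRangeMs[1] <= 0)
      msg <- c(msg, "isiRangeMs must be a positive ordered pair")
    if (length(object@fingerSites) != 5L ||
        anyDuplicated(object@fingerSites))
      msg <- c(msg, "fingerSites must be 5 distinct electrode labels")
    if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
      msg <- c(msg, "gridShape must be c(rows, cols)")
    if (!rng(object@ersBandHz) || object@ersBandHz[2] >= object@fs / 2)
      msg <- c(msg, "ersBandHz must lie within (0, fs/2)")
    if (object@erdAttenuation < 0 || object@erdAttenuation > 1)
      msg <- c(msg, "erdAttenuation must be in [0, 1]")
    if (!all(object@hands %in% c("CL", "IL")))
      msg <- c(msg, "hands must be CL and/or IL")
    if (length(msg)) msg else TRUE
  })
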