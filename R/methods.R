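#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an ECoG recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelNames optional channel labels; defaults to existing row
#'   names.
#' @param startTime offset of the first sample in seconds.
#' @return An [EcogRecording-class].
#' @examples
#' rec <- ecogRecording(matrix(rnorm(200), 2), fs = 100,
#'                      channelNames = c("e1", "e2"))
#' nChannels(rec)
#' @export
ecogRecording <- function(data, fs, channelNames = rownames(data),
                          startTime = 0) {
  data <- as.matrix(data)
  if (is.null(channelNames))
    stop("channel names are required")
  if (length(channelNames) != nrow(data))
    stop("number of channel names must equal the number of data rows")
  rownames(data) <- channelNames
  new("EcogRecording", data = data, fs = as.numeric(fs),
      startTime = as.numeric(startTime))
}

#' @describeIn ecogRecording signal matrix accessor.
#' @param x an `EcogRecording`.
#' @export
signalData <- function(x) x@data

#' @describeIn ecogRecording number of samples.
#' @export
nSamples <- function(x) ncol(x@data)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EcogRecording", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TrialTensor", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TFRTensor", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "Evoked", function(x) x@fs)

#' @rdname channelNames
#' @export
setMethod("channelNames", "EcogRecording", function(x) rownames(x@data))
#' @rdname channelNames
#' @export
setMethod("channelNames", "TrialTensor", function(x) dimnames(x@data)[[2]])
#' @rdname channelNames
#' @export
setMethod("channelNames", "TFRTensor", function(x) dimnames(x@power)[[2]])
#' @rdname channelNames
#' @export
setMethod("channelNames", "Evoked", function(x) rownames(x@data))

#' @rdname nChannels
#' @export
setMethod("nChannels", "EcogRecording", function(x) nrow(x@data))
#' @rdname nChannels
#' @export
setMethod("nChannels", "TrialTensor", function(x) dim(x@data)[2])
#' @rdname nChannels
#' @export
setMethod("nChannels", "TFRTensor", function(x) dim(x@power)[2])

#' @rdname timeMs
#' @export
setMethod("timeMs", "TrialTensor", function(x) x@timeMs)
#' @rdname timeMs
#' @export
setMethod("timeMs", "TFRTensor", function(x) x@timeMs)
#' @rdname timeMs
#' @export
setMethod("timeMs", "Evoked", function(x) x@timeMs)

#' @rdname nTrials
#' @export
setMethod("nTrials", "TrialTensor", function(x) dim(x@data)[1])
#' @rdname nTrials
#' @export
setMethod("nTrials", "TFRTensor", function(x) dim(x@power)[1])
#' @rdname nTrials
#' @export
setMethod("nTrials", "Evoked", function(x) x@nTrials)

#' @rdname trialLabels
#' @export
setMethod("trialLabels", "TrialTensor", function(x) x@labels)
#' @rdname trialLabels
#' @export
setMethod("trialLabels", "TFRTensor", function(x) x@labels)

#' @rdname freqsHz
#' @export
setMethod("freqsHz", "TFRTensor", function(x) x@freqsHz)

#' Trial data accessor
#'
#' @param x a [TrialTensor-class].
#' @return The trial x channel x time array.
#' @export
trialData <- function(x) x@data

#' TFR power accessor
#'
#' @param x a [TFRTensor-class].
#' @return The trial x channel x frequency x time array (raw power or
#'   normalized log-ratio values, see `isNormalized`).
#' @export
tfrPower <- function(x) x@power

#' @describeIn tfrPower whether the tensor is baseline-normalized.
#' @export
isNormalized <- function(x) x@normalized

#' @rdname clusterTable
#' @export
setMethod("clusterTable", "ClusterResult", function(x) x@table)

#' Member cells of each cluster
#'
#' @param x a [ClusterResult-class].
#' @return List of `data.frame`s (`channel`, `freq_hz`, `time_ms`, `t`),
#'   one per cluster, parallel to [clusterTable()].
#' @export
clusterMembers <- function(x) x@members

#' Significant clusters of a result
#'
#' @param x a [ClusterResult-class].
#' @return The rows of [clusterTable()] with `p_value <= alpha`.
#' @export
significantClusters <- function(x) x@table[x@table$significant, , drop = FALSE]

#' @rdname centroids
#' @export
setMethod("centroids", "FingerMap", function(x) x@centroids)
#' @rdname mapSpan
#' @export
setMethod("mapSpan", "FingerMap", function(x) x@spanMm)
#' @rdname orderScore
#' @export
setMethod("orderScore", "FingerMap", function(x) x@orderScore)

setMethod("show", "EcogRecording", function(object) {
  cat(sprintf("EcogRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialTensor: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  time %g..%g ms; fingers: %s\n", min(object@timeMs),
              max(object@timeMs),
              paste(sort(unique(object@labels$finger)), collapse = " ")))
})

setMethod("show", "TFRTensor", function(object) {
  d <- dim(object@power)
  cat(sprintf(
    "TFRTensor: %d trials x %d channels x %d freqs x %d times (%s)\n",
    d[1], d[2], d[3], d[4],
    if (object@normalized) paste0("normalized, ", object@logBase)
    else "raw power"))
})

setMethod("show", "Evoked", function(object) {
  cat(sprintf("Evoked: %d channels x %d samples, mean of %d trials\n",
              nrow(object@data), ncol(object@data), object@nTrials))
  if (length(object@group))
    cat("  group:", paste(names(object@group), unlist(object@group),
                          sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  ns <- sum(object@table$significant)
  cat(sprintf(
    "ClusterResult [%s %s finger %d]: %d clusters (%d significant at %g), %d permutations\n",
    object@condition, object@band, object@finger, nrow(object@table), ns,
    object@alpha, object@nPermutations))
})

setMethod("show", "FingerMap", function(object) {
  cat(sprintf("FingerMap: %d/5 fingers mapped; span %.1f mm; order score %s\n",
              sum(object@centroids$mapped), object@spanMm,
              format(object@orderScore)))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n")
  cat(sprintf("  epoch %g..%g ms; analysis %g..%g ms; baseline %g..%g ms\n",
              object@epochWindowMs[1], object@epochWindowMs[2],
              object@analysisWindowMs[1], object@analysisWindowMs[2],
              object@baselineWindowMs[1], object@baselineWindowMs[2]))
  cat("  bands:", paste(sprintf("%s %g-%g", names(object@bands),
                                vapply(object@bands, `[`, 0, 1),
                                vapply(object@bands, `[`, 0, 2)),
                        collapse = ", "), "Hz\n")
  cat(sprintf("  %d permutations, alpha %g (forming %g), %g wavelet cycles\n",
              object@nPermutations, object@alphaCluster, object@alphaForming,
              object@waveletCycles))
  cat(sprintf("  %s null, cluster %s, %s baseline, CAR %s\n",
              object@nullMethod, object@clusterStat, object@baselineStat,
              if (object@carEnabled) "on" else "off"))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d set(s) x %d trials/finger, %dx%d grid @ %g mm, fs %g Hz, seed %d\n",
    object@nSets, object@trialsPerFinger, object@gridShape[1],
    object@gridShape[2], object@gridPitchMm, object@fs, object@seed))
})
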