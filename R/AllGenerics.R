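#' @include AllClasses.R
NULL

#' Sampling rate accessor
#'
#' @param x An object carrying a sampling rate (e.g. [EcogRecording-class],
#'   [TrialTensor-class], [TFRTensor-class]).
#' @return Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel name accessor
#'
#' @param x An object with named channels.
#' @return Character vector of channel labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Number of channels
#'
#' @param x An object with channels.
#' @return Integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Time axis accessor
#'
#' @param x An object with a time axis relative to stimulus onset.
#' @return Numeric vector of times in milliseconds.
#' @export
setGeneric("timeMs", function(x) standardGeneric("timeMs"))

#' Number of trials
#'
#' @param x A trial-indexed object.
#' @return Integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Per-trial label accessor
#'
#' @param x A trial-indexed object.
#' @return A `data.frame` with one row per trial (columns `finger`, `hand`,
#'   `task`, `onset_ms`).
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' Frequency axis accessor
#'
#' @param x A time-frequency object.
#' @return Numeric vector of analysis frequencies in Hz.
#' @export
setGeneric("freqsHz", function(x) standardGeneric("freqsHz"))

#' Cluster summary table accessor
#'
#' @param x A [ClusterResult-class] (or list thereof).
#' @return A `data.frame` with one row per cluster: sign, size, mass,
#'   onset, Monte Carlo p-value and significance flag.
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' Finger centroid table accessor
#'
#' @param x A [FingerMap-class].
#' @return A `data.frame` with one row per finger.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' Somatotopic map span
#'
#' Maximum pairwise distance between mapped finger centroids.
#'
#' @param x A [FingerMap-class].
#' @return Span in mm, or `NA` if fewer than two fingers are mapped.
#' @export
setGeneric("mapSpan", function(x) standardGeneric("mapSpan"))

#' Somatotopic order score
#'
#' Spearman rank correlation between finger index (1 = thumb ... 5 = small
#' finger) and the centroid position projected on the latero-medial axis.
#'
#' @param x A [FingerMap-class].
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
setGeneric("orderScore", function(x) standardGeneric("orderScore"))
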