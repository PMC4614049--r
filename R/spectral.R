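#' @include AllClasses.R methods.R preprocess.R
NULL

#' Analysis frequencies of a band set
#'
#' Integer (1 Hz-spaced) frequencies covered by the configured bands,
#' band edges inclusive; frequencies in the gaps between bands (e.g.
#' 55-65 and 115-125 Hz with the defaults) are not analysed.
#'
#' @param bands named list of `c(lo, hi)` pairs.
#' @return Sorted unique integer frequencies in Hz.
#' @export
bandFrequencies <- function(bands = defaultBands()) {
  sort(unique(unlist(lapply(bands, function(b) seq(b[1], b[2], by = 1)))))
}

#' Morlet wavelet time-frequency decomposition
#'
#' Complex Morlet transform (Gaussian envelope, `nCycles` cycles at every
#' frequency) computed by multiplication in the frequency domain over the
#' full epoch, with power sampled on a `timeStepMs` output grid. The
#' wavelet's spectrum is a unit-peak Gaussian of width
#' `sigma_f = f / nCycles`; negative frequencies are zeroed (analytic
#' signal), so power is the squared magnitude of the analytic wavelet
#' coefficient. Frequencies whose `nCycles`-cycle wavelet does not fit in
#' the epoch, or that reach Nyquist, are dropped with a warning.
#'
#' @param trials a [TrialTensor-class] (typically full -1000..1000 ms
#'   epochs, so that edge effects can be cropped away afterwards).
#' @param freqsHz analysis frequencies (default: the study bands at 1 Hz
#'   spacing).
#' @param nCycles Morlet cycles (default 7).
#' @param timeStepMs output grid step (default 20 ms).
#' @param outWindowMs optional window restricting the output grid (e.g.
#'   `c(-160, 500)` to keep just baseline + analysis interval); default
#'   keeps the full epoch.
#' @return A raw-power [TFRTensor-class] (microvolts squared).
#' @export
morletTfr <- function(trials, freqsHz = bandFrequencies(), nCycles = 7,
                      timeStepMs = 20, outWindowMs = NULL) {
  fs <- samplingRate(trials)
  nT <- length(trials@timeMs)
  epochS <- nT / fs
  ok <- freqsHz < fs / 2 & nCycles / freqsHz <= epochS
  if (!all(ok)) {
    warning(sprintf("%d frequency(ies) dropped (wavelet exceeds epoch or Nyquist)",
                    sum(!ok)))
    freqsHz <- freqsHz[ok]
  }
  if (!length(freqsHz)) stop("no analysable frequencies left")

  d <- round(timeStepMs / 1000 * fs)
  if (d < 1) stop("timeStepMs below one sample")
  # output grid: epoch samples whose onset-relative offset is a multiple
  # of the step
  offs <- round(trials@timeMs * fs / 1000)
  outPos <- which(offs %% d == 0)
  outTimeMs <- trials@timeMs[outPos]
  if (!is.null(outWindowMs)) {
    keep <- outTimeMs >= outWindowMs[1] & outTimeMs < outWindowMs[2]
    outPos <- outPos[keep]; outTimeMs <- outTimeMs[keep]
  }
  foldable <- nT %% d == 0 && all((outPos - 1L) %% d == 0L)

  nt <- nTrials(trials); nc <- nChannels(trials)
  binHz <- fs / nT
  fbins <- (seq_len(nT) - 1) * binHz
  oneSided <- fbins <= fs / 2
  W <- vapply(freqsHz, function(f) {
    sf <- f / nCycles
    w <- exp(-0.5 * ((fbins - f) / sf)^2)
    w[!oneSided] <- 0
    w
  }, numeric(nT))

  nout <- length(outPos)
  out <- array(0, c(nt, nc, length(freqsHz), nout),
               dimnames = list(NULL, channelNames(trials), NULL, NULL))
  S <- matrix(aperm(trials@data, c(3, 1, 2)), nrow = nT)   # trial fastest
  chansPerChunk <- max(1L, floor(4e6 / (nT * nt)))
  for (c0 in seq(1L, nc, by = chansPerChunk)) {
    chs <- c0:min(nc, c0 + chansPerChunk - 1L)
    cols <- ((chs[1] - 1L) * nt + 1L):(chs[length(chs)] * nt)
    Fhat <- stats::mvfft(S[, cols, drop = FALSE])
    for (fi in seq_along(freqsHz)) {
      Y <- Fhat * W[, fi]
      if (foldable) {
        nd <- nT %/% d
        Z <- array(Y, c(nd, d, length(cols)))
        acc <- array(Z[, 1, ], c(nd, length(cols)))
        for (b in seq_len(d)[-1])
          acc <- acc + array(Z[, b, ], c(nd, length(cols)))
        z <- stats::mvfft(acc, inverse = TRUE) / nT
        p <- abs(z[((outPos - 1L) %/% d) + 1L, , drop = FALSE])^2
      } else {
        z <- stats::mvfft(Y, inverse = TRUE) / nT
        p <- abs(z[outPos, , drop = FALSE])^2
      }
      # p: time x (trial-fastest, channel) block -> trial x channel x time
      out[, chs, fi, ] <- array(t(p), c(nt, length(chs), nout))
    }
  }
  new("TFRTensor", power = out, freqsHz = freqsHz, timeMs = outTimeMs,
      labels = trials@labels, fs = fs, normalized = FALSE,
      logBase = "none")
}

#' Baseline normalisation of wavelet power
#'
#' Converts raw power to stimulus-locked change relative to the pre-
#' stimulus baseline: positive values are event-related synchronisation
#' (ERS), negative values desynchronisation (ERD). For each trial,
#' channel and frequency the baseline level is the mean over
#' `baselineMs` (default -150..-10 ms); with
#' `baselineStat = "geometric"` (default) the geometric mean is used,
#' i.e. values are `log(P) - mean(log(P_baseline))`, which centres the
#' null distribution of stochastic power at 0 (see the methods
#' vignette); `"arithmetic"` divides by the arithmetic-mean baseline
#' power. `logBase = "db10"` scales to decibels (`10*log10`),
#' `"natural"` uses the natural logarithm.
#'
#' @param tfr a raw-power [TFRTensor-class] whose time grid covers the
#'   baseline window.
#' @param baselineMs baseline window (closed-open).
#' @param logBase `"db10"` (default) or `"natural"`.
#' @param baselineStat `"geometric"` (default) or `"arithmetic"`.
#' @return The normalized [TFRTensor-class].
#' @export
baselineNormalize <- function(tfr, baselineMs = c(-150, -10),
                              logBase = c("db10", "natural"),
                              baselineStat = c("geometric", "arithmetic")) {
  logBase <- match.arg(logBase)
  baselineStat <- match.arg(baselineStat)
  if (tfr@normalized) stop("TFR is already normalized")
  idx <- tfr@timeMs >= baselineMs[1] & tfr@timeMs < baselineMs[2]
  if (!any(idx)) stop("baseline window not covered by the TFR time grid")
  P <- tfr@power
  dm <- dim(P)
  B <- P[, , , idx, drop = FALSE]
  dim(B) <- c(prod(dm[1:3]), sum(idx))
  bad <- which(rowSums(B <= 0) > 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dm[1:3])
    stop(sprintf(
      "degenerate input: non-positive baseline power at trial %d, channel %s, %g Hz",
      i[1], channelNames(tfr)[i[2]], tfr@freqsHz[i[3]]))
  }
  scale <- if (logBase == "db10") 10 / log(10) else 1
  if (baselineStat == "geometric") {
    L <- log(P)
    m <- rowMeans(matrix(L[, , , idx], prod(dm[1:3]), sum(idx)))
    out <- scale * (L - array(m, dm))
  } else {
    m <- rowMeans(B)
    out <- scale * log(P / array(m, dm))
  }
  dimnames(out) <- dimnames(P)
  initialize(tfr, power = out, normalized = TRUE, logBase = logBase)
}

#' Crop a TFR to a time window
#'
#' @param tfr a [TFRTensor-class].
#' @param windowMs window (closed-open), inside the current grid.
#' @return The cropped [TFRTensor-class].
#' @export
cropTfr <- function(tfr, windowMs = c(-150, 500)) {
  idx <- tfr@timeMs >= windowMs[1] & tfr@timeMs < windowMs[2]
  if (!any(idx)) stop("crop window outside TFR time grid")
  initialize(tfr, power = tfr@power[, , , idx, drop = FALSE],
             timeMs = tfr@timeMs[idx])
}

#' Restrict a TFR to one frequency band
#'
#' @param tfr a [TFRTensor-class].
#' @param bandHz `c(lo, hi)` in Hz, edges inclusive.
#' @return The band-restricted [TFRTensor-class].
#' @export
bandTfr <- function(tfr, bandHz) {
  idx <- tfr@freqsHz >= bandHz[1] & tfr@freqsHz <= bandHz[2]
  if (!any(idx)) stop("band not covered by analysed frequencies")
  initialize(tfr, power = tfr@power[, , idx, , drop = FALSE],
             freqsHz = tfr@freqsHz[idx])
}
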