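#' @include AllClasses.R methods.R io.R
NULL

#' Segment a recording into trials
#'
#' Cuts one epoch per event, `windowMs` relative to stimulus onset
#' (closed on the left, open on the right; default -1000..1000 ms, i.e. 2 s
#' trials centred on onset). Events whose epoch extends outside the
#' recording are dropped with a warning.
#'
#' @param rec an [EcogRecording-class].
#' @param events validated event table.
#' @param windowMs epoch window in ms.
#' @return A [TrialTensor-class].
#' @examples
#' rec <- ecogRecording(matrix(rnorm(4000), 2), 500, c("a", "b"))
#' ev <- data.frame(onset_ms = c(2000, 4000), duration_ms = 300,
#'                  finger = 1:2, hand = "CL", task = "s")
#' epochTrials(rec, ev, c(-500, 500))
#' @export
epochTrials <- function(rec, events, windowMs = c(-1000, 1000)) {
  events <- validateEvents(events, rec)
  fs <- samplingRate(rec)
  off <- seq(round(windowMs[1] / 1000 * fs),
             round(windowMs[2] / 1000 * fs) - 1L)
  ns <- nSamples(rec)
  i0 <- round(events$onset_ms / 1000 * fs) + 1L
  ok <- i0 + off[1] >= 1L & i0 + off[length(off)] <= ns
  if (!all(ok))
    warning(sprintf("%d event(s) dropped: epoch outside recording",
                    sum(!ok)))
  if (!any(ok)) stop("no usable events: every epoch falls outside recording")
  i0 <- i0[ok]
  nt <- length(i0); nc <- nChannels(rec); nT <- length(off)
  data <- array(0, c(nt, nc, nT),
                dimnames = list(NULL, channelNames(rec), NULL))
  sig <- signalData(rec)
  for (t in seq_len(nt))
    data[t, , ] <- sig[, i0[t] + off]
  labels <- events[ok, c("finger", "hand", "task", "onset_ms"),
                   drop = FALSE]
  rownames(labels) <- NULL
  new("TrialTensor", data = data, timeMs = off / fs * 1000,
      labels = labels, fs = fs)
}

#' Per-grid common average reference
#'
#' Subtracts, per grid, trial and time point, the instantaneous mean of
#' that grid's channels from each of its channels. With
#' `enabled = FALSE` this is the identity (the reference choice is an
#' explicit flag; no automatic common-noise detection is attempted).
#'
#' @param trials a [TrialTensor-class].
#' @param layout electrode layout with a `grid_id` per channel.
#' @param enabled apply the reference (default `TRUE`).
#' @return The re-referenced [TrialTensor-class].
#' @export
commonAverageReference <- function(trials, layout, enabled = TRUE) {
  if (!enabled) return(trials)
  layout <- validateElectrodes(layout)
  chans <- channelNames(trials)
  pos <- match(chans, layout$name)
  if (anyNA(pos))
    stop("layout misses channel(s): ",
         paste(chans[is.na(pos)], collapse = ", "))
  grid <- layout$grid_id[pos]
  data <- trials@data
  for (g in unique(grid)) {
    idx <- which(grid == g)
    if (length(idx) < 2L)
      stop("configuration error: grid ", g,
           " has fewer than 2 channels; CAR undefined")
    m <- colMeans(aperm(data[, idx, , drop = FALSE], c(2, 1, 3)))
    for (ch in idx) data[, ch, ] <- data[, ch, ] - m
  }
  initialize(trials, data = data)
}

# Hamming-window linear-phase FIR band-pass taps (odd length, type I).
firBandpassTaps <- function(loHz, hiHz, fs, transitionHz = 10) {
  if (hiHz >= fs / 2)
    stop("configuration error: high edge must be below Nyquist")
  if (loHz <= 0 || loHz >= hiHz)
    stop("configuration error: need 0 < lo < hi")
  n <- 2L * floor(3.3 * fs / transitionHz / 2)
  signal::fir1(n, c(loHz, hiHz) * 2 / fs, type = "pass")
}

# Zero-phase two-pass filtering of every time series of a TrialTensor:
# convolution with b * rev(b) via FFT, centred so net delay is zero.
# Edge transients decay within one kernel length and fall outside the
# later analysis crop.
filterTwoPass <- function(data, b) {
  d <- dim(data)
  nT <- d[3]
  h2 <- stats::convolve(b, b, type = "open")    # b * rev(b), symmetric
  L <- length(b)
  N2 <- stats::nextn(nT + 2 * (L - 1), c(2, 3, 5))
  hpad <- numeric(N2)
  hpad[1:L] <- h2[L:(2 * L - 1)]                # causal half at 0
  hpad[N2 - (1:(L - 1)) + 1] <- h2[(L - 1):1]   # anticausal half wrapped
  H <- stats::fft(hpad)
  S <- matrix(aperm(data, c(3, 1, 2)), nrow = nT)
  ncolS <- ncol(S)
  out <- matrix(0, nT, ncolS)
  chunk <- max(1L, floor(4e6 / N2))
  for (j0 in seq(1L, ncolS, by = chunk)) {
    cols <- j0:min(ncolS, j0 + chunk - 1L)
    P <- matrix(0, N2, length(cols))
    P[1:nT, ] <- S[, cols, drop = FALSE]
    Y <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / N2
    out[, cols] <- Y[1:nT, , drop = FALSE]
  }
  aperm(array(out, c(nT, d[1], d[2])), c(2, 3, 1))
}

#' Zero-phase FIR band-pass filtering
#'
#' Two-pass (forward-backward) windowed linear-phase FIR applied to every
#' trial and channel: zero net phase, passband amplitude preserved, at
#' least 40 dB attenuation one octave above the high edge. Taps are a
#' Hamming-window design of order `3.3 * fs / transition` with a 10 Hz
#' transition band.
#'
#' @param trials a [TrialTensor-class].
#' @param loHz,hiHz band edges in Hz (0 < lo < hi < fs/2).
#' @return The filtered [TrialTensor-class].
#' @export
bandpassFir <- function(trials, loHz, hiHz) {
  b <- firBandpassTaps(loHz, hiHz, samplingRate(trials))
  out <- filterTwoPass(trials@data, b)
  dimnames(out) <- dimnames(trials@data)
  initialize(trials, data = out)
}

#' Baseline correction of time-domain trials
#'
#' Removes, per trial and channel, the mean over the baseline window
#' (default -150..-10 ms, closed-open) from the whole trial.
#'
#' @param trials a [TrialTensor-class].
#' @param baselineMs baseline window in ms.
#' @return The corrected [TrialTensor-class].
#' @export
baselineCorrectTime <- function(trials, baselineMs = c(-150, -10)) {
  idx <- trials@timeMs >= baselineMs[1] & trials@timeMs < baselineMs[2]
  if (!any(idx))
    stop("configuration error: empty baseline window")
  B <- trials@data[, , idx, drop = FALSE]
  dim(B) <- c(prod(dim(trials@data)[1:2]), sum(idx))
  m <- rowMeans(B)
  out <- trials@data - array(m, dim(trials@data))
  dimnames(out) <- dimnames(trials@data)
  initialize(trials, data = out)
}

#' Crop trials to a shorter window
#'
#' Restricts the time axis to `windowMs` (closed-open); data on retained
#' samples are untouched. The default -150..500 ms analysis window keeps
#' filter and wavelet edge effects outside the analysed interval.
#'
#' @param trials a [TrialTensor-class].
#' @param windowMs requested window, inside the current extent.
#' @return The cropped [TrialTensor-class].
#' @export
cropTrials <- function(trials, windowMs = c(-150, 500)) {
  dt <- 1000 / samplingRate(trials)
  tm <- trials@timeMs
  if (windowMs[1] < tm[1] || windowMs[2] > tm[length(tm)] + dt)
    stop("crop window outside current trial extent")
  idx <- tm >= windowMs[1] & tm < windowMs[2]
  initialize(trials, data = trials@data[, , idx, drop = FALSE],
             timeMs = tm[idx])
}

#' Subset trials
#'
#' @param x a [TrialTensor-class] or [TFRTensor-class].
#' @param idx trial indices or a logical mask.
#' @return Object of the same class restricted to those trials.
#' @export
selectTrials <- function(x, idx) {
  if (is(x, "TrialTensor"))
    return(initialize(x, data = x@data[idx, , , drop = FALSE],
                      labels = x@labels[idx, , drop = FALSE]))
  if (is(x, "TFRTensor"))
    return(initialize(x, power = x@power[idx, , , , drop = FALSE],
                      labels = x@labels[idx, , drop = FALSE]))
  stop("selectTrials: unsupported class ", class(x))
}
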