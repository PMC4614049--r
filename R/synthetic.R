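#' @include AllClasses.R config.R io.R
NULL

#' Electrode layout of the synthetic grid
#'
#' Builds the rectangular grid described by a [SimConfig-class]:
#' electrodes named `e01`, `e02`, ... row-major, x = latero-medial axis,
#' y = row axis, z = 0, one grid id `G1`.
#'
#' @param cfg a [SimConfig-class].
#' @return Electrode layout `data.frame` (see [validateElectrodes()]).
#' @export
gridLayout <- function(cfg) {
  nr <- cfg@gridShape[1]; nc <- cfg@gridShape[2]
  idx <- seq_len(nr * nc)
  row <- (idx - 1L) %/% nc
  col <- (idx - 1L) %% nc
  validateElectrodes(data.frame(
    name = sprintf("e%02d", idx),
    x = col * cfg@gridPitchMm,
    y = row * cfg@gridPitchMm,
    z = 0, grid_id = "G1"))
}

#' Schedule randomised vibrotactile stimulation events
#'
#' Per set, each finger appears exactly `trialsPerFinger` times in random
#' order; vibration durations are uniform in `stimDurationRangeMs` and
#' offset-to-onset gaps uniform in `isiRangeMs`. Sets are separated by a
#' 2 s pause; the first onset follows a 2 s lead-in. Uses the current R
#' RNG state unless `seed` is given.
#'
#' @param cfg a [SimConfig-class].
#' @param seed optional RNG seed.
#' @return Validated event `data.frame` with strictly increasing onsets.
#' @examples
#' ev <- scheduleEvents(simConfig(nSets = 1), seed = 1)
#' table(ev$finger)
#' @export
scheduleEvents <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  leadMs <- 2000; gapMs <- 2000
  t <- leadMs
  rows <- vector("list", cfg@nSets)
  for (s in seq_len(cfg@nSets)) {
    fingers <- sample(rep(1:5, cfg@trialsPerFinger))
    n <- length(fingers)
    dur <- stats::runif(n, cfg@stimDurationRangeMs[1],
                        cfg@stimDurationRangeMs[2])
    isi <- stats::runif(n, cfg@isiRangeMs[1], cfg@isiRangeMs[2])
    onset <- t + c(0, cumsum(dur[-n] + isi[-n]))
    rows[[s]] <- data.frame(
      onset_ms = onset, duration_ms = dur, finger = fingers,
      hand = cfg@hands[(s - 1L) %% length(cfg@hands) + 1L],
      task = cfg@task)
    t <- onset[n] + dur[n] + isi[n] + gapMs
  }
  validateEvents(do.call(rbind, rows))
}

#' Generate 1/f-type background activity
#'
#' Gaussian noise shaped in the frequency domain so that each channel's
#' power spectral density is proportional to 1/f^exponent, scaled to an
#' exact per-channel RMS; optionally adds a shared 60 Hz sinusoid
#' identically to every channel.
#'
#' @param cfg a [SimConfig-class] (`backgroundExponent`,
#'   `backgroundRmsUv`, `lineNoise60Uv`, `fs`).
#' @param nChannels,nSamples output size.
#' @return channels x samples numeric matrix (microvolts).
#' @export
backgroundNoise <- function(cfg, nChannels, nSamples) {
  stopifnot(nSamples > 0)
  # shape at an FFT-friendly length and truncate: R's mixed-radix FFT is
  # O(n^2) when n has a large prime factor
  n <- smoothLength(nSamples)
  freqs <- seq(0, n - 1) * cfg@fs / n
  freqs <- pmin(freqs, cfg@fs - freqs)          # two-sided frequency axis
  shape <- rep(0, n)
  nz <- freqs > 0
  shape[nz] <- freqs[nz] ^ (-cfg@backgroundExponent / 2)
  white <- matrix(stats::rnorm(nChannels * n), n, nChannels)
  spec <- stats::mvfft(white) * shape
  col <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  col <- col[seq_len(nSamples), , drop = FALSE]
  rms <- sqrt(colMeans(col ^ 2))
  out <- t(col) * (cfg@backgroundRmsUv / rms)
  if (cfg@lineNoise60Uv > 0) {
    tt <- seq_len(nSamples) / cfg@fs
    line <- cfg@lineNoise60Uv *
      sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi))
    out <- out + matrix(line, nChannels, n, byrow = TRUE)
  }
  out
}

# Gaussian spatial falloff weights of one site over the layout; electrodes
# with weight below `cut` are dropped.
spatialWeights <- function(layout, site, sigmaMm, cut = 0.01) {
  i <- match(site, layout$name)
  if (is.na(i)) stop("finger site not found in layout: ", site)
  d2 <- (layout$x - layout$x[i])^2 + (layout$y - layout$y[i])^2 +
    (layout$z - layout$z[i])^2
  w <- exp(-d2 / (2 * sigmaMm^2))
  keep <- w >= cut
  data.frame(name = layout$name[keep], weight = w[keep])
}

# Smallest 2-3-5-smooth integer >= n (R's FFT is fast only for such
# lengths; a large prime length degrades it to quadratic time).
smoothLength <- function(n) {
  best <- Inf
  p5 <- 1
  while (p5 < 5 * n) {
    p35 <- p5
    while (p35 < 5 * n) {
      m <- p35 * 2 ^ max(0, ceiling(log2(n / p35)))
      if (m >= n && m < best) best <- m
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

# Band-limited unit-RMS Gaussian noise of n samples via a hard FFT mask.
bandNoise <- function(n, bandHz, fs) {
  x <- stats::rnorm(n)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= bandHz[1] & f <= bandHz[2])
  y <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
  y / sqrt(mean(y ^ 2))
}

# Hann on/off envelope with `ramp` samples on each side.
rampEnvelope <- function(n, ramp) {
  env <- rep(1, n)
  if (ramp > 0 && n >= 2 * ramp) {
    r <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[seq_len(ramp)] <- r
    env[n + 1 - seq_len(ramp)] <- rev(r)
  }
  env
}

# FFT band-pass of every row of a matrix (hard mask; used for the ERD
# manipulation of ongoing band content).
fftBandpassRows <- function(x, bandHz, fs) {
  n0 <- ncol(x)
  n <- smoothLength(n0)
  xp <- cbind(x, matrix(0, nrow(x), n - n0))    # zero-pad to a fast length
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= bandHz[1] & f <= bandHz[2])
  sp <- stats::mvfft(t(xp)) * mask
  t(Re(stats::mvfft(sp, inverse = TRUE)) / n)[, seq_len(n0), drop = FALSE]
}

#' Inject stimulus-locked responses into a background signal
#'
#' For every contralateral event, at the stimulated finger's site (and
#' its neighbours, with Gaussian spatial falloff `spatialSigmaMm`):
#' (a) adds the configured evoked components (Gaussian-windowed atoms at
#' their latencies and polarities); (b) adds a band-limited noise burst
#' (`ersBandHz`) with smooth on/off ramps starting `ersOnsetMs` after
#' onset; (c) attenuates the ongoing `erdBandHz` content by
#' `erdAttenuation` inside `erdWindowMs`. Ipsilateral events receive no
#' response unless `ilResponse` is set (then a half-amplitude response
#' delayed by 100 ms). Events whose response windows extend past the
#' signal end are skipped with a warning.
#'
#' @param signal channels x samples matrix whose rows match
#'   `layout$name`.
#' @param events validated event table.
#' @param cfg a [SimConfig-class].
#' @param layout electrode layout `data.frame`.
#' @return `list(signal, truth)` where `truth` is the ground-truth
#'   manifest: `$events` (one row per event: target electrode, actual ERS
#'   window and band, ERD window, whether injected), `$sites` (per-finger
#'   true coordinates) and `$seed`.
#' @export
injectResponses <- function(signal, events, cfg, layout) {
  stopifnot(nrow(signal) == nrow(layout))
  fs <- cfg@fs; ns <- ncol(signal)
  chIndex <- stats::setNames(seq_len(nrow(layout)), layout$name)
  siteW <- lapply(cfg@fingerSites, spatialWeights, layout = layout,
                  sigmaMm = cfg@spatialSigmaMm)
  doErp <- any(cfg@erpComponents$amplitude_uv != 0)
  doErs <- cfg@ersAmpUv > 0
  doErd <- cfg@erdAttenuation > 0
  erdComp <- if (doErd) fftBandpassRows(signal, cfg@erdBandHz, fs) else NULL
  ramp <- round(0.02 * fs)
  nbErs <- round(cfg@ersDurationMs / 1000 * fs)
  ersEnv <- rampEnvelope(nbErs, ramp)
  erdLen <- round(diff(cfg@erdWindowMs) / 1000 * fs)
  erdEnv <- rampEnvelope(erdLen, ramp)

  tr <- events
  tr$target <- cfg@fingerSites[tr$finger]
  tr$injected <- FALSE
  tr$ers_start_ms <- tr$ers_end_ms <- NA_real_
  tr$ers_lo_hz <- cfg@ersBandHz[1]; tr$ers_hi_hz <- cfg@ersBandHz[2]
  tr$erd_start_ms <- tr$erd_end_ms <- NA_real_

  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    il <- ev$hand == "IL"
    if (il && !cfg@ilResponse) next
    scale <- if (il) 0.5 else 1
    delay <- cfg@onsetLatencyOffsetMs + if (il) 100 else 0
    on0 <- ev$onset_ms + delay
    n0 <- round(on0 / 1000 * fs) + 1L
    lastNeeded <- n0 + round(max(cfg@erdWindowMs[2], cfg@ersOnsetMs +
                                 cfg@ersDurationMs, 300) / 1000 * fs)
    if (lastNeeded > ns || n0 < 1L) {
      warning(sprintf("event %d at %.0f ms extends past signal end; skipped",
                      k, ev$onset_ms))
      next
    }
    w <- siteW[[ev$finger]]
    rows <- chIndex[w$name]
    if (doErp) {
      for (j in seq_len(nrow(cfg@erpComponents))) {
        cmp <- cfg@erpComponents[j, ]
        sd_s <- cmp$width_ms / 1000 / (2 * sqrt(2 * log(2)))  # FWHM -> sd
        half <- ceiling(3 * sd_s * fs)
        cen <- n0 + round(cmp$latency_ms / 1000 * fs)
        idx <- (cen - half):(cen + half)
        atom <- cmp$polarity * cmp$amplitude_uv * scale *
          exp(-((idx - cen) / fs)^2 / (2 * sd_s^2))
        signal[rows, idx] <- signal[rows, idx] +
          outer(w$weight, atom)
      }
    }
    if (doErs) {
      i0 <- n0 + round(cfg@ersOnsetMs / 1000 * fs)
      idx <- i0:(i0 + nbErs - 1L)
      burst <- cfg@ersAmpUv * scale * ersEnv *
        bandNoise(nbErs, cfg@ersBandHz, fs)
      signal[rows, idx] <- signal[rows, idx] + outer(w$weight, burst)
      tr$ers_start_ms[k] <- on0 - ev$onset_ms + cfg@ersOnsetMs
      tr$ers_end_ms[k] <- tr$ers_start_ms[k] + cfg@ersDurationMs
    }
    if (doErd) {
      i0 <- n0 + round(cfg@erdWindowMs[1] / 1000 * fs)
      idx <- i0:(i0 + erdLen - 1L)
      gain <- outer(cfg@erdAttenuation * scale * w$weight, erdEnv)
      signal[rows, idx] <- signal[rows, idx] - gain * erdComp[rows, idx]
      tr$erd_start_ms[k] <- on0 - ev$onset_ms + cfg@erdWindowMs[1]
      tr$erd_end_ms[k] <- on0 - ev$onset_ms + cfg@erdWindowMs[2]
    }
    tr$injected[k] <- doErp || doErs || doErd
  }
  sites <- layout[match(cfg@fingerSites, layout$name),
                  c("name", "x", "y", "z")]
  sites <- cbind(finger = 1:5, sites)
  rownames(sites) <- NULL
  list(signal = signal,
       truth = list(events = tr, sites = sites, seed = cfg@seed))
}

# Random biphasic interictal transients (derivative-of-Gaussian, 50-100 uV,
# ~100 ms) at random electrodes; emulates strong interictal activity.
addInterictal <- function(signal, cfg) {
  ns <- ncol(signal); fs <- cfg@fs
  nSpike <- stats::rpois(1, cfg@interictalRateHz * ns / fs)
  if (nSpike == 0) return(signal)
  sd_s <- 0.02
  half <- ceiling(3 * sd_s * fs)
  for (i in seq_len(nSpike)) {
    cen <- sample(seq(half + 1L, ns - half), 1)
    ch <- sample(nrow(signal), 1)
    idx <- (cen - half):(cen + half)
    tt <- (idx - cen) / fs
    shape <- -tt / sd_s * exp(0.5 - tt^2 / (2 * sd_s^2))  # peak amp = 1
    amp <- stats::runif(1, 50, 100) * sample(c(-1, 1), 1)
    signal[ch, idx] <- signal[ch, idx] + amp * shape
  }
  signal
}

#' Generate a complete synthetic ECoG session
#'
#' Seeds the RNG from `cfg@seed`, then composes [gridLayout()],
#' [scheduleEvents()], [backgroundNoise()] and [injectResponses()] into a
#' fully reproducible session. The recording is padded so every event's
#' epoch fits.
#'
#' @param cfg a [SimConfig-class].
#' @return `list(recording, events, layout, truth, cfg)`.
#' @examples
#' ses <- generateSession(simConfig(nSets = 1, gridShape = c(4, 4),
#'                                  fingerSites = sprintf("e%02d", 6:10),
#'                                  seed = 42))
#' ses$recording
#' @export
generateSession <- function(cfg) {
  set.seed(cfg@seed)
  layout <- gridLayout(cfg)
  events <- scheduleEvents(cfg)
  last <- events$onset_ms[nrow(events)] + events$duration_ms[nrow(events)]
  totalMs <- last + 2500
  ns <- ceiling(totalMs / 1000 * cfg@fs)
  sig <- backgroundNoise(cfg, nrow(layout), ns)
  if (cfg@interictalRateHz > 0) sig <- addInterictal(sig, cfg)
  inj <- injectResponses(sig, events, cfg, layout)
  rec <- ecogRecording(inj$signal, cfg@fs, layout$name)
  list(recording = rec, events = events, layout = layout,
       truth = inj$truth, cfg = cfg)
}

#' Write a synthetic session to disk
#'
#' Writes `signal/` (interchange format), `events.tsv`,
#' `electrodes.tsv`, `truth_events.tsv` and `truth_sites.tsv` under
#' `dir`.
#'
#' @param session result of [generateSession()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeRecording(session$recording, file.path(dir, "signal"))
  writeEvents(session$events, file.path(dir, "events.tsv"))
  writeElectrodes(session$layout, file.path(dir, "electrodes.tsv"))
  utils::write.table(session$truth$events, file.path(dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(session$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
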