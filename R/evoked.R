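#' @include AllClasses.R methods.R preprocess.R
NULL

#' Average evoked responses by trial groups
#'
#' Arithmetic mean over trials, split by the given label columns (e.g.
#' per finger). Groups are taken from the combinations present in the
#' labels; empty groups cannot arise.
#'
#' @param trials a [TrialTensor-class] (typically band-passed 1-30 Hz,
#'   baseline-corrected and cropped).
#' @param by label columns to group by (default `"finger"`).
#' @return Named list of [Evoked-class] objects.
#' @export
averageEvoked <- function(trials, by = "finger") {
  lab <- trials@labels
  miss <- setdiff(by, names(lab))
  if (length(miss)) stop("unknown label column(s): ",
                         paste(miss, collapse = ", "))
  key <- interaction(lab[, by, drop = FALSE], sep = ".", drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    m <- colMeans(trials@data[idx, , , drop = FALSE], dims = 1)
    rownames(m) <- channelNames(trials)
    grp <- as.list(lab[idx[1], by, drop = FALSE])
    out[[g]] <- new("Evoked", data = m, timeMs = trials@timeMs,
                    nTrials = length(idx), fs = trials@fs, group = grp)
  }
  out
}

#' Default peak search windows
#'
#' Polarity-specific windows bracketing the long-latency somatosensory
#' sequence N40, P100, N140, P200.
#'
#' @return `data.frame` with columns `polarity` (`"N"`/`"P"`), `lo_ms`,
#'   `hi_ms`.
#' @export
defaultPeakWindows <- function() {
  data.frame(polarity = c("N", "P", "N", "P"),
             lo_ms = c(20, 70, 120, 160),
             hi_ms = c(60, 130, 170, 240))
}

#' Detect and label evoked peaks
#'
#' Within each search window, finds the extremum of the requested
#' polarity per channel and labels it polarity letter + latency rounded
#' to the nearest millisecond (e.g. `N40`). Peaks whose correctly-signed
#' amplitude is below `floorK` times the channel's baseline-period
#' standard deviation of the evoked are omitted (so a flat signal yields
#' an empty list).
#'
#' @param evoked an [Evoked-class].
#' @param searchWindows `data.frame` as [defaultPeakWindows()]; windows
#'   are closed-open and must lie within the evoked extent.
#' @param floorK amplitude floor in baseline standard deviations
#'   (default 2).
#' @param baselineMs window for the noise floor estimate.
#' @return `data.frame`: `channel`, `polarity`, `latency_ms`,
#'   `amplitude_uv`, `label` (zero rows allowed).
#' @export
detectPeaks <- function(evoked, searchWindows = defaultPeakWindows(),
                        floorK = 2, baselineMs = c(-150, -10)) {
  tm <- evoked@timeMs
  if (any(searchWindows$lo_ms < tm[1]) ||
      any(searchWindows$hi_ms > tm[length(tm)] + 1000 / evoked@fs))
    stop("search window outside evoked extent")
  bidx <- tm >= baselineMs[1] & tm < baselineMs[2]
  if (!any(bidx)) stop("baseline window outside evoked extent")
  rows <- list()
  for (ch in rownames(evoked@data)) {
    y <- evoked@data[ch, ]
    floor <- floorK * stats::sd(y[bidx])
    for (w in seq_len(nrow(searchWindows))) {
      pol <- searchWindows$polarity[w]
      idx <- which(tm >= searchWindows$lo_ms[w] & tm < searchWindows$hi_ms[w])
      if (!length(idx)) next
      i <- if (pol == "P") idx[which.max(y[idx])] else idx[which.min(y[idx])]
      amp <- y[i]
      if ((if (pol == "P") amp else -amp) <= floor) next
      lat <- tm[i]
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, polarity = pol, latency_ms = lat,
        amplitude_uv = amp, label = paste0(pol, round(lat)))
    }
  }
  if (!length(rows))
    return(data.frame(channel = character(), polarity = character(),
                      latency_ms = numeric(), amplitude_uv = numeric(),
                      label = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
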