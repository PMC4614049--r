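#' @include AllClasses.R methods.R spectral.R
NULL

#' Electrode adjacency graph
#'
#' Two electrodes are neighbours iff they belong to the same grid and
#' their Euclidean distance is at most `maxDistMm`. With the study's
#' 10 mm grid pitch and the 15 mm default radius, interior electrodes
#' have eight neighbours (diagonal contacts lie at 14.1 mm).
#'
#' @param layout electrode layout `data.frame`.
#' @param maxDistMm neighbourhood radius in mm (default 15).
#' @return Symmetric logical matrix with electrode names as dimnames and
#'   `FALSE` diagonal.
#' @export
electrodeAdjacency <- function(layout, maxDistMm = 15) {
  layout <- validateElectrodes(layout)
  p <- as.matrix(layout[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(p))
  adj <- d <= maxDistMm & outer(layout$grid_id, layout$grid_id, "==")
  diag(adj) <- FALSE
  dimnames(adj) <- list(layout$name, layout$name)
  adj
}

# CSR form (0-based) of a logical adjacency matrix
adjacencyCsr <- function(adj) {
  idx <- lapply(seq_len(nrow(adj)), function(i) which(adj[i, ]) - 1L)
  list(ptr = c(0L, cumsum(lengths(idx))),
       idx = as.integer(unlist(idx)))
}

#' One-sample t statistic map
#'
#' Per cell, the one-sample t of baseline-normalized power against 0:
#' `t = mean / (sd / sqrt(n))`, with n - 1 degrees of freedom. Cells
#' with zero variance are flagged `+Inf`/`-Inf` (handled as
#' suprathreshold downstream); zero mean with zero variance gives 0.
#'
#' @param x trials x cells numeric matrix, or a normalized
#'   [TFRTensor-class] (then a channel x frequency x time array is
#'   returned).
#' @return Numeric vector (matrix input) or 3-D array (TFR input) of
#'   t-values.
#' @examples
#' sampleStatistic(matrix(c(1, 2, 3), 3, 1))  # 2 / (1 / sqrt(3))
#' @export
sampleStatistic <- function(x) {
  if (is(x, "TFRTensor")) {
    if (!x@normalized) stop("TFR must be baseline-normalized first")
    dm <- dim(x@power)
    X <- matrix(x@power, dm[1], prod(dm[2:4]))
    t <- sampleStatistic(X)
    return(array(t, dm[2:4],
                 dimnames = list(channelNames(x), NULL, NULL)))
  }
  n <- nrow(x)
  if (n < 2) stop("need at least 2 trials")
  m <- colMeans(x)
  v <- (colSums(x^2) - n * m^2) / (n - 1)
  t <- ifelse(v < 1e-20,
              ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)),
              m / sqrt(v / n))
  t
}

#' Form suprathreshold clusters
#'
#' Connected components of cells with `t > threshold` (positive, ERS)
#' and, separately, `t < -threshold` (negative, ERD), under the
#' 6-neighbourhood: one step along time, one along frequency, and
#' electrode-graph edges. Cluster mass is the sum of member t-values.
#'
#' @param stat 3-D channel x frequency x time t-value array.
#' @param threshold positive forming threshold.
#' @param adjacency electrode adjacency matrix (see
#'   [electrodeAdjacency()]); rows must match the channel dimension.
#' @return List with `table` (`data.frame`: `id`, `sign`, `size`,
#'   `mass`) and `cells` (list of member linear indices into `stat`).
#' @export
formClusters <- function(stat, threshold, adjacency) {
  stopifnot(length(dim(stat)) == 3L, threshold > 0,
            nrow(adjacency) == dim(stat)[1])
  csr <- adjacencyCsr(adjacency)
  d <- dim(stat)
  res <- cppLabelClusters(as.numeric(stat), d[1], d[2], d[3],
                          threshold, csr$ptr, csr$idx)
  k <- length(res$mass)
  cells <- if (k) split(which(res$labels > 0),
                        factor(res$labels[res$labels > 0],
                               levels = seq_len(k))) else list()
  list(table = data.frame(id = seq_len(k), sign = res$sign,
                          size = res$size, mass = res$mass),
       cells = unname(cells))
}

#' Extended TFR window for the time-shift surrogate null
#'
#' Returns the output window to request from [morletTfr()] so that the
#' analysis-plus-baseline window can be slid in time when building the
#' surrogate null: the analysis window padded backwards by `padPreMs`
#' and forwards by `padPostMs`, clipped to the part of the epoch where
#' the slowest wavelet (lowest analysed frequency) has full support
#' (half-support taken as 3 standard deviations of the Morlet envelope,
#' `3 * cycles / (2 pi f)`), so surrogate windows never include
#' edge-contaminated bins.
#'
#' @param cfg an [AnalysisConfig-class].
#' @param fminHz lowest analysed frequency in Hz.
#' @param padPreMs,padPostMs requested padding before/after the analysis
#'   window (defaults 420 and 100 ms; pre-stimulus placements are
#'   favoured because the epoch extends 1 s before onset while the
#'   response occupies the post-stimulus side).
#' @return `c(lo, hi)` window in ms.
#' @export
extendedTfrWindow <- function(cfg, fminHz, padPreMs = 420,
                              padPostMs = 100) {
  half <- 3 * cfg@waveletCycles / (2 * pi * fminHz) * 1000
  lo0 <- min(cfg@analysisWindowMs[1], cfg@baselineWindowMs[1])
  hi0 <- max(cfg@analysisWindowMs[2], cfg@baselineWindowMs[2])
  lo <- max(cfg@epochWindowMs[1] + half, lo0 - padPreMs)
  hi <- min(cfg@epochWindowMs[2] - half, hi0 + padPostMs)
  if (lo > lo0 || hi < hi0)
    stop("epoch too short for the wavelet support at ", fminHz, " Hz")
  c(lo, hi)
}

#' Cluster-based nonparametric permutation test
#'
#' Tests one (condition, band, finger) map of baseline-normalized power
#' for a stimulation effect. Sample-level statistic: one-sample t
#' against 0; clusters formed at the two-sided `alphaForming` t
#' threshold; cluster-level statistic: mass (sum of t; or size). The
#' null records, per Monte Carlo resample, the maximum |cluster
#' statistic| over both signs; each observed cluster gets the plus-one
#' p-value `(1 + #{resample >= observed}) / (nPermutations + 1)`, so the
#' smallest attainable p is `1/(nPermutations + 1)`.
#'
#' Resamples are drawn per `cfg@nullMethod`:
#' * `"shift"` (default): time-shift surrogates. Each trial's
#'   analysis-plus-baseline window is slid, as a block, by a random
#'   number of TFR bins within the extended raw TFR (`rawTfr`,
#'   see [extendedTfrWindow()]), re-normalized against the shifted
#'   baseline, and the t map of the re-normalized trials is clustered.
#'   Under the null of no stimulus-locked power modulation the shifted
#'   windows are exchangeable with the original, so the test is
#'   calibrated without any symmetry assumption - in particular for
#'   normalized log power, whose left skew breaks the sign-flip scheme.
#' * `"bootstrap"`: trials are drawn with replacement from the per-cell
#'   centered values (bootstrap-t); preserves the skew but is
#'   conservative at small trial counts.
#' * `"signflip"`: each trial's sign is flipped with probability 1/2,
#'   the classical scheme, exact only under the stronger null that
#'   normalized power is symmetric about 0 - an assumption log power
#'   violates, which inflates the ERS false-positive rate at small
#'   trial counts (see the methods vignette).
#'
#' @param tfr normalized [TFRTensor-class], already restricted to the
#'   trials and frequency band under test.
#' @param cfg an [AnalysisConfig-class] (`nPermutations`,
#'   `alphaForming`, `alphaCluster`, `clusterStat`, `nullMethod`).
#' @param adjacency electrode adjacency matrix matching the TFR
#'   channels.
#' @param condition,band,finger labels stored in the result.
#' @param seed permutation RNG seed (default `cfg@rngSeed`).
#' @param rawTfr for `nullMethod = "shift"`: the raw (unnormalized)
#'   [TFRTensor-class] of the same trials, channels and frequencies on
#'   the extended time grid of [extendedTfrWindow()]; its analysis-window
#'   bins must be the bins of `tfr`.
#' @return A [ClusterResult-class].
#' @export
permutationTest <- function(tfr, cfg, adjacency, condition = "CLs",
                            band = "MidG", finger = NA_integer_,
                            seed = cfg@rngSeed, rawTfr = NULL) {
  stopifnot(is(tfr, "TFRTensor"), tfr@normalized)
  dm <- dim(tfr@power)
  n <- dm[1]
  if (n < 2) stop("need at least 2 trials")
  if (n < 8) warning("fewer than 8 trials: permutation test is low-powered")
  nperm <- cfg@nPermutations
  thr <- stats::qt(1 - cfg@alphaForming / 2, df = n - 1)
  X <- matrix(tfr@power, n, prod(dm[2:4]))
  stat <- array(sampleStatistic(X), dm[2:4])
  fc <- formClusters(stat, thr, adjacency)

  csr <- adjacencyCsr(adjacency)
  set.seed(seed)
  useSize <- as.integer(cfg@clusterStat == "size")
  if (cfg@nullMethod == "shift") {
    if (is.null(rawTfr))
      stop("nullMethod 'shift' needs rawTfr, the raw TFR on the ",
           "extended time grid (see extendedTfrWindow)")
    stopifnot(is(rawTfr, "TFRTensor"), !rawTfr@normalized)
    dmr <- dim(rawTfr@power)
    if (!identical(dmr[1:3], dm[1:3]) ||
        !isTRUE(all.equal(rawTfr@freqsHz, tfr@freqsHz)))
      stop("rawTfr trials/channels/frequencies disagree with tfr")
    anaPos <- match(round(tfr@timeMs, 6), round(rawTfr@timeMs, 6))
    if (anyNA(anaPos))
      stop("rawTfr time grid does not contain the analysis bins")
    basePos <- which(rawTfr@timeMs >= cfg@baselineWindowMs[1] &
                     rawTfr@timeMs < cfg@baselineWindowMs[2])
    if (!length(basePos))
      stop("rawTfr time grid does not cover the baseline window")
    allPos <- c(anaPos, basePos)
    offsets <- (1L - min(allPos)):(dmr[4] - max(allPos))
    if (length(offsets) < 8L)
      stop("extended TFR leaves fewer than 8 admissible time shifts; ",
           "widen the epoch or the extended window")
    shiftIdx <- matrix(sample.int(length(offsets), n * nperm,
                                  replace = TRUE) - 1L, n, nperm)
    geom <- cfg@baselineStat == "geometric"
    L <- aperm(rawTfr@power, c(2, 3, 4, 1))
    if (geom) L <- log(L)
    null <- cppShiftMaxStat(as.numeric(L), n, dm[2], dm[3], dmr[4],
                            anaPos - 1L, basePos - 1L, as.integer(offsets),
                            shiftIdx, thr, useSize, as.integer(geom),
                            csr$ptr, csr$idx)
  } else {
    boot <- cfg@nullMethod == "bootstrap"
    if (boot) {
      # multiplicity matrix of trial resamples, on per-cell centered values
      S <- vapply(seq_len(nperm), function(j)
        tabulate(sample.int(n, n, replace = TRUE), n), integer(n))
      S <- matrix(as.numeric(S), n, nperm)
      Xn <- sweep(X, 2, colMeans(X))
    } else {
      S <- matrix(sample(c(-1, 1), n * nperm, replace = TRUE), n, nperm)
      Xn <- X
    }
    null <- cppPermMaxStat(Xn, S, colSums(Xn^2), thr, dm[2], dm[3], dm[4],
                           useSize, as.integer(boot), csr$ptr, csr$idx)
  }

  k <- nrow(fc$table)
  obsStat <- if (cfg@clusterStat == "size") fc$table$size
             else abs(fc$table$mass)
  p <- vapply(obsStat, function(s) (1 + sum(null >= s)) / (nperm + 1), 0)
  members <- lapply(fc$cells, function(li) {
    li <- li - 1L
    ch <- li %% dm[2] + 1L
    fr <- (li %/% dm[2]) %% dm[3] + 1L
    ti <- li %/% (dm[2] * dm[3]) + 1L
    data.frame(channel = channelNames(tfr)[ch],
               freq_hz = tfr@freqsHz[fr],
               time_ms = tfr@timeMs[ti],
               t = stat[cbind(ch, fr, ti)])
  })
  onset <- vapply(members, function(m)
    if (nrow(m)) min(m$time_ms) else NA_real_, 0)
  tab <- data.frame(id = seq_len(k), sign = fc$table$sign,
                    size = fc$table$size, mass = fc$table$mass,
                    onset_ms = onset, p_value = p,
                    significant = p <= cfg@alphaCluster)
  ord <- order(tab$p_value, -abs(tab$mass), tab$onset_ms)
  new("ClusterResult", table = tab[ord, , drop = FALSE],
      members = members[ord], band = band, condition = condition,
      finger = as.integer(finger), nPermutations = as.integer(nperm),
      formingThreshold = thr, alpha = cfg@alphaCluster,
      permMaxMass = as.numeric(null))
}

#' Run the permutation test over all conditions, bands and fingers
#'
#' One [permutationTest()] per (condition present in the trial labels,
#' configured band, finger): the per-finger trials of that condition,
#' restricted to the band's frequency bins. Conditions or fingers with
#' no trials are skipped with a message.
#'
#' @param tfr normalized [TFRTensor-class] covering all configured band
#'   frequencies.
#' @param cfg an [AnalysisConfig-class].
#' @param adjacency electrode adjacency matrix.
#' @param bands subset of band names to run (default: all configured).
#' @param fingers fingers to test (default 1:5).
#' @param trials for `cfg@nullMethod = "shift"`: the band-passed
#'   full-epoch [TrialTensor-class] that `tfr` was computed from (same
#'   trials, same order); per test, the raw TFR of the trials under test
#'   is recomputed over the extended time grid for the surrogate null.
#' @return List of [ClusterResult-class] objects, named
#'   `condition.band.finger`.
#' @export
runAllBands <- function(tfr, cfg, adjacency, bands = names(cfg@bands),
                        fingers = 1:5, trials = NULL) {
  lab <- tfr@labels
  cond <- paste0(lab$hand, lab$task)
  shift <- cfg@nullMethod == "shift"
  if (shift) {
    if (is.null(trials))
      stop("nullMethod 'shift' needs the band-passed full-epoch trials")
    if (nTrials(trials) != nTrials(tfr))
      stop("trials and tfr disagree in trial count")
  }
  out <- list()
  for (cn in unique(cond)) {
    for (b in bands) {
      bf <- cfg@bands[[b]]
      if (is.null(bf)) stop("unknown band: ", b)
      if (!any(tfr@freqsHz >= bf[1] & tfr@freqsHz <= bf[2])) {
        message("band ", b, " not covered by analysed frequencies; skipped")
        next
      }
      for (fg in fingers) {
        idx <- which(cond == cn & lab$finger == fg)
        if (!length(idx)) {
          message("no trials for ", cn, " finger ", fg, "; skipped")
          next
        }
        sub <- bandTfr(selectTrials(tfr, idx), bf)
        raw <- if (shift)
          morletTfr(selectTrials(trials, idx), sub@freqsHz,
                    cfg@waveletCycles, cfg@tfrTimeStepMs,
                    outWindowMs = extendedTfrWindow(cfg, min(sub@freqsHz)))
        out[[paste(cn, b, fg, sep = ".")]] <-
          permutationTest(sub, cfg, adjacency, condition = cn, band = b,
                          finger = fg, rawTfr = raw)
      }
    }
  }
  out
}

#' Combined cluster table of a result list
#'
#' @param results list of [ClusterResult-class] (e.g. from
#'   [runAllBands()]).
#' @return `data.frame` with one row per cluster across all results:
#'   `condition`, `band`, `finger`, `sign`, `size`, `mass`, `onset_ms`,
#'   `p_value`, `significant`.
#' @export
combinedClusterTable <- function(results) {
  rows <- lapply(results, function(r) {
    if (!nrow(r@table)) return(NULL)
    cbind(condition = r@condition, band = r@band, finger = r@finger,
          r@table[, c("sign", "size", "mass", "onset_ms", "p_value",
                      "significant")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(condition = character(), band = character(),
                      finger = integer(), sign = integer(),
                      size = integer(), mass = numeric(),
                      onset_ms = numeric(), p_value = numeric(),
                      significant = logical())
  rownames(out) <- NULL
  out
}
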