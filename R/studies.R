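#' @include reporting.R synthetic.R
NULL

# MidG-only analysis of one session's trials: epoch, optional CAR,
# band-pass, Morlet over the mid-gamma bins on the extended time grid
# (so the time-shift surrogate null can slide the window), then
# baseline normalisation of the analysis-window crop. Returns
# list(tfr = normalized analysis-window TFR, raw = extended raw TFR).
midGammaTfr <- function(session, acfg, trialIdx = NULL) {
  trials <- epochTrials(session$recording, session$events,
                        acfg@epochWindowMs)
  if (!is.null(trialIdx)) trials <- selectTrials(trials, trialIdx)
  trials <- commonAverageReference(trials, session$layout, acfg@carEnabled)
  trials <- bandpassFir(trials, acfg@tfrBandpassHz[1], acfg@tfrBandpassHz[2])
  freqs <- bandFrequencies(acfg@bands["MidG"])
  raw <- morletTfr(trials, freqs, acfg@waveletCycles, acfg@tfrTimeStepMs,
                   outWindowMs = extendedTfrWindow(acfg, min(freqs)))
  tfr <- baselineNormalize(cropTfr(raw, acfg@analysisWindowMs),
                           acfg@baselineWindowMs, acfg@logBase,
                           acfg@baselineStat)
  list(tfr = tfr, raw = raw)
}

#' Family-wise error calibration under the null
#'
#' Generates null-world synthetic sessions (background activity only, no
#' injected responses), runs the per-finger mid-gamma cluster
#' permutation test on each (the ten trials of one finger), and reports
#' the fraction of tests rejecting at the nominal level - the empirical
#' family-wise error rate, which should match `alphaCluster` (0.05).
#' Null replicates use a 4 x 4 grid at the study pitch: FWER control of
#' a max-statistic permutation test does not depend on map size.
#'
#' @param nSessions number of null replicates (default 200).
#' @param nPermutations permutations per test (default 500).
#' @param seed master seed; per-session seeds are drawn from it.
#' @param alpha nominal cluster significance level.
#' @return List: `rate` (empirical FWER), `rejected` (logical per
#'   replicate), `nSessions`, `alpha`.
#' @export
fwerCalibration <- function(nSessions = 200, nPermutations = 500,
                            seed = 1, alpha = 0.05) {
  set.seed(seed)
  seeds <- sample.int(2^30, nSessions)
  acfg <- analysisConfig(nPermutations = nPermutations,
                         alphaCluster = alpha, carEnabled = FALSE)
  rejected <- logical(nSessions)
  for (i in seq_len(nSessions)) {
    scfg <- simConfig(nSets = 1, gridShape = c(4, 4),
                      fingerSites = sprintf("e%02d", 1:5),
                      ersAmpUv = 0, erdAttenuation = 0,
                      erpComponents = within(defaultErpComponents(),
                                             amplitude_uv <- 0),
                      seed = seeds[i])
    ses <- generateSession(scfg)
    idx <- which(ses$events$finger == 1)
    mg <- midGammaTfr(ses, acfg, trialIdx = idx)
    adj <- electrodeAdjacency(ses$layout, acfg@adjacencyMaxDistMm)
    res <- permutationTest(mg$tfr, acfg, adj, finger = 1L,
                           seed = seeds[i] + 1L, rawTfr = mg$raw)
    rejected[i] <- any(res@table$significant)
  }
  list(rate = mean(rejected), rejected = rejected,
       nSessions = nSessions, alpha = alpha)
}

# primary significant positive (ERS) cluster of a result, same tie rules
# as selectPrimaryCluster
primaryErsCluster <- function(result) {
  tab <- result@table
  sig <- which(tab$significant & tab$sign > 0)
  if (!length(sig)) return(NA_integer_)
  ord <- order(tab$p_value[sig], -abs(tab$mass[sig]), tab$onset_ms[sig])
  sig[ord[1]]
}

#' Finger-recovery and somatotopy simulation study
#'
#' Generates default-SNR synthetic sessions, runs the per-finger
#' mid-gamma cluster permutation test, and scores recovery against the
#' generator's ground truth: whether the primary significant ERS
#' cluster contains the true injected electrode, the distance from the
#' power-weighted centroid to the true site, and per session the
#' somatotopic order score and map span.
#'
#' @param nSessions number of sessions (default 20).
#' @param seed master seed.
#' @param simCfgFn function mapping a session seed to a
#'   [SimConfig-class]; default: one stimulation set of the standard
#'   session (`simConfig(nSets = 1, seed = s)`).
#' @param nPermutations permutations per test (default 1000).
#' @return List: `perFinger` (`data.frame`: session, finger, significant,
#'   containsTarget, centroidErrMm), `perSession` (`data.frame`:
#'   session, nMapped, orderScore, spanMm), `trueSpanMm`.
#' @export
fingerRecoveryStudy <- function(nSessions = 20, seed = 1,
                                simCfgFn = function(s)
                                  simConfig(nSets = 1, seed = s),
                                nPermutations = 1000) {
  set.seed(seed)
  seeds <- sample.int(2^30, nSessions)
  acfg <- analysisConfig(nPermutations = nPermutations)
  pf <- list(); ps <- list()
  trueSpan <- NA_real_
  for (i in seq_len(nSessions)) {
    ses <- generateSession(simCfgFn(seeds[i]))
    sites <- ses$truth$sites
    trueSpan <- max(stats::dist(as.matrix(sites[, c("x", "y", "z")])))
    mg <- midGammaTfr(ses, acfg)
    tfr <- mg$tfr
    adj <- electrodeAdjacency(ses$layout, acfg@adjacencyMaxDistMm)
    lab <- tfr@labels
    cond <- paste0(lab$hand, lab$task)
    results <- list()
    for (fg in 1:5) {
      idx <- which(cond == "CLs" & lab$finger == fg)
      res <- permutationTest(selectTrials(tfr, idx), acfg, adj,
                             condition = "CLs", band = "MidG",
                             finger = fg, seed = seeds[i] + fg,
                             rawTfr = selectTrials(mg$raw, idx))
      results[[fg]] <- res
      pri <- primaryErsCluster(res)
      if (is.na(pri)) {
        pf[[length(pf) + 1L]] <- data.frame(
          session = i, finger = fg, significant = FALSE,
          containsTarget = FALSE, centroidErrMm = NA_real_)
        next
      }
      mem <- res@members[[pri]]
      target <- sites$name[sites$finger == fg]
      sub <- selectTrials(tfr, idx)
      cc <- clusterCentroid(mem, sub, ses$layout)
      tpos <- unlist(sites[sites$finger == fg, c("x", "y", "z")])
      err <- sqrt(sum((cc$centroid - tpos)^2))
      pf[[length(pf) + 1L]] <- data.frame(
        session = i, finger = fg, significant = TRUE,
        containsTarget = target %in% mem$channel,
        centroidErrMm = err)
    }
    fmap <- suppressMessages(
      buildFingerMap(results, tfr, acfg, ses$layout))
    ps[[length(ps) + 1L]] <- data.frame(
      session = i, nMapped = sum(centroids(fmap)$mapped),
      orderScore = orderScore(fmap), spanMm = mapSpan(fmap))
  }
  list(perFinger = do.call(rbind, pf), perSession = do.call(rbind, ps),
       trueSpanMm = trueSpan)
}

#' @describeIn fingerRecoveryStudy the same study on a fine-pitch (4 mm)
#'   grid, so the five sites span 16 mm - the sub-2 cm somatotopic
#'   regime - for assessing order-score and span recovery. The grid is
#'   enlarged to 12 x 16 contacts so that every site's response
#'   footprint (Gaussian falloff, sigma 8 mm, cluster support extending
#'   to roughly 14 mm) lies fully inside the array: the power-weighted
#'   centroid is unbiased only when its support is not truncated by the
#'   grid edge, and on an 8 x 8 grid at 4 mm pitch (28 mm wide) edge
#'   truncation pulls the outer fingers' centroids inward, shrinking the
#'   recovered span.
#' @export
somatotopyRecoveryStudy <- function(nSessions = 20, seed = 1,
                                    nPermutations = 1000) {
  fingerRecoveryStudy(nSessions, seed,
                      simCfgFn = function(s)
                        simConfig(nSets = 1, gridShape = c(12, 16),
                                  gridPitchMm = 4, seed = s),
                      nPermutations = nPermutations)
}

#' Evoked-latency recovery study
#'
#' Generates default sessions, averages the contralateral trials of each
#' finger at its true site electrode (1-30 Hz band, baseline-corrected,
#' cropped) and checks that the four injected components are detected
#' within `toleranceMs` of their configured latencies.
#'
#' @param nSeeds number of sessions (default 20).
#' @param seed master seed.
#' @param simCfgFn function mapping a seed to a [SimConfig-class]
#'   (default: the full six-set standard session).
#' @param toleranceMs latency tolerance (default 6 ms).
#' @return List: `perCase` (`data.frame`: session, finger, one logical
#'   column per component, `allRecovered`), `rate` (fraction of
#'   session x finger cases with all four components recovered).
#' @export
erpRecoveryStudy <- function(nSeeds = 20, seed = 1,
                             simCfgFn = function(s) simConfig(seed = s),
                             toleranceMs = 6) {
  set.seed(seed)
  seeds <- sample.int(2^30, nSeeds)
  acfg <- analysisConfig()
  rows <- list()
  for (i in seq_len(nSeeds)) {
    scfg <- simCfgFn(seeds[i])
    ses <- generateSession(scfg)
    sites <- ses$truth$sites
    # time-domain branch restricted to the five site electrodes
    sig <- signalData(ses$recording)[sites$name, , drop = FALSE]
    rec <- ecogRecording(sig, samplingRate(ses$recording))
    trials <- epochTrials(rec, ses$events, acfg@epochWindowMs)
    trials <- bandpassFir(trials, acfg@timeBandpassHz[1],
                          acfg@timeBandpassHz[2])
    trials <- baselineCorrectTime(trials, acfg@baselineWindowMs)
    trials <- cropTrials(trials, acfg@analysisWindowMs)
    lab <- trials@labels
    comps <- scfg@erpComponents
    for (fg in 1:5) {
      idx <- which(lab$hand == "CL" & lab$finger == fg)
      ev <- averageEvoked(selectTrials(trials, idx), by = "finger")[[1]]
      pk <- detectPeaks(ev, baselineMs = acfg@baselineWindowMs)
      pk <- pk[pk$channel == sites$name[sites$finger == fg], ,
               drop = FALSE]
      hit <- vapply(seq_len(nrow(comps)), function(j) {
        pol <- if (comps$polarity[j] > 0) "P" else "N"
        any(pk$polarity == pol &
            abs(pk$latency_ms - comps$latency_ms[j]) <= toleranceMs)
      }, logical(1))
      row <- data.frame(session = i, finger = fg)
      row[comps$label] <- as.list(hit)
      row$allRecovered <- all(hit)
      rows[[length(rows) + 1L]] <- row
    }
  }
  perCase <- do.call(rbind, rows)
  list(perCase = perCase, rate = mean(perCase$allRecovered))
}
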