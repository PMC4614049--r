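#' @include AllClasses.R clusters.R somatotopy.R evoked.R
NULL

#' Count significant clusters per condition, band and sign
#'
#' Tabulates significant ERS and ERD clusters into a condition x band
#' count table (summed over fingers), the granularity of the published
#' summary tables for this paradigm.
#'
#' @param x a combined cluster table (see [combinedClusterTable()]), a
#'   list of [ClusterResult-class] objects, or an already-tabulated
#'   `data.frame` with columns `condition`, `band`, `n_ers`, `n_erd`.
#' @param alpha significance level applied to `p_value` (default 0.05).
#' @param conditions,bands row/column order of the table; defaults to
#'   the four study conditions and five bands.
#' @return `data.frame` with columns `condition`, `band`, `n_ers`,
#'   `n_erd`, one row per condition x band cell.
#' @examples
#' countClusters(data.frame(condition = "CLs", band = "MidG", sign = 1,
#'                          p_value = 0.01))
#' @export
countClusters <- function(x, alpha = 0.05,
                          conditions = c("CLs", "CLsm", "ILs", "ILsm"),
                          bands = names(defaultBands())) {
  if (is.list(x) && !is.data.frame(x)) x <- combinedClusterTable(x)
  if (all(c("n_ers", "n_erd") %in% names(x))) {
    tab <- x      # already tabulated
  } else {
    x <- x[x$p_value <= alpha, , drop = FALSE]
    grid <- expand.grid(condition = conditions, band = bands,
                        stringsAsFactors = FALSE)
    tab <- grid
    tab$n_ers <- mapply(function(cn, b)
      sum(x$condition == cn & x$band == b & x$sign > 0),
      grid$condition, grid$band)
    tab$n_erd <- mapply(function(cn, b)
      sum(x$condition == cn & x$band == b & x$sign < 0),
      grid$condition, grid$band)
  }
  tab$n_ers <- as.integer(tab$n_ers); tab$n_erd <- as.integer(tab$n_erd)
  if (any(tab$n_ers < 0 | tab$n_erd < 0)) stop("negative counts")
  rownames(tab) <- NULL
  tab
}

#' Grand total of a count table
#'
#' @param tab a count table from [countClusters()].
#' @return Sum of all ERS and ERD cells.
#' @export
grandTotal <- function(tab) sum(tab$n_ers) + sum(tab$n_erd)

#' Derived percentages of a count table
#'
#' The two headline shares of the count table: the percentage of all
#' significant clusters that are contralateral ERS above 65 Hz (MidG +
#' HigG bands of the CLs and CLsm conditions) and contralateral ERD
#' below 30 Hz (Alpha + Beta of CLs and CLsm), each reported to one
#' decimal.
#'
#' @param tab a count table from [countClusters()].
#' @return Named numeric vector `pct_cl_ers_above65`,
#'   `pct_cl_erd_below30` (both `NA` when the table is empty).
#' @examples
#' derivedPercentages(referenceClusterCounts())
#' @export
derivedPercentages <- function(tab) {
  gt <- grandTotal(tab)
  if (gt == 0)
    return(c(pct_cl_ers_above65 = NA_real_, pct_cl_erd_below30 = NA_real_))
  cl <- tab$condition %in% c("CLs", "CLsm")
  ers <- sum(tab$n_ers[cl & tab$band %in% c("MidG", "HigG")])
  erd <- sum(tab$n_erd[cl & tab$band %in% c("Alpha", "Beta")])
  c(pct_cl_ers_above65 = round(100 * ers / gt, 1),
    pct_cl_erd_below30 = round(100 * erd / gt, 1))
}

#' Bundled reference cluster-count table
#'
#' The published condition x band table of significant cluster counts
#' for this vibrotactile ECoG mapping paradigm (pooled over subjects and
#' fingers), shipped as a plain-text fixture so the summary arithmetic
#' ([grandTotal()], [derivedPercentages()]) can be exercised as a worked
#' example independent of any synthetic data.
#'
#' @return Count table `data.frame` (`condition`, `band`, `n_ers`,
#'   `n_erd`).
#' @examples
#' grandTotal(referenceClusterCounts())
#' @export
referenceClusterCounts <- function() {
  path <- system.file("extdata", "reference_cluster_counts.tsv",
                      package = "vibromap", mustWork = TRUE)
  countClusters(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Mean cluster onset per band and sign
#'
#' @param x combined cluster table or list of [ClusterResult-class].
#' @param alpha significance level (default 0.05).
#' @param bands band order (default the five study bands).
#' @return `data.frame`: `band`, `sign`, `n`, `mean_onset_ms` (`NA`
#'   where a cell has no significant clusters).
#' @export
onsetSummary <- function(x, alpha = 0.05, bands = names(defaultBands())) {
  if (is.list(x) && !is.data.frame(x)) x <- combinedClusterTable(x)
  x <- x[x$p_value <= alpha, , drop = FALSE]
  grid <- expand.grid(band = bands, sign = c(1, -1),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(b, s)
    sum(x$band == b & x$sign == s), grid$band, grid$sign)
  grid$mean_onset_ms <- mapply(function(b, s) {
    o <- x$onset_ms[x$band == b & x$sign == s]
    if (length(o)) mean(o) else NA_real_
  }, grid$band, grid$sign)
  grid
}

#' Run the full mapping pipeline
#'
#' Executes the whole analysis on one session: epoching, optional
#' per-grid common average reference, the time-domain branch (1-30 Hz
#' band-pass, baseline correction, crop, per-finger evoked averages and
#' peak detection) and the time-frequency branch (1-230 Hz band-pass,
#' Morlet transform, baseline normalisation, per-band per-finger
#' cluster permutation tests), then summarises counts, onsets and the
#' somatotopic finger map of the mapping band.
#'
#' @param rec an [EcogRecording-class].
#' @param events validated event table.
#' @param layout electrode layout `data.frame`.
#' @param cfg an [AnalysisConfig-class].
#' @param bands bands to test (default: all configured).
#' @param fingers fingers to test (default 1:5).
#' @param mapBand band used for the finger map (default `"MidG"`).
#' @param outDir optional directory; when given, writes `clusters.tsv`,
#'   `counts.tsv`, `onsets.tsv`, `fingermap.tsv`, `peaks.tsv` and
#'   `run_log.txt`.
#' @return List: `trials` (preprocessed, uncropped), `evoked`, `peaks`,
#'   `tfr` (normalized, analysis window), `results`, `clusterTable`,
#'   `countTable`, `onsets`, `fingerMap`, `config`.
#' @export
runPipeline <- function(rec, events, layout, cfg = analysisConfig(),
                        bands = names(cfg@bands), fingers = 1:5,
                        mapBand = "MidG", outDir = NULL) {
  layout <- validateElectrodes(layout, rec)
  trials <- epochTrials(rec, events, cfg@epochWindowMs)
  trials <- commonAverageReference(trials, layout, cfg@carEnabled)

  # time-domain branch
  tb <- bandpassFir(trials, cfg@timeBandpassHz[1], cfg@timeBandpassHz[2])
  tb <- baselineCorrectTime(tb, cfg@baselineWindowMs)
  tb <- cropTrials(tb, cfg@analysisWindowMs)
  evoked <- averageEvoked(tb, by = c("hand", "task", "finger"))
  peaks <- do.call(rbind, lapply(names(evoked), function(g) {
    p <- detectPeaks(evoked[[g]], baselineMs = cfg@baselineWindowMs)
    if (nrow(p)) cbind(group = g, p) else NULL
  }))

  # time-frequency branch
  fb <- bandpassFir(trials, cfg@tfrBandpassHz[1], cfg@tfrBandpassHz[2])
  freqs <- bandFrequencies(cfg@bands[bands])
  tfr <- morletTfr(fb, freqs, cfg@waveletCycles, cfg@tfrTimeStepMs,
                   outWindowMs = cfg@analysisWindowMs)
  tfr <- baselineNormalize(tfr, cfg@baselineWindowMs, cfg@logBase,
                           cfg@baselineStat)

  adj <- electrodeAdjacency(layout, cfg@adjacencyMaxDistMm)
  results <- runAllBands(tfr, cfg, adj, bands = bands, fingers = fingers,
                         trials = fb)
  ctab <- combinedClusterTable(results)
  counts <- countClusters(ctab, cfg@alphaCluster)
  onsets <- onsetSummary(ctab, cfg@alphaCluster)

  fmap <- NULL
  if (mapBand %in% bands) {
    lab <- tfr@labels
    conds <- unique(paste0(lab$hand, lab$task))
    mapCond <- if ("CLs" %in% conds) "CLs" else conds[1]
    sel <- Filter(function(r) r@band == mapBand && r@condition == mapCond,
                  results)
    fmap <- buildFingerMap(sel, tfr, cfg, layout)
  }

  out <- list(trials = trials, evoked = evoked, peaks = peaks, tfr = tfr,
              results = results, clusterTable = ctab, countTable = counts,
              onsets = onsets, fingerMap = fmap, config = cfg)
  if (!is.null(outDir)) writePipelineOutputs(out, layout, outDir)
  out
}

writePipelineOutputs <- function(out, layout, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(out$clusterTable, "clusters.tsv")
  wt(out$countTable, "counts.tsv")
  wt(out$onsets, "onsets.tsv")
  if (!is.null(out$peaks)) wt(out$peaks, "peaks.tsv")
  if (!is.null(out$fingerMap)) {
    cm <- centroids(out$fingerMap)
    cm$span_mm <- mapSpan(out$fingerMap)
    cm$order_score <- orderScore(out$fingerMap)
    wt(cm, "fingermap.tsv")
  }
  cfgFile <- file.path(outDir, "analysis_config.txt")
  writeAnalysisConfig(out$config, cfgFile)
  cfgTxt <- paste(readLines(cfgFile), collapse = "\n")
  hash <- sprintf("%08x", sum(utf8ToInt(cfgTxt) *
                              seq_along(utf8ToInt(cfgTxt))) %% 0xffffffff)
  writeLines(c(
    sprintf("vibromap %s", as.character(utils::packageVersion("vibromap"))),
    sprintf("R %s", R.version.string),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("rng seed %d", out$config@rngSeed),
    sprintf("config hash %s", hash),
    sprintf("n clusters %d (significant %d)", nrow(out$clusterTable),
            sum(out$clusterTable$significant))),
    file.path(outDir, "run_log.txt"))
  invisible(outDir)
}
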