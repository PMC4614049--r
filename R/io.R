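#' @include AllClasses.R methods.R
NULL

# ---- signal directory (header.txt + data.f32) -------------------------------

#' Read and write recordings in the interchange signal format
#'
#' A recording is stored as a directory holding `header.txt` (plain-text
#' `key = value` lines: `fs`, `n_channels`, `n_samples`, `start_time`,
#' `channels` as a comma-separated list) and `data.f32`, the channels x
#' samples matrix as little-endian 32-bit floats, channel index varying
#' fastest (sample-interleaved). Values are microvolts. Write followed by
#' read is exact for float32-representable data.
#'
#' @param path signal directory.
#' @return `readRecording` returns an [EcogRecording-class];
#'   `writeRecording` returns `path` invisibly.
#' @examples
#' dir <- tempfile()
#' rec <- ecogRecording(matrix(0, 2, 10), 500, c("a", "b"))
#' writeRecording(rec, dir)
#' readRecording(dir)
#' @export
readRecording <- function(path) {
  hpath <- file.path(path, "header.txt")
  dpath <- file.path(path, "data.f32")
  if (!file.exists(hpath) || !file.exists(dpath))
    stop("signal directory must contain header.txt and data.f32: ", path)
  h <- parseKeyValues(readLines(hpath, warn = FALSE))
  for (k in c("fs", "n_channels", "n_samples", "channels"))
    if (is.null(h[[k]]))
      stop("format error: header field missing: ", k)
  fs <- as.numeric(h$fs)
  nch <- as.integer(h$n_channels)
  ns <- as.integer(h$n_samples)
  chans <- trimws(strsplit(h$channels, ",")[[1]])
  if (length(chans) != nch)
    stop("format error: channel list length disagrees with n_channels")
  expect <- as.numeric(nch) * ns
  avail <- file.size(dpath) / 4
  if (avail != expect)
    stop(sprintf(
      "corruption error: data.f32 holds %g samples, header declares %g",
      avail, expect))
  raw <- readBin(dpath, what = "numeric", n = expect, size = 4L,
                 endian = "little")
  data <- matrix(raw, nrow = nch, ncol = ns)
  ecogRecording(data, fs, chans,
                startTime = as.numeric(h$start_time %||% 0))
}

#' @rdname readRecording
#' @param rec an [EcogRecording-class].
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "EcogRecording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    sprintf("fs = %.10g", rec@fs),
    sprintf("n_channels = %d", nrow(rec@data)),
    sprintf("n_samples = %d", ncol(rec@data)),
    sprintf("start_time = %.10g", rec@startTime),
    sprintf("channels = %s", paste(rownames(rec@data), collapse = ","))),
    file.path(path, "header.txt"))
  writeBin(as.vector(rec@data), file.path(path, "data.f32"), size = 4L,
           endian = "little")
  invisible(path)
}

# ---- event tables -----------------------------------------------------------

#' Validate an event table
#'
#' Checks the event-table contract: columns `onset_ms`, `duration_ms`,
#' `finger`, `hand`, `task`; strictly increasing onsets; positive
#' durations (shorter than the recording, when one is given); fingers in
#' 1..5 (1 = thumb, 5 = small finger); hand `CL`/`IL`; task `s`/`sm`.
#'
#' @param events a `data.frame`.
#' @param rec optional [EcogRecording-class] to bound durations against.
#' @return The validated `data.frame`, invisibly coerced to canonical
#'   column types.
#' @export
validateEvents <- function(events, rec = NULL) {
  need <- c("onset_ms", "duration_ms", "finger", "hand", "task")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table misses column(s): ", paste(miss, collapse = ", "))
  events$onset_ms <- as.numeric(events$onset_ms)
  events$duration_ms <- as.numeric(events$duration_ms)
  events$finger <- as.integer(events$finger)
  events$hand <- as.character(events$hand)
  events$task <- as.character(events$task)
  if (nrow(events) > 1 && any(diff(events$onset_ms) <= 0))
    stop("validation error: onsets must be strictly increasing")
  if (any(!events$finger %in% 1:5))
    stop("validation error: finger must be in 1..5")
  if (any(!events$hand %in% c("CL", "IL")))
    stop("validation error: hand must be CL or IL")
  if (any(!events$task %in% c("s", "sm")))
    stop("validation error: task must be s or sm")
  maxdur <- if (is.null(rec)) Inf else 1000 * nSamples(rec) / samplingRate(rec)
  if (any(events$duration_ms <= 0 | events$duration_ms >= maxdur))
    stop("validation error: durations must lie in (0, recording length)")
  events
}

#' Read and write event tables
#'
#' Tab-separated text with header
#' `onset_ms  duration_ms  finger  hand  task`; validated on both ends
#' (see [validateEvents()]).
#'
#' @param path file path.
#' @return `readEvents` returns the validated `data.frame`.
#' @export
readEvents <- function(path) {
  validateEvents(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname readEvents
#' @param events event `data.frame`.
#' @export
writeEvents <- function(events, path) {
  events <- validateEvents(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- electrode layouts ------------------------------------------------------

#' Validate an electrode layout
#'
#' @param layout `data.frame` with columns `name`, `x`, `y`, `z` (mm) and
#'   `grid_id`.
#' @param rec optional [EcogRecording-class]; when given, every layout
#'   name must match a recording channel.
#' @return The validated `data.frame`.
#' @export
validateElectrodes <- function(layout, rec = NULL) {
  need <- c("name", "x", "y", "z", "grid_id")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    stop("electrode table misses column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(layout$name))
    stop("validation error: duplicated electrode label(s)")
  for (k in c("x", "y", "z")) layout[[k]] <- as.numeric(layout[[k]])
  layout$name <- as.character(layout$name)
  layout$grid_id <- as.character(layout$grid_id)
  if (!is.null(rec)) {
    unknown <- setdiff(layout$name, channelNames(rec))
    if (length(unknown))
      stop("validation error: electrode(s) not present in recording: ",
           paste(unknown, collapse = ", "))
  }
  layout
}

#' Read and write electrode layouts
#'
#' Tab-separated text with header `name  x  y  z  grid_id` (mm
#' coordinates).
#'
#' @param path file path.
#' @return `readElectrodes` returns the validated `data.frame`.
#' @export
readElectrodes <- function(path) {
  validateElectrodes(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname readElectrodes
#' @param layout electrode `data.frame`.
#' @export
writeElectrodes <- function(layout, path) {
  layout <- validateElectrodes(layout)
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- analysis configuration files -------------------------------------------

#' Read and write analysis configurations
#'
#' Plain-text `key = value` format with `[section]` headers; pairs such
#' as windows and band edges are comma-separated. Round-trips an
#' [AnalysisConfig-class] exactly.
#'
#' @param path file path.
#' @return `readAnalysisConfig` returns an [AnalysisConfig-class].
#' @export
readAnalysisConfig <- function(path) {
  sec <- parseSections(readLines(path, warn = FALSE))
  num <- function(s) as.numeric(trimws(strsplit(s, ",")[[1]]))
  w <- sec$windows; f <- sec$filters; tf <- sec$tfr; cl <- sec$cluster
  g <- sec$general
  bands <- lapply(sec$bands, num)
  analysisConfig(
    epochWindowMs = num(w$epoch_ms), analysisWindowMs = num(w$analysis_ms),
    baselineWindowMs = num(w$baseline_ms), bands = bands,
    timeBandpassHz = num(f$time_bandpass_hz),
    tfrBandpassHz = num(f$tfr_bandpass_hz),
    nPermutations = as.integer(cl$n_permutations),
    alphaCluster = as.numeric(cl$alpha_cluster),
    alphaForming = as.numeric(cl$alpha_forming),
    waveletCycles = as.numeric(tf$wavelet_cycles),
    tfrTimeStepMs = as.numeric(tf$time_step_ms),
    adjacencyMaxDistMm = as.numeric(cl$adjacency_max_dist_mm),
    logBase = tf$log_base, baselineStat = tf$baseline_stat,
    clusterStat = cl$cluster_stat,
    nullMethod = cl$null_method %||% "shift",
    carEnabled = as.logical(g$car_enabled),
    rngSeed = as.integer(g$rng_seed))
}

#' @rdname readAnalysisConfig
#' @param cfg an [AnalysisConfig-class].
#' @export
writeAnalysisConfig <- function(cfg, path) {
  stopifnot(is(cfg, "AnalysisConfig"))
  pair <- function(x) paste(format(x, scientific = FALSE), collapse = ", ")
  lines <- c(
    "[windows]",
    sprintf("epoch_ms = %s", pair(cfg@epochWindowMs)),
    sprintf("analysis_ms = %s", pair(cfg@analysisWindowMs)),
    sprintf("baseline_ms = %s", pair(cfg@baselineWindowMs)),
    "[filters]",
    sprintf("time_bandpass_hz = %s", pair(cfg@timeBandpassHz)),
    sprintf("tfr_bandpass_hz = %s", pair(cfg@tfrBandpassHz)),
    "[bands]",
    sprintf("%s = %s", names(cfg@bands),
            vapply(cfg@bands, pair, "")),
    "[tfr]",
    sprintf("wavelet_cycles = %g", cfg@waveletCycles),
    sprintf("time_step_ms = %g", cfg@tfrTimeStepMs),
    sprintf("log_base = %s", cfg@logBase),
    sprintf("baseline_stat = %s", cfg@baselineStat),
    "[cluster]",
    sprintf("n_permutations = %d", cfg@nPermutations),
    sprintf("alpha_cluster = %g", cfg@alphaCluster),
    sprintf("alpha_forming = %g", cfg@alphaForming),
    sprintf("adjacency_max_dist_mm = %g", cfg@adjacencyMaxDistMm),
    sprintf("cluster_stat = %s", cfg@clusterStat),
    sprintf("null_method = %s", cfg@nullMethod),
    "[general]",
    sprintf("car_enabled = %s", cfg@carEnabled),
    sprintf("rng_seed = %d", cfg@rngSeed))
  writeLines(lines, path)
  invisible(path)
}

# ---- helpers ----------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

parseKeyValues <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("format error: expected 'key = value' line: ", ln)
    out[[trimws(substr(ln, 1, eq - 1))]] <- trimws(substring(ln, eq + 1))
  }
  out
}

parseSections <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); cur <- "general"
  buf <- character()
  flush <- function(out, cur, buf) {
    if (length(buf))
      out[[cur]] <- utils::modifyList(out[[cur]] %||% list(),
                                      parseKeyValues(buf))
    out
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      out <- flush(out, cur, buf); buf <- character()
      cur <- sub("^\\[(.+)\\]$", "\\1", ln)
    } else buf <- c(buf, ln)
  }
  flush(out, cur, buf)
}
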