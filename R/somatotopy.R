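#' @include AllClasses.R methods.R clusters.R
NULL

#' Power-weighted centroid of a cluster
#'
#' Each electrode in the cluster is weighted by the sum, over its member
#' cells, of the absolute trial-averaged normalized power; the centroid
#' is the weight-weighted mean of the electrode coordinates. The
#' centroid therefore always lies within the convex hull of the
#' contributing electrodes, and is invariant to uniform weight scaling.
#'
#' @param members one cluster's member table (see [clusterMembers()]).
#' @param tfr the normalized [TFRTensor-class] restricted to the same
#'   trials and band the cluster was computed from.
#' @param layout electrode layout `data.frame`.
#' @return `list(centroid = c(x, y, z), weights = data.frame(name,
#'   weight))`.
#' @export
clusterCentroid <- function(members, tfr, layout) {
  if (!nrow(members)) stop("cluster has no member cells")
  layout <- validateElectrodes(layout)
  avg <- colMeans(tfr@power, dims = 1)       # channel x freq x time
  ch <- match(members$channel, channelNames(tfr))
  fr <- match(members$freq_hz, tfr@freqsHz)
  ti <- match(members$time_ms, tfr@timeMs)
  if (anyNA(ch) || anyNA(fr) || anyNA(ti))
    stop("member cells not found in the supplied TFR axes")
  w <- abs(avg[cbind(ch, fr, ti)])
  wByCh <- tapply(w, members$channel, sum)
  if (all(wByCh == 0)) stop("degenerate input: all cluster weights are zero")
  pos <- layout[match(names(wByCh), layout$name), c("x", "y", "z")]
  if (anyNA(pos[[1]])) stop("cluster channel(s) missing from layout")
  centroid <- colSums(pos * as.numeric(wByCh)) / sum(wByCh)
  list(centroid = centroid,
       weights = data.frame(name = names(wByCh),
                            weight = as.numeric(wByCh),
                            row.names = NULL))
}

#' Select the primary (most significant) cluster
#'
#' Among the significant clusters of one result: the smallest p-value;
#' ties broken by larger |mass|, then by earlier onset.
#'
#' @param result a [ClusterResult-class].
#' @return Row index into [clusterTable()] of the primary cluster, or
#'   `NA` if no cluster is significant.
#' @export
selectPrimaryCluster <- function(result) {
  tab <- result@table
  sig <- which(tab$significant)
  if (!length(sig)) return(NA_integer_)
  ord <- order(tab$p_value[sig], -abs(tab$mass[sig]), tab$onset_ms[sig])
  sig[ord[1]]
}

#' Build the somatotopic finger map
#'
#' For each finger with at least one significant cluster in the supplied
#' results, computes the power-weighted centroid of its primary cluster;
#' fingers without significant clusters are left unmapped. The map span
#' is the maximum pairwise centroid distance and the order score the
#' Spearman rank correlation between finger index (1..5) and the
#' centroid projection on the latero-medial axis; both are `NA` when
#' fewer than two fingers are mapped.
#'
#' @param results list of per-finger [ClusterResult-class] objects of
#'   one (condition, band), e.g. the `MidG` entries of [runAllBands()].
#' @param tfr the full normalized [TFRTensor-class] the tests were run
#'   on (all trials, frequencies covering the band).
#' @param cfg the [AnalysisConfig-class] used (for the band edges).
#' @param layout electrode layout `data.frame`.
#' @param axis latero-medial unit vector (default the grid x-axis).
#' @return A [FingerMap-class].
#' @export
buildFingerMap <- function(results, tfr, cfg, layout,
                           axis = c(1, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  cent <- data.frame(finger = 1:5, x = NA_real_, y = NA_real_,
                     z = NA_real_, p_value = NA_real_,
                     cluster_id = NA_integer_, mapped = FALSE)
  weights <- list()
  lab <- tfr@labels
  cond <- paste0(lab$hand, lab$task)
  for (r in results) {
    fg <- r@finger
    if (is.na(fg)) next
    pri <- selectPrimaryCluster(r)
    if (is.na(pri)) {
      message("finger ", fg, ": no significant cluster; unmapped")
      next
    }
    idx <- which(cond == r@condition & lab$finger == fg)
    sub <- bandTfr(selectTrials(tfr, idx), cfg@bands[[r@band]])
    cc <- clusterCentroid(r@members[[pri]], sub, layout)
    cent[fg, c("x", "y", "z")] <- as.list(cc$centroid)
    cent$p_value[fg] <- r@table$p_value[pri]
    cent$cluster_id[fg] <- r@table$id[pri]
    cent$mapped[fg] <- TRUE
    weights[[as.character(fg)]] <- cc$weights
  }
  m <- cent[cent$mapped, , drop = FALSE]
  if (nrow(m) >= 2) {
    span <- max(stats::dist(as.matrix(m[, c("x", "y", "z")])))
    proj <- as.matrix(m[, c("x", "y", "z")]) %*% axis
    ord <- suppressWarnings(
      stats::cor(m$finger, proj, method = "spearman"))
    # rank correlations are discrete (granularity >= 1/choose(n,2));
    # drop floating-point residue so exact comparisons behave
    ord <- round(ord, 10)
  } else {
    message("fewer than 2 mapped fingers: span and order undefined")
    span <- NA_real_; ord <- NA_real_
  }
  new("FingerMap", centroids = cent, spanMm = as.numeric(span),
      orderScore = as.numeric(ord), axis = as.numeric(axis),
      weights = weights)
}
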