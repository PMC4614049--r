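# Shared fixtures and oracles for the test suite.

# Brute-force reference clustering: connected components of same-sign
# suprathreshold cells of a channel x freq x time t array under the
# 6-neighbourhood (one step in time, one in frequency, electrode-graph
# edges), found by repeated neighbourhood expansion over a logical mask.
bruteClusters <- function(stat, threshold, adjacency) {
  d <- dim(stat)
  res <- list()
  for (sgn in c(1, -1)) {
    mask <- array(sgn * stat > threshold, d)
    repeat {
      seed <- which(mask)[1]
      if (is.na(seed)) break
      comp <- seed
      frontier <- seed
      mask[seed] <- FALSE
      while (length(frontier)) {
        nxt <- integer()
        for (cell in frontier) {
          i <- arrayInd(cell, d)
          nb <- list()
          if (i[2] > 1) nb <- c(nb, list(c(i[1], i[2] - 1, i[3])))
          if (i[2] < d[2]) nb <- c(nb, list(c(i[1], i[2] + 1, i[3])))
          if (i[3] > 1) nb <- c(nb, list(c(i[1], i[2], i[3] - 1)))
          if (i[3] < d[3]) nb <- c(nb, list(c(i[1], i[2], i[3] + 1)))
          for (ch2 in which(adjacency[i[1], ]))
            nb <- c(nb, list(c(ch2, i[2], i[3])))
          for (v in nb) {
            li <- v[1] + d[1] * ((v[2] - 1) + d[2] * (v[3] - 1))
            if (mask[li]) {
              mask[li] <- FALSE
              nxt <- c(nxt, li)
              comp <- c(comp, li)
            }
          }
        }
        frontier <- nxt
      }
      res[[length(res) + 1L]] <- list(sign = sgn, cells = sort(comp),
                                      size = length(comp),
                                      mass = sum(stat[comp]))
    }
  }
  res
}

# Small deterministic layout: nr x nc grid at `pitch` mm, names e01..
smallLayout <- function(nr = 3, nc = 3, pitch = 10) {
  idx <- seq_len(nr * nc)
  data.frame(name = sprintf("e%02d", idx),
             x = ((idx - 1) %% nc) * pitch,
             y = ((idx - 1) %/% nc) * pitch,
             z = 0, grid_id = "G1")
}

# Minimal normalized TFRTensor with given power array (trial x channel x
# freq x time) for unit tests of downstream code.
makeTfr <- function(power, freqsHz, timeMs, labels = NULL,
                    normalized = TRUE, fs = 500) {
  d <- dim(power)
  if (is.null(labels))
    labels <- data.frame(finger = rep(1L, d[1]), hand = "CL", task = "s",
                         onset_ms = seq_len(d[1]) * 1000)
  if (is.null(dimnames(power)[[2]]))
    dimnames(power) <- list(NULL, sprintf("e%02d", seq_len(d[2])),
                            NULL, NULL)
  new("TFRTensor", power = power, freqsHz = freqsHz, timeMs = timeMs,
      labels = labels, fs = fs, normalized = normalized,
      logBase = if (normalized) "db10" else "none")
}

# One small cached session for tests that only need plausible data.
localSessionCache <- new.env(parent = emptyenv())
smallSession <- function() {
  if (is.null(localSessionCache$ses))
    localSessionCache$ses <- generateSession(
      simConfig(nSets = 1, gridShape = c(4, 4),
                fingerSites = sprintf("e%02d", 6:10), seed = 11))
  localSessionCache$ses
}
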