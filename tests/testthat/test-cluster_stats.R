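test_that("electrode adjacency follows grid geometry and grid identity", {
  lay <- smallLayout(8, 8, pitch = 10)
  adj <- electrodeAdjacency(lay, 15)
  deg <- rowSums(adj)
  # interior contacts: 8 neighbours (diagonals at 14.1 mm), corners 3
  inner <- with(lay, x > 0 & x < 70 & y > 0 & y < 70)
  expect_true(all(deg[inner] == 8))
  expect_equal(deg[["e01"]], 3)
  expect_true(isSymmetric(adj))
  expect_true(all(!diag(adj)))
  # cross-grid pairs are never adjacent however close
  lay2 <- rbind(smallLayout(1, 2), within(smallLayout(1, 2), {
    name <- c("f01", "f02"); grid_id <- "G2"
  }))
  expect_true(all(!electrodeAdjacency(lay2, 15)[1:2, 3:4]))
  # radius 10: only lattice neighbours
  expect_equal(sum(electrodeAdjacency(lay, 10)["e10", ]), 4)
})

test_that("sampleStatistic matches the t formula and t.test", {
  expect_equal(sampleStatistic(matrix(c(1, 2, 3), 3, 1))[1],
               2 / (1 / sqrt(3)), tolerance = 1e-12)
  set.seed(3)
  X <- matrix(rnorm(12 * 7), 12, 7)
  tt <- vapply(1:7, function(j) unname(t.test(X[, j])$statistic), 0)
  expect_equal(sampleStatistic(X), tt, tolerance = 1e-12)
  # zero-variance cells flagged by sign of the mean
  Z <- cbind(rep(2, 5), rep(-2, 5), rep(0, 5))
  expect_identical(sampleStatistic(Z), c(Inf, -Inf, 0))
})

test_that("formClusters matches brute-force flood fill on random maps", {
  set.seed(42)
  for (rep in 1:100) {
    d <- c(sample(2:6, 1), sample(1:5, 1), sample(1:6, 1))
    stat <- array(rnorm(prod(d), sd = 2), d)
    adj <- matrix(FALSE, d[1], d[1])
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- pairs[stats::runif(nrow(pairs)) < 0.3, , drop = FALSE]
    adj[on] <- TRUE; adj <- adj | t(adj)
    dimnames(adj) <- list(sprintf("e%02d", 1:d[1]), sprintf("e%02d", 1:d[1]))
    thr <- stats::runif(1, 0.5, 2)
    got <- formClusters(stat, thr, adj)
    want <- bruteClusters(stat, thr, adj)
    expect_equal(nrow(got$table), length(want))
    if (!length(want)) next
    key <- function(cells) paste(cells, collapse = ",")
    gk <- vapply(got$cells, key, "")
    wk <- vapply(lapply(want, `[[`, "cells"), key, "")
    expect_setequal(gk, wk)
    m <- match(gk, wk)
    expect_false(anyNA(m))
    expect_equal(got$table$size, vapply(want, `[[`, 0L, "size")[m])
    expect_equal(got$table$mass, vapply(want, `[[`, 0, "mass")[m],
                 tolerance = 1e-10)
    expect_equal(got$table$sign,
                 vapply(want, `[[`, 0, "sign")[m])
  }
})

test_that("sign-flip null kernel matches a plain-R reference", {
  set.seed(7)
  n <- 8; nch <- 4; nf <- 3; nt <- 5
  ncell <- nch * nf * nt
  X <- matrix(rnorm(n * ncell), n, ncell)
  adj <- matrix(FALSE, nch, nch)
  adj[cbind(1:3, 2:4)] <- TRUE; adj <- adj | t(adj)
  dimnames(adj) <- list(sprintf("e%02d", 1:nch), sprintf("e%02d", 1:nch))
  csr <- vibromap:::adjacencyCsr(adj)
  thr <- stats::qt(0.975, n - 1)
  S <- matrix(sample(c(-1, 1), n * 50, replace = TRUE), n, 50)
  got <- vibromap:::cppPermMaxStat(X, S, colSums(X^2), thr, nch, nf, nt,
                                   0L, 0L, csr$ptr, csr$idx)
  want <- vapply(1:50, function(j) {
    t <- sampleStatistic(X * S[, j])
    cl <- bruteClusters(array(t, c(nch, nf, nt)), thr, adj)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
  }, 0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("bootstrap null kernel matches a plain-R reference", {
  set.seed(8)
  n <- 9; nch <- 3; nf <- 2; nt <- 4
  ncell <- nch * nf * nt
  X <- sweep(matrix(stats::rexp(n * ncell), n, ncell), 2,
             colMeans(matrix(stats::rexp(n * ncell), n, ncell)))
  Xc <- sweep(X, 2, colMeans(X))
  adj <- matrix(FALSE, nch, nch)
  dimnames(adj) <- list(sprintf("e%02d", 1:nch), sprintf("e%02d", 1:nch))
  csr <- vibromap:::adjacencyCsr(adj)
  thr <- 1.5
  S <- vapply(1:40, function(j)
    tabulate(sample.int(n, n, replace = TRUE), n), integer(n))
  S <- matrix(as.numeric(S), n, 40)
  got <- vibromap:::cppPermMaxStat(Xc, S, colSums(Xc^2), thr, nch, nf, nt,
                                   0L, 1L, csr$ptr, csr$idx)
  want <- vapply(1:40, function(j) {
    # resample rows with the drawn multiplicities
    idx <- rep(seq_len(n), S[, j])
    t <- sampleStatistic(Xc[idx, , drop = FALSE])
    t[!is.finite(t)] <- sign(t[!is.finite(t)]) * 1e6
    cl <- bruteClusters(array(t, c(nch, nf, nt)), thr, adj)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
  }, 0)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("shift null kernel at zero offset reproduces the observed map", {
  set.seed(9)
  n <- 10; nch <- 3; nf <- 4; ntExt <- 12
  CF <- nch * nf
  P <- array(stats::rlnorm(n * CF * ntExt), c(n, nch, nf, ntExt))
  anaPos <- 3:10; basePos <- 3:5
  nt <- length(anaPos)
  adj <- matrix(FALSE, nch, nch)
  adj[1, 2] <- adj[2, 1] <- TRUE
  dimnames(adj) <- list(sprintf("e%02d", 1:nch), sprintf("e%02d", 1:nch))
  csr <- vibromap:::adjacencyCsr(adj)
  thr <- 1.2
  L <- aperm(log(P), c(2, 3, 4, 1))
  zeroIdx <- matrix(0L, n, 5)
  got <- vibromap:::cppShiftMaxStat(as.numeric(L), n, nch, nf, ntExt,
                                    anaPos - 1L, basePos - 1L, 0L, zeroIdx,
                                    thr, 0L, 1L, csr$ptr, csr$idx)
  # observed statistic: geometric baseline normalisation then max cluster
  lp <- log(P)
  bm <- apply(lp[, , , basePos, drop = FALSE], 1:3, mean)
  V <- lp[, , , anaPos, drop = FALSE] - array(bm, c(n, nch, nf, nt))
  t <- sampleStatistic(matrix(V, n, CF * nt))
  cl <- bruteClusters(array(t, c(nch, nf, nt)), thr, adj)
  want <- max(abs(vapply(cl, `[[`, 0, "mass")))
  expect_equal(got, rep(want, 5), tolerance = 1e-10)
  # arithmetic-baseline flavour from raw power input
  got2 <- vibromap:::cppShiftMaxStat(as.numeric(aperm(P, c(2, 3, 4, 1))),
                                     n, nch, nf, ntExt, anaPos - 1L,
                                     basePos - 1L, 0L, zeroIdx, thr, 0L,
                                     0L, csr$ptr, csr$idx)
  bm2 <- apply(P[, , , basePos, drop = FALSE], 1:3, mean)
  V2 <- log(P[, , , anaPos, drop = FALSE] /
              array(bm2, c(n, nch, nf, nt)))
  t2 <- sampleStatistic(matrix(V2, n, CF * nt))
  cl2 <- bruteClusters(array(t2, c(nch, nf, nt)), thr, adj)
  expect_equal(got2, rep(max(abs(vapply(cl2, `[[`, 0, "mass"))), 5),
               tolerance = 1e-10)
})

test_that("shift null kernel honours per-trial offsets", {
  set.seed(10)
  n <- 6; nch <- 2; nf <- 2; ntExt <- 10
  CF <- nch * nf
  P <- array(stats::rlnorm(n * CF * ntExt), c(n, nch, nf, ntExt))
  anaPos <- 4:8; basePos <- 4:5
  nt <- length(anaPos)
  adj <- matrix(FALSE, nch, nch)
  dimnames(adj) <- list(c("e01", "e02"), c("e01", "e02"))
  csr <- vibromap:::adjacencyCsr(adj)
  offsets <- c(-3L, -1L, 0L, 2L)
  idx <- matrix(sample(0:3, n * 7, replace = TRUE), n, 7)
  got <- vibromap:::cppShiftMaxStat(as.numeric(aperm(log(P), c(2, 3, 4, 1))),
                                    n, nch, nf, ntExt, anaPos - 1L,
                                    basePos - 1L, offsets, idx, 1.1, 0L,
                                    1L, csr$ptr, csr$idx)
  want <- vapply(1:7, function(j) {
    V <- array(0, c(n, nch, nf, nt))
    for (tr in 1:n) {
      s <- offsets[idx[tr, j] + 1L]
      lp <- log(P[tr, , , , drop = FALSE])
      bm <- apply(lp[, , , basePos + s, drop = FALSE], 1:3, mean)
      V[tr, , , ] <- lp[, , , anaPos + s, drop = FALSE] -
        array(bm, c(1, nch, nf, nt))
    }
    t <- sampleStatistic(matrix(V, n, CF * nt))
    cl <- bruteClusters(array(t, c(nch, nf, nt)), 1.1, adj)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
  }, 0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("extendedTfrWindow pads around the analysed interval", {
  cfg <- analysisConfig()
  w <- extendedTfrWindow(cfg, 65)
  expect_lte(w[1], cfg@baselineWindowMs[1])
  expect_gte(w[2], cfg@analysisWindowMs[2])
  expect_equal(w, c(-570, 600))
  # the slowest default band is clipped by wavelet support, not padding
  w8 <- extendedTfrWindow(cfg, 8)
  half <- 3 * 7 / (2 * pi * 8) * 1000
  expect_equal(w8[2], 1000 - half)
  # too-short epochs are rejected
  cfgS <- analysisConfig(epochWindowMs = c(-600, 600))
  expect_error(extendedTfrWindow(cfgS, 8), "too short")
})

test_that("permutation test is deterministic and p-values are floored", {
  ses <- smallSession()
  acfg <- analysisConfig(nPermutations = 300)
  mg <- vibromap:::midGammaTfr(ses, acfg)
  adj <- electrodeAdjacency(ses$layout)
  idx <- which(trialLabels(mg$tfr)$finger == 2)
  sub <- selectTrials(mg$tfr, idx)
  raw <- selectTrials(mg$raw, idx)
  r1 <- permutationTest(sub, acfg, adj, finger = 2L, seed = 5, rawTfr = raw)
  r2 <- permutationTest(sub, acfg, adj, finger = 2L, seed = 5, rawTfr = raw)
  expect_identical(clusterTable(r1), clusterTable(r2))
  expect_identical(r1@permMaxMass, r2@permMaxMass)
  r3 <- permutationTest(sub, acfg, adj, finger = 2L, seed = 6, rawTfr = raw)
  expect_false(identical(r1@permMaxMass, r3@permMaxMass))
  tab <- clusterTable(r1)
  expect_true(all(tab$p_value >= 1 / 301))
  expect_true(all(diff(tab$p_value) >= 0))          # sorted by p
  expect_equal(nrow(tab), length(clusterMembers(r1)))
  # the injected finger-2 site is recovered as the top ERS cluster
  pri <- selectPrimaryCluster(r1)
  expect_false(is.na(pri))
  expect_true(ses$truth$sites$name[2] %in%
                clusterMembers(r1)[[pri]]$channel)
})

test_that("shift null requires a consistent raw TFR", {
  ses <- smallSession()
  acfg <- analysisConfig(nPermutations = 300)
  mg <- vibromap:::midGammaTfr(ses, acfg)
  adj <- electrodeAdjacency(ses$layout)
  idx <- which(trialLabels(mg$tfr)$finger == 1)
  sub <- selectTrials(mg$tfr, idx)
  expect_error(permutationTest(sub, acfg, adj), "rawTfr")
  wrong <- selectTrials(mg$raw, idx[-1])
  expect_error(permutationTest(sub, acfg, adj,
                               rawTfr = wrong), "disagree")
})

test_that("all three null methods agree on the obvious effect", {
  ses <- smallSession()
  adj <- electrodeAdjacency(ses$layout)
  for (nm in c("shift", "bootstrap", "signflip")) {
    acfg <- analysisConfig(nPermutations = 200, nullMethod = nm)
    mg <- vibromap:::midGammaTfr(ses, acfg, trialIdx =
                                   which(ses$events$finger == 4))
    res <- permutationTest(mg$tfr, acfg, adj, finger = 4L,
                           rawTfr = if (nm == "shift") mg$raw)
    sig <- significantClusters(res)
    expect_gte(nrow(sig), 1)
    pri <- selectPrimaryCluster(res)
    expect_true(ses$truth$sites$name[4] %in%
                  clusterMembers(res)[[pri]]$channel)
  }
})

test_that("runAllBands covers conditions, bands and fingers", {
  ses <- smallSession()
  acfg <- analysisConfig(nPermutations = 200,
                         bands = list(Beta = c(13, 30), MidG = c(65, 115)))
  trials <- epochTrials(ses$recording, ses$events, acfg@epochWindowMs)
  fb <- bandpassFir(trials, 1, 230)
  tfr <- morletTfr(fb, bandFrequencies(acfg@bands),
                   outWindowMs = acfg@analysisWindowMs)
  tfr <- baselineNormalize(tfr, acfg@baselineWindowMs)
  adj <- electrodeAdjacency(ses$layout)
  res <- runAllBands(tfr, acfg, adj, fingers = c(1, 3), trials = fb)
  expect_setequal(names(res), c("CLs.Beta.1", "CLs.Beta.3",
                                "CLs.MidG.1", "CLs.MidG.3"))
  expect_error(runAllBands(tfr, acfg, adj, fingers = 1), "full-epoch")
  ctab <- combinedClusterTable(res)
  expect_true(all(c("condition", "band", "finger", "p_value") %in%
                    names(ctab)))
  expect_equal(sum(ctab$band == "MidG" & ctab$finger == 1),
               nrow(clusterTable(res$CLs.MidG.1)))
})
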