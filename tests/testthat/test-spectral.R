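makeSine <- function(f, amp = 1, fs = 500, n = 1000, phase = 0) {
  tt <- (seq_len(n) - n / 2) / fs
  d <- array(amp * cos(2 * pi * f * tt + phase), c(1, 1, n),
             dimnames = list(NULL, "a", NULL))
  new("TrialTensor", data = d, timeMs = tt * 1000,
      labels = data.frame(finger = 1L, hand = "CL", task = "s",
                          onset_ms = 0), fs = fs)
}

test_that("bandFrequencies covers band interiors and skips gaps", {
  f <- bandFrequencies()
  expect_true(all(c(8, 13, 30, 55, 65, 115, 125, 230) %in% f))
  expect_false(any(f > 55 & f < 65))
  expect_false(any(f > 115 & f < 125))
  expect_equal(bandFrequencies(list(MidG = c(65, 115))), 65:115)
})

test_that("Morlet TFR localises a sinusoid at its frequency", {
  tfr <- morletTfr(makeSine(100), 80:120)
  p <- tfrPower(tfr)
  mid <- which(abs(timeMs(tfr)) < 400)
  prof <- colMeans(t(p[1, 1, , mid]))
  expect_equal(freqsHz(tfr)[which.max(prof)], 100)
  # unit-peak wavelet spectrum: analytic power of a unit cosine is 1/4
  expect_equal(max(prof), 0.25, tolerance = 0.02)
})

test_that("power scales with the square of amplitude", {
  t1 <- morletTfr(makeSine(100, amp = 1), 95:105)
  t2 <- morletTfr(makeSine(100, amp = 2), 95:105)
  mid <- abs(timeMs(t1)) < 400
  expect_equal(tfrPower(t2)[, , , mid], 4 * tfrPower(t1)[, , , mid],
               tolerance = 1e-10)
})

test_that("spectral selectivity matches the 7-cycle Gaussian wavelet", {
  # amplitude response of the 10 Hz wavelet to a detuned sinusoid is
  # exp(-(df)^2 / (2 sigma_f^2)) with sigma_f = 10/7: half amplitude at
  # df = sigma_f * sqrt(2 ln 2) = 1.68 Hz (FWHM 3.36 Hz)
  at10 <- function(fsig) {
    tfr <- morletTfr(makeSine(fsig, n = 4000), 10)
    mean(sqrt(tfrPower(tfr)[1, 1, 1, abs(timeMs(tfr)) < 2000]))
  }
  a0 <- at10(10)
  expect_equal(at10(10 + 1.68) / a0, 0.5, tolerance = 0.05)
  expect_equal(at10(10 - 1.68) / a0, 0.5, tolerance = 0.05)
  expect_lt(at10(20) / a0, 1e-6)
})

test_that("output grid, window and fold/no-fold agree with a direct DFT", {
  set.seed(6)
  n <- 1000; fs <- 500
  d <- array(rnorm(2 * 1 * n), c(2, 1, n), dimnames = list(NULL, "a", NULL))
  tr <- new("TrialTensor", data = d, timeMs = (seq_len(n) - 500) / fs * 1000,
            labels = data.frame(finger = c(1L, 1L), hand = "CL", task = "s",
                                onset_ms = c(0, 1)), fs = fs)
  freqs <- c(23, 80)
  # oracle: explicit frequency-domain wavelet filtering at full rate
  oracle <- function(x, f) {
    fb <- (seq_len(n) - 1) * fs / n
    w <- exp(-0.5 * ((fb - f) / (f / 7))^2)
    w[fb > fs / 2] <- 0
    Mod(stats::fft(stats::fft(x) * w, inverse = TRUE) / n)^2
  }
  # 20 ms step (d = 10 divides n: folded path)
  tfr <- morletTfr(tr, freqs, timeStepMs = 20)
  pos <- match(timeMs(tfr), tr@timeMs)
  for (k in 1:2)
    expect_equal(tfrPower(tfr)[1, 1, k, ], oracle(d[1, 1, ], freqs[k])[pos],
                 tolerance = 1e-10)
  # 14 ms step (d = 7 does not divide n: direct path), second trial
  tfr2 <- morletTfr(tr, freqs, timeStepMs = 14)
  pos2 <- match(timeMs(tfr2), tr@timeMs)
  expect_equal(tfrPower(tfr2)[2, 1, 2, ], oracle(d[2, 1, ], 80)[pos2],
               tolerance = 1e-10)
  # window restriction selects the same bins
  tfr3 <- morletTfr(tr, freqs, timeStepMs = 20, outWindowMs = c(-100, 200))
  keep <- timeMs(tfr) >= -100 & timeMs(tfr) < 200
  expect_equal(tfrPower(tfr3), tfrPower(tfr)[, , , keep, drop = FALSE])
  expect_equal(timeMs(tfr3), timeMs(tfr)[keep])
})

test_that("unanalysable frequencies are dropped with a warning", {
  tr <- makeSine(50, n = 500)      # 1 s epoch: 7 cycles need f >= 7 Hz
  expect_warning(tfr <- morletTfr(tr, c(5, 50, 260)), "dropped")
  expect_identical(freqsHz(tfr), 50)
  expect_error(suppressWarnings(morletTfr(tr, c(1, 2))), "no analysable")
})

test_that("baseline normalisation satisfies its closed-form identities", {
  # constant power P0 everywhere -> 0 dB everywhere
  p <- array(4, c(2, 1, 1, 20), dimnames = list(NULL, "a", NULL, NULL))
  tfr <- makeTfr(p, freqsHz = 10, timeMs = seq(-200, 180, by = 20),
                 normalized = FALSE)
  tfr@logBase <- "none"
  z <- baselineNormalize(tfr, c(-150, -10))
  expect_equal(as.numeric(tfrPower(z)), rep(0, 40), tolerance = 1e-12)
  expect_true(isNormalized(z))
  # 10x baseline -> +10 dB; e-fold -> +1 natural
  p2 <- p; p2[, , , 11:20] <- 40
  tfr2 <- makeTfr(p2, 10, seq(-200, 180, by = 20), normalized = FALSE)
  tfr2@logBase <- "none"
  z2 <- baselineNormalize(tfr2, c(-150, -10))
  expect_equal(as.numeric(tfrPower(z2)[, , , 11:20]), rep(10, 20),
               tolerance = 1e-12)
  p3 <- p; p3[, , , 11:20] <- 4 * exp(1)
  tfr3 <- makeTfr(p3, 10, seq(-200, 180, by = 20), normalized = FALSE)
  tfr3@logBase <- "none"
  z3 <- baselineNormalize(tfr3, c(-150, -10), logBase = "natural")
  expect_equal(as.numeric(tfrPower(z3)[, , , 11:20]), rep(1, 20),
               tolerance = 1e-12)
})

test_that("geometric and arithmetic baselines differ as mean-log vs log-mean", {
  set.seed(2)
  p <- array(stats::rlnorm(1 * 1 * 1 * 30), c(1, 1, 1, 30),
             dimnames = list(NULL, "a", NULL, NULL))
  tm <- seq(-150, 440, by = 20)
  tfr <- makeTfr(p, 20, tm, normalized = FALSE)
  tfr@logBase <- "none"
  bidx <- tm >= -150 & tm < -10
  g <- baselineNormalize(tfr, c(-150, -10), baselineStat = "geometric")
  a <- baselineNormalize(tfr, c(-150, -10), baselineStat = "arithmetic")
  expect_equal(as.numeric(tfrPower(g)),
               10 * log10(as.numeric(p)) -
                 mean(10 * log10(p[1, 1, 1, bidx])), tolerance = 1e-12)
  expect_equal(as.numeric(tfrPower(a)),
               10 * log10(as.numeric(p) / mean(p[1, 1, 1, bidx])),
               tolerance = 1e-12)
  # Jensen: arithmetic-mean baseline >= geometric -> smaller values
  expect_true(all(tfrPower(a) <= tfrPower(g) + 1e-12))
})

test_that("normalisation rejects double application and bad input", {
  p <- array(1, c(1, 1, 1, 20), dimnames = list(NULL, "a", NULL, NULL))
  tfr <- makeTfr(p, 10, seq(-200, 180, by = 20), normalized = FALSE)
  tfr@logBase <- "none"
  z <- baselineNormalize(tfr, c(-150, -10))
  expect_error(baselineNormalize(z, c(-150, -10)), "already")
  bad <- tfr; bad@power[1, 1, 1, 4] <- 0    # -140 ms, inside baseline
  expect_error(baselineNormalize(bad, c(-150, -10)), "degenerate")
  expect_error(baselineNormalize(tfr, c(900, 950)), "baseline window")
})

test_that("cropTfr and bandTfr subset their axes", {
  p <- array(seq_len(2 * 3 * 4 * 5), c(2, 3, 4, 5),
             dimnames = list(NULL, c("a", "b", "c"), NULL, NULL))
  tfr <- makeTfr(p, freqsHz = c(8, 10, 12, 14), timeMs = seq(0, 80, by = 20),
                 labels = data.frame(finger = c(1L, 2L), hand = "CL",
                                     task = "s", onset_ms = c(0, 1)))
  cr <- cropTfr(tfr, c(20, 60))
  expect_equal(timeMs(cr), c(20, 40))
  expect_identical(tfrPower(cr), p[, , , 2:3, drop = FALSE])
  bd <- bandTfr(tfr, c(10, 12))
  expect_equal(freqsHz(bd), c(10, 12))
  expect_identical(tfrPower(bd), p[, , 2:3, , drop = FALSE])
  expect_error(cropTfr(tfr, c(500, 600)), "outside")
  expect_error(bandTfr(tfr, c(100, 200)), "not covered")
})
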