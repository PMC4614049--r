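test_that("session generation is seed-deterministic", {
  cfg <- simConfig(nSets = 1, gridShape = c(4, 4),
                   fingerSites = sprintf("e%02d", 6:10), seed = 5)
  a <- generateSession(cfg)
  b <- generateSession(cfg)
  expect_identical(signalData(a$recording), signalData(b$recording))
  expect_identical(a$events, b$events)
  cfg2 <- simConfig(nSets = 1, gridShape = c(4, 4),
                    fingerSites = sprintf("e%02d", 6:10), seed = 6)
  expect_false(identical(signalData(generateSession(cfg2)$recording),
                         signalData(a$recording)))
})

test_that("event schedule honours counts, durations and intervals", {
  cfg <- simConfig(nSets = 2, seed = 3)
  ev <- scheduleEvents(cfg, seed = 3)
  expect_equal(nrow(ev), 100)
  expect_true(all(table(ev$finger) == 20))
  expect_true(all(diff(ev$onset_ms) > 0))
  expect_true(all(ev$duration_ms >= 100 & ev$duration_ms <= 500))
  # offset-to-onset gaps: inside a set in [1000, 1400], >= 3000 between
  # sets (1000 minimum ISI + 2000 pause)
  gaps <- ev$onset_ms[-1] - (ev$onset_ms[-100] + ev$duration_ms[-100])
  expect_true(all(gaps[c(1:49, 51:99)] >= 1000 - 1e-9))
  expect_true(all(gaps[c(1:49, 51:99)] <= 1400 + 1e-9))
  expect_gte(gaps[50], 3000)
})

test_that("hands cycle over sets", {
  cfg <- simConfig(nSets = 2, hands = c("CL", "IL"), seed = 1)
  ev <- scheduleEvents(cfg, seed = 1)
  expect_identical(unique(ev$hand[1:50]), "CL")
  expect_identical(unique(ev$hand[51:100]), "IL")
})

test_that("background noise has exact RMS and ~1/f^2 spectrum", {
  cfg <- simConfig(seed = 1)
  set.seed(2)
  sig <- backgroundNoise(cfg, nChannels = 4, nSamples = 60000)
  expect_equal(sqrt(rowMeans(sig^2)), rep(20, 4), tolerance = 1e-12)
  # log-log PSD slope over 2..100 Hz should be ~ -backgroundExponent
  sp <- stats::spectrum(sig[1, ], spans = c(11, 11), plot = FALSE)
  fHz <- sp$freq * cfg@fs
  keep <- fHz >= 2 & fHz <= 100
  slope <- stats::coef(stats::lm(log(sp$spec[keep]) ~ log(fHz[keep])))[2]
  expect_equal(unname(slope), -2, tolerance = 0.3)
})

test_that("line noise adds an identical 60 Hz component to all channels", {
  cfg <- simConfig(lineNoise60Uv = 10, seed = 1)
  set.seed(4)
  sig <- backgroundNoise(cfg, nChannels = 2, nSamples = 5000)
  set.seed(4)
  clean <- backgroundNoise(simConfig(lineNoise60Uv = 0, seed = 1),
                           nChannels = 2, nSamples = 5000)
  line <- sig - clean
  expect_equal(line[1, ], line[2, ])                  # common to the grid
  f <- stats::fft(line[1, ])
  peak <- which.max(Mod(f[2:2500])) * cfg@fs / 5000   # dominant frequency
  expect_equal(peak, 60, tolerance = 0.2)
  expect_equal(sqrt(mean(line[1, ]^2)), 10 / sqrt(2), tolerance = 1e-6)
})

test_that("null injection leaves the signal bit-identical", {
  cfg <- simConfig(nSets = 1, gridShape = c(4, 4),
                   fingerSites = sprintf("e%02d", 6:10),
                   ersAmpUv = 0, erdAttenuation = 0,
                   erpComponents = within(defaultErpComponents(),
                                          amplitude_uv <- 0),
                   seed = 8)
  layout <- gridLayout(cfg)
  events <- scheduleEvents(cfg, seed = 8)
  sig <- matrix(rnorm(16 * 40000), 16)
  out <- injectResponses(sig, events, cfg, layout)
  expect_identical(out$signal, sig)
  expect_false(any(out$truth$events$injected))
})

test_that("ERP injection matches its closed form with Gaussian falloff", {
  cfg <- simConfig(nSets = 1, ersAmpUv = 0, erdAttenuation = 0, seed = 1)
  layout <- gridLayout(cfg)
  ev <- data.frame(onset_ms = 2000, duration_ms = 300, finger = 1,
                   hand = "CL", task = "s")
  sig <- matrix(0, nrow(layout), 3000)
  out <- injectResponses(sig, ev, cfg, layout)$signal
  site <- cfg@fingerSites[1]
  i <- match(site, layout$name)
  # peak of the N40 atom at onset + 38 ms: amplitude 20, polarity -1
  n40 <- round((2000 + 38) / 1000 * cfg@fs) + 1L
  expect_equal(out[i, n40], -20, tolerance = 1e-10)
  # neighbour 10 mm away: Gaussian falloff exp(-100 / (2 * 64))
  nb <- which(layout$x == layout$x[i] + 10 & layout$y == layout$y[i])
  expect_equal(out[nb, n40], -20 * exp(-100 / 128), tolerance = 1e-10)
  # far corner electrode (weight below cutoff): untouched
  far <- which.max((layout$x - layout$x[i])^2 + (layout$y - layout$y[i])^2)
  expect_identical(out[far, ], rep(0, 3000))
})

test_that("ERS burst occupies its configured window and band", {
  cfg <- simConfig(nSets = 1, erdAttenuation = 0,
                   erpComponents = within(defaultErpComponents(),
                                          amplitude_uv <- 0),
                   seed = 2)
  layout <- gridLayout(cfg)
  ev <- data.frame(onset_ms = 2000, duration_ms = 300, finger = 3,
                   hand = "CL", task = "s")
  sig <- matrix(0, nrow(layout), 3000)
  set.seed(9)
  out <- injectResponses(sig, ev, cfg, layout)
  burst <- out$signal[match(cfg@fingerSites[3], layout$name), ]
  on <- round(2030 / 1000 * cfg@fs) + 1L     # onset + 30 ms
  len <- round(0.150 * cfg@fs)
  expect_true(all(burst[seq_len(on - 1)] == 0))
  expect_true(all(burst[(on + len):3000] == 0))
  seg <- burst[on:(on + len - 1)]
  # RMS ~ 5 uV (Hann ramps shave a little energy)
  expect_gt(sqrt(mean(seg^2)), 3.5)
  expect_lt(sqrt(mean(seg^2)), 5.5)
  tr <- out$truth$events
  expect_equal(tr$ers_start_ms[1], 30)
  expect_equal(tr$ers_end_ms[1], 180)
  # spectral content confined to 65-115 Hz (up to ramp leakage)
  f <- stats::fft(seg)
  fHz <- (seq_along(seg) - 1) * cfg@fs / length(seg)
  inband <- fHz >= 60 & fHz <= 120 | fHz >= cfg@fs - 120 & fHz <= cfg@fs - 60
  expect_gt(sum(Mod(f[inband])^2) / sum(Mod(f)^2), 0.95)
})

test_that("ERD attenuates ongoing band content in its window", {
  cfg <- simConfig(nSets = 1, ersAmpUv = 0,
                   erpComponents = within(defaultErpComponents(),
                                          amplitude_uv <- 0),
                   seed = 2)
  layout <- gridLayout(cfg)
  ev <- data.frame(onset_ms = 2000, duration_ms = 300, finger = 2,
                   hand = "CL", task = "s")
  set.seed(10)
  sig <- backgroundNoise(cfg, nrow(layout), 3000)
  out <- injectResponses(sig, ev, cfg, layout)$signal
  i <- match(cfg@fingerSites[2], layout$name)
  band <- function(x) {
    f <- stats::fft(x)
    fHz <- (seq_along(x) - 1) * cfg@fs / length(x)
    fHz <- pmin(fHz, cfg@fs - fHz)
    f[!(fHz >= 8 & fHz <= 30)] <- 0
    Re(stats::fft(f, inverse = TRUE)) / length(x)
  }
  mid <- round((2000 + 300) / 1000 * cfg@fs) + (1:100)  # inside 150-600 ms
  before <- band(sig[i, ])[mid]
  after <- band(out[i, ])[mid]
  # alpha/beta power drops by about (1 - 0.5)^2 at the site
  expect_lt(mean(after^2) / mean(before^2), 0.6)
  # outside the ERD window the signal is untouched
  pre <- 1:900
  expect_equal(out[i, pre], sig[i, pre], tolerance = 1e-12)
})

test_that("ipsilateral events get no response unless enabled", {
  cfg <- simConfig(nSets = 1, seed = 2)
  layout <- gridLayout(cfg)
  ev <- data.frame(onset_ms = 2000, duration_ms = 300, finger = 1,
                   hand = "IL", task = "s")
  sig <- matrix(0, nrow(layout), 3000)
  set.seed(3)
  out <- injectResponses(sig, ev, cfg, layout)
  expect_identical(out$signal, sig)
  cfg2 <- simConfig(nSets = 1, ilResponse = TRUE, seed = 2)
  set.seed(3)
  out2 <- injectResponses(sig, ev, cfg2, layout)
  expect_gt(max(abs(out2$signal)), 0)
})

test_that("truth manifest names the correct sites and coordinates", {
  ses <- smallSession()
  sites <- ses$truth$sites
  expect_identical(sites$finger, 1:5)
  expect_identical(sites$name, ses$cfg@fingerSites)
  pos <- ses$layout[match(sites$name, ses$layout$name), c("x", "y", "z")]
  expect_equal(unname(as.matrix(sites[, c("x", "y", "z")])),
               unname(as.matrix(pos)))
})

test_that("default finger sites are five consecutive mid-grid contacts", {
  cfg <- simConfig()
  expect_identical(cfg@fingerSites, sprintf("e%02d", 26:30))
  lay <- gridLayout(cfg)
  pos <- lay[match(cfg@fingerSites, lay$name), ]
  expect_equal(length(unique(pos$y)), 1L)            # one row
  expect_equal(diff(pos$x), rep(10, 4))              # consecutive along x
})

test_that("smoothLength returns the least 2-3-5-smooth length", {
  smooth235 <- function(m) {
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    m == 1
  }
  for (n in c(1, 2, 17, 97, 39233, 100001)) {
    m <- vibromap:::smoothLength(n)
    expect_gte(m, n)
    expect_true(smooth235(m))
  }
  # minimality, brute-forced for small n
  allSmooth <- Filter(smooth235, 1:1300)
  for (n in c(7, 11, 121, 243, 1001))
    expect_equal(vibromap:::smoothLength(n), min(allSmooth[allSmooth >= n]))
})

test_that("interictal transients appear at the configured rate", {
  cfg <- simConfig(nSets = 1, interictalRateHz = 0.5, seed = 21)
  set.seed(21)
  sig <- matrix(0, 4, 50000)   # 100 s at 500 Hz -> ~50 spikes expected
  out <- vibromap:::addInterictal(sig, cfg)
  changed <- which(colSums(abs(out)) > 0)
  # allow small gaps: the biphasic shape is zero at its own centre
  runs <- sum(diff(changed) > 5) + 1
  expect_gt(runs, 20)
  expect_lt(runs, 90)
  expect_gte(max(abs(out)), 50 * 0.9)
})
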