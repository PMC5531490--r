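# Photocurrent, I-V, action-spectrum, saturation, adaptation and spike metrics.

test_that("rectangular pulse gives peak == steady and ratio 1", {
  tr <- simulatePhotocurrent(20, 20, lightEpochs = c(50, 350),
                             samplingMs = 0.5)
  m <- photocurrentMetrics(tr)
  expect_equal(m$iPeak, 20, tolerance = 1e-9)
  expect_equal(m$iSs, 20, tolerance = 1e-9)
  expect_equal(m$inactivationRatio, 1, tolerance = 1e-9)
})

test_that("inactivation ratio reflects peak and steady state", {
  tr <- simulatePhotocurrent(40, 10, tauInactMs = 10, tauOffMs = 10,
                             lightEpochs = c(50, 350), samplingMs = 0.1)
  m <- photocurrentMetrics(tr)
  expect_equal(m$iPeak, 40, tolerance = 1e-3)
  expect_equal(m$iSs, 10, tolerance = 1e-3)
  expect_equal(m$inactivationRatio, 0.25, tolerance = 1e-2)
})

test_that("off-kinetics near 10 ms are recovered within 5% at 1% noise", {
  tr <- simulatePhotocurrent(40, 10, tauInactMs = 20, tauOffMs = 10,
                             lightEpochs = c(50, 350), samplingMs = 0.1,
                             noiseSd = 0.4, seed = 42)
  m <- photocurrentMetrics(tr)
  expect_equal(m$tauOff, 10, tolerance = 0.05)
})

test_that("metrics are invariant to a constant pre-light baseline", {
  tr <- simulatePhotocurrent(40, 10, lightEpochs = c(50, 350),
                             samplingMs = 0.1, noiseSd = 0.2, seed = 5)
  shifted <- tr
  shifted@current <- tr@current + 13.7
  m0 <- photocurrentMetrics(tr); m1 <- photocurrentMetrics(shifted)
  expect_equal(m1$iPeak, m0$iPeak, tolerance = 1e-3)
  expect_equal(m1$iSs, m0$iSs, tolerance = 1e-3)
  expect_equal(m1$tauOff, m0$tauOff, tolerance = 1e-3)
})

test_that("photocurrent metric preconditions are enforced", {
  noLight <- simulatePhotocurrent(20, 20,
                                  lightEpochs = matrix(numeric(0), ncol = 2),
                                  tMaxMs = 100)
  expect_error(photocurrentMetrics(noLight), "no light epoch")
  short <- simulatePhotocurrent(20, 20, lightEpochs = c(50, 51),
                                samplingMs = 0.5)
  expect_error(photocurrentMetrics(short), "5 samples")
})

test_that("I-V fit equals the closed-form OLS solution", {
  v <- c(-60, -40, -20, 0, 20, 40)
  i <- 0.5 * v + 30
  # a perfect line triggers summary.lm's note about exact fits
  f <- suppressWarnings(ivFit(v, i))
  expect_equal(f$slope, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 30, tolerance = 1e-12)
  expect_equal(f$rSquared, 1)
  expect_false(f$voltageInsensitive)

  # oracle check against the closed form on random inputs
  set.seed(3)
  for (r in 1:5) {
    vv <- sort(rnorm(6, sd = 40)); ii <- rnorm(6, sd = 10)
    f2 <- ivFit(vv, ii)
    slopeOracle <- sum((vv - mean(vv)) * (ii - mean(ii))) /
      sum((vv - mean(vv))^2)
    expect_equal(f2$slope, slopeOracle, tolerance = 1e-10)
  }
})

test_that("flat I-V relations are flagged voltage-insensitive", {
  v <- seq(-70, 50, 20)
  set.seed(4)
  f <- ivFit(v, rnorm(length(v), mean = 25, sd = 0.1))
  expect_true(f$voltageInsensitive)
  expect_lt(abs(f$slope), 0.02)
})

test_that("noisy I-V slope is recovered within 3 standard errors", {
  v <- seq(-60, 40, 10)
  set.seed(6)
  i <- 0.3 * v + 20 + rnorm(length(v), sd = 2)
  f <- ivFit(v, i)
  expect_lt(abs(f$slope - 0.3), 3 * f$slopeSe)
  expect_error(ivFit(c(0, 10), c(1, 2)), "3 voltage")
  expect_error(ivFit(c(0, 10, 10), c(1, 2, 3)), "distinct")
})

test_that("action-spectrum peaks interpolate between grid points", {
  wl <- seq(400, 650, 10)
  kr2 <- actionSpectrumPeak(wl, exp(-(wl - 520)^2 / (2 * 40^2)))
  sr <- actionSpectrumPeak(wl, exp(-(wl - 550)^2 / (2 * 42^2)))
  expect_equal(kr2$peakNm, 520, tolerance = 5 / 520)
  expect_equal(sr$peakNm, 550, tolerance = 5 / 550)
  expect_equal(max(kr2$normalizedCurrent), 1)
  # off-grid true maximum still recovered by the parabola
  off <- actionSpectrumPeak(wl, exp(-(wl - 523)^2 / (2 * 40^2)))
  expect_equal(off$peakNm, 523, tolerance = 2 / 523)
})

test_that("edge maxima are reported with a warning", {
  wl <- seq(400, 650, 10)
  expect_warning(asp <- actionSpectrumPeak(wl, seq_along(wl)), "edge")
  expect_true(asp$edgePeak)
  expect_equal(asp$peakNm, 650)
})

test_that("saturation hyperbola parameters are recovered", {
  P <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2)
  f <- saturationFit(P, 30 * P / (P + 0.2))
  expect_equal(f$iMax, 30, tolerance = 1e-3)
  expect_equal(f$pHalf, 0.2, tolerance = 1e-3)
  # half-saturation identity of the fitted curve
  expect_equal(f$iMax * f$pHalf / (f$pHalf + f$pHalf), f$iMax / 2)

  # 5% noise, fixed seed: within 10%
  set.seed(1)
  f2 <- saturationFit(P, 30 * P / (P + 0.2) + rnorm(length(P), sd = 0.05 * 30))
  expect_equal(f2$iMax, 30, tolerance = 0.10)
  expect_equal(f2$pHalf, 0.2, tolerance = 0.10)
})

test_that("pulse-train adaptation ratio tracks per-pulse peaks", {
  onsets <- seq(100, 2600, by = 500)
  epochs <- cbind(onsets, onsets + 3)
  # identical pulses
  tr <- simulatePhotocurrent(20, 20, lightEpochs = epochs, samplingMs = 0.5,
                             tauOffMs = 10)
  pa <- pulseAdaptation(tr, onsets)
  expect_equal(pa$adaptationRatio, 1, tolerance = 1e-6)
  # geometric decay of the peak by 0.9 across 6 pulses
  peaks <- 20 * 0.9^(0:5)
  tr2 <- simulatePhotocurrent(peaks, 0, tauInactMs = 5, tauOffMs = 10,
                              lightEpochs = epochs, samplingMs = 0.5)
  pa2 <- pulseAdaptation(tr2, onsets)
  expect_equal(pa2$adaptationRatio, 0.9^5, tolerance = 1e-3)
  # pulses below trace resolution are rejected
  expect_error(pulseAdaptation(tr, c(100, 100.1)), "resolution")
})

test_that("spike detection and silencing comparison behave by construction", {
  tt <- seq(0, 500, by = 0.1)
  spikeAt <- function(times) {
    v <- rep(-65, length(tt))
    for (s in times) v <- v + 85 * exp(-(tt - s)^2 / (2 * 0.5^2))
    v
  }
  unlit <- spikeMetrics(tt, spikeAt(c(50, 100, 150, 200, 250)))
  expect_identical(unlit$nSpikes, 5L)
  expect_equal(unlit$latencyFirstSpike, 50, tolerance = 0.05)

  # identical traces: T = 0, delta n = 0
  same <- silencingCompare(unlit, unlit)
  expect_identical(same$latencyShiftT, 0)
  expect_identical(same$deltaNSpikes, 0L)

  # first spike delayed by 120 ms and two spikes suppressed under light
  lit <- spikeMetrics(tt, spikeAt(c(170, 220, 270)))
  cmp <- silencingCompare(lit, unlit)
  expect_equal(cmp$latencyShiftT, 120, tolerance = 0.05)
  expect_identical(cmp$deltaNSpikes, -2L)

  # amplitude scaling above the threshold margin does not change the count
  v <- spikeAt(c(50, 100, 150, 200, 250))
  scaled <- -65 + 2.5 * (v + 65)
  expect_identical(spikeMetrics(tt, scaled)$nSpikes, 5L)
})
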