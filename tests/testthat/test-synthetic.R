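# Synthetic-data generators: closed-form kinetics, conservation, determinism.

test_that("Bateman solution matches single- and two-step closed forms", {
  # single intermediate at rate 1000/s: pure exponential decay
  tt <- c(1e-6, 1e-3)
  conc <- batemanConcentrations(1000, tt, excitedFraction = 0.1)
  expect_equal(unname(conc[2, 1] / conc[1, 1]), exp(-1) / exp(-1e-3),
               tolerance = 1e-12)

  # two-step chain: c2(t) = f k1/(k1-k2) (e^{-k2 t} - e^{-k1 t})
  k1 <- 100; k2 <- 10; f <- 0.1; t0 <- 0.01
  expected <- f * k1 / (k1 - k2) * (exp(-k2 * t0) - exp(-k1 * t0))
  conc2 <- batemanConcentrations(c(k1, k2), t0, excitedFraction = f)
  expect_equal(unname(conc2[1, 2]), expected, tolerance = 1e-12)
})

test_that("simulated surface reproduces the chain kinetics at a grid point", {
  k1 <- 100; k2 <- 10; f <- 0.1; t0 <- 0.01
  tt <- c(1e-4, 1e-3, t0, 0.1)
  surf <- simulatePhotocycle(isolatedChainModel(k1, k2, f), times = tt,
                             wavelengths = seq(360, 710, 10))
  # at 400 nm only intermediate 2 absorbs (dark band is at 700 nm)
  expected <- f * k1 / (k1 - k2) * (exp(-k2 * t0) - exp(-k1 * t0))
  got <- deltaA(surf)[match(400, wavelengths(surf)), match(t0, timePoints(surf))]
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("single-exponential surface decays by e^-1 over one lifetime", {
  surf <- simulatePhotocycle(oneStepModel(1000), times = c(1e-9, 1e-3),
                             wavelengths = seq(360, 710, 10))
  i410 <- match(410, wavelengths(surf))
  expect_equal(deltaA(surf)[i410, 2] / deltaA(surf)[i410, 1], exp(-1),
               tolerance = 1e-3)
})

test_that("zero excited fraction yields an identically zero surface", {
  surf <- simulatePhotocycle(oneStepModel(f = 0))
  expect_true(all(deltaA(surf) == 0))
})

test_that("concentrations conserve mass and the surface fully recovers", {
  m <- kr2PhotocycleModel()
  tt <- defaultTimeGrid()
  conc <- batemanConcentrations(rateConstants(m), tt, excitedFraction(m))
  expect_true(all(abs(rowSums(conc) - excitedFraction(m)) < 1e-10))
  surf <- simulatePhotocycle(m, times = c(tt, 1e4))
  expect_lt(max(abs(deltaA(surf)[, ncol(deltaA(surf))])), 1e-12)
})

test_that("duplicate or invalid rates are rejected with guidance", {
  expect_error(batemanConcentrations(c(10, 10), 1), "perturb")
  expect_error(batemanConcentrations(c(10, -1), 1), "> 0")
  expect_error(simulatePhotocycle(oneStepModel(), times = c(-1, 1)),
               "positive")
})

test_that("photocurrent generator follows the peak/steady/off model", {
  # rectangular pulse when peak == steady
  tr <- simulatePhotocurrent(20, 20, lightEpochs = c(10, 110),
                             samplingMs = 0.5)
  lit <- tr@time >= 10 & tr@time < 110
  expect_true(all(abs(tr@current[lit] - 20) < 1e-12))
  expect_true(all(abs(tr@current[tr@time < 10]) < 1e-12))

  # light-off relaxation: e^-1 drop one tau_off after light-off
  tr2 <- simulatePhotocurrent(40, 10, tauInactMs = 20, tauOffMs = 10,
                              lightEpochs = c(0, 300), samplingMs = 0.1)
  at <- function(t) tr2@current[which.min(abs(tr2@time - t))]
  expect_equal(at(310) / at(300), exp(-1), tolerance = 1e-6)

  # no light epochs: zero-mean noise only
  tr3 <- simulatePhotocurrent(20, 20, lightEpochs = matrix(numeric(0), ncol = 2),
                              noiseSd = 1, seed = 3, tMaxMs = 500)
  expect_lt(abs(mean(tr3@current)), 5 * 1 / sqrt(length(tr3@current)))

  expect_error(simulatePhotocurrent(20, 20, tauOffMs = -1,
                                    lightEpochs = c(0, 10)), "positive")
  expect_error(simulatePhotocurrent(10, 20, lightEpochs = c(0, 10)),
               "peak >= steady")
})

test_that("pump-trace generator matches mode arithmetic", {
  # h_export, 0.002 pH/s over 150 s -> net -0.3
  tr <- simulatePumpTrace("h_export", ratePHPerS = 0.002, noiseSd = 0)
  inWin <- tr@time >= 0 & tr@time <= 150
  expect_equal(tr@pH[max(which(inWin))] - tr@pH[min(which(inWin))], -0.3,
               tolerance = 1e-9)
  # plateaus outside the window
  expect_equal(diff(range(tr@pH[tr@time > 150])), 0, tolerance = 1e-12)

  # none: |delta pH| below 3x noise
  tr0 <- simulatePumpTrace("none", noiseSd = 0.002, seed = 4)
  expect_lt(abs(mean(tail(tr0@pH, 10)) - mean(head(tr0@pH, 10))), 3 * 0.002)

  # na_export CCCP enhancement: slope ratio equals cccpFactor
  s <- function(cccp) {
    t <- simulatePumpTrace("na_export", cccpFactor = 2, cccpPresent = cccp,
                           noiseSd = 0)
    sel <- t@time >= 0 & t@time <= 150
    unname(coef(lm(t@pH[sel] ~ t@time[sel]))[2])
  }
  expect_equal(s(TRUE) / s(FALSE), 2, tolerance = 1e-9)
})

test_that("alignment simulator obeys the Poisson substitution model", {
  # zero-length branches: all sequences identical
  tr <- fourTaxonTree(0, 0)
  aln <- simulateAlignment(tr, 100, seed = 1)
  seqs <- as.character(alignment(aln))
  expect_true(all(seqs == seqs[1]))

  # two taxa, total path d = 0.1: E[p] = (19/20)(1 - e^{-20 d/19}),
  # checked within 3 binomial standard errors at 50k sites
  d <- 0.1; n <- 50000
  two <- ape::read.tree(text = "(A:0.05,B:0.05);")
  p <- pDistance(simulateAlignment(two, n, seed = 2))["A", "B"]
  pExp <- (19 / 20) * (1 - exp(-20 * d / 19))
  se <- sqrt(pExp * (1 - pExp) / n)
  expect_lt(abs(p - pExp), 3 * se)
})

test_that("all generators are bit-identical under a fixed seed", {
  m <- srnarPhotocycleModel()
  expect_identical(deltaA(simulatePhotocycle(m, noiseSd = 1e-4, seed = 9)),
                   deltaA(simulatePhotocycle(m, noiseSd = 1e-4, seed = 9)))
  expect_identical(
    simulatePhotocurrent(40, 10, lightEpochs = c(0, 100), noiseSd = 1, seed = 9)@current,
    simulatePhotocurrent(40, 10, lightEpochs = c(0, 100), noiseSd = 1, seed = 9)@current)
  expect_identical(simulatePumpTrace("h_export", seed = 9)@pH,
                   simulatePumpTrace("h_export", seed = 9)@pH)
  tr <- fourTaxonTree()
  expect_identical(as.character(alignment(simulateAlignment(tr, 200, seed = 9))),
                   as.character(alignment(simulateAlignment(tr, 200, seed = 9))))
})

test_that("model and surface validity rules are enforced", {
  expect_error(photocycleModel("A", 10, c(200, 30, 1), c(525, 40, 1)),
               "300-800")
  expect_error(photocycleModel("A", c(10, 20), c(500, 30, 1), c(525, 40, 1)),
               "number of rate constants")
  expect_error(photocycleModel("A", 10, c(500, 30, 1), c(525, 40, 1),
                               excitedFraction = 1.5), "excitedFraction")
})
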