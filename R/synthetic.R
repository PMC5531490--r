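#' Construct a sequential photocycle model
#'
#' @param intermediateNames character labels in kinetic order.
#' @param rateConstants first-order decay rates (s^-1), one per intermediate;
#'   the last step returns to the dark state. Must be pairwise distinct
#'   (perturb duplicates by ~0.1\%).
#' @param intermediateSpectra n x 3 matrix (or something coercible) of
#'   \code{center} nm, \code{width} nm, \code{amplitude} per intermediate.
#' @param darkSpectrum length-3 \code{c(center, width, amplitude)} of the
#'   dark state.
#' @param excitedFraction photolyzed fraction in [0, 1] (default 0.1; the
#'   flash-photolysis yield is instrument dependent and not identifiable from
#'   the surface shape).
#' @return A validated [PhotocycleModel-class].
#' @examples
#' m <- photocycleModel("M", 1000, c(410, 35, 1), c(525, 40, 1))
#' m
#' @export
photocycleModel <- function(intermediateNames, rateConstants,
                            intermediateSpectra, darkSpectrum,
                            excitedFraction = 0.1) {
  sp <- if (is.null(dim(intermediateSpectra)))
    matrix(as.numeric(intermediateSpectra), ncol = 3L, byrow = TRUE)
  else as.matrix(intermediateSpectra)
  dimnames(sp) <- list(intermediateNames, c("center", "width", "amplitude"))
  new("PhotocycleModel",
      intermediateNames = as.character(intermediateNames),
      rateConstants = as.numeric(rateConstants),
      intermediateSpectra = sp,
      darkSpectrum = as.numeric(darkSpectrum),
      excitedFraction = excitedFraction)
}

#' Default log-spaced delay grid
#'
#' 200 log-spaced delays from 1 us to 10 s, giving at least 10 points per
#' decade across the lifetimes encountered in NaR photocycles (tens of us to
#' seconds).
#'
#' @param n number of points.
#' @param from,to span in seconds.
#' @return numeric vector of delay times (s).
#' @export
defaultTimeGrid <- function(n = 200L, from = 1e-6, to = 10) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Default probe-wavelength grid
#'
#' 360 to 710 nm in 10-nm steps (36 points), the standard multichannel
#' flash-photolysis acquisition grid.
#'
#' @return numeric vector of wavelengths (nm).
#' @export
defaultWavelengthGrid <- function() seq(360, 710, by = 10)

# Gaussian absorption band evaluated on a wavelength grid.
gaussianBand <- function(wl, band) {
  band[3L] * exp(-((wl - band[1L])^2) / (2 * band[2L]^2))
}

#' Intermediate concentrations of a sequential first-order chain
#'
#' Closed-form (Bateman) solution of the linear kinetics
#' \eqn{X_1 \to X_2 \to \dots \to dark} with distinct rate constants and
#' initial condition \eqn{c_1(0) = f}, all others zero:
#' \deqn{c_i(t) = f \prod_{j<i} k_j \sum_{j \le i}
#'   \frac{e^{-k_j t}}{\prod_{l \le i, l \ne j}(k_l - k_j)}.}
#'
#' @param rateConstants distinct positive rates (s^-1).
#' @param times evaluation times (s).
#' @param excitedFraction initial population of the first intermediate.
#' @return matrix of concentrations, rows = times, one column per
#'   intermediate, plus a final column \code{dark_recovered} so that each row
#'   sums to \code{excitedFraction} exactly (mass conservation).
#' @export
batemanConcentrations <- function(rateConstants, times, excitedFraction = 1) {
  k <- as.numeric(rateConstants)
  if (any(k <= 0)) stop("rate constants must be > 0")
  if (anyDuplicated(k))
    stop("duplicate rate constants: the confluent Bateman form is not ",
         "implemented; perturb equal rates by ~0.1%")
  n <- length(k)
  conc <- matrix(0, nrow = length(times), ncol = n)
  E <- exp(-outer(times, k))               # times x n
  for (i in seq_len(n)) {
    pref <- if (i > 1L) prod(k[seq_len(i - 1L)]) else 1
    coef <- vapply(seq_len(i), function(j) {
      denom <- prod(k[setdiff(seq_len(i), j)] - k[j])
      1 / denom
    }, numeric(1))
    conc[, i] <- excitedFraction * pref * (E[, seq_len(i), drop = FALSE] %*% coef)
  }
  dark <- excitedFraction - rowSums(conc)
  cbind(conc, dark_recovered = dark)
}

#' Simulate a flash-photolysis transient-absorption surface
#'
#' Solves the sequential photocycle kinetics in closed form and composes the
#' absorbance-change surface
#' \deqn{\Delta A(\lambda, t) = \sum_i c_i(t)\,[\varepsilon_i(\lambda) -
#'   \varepsilon_{dark}(\lambda)]}
#' which includes the dark-state bleach through the depleted ground-state
#' population (the photolyzed molecules currently in intermediate i no longer
#' absorb as dark pigment). Optional i.i.d. Gaussian noise, homoscedastic
#' across wavelengths and delays, emulates shot-noise-dominated detection.
#'
#' @param model a [PhotocycleModel-class].
#' @param times delay grid (s), default [defaultTimeGrid()].
#' @param wavelengths probe grid (nm), default [defaultWavelengthGrid()].
#' @param noiseSd Gaussian noise sd in absorbance units (0 = noiseless).
#' @param seed integer seed for the noise (ignored when \code{noiseSd == 0}).
#' @return A [TransientAbsorptionSurface-class].
#' @examples
#' surf <- simulatePhotocycle(kr2PhotocycleModel())
#' surf
#' @export
simulatePhotocycle <- function(model, times = defaultTimeGrid(),
                               wavelengths = defaultWavelengthGrid(),
                               noiseSd = 0, seed = NULL) {
  stopifnot(is(model, "PhotocycleModel"))
  validObject(model)
  if (any(times <= 0)) stop("all delay times must be positive")
  conc <- batemanConcentrations(model@rateConstants, times,
                                model@excitedFraction)
  nInt <- length(model@rateConstants)
  epsDark <- gaussianBand(wavelengths, model@darkSpectrum)
  dA <- matrix(0, nrow = length(wavelengths), ncol = length(times))
  for (i in seq_len(nInt)) {
    diffSpec <- gaussianBand(wavelengths, model@intermediateSpectra[i, ]) - epsDark
    dA <- dA + outer(diffSpec, conc[, i])
  }
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    dA <- dA + matrix(stats::rnorm(length(dA), sd = noiseSd), nrow = nrow(dA))
  }
  new("TransientAbsorptionSurface",
      wavelengths = as.numeric(wavelengths), times = as.numeric(times),
      deltaA = dA, noiseSd = noiseSd,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Simulate a whole-cell pump photocurrent trace
#'
#' During each light epoch the current follows
#' \eqn{I(t) = I_{ss} + (I_{peak} - I_{ss}) e^{-(t - t_{on})/\tau_{inact}}}
#' (transient peak inactivating to a steady state); after light-off it
#' relaxes mono-exponentially to baseline with \code{tauOffMs}. Outward pump
#' current is positive. Each epoch contributes independently (its off-tail
#' extends to the end of the trace), so closely spaced pulses superpose.
#'
#' @param peakPa,steadyPa peak and steady-state amplitudes (pA); vectors are
#'   recycled across epochs, which allows adaptation of peak amplitude over a
#'   pulse train. Requires \code{peak >= steady >= 0}.
#' @param tauInactMs,tauOffMs inactivation and off-relaxation time constants
#'   (ms), both > 0.
#' @param lightEpochs two-column matrix (or length-2 vector) of (on, off) ms.
#'   May be empty (zero-row matrix) for a light-free control trace.
#' @param samplingMs sampling interval (ms).
#' @param tMaxMs trace duration; default covers the last epoch plus 10 off
#'   time constants.
#' @param noiseSd Gaussian current noise sd (pA).
#' @param seed integer RNG seed.
#' @param holdingPotential,irradiance recording metadata.
#' @return A [PhotocurrentTrace-class].
#' @export
simulatePhotocurrent <- function(peakPa, steadyPa, tauInactMs = 20,
                                 tauOffMs = 10, lightEpochs,
                                 samplingMs = 0.1, tMaxMs = NULL,
                                 noiseSd = 0, seed = NULL,
                                 holdingPotential = 0, irradiance = 0.8) {
  if (tauInactMs <= 0 || tauOffMs <= 0)
    stop("time constants must be positive")
  if (is.vector(lightEpochs) && length(lightEpochs) == 2L)
    lightEpochs <- matrix(lightEpochs, ncol = 2L)
  if (is.null(lightEpochs)) lightEpochs <- matrix(numeric(0), ncol = 2L)
  nEp <- nrow(lightEpochs)
  peakPa <- rep_len(peakPa, max(nEp, 1L))
  steadyPa <- rep_len(steadyPa, max(nEp, 1L))
  if (any(peakPa < steadyPa) || any(steadyPa < 0))
    stop("pump currents require peak >= steady >= 0 (outward positive)")
  if (is.null(tMaxMs))
    tMaxMs <- if (nEp) max(lightEpochs[, 2L]) + 10 * tauOffMs else 100
  time <- seq(0, tMaxMs, by = samplingMs)
  current <- numeric(length(time))
  for (e in seq_len(nEp)) {
    on <- lightEpochs[e, 1L]; off <- lightEpochs[e, 2L]
    lit <- time >= on & time < off
    current[lit] <- current[lit] + steadyPa[e] +
      (peakPa[e] - steadyPa[e]) * exp(-(time[lit] - on) / tauInactMs)
    iOff <- steadyPa[e] + (peakPa[e] - steadyPa[e]) * exp(-(off - on) / tauInactMs)
    post <- time >= off
    current[post] <- current[post] + iOff * exp(-(time[post] - off) / tauOffMs)
  }
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    current <- current + stats::rnorm(length(current), sd = noiseSd)
  }
  new("PhotocurrentTrace", time = time, current = current,
      lightEpochs = lightEpochs, holdingPotential = holdingPotential,
      irradiance = irradiance)
}

#' Simulate a pH-electrode pump-assay trace
#'
#' Emulates the suspension-pH read-out of light-driven transport:
#' \code{h_export} acidifies the medium during illumination (slope
#' suppressed by \code{cccpFactor} when the protonophore CCCP is present);
#' \code{na_export} alkalizes it via secondary proton uptake after Na+
#' extrusion (slope enhanced by \code{cccpFactor} with CCCP); \code{none}
#' leaves only noise. Outside the illumination window the trace plateaus.
#'
#' @param mode one of \code{"h_export"}, \code{"na_export"}, \code{"none"}.
#' @param ratePHPerS light-on pH slope magnitude (pH/s), default 0.002.
#' @param cccpFactor multiplicative CCCP modulation (> 1), default 2.
#' @param cccpPresent whether CCCP is in the cuvette.
#' @param window illumination window \code{c(start, end)} in s, default
#'   \code{c(0, 150)}.
#' @param time sampling grid (s); starts before the window so that dark
#'   baseline drift can be estimated.
#' @param noiseSd electrode noise sd (pH units).
#' @param pH0 starting pH.
#' @param naclPresent metadata flag (Na+ present in the medium).
#' @param seed integer RNG seed.
#' @return A [PumpTrace-class].
#' @export
simulatePumpTrace <- function(mode = c("none", "h_export", "na_export"),
                              ratePHPerS = 0.002, cccpFactor = 2,
                              cccpPresent = FALSE, window = c(0, 150),
                              time = seq(-60, 300, by = 0.5),
                              noiseSd = 0.002, pH0 = 7, naclPresent = TRUE,
                              seed = NULL) {
  mode <- match.arg(mode)
  slope <- switch(mode,
    none = 0,
    h_export = -ratePHPerS / (if (cccpPresent) cccpFactor else 1),
    na_export = ratePHPerS * (if (cccpPresent) cccpFactor else 1))
  litTime <- pmin(pmax(time, window[1L]), window[2L]) - window[1L]
  pH <- pH0 + slope * litTime
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    pH <- pH + stats::rnorm(length(pH), sd = noiseSd)
  }
  new("PumpTrace", time = as.numeric(time), pH = pH,
      illuminationWindow = as.numeric(window), cccpPresent = cccpPresent,
      naclPresent = naclPresent)
}

#' Simulate an amino-acid alignment on a known tree
#'
#' Sites evolve independently along the tree under the uniform-rate Poisson
#' model: substitution events occur as a Poisson process with intensity equal
#' to the branch length (substitutions/site), and each event replaces the
#' residue by one of the 19 alternatives with equal probability. For two
#' sequences separated by total path length d the expected proportion of
#' differing sites is \eqn{p = (19/20)(1 - e^{-20d/19})} — the relationship
#' inverted by the Poisson distance correction.
#'
#' @param trueTree a rooted or unrooted \code{phylo} with branch lengths in
#'   substitutions/site.
#' @param nSites alignment length.
#' @param seed integer RNG seed (fixed seed gives a bit-identical alignment).
#' @return A [SyntheticAlignment-class].
#' @export
simulateAlignment <- function(trueTree, nSites, seed = NULL) {
  stopifnot(inherits(trueTree, "phylo"), nSites >= 1)
  if (is.null(trueTree$edge.length))
    stop("trueTree must have branch lengths")
  if (!is.null(seed)) set.seed(as.integer(seed))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  nTip <- length(trueTree$tip.label)
  tr <- stats::reorder(trueTree)                 # preorder: parents first
  root <- nTip + 1L
  seqs <- vector("list", max(tr$edge))
  seqs[[root]] <- sample(aa, nSites, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    s <- seqs[[parent]]
    nev <- stats::rpois(nSites, tr$edge.length[e])
    maxEv <- if (length(nev)) max(nev) else 0L
    for (round in seq_len(maxEv)) {
      hit <- which(nev >= round)
      if (!length(hit)) break
      cur <- s[hit]
      # draw uniformly among the 19 alternatives to the current residue
      repl <- aa[(match(cur, aa) - 1L +
                  sample.int(19L, length(hit), replace = TRUE)) %% 20L + 1L]
      s[hit] <- repl
    }
    seqs[[child]] <- s
  }
  tipSeqs <- vapply(seq_len(nTip), function(i) paste(seqs[[i]], collapse = ""),
                    character(1))
  names(tipSeqs) <- trueTree$tip.label
  new("SyntheticAlignment",
      alignment = Biostrings::AAStringSet(tipSeqs), trueTree = trueTree,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
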