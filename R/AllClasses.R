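#' @import methods
NULL

setOldClass("phylo")

#' Sequential photocycle model
#'
#' Ground-truth description of a microbial-rhodopsin photocycle as a linear,
#' irreversible chain of spectrally distinct intermediates (e.g. K -> L/M ->
#' O1 -> O2 -> dark). Each step is first order; the reciprocal of each rate
#' constant is the lifetime of the corresponding intermediate. Absorption
#' bands are parameterized as Gaussians in wavelength.
#'
#' @slot intermediateNames ordered labels of the intermediates.
#' @slot rateConstants per-step first-order decay rates (s^-1); the last rate
#'   returns the chain to the dark state, so there are exactly as many rates
#'   as intermediates.
#' @slot intermediateSpectra numeric matrix, one row per intermediate, with
#'   columns \code{center} (nm), \code{width} (Gaussian sd, nm) and
#'   \code{amplitude} (relative extinction).
#' @slot darkSpectrum length-3 numeric \code{c(center, width, amplitude)} for
#'   the unphotolyzed pigment.
#' @slot excitedFraction fraction of the dark population photolyzed by the
#'   flash, in [0, 1]. Zero is allowed as a null control and yields an
#'   identically-zero surface.
#'
#' @seealso [photocycleModel()], [simulatePhotocycle()]
#' @export
setClass("PhotocycleModel",
  representation(
    intermediateNames  = "character",
    rateConstants      = "numeric",
    intermediateSpectra = "matrix",
    darkSpectrum       = "numeric",
    excitedFraction    = "numeric"
  )
)

setValidity("PhotocycleModel", function(object) {
  msg <- character()
  n <- length(object@intermediateNames)
  if (n < 1L) msg <- c(msg, "at least one intermediate is required")
  if (length(object@rateConstants) != n)
    msg <- c(msg, "number of rate constants must equal number of intermediates")
  if (any(!is.finite(object@rateConstants)) || any(object@rateConstants <= 0))
    msg <- c(msg, "all rate constants must be finite and > 0")
  sp <- object@intermediateSpectra
  if (nrow(sp) != n || ncol(sp) != 3L)
    msg <- c(msg, "intermediateSpectra must be an n x 3 (center, width, amplitude) matrix")
  centers <- c(sp[, 1L], object@darkSpectrum[1L])
  if (any(centers < 300 | centers > 800))
    msg <- c(msg, "spectral band centers must lie within 300-800 nm")
  if (length(object@darkSpectrum) != 3L)
    msg <- c(msg, "darkSpectrum must be c(center, width, amplitude)")
  f <- object@excitedFraction
  if (length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    msg <- c(msg, "excitedFraction must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Flash-photolysis transient-absorption surface
#'
#' Absorbance change \eqn{\Delta A(\lambda, t)} measured (or simulated) after
#' pulsed excitation, stored as a wavelength-by-time matrix. The default
#' acquisition grid is 360-710 nm in 10-nm steps with log-spaced delays from
#' 1 us to 10 s.
#'
#' @slot wavelengths probe wavelengths (nm), strictly increasing.
#' @slot times delay times (s), strictly increasing and positive.
#' @slot deltaA numeric matrix of absorbance change, rows = wavelengths,
#'   columns = times.
#' @slot noiseSd standard deviation of the additive Gaussian noise used when
#'   the surface was simulated (0 for noiseless or measured data).
#' @slot seed RNG seed used at simulation time (NA if none).
#'
#' @export
setClass("TransientAbsorptionSurface",
  representation(
    wavelengths = "numeric",
    times       = "numeric",
    deltaA      = "matrix",
    noiseSd     = "numeric",
    seed        = "integer"
  ),
  prototype(noiseSd = 0, seed = NA_integer_)
)

setValidity("TransientAbsorptionSurface", function(object) {
  msg <- character()
  if (nrow(object@deltaA) != length(object@wavelengths))
    msg <- c(msg, "nrow(deltaA) must equal length(wavelengths)")
  if (ncol(object@deltaA) != length(object@times))
    msg <- c(msg, "ncol(deltaA) must equal length(times)")
  if (any(object@times <= 0)) msg <- c(msg, "times must be > 0")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (is.unsorted(object@wavelengths, strictly = TRUE))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Whole-cell photocurrent trace
#'
#' Uniformly sampled current record with one or more illumination epochs.
#' Sign convention: outward pump current is positive; depolarizing inward
#' current is negative. This convention is used throughout the package.
#'
#' @slot time time base (ms), uniform sampling.
#' @slot current measured current (pA).
#' @slot lightEpochs two-column matrix of (on, off) times in ms.
#' @slot holdingPotential holding potential (mV).
#' @slot irradiance light intensity (mW/mm^2).
#'
#' @export
setClass("PhotocurrentTrace",
  representation(
    time             = "numeric",
    current          = "numeric",
    lightEpochs      = "matrix",
    holdingPotential = "numeric",
    irradiance       = "numeric"
  ),
  prototype(holdingPotential = 0, irradiance = 0.8)
)

setValidity("PhotocurrentTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@current))
    msg <- c(msg, "time and current must have equal length")
  if (length(object@time) >= 3L) {
    dt <- diff(object@time)
    if (diff(range(dt)) > 1e-6 * stats::median(dt))
      msg <- c(msg, "sampling must be uniform")
  }
  ep <- object@lightEpochs
  if (nrow(ep) > 0L) {
    if (ncol(ep) != 2L) msg <- c(msg, "lightEpochs must have two columns (on, off)")
    else {
      if (any(ep[, 2L] <= ep[, 1L])) msg <- c(msg, "each epoch must have off > on")
      if (any(ep < min(object@time)) || any(ep > max(object@time)))
        msg <- c(msg, "light epochs must lie within the trace span")
    }
  }
  if (length(msg)) msg else TRUE
})

#' pH-electrode pump-assay trace
#'
#' Suspension pH versus time for a cell-suspension transport assay with a
#' single illumination window (default 0-150 s), recorded with or without the
#' protonophore CCCP and with or without NaCl in the medium.
#'
#' @slot time time (s).
#' @slot pH electrode reading, within 0-14.
#' @slot illuminationWindow numeric \code{c(start, end)} in s.
#' @slot cccpPresent logical flag.
#' @slot naclPresent logical flag.
#'
#' @export
setClass("PumpTrace",
  representation(
    time               = "numeric",
    pH                 = "numeric",
    illuminationWindow = "numeric",
    cccpPresent        = "logical",
    naclPresent        = "logical"
  ),
  prototype(illuminationWindow = c(0, 150), cccpPresent = FALSE,
            naclPresent = TRUE)
)

setValidity("PumpTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@pH))
    msg <- c(msg, "time and pH must have equal length")
  if (any(object@pH < 0 | object@pH > 14)) msg <- c(msg, "pH must lie within 0-14")
  w <- object@illuminationWindow
  if (length(w) != 2L || w[2L] <= w[1L])
    msg <- c(msg, "illuminationWindow must be c(start, end) with end > start")
  if (length(msg)) msg else TRUE
})

#' Result of a global multi-exponential fit
#'
#' Shared time constants with per-wavelength amplitudes (decay-associated
#' spectra, DAS) obtained by variable projection. The fitted model is
#' \deqn{\Delta A(\lambda, t) = \sum_i DAS_i(\lambda) e^{-t/\tau_i} +
#' offset(\lambda).}
#' Components are stored in ascending order of tau.
#'
#' @slot taus fitted time constants (s), strictly ascending.
#' @slot das DAS matrix, rows = wavelengths, one column per component.
#' @slot offsetSpectrum non-decaying baseline per wavelength (all zero when
#'   the offset was not fitted).
#' @slot offsetFitted whether the offset column was part of the design.
#' @slot wavelengths,times grids of the fitted surface.
#' @slot residualMatrix data minus fit, same shape as the input surface.
#' @slot rss summed squared residuals.
#' @slot nParameters total parameter count (taus + DAS + offset entries).
#' @slot bic Bayesian information criterion under i.i.d. Gaussian residuals.
#'
#' @seealso [fitGlobal()], [decayComponents()]
#' @export
setClass("GlobalFitResult",
  representation(
    taus           = "numeric",
    das            = "matrix",
    offsetSpectrum = "numeric",
    offsetFitted   = "logical",
    wavelengths    = "numeric",
    times          = "numeric",
    residualMatrix = "matrix",
    rss            = "numeric",
    nParameters    = "numeric",
    bic            = "numeric"
  )
)

setValidity("GlobalFitResult", function(object) {
  msg <- character()
  if (length(object@taus) != ncol(object@das))
    msg <- c(msg, "one DAS column per component is required")
  if (length(object@taus) > 1L && is.unsorted(object@taus, strictly = TRUE))
    msg <- c(msg, "components must be strictly ordered by ascending tau")
  if (any(object@taus <= 0)) msg <- c(msg, "all taus must be > 0")
  if (nrow(object@das) != length(object@wavelengths))
    msg <- c(msg, "DAS rows must match the wavelength grid")
  if (length(msg)) msg else TRUE
})

#' Photocycle interpretation of a global fit
#'
#' Rule-based labelling of fitted exponential components as photocycle
#' intermediates (K, L/M, O) from their DAS signatures, plus cycle time
#' (sum of taus) and pump turnover (60 / cycle time, per minute).
#'
#' @slot labels one of "K", "L/M", "O", "unassigned" per component.
#' @slot taus component time constants (s), ascending.
#' @slot peakWavelengths positive-lobe DAS peak per component (nm; NA when a
#'   component has no positive lobe).
#' @slot darkLambdaMax dark-state absorption maximum used as reference (nm).
#' @slot schemeString arrow notation of the observed scheme.
#' @slot oDetected whether any red-shifted slow (O) intermediate accumulates.
#' @slot cycleTime photocycle duration (s).
#' @slot turnoverPerMin single-pump turnover (min^-1).
#'
#' @export
setClass("PhotocycleAssignment",
  representation(
    labels          = "character",
    taus            = "numeric",
    peakWavelengths = "numeric",
    darkLambdaMax   = "numeric",
    schemeString    = "character",
    oDetected       = "logical",
    cycleTime       = "numeric",
    turnoverPerMin  = "numeric"
  )
)

setValidity("PhotocycleAssignment", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@taus))
    msg <- c(msg, "labels must cover all components")
  bad <- setdiff(object@labels, c("K", "L/M", "O", "unassigned"))
  if (length(bad)) msg <- c(msg, paste("unknown label:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Alignment simulated on a known tree
#'
#' Amino-acid alignment evolved under the uniform-rate Poisson substitution
#' process, together with the generating topology and branch lengths
#' (substitutions/site) so that downstream tree inference can be scored
#' against truth.
#'
#' @slot alignment \code{AAStringSet} of equal-width sequences.
#' @slot trueTree the generating \code{phylo} tree.
#' @slot seed RNG seed used (NA if none).
#'
#' @export
setClass("SyntheticAlignment",
  representation(
    alignment = "AAStringSet",
    trueTree  = "phylo",
    seed      = "integer"
  ),
  prototype(seed = NA_integer_)
)

setValidity("SyntheticAlignment", function(object) {
  msg <- character()
  w <- Biostrings::width(object@alignment)
  if (length(w) && length(unique(w)) != 1L)
    msg <- c(msg, "all sequences must have the same aligned length")
  nm <- names(object@alignment)
  if (is.null(nm) || anyDuplicated(nm)) msg <- c(msg, "taxa names must be unique")
  if (length(msg)) msg else TRUE
})
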