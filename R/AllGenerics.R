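#' @importClassesFrom Biostrings AAStringSet
NULL

#' Accessors for NaRtools data objects
#'
#' Slot access for the S4 containers. Use these rather than \code{@}.
#'
#' @param x an object of one of the package classes.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("deltaA", function(x) standardGeneric("deltaA"))
#' @rdname accessors
#' @export
setGeneric("rateConstants", function(x) standardGeneric("rateConstants"))
#' @rdname accessors
#' @export
setGeneric("excitedFraction", function(x) standardGeneric("excitedFraction"))
#' @rdname accessors
#' @export
setGeneric("intermediateNames", function(x) standardGeneric("intermediateNames"))
#' @rdname accessors
#' @export
setGeneric("taus", function(x) standardGeneric("taus"))
#' @rdname accessors
#' @export
setGeneric("das", function(x) standardGeneric("das"))
#' @rdname accessors
#' @export
setGeneric("offsetSpectrum", function(x) standardGeneric("offsetSpectrum"))
#' @rdname accessors
#' @export
setGeneric("rss", function(x) standardGeneric("rss"))
#' @rdname accessors
#' @export
setGeneric("bic", function(x) standardGeneric("bic"))
#' @rdname accessors
#' @export
setGeneric("lightEpochs", function(x) standardGeneric("lightEpochs"))
#' @rdname accessors
#' @export
setGeneric("trueTree", function(x) standardGeneric("trueTree"))
#' @rdname accessors
#' @export
setGeneric("alignment", function(x) standardGeneric("alignment"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "TransientAbsorptionSurface", function(x) x@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "GlobalFitResult", function(x) x@wavelengths)
#' @rdname accessors
#' @export
setMethod("timePoints", "TransientAbsorptionSurface", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("timePoints", "GlobalFitResult", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("deltaA", "TransientAbsorptionSurface", function(x) x@deltaA)
#' @rdname accessors
#' @export
setMethod("rateConstants", "PhotocycleModel", function(x) x@rateConstants)
#' @rdname accessors
#' @export
setMethod("excitedFraction", "PhotocycleModel", function(x) x@excitedFraction)
#' @rdname accessors
#' @export
setMethod("intermediateNames", "PhotocycleModel", function(x) x@intermediateNames)
#' @rdname accessors
#' @export
setMethod("taus", "GlobalFitResult", function(x) x@taus)
#' @rdname accessors
#' @export
setMethod("taus", "PhotocycleAssignment", function(x) x@taus)
#' @rdname accessors
#' @export
setMethod("das", "GlobalFitResult", function(x) x@das)
#' @rdname accessors
#' @export
setMethod("offsetSpectrum", "GlobalFitResult", function(x) x@offsetSpectrum)
#' @rdname accessors
#' @export
setMethod("rss", "GlobalFitResult", function(x) x@rss)
#' @rdname accessors
#' @export
setMethod("bic", "GlobalFitResult", function(x) x@bic)
#' @rdname accessors
#' @export
setMethod("lightEpochs", "PhotocurrentTrace", function(x) x@lightEpochs)
#' @rdname accessors
#' @export
setMethod("trueTree", "SyntheticAlignment", function(x) x@trueTree)
#' @rdname accessors
#' @export
setMethod("alignment", "SyntheticAlignment", function(x) x@alignment)

#' Residuals of a global fit
#'
#' @param object a [GlobalFitResult-class].
#' @param ... ignored.
#' @return wavelength-by-time residual matrix (data minus fit).
#' @export
setMethod("residuals", "GlobalFitResult", function(object, ...) object@residualMatrix)

#' Decay components of a global fit
#'
#' @param fit a [GlobalFitResult-class].
#' @return A list with one element per component, each a list with entries
#'   \code{tau} (s) and \code{das} (amplitude per wavelength), in ascending
#'   order of tau.
#' @export
decayComponents <- function(fit) {
  stopifnot(is(fit, "GlobalFitResult"))
  lapply(seq_along(fit@taus), function(i)
    list(tau = fit@taus[i], das = fit@das[, i]))
}

setMethod("show", "PhotocycleModel", function(object) {
  cat("PhotocycleModel with", length(object@intermediateNames),
      "intermediate(s):", paste(object@intermediateNames, collapse = " -> "),
      "-> dark\n")
  cat("  lifetimes (s):",
      paste(signif(1 / object@rateConstants, 4), collapse = ", "), "\n")
  cat("  dark band:", object@darkSpectrum[1L], "nm; excited fraction:",
      object@excitedFraction, "\n")
})

setMethod("show", "TransientAbsorptionSurface", function(object) {
  cat("TransientAbsorptionSurface:", length(object@wavelengths),
      "wavelengths x", length(object@times), "times\n")
  cat(sprintf("  lambda %g-%g nm; t %.3g-%.3g s; noise sd %g\n",
              min(object@wavelengths), max(object@wavelengths),
              min(object@times), max(object@times), object@noiseSd))
})

setMethod("show", "GlobalFitResult", function(object) {
  cat("GlobalFitResult with", length(object@taus), "component(s)\n")
  cat("  tau (s):", paste(signif(object@taus, 5), collapse = ", "), "\n")
  cat(sprintf("  RSS %.4g; BIC %.4g; offset %s\n", object@rss, object@bic,
              if (object@offsetFitted) "fitted" else "absent"))
})

setMethod("show", "PhotocurrentTrace", function(object) {
  cat(sprintf("PhotocurrentTrace: %d samples, %g-%g ms, %d light epoch(s)\n",
              length(object@time), min(object@time), max(object@time),
              nrow(object@lightEpochs)))
  cat(sprintf("  holding %g mV; irradiance %g mW/mm^2\n",
              object@holdingPotential, object@irradiance))
})

setMethod("show", "PumpTrace", function(object) {
  cat(sprintf("PumpTrace: %d samples, %g-%g s; light %g-%g s; CCCP %s; NaCl %s\n",
              length(object@time), min(object@time), max(object@time),
              object@illuminationWindow[1L], object@illuminationWindow[2L],
              object@cccpPresent, object@naclPresent))
})

setMethod("show", "PhotocycleAssignment", function(object) {
  cat("PhotocycleAssignment:", object@schemeString, "\n")
  cat(sprintf("  O detected: %s; cycle time %.4g s; turnover %.4g min^-1\n",
              object@oDetected, object@cycleTime, object@turnoverPerMin))
})

setMethod("show", "SyntheticAlignment", function(object) {
  cat(sprintf("SyntheticAlignment: %d taxa x %d sites\n",
              length(object@alignment),
              if (length(object@alignment)) Biostrings::width(object@alignment)[1L] else 0L))
})
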