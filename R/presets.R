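#' Photocycle model presets for the characterized NaRs
#'
#' Ready-made [PhotocycleModel-class] objects whose lifetimes equal the
#' published flash-photolysis fitting results:
#' \describe{
#'   \item{KR2}{K (26 us) -> L/M (1 ms) -> O1 (7.9 ms) -> O2 (112 ms) -> dark;
#'     dark band at 525 nm.}
#'   \item{FdNaR}{same scheme, slightly slower: 40 us, 1.63 ms, 15 ms, 55 ms.}
#'   \item{SrNaR}{no detectable K or O accumulation; a blue-shifted L/M state
#'     whose decay mirrors dark-state recovery, biexponential with 590 ms and
#'     1540 ms; dark band at 550 nm (30 nm red-shifted vs KR2).}
#' }
#' Band centers and widths are representative of microbial-rhodopsin
#' intermediates (red-shifted K/O near 590-600 nm, blue-shifted M near
#' 400-420 nm); only the lifetimes are constrained by measurement.
#'
#' @param excitedFraction photolyzed fraction (default 0.1).
#' @return A [PhotocycleModel-class].
#' @name photocyclePresets
NULL

#' @rdname photocyclePresets
#' @export
kr2PhotocycleModel <- function(excitedFraction = 0.1) {
  photocycleModel(
    intermediateNames = c("K", "L/M", "O1", "O2"),
    rateConstants = 1 / c(26e-6, 1e-3, 7.9e-3, 112e-3),
    intermediateSpectra = rbind(
      c(600, 42, 1.05),   # K: red-shifted early intermediate
      c(400, 35, 0.90),   # L/M: strongly blue-shifted
      c(590, 45, 1.00),   # O1
      c(595, 45, 0.95)),  # O2
    darkSpectrum = c(525, 40, 1.0),
    excitedFraction = excitedFraction)
}

#' @rdname photocyclePresets
#' @export
fdnarPhotocycleModel <- function(excitedFraction = 0.1) {
  photocycleModel(
    intermediateNames = c("K", "L/M", "O1", "O2"),
    rateConstants = 1 / c(40e-6, 1.63e-3, 15e-3, 55e-3),
    intermediateSpectra = rbind(
      c(600, 42, 1.05),
      c(405, 35, 0.90),
      c(590, 45, 1.00),
      c(595, 45, 0.95)),
    darkSpectrum = c(525, 40, 1.0),
    excitedFraction = excitedFraction)
}

#' @rdname photocyclePresets
#' @export
srnarPhotocycleModel <- function(excitedFraction = 0.1) {
  photocycleModel(
    intermediateNames = c("L/M", "L/M'"),
    rateConstants = 1 / c(0.59, 1.54),
    intermediateSpectra = rbind(
      c(420, 36, 0.95),
      c(428, 36, 0.90)),
    darkSpectrum = c(550, 42, 1.0),
    excitedFraction = excitedFraction)
}

#' @rdname photocyclePresets
#' @param protein one of \code{"KR2"}, \code{"FdNaR"}, \code{"SrNaR"}
#'   (case-insensitive).
#' @export
photocycleModelPreset <- function(protein, excitedFraction = 0.1) {
  switch(toupper(protein),
    KR2 = kr2PhotocycleModel(excitedFraction),
    FDNAR = fdnarPhotocycleModel(excitedFraction),
    SRNAR = srnarPhotocycleModel(excitedFraction),
    stop("unknown preset '", protein, "'; available: KR2, FdNaR, SrNaR"))
}
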