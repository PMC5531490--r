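#' Quantify and classify a pH-electrode pump-assay trace
#'
#' Estimates the light-induced pH slope over the first \code{slopeWindowS}
#' seconds of illumination after removing the dark baseline drift (the OLS
#' slope of the pre-illumination segment is subtracted from the whole trace),
#' and classifies the transport mode from the sign and significance of the
#' slope:
#' \itemize{
#'   \item slope < -3 SE — \code{"H_export"} (medium acidifies: outward
#'     proton pumping);
#'   \item slope > +3 SE — \code{"Na_export_alkalinization"} (medium
#'     alkalizes: secondary proton uptake following Na+ extrusion);
#'   \item otherwise — \code{"none"}.
#' }
#' When a paired CCCP trace is supplied, \code{cccpRatio} =
#' slope(CCCP) / slope(no CCCP) is also returned; for a Na+ pump the
#' protonophore enhances alkalinization (ratio > 1), whereas it collapses the
#' signal of a pure H+ pump.
#'
#' @param trace a [PumpTrace-class] recorded without CCCP.
#' @param pairedCccpTrace optional [PumpTrace-class] of the same sample with
#'   CCCP; must share the illumination window.
#' @param slopeWindowS slope-estimation window from light-on (s), default 30.
#' @return list with \code{initialSlope} (pH/s), \code{slopeSe},
#'   \code{netDeltaPH} (drift-corrected pH change over the full window),
#'   \code{classification} and \code{cccpRatio} (NA without a paired trace).
#' @export
pumpMetrics <- function(trace, pairedCccpTrace = NULL, slopeWindowS = 30) {
  stopifnot(is(trace, "PumpTrace"))
  w <- trace@illuminationWindow
  tt <- trace@time
  if (w[1L] < min(tt) || w[2L] > max(tt))
    stop("illumination window lies outside the trace span")
  inWin <- tt >= w[1L] & tt <= w[2L]
  if (sum(inWin) < 10L) stop("fewer than 10 samples in the illumination window")

  corrected <- driftCorrect(tt, trace@pH, w[1L])
  sl <- slopeInWindow(tt, corrected, w[1L], min(w[1L] + slopeWindowS, w[2L]))

  headIdx <- which(inWin)[seq_len(min(5L, sum(inWin)))]
  tailIdx <- rev(which(inWin))[seq_len(min(5L, sum(inWin)))]
  netDelta <- mean(corrected[tailIdx]) - mean(corrected[headIdx])

  classification <- if (sl$slope < -3 * sl$se) "H_export"
    else if (sl$slope > 3 * sl$se) "Na_export_alkalinization"
    else "none"

  cccpRatio <- NA_real_
  if (!is.null(pairedCccpTrace)) {
    stopifnot(is(pairedCccpTrace, "PumpTrace"))
    if (!isTRUE(all.equal(pairedCccpTrace@illuminationWindow, w)))
      stop("paired trace has a mismatched illumination window")
    cc <- driftCorrect(pairedCccpTrace@time, pairedCccpTrace@pH, w[1L])
    slC <- slopeInWindow(pairedCccpTrace@time, cc, w[1L],
                         min(w[1L] + slopeWindowS, w[2L]))
    cccpRatio <- slC$slope / sl$slope
  }
  list(initialSlope = sl$slope, slopeSe = sl$se, netDeltaPH = netDelta,
       classification = classification, cccpRatio = cccpRatio)
}

# Subtract the pre-illumination OLS drift line (slope only; the intercept is
# irrelevant to slope- and difference-based metrics, so classification is
# invariant to any constant pH offset).
driftCorrect <- function(time, pH, lightOn) {
  pre <- time < lightOn
  if (sum(pre) >= 2L) {
    drift <- unname(stats::coef(stats::lm(pH[pre] ~ time[pre]))[2L])
    pH - drift * time
  } else pH
}

slopeInWindow <- function(time, value, from, to) {
  sel <- time >= from & time <= to
  fit <- summary(stats::lm(value[sel] ~ time[sel]))
  list(slope = fit$coefficients[2L, 1L], se = fit$coefficients[2L, 2L])
}
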