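#' Peak, steady-state and off-kinetics of a photocurrent trace
#'
#' Subtracts the pre-light baseline (mean current before the epoch onset),
#' then reports the peak current during the epoch, the steady-state current
#' as the mean over the last 20\% of the epoch, their ratio, and the
#' light-off relaxation time constant from a mono-exponential fit
#' ([fitTraceMultiexp()] with n = 1) to the post-light segment.
#'
#' @param trace a [PhotocurrentTrace-class].
#' @param epochIndex which light epoch to analyze when the trace holds more
#'   than one (default: the only/first epoch; an error is raised when several
#'   epochs exist and none is named).
#' @param ssFraction fraction of the epoch tail used for the steady-state
#'   mean (default 0.2).
#' @return list with \code{iPeak} (pA), \code{iSs} (pA),
#'   \code{inactivationRatio} (iSs/iPeak), \code{tauOff} (ms),
#'   \code{baseline} (pA, the value subtracted) and \code{tauOffFit} (the
#'   full [fitTraceMultiexp()] result).
#' @export
photocurrentMetrics <- function(trace, epochIndex = NULL, ssFraction = 0.2) {
  stopifnot(is(trace, "PhotocurrentTrace"))
  ep <- trace@lightEpochs
  if (nrow(ep) == 0L) stop("trace has no light epoch")
  if (is.null(epochIndex)) {
    if (nrow(ep) > 1L)
      stop("trace has ", nrow(ep), " light epochs; give epochIndex")
    epochIndex <- 1L
  }
  on <- ep[epochIndex, 1L]; off <- ep[epochIndex, 2L]
  tt <- trace@time; cur <- trace@current
  pre <- tt < on
  baseline <- if (any(pre)) mean(cur[pre]) else 0
  y <- cur - baseline
  lit <- tt >= on & tt < off
  if (sum(lit) < 5L) stop("light epoch shorter than 5 samples")
  iPeak <- max(y[lit])
  ssWin <- tt >= off - ssFraction * (off - on) & tt < off
  iSs <- mean(y[ssWin])
  nextOn <- if (epochIndex < nrow(ep)) ep[epochIndex + 1L, 1L] else Inf
  post <- tt >= off & tt < nextOn
  tauFit <- fitTraceMultiexp(tt[post], y[post], n = 1L)
  list(iPeak = iPeak, iSs = iSs, inactivationRatio = iSs / iPeak,
       tauOff = tauFit$taus[1L], baseline = baseline, tauOffFit = tauFit)
}

#' Current-voltage (I-V) line fit
#'
#' Ordinary least squares of photocurrent on holding potential. Pumps driven
#' by the photocycle alone give nearly flat I-V relations; the fit is flagged
#' voltage-insensitive when |slope| falls below \code{flatThreshold}
#' (default 0.02 pA/mV, about 5\% of typical fitted slopes).
#'
#' @param voltages holding potentials (mV), at least 3 distinct values.
#' @param currents photocurrents (pA).
#' @param flatThreshold flag threshold on |slope| (pA/mV).
#' @return list with \code{slope} (pA/mV), \code{intercept} (pA),
#'   \code{rSquared}, \code{slopeSe}, \code{voltageInsensitive} and the
#'   underlying \code{lm} fit.
#' @export
ivFit <- function(voltages, currents, flatThreshold = 0.02) {
  if (length(voltages) < 3L) stop("at least 3 voltage points are required")
  if (anyDuplicated(voltages)) stop("voltages must be distinct")
  if (length(voltages) != length(currents))
    stop("voltages and currents must have equal length")
  fit <- stats::lm(currents ~ voltages)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1L]),
       rSquared = sm$r.squared,
       slopeSe = sm$coefficients[2L, 2L],
       voltageInsensitive = abs(slope) < flatThreshold,
       fit = fit)
}

#' Action-spectrum normalization and peak wavelength
#'
#' Normalizes photocurrents to a maximum of 1 and locates the peak by a
#' quadratic (three-point parabolic) interpolation through the maximum sample
#' and its two neighbours, which recovers band maxima lying between grid
#' points of the usual 10-nm wavelength sampling. A maximum at either grid
#' edge cannot be interpolated and is returned as-is with a warning.
#'
#' @param wavelengths stimulation wavelengths (nm), strictly increasing.
#' @param currents photocurrent amplitudes at equal light power.
#' @param irradiance common light intensity (mW/mm^2), metadata only.
#' @return list with \code{wavelengths}, \code{normalizedCurrent} (max 1),
#'   \code{peakNm}, \code{irradiance} and \code{edgePeak} flag.
#' @export
actionSpectrumPeak <- function(wavelengths, currents, irradiance = 0.2) {
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (length(wavelengths) != length(currents))
    stop("wavelengths and currents must have equal length")
  norm <- currents / max(currents)
  iMax <- which.max(norm)
  edge <- iMax == 1L || iMax == length(norm)
  if (edge) {
    warning("spectrum maximum lies at the grid edge; peak not interpolated")
    peak <- wavelengths[iMax]
  } else {
    x <- wavelengths[(iMax - 1L):(iMax + 1L)]
    y <- norm[(iMax - 1L):(iMax + 1L)]
    # vertex of the parabola through three points
    d1 <- (x[2L] - x[1L]) * (y[2L] - y[3L])
    d2 <- (x[2L] - x[3L]) * (y[2L] - y[1L])
    peak <- x[2L] - 0.5 * ((x[2L] - x[1L]) * d1 - (x[2L] - x[3L]) * d2) /
      (d1 - d2)
  }
  list(wavelengths = wavelengths, normalizedCurrent = norm,
       peakNm = peak, irradiance = irradiance, edgePeak = edge)
}

#' Light-saturation fit of photocurrent versus irradiance
#'
#' Fits the single-photon saturation hyperbola
#' \eqn{I(P) = I_{max} P / (P + P_{1/2})} by nonlinear least squares.
#'
#' @param irradiances light intensities (mW/mm^2), > 0.
#' @param currents photocurrents (pA).
#' @return list with \code{iMax}, \code{pHalf}, \code{fitted} and the
#'   \code{nls} fit object. By construction the fitted current at
#'   \code{P = pHalf} equals \code{iMax / 2}.
#' @export
saturationFit <- function(irradiances, currents) {
  stopifnot(length(irradiances) == length(currents), all(irradiances > 0))
  df <- data.frame(P = irradiances, I = currents)
  iMax0 <- 1.05 * max(currents)
  pHalf0 <- irradiances[which.min(abs(currents - iMax0 / 2))]
  fit <- stats::nls(I ~ imax * P / (P + phalf), data = df,
                    start = list(imax = iMax0, phalf = max(pHalf0, min(irradiances))),
                    algorithm = "port",
                    lower = c(imax = 0, phalf = .Machine$double.eps))
  co <- stats::coef(fit)
  list(iMax = unname(co["imax"]), pHalf = unname(co["phalf"]),
       fitted = stats::fitted(fit), fit = fit)
}

#' Per-pulse peak currents and adaptation ratio in a pulse train
#'
#' Measures the baseline-subtracted peak current evoked by each light pulse
#' of a repetitive stimulation train and reports the adaptation ratio
#' (last peak / first peak).
#'
#' @param trace a [PhotocurrentTrace-class].
#' @param pulseTimes pulse onset times (ms), strictly increasing; pulses
#'   closer together than the sampling interval are rejected.
#' @param windowMs search window after each onset; defaults to the
#'   inter-pulse interval.
#' @return list with \code{peaks} (pA, one per pulse), \code{adaptationRatio}
#'   and \code{baseline}.
#' @export
pulseAdaptation <- function(trace, pulseTimes, windowMs = NULL) {
  stopifnot(is(trace, "PhotocurrentTrace"), length(pulseTimes) >= 2L)
  dt <- stats::median(diff(trace@time))
  if (any(diff(pulseTimes) < dt))
    stop("pulses are closer together than the trace resolution (", dt, " ms)")
  if (is.null(windowMs)) windowMs <- min(diff(pulseTimes))
  tt <- trace@time
  baseline <- if (any(tt < pulseTimes[1L])) mean(trace@current[tt < pulseTimes[1L]]) else 0
  y <- trace@current - baseline
  ends <- c(pulseTimes[-1L], pulseTimes[length(pulseTimes)] + windowMs)
  peaks <- vapply(seq_along(pulseTimes), function(i) {
    win <- tt >= pulseTimes[i] & tt < min(pulseTimes[i] + windowMs, ends[i])
    if (!any(win)) stop("no samples in the window of pulse ", i)
    max(y[win])
  }, numeric(1))
  list(peaks = peaks,
       adaptationRatio = peaks[length(peaks)] / peaks[1L],
       baseline = baseline)
}

#' Spike detection on a current-clamp voltage trace
#'
#' Detects action potentials as upward crossings of a fixed voltage
#' threshold, with a refractory lockout that suppresses re-triggering on the
#' same spike. Latency is measured from the start of the trace (align traces
#' to the stimulus onset before calling).
#'
#' @param time time base (ms).
#' @param voltage membrane potential (mV).
#' @param thresholdMv detection threshold (mV), default -20.
#' @param lockoutMs refractory lockout (ms), default 2.
#' @return list with \code{spikeTimes} (ms), \code{nSpikes} and
#'   \code{latencyFirstSpike} (ms; NA when no spike is detected).
#' @export
spikeMetrics <- function(time, voltage, thresholdMv = -20, lockoutMs = 2) {
  stopifnot(length(time) == length(voltage))
  up <- which(voltage[-1L] >= thresholdMv & voltage[-length(voltage)] < thresholdMv) + 1L
  spikes <- numeric(0)
  lastT <- -Inf
  for (i in up) {
    if (time[i] - lastT >= lockoutMs) {
      spikes <- c(spikes, time[i])
      lastT <- time[i]
    }
  }
  list(spikeTimes = spikes, nSpikes = length(spikes),
       latencyFirstSpike = if (length(spikes)) spikes[1L] - time[1L] else NA_real_)
}

#' Optical-silencing comparison of lit versus unlit responses
#'
#' Quantifies silencing efficacy as the shift in time of the first evoked
#' action potential (T = lit latency - unlit latency) and the change in
#' evoked spike count, from two [spikeMetrics()] results recorded with and
#' without light during identical current injections.
#'
#' @param lit,unlit [spikeMetrics()] results for the illuminated and control
#'   sweeps.
#' @return list with \code{latencyShiftT} (ms; Inf when light abolishes all
#'   spikes, NA when the control sweep itself has none) and
#'   \code{deltaNSpikes} (lit - unlit).
#' @export
silencingCompare <- function(lit, unlit) {
  shift <- if (is.na(unlit$latencyFirstSpike)) NA_real_
    else if (is.na(lit$latencyFirstSpike)) Inf
    else lit$latencyFirstSpike - unlit$latencyFirstSpike
  list(latencyShiftT = shift,
       deltaNSpikes = lit$nSpikes - unlit$nSpikes)
}
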