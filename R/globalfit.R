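#' Reconstruct transient absorption spectra at chosen delays
#'
#' For each requested delay, interpolates every wavelength channel of the
#' surface linearly in log(time). Delays falling exactly on a grid time
#' return that matrix column unchanged.
#'
#' @param surface a [TransientAbsorptionSurface-class].
#' @param delayTimes delays (s); each must lie within the time span.
#' @return numeric matrix, rows = wavelengths, one column per delay, with
#'   dimnames set to the grids.
#' @export
reconstructSpectra <- function(surface, delayTimes) {
  stopifnot(is(surface, "TransientAbsorptionSurface"))
  tt <- surface@times
  if (any(delayTimes < min(tt) | delayTimes > max(tt)))
    stop(sprintf("delay outside the measured span [%.3g, %.3g] s",
                 min(tt), max(tt)))
  lt <- log(tt)
  out <- vapply(delayTimes, function(d) {
    apply(surface@deltaA, 1L, function(y)
      stats::approx(lt, y, xout = log(d))$y)
  }, numeric(length(surface@wavelengths)))
  out <- matrix(out, nrow = length(surface@wavelengths),
                dimnames = list(surface@wavelengths, signif(delayTimes, 6)))
  out
}

# Variable-projection machinery ---------------------------------------------
#
# For fixed {tau_i} the model Y = E %*% C is linear: E has one column
# exp(-t/tau_i) per component plus (optionally) a constant offset column; C
# holds the DAS (and offset) for every wavelength channel. C is solved
# exactly by least squares, so the nonlinear search runs over log(tau) only.

varproDesign <- function(times, tau, fitOffset) {
  E <- exp(-outer(times, 1 / tau))
  if (fitOffset) E <- cbind(E, 1)
  E
}

# Y: times x channels. Returns list(rss, coef, resid).
varproSolve <- function(Y, times, tau, fitOffset) {
  E <- varproDesign(times, tau, fitOffset)
  qrE <- qr(E)
  C <- qr.coef(qrE, Y)
  C[is.na(C)] <- 0
  R <- Y - E %*% C
  list(rss = sum(R * R), coef = C, resid = R)
}

varproRSS <- function(logTau, Y, times, fitOffset) {
  tau <- 10^logTau
  if (anyDuplicated(signif(tau, 12))) return(Inf)
  varproSolve(Y, times, tau, fitOffset)$rss
}

# Deterministic multistart over log(tau): a grid of 8 seeds per decade of the
# time span; models are grown greedily (the n-component starts augment the
# best (n-1)-component solution with each grid point) plus one evenly spaced
# start. The best initial RSS candidates are refined with nlminb in log-tau.
varproFit <- function(Y, times, nComponents, fitOffset,
                      seedsPerDecade = 8, nRefine = 5) {
  lo <- log10(min(times)); hi <- log10(max(times))
  grid <- seq(lo, hi, by = 1 / seedsPerDecade)
  lower <- rep(lo - 2, nComponents); upper <- rep(hi + 2, nComponents)

  refine <- function(start) {
    fit <- stats::nlminb(start, varproRSS, Y = Y, times = times,
                         fitOffset = fitOffset,
                         lower = lower[seq_along(start)],
                         upper = upper[seq_along(start)],
                         control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                        iter.max = 500, eval.max = 2000))
    fit
  }

  best <- NULL
  for (n in seq_len(nComponents)) {
    starts <- list(seq(lo, hi, length.out = n + 2)[2:(n + 1)])
    if (n > 1L && !is.null(best)) {
      prev <- best$par
      for (g in grid) {
        cand <- sort(c(prev, g))
        if (min(diff(cand)) > 1e-3) starts[[length(starts) + 1L]] <- cand
      }
    } else if (n == 1L) {
      starts <- c(starts, as.list(grid))
    }
    score <- vapply(starts, varproRSS, numeric(1), Y = Y, times = times,
                    fitOffset = fitOffset)
    keep <- order(score)[seq_len(min(nRefine, length(starts)))]
    fits <- lapply(starts[keep], refine)
    obj <- vapply(fits, `[[`, numeric(1), "objective")
    stage <- fits[[which.min(obj)]]
    # polish once from the winner
    stage <- refine(stage$par)
    best <- stage
  }
  if (!is.finite(best$objective))
    stop("global fit failed to converge; best objective = ", best$objective,
         " at log10(tau) = ", paste(signif(best$par, 6), collapse = ", "))
  best
}

#' Global multi-exponential fit with decay-associated spectra
#'
#' Fits all wavelength channels of a transient-absorption surface
#' simultaneously with shared time constants,
#' \deqn{\Delta A(\lambda, t) = \sum_{i=1}^{n} DAS_i(\lambda)\,e^{-t/\tau_i}
#'   + offset(\lambda),}
#' by separable (variable-projection) least squares: for any trial set of
#' taus the DAS and offset are solved exactly per wavelength by linear least
#' squares, and only log(tau) is searched nonlinearly, with a deterministic
#' log-spaced multistart. Equal weighting across wavelengths and delays
#' assumes homoscedastic noise.
#'
#' @param surface a [TransientAbsorptionSurface-class].
#' @param nComponents number of exponential components (>= 1); the time grid
#'   must contain at least \code{2 * nComponents} points.
#' @param fitOffset include a non-decaying baseline spectrum (default TRUE);
#'   it absorbs any permanently bleached/photoproduct signal.
#' @return A [GlobalFitResult-class] with components sorted by ascending tau.
#' @examples
#' surf <- simulatePhotocycle(srnarPhotocycleModel())
#' fit <- fitGlobal(surf, 2)
#' taus(fit)   # ~0.59 s and ~1.54 s
#' @export
fitGlobal <- function(surface, nComponents, fitOffset = TRUE) {
  stopifnot(is(surface, "TransientAbsorptionSurface"))
  if (nComponents < 1L) stop("nComponents must be >= 1")
  nt <- length(surface@times)
  if (nt < 2L * nComponents)
    stop("nComponents too large for the time grid: ", nt,
         " time points cannot support ", nComponents, " components")
  Y <- t(surface@deltaA)                      # times x wavelengths
  opt <- varproFit(Y, surface@times, nComponents, fitOffset)
  tau <- sort(10^opt$par)
  sol <- varproSolve(Y, surface@times, tau, fitOffset)
  dasM <- t(sol$coef[seq_len(nComponents), , drop = FALSE])  # wl x comp
  offset <- if (fitOffset) as.numeric(sol$coef[nComponents + 1L, ])
            else rep(0, length(surface@wavelengths))
  nwl <- length(surface@wavelengths)
  p <- nComponents + nComponents * nwl + if (fitOffset) nwl else 0L
  N <- length(Y)
  rssVal <- max(sol$rss, 1e-300)
  new("GlobalFitResult",
      taus = tau, das = dasM, offsetSpectrum = offset,
      offsetFitted = fitOffset,
      wavelengths = surface@wavelengths, times = surface@times,
      residualMatrix = t(sol$resid), rss = sol$rss, nParameters = p,
      bic = N * log(rssVal / N) + p * log(N))
}

#' Choose the number of exponential components by BIC
#'
#' Runs [fitGlobal()] for n = 1..\code{maxN} plus the offset-only null model
#' (n = 0) and returns the BIC-minimizing order with the full per-n table.
#'
#' @param surface a [TransientAbsorptionSurface-class].
#' @param maxN largest model order to try.
#' @param fitOffset passed to [fitGlobal()].
#' @return list with \code{n} (chosen order), \code{table} (data.frame of n,
#'   rss, bic) and \code{fits} (the [GlobalFitResult-class] objects, NULL for
#'   n = 0).
#' @export
selectComponents <- function(surface, maxN, fitOffset = TRUE) {
  stopifnot(is(surface, "TransientAbsorptionSurface"), maxN >= 1L)
  Y <- t(surface@deltaA)
  N <- length(Y); nwl <- ncol(Y)
  # n = 0: offset-only (or empty) model
  if (fitOffset) {
    mu <- colMeans(Y)
    rss0 <- sum(sweep(Y, 2L, mu)^2)
    p0 <- nwl
  } else {
    rss0 <- sum(Y * Y); p0 <- 0L
  }
  tab <- data.frame(n = 0L, rss = rss0,
                    bic = N * log(max(rss0, 1e-300) / N) + p0 * log(N))
  fits <- vector("list", maxN + 1L)
  for (n in seq_len(maxN)) {
    f <- fitGlobal(surface, n, fitOffset = fitOffset)
    fits[[n + 1L]] <- f
    tab <- rbind(tab, data.frame(n = n, rss = f@rss, bic = f@bic))
  }
  list(n = tab$n[which.min(tab$bic)], table = tab, fits = fits)
}

#' Multi-exponential fit of a single trace
#'
#' Scalar-amplitude analog of [fitGlobal()] for a one-channel time series
#' (e.g. photocurrent off-relaxation): \eqn{y(t) = \sum_i a_i e^{-t/\tau_i}
#' (+ c)}. Time is shifted so the first sample is at the origin, making the
#' amplitudes the extrapolated values at the start of the segment.
#'
#' @param time,values the series; time in any unit (taus are returned in the
#'   same unit).
#' @param n number of exponentials.
#' @param fitOffset add a constant offset term (default FALSE).
#' @return list with \code{taus} (ascending), \code{amplitudes} (matching
#'   order), \code{offset}, \code{rss}, \code{fitted}, and
#'   \code{nonIdentifiable} — TRUE when an amplitude is negligible relative
#'   to the data scale or a tau ran to the search bound, as happens when the
#'   trace holds fewer decaying components than requested.
#' @export
fitTraceMultiexp <- function(time, values, n, fitOffset = FALSE) {
  stopifnot(length(time) == length(values), n >= 1L)
  if (length(time) < 2L * n + 1L)
    stop("too few samples for ", n, " exponential component(s)")
  t0 <- time[1L]
  ts <- time - t0 + diff(range(time)) * 1e-9  # strictly positive, ~origin
  Y <- matrix(values, ncol = 1L)
  opt <- varproFit(Y, ts, n, fitOffset)
  tau <- sort(10^opt$par)
  sol <- varproSolve(Y, ts, tau, fitOffset)
  amp <- as.numeric(sol$coef[seq_len(n), 1L])
  off <- if (fitOffset) sol$coef[n + 1L, 1L] else 0
  scale <- max(abs(values), .Machine$double.eps)
  lo <- log10(min(ts)) - 2 + 1e-6; hi <- log10(max(ts)) + 2 - 1e-6
  nonId <- any(abs(amp) < 1e-6 * scale) ||
    any(log10(tau) <= lo | log10(tau) >= hi)
  if (nonId)
    warning("trace component(s) not identifiable: amplitude ~ 0 or tau at bound")
  list(taus = tau, amplitudes = amp, offset = off, rss = sol$rss,
       fitted = as.numeric(varproDesign(ts, tau, fitOffset) %*% sol$coef),
       nonIdentifiable = nonId)
}
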