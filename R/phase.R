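# Oscillation phase assignment and circular statistics: resultant vector,
# Rayleigh uniformity test, Watson-Williams comparison of mean directions,
# phase histograms.  Phase convention throughout: 0 degrees = trough,
# 180 degrees = peak; ascending limb 0->180, descending limb 180->360.

#' Instantaneous phase of a band-passed trace
#'
#' Default method: piecewise-linear landmark interpolation — phase runs
#' 0->180 degrees from each trough to the following peak and 180->360 from
#' the peak to the next trough, so trough samples map exactly to 0 and peak
#' samples to 180 even for asymmetric cycles.  The alternative
#' \code{"analytic"} method uses the analytic-signal argument shifted so
#' troughs sit at 0 degrees; the two differ for asymmetric waveforms.
#' Samples before the first or after the last landmark are NA (unusable).
#'
#' @param filtered band-passed \linkS4class{LFPRecording}.
#' @param landmarks list(troughs, peaks) from
#'   \code{\link{findCycleLandmarks}} on the same trace (computed if NULL).
#' @param method \code{"landmark"} (default) or \code{"analytic"}.
#' @param band band label stored in the result.
#' @return A \linkS4class{PhaseSeries}.
#' @export
instantaneousPhase <- function(filtered, landmarks = NULL,
                               method = c("landmark", "analytic"),
                               band = "band") {
  stopifnot(is(filtered, "LFPRecording"))
  method <- match.arg(method)
  fs <- samplingRate(filtered)
  t <- sampleTimes(filtered)
  if (method == "analytic") {
    arg <- Arg(analyticSignal(traceSamples(filtered)))
    ph <- wrapDeg(radToDeg(arg) + 180)
    return(PhaseSeries(ph, fs, band))
  }
  if (is.null(landmarks)) landmarks <- findCycleLandmarks(filtered)
  lt <- c(landmarks$troughs, landmarks$peaks)
  if (length(lt) < 2L) rpStop("need at least 2 cycle landmarks")
  type <- c(rep(0, length(landmarks$troughs)), rep(1, length(landmarks$peaks)))
  o <- order(lt)
  lt <- lt[o]; type <- type[o]
  if (any(diff(type) == 0)) rpStop("landmarks must alternate trough/peak")
  # unwrapped anchor phase: each landmark is 180 degrees after the previous
  anchor <- (seq_along(lt) - 1L) * 180 + ifelse(type[1L] == 0, 0, 180)
  unwrapped <- stats::approx(lt, anchor, xout = t, rule = 1)$y
  PhaseSeries(wrapDeg(unwrapped), fs, band)
}

#' Look up oscillation phase at spike times
#'
#' Nearest-sample lookup of each spike's phase, restricted to the supplied
#' behavioral-state epochs.  Spikes outside the epochs or in unusable
#' (NA-phase) spans are excluded; exclusion counts are reported as
#' attributes \code{"nOutsideEpochs"} and \code{"nUnusable"}.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param phases a \linkS4class{PhaseSeries}.
#' @param epochs (start, end) intervals restricting the analysis.
#' @return Numeric vector of phases in degrees.
#' @export
spikePhases <- function(spikes, phases, epochs) {
  stopifnot(is(spikes, "SpikeTrain"), is(phases, "PhaseSeries"))
  epochs <- validateIntervals(epochs, "epochs")
  if (nrow(epochs) == 0L) rpStop("empty epoch set")
  st <- spikeTimes(spikes)
  inEp <- inIntervals(st, epochs)
  fs <- samplingRate(phases)
  idx <- pmin(pmax(round(st * fs) + 1L, 1L), length(phaseDeg(phases)))
  ph <- phaseDeg(phases)[idx]
  usable <- inEp & !is.na(ph)
  out <- ph[usable]
  attr(out, "nOutsideEpochs") <- sum(!inEp)
  attr(out, "nUnusable") <- sum(inEp & is.na(ph))
  out
}

#' Resultant vector of spike phases
#'
#' Mean resultant length \eqn{r = |\sum_j e^{i\theta_j}|/n} (0 = no phase
#' preference, 1 = all phases identical) and mean phase direction.  The
#' mean phase is flagged undefined when r = 0.
#'
#' @param phasesDeg spike phases in degrees (n >= 1).
#' @return A list with class \code{"phaseLockingResult"}: n, meanPhase
#'   (degrees in [0, 360), NA if undefined), r, rayleighP (NA until
#'   \code{\link{rayleighTest}} is applied).
#' @examples
#' resultantVector(c(0, 0, 90))
#' @export
resultantVector <- function(phasesDeg) {
  n <- length(phasesDeg)
  if (n < 1L) rpStop("need at least one phase")
  th <- degToRad(phasesDeg)
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  meanPhase <- if (r > 1e-12) wrapDeg(radToDeg(atan2(S, C))) else NA_real_
  structure(list(n = n, meanPhase = meanPhase, r = min(r, 1),
                 rayleighP = NA_real_),
            class = "phaseLockingResult")
}

#' @export
print.phaseLockingResult <- function(x, ...) {
  cat(sprintf("phaseLockingResult: n = %d, mean phase = %s deg, r = %.4f",
              x$n,
              if (is.na(x$meanPhase)) "undefined" else sprintf("%.1f", x$meanPhase)))
  if (!is.na(x$rayleighP)) cat(sprintf(", Rayleigh p = %.3g", x$rayleighP))
  cat("\n")
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of uniform phases with the statistic Z = n r^2 and the
#' standard finite-n corrected approximation
#' \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n))} with R = n r.
#'
#' @param phasesDeg spike phases in degrees; n >= 5 required for the
#'   approximation.
#' @return p-value in (0, 1].
#' @export
rayleighTest <- function(phasesDeg) {
  n <- length(phasesDeg)
  if (n < 5L) rpStop("Rayleigh test requires n >= 5")
  r <- resultantVector(phasesDeg)$r
  R <- n * r
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  min(max(p, .Machine$double.xmin), 1)
}

#' Fill in the Rayleigh p of a phase-locking result
#'
#' @param phasesDeg spike phases in degrees.
#' @return \code{phaseLockingResult} with \code{rayleighP} set (NA when
#'   n < 5).
#' @export
phaseLocking <- function(phasesDeg) {
  res <- resultantVector(phasesDeg)
  res$rayleighP <- if (res$n >= 5L) rayleighTest(phasesDeg) else NA_real_
  res
}

#' Watson-Williams test for equal mean directions
#'
#' Circular one-way ANOVA comparing the mean directions of two or more
#' groups of angles, with the standard concentration correction factor
#' (1 + 3/(8 kappa)).  The test assumes reasonably concentrated von
#' Mises-like samples; a warning is emitted when the pooled mean resultant
#' length is below 0.45 or any group has fewer than 5 observations (as when
#' comparing per-cell mean phases across small cell classes).
#'
#' @param groups list of >= 2 numeric vectors of angles in degrees.
#' @return list(F, df1, df2, p, n) with class \code{"watsonWilliamsResult"}.
#' @export
watsonWilliams <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    rpStop("need at least 2 groups of angles")
  }
  nj <- lengths(groups)
  if (any(nj < 2L)) rpStop("each group needs at least 2 angles")
  if (any(nj < 5L)) {
    warning("Watson-Williams with group size < 5: interpret with caution")
  }
  N <- sum(nj)
  k <- length(groups)
  Rj <- vapply(groups, function(g) length(g) * circularRbar(g), numeric(1))
  Rall <- N * circularRbar(unlist(groups))
  sumRj <- sum(Rj)
  rw <- sumRj / N
  if (rw < 0.45) {
    warning("pooled resultant length ", sprintf("%.2f", rw),
            " < 0.45: Watson-Williams assumptions questionable")
  }
  kap <- kappaFromRbar(rw)
  corr <- 1 + 3 / (8 * kap)
  Fstat <- corr * ((N - k) * (sumRj - Rall)) / ((k - 1) * (N - sumRj))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  structure(list(F = Fstat, df1 = k - 1, df2 = N - k, p = p, n = nj),
            class = "watsonWilliamsResult")
}

#' @export
print.watsonWilliamsResult <- function(x, ...) {
  cat(sprintf("Watson-Williams: F(%d, %d) = %.3f, p = %.4g (n = %s)\n",
              x$df1, x$df2, x$F, x$p, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Phase histogram
#'
#' Firing probability per phase bin: bins are half-open, cover [0, 360),
#' and the probabilities sum to 1.
#'
#' @param phasesDeg phases in degrees (n >= 1).
#' @param nBins number of bins (default 20, i.e. 18-degree bins).
#' @return list(breaks, centers, probability).
#' @export
phaseHistogram <- function(phasesDeg, nBins = 20) {
  if (!length(phasesDeg)) rpStop("need at least one phase")
  breaks <- seq(0, 360, length.out = nBins + 1L)
  idx <- pmin(floor(wrapDeg(phasesDeg) / (360 / nBins)) + 1L, nBins)
  counts <- tabulate(idx, nBins)
  list(breaks = breaks,
       centers = (breaks[-1L] + breaks[-(nBins + 1L)]) / 2,
       probability = counts / length(phasesDeg))
}

#' Group-level circular summary of per-cell mean phases
#'
#' Circular mean and circular SD across cells (each cell weighted equally),
#' matching the field's "mean +/- SD degrees" reporting style.
#'
#' @param meanPhasesDeg per-cell mean phases in degrees.
#' @return list(meanPhase, circSD, n).
#' @export
groupPhaseSummary <- function(meanPhasesDeg) {
  list(meanPhase = circularMeanDeg(meanPhasesDeg),
       circSD = circularSDDeg(meanPhasesDeg),
       n = length(meanPhasesDeg))
}
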