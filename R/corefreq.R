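# Intra-event ("core") frequency estimation by three methods —
# zero-crossing intervals, peak intervals, and complex Morlet wavelet
# scalogram peak — and spike-conditioned comparison of event core
# frequencies.

#' Core frequency from zero crossings
#'
#' Inverse of the mean interval between successive zero crossings of the
#' band-passed segment, divided by two (a cycle contains two crossings).
#' Crossings are located by linear interpolation between samples.
#'
#' @param segment numeric band-passed event samples.
#' @param fs sampling rate (Hz).
#' @return Frequency in Hz; NA (with a warning) when fewer than 3 crossings.
#' @export
coreFreqZeroCrossing <- function(segment, fs) {
  x <- as.numeric(segment)
  s <- sign(x)
  nz <- which(s != 0)
  if (length(nz) < 2L) {
    warning("too few zero crossings")
    return(NA_real_)
  }
  cross <- numeric(0)
  prev <- nz[1L]
  for (i in nz[-1L]) {
    if (s[i] != s[prev]) {
      # linear interpolation between samples prev and i
      tc <- prev + (0 - x[prev]) / (x[i] - x[prev]) * (i - prev)
      cross <- c(cross, tc)
    }
    prev <- i
  }
  if (length(cross) < 3L) {
    warning("too few zero crossings")
    return(NA_real_)
  }
  meanIv <- mean(diff(cross)) / fs
  (1 / meanIv) / 2
}

#' Core frequency from peak intervals
#'
#' Inverse of the mean interval between neighboring positive local maxima
#' of the band-passed segment, with parabolic sub-sample refinement of the
#' peak positions.
#'
#' @param segment numeric band-passed event samples.
#' @param fs sampling rate (Hz).
#' @return Frequency in Hz; NA (with a warning) when fewer than 2 peaks.
#' @export
coreFreqPeakInterval <- function(segment, fs) {
  x <- as.numeric(segment)
  n <- length(x)
  if (n < 3L) {
    warning("segment too short for peak intervals")
    return(NA_real_)
  }
  i <- 2:(n - 1L)
  pk <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > 0]
  if (length(pk) < 2L) {
    warning("fewer than 2 peaks in segment")
    return(NA_real_)
  }
  # parabolic interpolation around each peak sample
  a <- x[pk - 1L]; b <- x[pk]; c <- x[pk + 1L]
  denom <- a - 2 * b + c
  shift <- ifelse(abs(denom) > .Machine$double.eps, 0.5 * (a - c) / denom, 0)
  tp <- (pk - 1L + shift) / fs
  1 / mean(diff(tp))
}

#' Complex Morlet wavelet scalogram
#'
#' Continuous wavelet transform with the complex Morlet
#' \eqn{\psi(t) = (\pi f_b)^{-1/2} e^{2\pi i f_c t} e^{-t^2/f_b}} using
#' bandwidth parameter \eqn{f_b = 5} and center-frequency parameter
#' \eqn{f_c = 1}; a daughter at analysis frequency f is the mother scaled
#' by \eqn{s = f_c / f}.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param freqs analysis frequencies (Hz).
#' @param fb,fc Morlet bandwidth and center-frequency parameters.
#' @return Complex matrix, one row per frequency.
#' @export
morletCWT <- function(x, fs, freqs, fb = 5, fc = 1) {
  n <- length(x)
  out <- matrix(complex(1), nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    s <- fc / f
    halfN <- ceiling(3.5 * s * sqrt(fb) * fs)
    tt <- (-halfN:halfN) / fs
    psi <- (pi * fb)^(-0.5) / sqrt(s) *
      exp(2i * pi * fc * tt / s) * exp(-(tt / s)^2 / fb)
    m <- length(psi)
    # linear convolution via FFT, centered ("same" output)
    L <- stats::nextn(n + m - 1L, 2)
    X <- stats::fft(c(x, numeric(L - n)))
    P <- stats::fft(c(psi, complex(real = numeric(L - m))))
    conv <- stats::fft(X * P, inverse = TRUE) / L
    out[i, ] <- conv[halfN + seq_len(n)] / fs
  }
  out
}

#' Core frequency from the wavelet scalogram peak
#'
#' Computes the complex Morlet ('fb = 5, fc = 1') scalogram of the
#' band-passed segment over the analysis grid and returns the frequency of
#' the global magnitude maximum.
#'
#' @param segment numeric band-passed event samples (from the 90-200 Hz
#'   filtered trace).
#' @param fs sampling rate (Hz).
#' @param freqs analysis grid in Hz (default 90-200 Hz at 1 Hz spacing);
#'   must lie within \code{band}.
#' @param band (low, high) admissible frequency range for the grid.
#' @return Frequency in Hz.
#' @export
coreFreqWavelet <- function(segment, fs, freqs = seq(90, 200, by = 1),
                            band = c(90, 200)) {
  if (min(freqs) < band[1L] || max(freqs) > band[2L]) {
    rpStop("wavelet grid must lie within [", band[1L], ", ", band[2L], "] Hz")
  }
  if (max(freqs) >= fs / 2) rpStop("wavelet grid at or above Nyquist")
  W <- morletCWT(as.numeric(segment), fs, freqs)
  mag <- abs(W)
  freqs[which.max(apply(mag, 1L, max))]
}

#' Attach core frequencies to detected events
#'
#' Estimates each event's core frequency on the band-passed trace within
#' the event boundaries.  For the wavelet method the analysed segment is
#' extended by half the longest wavelet support on each side (the maximum
#' is still taken inside the event) to avoid edge loss.
#'
#' @param events events data.frame (start, end).
#' @param filtered band-passed \linkS4class{LFPRecording} (90-200 Hz for
#'   ripples).
#' @param method \code{"wavelet"} (default, as used for all reported
#'   values), \code{"zero_crossing"} or \code{"peak_interval"}.
#' @param freqs wavelet analysis grid (Hz).
#' @return \code{events} with the \code{core_freq} column filled.
#' @export
addCoreFrequencies <- function(events, filtered,
                               method = c("wavelet", "zero_crossing",
                                          "peak_interval"),
                               freqs = seq(90, 200, by = 1)) {
  stopifnot(is(filtered, "LFPRecording"))
  method <- match.arg(method)
  fs <- samplingRate(filtered)
  x <- traceSamples(filtered)
  n <- length(x)
  margin <- if (method == "wavelet") ceiling(3.5 * sqrt(5) / min(freqs) * fs) else 0L
  cf <- vapply(seq_len(nrow(events)), function(i) {
    i1 <- max(1L, round(events$start[i] * fs) + 1L)
    i2 <- min(n, round(events$end[i] * fs) + 1L)
    if (method == "wavelet") {
      j1 <- max(1L, i1 - margin)
      j2 <- min(n, i2 + margin)
      W <- morletCWT(x[j1:j2], fs, freqs)
      inside <- (i1:i2) - j1 + 1L
      mag <- abs(W[, inside, drop = FALSE])
      freqs[which.max(apply(mag, 1L, max))]
    } else if (method == "zero_crossing") {
      coreFreqZeroCrossing(x[i1:i2], fs)
    } else {
      coreFreqPeakInterval(x[i1:i2], fs)
    }
  }, numeric(1))
  events$core_freq <- cf
  events
}

#' Compare core frequencies of events with vs without spikes
#'
#' Partitions the events by the presence of at least one spike of the cell
#' and compares the two core-frequency samples with a rank-based two-sample
#' test.  The partitions are independent event sets, so the default is the
#' unpaired rank-sum (Mann-Whitney) test; a paired signed-rank variant is
#' available but requires equal-sized partitions.
#'
#' @param events events data.frame with \code{core_freq} filled.
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param test \code{"ranksum"} (default) or \code{"signedrank"}.
#' @return list with class \code{"coreFrequencyComparison"}: per-partition
#'   frequencies, means, SDs, n, p, test name, and \code{testable}.
#' @export
compareSpikeConditioned <- function(events, spikes,
                                    test = c("ranksum", "signedrank")) {
  stopifnot(is(spikes, "SpikeTrain"))
  test <- match.arg(test)
  if (is.null(events$core_freq) || anyNA(events$core_freq)) {
    rpStop("events must carry core_freq (run addCoreFrequencies first)")
  }
  st <- spikeTimes(spikes)
  has <- vapply(seq_len(nrow(events)), function(i) {
    any(st >= events$start[i] & st <= events$end[i])
  }, logical(1))
  fWith <- events$core_freq[has]
  fWithout <- events$core_freq[!has]
  testable <- length(fWith) >= 2L && length(fWithout) >= 2L
  p <- NA_real_
  if (testable) {
    p <- if (test == "ranksum") {
      stats::wilcox.test(fWith, fWithout, exact = FALSE)$p.value
    } else {
      if (length(fWith) != length(fWithout)) {
        rpStop("signed-rank test requires equal-sized partitions")
      }
      stats::wilcox.test(fWith, fWithout, paired = TRUE, exact = FALSE)$p.value
    }
  }
  structure(list(
    withSpikes = fWith, withoutSpikes = fWithout,
    meanWith = mean(fWith), sdWith = stats::sd(fWith),
    meanWithout = mean(fWithout), sdWithout = stats::sd(fWithout),
    nWith = length(fWith), nWithout = length(fWithout),
    p = p, test = test, testable = testable),
    class = "coreFrequencyComparison")
}

#' @export
print.coreFrequencyComparison <- function(x, ...) {
  cat(sprintf(
    "coreFrequencyComparison: with spikes %.1f +/- %.1f Hz (n = %d), without %.1f +/- %.1f Hz (n = %d)",
    x$meanWith, x$sdWith, x$nWith, x$meanWithout, x$sdWithout, x$nWithout))
  if (x$testable) cat(sprintf(", p = %.4g (%s)", x$p, x$test))
  else cat(" [not testable]")
  cat("\n")
  invisible(x)
}
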