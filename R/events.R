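# Behavioral-state segmentation, dual-threshold transient-event detection,
# cycle-landmark location, and peri-event window construction.

#' Segment behavior into run and rest epochs
#'
#' Thresholds the speed trace and keeps only episodes long enough for
#' analysis: running episodes must exceed \code{minRun} seconds and resting
#' episodes \code{minRest} seconds (sub-minimum episodes are discarded, not
#' merged).
#'
#' @param speed a \linkS4class{SpeedTrace}.
#' @param speedThreshold run/rest boundary in speed units (default 1; real
#'   recordings need a rig-specific value).
#' @param minRun,minRest minimum episode durations in seconds (defaults 20
#'   and 200).
#' @return A list with class \code{"behaviorEpochs"}: \code{run} and
#'   \code{rest} interval matrices plus the parameters used.
#' @export
segmentBehavior <- function(speed, speedThreshold = 1, minRun = 20,
                            minRest = 200) {
  stopifnot(is(speed, "SpeedTrace"))
  x <- traceSamples(speed)
  if (!length(x)) rpStop("empty speed trace")
  fs <- samplingRate(speed)
  isRun <- x > speedThreshold
  r <- rle(isRun)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  iv <- cbind((starts - 1L) / fs, ends / fs)
  durs <- iv[, 2L] - iv[, 1L]
  run <- iv[r$values & durs > minRun, , drop = FALSE]
  rest <- iv[!r$values & durs > minRest, , drop = FALSE]
  structure(list(run = run, rest = rest, speedThreshold = speedThreshold,
                 minRun = minRun, minRest = minRest),
            class = "behaviorEpochs")
}

#' @export
print.behaviorEpochs <- function(x, ...) {
  cat(sprintf("behaviorEpochs: %d run (>%g s), %d rest (>%g s)\n",
              nrow(x$run), x$minRun, nrow(x$rest), x$minRest))
  invisible(x)
}

#' Detection parameters for transient oscillation events
#'
#' @param band oscillation band searched (default ripple, 90-200 Hz).
#' @param highThreshold detection threshold in envelope SD units above the
#'   mean envelope (default 5).
#' @param edgeThreshold boundary threshold in SD units (default 2); events
#'   extend outward to these crossings.
#' @param minDuration minimum event duration in seconds (default 0.015,
#'   two cycles at the ripple-band center; the 2 SD span of the shortest
#'   ~40 ms ripples is only ~20 ms, so a longer minimum discards real
#'   events).
#' @param mergeGap events separated by less than this (s) are merged
#'   (default 0.01); prevents double-counting envelope dips inside one
#'   event.
#' @return A list with class \code{"detectionParams"}.
#' @export
detectionParams <- function(band = oscillationBands("ripple"),
                            highThreshold = 5, edgeThreshold = 2,
                            minDuration = 0.015, mergeGap = 0.01) {
  if (!(highThreshold > edgeThreshold && edgeThreshold > 0)) {
    rpStop("need highThreshold > edgeThreshold > 0")
  }
  structure(list(band = band, highThreshold = highThreshold,
                 edgeThreshold = edgeThreshold, minDuration = minDuration,
                 mergeGap = mergeGap),
            class = "detectionParams")
}

#' Dual-threshold event detection on a z-scored envelope
#'
#' Low-level detector used by \code{\link{detectEvents}}: on an envelope
#' expressed in SD units, an event is a contiguous excursion at or above
#' \code{edge} containing at least one sample at or above \code{high}.
#' Excursions closer than \code{mergeGap} are merged; events shorter than
#' \code{minDuration} are dropped.
#'
#' @param z numeric envelope in SD units.
#' @param fs sampling rate (Hz).
#' @param high,edge thresholds in SD units.
#' @param mergeGap,minDuration in seconds.
#' @param t0 time of the first sample (s).
#' @return data.frame(start, end, peak_time, peak_amplitude, core_freq=NA).
#' @export
thresholdEvents <- function(z, fs, high = 5, edge = 2, mergeGap = 0.01,
                            minDuration = 0.02, t0 = 0) {
  if (high <= edge) rpStop("need high > edge")
  above <- !is.na(z) & z >= edge
  if (!any(above)) return(emptyEvents())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg <- cbind(starts[r$values], ends[r$values])
  # keep excursions that reach the high threshold
  keep <- vapply(seq_len(nrow(seg)), function(i) {
    max(z[seg[i, 1L]:seg[i, 2L]]) >= high
  }, logical(1))
  seg <- seg[keep, , drop = FALSE]
  if (!nrow(seg)) return(emptyEvents())
  # merge excursions separated by less than mergeGap
  gapN <- mergeGap * fs
  merged <- seg[1L, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1L]) {
    if (seg[i, 1L] - merged[nrow(merged), 2L] - 1L < gapN) {
      merged[nrow(merged), 2L] <- seg[i, 2L]
    } else {
      merged <- rbind(merged, seg[i, ])
    }
  }
  out <- lapply(seq_len(nrow(merged)), function(i) {
    i1 <- merged[i, 1L]; i2 <- merged[i, 2L]
    pk <- i1 - 1L + which.max(z[i1:i2])
    data.frame(start = t0 + (i1 - 1L) / fs, end = t0 + (i2 - 1L) / fs,
               peak_time = t0 + (pk - 1L) / fs, peak_amplitude = z[pk],
               core_freq = NA_real_)
  })
  ev <- do.call(rbind, out)
  ev <- ev[ev$end - ev$start >= minDuration, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

emptyEvents <- function() {
  data.frame(start = numeric(0), end = numeric(0), peak_time = numeric(0),
             peak_amplitude = numeric(0), core_freq = numeric(0))
}

#' Detect transient high-frequency events
#'
#' Band-passes the raw trace, extracts the envelope, and normalizes it to
#' SD units using the mean and SD of the envelope within the supplied
#' epochs.  Events are envelope excursions reaching
#' \code{highThreshold} SD, extended outward to the
#' \code{edgeThreshold} SD crossings.  Because the thresholds are relative,
#' detections are invariant to rescaling the raw trace.
#'
#' @param lfp raw \linkS4class{LFPRecording}.
#' @param epochs behavioral-state intervals to search (and over which the
#'   baseline is computed); a matrix, a \code{behaviorEpochs} (its rest
#'   intervals are used), or NULL for the whole trace.
#' @param params a \code{\link{detectionParams}}.
#' @return data.frame of events (start, end, peak_time, peak_amplitude in
#'   SD units, core_freq = NA), sorted by start, with attributes
#'   \code{baselineMean}, \code{baselineSD} (envelope units) and \code{fs}.
#' @export
detectEvents <- function(lfp, epochs = NULL, params = detectionParams()) {
  stopifnot(is(lfp, "LFPRecording"))
  fs <- samplingRate(lfp)
  if (inherits(epochs, "behaviorEpochs")) epochs <- epochs$rest
  if (is.null(epochs)) epochs <- matrix(c(0, duration(lfp)), ncol = 2L)
  epochs <- validateIntervals(epochs, "epochs")
  if (nrow(epochs) == 0L) rpStop("no epochs supplied")
  if (min(epochs) < -1e-9 || max(epochs) > duration(lfp) + 1e-9) {
    rpStop("epochs extend outside the trace")
  }
  filt <- bandpassFilter(lfp, params$band)
  env <- traceSamples(signalEnvelope(filt))
  t <- sampleTimes(lfp)
  keep <- inIntervals(t, epochs)
  mu <- mean(env[keep])
  sd0 <- stats::sd(env[keep])
  if (!is.finite(sd0) || sd0 <= 0) rpStop("degenerate envelope baseline")
  z <- (env - mu) / sd0
  z[!keep] <- NA_real_   # search only inside the supplied epochs
  ev <- thresholdEvents(z, fs, params$highThreshold, params$edgeThreshold,
                        params$mergeGap, params$minDuration)
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "baselineMean") <- mu
  attr(ev, "baselineSD") <- sd0
  attr(ev, "fs") <- fs
  ev
}

#' Peri-event windows (before / during / after)
#'
#' For each event of duration d, the before window is [start - 2d, start)
#' and the after window (end, end + 2d], i.e. twice the event duration on
#' each side.  Windows truncated at the trace edges, or overlapping a
#' neighboring event's window, are flagged but preserved.
#'
#' @param events events data.frame (start, end), sorted by start.
#' @param traceDuration total trace duration (s); windows beyond
#'   [0, traceDuration] are flagged truncated.
#' @return data.frame with before/after window bounds and flags.
#' @export
periEventWindows <- function(events, traceDuration = Inf) {
  if (is.unsorted(events$start)) rpStop("events must be sorted by start")
  d <- events$end - events$start
  out <- data.frame(
    event = seq_len(nrow(events)),
    before_start = events$start - 2 * d, before_end = events$start,
    during_start = events$start, during_end = events$end,
    after_start = events$end, after_end = events$end + 2 * d
  )
  out$truncated <- out$before_start < 0 | out$after_end > traceDuration
  ne <- nrow(events)
  overlaps <- rep(FALSE, ne)
  if (ne > 1L) {
    overlaps <- out$before_start < c(-Inf, out$after_end[-ne]) |
      out$after_end > c(out$before_start[-1L], Inf)
  }
  out$overlapping <- overlaps
  out
}

#' Locate cycle landmarks (troughs and peaks)
#'
#' Local minima (troughs) and maxima (peaks) of a band-passed trace,
#' returned strictly interleaved: between two consecutive troughs there is
#' exactly one peak and vice versa (when several same-type extrema occur in
#' a row, the most extreme one is kept).
#'
#' @param filtered band-passed \linkS4class{LFPRecording}.
#' @return list(troughs, peaks) of times in seconds.
#' @export
findCycleLandmarks <- function(filtered) {
  stopifnot(is(filtered, "LFPRecording"))
  x <- traceSamples(filtered)
  fs <- samplingRate(filtered)
  d <- diff(x)
  s <- sign(d)
  # carry forward the sign over flat stretches
  nz <- s != 0
  if (!any(nz)) return(list(troughs = numeric(0), peaks = numeric(0)))
  idx <- cummax(seq_along(s) * nz)    # last non-zero sign at or before i
  idx[idx == 0L] <- which(nz)[1L]
  s <- s[idx]
  turn <- which(diff(s) != 0) + 1L    # index into x of the extremum
  if (!length(turn)) return(list(troughs = numeric(0), peaks = numeric(0)))
  isPeak <- s[turn - 1L] > 0
  # enforce strict alternation: among consecutive same-type extrema keep the
  # most extreme one
  keep <- rep(TRUE, length(turn))
  lastKept <- 1L
  for (i in seq_along(turn)[-1L]) {
    if (isPeak[i] == isPeak[lastKept]) {
      better <- if (isPeak[i]) x[turn[i]] > x[turn[lastKept]] else
        x[turn[i]] < x[turn[lastKept]]
      if (better) {
        keep[lastKept] <- FALSE
        lastKept <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      lastKept <- i
    }
  }
  turn <- turn[keep]
  isPeak <- isPeak[keep]
  list(troughs = (turn[!isPeak] - 1L) / fs,
       peaks = (turn[isPeak] - 1L) / fs)
}
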