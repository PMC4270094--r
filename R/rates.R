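# Firing rates by state and event, randomization significance tests,
# participation and early-spike fractions, doublet detection, and
# normalized peri-event histograms.

#' Mean firing rate over intervals
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param intervals (start, end) intervals; rate = spike count inside /
#'   total interval duration.
#' @return Rate in Hz.
#' @export
firingRate <- function(spikes, intervals) {
  stopifnot(is(spikes, "SpikeTrain"))
  iv <- validateIntervals(intervals, "intervals")
  tot <- intervalTotal(iv)
  if (tot <= 0) rpStop("total interval duration must be > 0")
  sum(inIntervals(spikeTimes(spikes), iv)) / tot
}

#' Randomization test of event-related rate modulation
#'
#' Compares the observed within-event firing rate against a Monte-Carlo
#' null built either by redrawing every spike time uniformly within the
#' behavioral-state intervals (\code{"spike_shuffle"}, preserving spike
#' count) or by uniformly repositioning the events within those intervals
#' (\code{"event_shuffle"}, preserving event durations and non-overlap).
#' The two-sided p-value doubles the more extreme tail with the add-one
#' floor \eqn{p = (k+1)/(N+1)}, capped at 1, where k counts surrogates at
#' least as extreme as the observation.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param events events data.frame (start, end) inside the state intervals.
#' @param stateIntervals behavioral-state intervals (start, end).
#' @param mode \code{"spike_shuffle"} (default) or \code{"event_shuffle"}.
#' @param nSurrogates number of surrogates (>= 100; default 1000).
#' @param seed RNG seed, recorded in the output.
#' @param alpha significance level used to call the direction.
#' @return list with class \code{"rateModulationResult"}: rateIn, rateOut
#'   (Hz), p, direction ("increase"/"decrease"/"none"), nSurrogates, seed.
#' @export
eventRateModulation <- function(spikes, events, stateIntervals,
                                mode = c("spike_shuffle", "event_shuffle"),
                                nSurrogates = 1000, seed = 1, alpha = 0.05) {
  stopifnot(is(spikes, "SpikeTrain"))
  mode <- match.arg(mode)
  if (nSurrogates < 100) rpStop("nSurrogates < 100 is underpowered; use >= 100")
  iv <- validateIntervals(stateIntervals, "stateIntervals")
  if (!nrow(events)) rpStop("no events supplied")
  evIv <- cbind(events$start, events$end)
  if (!all(inIntervals(events$start, iv) & inIntervals(events$end, iv))) {
    rpStop("events must lie within the state intervals")
  }
  T <- intervalTotal(iv)
  evDur <- sum(evIv[, 2L] - evIv[, 1L])
  outDur <- T - evDur
  st <- spikeTimes(spikes)
  st <- st[inIntervals(st, iv)]
  n <- length(st)
  # work in the concatenated state-time coordinate so surrogate placement is
  # uniform over the state regardless of interval fragmentation
  u <- toConcatTime(st, iv)
  evU <- cbind(toConcatTime(evIv[, 1L], iv), toConcatTime(evIv[, 2L], iv))
  evU <- evU[order(evU[, 1L]), , drop = FALSE]
  bounds <- as.vector(t(evU))        # sorted event boundaries in [0, T]
  countIn <- function(times) {
    idx <- findInterval(times, bounds)
    sum(idx %% 2L == 1L)
  }
  obsIn <- countIn(u)
  rateIn <- obsIn / evDur
  rateOut <- if (outDur > 0) (n - obsIn) / outDur else NA_real_
  durs <- evU[, 2L] - evU[, 1L]
  ne <- length(durs)
  surr <- withSeed(seed, {
    if (mode == "spike_shuffle") {
      m <- matrix(stats::runif(nSurrogates * n, 0, T), nrow = nSurrogates)
      idx <- matrix(findInterval(m, bounds), nrow = nSurrogates)
      rowSums(idx %% 2L == 1L)
    } else {
      vapply(seq_len(nSurrogates), function(s) {
        gaps <- sort(stats::runif(ne, 0, T - sum(durs)))
        starts <- gaps + c(0, cumsum(durs))[seq_len(ne)]
        b <- as.vector(rbind(starts, starts + durs))
        sum(findInterval(u, b) %% 2L == 1L)
      }, numeric(1))
    }
  })
  kHi <- sum(surr >= obsIn)
  kLo <- sum(surr <= obsIn)
  p <- min(1, 2 * (min(kHi, kLo) + 1) / (nSurrogates + 1))
  direction <- if (p < alpha) {
    if (obsIn > mean(surr)) "increase" else "decrease"
  } else "none"
  structure(list(rateIn = rateIn, rateOut = rateOut, p = p,
                 direction = direction, nSurrogates = nSurrogates,
                 seed = seed, mode = mode, nSpikes = n),
            class = "rateModulationResult")
}

#' @export
print.rateModulationResult <- function(x, ...) {
  cat(sprintf(
    "rateModulationResult (%s): in %.2f Hz, out %.2f Hz, p = %.4g (%s)\n",
    x$mode, x$rateIn, x$rateOut, x$p, x$direction))
  invisible(x)
}

#' Event participation fraction
#'
#' Fraction of events during which the cell fired at least one spike.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param events events data.frame (start, end); at least one event.
#' @return Fraction in [0, 1].
#' @export
participationFraction <- function(spikes, events) {
  stopifnot(is(spikes, "SpikeTrain"))
  if (!nrow(events)) rpStop("need at least one event")
  st <- spikeTimes(spikes)
  has <- vapply(seq_len(nrow(events)), function(i) {
    any(st >= events$start[i] & st <= events$end[i])
  }, logical(1))
  mean(has)
}

#' Early-spike fraction
#'
#' Fraction of in-event spikes fired before the event's envelope peak,
#' pooled over events (events without spikes are ignored).  A symmetric
#' envelope with phase-independent spiking gives about 0.5.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param events events data.frame with columns start, end, peak_time.
#' @return Fraction in [0, 1]; NA with a warning when no in-event spikes.
#' @export
earlySpikeFraction <- function(spikes, events) {
  stopifnot(is(spikes, "SpikeTrain"))
  if (is.null(events$peak_time)) rpStop("events must carry peak_time")
  st <- spikeTimes(spikes)
  nEarly <- 0L; nTot <- 0L
  for (i in seq_len(nrow(events))) {
    inEv <- st >= events$start[i] & st <= events$end[i]
    nTot <- nTot + sum(inEv)
    nEarly <- nEarly + sum(st[inEv] < events$peak_time[i])
  }
  if (nTot == 0L) {
    warning("no in-event spikes; early-spike fraction undefined")
    return(NA_real_)
  }
  nEarly / nTot
}

#' Detect doublet firing within event cycles
#'
#' A doublet is two or more spikes between two consecutive troughs of the
#' ripple-band trace inside an event (trough-to-trough being the unique
#' parameter-free cycle partition consistent with the 0-degrees-at-trough
#' convention).
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param events events data.frame (start, end).
#' @param rippleFiltered ripple-band-passed \linkS4class{LFPRecording}.
#' @return list(doubletFraction = fraction of events containing >= 1
#'   doublet, intraEventRate = pooled in-event firing rate in Hz,
#'   perEventDoublets = integer doublet-cycle count per event).
#' @export
detectDoublets <- function(spikes, events, rippleFiltered) {
  stopifnot(is(spikes, "SpikeTrain"), is(rippleFiltered, "LFPRecording"))
  troughs <- findCycleLandmarks(rippleFiltered)$troughs
  st <- spikeTimes(spikes)
  ne <- nrow(events)
  perEvent <- integer(ne)
  nIn <- 0L
  for (i in seq_len(ne)) {
    tin <- troughs[troughs >= events$start[i] & troughs <= events$end[i]]
    sIn <- st[st >= events$start[i] & st <= events$end[i]]
    nIn <- nIn + length(sIn)
    if (length(tin) < 2L || !length(sIn)) next
    counts <- tabulate(findInterval(sIn, tin), length(tin) - 1L)
    perEvent[i] <- sum(counts >= 2L)
  }
  totDur <- sum(events$end - events$start)
  list(doubletFraction = if (ne) mean(perEvent >= 1L) else NA_real_,
       intraEventRate = if (totDur > 0) nIn / totDur else NA_real_,
       perEventDoublets = perEvent)
}

#' Normalized peri-event histogram (40 / 20 / 40 bins)
#'
#' Spiking per normalized-time bin before, during and after each event: the
#' before span (twice the event duration) is divided into 40 bins, the
#' event span into 20, and the after span into 40.  Each bin value is the
#' mean spike count per event in that bin, so the sum over the 20 "during"
#' bins equals the mean in-event spike count per event.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param events events data.frame (start, end); >= 1 event.
#' @return list with class \code{"periEventHistogram"}: \code{value}
#'   (length 100), \code{span} (factor before/during/after), \code{nEvents}.
#' @export
periEventHistogram <- function(spikes, events) {
  stopifnot(is(spikes, "SpikeTrain"))
  ne <- nrow(events)
  if (!ne) rpStop("need at least one event")
  st <- spikeTimes(spikes)
  acc <- numeric(100L)
  for (i in seq_len(ne)) {
    s <- events$start[i]; e <- events$end[i]; d <- e - s
    edges <- c(seq(s - 2 * d, s, length.out = 41L),
               seq(s, e, length.out = 21L)[-1L],
               seq(e, e + 2 * d, length.out = 41L)[-1L])
    sp <- st[st >= edges[1L] & st < edges[101L]]
    if (length(sp)) {
      acc <- acc + tabulate(findInterval(sp, edges), 100L)
    }
  }
  structure(list(value = acc / ne,
                 span = factor(rep(c("before", "during", "after"),
                                   c(40L, 20L, 40L)),
                               levels = c("before", "during", "after")),
                 nEvents = ne),
            class = "periEventHistogram")
}

#' @export
print.periEventHistogram <- function(x, ...) {
  m <- tapply(x$value, x$span, sum)
  cat(sprintf(
    "periEventHistogram over %d events: mean spikes before/during/after = %.2f/%.2f/%.2f\n",
    x$nEvents, m["before"], m["during"], m["after"]))
  invisible(x)
}
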