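# Synthetic LFP / speed / spike-train generator with known ground truth.
# The generator emulates the statistical structure the analysis assumes:
# 1/f background, running-associated theta with theta-phase-coupled fast
# (epsilon-band) power, transient high-frequency ripple events during rest,
# and spike trains that are von Mises phase-locked with event-gated rate
# gains (including doublet firing).

#' Simulation configuration
#'
#' @param duration trace duration in seconds (> 0).
#' @param fs sampling rate in Hz.  Default 1250 Hz: comfortably above twice
#'   the fastest analysed frequency (200 Hz) while keeping desk-scale
#'   simulations light; recordings sampled at 12-20 kHz are handled by the same code; all
#'   operations are rate-agnostic.
#' @param seed integer RNG seed; identical seeds give bit-identical traces.
#' @param noiseExponent slope alpha of the 1/f^alpha background (default 1).
#' @param noiseScale background RMS amplitude in mV (default 0.05).
#' @return A validated list with class \code{"simConfig"}.
#' @export
simConfig <- function(duration, fs = 1250, seed = 1, noiseExponent = 1,
                      noiseScale = 0.05) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    rpStop("'duration' must be a single positive number of seconds")
  }
  if (!is.numeric(fs) || fs <= 0) rpStop("'fs' must be positive")
  if (noiseScale < 0) rpStop("'noiseScale' must be >= 0")
  structure(list(duration = duration, fs = fs, seed = as.integer(seed),
                 noiseExponent = noiseExponent, noiseScale = noiseScale),
            class = "simConfig")
}

#' Generate 1/f background LFP
#'
#' Spectrally shaped Gaussian noise: white noise is shaped in the frequency
#' domain by f^(-alpha/2) and rescaled to the requested RMS.  The log-log
#' power spectrum then has slope approximately -alpha.
#'
#' @param config a \code{\link{simConfig}}.
#' @return An \linkS4class{LFPRecording} of \code{duration * fs} samples.
#' @examples
#' lfp <- generateBackgroundLFP(simConfig(2, fs = 500, seed = 1))
#' @export
generateBackgroundLFP <- function(config) {
  if (!inherits(config, "simConfig")) rpStop("'config' must be a simConfig")
  n <- round(config$duration * config$fs)
  if (n < 2L) rpStop("duration x fs must give at least 2 samples")
  if (config$noiseScale == 0) {
    return(LFPRecording(numeric(n), config$fs))
  }
  x <- withSeed(config$seed, {
    white <- stats::rnorm(n)
    X <- stats::fft(white)
    k <- seq_len(n) - 1L
    kfold <- pmin(k, n - k)              # two-sided frequency index
    f <- kfold * config$fs / n
    shape <- numeric(n)
    shape[f > 0] <- f[f > 0]^(-config$noiseExponent / 2)
    y <- Re(stats::fft(X * shape, inverse = TRUE) / n)
    y * config$noiseScale / sqrt(mean(y^2))
  })
  LFPRecording(x, config$fs)
}

#' Define a rhythm to plant
#'
#' @param bandName label for the rhythm (e.g. "theta", "epsilon").
#' @param centerFreq oscillation frequency in Hz.
#' @param amplitude peak amplitude in mV.
#' @param epochs (start, end) intervals in seconds where the rhythm is
#'   present; must be disjoint and inside the trace.
#' @param coupling optional list \code{(carrier, preferredCarrierPhase,
#'   modulationDepth)}: the rhythm's amplitude is modulated by the phase of
#'   the named carrier rhythm, maximal at \code{preferredCarrierPhase}
#'   (degrees) with depth in [0, 1] (1 = fully suppressed at the
#'   anti-preferred phase).  This emulates fast oscillations nested at a
#'   fixed phase of a slower carrier.
#' @return A list with class \code{"plantedRhythm"}.
#' @export
plantedRhythm <- function(bandName, centerFreq, amplitude, epochs,
                          coupling = NULL) {
  epochs <- validateIntervals(epochs, paste0("epochs of rhythm '", bandName, "'"))
  if (centerFreq <= 0) rpStop("centerFreq must be positive")
  if (amplitude < 0) rpStop("amplitude must be >= 0")
  if (!is.null(coupling)) {
    need <- c("carrier", "preferredCarrierPhase", "modulationDepth")
    if (!all(need %in% names(coupling))) {
      rpStop("coupling needs fields: ", paste(need, collapse = ", "))
    }
    if (coupling$modulationDepth < 0 || coupling$modulationDepth > 1) {
      rpStop("modulationDepth must be in [0, 1]")
    }
  }
  structure(list(bandName = as.character(bandName), centerFreq = centerFreq,
                 amplitude = amplitude, epochs = epochs, coupling = coupling),
            class = "plantedRhythm")
}

#' Plant rhythms into a trace
#'
#' Adds each rhythm as a sinusoid (trough at epoch onset, matching the
#' 0-degrees-at-trough phase convention) within its epochs.  A coupled
#' rhythm's amplitude follows
#' \eqn{A (1 - m (1 - \cos(\phi_c - \phi_{pref})) / 2)} where \eqn{\phi_c}
#' is the carrier's ground-truth phase, so the fast envelope is maximal at
#' the preferred carrier phase.  Carriers must precede the rhythms coupled
#' to them in \code{rhythms}.
#'
#' @param lfp an \linkS4class{LFPRecording}.
#' @param rhythms list of \code{\link{plantedRhythm}} objects.
#' @return A list with elements \code{lfp} (trace with rhythms added) and
#'   \code{truth} (a \code{groundTruth} carrying the rhythm parameters;
#'   per-sample phase is reconstructed on demand by
#'   \code{\link{truthPhase}}).
#' @export
plantRhythms <- function(lfp, rhythms) {
  stopifnot(is(lfp, "LFPRecording"))
  if (inherits(rhythms, "plantedRhythm")) rhythms <- list(rhythms)
  fs <- samplingRate(lfp)
  dur <- duration(lfp)
  x <- traceSamples(lfp)
  t <- sampleTimes(lfp)
  planted <- list()
  for (r in rhythms) {
    if (!inherits(r, "plantedRhythm")) rpStop("rhythms must be plantedRhythm objects")
    if (r$centerFreq >= fs / 2) {
      rpStop("rhythm '", r$bandName, "' frequency ", r$centerFreq,
             " Hz is at or above Nyquist")
    }
    if (nrow(r$epochs) && max(r$epochs) > dur + 1e-9) {
      rpStop("epochs of rhythm '", r$bandName, "' extend beyond the trace")
    }
    phase <- rhythmPhaseVector(r, t)
    ampVal <- rep(r$amplitude, length(t))
    if (!is.null(r$coupling)) {
      carrier <- planted[[r$coupling$carrier]]
      if (is.null(carrier)) {
        rpStop("carrier rhythm '", r$coupling$carrier,
               "' must be planted before '", r$bandName, "'")
      }
      cph <- rhythmPhaseVector(carrier, t)
      m <- r$coupling$modulationDepth
      dphi <- degToRad(cph - r$coupling$preferredCarrierPhase)
      ampVal <- r$amplitude * (1 - m * (1 - cos(dphi)) / 2)
      ampVal[is.na(cph)] <- r$amplitude   # outside carrier epochs: unmodulated
    }
    inEp <- !is.na(phase)
    x[inEp] <- x[inEp] - ampVal[inEp] * cos(degToRad(phase[inEp]))
    planted[[r$bandName]] <- r
  }
  truth <- structure(list(rhythms = planted, events = NULL, cells = list()),
                     class = "groundTruth")
  list(lfp = LFPRecording(x, fs), truth = truth)
}

# Ground-truth phase (degrees, trough = 0) of a planted rhythm at times t;
# NA outside its epochs.  Phase restarts at 0 (a trough) at each epoch onset.
rhythmPhaseVector <- function(rhythm, t) {
  ph <- rep(NA_real_, length(t))
  ep <- rhythm$epochs
  for (i in seq_len(nrow(ep))) {
    inEp <- t >= ep[i, 1L] & t < ep[i, 2L]
    ph[inEp] <- wrapDeg(360 * rhythm$centerFreq * (t[inEp] - ep[i, 1L]))
  }
  ph
}

#' Ground-truth phase series
#'
#' Reconstructs the per-sample phase (degrees, trough = 0) of a planted
#' rhythm, or of planted events (phase within each event, NA elsewhere).
#'
#' @param truth a \code{groundTruth} from \code{\link{plantRhythms}} or
#'   \code{\link{plantEvents}}.
#' @param what a rhythm band name, or \code{"events"}.
#' @param t sample times in seconds.
#' @return Numeric degrees in [0, 360) or NA.
#' @export
truthPhase <- function(truth, what, t) {
  if (!inherits(truth, "groundTruth")) rpStop("'truth' must be a groundTruth")
  if (identical(what, "events")) {
    ev <- truth$events
    if (is.null(ev)) rpStop("ground truth holds no events")
    ph <- rep(NA_real_, length(t))
    for (i in seq_len(nrow(ev))) {
      inEv <- t >= ev$start[i] & t < ev$end[i]
      ph[inEv] <- wrapDeg(360 * ev$core_freq[i] * (t[inEv] - ev$start[i]))
    }
    return(ph)
  }
  r <- truth$rhythms[[what]]
  if (is.null(r)) rpStop("no planted rhythm named '", what, "'")
  rhythmPhaseVector(r, t)
}

#' Define a transient event to plant
#'
#' @param start onset time (s).
#' @param duration event duration (s); default admissible range 0.04-0.15 s
#'   matches the reported span of sharp-wave ripples.
#' @param coreFreq intra-event oscillation frequency (Hz), 90-200 Hz.
#' @param peakAmplitude envelope peak in mV.
#' @param envelope envelope shape; only \code{"hann"} is provided (smooth
#'   onset/offset so the 5 SD and 2 SD thresholds differ measurably).
#' @param durationRange,freqRange admissible ranges enforced on the event.
#' @return A list with class \code{"plantedEvent"}.
#' @export
plantedEvent <- function(start, duration, coreFreq, peakAmplitude,
                         envelope = "hann",
                         durationRange = c(0.04, 0.15),
                         freqRange = c(90, 200)) {
  if (duration < durationRange[1L] || duration > durationRange[2L]) {
    rpStop("event duration ", duration, " s outside admissible range [",
           durationRange[1L], ", ", durationRange[2L], "]")
  }
  if (coreFreq < freqRange[1L] || coreFreq > freqRange[2L]) {
    rpStop("event core frequency ", coreFreq, " Hz outside [",
           freqRange[1L], ", ", freqRange[2L], "] Hz")
  }
  if (peakAmplitude < 0) rpStop("peakAmplitude must be >= 0")
  if (!identical(envelope, "hann")) rpStop("only the 'hann' envelope is provided")
  structure(list(start = start, duration = duration, coreFreq = coreFreq,
                 peakAmplitude = peakAmplitude, envelope = envelope),
            class = "plantedEvent")
}

#' Plant transient events into a trace
#'
#' Each event adds a Hann-enveloped sinusoid at its core frequency (trough
#' at onset).  Events must lie inside the trace and must not overlap.
#'
#' @param lfp an \linkS4class{LFPRecording}.
#' @param events list of \code{\link{plantedEvent}} objects.
#' @return A list with elements \code{lfp} and \code{truth}; the ground
#'   truth's \code{events} data.frame records exact boundaries, core
#'   frequency and peak amplitude/time of every planted event.
#' @export
plantEvents <- function(lfp, events) {
  stopifnot(is(lfp, "LFPRecording"))
  if (inherits(events, "plantedEvent")) events <- list(events)
  fs <- samplingRate(lfp)
  dur <- duration(lfp)
  iv <- do.call(rbind, lapply(events, function(e) c(e$start, e$start + e$duration)))
  if (!is.null(iv)) {
    ivs <- iv[order(iv[, 1L]), , drop = FALSE]
    if (nrow(ivs) > 1L && any(ivs[-1L, 1L] < ivs[-nrow(ivs), 2L])) {
      rpStop("planted events must not overlap")
    }
    if (any(iv[, 1L] < 0) || any(iv[, 2L] > dur + 1e-9)) {
      rpStop("planted events must lie inside the trace")
    }
  }
  x <- traceSamples(lfp)
  t <- sampleTimes(lfp)
  rows <- vector("list", length(events))
  for (i in seq_along(events)) {
    e <- events[[i]]
    if (e$coreFreq >= fs / 2) rpStop("event core frequency at or above Nyquist")
    inEv <- t >= e$start & t < e$start + e$duration
    tau <- t[inEv] - e$start
    env <- 0.5 * (1 - cos(2 * pi * tau / e$duration))
    x[inEv] <- x[inEv] - e$peakAmplitude * env * cos(2 * pi * e$coreFreq * tau)
    rows[[i]] <- data.frame(start = e$start, end = e$start + e$duration,
                            peak_time = e$start + e$duration / 2,
                            peak_amplitude = e$peakAmplitude,
                            core_freq = e$coreFreq)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  truth <- structure(list(rhythms = list(), events = ev, cells = list()),
                     class = "groundTruth")
  list(lfp = LFPRecording(x, fs), truth = truth)
}

#' Envelope baseline of a band within epochs
#'
#' Mean and SD of the band-passed envelope over the supplied epochs - the
#' same baseline the dual-threshold detector uses.  Useful for planting
#' events at a prescribed height in detector SD units:
#' amplitude = mean + k * SD.
#'
#' @param lfp raw \linkS4class{LFPRecording}.
#' @param band oscillation band (default ripple).
#' @param epochs optional restriction intervals.
#' @return list(mean, sd) of the envelope.
#' @export
envelopeBaseline <- function(lfp, band = oscillationBands("ripple"),
                             epochs = NULL) {
  env <- traceSamples(signalEnvelope(bandpassFilter(lfp, band)))
  keep <- if (is.null(epochs)) rep(TRUE, length(env)) else {
    inIntervals(sampleTimes(lfp), validateIntervals(epochs))
  }
  list(mean = mean(env[keep]), sd = stats::sd(env[keep]))
}

#' Band-pass envelope gain of a Hann burst
#'
#' Peak of the band-passed envelope of a unit-amplitude Hann-enveloped
#' burst, relative to 1.  Short bursts and bursts near the band edges are
#' attenuated by the filter; dividing a desired in-band envelope height by
#' this gain gives the raw amplitude to plant so the event attains that
#' height in detector units.
#'
#' @param coreFreq burst carrier frequency (Hz).
#' @param durationS burst duration (s).
#' @param fs sampling rate (Hz).
#' @param band analysis band (default ripple).
#' @return Gain in (0, 1].
#' @export
burstBandGain <- function(coreFreq, durationS, fs,
                          band = oscillationBands("ripple")) {
  pad <- round(0.5 * fs)
  tt <- seq(0, durationS, by = 1 / fs)
  burst <- c(numeric(pad),
             0.5 * (1 - cos(2 * pi * tt / durationS)) *
               cos(2 * pi * coreFreq * tt),
             numeric(pad))
  filt <- bandpassFilter(LFPRecording(burst, fs), band)
  max(traceSamples(signalEnvelope(filt)))
}

#' Spike-train generative model
#'
#' @param baseRate baseline firing rate (Hz).
#' @param preferredPhase preferred oscillation phase (degrees).
#' @param kappa von Mises concentration (0 = no phase preference).
#' @param eventGain multiplicative rate factor inside events (default 1).
#' @param doubletProb probability per event cycle that the cycle's first
#'   spike is followed by a second spike 3-5 ms later.
#' @param refractory absolute refractory period in seconds (default 2 ms).
#' @return A list with class \code{"spikeModel"}.
#' @export
spikeModel <- function(baseRate, preferredPhase = 0, kappa = 0,
                       eventGain = 1, doubletProb = 0, refractory = 0.002) {
  if (baseRate < 0 || kappa < 0 || eventGain < 0) {
    rpStop("baseRate, kappa and eventGain must be >= 0")
  }
  if (!is.finite(baseRate) || !is.finite(kappa)) {
    rpStop("baseRate and kappa must be finite")
  }
  if (doubletProb < 0 || doubletProb > 1) rpStop("doubletProb must be in [0, 1]")
  structure(list(baseRate = baseRate, preferredPhase = preferredPhase,
                 kappa = kappa, eventGain = eventGain,
                 doubletProb = doubletProb, refractory = refractory),
            class = "spikeModel")
}

#' Generate a phase-locked spike train
#'
#' Inhomogeneous point process by thinning at the sampling resolution: the
#' rate is \code{baseRate * vonMises(phase; preferredPhase, kappa)}
#' (normalized so the cycle-averaged rate equals \code{baseRate}; where
#' phase is NA the modulation term is 1), multiplied by \code{eventGain}
#' inside events.  An absolute refractory period is enforced; doublets are
#' inserted as a second spike 3-5 ms after a cycle's first in-event spike
#' with probability \code{doubletProb} per event cycle.
#'
#' @param model a \code{\link{spikeModel}}.
#' @param fs sampling rate of the phase vector (Hz).
#' @param durationS length of the generated span in seconds (used when
#'   \code{phase} is NULL).
#' @param phase optional per-sample phase in degrees (NA where undefined),
#'   e.g. from \code{\link{truthPhase}}.
#' @param events optional events data.frame (columns start, end, core_freq)
#'   defining the event-gated span and the cycle partition for doublets.
#' @param seed RNG seed.
#' @param t0 time of the first sample (s), default 0.
#' @param cellId identifier stored in the returned train.
#' @return A \linkS4class{SpikeTrain}; attribute \code{"plantedDoublets"}
#'   records inserted doublet spikes per event, attribute \code{"truth"}
#'   the generating parameters.
#' @export
generateSpikes <- function(model, fs, durationS = NULL, phase = NULL,
                           events = NULL, seed = 1, t0 = 0, cellId = "cell") {
  if (!inherits(model, "spikeModel")) rpStop("'model' must be a spikeModel")
  if (is.null(phase)) {
    if (is.null(durationS)) rpStop("supply 'phase' or 'durationS'")
    n <- round(durationS * fs)
    phase <- rep(NA_real_, n)
  }
  n <- length(phase)
  t <- t0 + (seq_len(n) - 1L) / fs
  mod <- rep(1, n)
  if (model$kappa > 0) {
    ok <- !is.na(phase)
    mod[ok] <- exp(model$kappa * (cos(degToRad(phase[ok] - model$preferredPhase)) - 1)) /
      (besselI(model$kappa, 0, expon.scaled = TRUE))
  }
  rate <- model$baseRate * mod
  if (!is.null(events) && nrow(events)) {
    inEv <- inIntervals(t, cbind(events$start, events$end))
    rate[inEv] <- rate[inEv] * model$eventGain
  }
  p <- rate / fs
  if (any(p > 0.95)) {
    warning("thinning probability exceeds 0.95; increase fs for this rate")
    p <- pmin(p, 0.95)
  }
  res <- withSeed(seed, {
    u <- stats::runif(n)
    cand <- which(u < p)
    # jitter centered on the sample so the spike's phase is unbiased
    times <- t[cand] + (stats::runif(length(cand)) - 0.5) / fs
    times <- sort(pmax(times, t0))
    # refractory pruning
    if (length(times) > 1L && model$refractory > 0) {
      keep <- logical(length(times))
      last <- -Inf
      for (i in seq_along(times)) {
        if (times[i] - last >= model$refractory) {
          keep[i] <- TRUE
          last <- times[i]
        }
      }
      times <- times[keep]
    }
    doublets <- data.frame(event = integer(0), time = numeric(0))
    if (!is.null(events) && nrow(events) && model$doubletProb > 0 &&
        length(times)) {
      for (j in seq_len(nrow(events))) {
        evSpikes <- times[times >= events$start[j] & times <= events$end[j]]
        if (!length(evSpikes)) next
        cyc <- floor((evSpikes - events$start[j]) * events$core_freq[j])
        first <- evSpikes[!duplicated(cyc)]
        add <- first[stats::runif(length(first)) < model$doubletProb]
        if (length(add)) {
          extra <- add + stats::runif(length(add), 0.003, 0.005)
          doublets <- rbind(doublets,
                            data.frame(event = j, time = extra))
        }
      }
      times <- sort(c(times, doublets$time))
    }
    list(times = times, doublets = doublets)
  })
  st <- SpikeTrain(res$times, cellId)
  attr(st, "plantedDoublets") <- res$doublets
  attr(st, "truth") <- model
  st
}

#' Generate a piecewise run/rest speed trace
#'
#' Run segments sit above and rest segments below the default segmentation
#' threshold of 1 (speed units).
#'
#' @param segments list of \code{c(state, duration)} pairs or a data.frame
#'   with columns \code{state} ("run"/"rest") and \code{duration} (s).
#' @param fs sampling rate (Hz, default 50).
#' @param runSpeed,restSpeed speed values emitted in each state.
#' @return A \linkS4class{SpeedTrace}.
#' @examples
#' sp <- generateSpeedTrace(list(c("run", 30), c("rest", 250)))
#' duration(sp)
#' @export
generateSpeedTrace <- function(segments, fs = 50, runSpeed = 12,
                               restSpeed = 0.2) {
  if (is.data.frame(segments)) {
    segments <- lapply(seq_len(nrow(segments)),
                       function(i) c(segments$state[i], segments$duration[i]))
  }
  vals <- lapply(segments, function(s) {
    state <- as.character(s[[1L]])
    d <- as.numeric(s[[2L]])
    if (d <= 0) rpStop("segment durations must be positive")
    if (!state %in% c("run", "rest")) rpStop("segment state must be run or rest")
    rep(if (state == "run") runSpeed else restSpeed, round(d * fs))
  })
  SpeedTrace(unlist(vals), fs)
}

# ---- ground-truth serialization ---------------------------------------

#' Write / read ground truth
#'
#' Serializes a \code{groundTruth} (rhythm parameters, planted events,
#' per-cell generating models) as a structured YAML file.  Numerics are
#' written at 17 significant digits so the reloaded object is numerically
#' identical to the original.
#'
#' @param truth a \code{groundTruth}.
#' @param path file path.
#' @rdname groundTruthIO
#' @export
writeGroundTruth <- function(truth, path) {
  if (!inherits(truth, "groundTruth")) rpStop("'truth' must be a groundTruth")
  ser <- list(
    rhythms = lapply(truth$rhythms, function(r) {
      list(bandName = r$bandName, centerFreq = r$centerFreq,
           amplitude = r$amplitude,
           epochs = apply(r$epochs, 1L, as.numeric, simplify = FALSE),
           coupling = r$coupling)
    }),
    events = if (is.null(truth$events)) NULL else as.list(truth$events),
    cells = truth$cells
  )
  yaml::write_yaml(ser, path, precision = 17L)
  invisible(path)
}

#' @param path file path.
#' @rdname groundTruthIO
#' @export
readGroundTruth <- function(path) {
  ser <- yaml::read_yaml(path)
  rhythms <- lapply(ser$rhythms, function(r) {
    plantedRhythm(r$bandName, r$centerFreq, r$amplitude,
                  do.call(rbind, lapply(r$epochs, as.numeric)), r$coupling)
  })
  names(rhythms) <- vapply(rhythms, function(r) r$bandName, character(1))
  events <- if (is.null(ser$events)) NULL else as.data.frame(ser$events)
  structure(list(rhythms = rhythms, events = events, cells = ser$cells),
            class = "groundTruth")
}

#' Packaged cell metadata fixture
#'
#' The 27 in vivo juxtacellularly filled and anatomically identified PV
#' interneurons with their sub-class assignments (C-/H-BC, C-/O-Bistrat,
#' C-/E-AAC) and immunomarker test outcomes, as a validated data.frame.
#'
#' @return A data.frame of 27 \code{CellRecord} rows (see
#'   \code{\link{loadCellTable}} for the schema).
#' @examples
#' tab <- cellTableFixture()
#' table(tab$cell_class)
#' @export
cellTableFixture <- function() {
  loadCellTable(system.file("extdata", "pv_cell_table.tsv",
                            package = "ripplephase", mustWork = TRUE))
}
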