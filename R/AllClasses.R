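#' @import methods
NULL

# ---- LFPRecording ------------------------------------------------------

#' LFPRecording: a uniformly sampled voltage trace
#'
#' Container for a continuous local field potential (or unit-channel) trace:
#' a numeric sample vector plus its sampling rate in Hz.  All filtering,
#' envelope and detection operations act on this class.
#'
#' @slot samples numeric vector of voltages (mV).
#' @slot fs sampling rate in Hz.
#' @export
setClass("LFPRecording",
  representation(samples = "numeric", fs = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
      msg <- c(msg, "fs must be a single positive number")
    }
    if (length(object@samples) < 1L) {
      msg <- c(msg, "samples must be non-empty")
    }
    if (anyNA(object@samples)) msg <- c(msg, "samples must not contain NA")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an LFPRecording
#'
#' @param samples numeric voltage samples (mV).
#' @param fs sampling rate (Hz).
#' @return An \linkS4class{LFPRecording}.
#' @examples
#' lfp <- LFPRecording(sin(2 * pi * 8 * seq(0, 1, by = 1e-3)), fs = 1000)
#' duration(lfp)
#' @export
LFPRecording <- function(samples, fs) {
  new("LFPRecording", samples = as.numeric(samples), fs = as.numeric(fs))
}

#' SpeedTrace: treadmill speed signal
#'
#' Same layout as \linkS4class{LFPRecording}; values are speeds in the
#' recording rig's units (typically cm/s), used for run/rest segmentation.
#' @slot samples numeric speed samples.
#' @slot fs sampling rate in Hz.
#' @export
setClass("SpeedTrace", contains = "LFPRecording")

#' @rdname SpeedTrace-class
#' @param samples numeric speed samples.
#' @param fs sampling rate (Hz).
#' @export
SpeedTrace <- function(samples, fs) {
  new("SpeedTrace", samples = as.numeric(samples), fs = as.numeric(fs))
}

# ---- SpikeTrain --------------------------------------------------------

#' SpikeTrain: ordered spike timestamps of one cell
#'
#' @slot times strictly ordered spike times in seconds.
#' @slot cellId identifier of the recorded cell.
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", cellId = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@cellId) != 1L) msg <- c(msg, "cellId must be length 1")
    if (anyNA(object@times)) msg <- c(msg, "spike times must not contain NA")
    if (is.unsorted(object@times)) msg <- c(msg, "spike times must be ordered")
    if (length(object@times) && any(object@times < 0)) {
      msg <- c(msg, "spike times must be non-negative")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SpikeTrain
#'
#' @param times spike timestamps in seconds (sorted internally).
#' @param cellId cell identifier.
#' @return A \linkS4class{SpikeTrain}.
#' @export
SpikeTrain <- function(times, cellId = "cell") {
  new("SpikeTrain", times = sort(as.numeric(times)), cellId = as.character(cellId))
}

# ---- PhaseSeries -------------------------------------------------------

#' PhaseSeries: per-sample oscillation phase
#'
#' Phase in degrees on [0, 360) for every sample of a band-passed trace,
#' under the convention 0\eqn{^\circ} = trough, 180\eqn{^\circ} = peak
#' (ascending limb 0\eqn{\to}180, descending 180\eqn{\to}360).  Samples
#' before the first or after the last cycle landmark are NA (unusable).
#'
#' @slot phase numeric degrees in [0, 360) or NA per sample.
#' @slot fs sampling rate in Hz.
#' @slot band name of the source oscillation band.
#' @export
setClass("PhaseSeries",
  representation(phase = "numeric", fs = "numeric", band = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be positive")
    ph <- object@phase[!is.na(object@phase)]
    if (length(ph) && (any(ph < 0) || any(ph >= 360))) {
      msg <- c(msg, "phase values must lie in [0, 360)")
    }
    if (length(msg)) msg else TRUE
  }
)

PhaseSeries <- function(phase, fs, band = "band") {
  new("PhaseSeries", phase = as.numeric(phase), fs = as.numeric(fs),
      band = as.character(band))
}

# ---- TimeFrequencyMap --------------------------------------------------

#' TimeFrequencyMap: normalized narrow-band power
#'
#' Matrix of z-scored envelope power indexed by (center frequency, time),
#' as produced by \code{\link{filterbankPower}} and
#' \code{\link{triggeredAverage}}.
#'
#' @slot power numeric matrix, one row per center frequency.
#' @slot freqs center frequencies (Hz), length nrow(power).
#' @slot times time axis (s), length ncol(power).
#' @slot trigger description of the trigger used for averaging ("" if none).
#' @export
setClass("TimeFrequencyMap",
  representation(power = "matrix", freqs = "numeric", times = "numeric",
                 trigger = "character"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@power) != length(object@freqs)) {
      msg <- c(msg, "freqs length must match nrow(power)")
    }
    if (ncol(object@power) != length(object@times)) {
      msg <- c(msg, "times length must match ncol(power)")
    }
    if (length(msg)) msg else TRUE
  }
)

TimeFrequencyMap <- function(power, freqs, times, trigger = "") {
  new("TimeFrequencyMap", power = power, freqs = as.numeric(freqs),
      times = as.numeric(times), trigger = as.character(trigger))
}

# ---- generics and accessors -------------------------------------------

#' @rdname LFPRecording-class
#' @param object,x an object.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname LFPRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname LFPRecording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname LFPRecording-class
#' @export
setGeneric("traceSamples", function(x) standardGeneric("traceSamples"))
#' @rdname SpikeTrain-class
#' @param x a SpikeTrain.
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname SpikeTrain-class
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname SpikeTrain-class
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))
#' @rdname PhaseSeries-class
#' @param x a PhaseSeries.
#' @export
setGeneric("phaseDeg", function(x) standardGeneric("phaseDeg"))

#' @rdname LFPRecording-class
#' @export
setMethod("samplingRate", "LFPRecording", function(x) x@fs)
#' @rdname PhaseSeries-class
#' @export
setMethod("samplingRate", "PhaseSeries", function(x) x@fs)
#' @rdname LFPRecording-class
#' @export
setMethod("nSamples", "LFPRecording", function(x) length(x@samples))
#' @rdname LFPRecording-class
#' @export
setMethod("duration", "LFPRecording", function(x) length(x@samples) / x@fs)
#' @rdname LFPRecording-class
#' @export
setMethod("traceSamples", "LFPRecording", function(x) x@samples)
#' @rdname SpikeTrain-class
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
#' @rdname SpikeTrain-class
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))
#' @rdname SpikeTrain-class
#' @export
setMethod("cellId", "SpikeTrain", function(x) x@cellId)
#' @rdname PhaseSeries-class
#' @export
setMethod("phaseDeg", "PhaseSeries", function(x) x@phase)

# Sample times of a trace, starting at t = 0.
sampleTimes <- function(x) (seq_along(x@samples) - 1L) / x@fs

setMethod("show", "LFPRecording", function(object) {
  cat(sprintf("%s: %d samples @ %g Hz (%.3f s)\n", class(object),
              length(object@samples), object@fs,
              length(object@samples) / object@fs))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes", object@cellId, length(object@times)))
  if (length(object@times)) {
    cat(sprintf(" in [%.3f, %.3f] s", min(object@times), max(object@times)))
  }
  cat("\n")
})

setMethod("show", "PhaseSeries", function(object) {
  usable <- sum(!is.na(object@phase))
  cat(sprintf("PhaseSeries (%s): %d samples @ %g Hz, %d usable\n",
              object@band, length(object@phase), object@fs, usable))
})

setMethod("show", "TimeFrequencyMap", function(object) {
  cat(sprintf("TimeFrequencyMap: %d bands x %d time points", nrow(object@power),
              ncol(object@power)))
  if (nzchar(object@trigger)) cat(sprintf(" [trigger: %s]", object@trigger))
  cat("\n")
})
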