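# Cell-metadata handling, phase-lag latency conversion, and group
# comparisons across cell classes and sub-classes.

.subClasses <- c("C-BC", "H-BC", "C-Bistrat", "O-Bistrat", "C-AAC", "E-AAC")
.markerLevels <- c("+", "-", "n.t.")
.markerCols <- c("parvalbumin", "somatostatin", "mglur1a", "satb1")

#' Convert a phase lag to a latency
#'
#' A phase difference of \eqn{\Delta} degrees at an oscillation frequency f
#' corresponds to a delay of \eqn{(\Delta/360) \times (1000/f)}
#' milliseconds.  E.g. a 71-degree lag at 8 Hz theta (cycle 125 ms) is a
#' 25 ms delay; the same lag at a 140 Hz ripple is 1.4 ms.
#'
#' @param deltaDeg phase difference in degrees.
#' @param freqHz oscillation frequency in Hz (> 0).
#' @param granularityMs optional rounding granularity in ms (e.g. 1, 0.1,
#'   10); NULL returns the exact value.
#' @return Latency in milliseconds.
#' @examples
#' phaseLagToMs(71, 8, 1)      # 25
#' phaseLagToMs(71, 140, 0.1)  # 1.4
#' @export
phaseLagToMs <- function(deltaDeg, freqHz, granularityMs = NULL) {
  if (any(freqHz <= 0)) rpStop("frequency must be positive")
  ms <- deltaDeg / 360 * 1000 / freqHz
  if (!is.null(granularityMs)) {
    if (granularityMs <= 0) rpStop("granularity must be positive")
    ms <- round(ms / granularityMs) * granularityMs
  }
  ms
}

#' Load and validate a cell metadata table
#'
#' Reads a tab-delimited table with the schema: \code{cell_id},
#' \code{cell_type} (one of C-BC, H-BC, C-Bistrat, O-Bistrat, C-AAC,
#' E-AAC), the immunomarker columns \code{parvalbumin},
#' \code{somatostatin}, \code{mglur1a}, \code{satb1} (each "+", "-" or
#' "n.t."), and \code{bouton_targets}, \code{ankyring}, \code{em} (free
#' labels or "n.t.").  Adds a derived \code{cell_class} column (BC,
#' Bistrat, AAC).  Vocabulary violations are rejected with row numbers.
#'
#' @param path path to the TSV file.
#' @return A validated data.frame of cell records.
#' @seealso \code{\link{cellTableFixture}} for the packaged 27-cell table.
#' @export
loadCellTable <- function(path) {
  if (!file.exists(path)) rpStop("cell table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = NULL)
  need <- c("cell_id", "cell_type", .markerCols, "bouton_targets",
            "ankyring", "em")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    rpStop("cell table missing columns: ", paste(missing, collapse = ", "))
  }
  badType <- which(!tab$cell_type %in% .subClasses)
  if (length(badType)) {
    rpStop("unknown cell_type in rows ", paste(badType, collapse = ", "),
           ": ", paste(unique(tab$cell_type[badType]), collapse = ", "))
  }
  for (mc in .markerCols) {
    bad <- which(!tab[[mc]] %in% .markerLevels)
    if (length(bad)) {
      rpStop("invalid ", mc, " value in rows ", paste(bad, collapse = ", "),
             " (allowed: +, -, n.t.)")
    }
  }
  if (anyDuplicated(tab$cell_id)) rpStop("duplicate cell_id values")
  tab$cell_class <- sub("^[A-Z]+-", "", tab$cell_type)
  tab
}

#' Compare values across groups with a named test
#'
#' Dispatches to the appropriate test for linear or circular data:
#' one-way ANOVA, Kruskal-Wallis, Mann-Whitney (rank-sum), Wilcoxon signed
#' rank (paired), or Watson-Williams for circular data.  Circular data are
#' only accepted by \code{watson_williams}; passing them to a linear family
#' is rejected.
#'
#' @param values numeric vector of observations (degrees if circular).
#' @param groups grouping factor/vector aligned with \code{values}.
#' @param family one of \code{"anova"}, \code{"kruskal_wallis"},
#'   \code{"mann_whitney"}, \code{"wilcoxon_signed_rank"},
#'   \code{"watson_williams"}.
#' @param circular logical: are the values angles in degrees?
#' @return list(statistic, p, test, n) where n is the per-group size table.
#' @export
groupCompare <- function(values, groups,
                         family = c("anova", "kruskal_wallis",
                                    "mann_whitney", "watson_williams",
                                    "wilcoxon_signed_rank"),
                         circular = FALSE) {
  family <- match.arg(family)
  if (length(values) != length(groups)) rpStop("values/groups length mismatch")
  g <- factor(groups)
  sizes <- table(g)
  if (any(sizes < 2L)) rpStop("each group needs at least 2 observations")
  if (circular && family != "watson_williams") {
    rpStop("circular data require the watson_williams family")
  }
  if (!circular && family == "watson_williams") {
    rpStop("watson_williams expects circular data (set circular = TRUE)")
  }
  out <- switch(family,
    anova = {
      fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
      list(statistic = unname(fit$statistic), p = fit$p.value)
    },
    kruskal_wallis = {
      fit <- stats::kruskal.test(values, g)
      list(statistic = unname(fit$statistic), p = fit$p.value)
    },
    mann_whitney = {
      if (nlevels(g) != 2L) rpStop("mann_whitney requires exactly 2 groups")
      fit <- stats::wilcox.test(values[g == levels(g)[1L]],
                                values[g == levels(g)[2L]], exact = FALSE)
      list(statistic = unname(fit$statistic), p = fit$p.value)
    },
    wilcoxon_signed_rank = {
      if (nlevels(g) != 2L) rpStop("signed rank requires exactly 2 groups")
      a <- values[g == levels(g)[1L]]
      b <- values[g == levels(g)[2L]]
      if (length(a) != length(b)) rpStop("signed rank requires paired groups")
      fit <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
      list(statistic = unname(fit$statistic), p = fit$p.value)
    },
    watson_williams = {
      fit <- watsonWilliams(split(values, g))
      list(statistic = fit$F, p = fit$p)
    }
  )
  list(statistic = out$statistic, p = out$p, test = family,
       n = as.integer(sizes))
}

#' Export detected events as delimited text
#'
#' @param events events data.frame.
#' @param path output path; columns start, end, peak_time, peak_amplitude,
#'   core_freq in seconds/SD-units/Hz at 6 decimals.
#' @export
writeEvents <- function(events, path) {
  out <- events
  for (cc in names(out)) {
    if (is.numeric(out[[cc]])) out[[cc]] <- sprintf("%.6f", out[[cc]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export spike times as delimited text
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param path output path (headered, seconds at 6 decimals).
#' @export
writeSpikeTrain <- function(spikes, path) {
  utils::write.table(
    data.frame(cell_id = cellId(spikes),
               time_s = sprintf("%.6f", spikeTimes(spikes))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an LFP/speed bundle
#'
#' Serializes the recording channels with their sampling rates as a single
#' binary container (an RDS file holding one entry per channel plus its
#' rate).
#'
#' @param channels named list of \linkS4class{LFPRecording} /
#'   \linkS4class{SpeedTrace} objects.
#' @param path output path.
#' @rdname recordingBundle
#' @export
writeRecordingBundle <- function(channels, path) {
  ser <- lapply(channels, function(ch) {
    list(samples = traceSamples(ch), fs = samplingRate(ch),
         type = class(ch)[1L])
  })
  saveRDS(ser, path)
  invisible(path)
}

#' @rdname recordingBundle
#' @export
readRecordingBundle <- function(path) {
  ser <- readRDS(path)
  lapply(ser, function(ch) {
    if (identical(ch$type, "SpeedTrace")) SpeedTrace(ch$samples, ch$fs)
    else LFPRecording(ch$samples, ch$fs)
  })
}
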