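# End-to-end orchestration: synthetic cohort generation, event detection,
# per-cell phase / rate / core-frequency analysis, and the cohort report.

.pipelineStages <- c("simulate", "detect", "phases", "rates", "corefreq",
                     "report")

#' Read and validate a pipeline configuration
#'
#' The configuration is a structured YAML file (or an equivalent nested
#' list) with sections \code{behavior}, \code{background}, \code{theta},
#' \code{epsilon}, \code{ripples}, \code{detection}, \code{surrogates} and
#' a \code{cells} list.  See the packaged demo configuration
#' (\code{system.file("extdata", "demo_config.yaml", package =
#' "ripplephase")}) for the full schema.
#'
#' @param config path to a YAML file, or a list.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) rpStop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) rpStop("config must be a list or a YAML path")
  need <- c("seed", "fs", "behavior", "background", "ripples", "detection",
            "surrogates", "cells")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    rpStop("config missing sections: ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(config$fs) || config$fs <= 0) rpStop("invalid fs")
  if (is.null(config$behavior$run_duration) ||
      is.null(config$behavior$rest_duration)) {
    rpStop("behavior needs run_duration and rest_duration")
  }
  ids <- vapply(config$cells, function(cl) as.character(cl$id), character(1))
  if (anyDuplicated(ids)) rpStop("duplicate cell ids in config")
  for (cl in config$cells) {
    if (is.null(cl$sub_class) || !cl$sub_class %in% .subClasses) {
      rpStop("cell '", cl$id, "' has missing or unknown sub_class")
    }
  }
  config
}

#' Path of the packaged demo configuration
#'
#' A 6-cell synthetic cohort (2 cells per class, contrasting sub-class
#' parameters: BCs phase-locked at 55 degrees and Bistrat cells at 126
#' degrees during ripples, doublet-prone H-BC, ripple-activated E-AAC).
#'
#' @return File path to the YAML configuration.
#' @export
demoConfigPath <- function() {
  system.file("extdata", "demo_config.yaml", package = "ripplephase",
              mustWork = TRUE)
}

# Simulate the cohort described by a validated config.
simulateCohort <- function(config) {
  fs <- config$fs
  runDur <- config$behavior$run_duration
  restDur <- config$behavior$rest_duration
  totalDur <- runDur + restDur
  cfg <- simConfig(totalDur, fs = fs, seed = subSeed(config$seed, 1L),
                   noiseExponent = config$background$noise_exponent,
                   noiseScale = config$background$noise_scale)
  lfp <- generateBackgroundLFP(cfg)
  rhythms <- list()
  if (!is.null(config$theta) && runDur > 0) {
    rhythms <- c(rhythms, list(plantedRhythm(
      "theta", config$theta$freq, config$theta$amplitude,
      c(0, runDur))))
  }
  if (!is.null(config$epsilon) && runDur > 0) {
    rhythms <- c(rhythms, list(plantedRhythm(
      "epsilon", config$epsilon$freq, config$epsilon$amplitude,
      c(0, runDur),
      coupling = list(carrier = config$epsilon$carrier,
                      preferredCarrierPhase =
                        config$epsilon$preferred_carrier_phase,
                      modulationDepth = config$epsilon$modulation_depth))))
  }
  truthRhythms <- NULL
  if (length(rhythms)) {
    pr <- plantRhythms(lfp, rhythms)
    lfp <- pr$lfp
    truthRhythms <- pr$truth$rhythms
  }
  # plant ripple events in the rest span at the configured height (in
  # detector SD units of the pre-event ripple-band envelope)
  rp <- config$ripples
  restIv <- c(runDur, totalDur)
  base <- envelopeBaseline(lfp, oscillationBands("ripple"),
                           matrix(restIv, ncol = 2L))
  evs <- withSeed(subSeed(config$seed, 2L), {
    ne <- rp$n_events
    durs <- stats::runif(ne, rp$duration_range[1L], rp$duration_range[2L])
    freqsEv <- stats::runif(ne, rp$freq_range[1L], rp$freq_range[2L])
    minSep <- if (is.null(rp$min_separation)) 1 else rp$min_separation
    margin <- 1
    slack <- (restDur - 2 * margin) - sum(durs) - (ne - 1) * minSep
    if (slack <= 0) rpStop("rest span too short for the requested events")
    gaps <- sort(stats::runif(ne, 0, slack))
    starts <- restIv[1L] + margin + gaps +
      c(0, cumsum(durs[-ne] + minSep))
    # amplitude_sd is in detector SD units of the ripple-band envelope;
    # compensate each event for the band-pass gain of its burst shape
    target <- base$mean + rp$amplitude_sd * base$sd
    lapply(seq_len(ne), function(i) {
      g <- burstBandGain(freqsEv[i], durs[i], fs)
      plantedEvent(starts[i], durs[i], freqsEv[i], target / g)
    })
  })
  pe <- plantEvents(lfp, evs)
  lfp <- pe$lfp
  truth <- pe$truth
  truth$rhythms <- if (is.null(truthRhythms)) list() else truthRhythms
  speed <- generateSpeedTrace(list(c("run", runDur), c("rest", restDur)))
  # per-cell spike trains: theta-locked during running, event-gated and
  # ripple-phase-locked during rest
  t <- sampleTimes(lfp)
  runMask <- t < runDur
  thetaPhase <- if (!is.null(truth$rhythms$theta)) {
    truthPhase(truth, "theta", t[runMask])
  } else rep(NA_real_, sum(runMask))
  eventPhase <- truthPhase(truth, "events", t[!runMask])
  spikes <- list()
  for (i in seq_along(config$cells)) {
    cl <- config$cells[[i]]
    runModel <- spikeModel(cl$rate_run, cl$theta_pref, cl$theta_kappa)
    restModel <- spikeModel(cl$rate_rest, cl$event_pref, cl$event_kappa,
                            eventGain = cl$event_gain,
                            doubletProb = if (is.null(cl$doublet_prob)) 0
                                          else cl$doublet_prob)
    stRun <- generateSpikes(runModel, fs, phase = thetaPhase,
                            seed = subSeed(config$seed, 100L + i),
                            t0 = 0, cellId = cl$id)
    stRest <- generateSpikes(restModel, fs, phase = eventPhase,
                             events = truth$events,
                             seed = subSeed(config$seed, 200L + i),
                             t0 = runDur, cellId = cl$id)
    truth$cells[[cl$id]] <- list(run = unclass(runModel),
                                 rest = unclass(restModel))
    spikes[[cl$id]] <- SpikeTrain(c(spikeTimes(stRun), spikeTimes(stRest)),
                                  cl$id)
  }
  list(lfp = lfp, speed = speed, truth = truth, spikes = spikes)
}

writeTableWithHeader <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  out <- df
  for (cc in names(out)) {
    if (is.double(out[[cc]])) {
      out[[cc]] <- ifelse(is.na(out[[cc]]), "NA", sprintf("%.6f", out[[cc]]))
    }
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Orchestrates, deterministically for a given configuration and seed:
#' synthetic cohort generation, behavioral segmentation, ripple detection,
#' per-cell theta and ripple phase locking, rate and randomization
#' statistics, core-frequency estimation, and the cohort report.  Output
#' tables are byte-identical across reruns with the same configuration.
#'
#' @param config YAML path or list (see \code{\link{readPipelineConfig}}).
#' @param outDir output directory (created if needed); NULL for no files.
#' @param through last stage to run: one of "simulate", "detect", "phases",
#'   "rates", "corefreq", "report" (default; earlier stages always run).
#' @return Invisibly, a list with the simulated data, detected events,
#'   per-cell results data.frame, cohort summary and comparisons.
#' @export
runPipeline <- function(config, outDir = NULL, through = "report") {
  config <- readPipelineConfig(config)
  through <- match.arg(through, .pipelineStages)
  stageN <- match(through, .pipelineStages)
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  runLog <- c(
    sprintf("ripplephase %s",
            as.character(utils::packageVersion("ripplephase"))),
    sprintf("seed: %d", as.integer(config$seed)),
    yaml::as.yaml(config))
  bytes <- utf8ToInt(paste(runLog, collapse = "\n"))
  hash <- sprintf("%08x",
                  sum(bytes * (seq_along(bytes) %% 97 + 1)) %% 0xFFFFFFFF)
  header <- sprintf("# ripplephase %s seed=%d params=%s",
                    as.character(utils::packageVersion("ripplephase")),
                    as.integer(config$seed), hash)
  sim <- simulateCohort(config)
  if (!is.null(outDir)) {
    writeRecordingBundle(list(lfp = sim$lfp, speed = sim$speed),
                         file.path(outDir, "recording.rds"))
    writeGroundTruth(sim$truth, file.path(outDir, "ground_truth.yaml"))
    for (id in names(sim$spikes)) {
      writeSpikeTrain(sim$spikes[[id]],
                      file.path(outDir, sprintf("spikes_%s.tsv", id)))
    }
    writeLines(runLog, file.path(outDir, "run_log.txt"))
  }
  res <- list(sim = sim, config = config)
  if (stageN < 2L) return(invisible(res))

  # ---- detect ----------------------------------------------------------
  epochs <- segmentBehavior(sim$speed,
                            speedThreshold = config$behavior$speed_threshold %||% 1)
  det <- config$detection
  params <- detectionParams(
    highThreshold = det$high_threshold %||% 5,
    edgeThreshold = det$edge_threshold %||% 2,
    minDuration = det$min_duration %||% 0.02,
    mergeGap = det$merge_gap %||% 0.01)
  events <- detectEvents(sim$lfp, epochs, params)
  res$epochs <- epochs
  res$events <- events
  if (stageN >= 5L) {
    rippleFilt <- bandpassFilter(sim$lfp, oscillationBands("ripple"))
    events <- addCoreFrequencies(events, rippleFilt)
    res$events <- events
  }
  if (!is.null(outDir)) {
    writeTableWithHeader(events, file.path(outDir, "events.tsv"), header)
  }
  if (stageN < 3L) return(invisible(res))

  # ---- phases / rates / corefreq per cell ------------------------------
  thetaFilt <- bandpassFilter(sim$lfp, oscillationBands("theta"))
  thetaPhase <- instantaneousPhase(thetaFilt, band = "theta")
  if (!exists("rippleFilt", inherits = FALSE)) {
    rippleFilt <- bandpassFilter(sim$lfp, oscillationBands("ripple"))
  }
  ripplePhase <- instantaneousPhase(rippleFilt, band = "ripple")
  evIv <- cbind(events$start, events$end)
  cellRows <- list()
  comparisons <- list()
  pehs <- list()
  for (i in seq_along(config$cells)) {
    cl <- config$cells[[i]]
    st <- sim$spikes[[cl$id]]
    row <- data.frame(cell_id = cl$id, sub_class = cl$sub_class,
                      cell_class = sub("^[A-Z]+-", "", cl$sub_class),
                      stringsAsFactors = FALSE)
    # theta phase locking during running
    if (nrow(epochs$run)) {
      thPh <- spikePhases(st, thetaPhase, epochs$run)
      thRes <- phaseLocking(thPh)
      row$theta_rate <- firingRate(st, epochs$run)
      row$theta_n <- thRes$n
      row$theta_mean_phase <- thRes$meanPhase
      row$theta_r <- thRes$r
      row$theta_rayleigh_p <- thRes$rayleighP
    }
    # ripple phase locking (spikes within detected events)
    evPh <- spikePhases(st, ripplePhase, evIv)
    evRes <- phaseLocking(evPh)
    row$event_n <- evRes$n
    row$event_mean_phase <- evRes$meanPhase
    row$event_r <- evRes$r
    row$event_rayleigh_p <- evRes$rayleighP
    if (stageN >= 4L) {
      mod <- eventRateModulation(
        st, events, epochs$rest,
        mode = config$surrogates$mode %||% "spike_shuffle",
        nSurrogates = config$surrogates$n_surrogates %||% 1000,
        seed = subSeed(config$seed, 300L + i))
      row$rate_in <- mod$rateIn
      row$rate_out <- mod$rateOut
      row$mod_p <- mod$p
      row$mod_direction <- mod$direction
      row$participation <- participationFraction(st, events)
      row$early_fraction <- suppressWarnings(earlySpikeFraction(st, events))
      dbl <- detectDoublets(st, events, rippleFilt)
      row$doublet_fraction <- dbl$doubletFraction
      row$intra_event_rate <- dbl$intraEventRate
      pehs[[cl$id]] <- periEventHistogram(st, events)
    }
    if (stageN >= 5L) {
      cmp <- compareSpikeConditioned(events, st)
      row$core_with_mean <- cmp$meanWith
      row$core_without_mean <- cmp$meanWithout
      row$core_p <- cmp$p
    }
    cellRows[[i]] <- row
  }
  cells <- do.call(rbind, cellRows)
  res$cells <- cells
  res$pehs <- pehs
  if (!is.null(outDir)) {
    writeTableWithHeader(cells, file.path(outDir, "cell_results.tsv"), header)
    if (length(pehs)) {
      pehDf <- data.frame(bin = 1:100,
                          span = rep(c("before", "during", "after"),
                                     c(40, 20, 40)))
      for (id in names(pehs)) pehDf[[id]] <- pehs[[id]]$value
      writeTableWithHeader(pehDf, file.path(outDir, "peri_event_histograms.tsv"),
                           header)
    }
  }
  if (stageN < 6L) return(invisible(res))

  # ---- report ----------------------------------------------------------
  summarise <- function(df, by) {
    groups <- split(df, df[[by]])
    rows <- lapply(names(groups), function(gname) {
      g <- groups[[gname]]
      data.frame(
        group = gname, level = by, n = nrow(g),
        theta_phase = if (!is.null(g$theta_mean_phase))
          circularMeanDeg(g$theta_mean_phase) else NA_real_,
        theta_phase_sd = if (!is.null(g$theta_mean_phase))
          circularSDDeg(g$theta_mean_phase) else NA_real_,
        theta_r = if (!is.null(g$theta_r)) mean(g$theta_r) else NA_real_,
        theta_rate = if (!is.null(g$theta_rate)) mean(g$theta_rate) else NA_real_,
        event_phase = circularMeanDeg(g$event_mean_phase),
        event_phase_sd = circularSDDeg(g$event_mean_phase),
        event_r = mean(g$event_r),
        rate_in = mean(g$rate_in),
        participation = mean(g$participation),
        doublet_fraction = mean(g$doublet_fraction),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  summary <- rbind(summarise(cells, "cell_class"),
                   summarise(cells, "sub_class"))
  res$summary <- summary
  # pairwise class comparisons where group sizes allow
  addComparison <- function(name, values, groups, family, circular = FALSE) {
    ok <- !is.na(values)
    g <- factor(groups[ok])
    if (nlevels(g) < 2L || any(table(g) < 2L)) return(NULL)
    cmpRes <- suppressWarnings(
      groupCompare(values[ok], g, family, circular = circular))
    data.frame(comparison = name, test = cmpRes$test,
               statistic = cmpRes$statistic, p = cmpRes$p,
               n = paste(cmpRes$n, collapse = "/"),
               stringsAsFactors = FALSE)
  }
  bcBistrat <- cells$cell_class %in% c("BC", "Bistrat")
  comparisons <- do.call(rbind, Filter(Negate(is.null), list(
    addComparison("event_phase_BC_vs_Bistrat",
                  cells$event_mean_phase[bcBistrat],
                  cells$cell_class[bcBistrat], "watson_williams",
                  circular = TRUE),
    addComparison("theta_phase_by_class", cells$theta_mean_phase,
                  cells$cell_class, "watson_williams", circular = TRUE),
    addComparison("rate_in_BC_vs_Bistrat", cells$rate_in[bcBistrat],
                  cells$cell_class[bcBistrat], "mann_whitney"),
    addComparison("theta_rate_by_class", cells$theta_rate,
                  cells$cell_class, "anova")
  )))
  res$comparisons <- comparisons
  if (!is.null(outDir)) {
    writeTableWithHeader(summary, file.path(outDir, "cohort_summary.tsv"),
                         header)
    if (!is.null(comparisons)) {
      writeTableWithHeader(comparisons, file.path(outDir, "comparisons.tsv"),
                           header)
    }
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
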