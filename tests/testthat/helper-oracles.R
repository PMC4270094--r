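# Shared fixtures and independent oracles, all built in code.

# Independent von Mises sampler (Best & Fisher rejection algorithm), used
# as an oracle for circular-statistics tests; deliberately separate from
# the package's thinning-based spike generator.
rVonMisesDeg <- function(n, muDeg, kappa) {
  if (kappa == 0) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      theta <- sign(u[3L] - 0.5) * acos(f)
      out[i] <- (muDeg + theta * 180 / pi) %% 360
      i <- i + 1L
    }
  }
  out
}

# Pure-tone recording.
toneLFP <- function(freq, durS, fs, amp = 1) {
  t <- seq(0, durS - 1 / fs, by = 1 / fs)
  LFPRecording(amp * sin(2 * pi * freq * t), fs)
}

# Hann-enveloped burst segment (vector), trough-at-onset convention.
hannBurst <- function(freq, durS, fs, amp = 1) {
  tt <- seq(0, durS, by = 1 / fs)
  amp * 0.5 * (1 - cos(2 * pi * tt / durS)) * cos(2 * pi * freq * tt)
}

# Homogeneous Poisson spike train on [0, durS].
poissonTrain <- function(rateHz, durS, id = "poisson") {
  SpikeTrain(sort(runif(rpois(1, rateHz * durS), 0, durS)), id)
}

# Background trace with planted ripple events at a prescribed height in
# detector SD units; returns lfp, truth and the baseline used.
plantedRippleScene <- function(durS, nEvents, seed, sdUnits = 9,
                               fs = 1250, freqRange = c(100, 180),
                               durRange = c(0.05, 0.12), margin = 2,
                               sep = 1) {
  bg <- generateBackgroundLFP(simConfig(durS, fs = fs, seed = seed))
  base <- envelopeBaseline(bg)
  set.seed(seed + 5000L)
  durs <- runif(nEvents, durRange[1L], durRange[2L])
  freqs <- runif(nEvents, freqRange[1L], freqRange[2L])
  slack <- (durS - 2 * margin) - sum(durs) - (nEvents - 1) * sep
  stopifnot(slack > 0)
  starts <- margin + sort(runif(nEvents, 0, slack)) +
    c(0, cumsum(durs[-nEvents] + sep))
  # plant so every event attains sdUnits in ripple-band envelope units,
  # compensating the band-pass gain of each burst shape
  target <- base$mean + sdUnits * base$sd
  evs <- lapply(seq_len(nEvents), function(i) {
    g <- burstBandGain(freqs[i], durs[i], fs)
    plantedEvent(starts[i], durs[i], freqs[i], target / g)
  })
  pe <- plantEvents(bg, evs)
  list(lfp = pe$lfp, truth = pe$truth, baseline = base, fs = fs,
       bandPeak = target)
}

# Expected 2-SD boundary-crossing times of a planted Hann event, given the
# detector's measured baseline: solves sqrt((a h(t))^2 + m2) = mu + k sd
# where m2 is the mean-square noise envelope and a the attained in-band
# envelope peak.  Analytic oracle for boundary-localization accuracy.
expectedEdgeCrossing <- function(event, baselineMean, baselineSD, k = 2,
                                 aBand = event$peak_amplitude) {
  sigx <- baselineSD / sqrt(2 - pi / 2)   # Rayleigh envelope: sd = sigx*sqrt(2-pi/2)
  m2 <- 2 * sigx^2
  thr <- baselineMean + k * baselineSD
  a <- aBand
  d <- event$end - event$start
  hCross <- sqrt(max(thr^2 - m2, 0)) / a
  if (hCross >= 1) return(c(NA_real_, NA_real_))
  tc <- d / (2 * pi) * acos(1 - 2 * hCross)
  c(event$start + tc, event$end - tc)
}

# Match detected to true events by overlap; returns indices or NA.
matchEvents <- function(detected, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    j <- which(detected$start < truth$end[i] & detected$end > truth$start[i])
    if (length(j)) j[1L] else NA_integer_
  }, integer(1))
}
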