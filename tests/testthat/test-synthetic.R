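# Synthetic generator: background spectrum, planted rhythms and events,
# phase-locked spike trains, speed traces, ground-truth round trip.

test_that("background LFP has the requested length, scale and determinism", {
  cfg <- simConfig(10, fs = 1000, seed = 1)
  lfp <- generateBackgroundLFP(cfg)
  expect_equal(nSamples(lfp), 10000L)
  expect_equal(samplingRate(lfp), 1000)
  # zero noise scale -> all-zero trace
  z <- generateBackgroundLFP(simConfig(1, fs = 1000, seed = 1, noiseScale = 0))
  expect_true(all(traceSamples(z) == 0))
  # identical seed => bit-identical output
  expect_identical(traceSamples(lfp),
                   traceSamples(generateBackgroundLFP(cfg)))
  expect_false(identical(
    traceSamples(lfp),
    traceSamples(generateBackgroundLFP(simConfig(10, fs = 1000, seed = 2)))))
})

test_that("background spectrum follows the 1/f^alpha slope", {
  lfp <- generateBackgroundLFP(simConfig(60, fs = 1000, seed = 3,
                                         noiseExponent = 1))
  sp <- spec.pgram(ts(traceSamples(lfp), frequency = 1000), plot = FALSE,
                   taper = 0)
  keep <- sp$freq > 1 & sp$freq < 100
  slope <- unname(coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2L])
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("planted pure tone passes through its band at full amplitude", {
  fs <- 1250
  silent <- generateBackgroundLFP(simConfig(10, fs = fs, seed = 1,
                                            noiseScale = 0))
  pr <- plantRhythms(silent, plantedRhythm("theta", 8, 0.3, c(0, 10)))
  bp <- traceSamples(bandpassFilter(pr$lfp, "theta"))
  mid <- seq(2 * fs, 8 * fs)
  expect_lt(abs(diff(range(bp[mid])) - 0.6), 0.6 * 0.05)
  # ground-truth phase: trough at epoch onset, full cycles of 8 Hz
  ph <- truthPhase(pr$truth, "theta", c(0, 1 / 16, 1 / 8))
  expect_equal(ph, c(0, 180, 0), tolerance = 1e-9)
})

test_that("cross-frequency coupling places fast power at the preferred carrier phase", {
  fs <- 1250
  lfp <- generateBackgroundLFP(simConfig(30, fs = fs, seed = 4, noiseScale = 0))
  mk <- function(depth) {
    plantRhythms(lfp, list(
      plantedRhythm("theta", 8, 0.2, c(0, 30)),
      plantedRhythm("epsilon", 110, 0.05, c(0, 30),
                    coupling = list(carrier = "theta",
                                    preferredCarrierPhase = 270,
                                    modulationDepth = depth))))
  }
  pr <- mk(1)
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  thp <- truthPhase(pr$truth, "theta", t)
  env <- traceSamples(signalEnvelope(bandpassFilter(pr$lfp, "epsilon")))
  binMean <- tapply(env, floor(thp / 18), mean)
  peakBin <- (as.numeric(names(which.max(binMean))) + 0.5) * 18
  expect_lt(abs(peakBin - 270), 20)
  # depth 0 -> envelope flat across carrier bins
  pr0 <- mk(0)
  env0 <- traceSamples(signalEnvelope(bandpassFilter(pr0$lfp, "epsilon")))
  bm0 <- tapply(env0, floor(thp / 18), mean)
  expect_lt((max(bm0) - min(bm0)) / mean(bm0), 0.05)
  # overlapping epochs for one rhythm are rejected
  expect_error(plantedRhythm("theta", 8, 0.1, rbind(c(0, 10), c(5, 15))),
               "disjoint")
})

test_that("planted events carry f x d carrier cycles and zero amplitude is a no-op", {
  fs <- 1250
  lfp <- generateBackgroundLFP(simConfig(5, fs = fs, seed = 5, noiseScale = 0))
  ev <- plantedEvent(1, 0.1, 140, 1)
  pe <- plantEvents(lfp, ev)
  # 14 carrier cycles inside the event: 14 ground-truth phase wraps
  t <- seq(1, 1.1 - 1 / fs, by = 1 / fs)
  ph <- truthPhase(pe$truth, "events", t)
  wraps <- sum(diff(ph) < 0)
  expect_equal(wraps + 1L, 14L)   # f * d = 140 * 0.1
  # amplitude 0 leaves the trace unchanged
  pe0 <- plantEvents(lfp, plantedEvent(1, 0.1, 140, 0))
  expect_identical(traceSamples(pe0$lfp), traceSamples(lfp))
  # overlap rejected
  expect_error(plantEvents(lfp, list(plantedEvent(1, 0.1, 140, 1),
                                     plantedEvent(1.05, 0.1, 140, 1))),
               "overlap")
})

test_that("planting a fast event leaves theta-band power unchanged (energy locality)", {
  fs <- 1250
  bg <- generateBackgroundLFP(simConfig(20, fs = fs, seed = 6))
  p0 <- var(traceSamples(bandpassFilter(bg, "theta")))
  pe <- plantEvents(bg, plantedEvent(10, 0.1, 140, 0.2))
  p1 <- var(traceSamples(bandpassFilter(pe$lfp, "theta")))
  expect_lt(abs(p1 - p0) / p0, 0.01)
})

test_that("unmodulated spike trains pass the Rayleigh uniformity screen", {
  fs <- 1250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  ph <- (360 * 8 * t) %% 360
  m0 <- spikeModel(15, 0, kappa = 0)
  ps <- vapply(1:100, function(s) {
    st <- generateSpikes(m0, fs, phase = ph, seed = s)
    sph <- ph[pmin(round(spikeTimes(st) * fs) + 1L, length(ph))]
    rayleighTest(sph)
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.90)
})

test_that("strongly concentrated spike trains recover the preferred phase", {
  fs <- 1250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  ph <- (360 * 8 * t) %% 360
  m <- spikeModel(20, 126, kappa = 100)
  st <- generateSpikes(m, fs, phase = ph, seed = 11)
  expect_gte(nSpikes(st), 500L)
  sph <- ph[pmin(round(spikeTimes(st) * fs) + 1L, length(ph))]
  rv <- resultantVector(sph)
  expect_lt(abs(rv$meanPhase - 126), 5)
})

test_that("event gain zero silences the cell inside events", {
  fs <- 1250
  ev <- data.frame(start = c(1, 3), end = c(1.1, 3.1),
                   core_freq = c(140, 140))
  m <- spikeModel(30, 0, 0, eventGain = 0)
  st <- generateSpikes(m, fs, durationS = 5, events = ev, seed = 2)
  expect_equal(sum(spikeTimes(st) >= 1 & spikeTimes(st) <= 1.1), 0L)
  expect_equal(sum(spikeTimes(st) >= 3 & spikeTimes(st) <= 3.1), 0L)
  expect_gt(nSpikes(st), 0L)
})

test_that("generated spike phases converge to the von Mises resultant length", {
  fs <- 1250
  for (kappa in c(0, 1, 4)) {
    expected <- if (kappa == 0) 0 else
      besselI(kappa, 1, TRUE) / besselI(kappa, 0, TRUE)
    t <- seq(0, 200 - 1 / fs, by = 1 / fs)
    ph <- (360 * 8 * t) %% 360
    m <- spikeModel(25, 90, kappa, refractory = 0.002)
    st <- generateSpikes(m, fs, phase = ph, seed = 20 + kappa)
    expect_gte(nSpikes(st), 4000L)
    sph <- ph[pmin(round(spikeTimes(st) * fs) + 1L, length(ph))]
    expect_lt(abs(resultantVector(sph)$r - expected), 0.03)
  }
})

test_that("spike trains respect the refractory period and determinism", {
  fs <- 1250
  m <- spikeModel(80, 0, 0, refractory = 0.002)
  st <- generateSpikes(m, fs, durationS = 30, seed = 7)
  expect_gte(min(diff(spikeTimes(st))), 0.002)
  st2 <- generateSpikes(m, fs, durationS = 30, seed = 7)
  expect_identical(spikeTimes(st), spikeTimes(st2))
})

test_that("speed traces encode the requested run/rest program", {
  sp <- generateSpeedTrace(list(c("run", 30), c("rest", 250)))
  expect_equal(duration(sp), 280)
  ep <- segmentBehavior(sp)
  expect_equal(nrow(ep$run), 1L)
  expect_equal(nrow(ep$rest), 1L)
  # all-rest input yields zero running epochs downstream
  epR <- segmentBehavior(generateSpeedTrace(list(c("rest", 300))))
  expect_equal(nrow(epR$run), 0L)
})

test_that("ground truth serializes and reloads identically", {
  fs <- 1250
  lfp <- generateBackgroundLFP(simConfig(20, fs = fs, seed = 8))
  pr <- plantRhythms(lfp, list(
    plantedRhythm("theta", 8, 0.2, rbind(c(0, 9.5), c(10, 20))),
    plantedRhythm("epsilon", 110, 0.05, c(0, 9.5),
                  coupling = list(carrier = "theta",
                                  preferredCarrierPhase = 270,
                                  modulationDepth = 0.8))))
  pe <- plantEvents(pr$lfp, list(plantedEvent(10.5, 0.1, 140, 0.123456789),
                                 plantedEvent(12, 0.08, 170.5, 0.2)))
  truth <- pe$truth
  truth$rhythms <- pr$truth$rhythms
  truth$cells <- list(cellA = list(baseRate = 12.3, kappa = 4))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeGroundTruth(truth, path)
  back <- readGroundTruth(path)
  expect_equal(back$events, truth$events, tolerance = 0)
  expect_equal(back$rhythms$theta$epochs, truth$rhythms$theta$epochs,
               tolerance = 0)
  expect_equal(back$rhythms$epsilon$coupling, truth$rhythms$epsilon$coupling,
               tolerance = 0)
  expect_equal(back$cells, truth$cells, tolerance = 0)
})
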