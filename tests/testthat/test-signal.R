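# Band filtering, downsampling, envelope, filterbank, triggered averaging.

test_that("band-pass preserves passband tones and rejects stopband tones", {
  fs <- 1000
  mid <- seq(1 * fs, 3 * fs)
  th8 <- traceSamples(bandpassFilter(toneLFP(8, 4, fs), "theta"))
  expect_gte(max(abs(th8[mid])), 0.95)
  th50 <- traceSamples(bandpassFilter(toneLFP(50, 4, fs), "theta"))
  expect_lte(max(abs(th50[mid])), 0.1)
  expect_error(bandpassFilter(toneLFP(8, 1, 300), "ripple"), "Nyquist")
})

test_that("band-pass is zero-phase: a burst's peak does not move", {
  fs <- 1250
  n <- 4 * fs
  x <- numeric(n)
  burst <- hannBurst(140, 0.1, fs)
  i0 <- 2 * fs
  x[i0 + seq_along(burst)] <- burst
  filt <- bandpassFilter(LFPRecording(x, fs), "ripple")
  envIn <- Mod(ripplephase:::analyticSignal(x))
  envOut <- traceSamples(signalEnvelope(filt))
  shift <- abs(which.max(envOut) - which.max(envIn)) / fs
  expect_lt(shift, 0.001)
})

test_that("filtering commutes with time reversal (zero-phase property)", {
  fs <- 1000
  set.seed(1)
  x <- rnorm(6000)
  for (band in c("theta", "ripple")) {
    a <- traceSamples(bandpassFilter(LFPRecording(x, fs), band))
    b <- rev(traceSamples(bandpassFilter(LFPRecording(rev(x), fs), band)))
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
  }
})

test_that("downsampling decimates with anti-aliasing and keeps slow content", {
  fs <- 20000
  lfp <- toneLFP(8, 5, fs)
  expect_identical(traceSamples(downsampleLFP(lfp, 1)), traceSamples(lfp))
  d <- downsampleLFP(lfp, 20)
  expect_equal(samplingRate(d), 1000)
  mid <- seq(1000, 4000)
  expect_lt(abs(max(abs(traceSamples(d)[mid])) - 1), 0.02)
  expect_error(downsampleLFP(lfp, 2.5), "integer")
})

test_that("envelope recovers tone amplitude and tracks amplitude modulation", {
  fs <- 1250
  env <- traceSamples(signalEnvelope(toneLFP(140, 4, fs)))
  mid <- seq(fs, 3 * fs)
  expect_true(all(abs(env[mid] - 1) < 0.05))
  expect_true(all(env >= 0))
  z <- signalEnvelope(LFPRecording(numeric(1000), fs))
  expect_true(all(traceSamples(z) == 0))
  # AM tone: envelope follows |sin(2 pi 2 t)|
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  am <- abs(sin(2 * pi * 2 * t)) * sin(2 * pi * 140 * t)
  envAM <- traceSamples(signalEnvelope(LFPRecording(am, fs)))
  expect_lt(max(abs(envAM[mid] - abs(sin(2 * pi * 2 * t))[mid])), 0.1)
  # envelope upper-bounds the rectified trace (up to tolerance)
  expect_true(all(envAM[mid] >= abs(am[mid]) - 1e-6))
})

test_that("filterbank grid enumerates 96 bands and finds a planted tone", {
  grid <- filterbankGrid()
  expect_equal(grid$centers, seq(10, 200, by = 2))
  expect_length(grid$centers, 96L)
  fs <- 1000
  set.seed(2)
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  # transient 60 Hz tone: rows are z-scored, so the tone registers as a
  # power excursion of its band during the tone epoch
  x <- rnorm(20 * fs) * 0.1 +
    sin(2 * pi * 60 * t) * (t >= 5 & t < 10)
  map <- filterbankPower(LFPRecording(x, fs))
  expect_s4_class(map, "TimeFrequencyMap")
  expect_equal(nrow(map@power), 96L)
  # every row z-scored
  expect_lt(max(abs(rowMeans(map@power))), 1e-8)
  expect_lt(max(abs(apply(map@power, 1, sd) - 1)), 1e-8)
  # the tone epoch elevates the 60 Hz row's normalized power
  toneCols <- map@times >= 5 & map@times < 10
  peakRow <- map@freqs[which.max(rowMeans(map@power[, toneCols]))]
  expect_equal(peakRow, 60)
})

test_that("filterbank rows are invariant to affine rescaling of the trace", {
  fs <- 1000
  set.seed(3)
  x <- rnorm(8 * fs)
  m1 <- filterbankPower(LFPRecording(x, fs), filterbankGrid(20, 180, 10, 4))
  m2 <- filterbankPower(LFPRecording(3.7 * x + 2, fs),
                        filterbankGrid(20, 180, 10, 4))
  expect_equal(m1@power, m2@power, tolerance = 1e-8)
})

test_that("triggered averaging aligns windows and averages identical content", {
  # K identical windows average to any single window
  fs <- 100
  period <- 1
  times <- seq(0, 10 - 1 / fs, by = 1 / fs)
  row <- sin(2 * pi * times / period)
  map <- TimeFrequencyMap(rbind(row, 2 * row), c(10, 20), times)
  trig <- seq(2, 8, by = period)
  avg <- triggeredAverage(map, trig, c(0.25, 0.25))
  one <- triggeredAverage(map, trig[1L], c(0.25, 0.25))
  expect_equal(avg@power, one@power, tolerance = 1e-10)
  # triggers too close to the edge are dropped and counted
  avg2 <- triggeredAverage(map, c(0.01, trig), c(0.25, 0.25))
  expect_equal(attr(avg2, "nDropped"), 1L)
  expect_error(triggeredAverage(map, -5, c(0.25, 0.25)), "window")
})

test_that("theta-trough triggered maps localize coupled fast power; shuffled triggers flatten it", {
  fs <- 1000
  lfp <- generateBackgroundLFP(simConfig(30, fs = fs, seed = 9,
                                         noiseScale = 0.02))
  pr <- plantRhythms(lfp, list(
    plantedRhythm("theta", 8, 0.3, c(0, 30)),
    plantedRhythm("epsilon", 110, 0.08, c(0, 30),
                  coupling = list(carrier = "theta",
                                  preferredCarrierPhase = 270,
                                  modulationDepth = 1))))
  # a 20 Hz analysis bandwidth lets the band envelope follow the 8 Hz
  # amplitude modulation (a 4 Hz band rejects the +/-8 Hz sidebands and is
  # blind to within-cycle timing)
  map <- filterbankPower(pr$lfp, filterbankGrid(80, 140, 5, 20))
  thetaFilt <- bandpassFilter(pr$lfp, "theta")
  troughs <- findCycleLandmarks(thetaFilt)$troughs
  period <- 1 / 8
  avg <- triggeredAverage(map, troughs, c(period / 2, period / 2))
  epsRows <- avg@freqs >= 100 & avg@freqs <= 120
  prof <- colMeans(avg@power[epsRows, , drop = FALSE])
  tPeak <- avg@times[which.max(prof)]
  # power maximal at the planted 270-degree theta phase: -90 or +270 degrees
  # relative to the trough, i.e. -period/4 within the one-cycle window
  expect_lt(min(abs(tPeak - c(-period / 4, 3 * period / 4))), 0.02)
  # surrogate triggers erase the phase structure
  set.seed(4)
  shuf <- runif(length(troughs), period, 30 - period)
  avgS <- triggeredAverage(map, shuf, c(period / 2, period / 2))
  profS <- colMeans(avgS@power[epsRows, , drop = FALSE])
  expect_lt(max(profS) - min(profS), 0.5)
})
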