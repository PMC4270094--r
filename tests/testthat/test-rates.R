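# Firing rates, randomization tests, participation, early-spike fraction,
# doublets, peri-event histograms.

test_that("firing rate is count over epoch duration", {
  st <- SpikeTrain(seq(0.01, 4, length.out = 100))
  expect_equal(firingRate(st, c(0, 4)), 25)
  expect_equal(firingRate(SpikeTrain(numeric(0)), c(0, 4)), 0)
  expect_error(firingRate(st, matrix(numeric(0), ncol = 2)), "duration")
  # Poisson rate recovery within +/- 3 Hz for most seeds
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    abs(firingRate(poissonTrain(30, 60), c(0, 60)) - 30) <= 3
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("event-gated and event-silenced cells are flagged with the right direction", {
  fs <- 1250
  iv <- c(0, 100)
  ev <- data.frame(start = seq(2, 95, by = 3), end = seq(2, 95, by = 3) + 0.08,
                   core_freq = 140)
  mUp <- spikeModel(10, 0, 0, eventGain = 20)
  stUp <- generateSpikes(mUp, fs, durationS = 100, events = ev, seed = 41)
  rUp <- eventRateModulation(stUp, ev, iv, nSurrogates = 999, seed = 1)
  expect_equal(rUp$direction, "increase")
  expect_lte(rUp$p, 0.01)
  mDn <- spikeModel(10, 0, 0, eventGain = 0)
  stDn <- generateSpikes(mDn, fs, durationS = 100, events = ev, seed = 42)
  rDn <- eventRateModulation(stDn, ev, iv, nSurrogates = 999, seed = 1)
  expect_equal(rDn$direction, "decrease")
  expect_lte(rDn$p, 0.01)
  expect_equal(rDn$rateIn, 0)
  expect_error(eventRateModulation(stUp, ev, iv, nSurrogates = 50), "100")
  # event-shuffle mode agrees on the strong effect
  rShuf <- eventRateModulation(stUp, ev, iv, mode = "event_shuffle",
                               nSurrogates = 499, seed = 2)
  expect_equal(rShuf$direction, "increase")
  expect_lte(rShuf$p, 0.01)
})

test_that("surrogate p-values are super-uniform under the null", {
  set.seed(43)
  iv <- c(0, 60)
  ev <- data.frame(start = seq(2, 57, by = 2.5), end = seq(2, 57, by = 2.5) + 0.08)
  ps <- vapply(1:300, function(s) {
    st <- poissonTrain(20, 60)
    eventRateModulation(st, ev, iv, nSurrogates = 199, seed = s)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("statistics are invariant to a joint time shift of spikes and events", {
  set.seed(44)
  st <- poissonTrain(15, 50)
  ev <- data.frame(start = seq(5, 45, by = 5), end = seq(5, 45, by = 5) + 0.1,
                   peak_time = seq(5, 45, by = 5) + 0.05)
  shift <- 123.456
  st2 <- SpikeTrain(spikeTimes(st) + shift)
  ev2 <- ev
  ev2$start <- ev$start + shift; ev2$end <- ev$end + shift
  ev2$peak_time <- ev$peak_time + shift
  expect_equal(participationFraction(st, ev), participationFraction(st2, ev2))
  expect_equal(earlySpikeFraction(st, ev), earlySpikeFraction(st2, ev2))
  r1 <- eventRateModulation(st, ev, c(0, 50), nSurrogates = 199, seed = 3)
  r2 <- eventRateModulation(st2, ev2, c(shift, 50 + shift),
                            nSurrogates = 199, seed = 3)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$rateIn, r2$rateIn)
})

test_that("participation fraction counts events with spikes and grows with gain", {
  ev <- data.frame(start = c(1, 3, 5), end = c(1.1, 3.1, 5.1))
  expect_equal(participationFraction(SpikeTrain(c(1.05, 3.05, 5.05)), ev), 1)
  expect_equal(participationFraction(SpikeTrain(numeric(0)), ev), 0)
  # monotone non-decreasing in event gain on matched seeds
  fs <- 1250
  ev2 <- data.frame(start = seq(2, 95, by = 3), end = seq(2, 95, by = 3) + 0.08,
                    core_freq = 140)
  parts <- vapply(c(1, 3, 10), function(g) {
    st <- generateSpikes(spikeModel(3, 0, 0, eventGain = g), fs,
                         durationS = 100, events = ev2, seed = 45)
    participationFraction(st, ev2)
  }, numeric(1))
  expect_true(all(diff(parts) >= 0))
  # generator truth: with base rate 0, participation equals the fraction of
  # events that received at least one generated spike
  stG <- generateSpikes(spikeModel(0.001, 0, 0, eventGain = 20000), fs,
                        durationS = 100, events = ev2, seed = 46)
  got <- vapply(seq_len(nrow(ev2)), function(i) {
    any(spikeTimes(stG) >= ev2$start[i] & spikeTimes(stG) <= ev2$end[i])
  }, logical(1))
  expect_equal(participationFraction(stG, ev2), mean(got))
})

test_that("early-spike fraction reflects spike timing relative to the envelope peak", {
  ev <- data.frame(start = c(1, 3), end = c(1.1, 3.1),
                   peak_time = c(1.05, 3.05))
  expect_equal(earlySpikeFraction(SpikeTrain(c(1.01, 3.02)), ev), 1)
  expect_equal(earlySpikeFraction(SpikeTrain(c(1.09, 3.09)), ev), 0)
  expect_warning(f <- earlySpikeFraction(SpikeTrain(10), ev), "undefined")
  expect_true(is.na(f))
  # symmetric envelope + phase-independent spiking: about one half
  set.seed(47)
  evBig <- data.frame(start = seq(1, 199, by = 1),
                      end = seq(1, 199, by = 1) + 0.1,
                      peak_time = seq(1, 199, by = 1) + 0.05)
  st <- poissonTrain(60, 200)
  expect_lt(abs(earlySpikeFraction(st, evBig) - 0.5), 0.05)
})

test_that("doublet detection counts multi-spike ripple cycles", {
  fs <- 1250
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  ripple <- LFPRecording(-cos(2 * pi * 140 * t), fs)
  ev <- data.frame(start = 1, end = 1.1)
  # two spikes 3 ms apart inside one 140 Hz cycle
  cyc <- 1 + 1 / 140 * 3 + 0.0005
  d1 <- detectDoublets(SpikeTrain(c(cyc, cyc + 0.003)), ev, ripple)
  expect_equal(d1$doubletFraction, 1)
  # one spike per cycle: no doublets
  singles <- 1 + (0:12) / 140 + 0.0035
  d2 <- detectDoublets(SpikeTrain(singles), ev, ripple)
  expect_equal(d2$doubletFraction, 0)
  expect_equal(d2$intraEventRate, 13 / 0.1, tolerance = 1e-6)
})

test_that("detected doublet fractions track the planted doublet probability", {
  scene <- plantedRippleScene(150, 40, seed = 48, sdUnits = 10)
  tr <- scene$truth$events
  fs <- scene$fs
  phv <- truthPhase(scene$truth, "events",
                    seq(0, 150 - 1 / fs, by = 1 / fs))
  rippleFilt <- bandpassFilter(scene$lfp, "ripple")
  # ground truth: events whose true cycle partition (core_freq cycles from
  # event onset) contains a multi-spike cycle, planted doublets and chance
  # coincidences alike
  truthDoubletFrac <- function(st, events) {
    mean(vapply(seq_len(nrow(events)), function(i) {
      sIn <- spikeTimes(st)[spikeTimes(st) >= events$start[i] &
                              spikeTimes(st) <= events$end[i]]
      cyc <- floor((sIn - events$start[i]) * events$core_freq[i])
      anyDuplicated(cyc) > 0L
    }, logical(1)))
  }
  fracs <- vapply(c(0.1, 0.8), function(dp) {
    m <- spikeModel(1.5, 55, 2, eventGain = 25, doubletProb = dp)
    st <- generateSpikes(m, fs, phase = phv, events = tr, seed = 49)
    det <- detectDoublets(st, tr, rippleFilt)
    expect_lt(abs(det$doubletFraction - truthDoubletFrac(st, tr)), 0.1 + 1e-9)
    det$doubletFraction
  }, numeric(1))
  expect_lt(fracs[1L], fracs[2L])
})

test_that("peri-event histograms use 40/20/40 normalized-time bins", {
  ev <- data.frame(start = c(10, 20), end = c(10.1, 20.1))
  h0 <- periEventHistogram(SpikeTrain(numeric(0)), ev)
  expect_length(h0$value, 100L)
  expect_true(all(h0$value == 0))
  expect_equal(as.vector(table(h0$span)), c(40L, 20L, 40L))
  # area: sum of during bins equals the mean in-event spike count
  set.seed(50)
  evBig <- data.frame(start = seq(2, 198, by = 2), end = seq(2, 198, by = 2) + 0.1)
  st <- poissonTrain(40, 200)
  h <- periEventHistogram(st, evBig)
  meanCount <- mean(vapply(seq_len(nrow(evBig)), function(i) {
    sum(spikeTimes(st) >= evBig$start[i] & spikeTimes(st) < evBig$end[i])
  }, numeric(1)))
  expect_equal(sum(h$value[41:60]), meanCount, tolerance = 1e-9)
  # event-gated cell: during bins elevated over the flanks
  fs <- 1250
  evG <- data.frame(start = seq(2, 195, by = 2), end = seq(2, 195, by = 2) + 0.1,
                    core_freq = 140)
  stG <- generateSpikes(spikeModel(8, 0, 0, eventGain = 5), fs,
                        durationS = 200, events = evG, seed = 51)
  hG <- periEventHistogram(stG, evG)
  expect_gt(mean(hG$value[41:60]), 2 * mean(hG$value[c(1:40, 61:100)]))
})

test_that("a uniform cell gives a flat 100-bin peri-event profile", {
  set.seed(52)
  ev <- data.frame(start = seq(2, 398, by = 2), end = seq(2, 398, by = 2) + 0.12)
  st <- poissonTrain(300, 400)
  h <- periEventHistogram(st, ev)
  expect_lt(max(h$value) / min(h$value), 1.5)
})
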