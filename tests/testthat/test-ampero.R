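# Detection and quantification are exercised on generator output (truth
# table as oracle) and on hand-built analytic pulse shapes.

test_that("a noise-only trace yields no events", {
  p <- amperoSimParams(event_rate_hz = 0, duration_s = 3, seed = 1)
  ev <- detectSpikes(simulateAmperometry(p)@trace)
  expect_equal(nrow(ev), 0)
})

test_that("eligibility filters reproduce the printed thresholds", {
  ## 10 events: 2 tiny (charge < 10 fC), 1 mid (4-7 pA band), 7 large
  amps <- c(0.8, 0.9, 5.5, rep(25, 7))
  p <- amperoSimParams(duration_s = 12, seed = 3,
                       baseline_noise_sd_pA = 0, foot_prob = 0,
                       event_times_s = seq(1, 11.8, length.out = 10),
                       spike_amps_pA = amps)
  sim <- simulateAmperometry(p)
  ev <- detectSpikes(sim@trace)
  expect_equal(nrow(ev), 10)
  expect_equal(sum(ev$eligible_frequency), 8)
  expect_identical(ev$eligible_frequency, sim@truth$eligible_frequency)
  expect_identical(ev$eligible_kinetics, sim@truth$eligible_kinetics)
  ## the 5.5 pA event: counted for frequency, excluded from kinetics
  mid <- which.min(abs(ev$amp_pA - 5.5))
  expect_true(ev$eligible_frequency[mid])
  expect_false(ev$eligible_kinetics[mid])
  ## charge of disjoint events is additive: total integral = sum
  base <- attr(ev, "baseline")
  resid <- traceValues(sim@trace) - base
  total <- sum(diff(traceTime(sim@trace))[1] * resid) * 1000
  expect_equal(sum(ev$charge_fC), total, tolerance = 0.05)
})

test_that("triangular and rectangular pulses give closed-form kinetics", {
  fs <- 25000
  t <- seq(0, 1, by = 1 / fs)
  ## symmetric triangle: amp 20 pA, base 4 ms
  tri <- pmax(0, 20 * (1 - abs(t - 0.5) / 0.002))
  ev <- spikeKinetics(currentTrace(t, tri, fs),
                      detectSpikes(currentTrace(t, tri, fs)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$half_width_ms, 2, tolerance = 0.02)
  expect_equal(ev$rise_50_90_ms, 0.8, tolerance = 0.02)
  ## rectangle: amp 15 pA, width 3 ms
  rect <- ifelse(t >= 0.5 & t < 0.503, 15, 0)
  evr <- spikeKinetics(currentTrace(t, rect, fs),
                       detectSpikes(currentTrace(t, rect, fs)))
  expect_equal(evr$half_width_ms, 3, tolerance = 0.05)
  expect_equal(evr$charge_fC, 15 * 3, tolerance = 1)
})

test_that("spike kinetics on generator events match the filtered template", {
  p <- amperoSimParams(duration_s = 5, seed = 8, baseline_noise_sd_pA = 0,
                       event_times_s = c(1, 2.5, 4),
                       spike_amps_pA = rep(30, 3), foot_prob = 0)
  sim <- simulateAmperometry(p)
  ev <- spikeKinetics(sim@trace, detectSpikes(sim@trace))
  ## 2 kHz filtering broadens the template slightly; accept 15%
  expect_equal(ev$rise_50_90_ms, sim@truth$rise_50_90_ms,
               tolerance = 0.15)
  expect_equal(ev$half_width_ms, sim@truth$half_width_ms,
               tolerance = 0.05)
  expect_equal(ev$charge_fC, sim@truth$charge_fC, tolerance = 0.03)
})

test_that("feet are detected with duration, charge and the 2 ms rule", {
  mk <- function(dur_ms) amperoSimParams(
    duration_s = 4, seed = 5, baseline_noise_sd_pA = 0,
    event_times_s = c(1, 2, 3), spike_amps_pA = rep(25, 3),
    foot_prob = 1, foot_duration_mean_ms = dur_ms,
    foot_duration_sd_ms = 0, foot_amp_mean_pA = 6, foot_amp_sd_pA = 0)
  sim <- simulateAmperometry(mk(4))
  ev <- detectFoot(sim@trace, detectSpikes(sim@trace))
  expect_true(all(ev$foot_present))
  expect_true(all(ev$foot_analyzable))
  ## the takeoff (second-derivative maximum) sits partway up the spike
  ## upstroke, so measured durations overshoot the injected plateau end
  ## by a sub-millisecond offset
  expect_true(all(ev$foot_duration_ms > 3.9 & ev$foot_duration_ms < 5))
  ## charge ~ plateau amplitude x duration: 6 pA x 4 ms ~ 24 fC
  expect_equal(ev$foot_charge_fC, rep(24, 3), tolerance = 0.08)
  ## a 1 ms foot is detected but not analyzable
  sim2 <- simulateAmperometry(mk(1.0))
  ev2 <- detectFoot(sim2@trace, detectSpikes(sim2@trace))
  expect_true(all(ev2$foot_present))
  expect_false(any(ev2$foot_analyzable))
  expect_error(footFlickerStats(sim2@trace, ev2, 1), "2 ms")
  ## footless events have no foot
  p0 <- amperoSimParams(duration_s = 3, seed = 5, baseline_noise_sd_pA = 0,
                        event_times_s = c(1, 2), spike_amps_pA = c(25, 25),
                        foot_prob = 0)
  sim0 <- simulateAmperometry(p0)
  ev0 <- detectFoot(sim0@trace, detectSpikes(sim0@trace))
  expect_false(any(ev0$foot_present))
})

test_that("flicker counting obeys the derivative threshold", {
  mk <- function(slope, seed = 11) amperoSimParams(
    duration_s = 6, seed = seed, baseline_noise_sd_pA = 0,
    event_times_s = 1:5, spike_amps_pA = rep(25, 5),
    foot_prob = 1, foot_duration_mean_ms = 5, foot_duration_sd_ms = 0,
    foot_amp_mean_pA = 6, foot_amp_sd_pA = 0,
    flicker_rate_per_ms = 1, flicker_amp_pAms = slope)
  ## suprathreshold 12 pA/ms pulses: count matches injection exactly
  sim <- simulateAmperometry(mk(12))
  ev <- analyzeAmperometry(sim@trace)
  expect_identical(as.integer(ev$flicker_count),
                   as.integer(sim@truth$flicker_count))
  expect_equal(ev$flicker_freq_per_ms,
               ev$flicker_count / ev$foot_duration_ms)
  ## sub-threshold 4 pA/ms pulses: nothing counted
  ev_sub <- analyzeAmperometry(simulateAmperometry(mk(4))@trace)
  expect_true(all(ev_sub$flicker_count == 0))
  ## a plain linear-ramp foot (constant slope < 6 pA/ms): no flickers
  ev_none <- analyzeAmperometry(simulateAmperometry(
    amperoSimParams(duration_s = 3, seed = 2, baseline_noise_sd_pA = 0,
                    event_times_s = c(1, 2), spike_amps_pA = c(25, 25),
                    foot_prob = 1, foot_duration_mean_ms = 5,
                    foot_duration_sd_ms = 0, foot_amp_mean_pA = 6,
                    foot_amp_sd_pA = 0))@trace)
  expect_true(all(ev_none$flicker_count == 0))
})

test_that("raising the flicker threshold never increases the count", {
  p <- amperoSimParams(duration_s = 6, seed = 13, baseline_noise_sd_pA = 0.5,
                       event_times_s = 1:5, spike_amps_pA = rep(25, 5),
                       foot_prob = 1, foot_duration_mean_ms = 5,
                       foot_duration_sd_ms = 0, foot_amp_mean_pA = 6,
                       foot_amp_sd_pA = 0, flicker_rate_per_ms = 1,
                       flicker_amp_pAms = 12)
  tr <- simulateAmperometry(p)@trace
  ev <- detectFoot(tr, detectSpikes(tr))
  last <- Inf
  for (thr in c(4, 6, 8, 12)) {
    cnt <- sum(footFlickers(tr, ev, threshold_pAms = thr)$flicker_count,
               na.rm = TRUE)
    expect_lte(cnt, last)
    last <- cnt
  }
})

test_that("flicker frequency is invariant to a trace-wide offset", {
  p <- amperoSimParams(duration_s = 4, seed = 17, baseline_noise_sd_pA = 0.5,
                       event_times_s = c(1, 2, 3), spike_amps_pA = rep(25, 3),
                       foot_prob = 1, foot_duration_mean_ms = 5,
                       foot_duration_sd_ms = 0, foot_amp_mean_pA = 6,
                       foot_amp_sd_pA = 0, flicker_rate_per_ms = 1,
                       flicker_amp_pAms = 12)
  tr <- simulateAmperometry(p)@trace
  tr_off <- currentTrace(traceTime(tr), traceValues(tr) + 50,
                         sampleRate = sampleRate(tr))
  ev <- analyzeAmperometry(tr)
  ev_off <- analyzeAmperometry(tr_off)
  expect_identical(ev$flicker_count, ev_off$flicker_count)
  expect_equal(ev$flicker_freq_per_ms, ev_off$flicker_freq_per_ms)
})

test_that("event frequency counts eligible events per second", {
  p <- amperoSimParams(duration_s = 10, seed = 3, baseline_noise_sd_pA = 0,
                       foot_prob = 0,
                       event_times_s = seq(1, 9, length.out = 8),
                       spike_amps_pA = rep(20, 8))
  sim <- simulateAmperometry(p)
  ev <- detectSpikes(sim@trace)
  expect_equal(eventFrequency(sim@trace, ev), 0.8, tolerance = 0.001)
  empty <- detectSpikes(simulateAmperometry(
    amperoSimParams(event_rate_hz = 0, duration_s = 2, seed = 1))@trace)
  expect_equal(eventFrequency(sim@trace, empty), 0)
})

test_that("cell summaries weight cells, not events", {
  ev <- data.frame(cell = rep(c("c1", "c2"), c(3, 7)),
                   amp_pA = c(1, 2, 9, rep(4, 7)))
  cs <- cellSummary(ev, min_events = 1)
  expect_equal(sort(cs$per_cell$amp_pA), c(2, 4))
  ## equal cell weighting regardless of event counts
  expect_equal(cs$summary$mean_of_medians[cs$summary$parameter == "amp_pA"],
               3)
  ## the >20 events rule excludes sparse cells
  cs20 <- suppressWarnings(cellSummary(ev))
  expect_false(any(cs20$per_cell$included))
  expect_error(cellSummary(ev[0, ]), "no events")
  ## order-statistic recovery: medians of generated cells
  set.seed(42)
  evb <- do.call(rbind, lapply(1:6, function(i)
    data.frame(cell = paste0("c", i), amp_pA = rnorm(200, mean = 10))))
  csb <- cellSummary(evb, min_events = 21)
  expect_equal(
    csb$summary$mean_of_medians[csb$summary$parameter == "amp_pA"],
    10, tolerance = 0.1)
})
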