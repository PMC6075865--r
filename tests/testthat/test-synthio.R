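test_that("flash generator reduces to a constant in the degenerate case", {
  p <- flashSimParams(A0_fF = 4200, A_rrp_fF = 0, A_srp_fF = 0,
                      k_sus_fFps = 0, pre_rate_fFps = 0, noise_sd_fF = 0)
  tr <- simulateFlashTrace(p)
  expect_equal(length(traceValues(tr)),
               round(p@duration_s * p@sample_rate_hz))
  expect_true(all(traceValues(tr) == 4200))
})

test_that("noiseless flash trace follows the generating law exactly", {
  p <- flashSimParams(A0_fF = 5000, A_rrp_fF = 150, tau_rrp_ms = 20,
                      A_srp_fF = 200, tau_srp_ms = 250, k_sus_fFps = 15,
                      onset_delay_ms = 2, noise_sd_fF = 0)
  tr <- simulateFlashTrace(p)
  t <- traceTime(tr)
  expect_equal(traceValues(tr), flashModel(t, p))
  ## asymptotic flash-locked rise above baseline: A1 + A2 + k t'
  t_on <- p@flash_time_s + p@onset_delay_ms / 1000
  late <- t > t_on + 2.5           # both exponentials fully decayed
  tp <- t[late] - t_on
  expect_equal(traceValues(tr)[late] - 5000, 150 + 200 + 15 * tp,
               tolerance = 1e-4)
  ## continuity at the onset: no step
  i_on <- which(t >= t_on)[1]
  expect_lt(abs(traceValues(tr)[i_on] - traceValues(tr)[i_on - 1]), 1)
})

test_that("flash generator is seed-deterministic", {
  p <- flashSimParams(noise_sd_fF = 5, seed = 42L)
  expect_identical(traceValues(simulateFlashTrace(p)),
                   traceValues(simulateFlashTrace(p)))
  p2 <- flashSimParams(noise_sd_fF = 5, seed = 43L)
  expect_false(identical(traceValues(simulateFlashTrace(p)),
                         traceValues(simulateFlashTrace(p2))))
})

test_that("flash parameter invariants are enforced", {
  expect_error(flashSimParams(tau_rrp_ms = 300, tau_srp_ms = 250),
               "tau_rrp_ms")
  expect_error(flashSimParams(A_rrp_fF = -1), "A_rrp_fF")
  expect_error(flashSimParams(flash_time_s = 7, duration_s = 6), "inside")
})

test_that("amperometric generator with zero rate gives noise only", {
  p <- amperoSimParams(event_rate_hz = 0, duration_s = 2, seed = 5)
  sim <- simulateAmperometry(p)
  expect_equal(nrow(sim@truth), 0)
  expect_lt(max(abs(traceValues(sim@trace))), 5)   # pure filtered noise
  expect_gt(stats::sd(traceValues(sim@trace)), 0)
})

test_that("event counts follow the Poisson mean over many seeds", {
  counts <- vapply(1:200, function(s) {
    p <- amperoSimParams(event_rate_hz = 2, duration_s = 10, seed = s,
                         baseline_noise_sd_pA = 0, foot_prob = 0)
    nrow(simulateAmperometry(p)@truth)
  }, numeric(1))
  ## mean within 3 standard errors of rate x duration
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 200))
})

test_that("injected flicker counts average near rate x foot duration", {
  counts <- unlist(lapply(1:60, function(s) {
    p <- amperoSimParams(duration_s = 4, seed = s,
                         baseline_noise_sd_pA = 0,
                         event_times_s = c(1, 2, 3),
                         spike_amps_pA = rep(25, 3), foot_prob = 1,
                         foot_duration_mean_ms = 5, foot_duration_sd_ms = 0,
                         foot_amp_mean_pA = 6, foot_amp_sd_pA = 0,
                         foot_ramp_frac = 0.1, flicker_rate_per_ms = 1)
    simulateAmperometry(p)@truth$flicker_count
  }))
  ## the generator truncates Poisson(5) at the plateau's slot capacity;
  ## oracle: capped-Poisson mean at the default geometry (capacity 7)
  oracle <- cappedPoissonMean(5, 7)
  expect_lt(abs(mean(counts) - oracle), 3 * stats::sd(counts) / sqrt(length(counts)))
  expect_gt(mean(counts), 0.85 * 5)   # approximately 5 per 5 ms foot
})

test_that("amperometric generator is seed-deterministic", {
  p <- amperoSimParams(event_rate_hz = 1, duration_s = 3, seed = 9,
                       flicker_rate_per_ms = 0.5)
  s1 <- simulateAmperometry(p); s2 <- simulateAmperometry(p)
  expect_identical(traceValues(s1@trace), traceValues(s2@trace))
  expect_identical(s1@truth, s2@truth)
})

test_that("assembly law hits its analytic landmarks", {
  p <- assemblySimParams(SC0_au = 0.2, SCinf_au = 1.4, cv_noise = 0)
  ## law at t = 0
  expect_equal(assemblyLaw(0, 0.2, 1.4, p@A0_M, p@k_M1s1), 0.2)
  ## half-saturation where A0 k t = 1
  t_half <- 1 / (p@A0_M * p@k_M1s1 * 60)
  expect_equal(assemblyLaw(t_half, 0.2, 1.4, p@A0_M, p@k_M1s1),
               0.2 + (1.4 - 0.2) / 2)
  ## 99% of the span where A0 k t = 99
  t99 <- 99 / (p@A0_M * p@k_M1s1 * 60)
  expect_equal(assemblyLaw(t99, 0.2, 1.4, p@A0_M, p@k_M1s1),
               0.2 + 0.99 * (1.4 - 0.2))
})

test_that("noiseless assembly generator returns the law exactly", {
  p <- assemblySimParams(cv_noise = 0)
  tc <- simulateAssembly(p)
  expect_equal(traceValues(tc),
               assemblyLaw(p@times_min, p@SC0_au, p@SCinf_au, p@A0_M,
                           p@k_M1s1))
  ## determinism with noise
  pn <- assemblySimParams(cv_noise = 0.1, seed = 7)
  expect_identical(traceValues(simulateAssembly(pn)),
                   traceValues(simulateAssembly(pn)))
})

test_that("assembly parameter invariants are enforced", {
  expect_error(assemblySimParams(SC0_au = 2, SCinf_au = 1), "SCinf")
  expect_error(assemblySimParams(k_M1s1 = -5), "positive")
  expect_error(assemblySimParams(times_min = c(0, 10, 5)), "increasing")
})
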