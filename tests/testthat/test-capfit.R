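test_that("noiseless flash responses are recovered to machine tolerance", {
  p <- flashSimParams(A0_fF = 5000, A_rrp_fF = 150, tau_rrp_ms = 20,
                      A_srp_fF = 200, tau_srp_ms = 250, k_sus_fFps = 15,
                      onset_delay_ms = 3, noise_sd_fF = 0)
  fit <- fitFlashResponse(simulateFlashTrace(p))
  expect_true(fit@converged)
  expect_equal(fit@A0_fF, 5000, tolerance = 1e-6)
  expect_equal(fit@A_rrp_fF, 150, tolerance = 1e-6)
  expect_equal(fit@tau_rrp_ms, 20, tolerance = 1e-6)
  expect_equal(fit@A_srp_fF, 200, tolerance = 1e-6)
  expect_equal(fit@tau_srp_ms, 250, tolerance = 1e-6)
  expect_equal(fit@k_sus_fFps, 15, tolerance = 1e-6)
  expect_equal(fit@delay_ms, 3, tolerance = 1e-3)
})

test_that("a burst-free trace yields near-zero amplitudes and rate", {
  p <- flashSimParams(A0_fF = 4100, A_rrp_fF = 0, A_srp_fF = 0,
                      k_sus_fFps = 0, noise_sd_fF = 0)
  fit <- fitFlashResponse(simulateFlashTrace(p))
  expect_equal(fit@A0_fF, 4100, tolerance = 1e-6)
  expect_lt(fit@A_rrp_fF, 1e-3)
  expect_lt(fit@A_srp_fF, 1e-3)
  expect_lt(abs(fit@k_sus_fFps), 1e-3)
})

test_that("pool sizes are recovered without bias from noisy traces", {
  fits <- lapply(1:50, function(s) {
    p <- flashSimParams(A_rrp_fF = 150, A_srp_fF = 200, noise_sd_fF = 5,
                        onset_delay_ms = 2, seed = s)
    fitFlashResponse(simulateFlashTrace(p))
  })
  expect_true(all(vapply(fits, function(f) f@converged, logical(1))))
  a1 <- vapply(fits, function(f) f@A_rrp_fF, numeric(1))
  a2 <- vapply(fits, function(f) f@A_srp_fF, numeric(1))
  expect_lt(abs(mean(a1) - 150) / 150, 0.05)
  expect_lt(abs(mean(a2) - 200) / 200, 0.05)
  ## tau ordering is a structural invariant, never start-dependent
  expect_true(all(vapply(fits, function(f)
    f@tau_rrp_ms < f@tau_srp_ms, logical(1))))
  ## mean delay unbiased within its Monte-Carlo confidence interval
  d <- vapply(fits, function(f) f@delay_ms, numeric(1))
  expect_lt(abs(mean(d) - 2), 3 * stats::sd(d) / sqrt(length(d)) + 0.05)
})

test_that("secretory delay follows the generator onset", {
  for (delay in c(0, 3)) {
    p <- flashSimParams(onset_delay_ms = delay, noise_sd_fF = 0)
    fit <- fitFlashResponse(simulateFlashTrace(p))
    expect_equal(secretoryDelay(fit), delay, tolerance = 0.1)
  }
  bad <- new("FlashFit", A0_fF = 0, A_rrp_fF = NA_real_,
             tau_rrp_ms = NA_real_, A_srp_fF = NA_real_,
             tau_srp_ms = NA_real_, k_sus_fFps = NA_real_,
             onset_s = NA_real_, delay_ms = NA_real_,
             residual_rms_fF = NA_real_, converged = FALSE)
  expect_error(secretoryDelay(bad), "non-converged")
})

test_that("tonic rate is the least-squares slope", {
  t <- seq(0, 10, by = 0.01)
  expect_equal(tonicRate(capacitanceTrace(t, 5000 + 2 * t)), 2)
  expect_equal(tonicRate(capacitanceTrace(t, rep(5000, length(t)))), 0)
  ## generator oracle: pre-flash ramp under noise
  rates <- vapply(1:30, function(s) {
    p <- flashSimParams(pre_rate_fFps = 1.5, noise_sd_fF = 2,
                        flash_time_s = 121, duration_s = 122,
                        sample_rate_hz = 100, seed = s)
    tonicRate(simulateFlashTrace(p), window_s = c(0, 120))
  }, numeric(1))
  expect_lt(abs(mean(rates) - 1.5), 0.1)
  expect_error(tonicRate(capacitanceTrace(t, 5000 + 2 * t,
                                          flashTime = 5),
                         window_s = c(0, 8)),
               "before the flash")
  expect_error(tonicRate(capacitanceTrace(t, 5000 + 2 * t),
                         window_s = c(0, 0.001)), "2 samples")
})

test_that("total capacitance rise matches ramps exactly and adds linearly", {
  t <- seq(0, 125, by = 0.1)
  ramp <- capacitanceTrace(t, 2 * t)
  expect_equal(deltaCm(ramp, 120), 240)
  expect_equal(deltaCm(capacitanceTrace(t, rep(7, length(t))), 120), 0)
  ## linearity on noiseless inputs
  tr_a <- capacitanceTrace(t, 2 * t)
  tr_b <- capacitanceTrace(t, 100 + 0.5 * t^0.8)
  tr_ab <- capacitanceTrace(t, 2 * t + 100 + 0.5 * t^0.8)
  expect_equal(deltaCm(tr_ab, 120),
               deltaCm(tr_a, 120) + deltaCm(tr_b, 120), tolerance = 1e-9)
  expect_error(deltaCm(ramp, 500), "shorter")
  ## unbiased on noisy ramps
  d <- vapply(1:50, function(s) {
    set.seed(s)
    deltaCm(capacitanceTrace(t, 2 * t + rnorm(length(t), 0, 2)), 120)
  }, numeric(1))
  expect_lt(abs(mean(d) - 240), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("flash fitting rejects unusable windows", {
  p <- flashSimParams(noise_sd_fF = 0)
  tr <- simulateFlashTrace(p)
  expect_error(fitFlashResponse(tr, fit_window_s = c(0.5, 1.0)), "1 s")
  tr_noflash <- capacitanceTrace(traceTime(tr), traceValues(tr))
  expect_error(fitFlashResponse(tr_noflash), "flash_time")
})
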