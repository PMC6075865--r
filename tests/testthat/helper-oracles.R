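# Independent oracles used to freeze expected values.

# Exact two-sided Mann-Whitney p by brute-force enumeration of all
# choose(n+m, n) group assignments of the pooled sample.
enumerateMWU <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  u_stat <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
  }
  u_obs <- u_stat(a, b)
  mu <- n * length(b) / 2
  dev_obs <- abs(u_obs - mu)
  devs <- apply(idx, 2, function(i) {
    abs(u_stat(pooled[i], pooled[-i]) - mu)
  })
  mean(devs >= dev_obs - 1e-12)
}

# Mean of min(Poisson(lambda), cap) by direct enumeration.
cappedPoissonMean <- function(lambda, cap, kmax = 200) {
  k <- 0:kmax
  sum(pmin(k, cap) * stats::dpois(k, lambda))
}

# Hydrophobic moment with an explicit phase origin, straight from the
# vector-sum definition (used for rotation-invariance checks).
muHWithPhase <- function(H, delta_deg, phase_deg) {
  ang <- (seq_along(H) * delta_deg + phase_deg) * pi / 180
  sqrt(sum(H * sin(ang))^2 + sum(H * cos(ang))^2) / length(H)
}

# Angular span (smallest arc containing all angles), by brute force over
# candidate gap positions.
angularSpan <- function(angles_deg) {
  a <- sort(angles_deg %% 360)
  if (length(a) < 2) return(0)
  gaps <- diff(c(a, a[1] + 360))
  360 - max(gaps)
}

# Poisson-placed event generator used in detection-fidelity loops.
noisyAmperoParams <- function(seed, ...) {
  amperoSimParams(event_rate_hz = 1, duration_s = 10, seed = seed,
                  baseline_noise_sd_pA = 1, spike_amp_mean_pA = 15,
                  spike_amp_cv = 0.3, foot_prob = 0.5, ...)
}

# Match detected to truth events by peak time (tolerance in seconds).
matchEvents <- function(truth_t, det_t, tol = 0.003) {
  list(
    sens = if (length(truth_t))
      mean(vapply(truth_t, function(tp) any(abs(det_t - tp) < tol),
                  logical(1))) else NA_real_,
    false_pos = sum(vapply(det_t, function(tp)
      !any(abs(truth_t - tp) < tol), logical(1)))
  )
}
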