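## Seeded generators for the three recording modalities the package
## analyzes. Every generator draws all randomness from one explicit
## integer seed and restores the caller's RNG state on exit, so identical
## parameters + seed give bitwise-identical output.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Flash-trace simulation parameters
#'
#' Parameters of the synthetic flash-evoked capacitance response:
#' a tonic pre-flash ramp, then (after the exocytotic onset delay) a
#' double-exponential burst plus a linear sustained component, with
#' additive Gaussian noise. The flash-locked component starts at the
#' back-extrapolated baseline value at `flash_time_s + onset_delay_ms`
#' (no step), so delay recovery is well-posed.
#'
#' @slot A0_fF baseline capacitance (fF).
#' @slot A_rrp_fF,tau_rrp_ms RRP burst amplitude (fF) and time constant (ms).
#' @slot A_srp_fF,tau_srp_ms SRP burst amplitude (fF) and time constant (ms).
#' @slot k_sus_fFps sustained rate (fF/s).
#' @slot flash_time_s flash instant (s).
#' @slot onset_delay_ms exocytotic delay between flash and burst onset (ms).
#' @slot pre_rate_fFps tonic pre-flash rate (fF/s).
#' @slot noise_sd_fF additive Gaussian noise SD (fF).
#' @slot duration_s,sample_rate_hz trace length (s) and sampling rate (Hz).
#' @slot seed integer RNG seed.
#' @seealso [flashSimParams()], [simulateFlashTrace()]
#' @export
setClass("FlashSimParams",
  representation(
    A0_fF = "numeric", A_rrp_fF = "numeric", tau_rrp_ms = "numeric",
    A_srp_fF = "numeric", tau_srp_ms = "numeric", k_sus_fFps = "numeric",
    flash_time_s = "numeric", onset_delay_ms = "numeric",
    pre_rate_fFps = "numeric", noise_sd_fF = "numeric",
    duration_s = "numeric", sample_rate_hz = "numeric", seed = "integer"
  )
)

setValidity("FlashSimParams", function(object) {
  msg <- character()
  if (object@tau_rrp_ms >= object@tau_srp_ms)
    msg <- c(msg, "tau_rrp_ms must be smaller than tau_srp_ms")
  for (f in c("A_rrp_fF", "A_srp_fF", "noise_sd_fF", "onset_delay_ms"))
    if (slot(object, f) < 0) msg <- c(msg, paste(f, "must be >= 0"))
  if (object@duration_s <= 0 || object@sample_rate_hz <= 0)
    msg <- c(msg, "duration_s and sample_rate_hz must be positive")
  onset <- object@flash_time_s + object@onset_delay_ms / 1000
  if (!is.na(object@flash_time_s) &&
      (onset <= 0 || onset >= object@duration_s))
    msg <- c(msg, "flash_time_s + onset delay must fall inside (0, duration)")
  if (length(msg)) msg else TRUE
})

#' Create flash-trace simulation parameters
#'
#' Defaults emulate a chromaffin-cell Ca2+-uncaging experiment: a 4 pF
#' cell, RRP and SRP bursts of order 10^2 fF with ~20 ms and ~250 ms time
#' constants, a sustained rate of ~15 fF/s, the flash at t = 0.5 s, and a
#' few-millisecond secretory delay.
#'
#' @param A0_fF,A_rrp_fF,tau_rrp_ms,A_srp_fF,tau_srp_ms,k_sus_fFps model
#'   parameters (see [FlashSimParams-class]).
#' @param flash_time_s,onset_delay_ms,pre_rate_fFps stimulus timing and
#'   tonic pre-flash rate.
#' @param noise_sd_fF,duration_s,sample_rate_hz,seed acquisition settings.
#' @return A validated [FlashSimParams-class] object.
#' @export
flashSimParams <- function(A0_fF = 4000, A_rrp_fF = 150, tau_rrp_ms = 20,
                           A_srp_fF = 200, tau_srp_ms = 250,
                           k_sus_fFps = 15, flash_time_s = 0.5,
                           onset_delay_ms = 2, pre_rate_fFps = 0,
                           noise_sd_fF = 5, duration_s = 6,
                           sample_rate_hz = 1000, seed = 1L) {
  new("FlashSimParams", A0_fF = A0_fF, A_rrp_fF = A_rrp_fF,
      tau_rrp_ms = tau_rrp_ms, A_srp_fF = A_srp_fF, tau_srp_ms = tau_srp_ms,
      k_sus_fFps = k_sus_fFps, flash_time_s = flash_time_s,
      onset_delay_ms = onset_delay_ms, pre_rate_fFps = pre_rate_fFps,
      noise_sd_fF = noise_sd_fF, duration_s = duration_s,
      sample_rate_hz = sample_rate_hz, seed = as.integer(seed))
}

#' Amperometric-trace simulation parameters
#'
#' Phenomenological model of carbon-fiber amperometry: Poisson-placed
#' secretory events, each an optional prespike foot (linear ramp to a
#' plateau) followed by a log-normal-shaped main spike; brief slope
#' excursions ("flickers") injected into the foot plateau; Gaussian
#' baseline noise; the whole trace low-pass filtered at `filter_cutoff_hz`
#' (Gaussian FIR, see [gaussianLowpass()]).
#'
#' A flicker is a single slope pulse: a linear step of the foot current
#' by `flicker_amp_pAms * flicker_rise_ms` pA over `flicker_rise_ms` ms.
#' Pulses alternate in sign (up, down, up, ...) so the foot toggles
#' between two levels and each injected pulse produces exactly one
#' excursion of the current derivative, of alternating polarity;
#' same-polarity pulses are spaced far enough apart that the derivative
#' filter cannot merge their excursions.
#'
#' @slot event_rate_hz Poisson event rate (Hz).
#' @slot spike_amp_mean_pA,spike_amp_cv log-normal main-spike amplitude
#'   distribution (mean, coefficient of variation).
#' @slot spike_t_peak_ms,spike_sigma log-normal spike template shape:
#'   time-to-peak (ms) and dimensionless log-width.
#' @slot spike_charge_range_fC admissible spike charge range; amplitude
#'   draws are rejected outside it (set to `c(0, Inf)` to disable).
#' @slot foot_prob fraction of events preceded by a foot.
#' @slot foot_duration_mean_ms,foot_duration_sd_ms,foot_amp_mean_pA,foot_amp_sd_pA
#'   foot duration and plateau-amplitude distributions (truncated normal).
#' @slot foot_ramp_frac fraction of the foot occupied by the initial ramp.
#' @slot flicker_rate_per_ms Poisson rate of flickers within the plateau.
#' @slot flicker_amp_pAms flicker rising slope (pA/ms).
#' @slot flicker_rise_ms duration of the flicker rise (ms).
#' @slot baseline_noise_sd_pA Gaussian noise SD before filtering (pA).
#' @slot filter_cutoff_hz,sample_rate_hz acquisition chain (2 kHz / 25 kHz).
#' @slot duration_s,seed trace length and RNG seed.
#' @slot event_times_s,spike_amps_pA optional fixed event times and
#'   amplitudes overriding the random draws (length 0 = draw randomly).
#' @seealso [amperoSimParams()], [simulateAmperometry()]
#' @export
setClass("AmperoSimParams",
  representation(
    event_rate_hz = "numeric",
    spike_amp_mean_pA = "numeric", spike_amp_cv = "numeric",
    spike_t_peak_ms = "numeric", spike_sigma = "numeric",
    spike_charge_range_fC = "numeric",
    foot_prob = "numeric",
    foot_duration_mean_ms = "numeric", foot_duration_sd_ms = "numeric",
    foot_amp_mean_pA = "numeric", foot_amp_sd_pA = "numeric",
    foot_ramp_frac = "numeric",
    flicker_rate_per_ms = "numeric", flicker_amp_pAms = "numeric",
    flicker_rise_ms = "numeric",
    baseline_noise_sd_pA = "numeric",
    filter_cutoff_hz = "numeric", sample_rate_hz = "numeric",
    duration_s = "numeric", seed = "integer",
    event_times_s = "numeric", spike_amps_pA = "numeric"
  )
)

setValidity("AmperoSimParams", function(object) {
  msg <- character()
  if (object@sample_rate_hz < 2 * object@filter_cutoff_hz)
    msg <- c(msg, "sample_rate_hz must be at least twice filter_cutoff_hz")
  for (f in c("event_rate_hz", "baseline_noise_sd_pA",
              "flicker_rate_per_ms", "foot_duration_sd_ms", "foot_amp_sd_pA"))
    if (slot(object, f) < 0) msg <- c(msg, paste(f, "must be >= 0"))
  if (object@foot_prob < 0 || object@foot_prob > 1)
    msg <- c(msg, "foot_prob must lie in [0, 1]")
  if (object@duration_s <= 0) msg <- c(msg, "duration_s must be positive")
  if (object@foot_ramp_frac <= 0 || object@foot_ramp_frac >= 1)
    msg <- c(msg, "foot_ramp_frac must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Create amperometric simulation parameters
#'
#' Defaults emulate chromaffin-cell granule release recorded at 25 kHz
#' and filtered at 2 kHz: ~20 pA spikes of 50-200 fC, 60% of events with
#' a 2-6 ms, ~6 pA prespike foot, and ~1 pA baseline noise.
#'
#' @param event_rate_hz,duration_s,seed trace layout.
#' @param spike_amp_mean_pA,spike_amp_cv,spike_t_peak_ms,spike_sigma,spike_charge_range_fC
#'   main-spike distribution and template shape.
#' @param foot_prob,foot_duration_mean_ms,foot_duration_sd_ms,foot_amp_mean_pA,foot_amp_sd_pA,foot_ramp_frac
#'   prespike-foot distribution.
#' @param flicker_rate_per_ms,flicker_amp_pAms,flicker_rise_ms fusion-pore
#'   flicker process.
#' @param baseline_noise_sd_pA,filter_cutoff_hz,sample_rate_hz acquisition.
#' @param event_times_s,spike_amps_pA optional deterministic overrides.
#' @return A validated [AmperoSimParams-class] object.
#' @export
amperoSimParams <- function(event_rate_hz = 0.5, duration_s = 10, seed = 1L,
                            spike_amp_mean_pA = 20, spike_amp_cv = 0.4,
                            spike_t_peak_ms = 2, spike_sigma = 0.45,
                            spike_charge_range_fC = c(0, Inf),
                            foot_prob = 0.6,
                            foot_duration_mean_ms = 4,
                            foot_duration_sd_ms = 1,
                            foot_amp_mean_pA = 6, foot_amp_sd_pA = 1,
                            foot_ramp_frac = 0.3,
                            flicker_rate_per_ms = 0,
                            flicker_amp_pAms = 12, flicker_rise_ms = 0.3,
                            baseline_noise_sd_pA = 1,
                            filter_cutoff_hz = 2000,
                            sample_rate_hz = 25000,
                            event_times_s = numeric(0),
                            spike_amps_pA = numeric(0)) {
  new("AmperoSimParams", event_rate_hz = event_rate_hz,
      spike_amp_mean_pA = spike_amp_mean_pA, spike_amp_cv = spike_amp_cv,
      spike_t_peak_ms = spike_t_peak_ms, spike_sigma = spike_sigma,
      spike_charge_range_fC = spike_charge_range_fC,
      foot_prob = foot_prob,
      foot_duration_mean_ms = foot_duration_mean_ms,
      foot_duration_sd_ms = foot_duration_sd_ms,
      foot_amp_mean_pA = foot_amp_mean_pA, foot_amp_sd_pA = foot_amp_sd_pA,
      foot_ramp_frac = foot_ramp_frac,
      flicker_rate_per_ms = flicker_rate_per_ms,
      flicker_amp_pAms = flicker_amp_pAms, flicker_rise_ms = flicker_rise_ms,
      baseline_noise_sd_pA = baseline_noise_sd_pA,
      filter_cutoff_hz = filter_cutoff_hz, sample_rate_hz = sample_rate_hz,
      duration_s = duration_s, seed = as.integer(seed),
      event_times_s = as.numeric(event_times_s),
      spike_amps_pA = as.numeric(spike_amps_pA))
}

#' Assembly time-course simulation parameters
#'
#' Parameters of the integrated second-order law
#' `SC(t) = SC0 + (SCinf - SC0) * A0 k t / (A0 k t + 1)` (equimolar
#' reactants) with multiplicative Gaussian noise.
#'
#' @slot SC0_au,SCinf_au densitometry values at t = 0 and t = Inf (a.u.).
#' @slot A0_M initial reactant concentration (mol/L).
#' @slot k_M1s1 rate constant (1/(M s)).
#' @slot times_min sampling times (min), strictly increasing, >= 0.
#' @slot cv_noise multiplicative noise coefficient of variation.
#' @slot seed integer RNG seed.
#' @seealso [assemblySimParams()], [simulateAssembly()]
#' @export
setClass("AssemblySimParams",
  representation(
    SC0_au = "numeric", SCinf_au = "numeric", A0_M = "numeric",
    k_M1s1 = "numeric", times_min = "numeric", cv_noise = "numeric",
    seed = "integer"
  )
)

setValidity("AssemblySimParams", function(object) {
  msg <- character()
  if (!(object@SCinf_au > object@SC0_au) || object@SC0_au < 0)
    msg <- c(msg, "need SCinf_au > SC0_au >= 0")
  if (object@k_M1s1 <= 0 || object@A0_M <= 0)
    msg <- c(msg, "k_M1s1 and A0_M must be positive")
  if (any(object@times_min < 0) ||
      (length(object@times_min) > 1 && any(diff(object@times_min) <= 0)))
    msg <- c(msg, "times_min must be non-negative and strictly increasing")
  if (object@cv_noise < 0) msg <- c(msg, "cv_noise must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create assembly simulation parameters
#'
#' Defaults emulate the in-vitro assay the package models: 3 uM limiting
#' reactant, sampling out to 240 min, and ~10% multiplicative
#' densitometry noise.
#'
#' @param SC0_au,SCinf_au,A0_M,k_M1s1 law parameters.
#' @param times_min sampling times (min).
#' @param cv_noise multiplicative noise CV.
#' @param seed RNG seed.
#' @return A validated [AssemblySimParams-class] object.
#' @export
assemblySimParams <- function(SC0_au = 0.05, SCinf_au = 1, A0_M = 3e-6,
                              k_M1s1 = 300,
                              times_min = c(0, 5, 15, 30, 60, 90, 120, 180, 240),
                              cv_noise = 0.1, seed = 1L) {
  new("AssemblySimParams", SC0_au = SC0_au, SCinf_au = SCinf_au,
      A0_M = A0_M, k_M1s1 = k_M1s1, times_min = as.numeric(times_min),
      cv_noise = cv_noise, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Flash trace generator
## ---------------------------------------------------------------------------

#' Evaluate the flash-response model
#'
#' Noise-free value of the synthetic flash response at arbitrary times:
#' tonic ramp `A0 + pre_rate * t` up to the burst onset, then (with the
#' baseline frozen at its onset value) the double-exponential burst plus
#' sustained line in the time since onset.
#'
#' @param t_s times (s).
#' @param params a [FlashSimParams-class] object.
#' @return Numeric capacitance values (fF).
#' @export
flashModel <- function(t_s, params) {
  t_on <- params@flash_time_s + params@onset_delay_ms / 1000
  base <- params@A0_fF + params@pre_rate_fFps * pmin(t_s, t_on)
  tp <- pmax(t_s - t_on, 0)
  on <- as.numeric(t_s >= t_on)
  base + on * (
    params@A_rrp_fF * (1 - exp(-tp / (params@tau_rrp_ms / 1000))) +
    params@A_srp_fF * (1 - exp(-tp / (params@tau_srp_ms / 1000))) +
    params@k_sus_fFps * tp)
}

#' Simulate a flash-evoked capacitance trace
#'
#' @param params a [FlashSimParams-class] object (see [flashSimParams()]).
#' @return A [CapacitanceTrace-class]; the generating parameters are kept
#'   in `meta$params`.
#' @examples
#' tr <- simulateFlashTrace(flashSimParams(noise_sd_fF = 0))
#' tr
#' @export
simulateFlashTrace <- function(params) {
  stopifnot(is(params, "FlashSimParams"))
  validObject(params)
  n <- round(params@duration_s * params@sample_rate_hz)
  t_s <- (seq_len(n) - 1) / params@sample_rate_hz
  cm <- flashModel(t_s, params)
  if (params@noise_sd_fF > 0)
    cm <- cm + .withSeed(params@seed, stats::rnorm(n, 0, params@noise_sd_fF))
  capacitanceTrace(t_s, cm, flashTime = params@flash_time_s,
                   meta = list(params = params))
}

## ---------------------------------------------------------------------------
## Amperometric trace generator
## ---------------------------------------------------------------------------

## Log-normal spike template evaluated at t seconds after spike onset.
## Unit peak amplitude; peak at t_peak.
.spikeTemplate <- function(t_s, t_peak_s, sigma) {
  out <- numeric(length(t_s))
  pos <- t_s > 0
  out[pos] <- exp(-(log(t_s[pos] / t_peak_s))^2 / (2 * sigma^2))
  out
}

## Analytic properties of the unit log-normal template.
.spikeShape <- function(t_peak_ms, sigma) {
  a50 <- sigma * sqrt(2 * log(2))
  a90 <- sigma * sqrt(2 * log(1 / 0.9))
  list(
    integral_ms  = t_peak_ms * sigma * sqrt(2 * pi) * exp(sigma^2 / 2),
    half_width_ms = t_peak_ms * (exp(a50) - exp(-a50)),
    rise_50_90_ms = t_peak_ms * (exp(-a90) - exp(-a50))
  )
}

#' Simulation result of [simulateAmperometry()]
#'
#' @slot trace the noisy, filtered [CurrentTrace-class].
#' @slot truth ground-truth event table, one row per event: spike peak
#'   time, post-filter peak amplitude, total charge, analytic rise time
#'   and half width, foot parameters, injected flicker count, and the
#'   eligibility labels implied by the standard selection thresholds
#'   (amplitude > 4 pA with charge 10-5000 fC for frequency analysis,
#'   amplitude > 7 pA for kinetics).
#' @slot params the generating [AmperoSimParams-class].
#' @export
setClass("AmperoSimulation",
  representation(trace = "CurrentTrace", truth = "data.frame",
                 params = "AmperoSimParams"))

setMethod("show", "AmperoSimulation", function(object) {
  show(object@trace)
  cat(sprintf("  %d ground-truth events (%d with foot)\n",
              nrow(object@truth), sum(object@truth$has_foot)))
})

#' Simulate a carbon-fiber amperometry recording
#'
#' Places secretory events on the time axis (Poisson, or at the fixed
#' times in `params@event_times_s`), renders each as an optional
#' ramp-to-plateau prespike foot followed by a log-normal main spike,
#' injects flicker slope excursions into foot plateaus, adds Gaussian
#' baseline noise and applies the 2 kHz Gaussian low-pass. Overlapping
#' events superpose. The returned ground truth records per event the
#' post-filter peak amplitude (measured on the event rendered in
#' isolation) and the analytic charge (the filter has unit DC gain, so
#' charge is preserved exactly).
#'
#' @param params an [AmperoSimParams-class] object (see
#'   [amperoSimParams()]).
#' @return An [AmperoSimulation-class] object.
#' @examples
#' sim <- simulateAmperometry(amperoSimParams(event_rate_hz = 1,
#'                                            duration_s = 5, seed = 7))
#' sim
#' @export
simulateAmperometry <- function(params) {
  stopifnot(is(params, "AmperoSimParams"))
  validObject(params)
  if (params@duration_s <= 0) stop("duration_s must be positive")
  fs <- params@sample_rate_hz
  n <- round(params@duration_s * fs)
  t_s <- (seq_len(n) - 1) / fs
  shape <- .spikeShape(params@spike_t_peak_ms, params@spike_sigma)

  sim <- .withSeed(params@seed, {
    ## --- event times ------------------------------------------------------
    pad <- 0.03 + params@foot_duration_mean_ms / 1000 +
      3 * params@foot_duration_sd_ms / 1000
    if (length(params@event_times_s)) {
      ev_t <- sort(params@event_times_s)
    } else {
      n_ev <- stats::rpois(1, params@event_rate_hz * params@duration_s)
      lo <- min(pad, params@duration_s / 4)
      hi <- max(params@duration_s - pad, lo + 1e-6)
      ev_t <- sort(stats::runif(n_ev, lo, hi))
    }
    n_ev <- length(ev_t)

    ## --- per-event draws --------------------------------------------------
    if (length(params@spike_amps_pA)) {
      amp <- rep_len(params@spike_amps_pA, n_ev)
    } else {
      sdlog <- sqrt(log(1 + params@spike_amp_cv^2))
      meanlog <- log(params@spike_amp_mean_pA) - sdlog^2 / 2
      amp <- numeric(n_ev)
      rng <- params@spike_charge_range_fC
      for (i in seq_len(n_ev)) {
        for (try in 1:100) {
          a <- stats::rlnorm(1, meanlog, sdlog)
          q <- a * shape$integral_ms
          if (q >= rng[1] && q <= rng[2]) break
        }
        amp[i] <- a
      }
    }
    has_foot <- stats::runif(n_ev) < params@foot_prob
    foot_dur <- pmax(0.5, stats::rnorm(n_ev, params@foot_duration_mean_ms,
                                       params@foot_duration_sd_ms))
    foot_amp <- pmax(0.5, stats::rnorm(n_ev, params@foot_amp_mean_pA,
                                       params@foot_amp_sd_pA))
    foot_dur[!has_foot] <- NA_real_
    foot_amp[!has_foot] <- NA_real_

    ## --- render -----------------------------------------------------------
    clean <- numeric(n)
    tp_s <- params@spike_t_peak_ms / 1000
    ## spike support: template < 1e-5 beyond exp(+/- 4.8 sigma)
    sup_s <- tp_s * exp(4.8 * params@spike_sigma)
    flick_n <- integer(n_ev)
    amp_filt <- numeric(n_ev)

    renderEvent <- function(i, grid_t0, grid_n) {
      ## event waveform on a local uniform grid starting at grid_t0
      tg <- grid_t0 + (seq_len(grid_n) - 1) / fs
      w <- amp[i] * .spikeTemplate(tg - ev_t[i], tp_s, params@spike_sigma)
      if (isTRUE(has_foot[i])) {
        d <- foot_dur[i] / 1000
        r <- params@foot_ramp_frac * d
        ts <- ev_t[i] - d
        rel <- tg - ts
        foot <- ifelse(rel < 0, 0,
                ifelse(rel < r, foot_amp[i] * rel / r,
                ifelse(rel < d, foot_amp[i], 0)))
        ## the foot decays gently under the spike (2 ms; the slope stays
        ## below the flicker threshold and the spike dominates there)
        dec <- 2e-3
        after <- rel >= d & rel < d + dec
        foot[after] <- foot_amp[i] * (1 - (rel[after] - d) / dec)
        w <- w + foot
      }
      w
    }

    ## flicker waveform added separately (counts recorded); alternating
    ## step toggles, each one slope pulse
    flickerWave <- function(i, tg) {
      w <- numeric(length(tg))
      if (!isTRUE(has_foot[i]) || params@flicker_rate_per_ms <= 0)
        return(list(w = w, count = 0L))
      d <- foot_dur[i] / 1000
      r <- params@foot_ramp_frac * d
      rise <- params@flicker_rise_ms / 1000
      t0 <- ev_t[i] - d + r + 0.25e-3       # plateau only: no slope
      t1 <- ev_t[i] - 0.6e-3 - rise         # superposition with the ramp
      if (t1 <= t0) return(list(w = w, count = 0L))
      k <- stats::rpois(1, params@flicker_rate_per_ms * foot_dur[i])
      if (k == 0) return(list(w = w, count = 0L))
      ## equally spaced slots; separation keeps same-polarity derivative
      ## excursions (2 slots apart) from merging after 1.2 kHz filtering
      sep <- rise + 0.25e-3
      cap <- max(1L, floor((t1 - t0) / sep) + 1L)
      k <- min(k, cap)
      slots <- t0 + (sort(sample.int(cap, k)) - 1L) * sep
      step <- params@flicker_amp_pAms * params@flicker_rise_ms   # pA
      sgn <- rep_len(c(1, -1), k)
      for (j in seq_len(k)) {
        rel <- (tg - slots[j]) / rise
        w <- w + sgn[j] * step * pmin(pmax(rel, 0), 1)
      }
      ## an odd number of toggles leaves the level high; step back down
      ## inside the spike upstroke where the derivative is dominated by
      ## the spike anyway
      if (sum(sgn) > 0) {
        rel <- (tg - (ev_t[i] + 0.2e-3)) / (4 * rise)
        w <- w - step * pmin(pmax(rel, 0), 1)
      }
      list(w = w, count = k)
    }

    for (i in seq_len(n_ev)) {
      d_s <- if (isTRUE(has_foot[i])) foot_dur[i] / 1000 else 0
      w0 <- ev_t[i] - d_s - 2e-3
      w1 <- ev_t[i] + sup_s
      i0 <- max(1L, floor(w0 * fs) + 1L)
      i1 <- min(n, ceiling(w1 * fs) + 1L)
      gn <- i1 - i0 + 1L
      g0 <- (i0 - 1) / fs
      w <- renderEvent(i, g0, gn)
      fl <- flickerWave(i, g0 + (seq_len(gn) - 1) / fs)
      flick_n[i] <- fl$count
      clean[i0:i1] <- clean[i0:i1] + w + fl$w
      ## isolated-event post-filter peak (with margin for the kernel)
      marg <- ceiling(0.005 * fs)
      iso <- c(numeric(marg), w + fl$w, numeric(marg))
      iso_f <- gaussianLowpass(iso, fs, params@filter_cutoff_hz)
      amp_filt[i] <- max(iso_f)
    }

    noisy <- clean
    if (params@baseline_noise_sd_pA > 0)
      noisy <- noisy + stats::rnorm(n, 0, params@baseline_noise_sd_pA)
    i_f <- gaussianLowpass(noisy, fs, params@filter_cutoff_hz)

    foot_charge <- ifelse(has_foot,
                          foot_amp * foot_dur * (1 - params@foot_ramp_frac / 2),
                          0)
    ## event charge includes the 2 ms wedge where the foot decays under
    ## the spike (outside the foot segment proper)
    charge <- amp * shape$integral_ms + foot_charge +
      ifelse(has_foot, foot_amp * 1, 0)
    truth <- data.frame(
      event = seq_len(n_ev),
      t_peak_s = ev_t + tp_s,
      amp_pA = amp_filt,
      charge_fC = charge,
      rise_50_90_ms = amp * 0 + shape$rise_50_90_ms,
      half_width_ms = amp * 0 + shape$half_width_ms,
      has_foot = has_foot,
      foot_duration_ms = foot_dur,
      foot_amp_pA = ifelse(has_foot, foot_charge / foot_dur, NA_real_),
      foot_charge_fC = ifelse(has_foot, foot_charge, NA_real_),
      flicker_count = flick_n
    )
    truth$eligible_frequency <- truth$amp_pA > 4 &
      truth$charge_fC >= 10 & truth$charge_fC <= 5000
    truth$eligible_kinetics <- truth$amp_pA > 7
    list(i = i_f, truth = truth)
  })

  tr <- currentTrace(t_s, sim$i, sampleRate = fs,
                     filterCutoff = params@filter_cutoff_hz,
                     meta = list(params = params, filter = "gaussian"))
  new("AmperoSimulation", trace = tr, truth = sim$truth, params = params)
}

## ---------------------------------------------------------------------------
## Assembly generator
## ---------------------------------------------------------------------------

#' Evaluate the second-order assembly law
#'
#' `SC(t) = SC0 + (SCinf - SC0) * x / (x + 1)` with `x = A0 * k * t`
#' (t converted from minutes to seconds), the integrated rate law of the
#' equimolar second-order reaction A + B -> P.
#'
#' @param t_min times (min).
#' @param SC0_au,SCinf_au,A0_M,k_M1s1 law parameters.
#' @return Numeric values (a.u.).
#' @export
assemblyLaw <- function(t_min, SC0_au, SCinf_au, A0_M, k_M1s1) {
  x <- A0_M * k_M1s1 * t_min * 60
  SC0_au + (SCinf_au - SC0_au) * x / (x + 1)
}

#' Simulate a SNARE-assembly time course
#'
#' Evaluates [assemblyLaw()] at the requested times and applies
#' multiplicative Gaussian noise `SC(t) * (1 + eps)`,
#' `eps ~ N(0, cv_noise)`. With `cv_noise = 0` the law is returned
#' exactly.
#'
#' @param params an [AssemblySimParams-class] object.
#' @param group,replicate labels stored in the result.
#' @return An [AssemblyTimeCourse-class] object.
#' @export
simulateAssembly <- function(params, group = "control", replicate = "r1") {
  stopifnot(is(params, "AssemblySimParams"))
  validObject(params)
  v <- assemblyLaw(params@times_min, params@SC0_au, params@SCinf_au,
                   params@A0_M, params@k_M1s1)
  if (params@cv_noise > 0)
    v <- v * (1 + .withSeed(params@seed,
              stats::rnorm(length(v), 0, params@cv_noise)))
  v <- pmax(v, 0)
  assemblyTimeCourse(params@times_min, v, group = group,
                     replicate = replicate)
}
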