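## Amperometric spike detection and quantification: main-spike kinetics,
## prespike-foot parameters, fusion-pore flicker statistics, and per-cell
## aggregation.
##
## Events are represented as rows of a data.frame (one row per event)
## rather than one object per event; downstream operations add columns to
## the same table. The running baseline and robust noise SD estimated
## during detection travel with the table as attributes.

.runningBaseline <- function(i_pA, fs, window_s = 0.2) {
  k <- max(3L, round(window_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (length(i_pA) %% 2 == 1) length(i_pA) else length(i_pA) - 1L)
  as.numeric(stats::runmed(i_pA, k, endrule = "median"))
}

#' Detect amperometric spikes
#'
#' Localizes secretory events as excursions of the baseline-subtracted
#' current above a robust noise threshold. The baseline is a running
#' median (window `baseline_window_s`, robust to the sparse, brief
#' events); the noise SD is the median absolute deviation of the
#' residual, floored at `min_sd_pA` so noise-free synthetic traces remain
#' analyzable. An event opens where the residual exceeds
#' `onset_sd` x SD and extends outward to the surrounding
#' `hysteresis_sd` x SD re-crossings, which places the event boundaries
#' at the return to baseline.
#'
#' Detection itself is threshold-based only; the published selection
#' cuts are applied afterwards as eligibility flags:
#' `eligible_frequency` (peak amplitude > 4 pA and charge within
#' 10-5000 fC) and `eligible_kinetics` (peak amplitude > 7 pA).
#'
#' @param trace a [CurrentTrace-class].
#' @param baseline_window_s running-median window (s), default 0.2.
#' @param onset_sd,hysteresis_sd detection and boundary thresholds in
#'   noise SDs (defaults 4 and 2).
#' @param min_sd_pA floor for the noise SD estimate (pA).
#' @param min_gap_ms events separated by less than this are merged.
#' @param min_event_ms shortest admissible event (default 1 ms): the
#'   region above the hysteresis threshold must last at least this long,
#'   which rejects single-sample noise excursions that clear the
#'   amplitude threshold by chance (secretory events last milliseconds).
#' @return A `data.frame` with one row per detected event: sample and
#'   time boundaries, peak time, baseline-subtracted peak amplitude (pA),
#'   charge (fC, trapezoidal integral of the baseline-subtracted
#'   current), and the two eligibility flags. The running baseline and
#'   the noise SD are attached as attributes `"baseline"` and `"sd_pA"`.
#' @examples
#' sim <- simulateAmperometry(amperoSimParams(event_rate_hz = 1,
#'                                            duration_s = 5, seed = 2))
#' ev <- detectSpikes(sim@trace)
#' nrow(ev)
#' @export
detectSpikes <- function(trace, baseline_window_s = 0.2, onset_sd = 4,
                         hysteresis_sd = 2, min_sd_pA = 0.05,
                         min_gap_ms = 0.5, min_event_ms = 1) {
  stopifnot(is(trace, "CurrentTrace"))
  fs <- trace@sampleRate
  if (diff(range(trace@time_s)) < 1)
    warning("less than 1 s of data; baseline estimate may be unreliable")
  base <- .runningBaseline(trace@i_pA, fs, baseline_window_s)
  resid <- trace@i_pA - base
  sd_est <- max(stats::mad(resid), min_sd_pA)

  hi <- resid > onset_sd * sd_est
  lo <- resid > hysteresis_sd * sd_est
  runs <- .runsTrue(lo)
  if (nrow(runs)) {
    keep <- vapply(seq_len(nrow(runs)), function(r)
      any(hi[runs$start[r]:runs$end[r]]), logical(1))
    runs <- runs[keep, , drop = FALSE]
  }
  ## merge runs separated by less than min_gap_ms
  if (nrow(runs) > 1) {
    gap <- (runs$start[-1] - runs$end[-nrow(runs)]) / fs * 1000
    grp <- cumsum(c(TRUE, gap >= min_gap_ms))
    runs <- data.frame(
      start = tapply(runs$start, grp, min),
      end   = tapply(runs$end, grp, max))
  }
  ## discard events shorter than min_event_ms
  if (nrow(runs)) {
    long_enough <- (runs$end - runs$start + 1L) / fs * 1000 >= min_event_ms
    runs <- runs[long_enough, , drop = FALSE]
  }
  n_ev <- nrow(runs)
  if (n_ev == 0) {
    out <- data.frame(event = integer(0), i_start = integer(0),
                      i_end = integer(0), t_start_s = numeric(0),
                      t_end_s = numeric(0), t_peak_s = numeric(0),
                      amp_pA = numeric(0), charge_fC = numeric(0),
                      eligible_frequency = logical(0),
                      eligible_kinetics = logical(0))
  } else {
    out <- do.call(rbind, lapply(seq_len(n_ev), function(r) {
      idx <- runs$start[r]:runs$end[r]
      pk <- idx[which.max(resid[idx])]
      data.frame(
        event = r, i_start = runs$start[r], i_end = runs$end[r],
        t_start_s = trace@time_s[runs$start[r]],
        t_end_s = trace@time_s[runs$end[r]],
        t_peak_s = trace@time_s[pk],
        amp_pA = resid[pk],
        charge_fC = .trapz(trace@time_s[idx], resid[idx]) * 1000)
    }))
    out$eligible_frequency <- out$amp_pA > 4 &
      out$charge_fC >= 10 & out$charge_fC <= 5000
    out$eligible_kinetics <- out$amp_pA > 7
  }
  attr(out, "baseline") <- base
  attr(out, "sd_pA") <- sd_est
  attr(out, "duration_s") <- diff(range(trace@time_s)) +
    1 / fs
  out
}

## interpolated crossing time of `level` between samples j and j+1
.crossTime <- function(t, y, j, level) {
  if (y[j + 1] == y[j]) return(t[j])
  t[j] + (level - y[j]) / (y[j + 1] - y[j]) * (t[j + 1] - t[j])
}

#' Main-spike kinetics
#'
#' Fills 50-90% rise time and half width (both ms) for each
#' kinetics-eligible event: the rise time is measured between the
#' interpolated 50% and 90% crossings on the rising limb, the half width
#' between the interpolated 50% crossings on either side of the peak.
#' Events whose window contains more than one prominent peak (a second
#' local maximum above half of the main peak) are flagged as overlapping
#' and their kinetics left `NA`.
#'
#' @param trace the [CurrentTrace-class] the events came from.
#' @param events the event table from [detectSpikes()].
#' @return `events` with columns `rise_50_90_ms`, `half_width_ms` and
#'   `overlap` added.
#' @export
spikeKinetics <- function(trace, events) {
  base <- attr(events, "baseline")
  if (is.null(base)) stop("events must come from detectSpikes()")
  resid <- trace@i_pA - base
  t <- trace@time_s
  events$rise_50_90_ms <- NA_real_
  events$half_width_ms <- NA_real_
  events$overlap <- FALSE
  pad <- round(0.001 * trace@sampleRate)   # 1 ms: crossings can sit just
  for (r in seq_len(nrow(events))) {       # outside the detection region
    if (!isTRUE(events$eligible_kinetics[r])) next
    idx <- max(1L, events$i_start[r] - pad):
      min(length(resid), events$i_end[r] + pad)
    y <- resid[idx]; tt <- t[idx]
    pk <- which.max(y); A <- y[pk]
    ## overlap check: second prominent local maximum
    if (length(y) > 4) {
      locmax <- which(diff(sign(diff(y))) == -2) + 1L
      locmax <- locmax[y[locmax] > 0.5 * A & locmax != pk]
      ## require a real valley between the secondary peak and the main one
      is_sep <- vapply(locmax, function(m) {
        rng <- if (m < pk) m:pk else pk:m
        min(y[rng]) < 0.7 * min(y[m], A)
      }, logical(1))
      if (any(is_sep)) {
        events$overlap[r] <- TRUE
        next
      }
    }
    ## rising limb crossings (last crossing below the peak)
    up50 <- which(y[seq_len(pk - 1)] < 0.5 * A & y[2:pk] >= 0.5 * A)
    up90 <- which(y[seq_len(pk - 1)] < 0.9 * A & y[2:pk] >= 0.9 * A)
    dn50 <- which(y[pk:(length(y) - 1)] >= 0.5 * A &
                  y[(pk + 1):length(y)] < 0.5 * A) + pk - 1L
    if (!length(up50) || !length(up90) || !length(dn50)) next
    t50u <- .crossTime(tt, y, max(up50), 0.5 * A)
    t90u <- .crossTime(tt, y, max(up90), 0.9 * A)
    t50d <- .crossTime(tt, y, min(dn50), 0.5 * A)
    events$rise_50_90_ms[r] <- (t90u - t50u) * 1000
    events$half_width_ms[r] <- (t50d - t50u) * 1000
  }
  events
}

#' Detect the prespike foot of each event
#'
#' The foot is the segment from the first sustained rise of the
#' baseline-subtracted current above `foot_sd` x noise SD to the
#' main-spike takeoff, located at the maximum of the (lightly smoothed)
#' second derivative of the current preceding the peak. Duration, mean
#' amplitude (charge/duration) and charge are computed on the
#' baseline-subtracted current; feet shorter than `min_foot_ms` are
#' reported absent; the `foot_analyzable` flag marks feet longer than
#' 2 ms, the minimum for fluctuation analysis.
#'
#' @param trace the [CurrentTrace-class].
#' @param events the event table from [detectSpikes()].
#' @param foot_sd onset threshold in noise SDs (default 3).
#' @param sustained_ms minimum time the current must stay above threshold
#'   to count as the foot onset (default 0.2 ms).
#' @param min_foot_ms shortest resolvable foot (default 0.5 ms).
#' @param search_back_ms how far before the peak the takeoff is searched
#'   (default 2 ms, an upper bound on the main-spike upstroke duration;
#'   restricting the search keeps curvature inside the foot — e.g. pore
#'   flickers — from masquerading as the spike takeoff).
#' @return `events` with columns `foot_present`, `foot_i_start`,
#'   `foot_i_end` (takeoff sample), `foot_duration_ms`, `foot_amp_pA`,
#'   `foot_charge_fC` and `foot_analyzable` added.
#' @export
detectFoot <- function(trace, events, foot_sd = 3, sustained_ms = 0.2,
                       min_foot_ms = 0.5, search_back_ms = 2) {
  base <- attr(events, "baseline")
  if (is.null(base)) stop("events must come from detectSpikes()")
  sd_est <- attr(events, "sd_pA")
  fs <- trace@sampleRate
  resid <- trace@i_pA - base
  t <- trace@time_s
  events$foot_present <- FALSE
  events$foot_i_start <- NA_integer_
  events$foot_i_end <- NA_integer_
  events$foot_duration_ms <- NA_real_
  events$foot_amp_pA <- NA_real_
  events$foot_charge_fC <- NA_real_
  events$foot_analyzable <- FALSE
  n_sus <- max(1L, round(sustained_ms / 1000 * fs))
  for (r in seq_len(nrow(events))) {
    idx <- events$i_start[r]:events$i_end[r]
    y <- resid[idx]
    pk <- which.max(y)
    if (pk < 5) next
    ## takeoff: max of smoothed second difference in the search window
    ## just before the peak
    d2 <- diff(y, differences = 2)
    if (length(d2) >= 3) d2 <- stats::filter(d2, rep(1 / 3, 3), sides = 2)
    nback <- max(3L, round(search_back_ms / 1000 * fs))
    upto <- min(max(pk - 2L, 1L), length(d2))
    from <- max(1L, pk - nback)
    win <- from:upto
    win <- win[!is.na(d2[win])]
    if (!length(win)) next
    takeoff <- win[which.max(d2[win])] + 1L   # second-diff index offset
    ## foot onset: first sustained crossing above foot_sd * SD
    thr <- foot_sd * sd_est
    above <- y[seq_len(takeoff)] > thr
    runs <- .runsTrue(above)
    runs <- runs[runs$end - runs$start + 1L >= n_sus |
                   runs$end >= takeoff, , drop = FALSE]
    if (!nrow(runs)) next
    fstart <- runs$start[1]
    dur_ms <- (t[idx[takeoff]] - t[idx[fstart]]) * 1000
    if (dur_ms < min_foot_ms) next
    fidx <- idx[fstart:takeoff]
    q <- .trapz(t[fidx], resid[fidx]) * 1000
    events$foot_present[r] <- TRUE
    events$foot_i_start[r] <- idx[fstart]
    events$foot_i_end[r] <- idx[takeoff]
    events$foot_duration_ms[r] <- dur_ms
    events$foot_amp_pA[r] <- q / dur_ms
    events$foot_charge_fC[r] <- q
    events$foot_analyzable[r] <- dur_ms > 2
  }
  events
}

#' Fusion-pore flicker statistics of analyzable feet
#'
#' The current derivative (pA/ms) within each foot is low-pass filtered
#' at `deriv_cutoff_hz` (1.2 kHz) and excursions beyond the +/-
#' `threshold_pAms` level are counted, one count per contiguous
#' suprathreshold run, positive and negative polarity counted separately
#' and summed. Runs that touch the foot boundaries are not counted: at
#' the start they reflect the foot onset ramp, at the end the main-spike
#' upstroke, neither of which is a fusion-pore flicker. The fluctuation
#' frequency is the count divided by the foot duration. The rms noise
#' (a threshold-independent parameter) is the root mean square of the
#' foot current after removing a 3rd-order polynomial trend.
#'
#' With `adaptive = TRUE` the threshold is instead 4x the robust SD of
#' the filtered derivative over event-free stretches of the trace; the
#' threshold actually used is recorded in the `flicker_threshold_pAms`
#' column.
#'
#' @param trace the [CurrentTrace-class].
#' @param events event table from [detectFoot()].
#' @param threshold_pAms fixed derivative threshold (default 6 pA/ms).
#' @param deriv_cutoff_hz derivative low-pass cutoff (default 1200 Hz).
#' @param adaptive use the 4 x SD-of-derivative threshold instead of the
#'   fixed level.
#' @param trend_order polynomial order for the rms-noise detrend.
#' @return `events` with `flicker_count`, `flicker_freq_per_ms`,
#'   `flicker_threshold_pAms` and `foot_rms_pA` added (NA for feet that
#'   are absent or not analyzable).
#' @export
footFlickers <- function(trace, events, threshold_pAms = 6,
                         deriv_cutoff_hz = 1200, adaptive = FALSE,
                         trend_order = 3) {
  base <- attr(events, "baseline")
  if (is.null(base)) stop("events must come from detectSpikes()")
  if (is.null(events$foot_present))
    stop("run detectFoot() before footFlickers()")
  fs <- trace@sampleRate
  resid <- trace@i_pA - base
  ## derivative in pA/ms, filtered at deriv_cutoff_hz
  d <- c(diff(resid), 0) * fs / 1000
  d <- gaussianLowpass(d, fs, deriv_cutoff_hz)
  thr <- threshold_pAms
  if (adaptive) {
    free <- rep(TRUE, length(d))
    for (r in seq_len(nrow(events)))
      free[events$i_start[r]:events$i_end[r]] <- FALSE
    thr <- 4 * max(stats::mad(d[free]), 1e-6)
  }
  events$flicker_count <- NA_integer_
  events$flicker_freq_per_ms <- NA_real_
  events$flicker_threshold_pAms <- thr
  events$foot_rms_pA <- NA_real_
  for (r in seq_len(nrow(events))) {
    if (!isTRUE(events$foot_analyzable[r])) next
    fidx <- events$foot_i_start[r]:events$foot_i_end[r]
    ds <- d[fidx]
    cnt <- 0L
    for (sgn in c(1, -1)) {
      runs <- .runsTrue(sgn * ds > thr)
      if (nrow(runs)) {
        interior <- runs$start > 1 & runs$end < length(ds)
        cnt <- cnt + sum(interior)
      }
    }
    events$flicker_count[r] <- cnt
    events$flicker_freq_per_ms[r] <- cnt / events$foot_duration_ms[r]
    ## rms of polynomial-detrended foot current
    y <- resid[fidx]
    x <- seq_along(y)
    ord <- min(trend_order, length(y) - 1)
    fitv <- if (ord >= 1)
      stats::fitted(stats::lm(y ~ stats::poly(x, ord))) else mean(y)
    events$foot_rms_pA[r] <- sqrt(mean((y - fitv)^2))
  }
  events
}

#' Flicker statistics of a single analyzable foot
#'
#' Convenience wrapper running [footFlickers()] for one event row and
#' returning its foot columns; errors if the foot is absent or does not
#' satisfy the 2 ms minimum-duration rule.
#'
#' @param trace the [CurrentTrace-class].
#' @param events event table from [detectFoot()].
#' @param event which event (row of `events`) to analyze.
#' @param ... passed to [footFlickers()].
#' @return A one-row `data.frame` of foot parameters.
#' @export
footFlickerStats <- function(trace, events, event, ...) {
  r <- which(events$event == event)
  if (!length(r)) stop("no such event")
  if (!isTRUE(events$foot_present[r]))
    stop("event has no resolvable foot")
  if (!isTRUE(events$foot_analyzable[r]))
    stop("foot shorter than 2 ms; fluctuation analysis is restricted to ",
         "prespike durations longer than 2 ms")
  out <- footFlickers(trace, events, ...)
  out[r, c("event", "foot_duration_ms", "foot_amp_pA", "foot_charge_fC",
           "flicker_count", "flicker_freq_per_ms",
           "flicker_threshold_pAms", "foot_rms_pA")]
}

#' Run the full amperometric analysis chain
#'
#' [detectSpikes()], [spikeKinetics()], [detectFoot()] and
#' [footFlickers()] in sequence.
#'
#' @param trace a [CurrentTrace-class].
#' @param ... passed to [detectSpikes()].
#' @return The fully annotated event table.
#' @export
analyzeAmperometry <- function(trace, ...) {
  ev <- detectSpikes(trace, ...)
  ev <- spikeKinetics(trace, ev)
  ev <- detectFoot(trace, ev)
  footFlickers(trace, ev)
}

#' Event frequency of a recording
#'
#' Number of frequency-eligible events (amplitude > 4 pA, charge
#' 10-5000 fC) divided by the recording duration.
#'
#' @param trace the analyzed [CurrentTrace-class].
#' @param events event table from [detectSpikes()].
#' @return Events per second.
#' @export
eventFrequency <- function(trace, events) {
  dur <- diff(range(trace@time_s)) + 1 / trace@sampleRate
  sum(events$eligible_frequency) / dur
}

#' Per-cell medians and cell-weighted means
#'
#' Summarizes event parameters the way cell-based studies report them:
#' the median of each parameter is taken over the events of each cell,
#' and cells are then averaged with equal weight (mean of medians +/-
#' SEM), so cells with many events do not dominate. Cells with fewer
#' than `min_events` events are excluded from the across-cell average
#' (but retained, flagged, in the per-cell table).
#'
#' @param events a `data.frame` of events from one or more cells.
#' @param cell name of the column identifying the cell.
#' @param parameters character vector of numeric columns to summarize;
#'   default all numeric columns except indices.
#' @param min_events minimum events per cell for inclusion (default 21,
#'   i.e. more than 20 events per cell).
#' @return A list with `per_cell` (cell x parameter median table with an
#'   `n_events`/`included` bookkeeping block) and `summary` (parameter,
#'   mean of medians, SEM, number of cells).
#' @examples
#' ev <- data.frame(cell = rep(c("c1", "c2"), c(3, 3)),
#'                  amp_pA = c(1, 2, 9, 3, 4, 5))
#' cellSummary(ev, min_events = 1)$summary
#' @export
cellSummary <- function(events, cell = "cell", parameters = NULL,
                        min_events = 21) {
  if (!nrow(events)) stop("no events to summarize")
  if (!cell %in% names(events)) stop("no '", cell, "' column in events")
  if (is.null(parameters)) {
    num <- vapply(events, is.numeric, logical(1))
    parameters <- setdiff(names(events)[num],
                          c("event", "i_start", "i_end", "foot_i_start",
                            "foot_i_end"))
  }
  cells <- split(events, events[[cell]])
  per_cell <- do.call(rbind, lapply(names(cells), function(cn) {
    df <- cells[[cn]]
    med <- vapply(parameters, function(p)
      stats::median(df[[p]], na.rm = TRUE), numeric(1))
    cbind(data.frame(cell = cn, n_events = nrow(df),
                     included = nrow(df) >= min_events),
          as.data.frame(as.list(med)))
  }))
  inc <- per_cell[per_cell$included, , drop = FALSE]
  if (!nrow(inc))
    warning("no cell reaches min_events; summary is empty")
  summary <- do.call(rbind, lapply(parameters, function(p) {
    v <- inc[[p]][is.finite(inc[[p]])]
    data.frame(parameter = p,
               mean_of_medians = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) .sem(v) else NA_real_,
               n_cells = length(v))
  }))
  list(per_cell = per_cell, summary = summary)
}
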