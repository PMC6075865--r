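#' @import methods
NULL

## ---------------------------------------------------------------------------
## Trace containers
## ---------------------------------------------------------------------------

#' Membrane-capacitance trace
#'
#' A sampled whole-cell membrane-capacitance (CM) time series, optionally
#' carrying the instant of the UV flash that triggered Ca2+ uncaging.
#'
#' @slot time_s numeric, strictly increasing sample times in seconds.
#' @slot cm_fF numeric, capacitance in femtofarad, same length as `time_s`.
#' @slot flashTime numeric(1), flash instant in seconds, or `NA_real_` when
#'   the recording has no flash stimulus.
#' @slot meta list of acquisition notes (free form; generators store their
#'   parameters here).
#'
#' @seealso [capacitanceTrace()], [simulateFlashTrace()], [fitFlashResponse()]
#' @export
setClass("CapacitanceTrace",
  representation(
    time_s    = "numeric",
    cm_fF     = "numeric",
    flashTime = "numeric",
    meta      = "list"
  ),
  prototype(flashTime = NA_real_, meta = list())
)

setValidity("CapacitanceTrace", function(object) {
  msg <- character()
  if (length(object@time_s) != length(object@cm_fF))
    msg <- c(msg, "time_s and cm_fF must have equal length")
  if (length(object@time_s) > 1 && any(diff(object@time_s) <= 0))
    msg <- c(msg, "time_s must be strictly increasing")
  if (any(!is.finite(object@cm_fF)))
    msg <- c(msg, "cm_fF must be finite")
  if (length(object@flashTime) != 1)
    msg <- c(msg, "flashTime must be a single number (or NA)")
  if (length(msg)) msg else TRUE
})

#' Amperometric current trace
#'
#' A uniformly sampled carbon-fiber amperometry recording (oxidation
#' current positive).
#'
#' @slot time_s numeric, strictly increasing sample times in seconds.
#' @slot i_pA numeric, current in picoampere.
#' @slot sampleRate numeric(1), sampling rate in Hz (25 kHz in the
#'   experiments this package models).
#' @slot filterCutoff numeric(1), -3 dB low-pass cutoff already applied to
#'   the signal, in Hz (2 kHz by convention).
#' @slot meta list of acquisition notes.
#'
#' @seealso [currentTrace()], [simulateAmperometry()], [detectSpikes()]
#' @export
setClass("CurrentTrace",
  representation(
    time_s       = "numeric",
    i_pA         = "numeric",
    sampleRate   = "numeric",
    filterCutoff = "numeric",
    meta         = "list"
  ),
  prototype(sampleRate = 25000, filterCutoff = 2000, meta = list())
)

setValidity("CurrentTrace", function(object) {
  msg <- character()
  if (length(object@time_s) != length(object@i_pA))
    msg <- c(msg, "time_s and i_pA must have equal length")
  if (length(object@time_s) > 2) {
    dt <- diff(object@time_s)
    if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
      msg <- c(msg, "sampling must be uniform")
  }
  if (any(!is.finite(object@i_pA)))
    msg <- c(msg, "i_pA must be finite")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (length(msg)) msg else TRUE
})

#' SNARE-assembly time course
#'
#' Densitometry readout of SDS-resistant ternary SNARE complex formation
#' sampled at discrete incubation times.
#'
#' @slot times_min numeric, strictly increasing sampling times in minutes.
#' @slot values_au numeric, integrated band density (arbitrary units) or a
#'   normalized fraction; non-negative.
#' @slot group character(1), experimental group label (e.g. `"control"`,
#'   `"CTD"`, `"scrambled"`).
#' @slot replicate character(1), replicate identifier.
#'
#' @seealso [assemblyTimeCourse()], [simulateAssembly()], [fitAssembly()]
#' @export
setClass("AssemblyTimeCourse",
  representation(
    times_min = "numeric",
    values_au = "numeric",
    group     = "character",
    replicate = "character"
  ),
  prototype(group = NA_character_, replicate = NA_character_)
)

setValidity("AssemblyTimeCourse", function(object) {
  msg <- character()
  if (length(object@times_min) != length(object@values_au))
    msg <- c(msg, "times_min and values_au must have equal length")
  if (length(object@times_min) > 1 && any(diff(object@times_min) <= 0))
    msg <- c(msg, "times_min must be strictly increasing")
  if (any(!is.finite(object@values_au)) || any(object@values_au < 0))
    msg <- c(msg, "values_au must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Fit results
## ---------------------------------------------------------------------------

#' Flash-response decomposition result
#'
#' Parameter estimates of the double-exponential-plus-line model of the
#' flash-evoked capacitance rise:
#' \deqn{f(t) = A_0 + A_1(1-e^{-t'/\tau_1}) + A_2(1-e^{-t'/\tau_2}) + k t'}
#' with \eqn{t' = t - t_{on}}. The faster exponential (smaller tau) is the
#' readily releasable pool (RRP), the slower the slowly releasable pool
#' (SRP), and \eqn{k} the sustained rate.
#'
#' @slot A0_fF baseline capacitance (fF).
#' @slot A_rrp_fF,tau_rrp_ms RRP amplitude (fF) and time constant (ms).
#' @slot A_srp_fF,tau_srp_ms SRP amplitude (fF) and time constant (ms).
#' @slot k_sus_fFps sustained rate (fF/s).
#' @slot onset_s fitted burst onset (s).
#' @slot delay_ms secretory delay, `onset_s - flashTime` in ms.
#' @slot residual_rms_fF root-mean-square fit residual (fF).
#' @slot converged logical(1), optimizer convergence flag.
#'
#' @seealso [fitFlashResponse()], [secretoryDelay()]
#' @export
setClass("FlashFit",
  representation(
    A0_fF           = "numeric",
    A_rrp_fF        = "numeric",
    tau_rrp_ms      = "numeric",
    A_srp_fF        = "numeric",
    tau_srp_ms      = "numeric",
    k_sus_fFps      = "numeric",
    onset_s         = "numeric",
    delay_ms        = "numeric",
    residual_rms_fF = "numeric",
    converged       = "logical"
  )
)

setValidity("FlashFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged)) {
    if (object@tau_rrp_ms >= object@tau_srp_ms)
      msg <- c(msg, "tau_rrp_ms must be smaller than tau_srp_ms")
    if (object@A_rrp_fF < 0 || object@A_srp_fF < 0)
      msg <- c(msg, "pool amplitudes must be non-negative")
    if (!is.na(object@delay_ms) && object@delay_ms < -1e-9)
      msg <- c(msg, "delay_ms must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Second-order SNARE assembly fit
#'
#' Estimates of the integrated second-order rate law
#' \deqn{SC(t) = SC_0 + (SC_\infty - SC_0)\frac{A_0 k t}{A_0 k t + 1}}
#' for equimolar reactants (\eqn{A_0 = B_0}). \eqn{A_0} is fixed from the
#' experimental design; \eqn{k} is the bimolecular rate constant.
#'
#' @slot SC0_au densitometry value at t = 0 (a.u.).
#' @slot SCinf_au asymptotic value (a.u.).
#' @slot A0_M initial reactant concentration (mol/L), fixed.
#' @slot k_M1s1 rate constant (1/(M s)).
#' @slot residual_rms root-mean-square residual (a.u.).
#' @slot converged logical(1).
#'
#' @seealso [fitAssembly()], [compareAssemblyRates()]
#' @export
setClass("AssemblyFit",
  representation(
    SC0_au       = "numeric",
    SCinf_au     = "numeric",
    A0_M         = "numeric",
    k_M1s1       = "numeric",
    residual_rms = "numeric",
    converged    = "logical"
  )
)

setValidity("AssemblyFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged)) {
    if (object@SCinf_au < object@SC0_au)
      msg <- c(msg, "SCinf_au must be >= SC0_au")
    if (object@k_M1s1 <= 0)
      msg <- c(msg, "k_M1s1 must be positive on a converged fit")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Peptide analysis
## ---------------------------------------------------------------------------

#' Peptide segment
#'
#' A contiguous stretch of a protein in one-letter code with 1-based
#' inclusive residue coordinates in the parent protein.
#'
#' @slot name character(1) label.
#' @slot sequence character(1), standard 20-letter amino-acid alphabet.
#' @slot startRes,endRes integer(1), residue numbers in the parent protein
#'   (`NA` when the segment is free-standing).
#'
#' @seealso [peptideSegment()], [snareSegments()]
#' @export
setClass("PeptideSegment",
  representation(
    name     = "character",
    sequence = "character",
    startRes = "integer",
    endRes   = "integer"
  ),
  prototype(startRes = NA_integer_, endRes = NA_integer_)
)

setValidity("PeptideSegment", function(object) {
  msg <- character()
  if (nchar(object@sequence) < 1) msg <- c(msg, "sequence must be non-empty")
  bad <- .nonStandardResidues(object@sequence)
  if (length(bad))
    msg <- c(msg, sprintf("non-standard residue '%s' at position %d",
                          bad[[1]][1], as.integer(names(bad)[1])))
  if (!is.na(object@startRes) && !is.na(object@endRes) &&
      nchar(object@sequence) != object@endRes - object@startRes + 1)
    msg <- c(msg, "sequence length must equal endRes - startRes + 1")
  if (length(msg)) msg else TRUE
})

#' Pairwise percent-similarity result
#'
#' @slot matrixName substitution matrix used (BLOSUM62).
#' @slot alignedLength number of aligned (non-gap) columns.
#' @slot nSimilar aligned columns whose substitution score is positive
#'   (identities included).
#' @slot percentSimilarity `100 * nSimilar / alignedLength`.
#' @slot mode `"gapless"` (equal-length position-wise) or
#'   `"global-affine"` (Needleman-Wunsch, gap open 10 / extend 0.5).
#'
#' @seealso [percentSimilarity()]
#' @export
setClass("SimilarityResult",
  representation(
    matrixName        = "character",
    alignedLength     = "integer",
    nSimilar          = "integer",
    percentSimilarity = "numeric",
    mode              = "character"
  )
)

setValidity("SimilarityResult", function(object) {
  msg <- character()
  if (object@percentSimilarity < 0 || object@percentSimilarity > 100)
    msg <- c(msg, "percentSimilarity must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Helical projection of a peptide segment
#'
#' Per-residue helical-wheel angles and hydrophobicities, with the mean
#' hydrophobic moment per residue (Eisenberg).
#'
#' @slot segment the [PeptideSegment-class] projected.
#' @slot delta_deg helix angle per residue in degrees (100 for an ideal
#'   alpha helix).
#' @slot angle_deg numeric, angle of each residue, `(n-1) * delta mod 360`.
#' @slot H numeric, per-residue hydrophobicity on the chosen scale.
#' @slot scale character(1), name of the hydrophobicity scale.
#' @slot muH numeric(1), mean hydrophobic moment per residue.
#'
#' @seealso [hydrophobicMoment()], [helicalWheel()]
#' @export
setClass("HelixWindow",
  representation(
    segment   = "PeptideSegment",
    delta_deg = "numeric",
    angle_deg = "numeric",
    H         = "numeric",
    scale     = "character",
    muH       = "numeric"
  )
)

setValidity("HelixWindow", function(object) {
  msg <- character()
  if (object@muH < 0) msg <- c(msg, "muH must be non-negative")
  if (length(object@H) && object@muH > max(abs(object@H)) + 1e-12)
    msg <- c(msg, "muH cannot exceed the largest |H|")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "CapacitanceTrace", function(object) {
  cat(sprintf("CapacitanceTrace: %d samples, %.3f-%.3f s",
              length(object@time_s),
              object@time_s[1], object@time_s[length(object@time_s)]))
  if (!is.na(object@flashTime))
    cat(sprintf(", flash at %.3f s", object@flashTime))
  cat("\n")
})

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf(
    "CurrentTrace: %d samples @ %g kHz (low-pass %g kHz), %.2f s\n",
    length(object@time_s), object@sampleRate / 1000,
    object@filterCutoff / 1000, diff(range(object@time_s))))
})

setMethod("show", "AssemblyTimeCourse", function(object) {
  cat(sprintf("AssemblyTimeCourse [%s/%s]: %d points, %g-%g min\n",
              object@group, object@replicate, length(object@times_min),
              min(object@times_min), max(object@times_min)))
})

setMethod("show", "FlashFit", function(object) {
  cat("Flash-evoked capacitance decomposition",
      if (!object@converged) " (NOT converged)" else "", "\n", sep = "")
  cat(sprintf("  A0      = %.1f fF\n", object@A0_fF))
  cat(sprintf("  RRP     = %.1f fF  (tau = %.1f ms)\n",
              object@A_rrp_fF, object@tau_rrp_ms))
  cat(sprintf("  SRP     = %.1f fF  (tau = %.1f ms)\n",
              object@A_srp_fF, object@tau_srp_ms))
  cat(sprintf("  sustained rate = %.2f fF/s\n", object@k_sus_fFps))
  cat(sprintf("  secretory delay = %.2f ms\n", object@delay_ms))
  cat(sprintf("  residual rms = %.3g fF\n", object@residual_rms_fF))
})

setMethod("show", "AssemblyFit", function(object) {
  cat("Second-order SNARE assembly fit",
      if (!object@converged) " (NOT converged)" else "", "\n", sep = "")
  cat(sprintf("  SC0 = %.3g, SCinf = %.3g (a.u.), A0 = %.2g M\n",
              object@SC0_au, object@SCinf_au, object@A0_M))
  cat(sprintf("  k = %.4g 1/(M s), residual rms = %.3g\n",
              object@k_M1s1, object@residual_rms))
})

setMethod("show", "PeptideSegment", function(object) {
  coords <- if (!is.na(object@startRes))
    sprintf(" (%d-%d)", object@startRes, object@endRes) else ""
  cat(sprintf("PeptideSegment %s%s: %s\n",
              object@name, coords, object@sequence))
})

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("%s similarity (%s): %d/%d positions = %.1f%%\n",
              object@matrixName, object@mode, object@nSimilar,
              object@alignedLength, object@percentSimilarity))
})

setMethod("show", "HelixWindow", function(object) {
  cat(sprintf("HelixWindow %s (delta = %g deg, %s scale): muH = %.3f\n",
              object@segment@name, object@delta_deg, object@scale,
              object@muH))
})
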