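#' Construct a capacitance trace
#'
#' @param time_s sample times (s), strictly increasing.
#' @param cm_fF capacitance samples (fF).
#' @param flashTime flash instant (s) or `NA`.
#' @param meta optional list of acquisition notes.
#' @return A [CapacitanceTrace-class] object.
#' @examples
#' tr <- capacitanceTrace(seq(0, 1, by = 0.01), rep(5000, 101), flashTime = 0.5)
#' tr
#' @export
capacitanceTrace <- function(time_s, cm_fF, flashTime = NA_real_,
                             meta = list()) {
  new("CapacitanceTrace", time_s = as.numeric(time_s),
      cm_fF = as.numeric(cm_fF), flashTime = as.numeric(flashTime)[1],
      meta = meta)
}

#' Construct an amperometric current trace
#'
#' @param time_s sample times (s), uniform.
#' @param i_pA current samples (pA), oxidation positive.
#' @param sampleRate sampling rate (Hz).
#' @param filterCutoff low-pass cutoff already applied (Hz).
#' @param meta optional list.
#' @return A [CurrentTrace-class] object.
#' @export
currentTrace <- function(time_s, i_pA, sampleRate = 25000,
                         filterCutoff = 2000, meta = list()) {
  new("CurrentTrace", time_s = as.numeric(time_s), i_pA = as.numeric(i_pA),
      sampleRate = as.numeric(sampleRate)[1],
      filterCutoff = as.numeric(filterCutoff)[1], meta = meta)
}

#' Construct a SNARE-assembly time course
#'
#' @param times_min sampling times (min), strictly increasing.
#' @param values_au densitometry values (a.u.) or normalized fraction.
#' @param group group label.
#' @param replicate replicate identifier.
#' @return An [AssemblyTimeCourse-class] object.
#' @export
assemblyTimeCourse <- function(times_min, values_au,
                               group = NA_character_,
                               replicate = NA_character_) {
  new("AssemblyTimeCourse", times_min = as.numeric(times_min),
      values_au = as.numeric(values_au),
      group = as.character(group)[1], replicate = as.character(replicate)[1])
}

#' Construct a peptide segment
#'
#' @param name segment label.
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param startRes,endRes 1-based inclusive residue coordinates in the
#'   parent protein; may be omitted for free-standing peptides.
#' @return A [PeptideSegment-class] object.
#' @examples
#' peptideSegment("CpxII CTD box", "LDTVLKYLPGPLQDMFKK", 117, 134)
#' @export
peptideSegment <- function(name, sequence, startRes = NA, endRes = NA) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (is.na(startRes) && !is.na(endRes)) startRes <- endRes - nchar(sequence) + 1L
  if (!is.na(startRes) && is.na(endRes)) endRes <- startRes + nchar(sequence) - 1L
  new("PeptideSegment", name = as.character(name)[1], sequence = sequence,
      startRes = as.integer(startRes)[1], endRes = as.integer(endRes)[1])
}

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Accessors for trace and fit objects
#'
#' `traceTime()` and `traceValues()` return the time base and the sampled
#' signal of a trace; `flashTime()` the flash instant of a capacitance
#' trace; `sampleRate()` the sampling rate of a current trace;
#' `poolSizes()` the RRP/SRP amplitudes and sustained rate of a flash fit;
#' `rateConstant()` the second-order rate constant of an assembly fit;
#' `segmentSequence()` the amino-acid string of a peptide segment.
#'
#' @param object an object of the documented classes.
#' @return See individual generic descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("flashTime", function(object) standardGeneric("flashTime"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("poolSizes", function(object) standardGeneric("poolSizes"))
#' @rdname accessors
#' @export
setGeneric("rateConstant", function(object) standardGeneric("rateConstant"))
#' @rdname accessors
#' @export
setGeneric("segmentSequence", function(object) standardGeneric("segmentSequence"))

#' @rdname accessors
setMethod("traceTime", "CapacitanceTrace", function(object) object@time_s)
#' @rdname accessors
setMethod("traceTime", "CurrentTrace", function(object) object@time_s)
#' @rdname accessors
setMethod("traceValues", "CapacitanceTrace", function(object) object@cm_fF)
#' @rdname accessors
setMethod("traceValues", "CurrentTrace", function(object) object@i_pA)
#' @rdname accessors
setMethod("traceValues", "AssemblyTimeCourse", function(object) object@values_au)
#' @rdname accessors
setMethod("flashTime", "CapacitanceTrace", function(object) object@flashTime)
#' @rdname accessors
setMethod("sampleRate", "CurrentTrace", function(object) object@sampleRate)
#' @rdname accessors
setMethod("poolSizes", "FlashFit", function(object) {
  c(A_rrp_fF = object@A_rrp_fF, A_srp_fF = object@A_srp_fF,
    k_sus_fFps = object@k_sus_fFps)
})
#' @rdname accessors
setMethod("rateConstant", "AssemblyFit", function(object) object@k_M1s1)
#' @rdname accessors
setMethod("segmentSequence", "PeptideSegment", function(object) object@sequence)

#' Coerce a flash fit to a one-row data frame
#'
#' @param x a [FlashFit-class] object.
#' @param ... ignored.
#' @return A one-row `data.frame` with all fitted parameters.
#' @export
as.data.frame.FlashFit <- function(x, ...) {
  data.frame(A0_fF = x@A0_fF, A_rrp_fF = x@A_rrp_fF,
             tau_rrp_ms = x@tau_rrp_ms, A_srp_fF = x@A_srp_fF,
             tau_srp_ms = x@tau_srp_ms, k_sus_fFps = x@k_sus_fFps,
             onset_s = x@onset_s, delay_ms = x@delay_ms,
             residual_rms_fF = x@residual_rms_fF, converged = x@converged)
}

#' Coerce an assembly fit to a one-row data frame
#'
#' @param x an [AssemblyFit-class] object.
#' @param ... ignored.
#' @return A one-row `data.frame`.
#' @export
as.data.frame.AssemblyFit <- function(x, ...) {
  data.frame(SC0_au = x@SC0_au, SCinf_au = x@SCinf_au, A0_M = x@A0_M,
             k_M1s1 = x@k_M1s1, residual_rms = x@residual_rms,
             converged = x@converged)
}
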