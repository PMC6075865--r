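## Internal helpers shared across modules.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Positions (names) and letters of residues outside the standard alphabet.
.nonStandardResidues <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!(letters %in% .AA20))
  out <- as.list(letters[bad])
  names(out) <- bad
  out
}

.stopIfNonStandard <- function(sequence, what = "sequence") {
  bad <- .nonStandardResidues(sequence)
  if (length(bad))
    stop(sprintf("non-standard residue '%s' at position %s of %s",
                 bad[[1]][1], names(bad)[1], what), call. = FALSE)
  invisible(sequence)
}

#' Gaussian low-pass filter
#'
#' Zero-phase Gaussian FIR smoothing with the -3 dB point at `cutoff_hz`.
#' The Gaussian transfer function is `H(f) = exp(-f^2 / (2 sigma_f^2))`;
#' `|H(fc)| = 1/sqrt(2)` gives `sigma_f = fc / sqrt(ln 2)` and a
#' time-domain standard deviation `sigma_t = 1 / (2 pi sigma_f)`. Edges
#' are handled by renormalizing the truncated kernel, so a constant input
#' is reproduced exactly.
#'
#' @param x numeric signal.
#' @param sample_rate_hz sampling rate (Hz).
#' @param cutoff_hz -3 dB cutoff (Hz). `Inf` returns `x` unchanged.
#' @return Filtered numeric vector, same length as `x`.
#' @export
gaussianLowpass <- function(x, sample_rate_hz, cutoff_hz) {
  if (!is.finite(cutoff_hz)) return(x)
  stopifnot(sample_rate_hz > 0, cutoff_hz > 0)
  sigma_f <- cutoff_hz / sqrt(log(2))
  sigma_t <- 1 / (2 * pi * sigma_f)
  sigma_n <- sigma_t * sample_rate_hz
  half <- max(1L, ceiling(4 * sigma_n))
  k <- exp(-0.5 * ((-half:half) / sigma_n)^2)
  k <- k / sum(k)
  n <- length(x)
  if (n == 0) return(x)
  ## reflect-pad so edges keep DC gain 1
  xp <- c(x[pmin(half:1 + 1, n)], x, x[pmax(n - (1:half), 1)])
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

## Trapezoidal integral of y over x.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

## Contiguous runs of TRUE in a logical vector: data.frame(start, end).
.runsTrue <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

## Least-squares slope of y vs x (closed form).
.lsSlope <- function(x, y) {
  xm <- x - mean(x)
  sum(xm * (y - mean(y))) / sum(xm^2)
}

## Standard error of the mean.
.sem <- function(x) stats::sd(x) / sqrt(length(x))
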