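## SNAP25-SN1 mimicry scoring of peptide segments: BLOSUM62 percent
## similarity, Eisenberg hydrophobic moment, helical-wheel projection,
## and sliding-window scans of whole proteins.

## Eisenberg normalized consensus hydrophobicity scale.
.EISENBERG <- c(
  A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
  Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
  L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08)

#' Hydrophobicity scales
#'
#' Returns a named per-residue hydrophobicity vector. Currently the
#' Eisenberg normalized consensus scale, the standard scale for
#' hydrophobic-moment calculations; the argument exists so alternative
#' scales can be swapped in.
#'
#' @param name scale name, `"eisenberg"`.
#' @return Named numeric vector over the 20 standard residues.
#' @export
hydrophobicityScale <- function(name = "eisenberg") {
  switch(match.arg(name, "eisenberg"), eisenberg = .EISENBERG)
}

.blosumCache <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' @return The BLOSUM62 integer matrix shipped with Biostrings.
#' @export
blosum62 <- function() {
  if (is.null(.blosumCache$B)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosumCache$B <- e$BLOSUM62
  }
  .blosumCache$B
}

.asSegment <- function(x, name = "segment") {
  if (is(x, "PeptideSegment")) return(x)
  peptideSegment(name, as.character(x))
}

#' BLOSUM62 percent similarity of two peptide segments
#'
#' A position is counted as similar iff its BLOSUM62 substitution score
#' is positive (identities included), and the percentage is taken over
#' the aligned (non-gap) columns — the similarity convention of the
#' standard global-alignment tools. Equal-length segments are compared
#' position by position (gapless); unequal lengths are first aligned
#' globally with affine gaps (open 10, extend 0.5, the conventional
#' defaults).
#'
#' @param a,b [PeptideSegment-class] objects or plain sequences.
#' @param mode `"auto"` (gapless when lengths match), `"gapless"`, or
#'   `"global"`.
#' @param gap_open,gap_extend affine gap penalties for global mode.
#' @return A [SimilarityResult-class] object.
#' @examples
#' seg <- snareSegments()
#' percentSimilarity(seg$cpx2_ctd_box, seg$snap25_sn1)
#' @export
percentSimilarity <- function(a, b, mode = c("auto", "gapless", "global"),
                              gap_open = 10, gap_extend = 0.5) {
  mode <- match.arg(mode)
  a <- .asSegment(a, "a"); b <- .asSegment(b, "b")
  .stopIfNonStandard(a@sequence, a@name)
  .stopIfNonStandard(b@sequence, b@name)
  B <- blosum62()
  if (mode == "auto")
    mode <- if (nchar(a@sequence) == nchar(b@sequence)) "gapless" else "global"
  if (mode == "gapless") {
    if (nchar(a@sequence) != nchar(b@sequence))
      stop("gapless mode requires equal-length segments")
    pa <- strsplit(a@sequence, "")[[1]]
    pb <- strsplit(b@sequence, "")[[1]]
  } else {
    aln <- Biostrings::pairwiseAlignment(
      a@sequence, b@sequence, type = "global",
      substitutionMatrix = B,
      gapOpening = gap_open, gapExtension = gap_extend)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  }
  keep <- pa != "-" & pb != "-"
  pa <- pa[keep]; pb <- pb[keep]
  n_sim <- sum(B[cbind(pa, pb)] > 0)
  new("SimilarityResult", matrixName = "BLOSUM62",
      alignedLength = length(pa), nSimilar = as.integer(n_sim),
      percentSimilarity = 100 * n_sim / length(pa),
      mode = if (mode == "gapless") "gapless" else "global-affine")
}

#' Eisenberg hydrophobic moment
#'
#' Mean hydrophobic moment per residue of an ideal helix:
#' \deqn{\mu_H = \frac{1}{N}\sqrt{\Big(\sum_n H_n \sin n\delta\Big)^2 +
#'   \Big(\sum_n H_n \cos n\delta\Big)^2}}
#' with per-residue hydrophobicities \eqn{H_n} on the Eisenberg
#' normalized consensus scale and the helix angle \eqn{\delta} (100
#' degrees per residue for an alpha helix). Large \eqn{\mu_H} marks an
#' amphipathic helix whose hydrophobic residues cluster on one face.
#'
#' @param seg a [PeptideSegment-class] or plain sequence.
#' @param delta_deg helix angle per residue (degrees), default 100.
#' @param scale hydrophobicity scale name, see [hydrophobicityScale()].
#' @return A [HelixWindow-class]; the moment is in slot `muH`.
#' @examples
#' hydrophobicMoment(snareSegments()$cpx2_ctd_box)   # muH = 0.506
#' @export
hydrophobicMoment <- function(seg, delta_deg = 100, scale = "eisenberg") {
  seg <- .asSegment(seg)
  .stopIfNonStandard(seg@sequence, seg@name)
  H <- hydrophobicityScale(scale)[strsplit(seg@sequence, "")[[1]]]
  n <- seq_along(H)
  rad <- delta_deg * pi / 180
  muH <- sqrt(sum(H * sin(n * rad))^2 + sum(H * cos(n * rad))^2) / length(H)
  new("HelixWindow", segment = seg, delta_deg = delta_deg,
      angle_deg = ((n - 1) * delta_deg) %% 360,
      H = unname(H), scale = scale, muH = muH)
}

#' Helical-wheel projection table
#'
#' Deterministic plotting table of an ideal-helix projection: residue n
#' sits at angle `(n - 1) * delta mod 360` degrees; the radius column
#' carries the residue hydrophobicity so amphipathic faces are visible.
#'
#' @param seg a [PeptideSegment-class] or plain sequence.
#' @param delta_deg helix angle per residue (degrees).
#' @param scale hydrophobicity scale for the radius column.
#' @return `data.frame(position, residue, angle_deg, hydrophobicity)`.
#' @examples
#' head(helicalWheel("LDTVLKYLPGPLQDMFKK"))
#' @export
helicalWheel <- function(seg, delta_deg = 100, scale = "eisenberg") {
  seg <- .asSegment(seg)
  .stopIfNonStandard(seg@sequence, seg@name)
  res <- strsplit(seg@sequence, "")[[1]]
  n <- seq_along(res)
  data.frame(position = n, residue = res,
             angle_deg = ((n - 1) * delta_deg) %% 360,
             hydrophobicity = unname(hydrophobicityScale(scale)[res]))
}

#' Scan a protein for SNARE-motif mimicry
#'
#' Slides a window along one or more query sequences and scores every
#' window against every target segment by BLOSUM62 percent similarity
#' (gapless when the window length equals the target length) and by
#' hydrophobic moment. The summary reports, per target, the best-window
#' similarity of each query and its mean +/- SEM across queries — the
#' form used to average one motif over several species.
#'
#' @param query named character vector of protein sequences (or a single
#'   sequence / [PeptideSegment-class]).
#' @param targets list of [PeptideSegment-class] targets (non-empty).
#' @param window window length, default the length of the first target;
#'   must not exceed any query length.
#' @param delta_deg helix angle for the window hydrophobic moments.
#' @return A list: `windows` (query, window start, sequence, target,
#'   percent similarity, muH of the window) and `summary` (target,
#'   per-query best percent mean, SEM, n).
#' @export
scanMimicry <- function(query, targets, window = NULL, delta_deg = 100) {
  if (!length(targets)) stop("no target segments supplied")
  if (is(query, "PeptideSegment")) {
    q <- stats::setNames(query@sequence, query@name)
  } else {
    q <- stats::setNames(as.character(query), names(query))
    if (is.null(names(q))) names(q) <- paste0("query", seq_along(q))
  }
  targets <- lapply(targets, .asSegment)
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    names(targets) <- vapply(targets, function(s) s@name, character(1))
  if (is.null(window)) window <- nchar(targets[[1]]@sequence)
  if (any(nchar(q) < window))
    stop("window exceeds the length of at least one query")
  rows <- list()
  for (qi in names(q)) {
    .stopIfNonStandard(q[[qi]], qi)
    starts <- seq_len(nchar(q[[qi]]) - window + 1L)
    for (s in starts) {
      wseq <- substr(q[[qi]], s, s + window - 1L)
      mu <- hydrophobicMoment(wseq, delta_deg = delta_deg)@muH
      for (tn in names(targets)) {
        ps <- percentSimilarity(wseq, targets[[tn]])
        rows[[length(rows) + 1L]] <- data.frame(
          query = qi, start = s, window_seq = wseq, target = tn,
          percent_similarity = ps@percentSimilarity, muH = mu)
      }
    }
  }
  windows <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(targets), function(tn) {
    best <- vapply(names(q), function(qi) {
      w <- windows[windows$query == qi & windows$target == tn, ]
      max(w$percent_similarity)
    }, numeric(1))
    data.frame(target = tn, mean_best_percent = mean(best),
               sem = if (length(best) > 1) .sem(best) else NA_real_,
               n_queries = length(best))
  }))
  list(windows = windows, summary = summary)
}

#' Built-in SNARE and complexin segments
#'
#' The peptide segments this package's mimicry analyses revolve around,
#' with 1-based residue coordinates in their parent proteins:
#'
#' * `cpx2_ctd` — mouse complexin-II C-terminal domain peptide,
#'   residues 101-134.
#' * `cpx2_ctd_scrambled` — scrambled-sequence control peptide (same
#'   composition).
#' * `cpx2_ctd_box` — the CTD comparison region, residues 117-134 (the
#'   last 18 residues of the CTD), spanning hydrophobic layers +2 to +7
#'   of the SNARE alignment.
#' * `snap25_sn1` — mouse SNAP25a SN1 motif segment, residues 60-77
#'   (the exon-5a isoform sequence).
#' * `snap25_sn2` — the matching SNAP25 SN2 segment, residues 183-200.
#' * `syb2` — the matching synaptobrevin-II segment, residues 63-80.
#' * `syx1a` — the matching syntaxin-1A segment, residues 233-250.
#'
#' The SNARE segments are the length-matched membrane-proximal regions
#' aligned to the CTD box; coordinates follow the canonical mouse
#' sequences.
#'
#' @return Named list of [PeptideSegment-class] objects.
#' @examples
#' snareSegments()$snap25_sn1
#' @export
snareSegments <- function() {
  list(
    cpx2_ctd = peptideSegment(
      "CpxII CTD", "IPAGCGDEEEEEEESILDTVLKYLPGPLQDMFKK", 101, 134),
    cpx2_ctd_scrambled = peptideSegment(
      "CpxII CTD scrambled", "KVPYELGGQLPELKTSDPIEGEDEDELFMKEIAC"),
    cpx2_ctd_box = peptideSegment(
      "CpxII CTD box", "LDTVLKYLPGPLQDMFKK", 117, 134),
    snap25_sn1 = peptideSegment(
      "SNAP25-SN1", "VEEGMNHINQDMKEAEKN", 60, 77),
    snap25_sn2 = peptideSegment(
      "SNAP25-SN2", "IMEKADSNKTRIDEANQR", 183, 200),
    syb2 = peptideSegment(
      "SybII", "LDDRADALQAGASQFETS", 63, 80),
    syx1a = peptideSegment(
      "Syx1A", "IEYNVEHAVDYVERAVSD", 233, 250)
  )
}
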