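## Plain-text interchange: traces as two-column CSV with a small
## commented header, assembly data as long-format TSV, fit results as
## TSV/JSON.

.readHeaderMeta <- function(file) {
  hdr <- character()
  con <- file(file, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  out <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("#\\s*([A-Za-z_0-9]+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

#' Read / write capacitance traces
#'
#' CSV with columns `time_s, cm_fF` and an optional commented header
#' line `# flash_time_s=<value>`.
#'
#' @param file path.
#' @return [CapacitanceTrace-class] for the reader; the writer returns
#'   `file` invisibly.
#' @export
readCapacitanceTrace <- function(file) {
  meta <- .readHeaderMeta(file)
  df <- utils::read.csv(file, comment.char = "#")
  stopifnot(all(c("time_s", "cm_fF") %in% names(df)))
  ft <- if (!is.null(meta$flash_time_s)) as.numeric(meta$flash_time_s)
        else NA_real_
  capacitanceTrace(df$time_s, df$cm_fF, flashTime = ft)
}

#' @rdname readCapacitanceTrace
#' @param trace a [CapacitanceTrace-class].
#' @export
writeCapacitanceTrace <- function(trace, file) {
  con <- file(file, "w"); on.exit(close(con))
  if (!is.na(trace@flashTime))
    writeLines(sprintf("# flash_time_s=%.10g", trace@flashTime), con)
  utils::write.csv(data.frame(time_s = trace@time_s, cm_fF = trace@cm_fF),
                   con, row.names = FALSE)
  invisible(file)
}

#' Read / write amperometric traces
#'
#' CSV with columns `time_s, i_pA` and optional commented headers
#' `# sample_rate_hz=` and `# filter_cutoff_hz=`.
#'
#' @param file path.
#' @return [CurrentTrace-class] for the reader; the writer returns
#'   `file` invisibly.
#' @export
readCurrentTrace <- function(file) {
  meta <- .readHeaderMeta(file)
  df <- utils::read.csv(file, comment.char = "#")
  stopifnot(all(c("time_s", "i_pA") %in% names(df)))
  fs <- if (!is.null(meta$sample_rate_hz)) as.numeric(meta$sample_rate_hz)
        else 1 / stats::median(diff(df$time_s))
  fc <- if (!is.null(meta$filter_cutoff_hz)) as.numeric(meta$filter_cutoff_hz)
        else 2000
  currentTrace(df$time_s, df$i_pA, sampleRate = fs, filterCutoff = fc)
}

#' @rdname readCurrentTrace
#' @param trace a [CurrentTrace-class].
#' @export
writeCurrentTrace <- function(trace, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(sprintf("# sample_rate_hz=%.10g", trace@sampleRate),
               sprintf("# filter_cutoff_hz=%.10g", trace@filterCutoff)), con)
  utils::write.csv(data.frame(time_s = trace@time_s, i_pA = trace@i_pA),
                   con, row.names = FALSE)
  invisible(file)
}

#' Read a long-format assembly table
#'
#' TSV with columns `group, replicate, time_min, value_au`; one
#' [AssemblyTimeCourse-class] is built per (group, replicate).
#'
#' @param file path.
#' @return List of [AssemblyTimeCourse-class] objects.
#' @export
readAssemblyTable <- function(file) {
  df <- utils::read.delim(file, comment.char = "#")
  stopifnot(all(c("group", "replicate", "time_min", "value_au") %in%
                  names(df)))
  sp <- split(df, interaction(df$group, df$replicate, drop = TRUE))
  lapply(sp, function(d) {
    d <- d[order(d$time_min), ]
    assemblyTimeCourse(d$time_min, d$value_au,
                       group = as.character(d$group[1]),
                       replicate = as.character(d$replicate[1]))
  })
}

#' Write fit results
#'
#' One row per fit, as TSV and/or JSON.
#'
#' @param fits list of [FlashFit-class] or [AssemblyFit-class] objects.
#' @param tsv,json output paths (either may be `NULL`).
#' @return The combined `data.frame`, invisibly.
#' @export
writeFitResults <- function(fits, tsv = NULL, json = NULL) {
  df <- do.call(rbind, lapply(fits, as.data.frame))
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
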