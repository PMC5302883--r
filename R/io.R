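# Shared delimited-text reader: header-validated, tab or comma separated.
.read_table2 <- function(path, expected_cols, optional_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)] # metadata/comment lines
  if (length(lines) < 2)
    stop(path, ": expected a header line (",
         paste(expected_cols, collapse = ", "), ") and at least one row")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  hdr <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  missing <- setdiff(expected_cols, hdr)
  if (length(missing))
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "),
         "; expected header with columns ",
         paste(c(expected_cols, optional_cols), collapse = ", "))
  rows <- strsplit(lines[-1], sep, fixed = TRUE)
  ncol_h <- length(hdr)
  bad <- which(vapply(rows, length, 0L) != ncol_h)
  if (length(bad))
    stop(path, ": line ", bad[1] + 1L, " has ",
         length(rows[[bad[1]]]), " fields, expected ", ncol_h)
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = ncol_h, byrow = TRUE)
  nas <- which(apply(m, 1, anyNA))
  if (length(nas))
    stop(path, ": line ", nas[1] + 1L, " contains a non-numeric value")
  df <- as.data.frame(m)
  names(df) <- hdr
  df
}

.write_table2 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read and write current traces as delimited text
#'
#' Traces are stored as two-column delimited text (tab default, comma
#' accepted) with header `time_s`, `current_pA`; lines beginning with `#`
#' carry optional metadata (`# sampling_rate_hz:`, `# filter_cutoff_hz:`)
#' and are written by `write_trace()`. Reading validates uniform sample
#' spacing; malformed rows are reported with their line number.
#'
#' @param path File path.
#' @param trace A [current_trace()] (for writing).
#' @return `read_trace()` returns a `current_trace`; `write_trace()`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path) {
  df <- .read_table2(path, c("time_s", "current_pA"))
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop(path, ": line ", which(dt <= 0)[1] + 2L,
         ": time axis is not strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop(path, ": sample spacing is not uniform")
  fs <- 1 / stats::median(dt)
  meta <- .read_meta(path)
  current_trace(df$current_pA,
                sampling_rate = meta$sampling_rate_hz %||% fs,
                filter_cutoff = meta$filter_cutoff_hz %||% NA_real_,
                t0 = df$time_s[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_meta <- function(path) {
  lines <- grep("^\\s*#", readLines(path, warn = FALSE), value = TRUE)
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z0-9_]+)\\s*:\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- suppressWarnings(as.numeric(m[3]))
  }
  out
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.10g", trace$sampling_rate), con)
  if (!is.na(trace$filter_cutoff))
    writeLines(sprintf("# filter_cutoff_hz: %.10g", trace$filter_cutoff), con)
  df <- data.frame(time_s = trace_times(trace), current_pA = trace$current)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write absorbance spectra as delimited text
#'
#' Spectra are two-column delimited text with header `wavelength_nm`,
#' `od`. Wavelengths must be strictly increasing; violations are reported
#' with the offending line number.
#'
#' @param path File path.
#' @param spectrum An [absorbance_spectrum()] (for writing).
#' @return `read_spectrum()` returns an `absorbance_spectrum`.
#' @export
read_spectrum <- function(path) {
  df <- .read_table2(path, c("wavelength_nm", "od"))
  bad <- which(diff(df$wavelength_nm) <= 0)
  if (length(bad))
    stop(path, ": line ", bad[1] + 2L,
         ": wavelengths must be strictly increasing")
  absorbance_spectrum(df$wavelength_nm, df$od)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  .write_table2(data.frame(wavelength_nm = spectrum$wavelength,
                           od = spectrum$od), path)
  invisible(path)
}

#' Read and write exchange time courses as delimited text
#'
#' Time courses are delimited text with header `time_min`, `fraction` and
#' optional `sd`.
#'
#' @param path File path.
#' @param timecourse An [exchange_timecourse()] (for writing).
#' @return `read_timecourse()` returns an `exchange_timecourse`.
#' @export
read_timecourse <- function(path) {
  df <- .read_table2(path, c("time_min", "fraction"), optional_cols = "sd")
  exchange_timecourse(df$time_min, df$fraction,
                      sd = if ("sd" %in% names(df)) df$sd else NA_real_)
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(timecourse, path) {
  stopifnot(inherits(timecourse, "exchange_timecourse"))
  .write_table2(data.frame(time_min = timecourse$time,
                           fraction = timecourse$fraction,
                           sd = timecourse$sd), path)
  invisible(path)
}
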