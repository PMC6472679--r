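#' Read wave summary records from CSV
#'
#' A wave record is one sea state summary: timestamp, significant wave
#' height `H` (m) and wave period `T` (s), as produced by a wave buoy's
#' half-hourly processing. Validation rejects non-positive `H` or `T`
#' naming the offending row.
#'
#' @param path CSV with columns `time`, `H`, `T` (metadata comment lines
#'   prefixed `#` are ignored).
#' @return data.frame of class `wave_records` with columns
#'   `time` (POSIXct UTC), `H` (m), `T` (s).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time,H,T", "2013-03-10T19:36:00Z,3.99,7.4"), f)
#' read_wave_records(f)
read_wave_records <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time", "H", "T")
  if (!all(need %in% names(df)))
    stop("read_wave_records: need columns ", paste(need, collapse = ", "))
  out <- data.frame(
    time = as.POSIXct(df$time, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%d %H:%M:%OS")),
    H = as.numeric(df$H), T = as.numeric(df$T))
  bad <- which(!is.finite(out$H) | out$H <= 0 | !is.finite(out$T) | out$T <= 0)
  if (length(bad) > 0)
    stop("read_wave_records: H and T must be > 0; offending row ", bad[1],
         " (time ", df$time[bad[1]], ")")
  class(out) <- c("wave_records", "data.frame")
  out
}

#' Write wave records to CSV
#' @param records data.frame with `time`, `H`, `T` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wave_records <- function(records, path) {
  df <- data.frame(time = fmt_iso(records$time), H = records$H, T = records$T)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dissolved-oxygen concentration series from CSV
#'
#' @param path CSV with columns `time`, `concentration` (mg/L) and
#'   optionally `temperature` (deg C).
#' @return data.frame of class `do_series` with strictly increasing
#'   `time` and positive `concentration`.
#' @export
read_do_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time", "concentration") %in% names(df)))
    stop("read_do_series: need columns time, concentration")
  out <- data.frame(
    time = as.POSIXct(df$time, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%d")),
    concentration = as.numeric(df$concentration))
  if ("temperature" %in% names(df))
    out$temperature <- as.numeric(df$temperature)
  bad <- which(!is.finite(out$concentration) | out$concentration <= 0)
  if (length(bad) > 0)
    stop("read_do_series: concentration must be > 0; offending row ", bad[1])
  if (anyNA(out$time) || any(diff(as.numeric(out$time)) <= 0))
    stop("read_do_series: times must be strictly increasing")
  class(out) <- c("do_series", "data.frame")
  out
}

#' Write a dissolved-oxygen series to CSV
#' @param series data.frame with `time`, `concentration` (and optional
#'   `temperature`) columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_do_series <- function(series, path) {
  df <- data.frame(time = fmt_iso(series$time),
                   concentration = series$concentration)
  if ("temperature" %in% names(series)) df$temperature <- series$temperature
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
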