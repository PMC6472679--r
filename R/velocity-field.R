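#' Depth-resolved flow-speed time series
#'
#' A `velocity_field` holds a time-by-height grid of flow-speed magnitude,
#' the container for both External Velocity Profiles (EVP, measured outside
#' an SBCC container, ADCP-style) and Internal Velocity Profiles (IVP,
#' predicted inside the container by [apply_transfer()]).
#'
#' The vertical coordinate is height above the seabed in metres (the ADCP
#' bin convention). Wave formulas work in `z`, measured downward from the
#' still-water surface; the single conversion site is [height_to_z()].
#' Missing samples are explicit `NA`s in the speed matrix, never silent
#' zeros.
#'
#' @param times `POSIXct` (UTC) sample times, strictly increasing.
#' @param heights numeric, heights above seabed (m), strictly increasing.
#' @param speed numeric matrix `length(times)` x `length(heights)` of
#'   non-negative flow speeds (m/s); `NA` marks a missing sample.
#' @param cadence nominal sampling interval in seconds (default 600 s,
#'   i.e. 10-minute means).
#' @param provenance `"external"` for measured/simulated ambient flow,
#'   `"internal"` for post-transfer in-container flow.
#' @param water_depth_ref reference water depth (m), used to convert
#'   heights to depth below surface; may be `NA` if never needed.
#'
#' @return An object of class `velocity_field`.
#' @seealso [read_velocity_field()], [write_velocity_field()],
#'   [apply_transfer()]
#' @export
#' @examples
#' tm <- as.POSIXct("2013-03-10 19:36", tz = "UTC") + 600 * (0:5)
#' vf <- velocity_field(tm, heights = c(1.24, 10, 20),
#'                      speed = matrix(0.2, 6, 3), water_depth_ref = 22)
#' vf
velocity_field <- function(times, heights, speed,
                           cadence = 600,
                           provenance = c("external", "internal"),
                           water_depth_ref = NA_real_) {
  provenance <- match.arg(provenance)
  times <- as.POSIXct(times, tz = "UTC")
  heights <- as.numeric(heights)
  speed <- as.matrix(speed)
  storage.mode(speed) <- "double"
  x <- structure(
    list(times = times, heights = heights, speed = speed,
         cadence = as.numeric(cadence), provenance = provenance,
         water_depth_ref = as.numeric(water_depth_ref)),
    class = "velocity_field")
  validate_velocity_field(x)
}

#' Validate a velocity field
#'
#' Checks the structural invariants of a [velocity_field()]: strictly
#' increasing times and heights, matching matrix dimensions, and finite
#' non-negative speeds (NA allowed as explicit missing marks). Errors name
#' the offending row/timestamp.
#'
#' @param x a `velocity_field`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_velocity_field <- function(x) {
  stopifnot(inherits(x, "velocity_field"))
  nt <- length(x$times); nh <- length(x$heights)
  if (anyNA(x$times)) stop("velocity_field: unparseable/NA timestamps present")
  if (nt > 1) {
    d <- diff(as.numeric(x$times))
    if (any(d == 0)) {
      i <- which(d == 0)[1]
      stop("velocity_field: duplicate timestamp at ",
           format(x$times[i + 1], "%Y-%m-%dT%H:%M:%SZ"))
    }
    if (any(d < 0)) {
      i <- which(d < 0)[1]
      stop("velocity_field: times not increasing at row ", i + 1,
           " (", format(x$times[i + 1], "%Y-%m-%dT%H:%M:%SZ"), ")")
    }
  }
  if (nh > 1 && any(diff(x$heights) <= 0))
    stop("velocity_field: heights must be strictly increasing")
  if (!identical(dim(x$speed), c(nt, nh)))
    stop("velocity_field: speed matrix is ", nrow(x$speed), "x", ncol(x$speed),
         ", expected ", nt, "x", nh)
  bad <- which(!is.na(x$speed) & (!is.finite(x$speed) | x$speed < 0),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("velocity_field: negative or non-finite speed at row ", bad[1, 1],
         ", height ", x$heights[bad[1, 2]], " m")
  if (!(x$provenance %in% c("external", "internal")))
    stop("velocity_field: provenance must be 'external' or 'internal'")
  if (length(x$cadence) != 1 || !is.finite(x$cadence) || x$cadence <= 0)
    stop("velocity_field: cadence must be a positive scalar (seconds)")
  invisible(x)
}

#' Convert height above seabed to depth coordinate z
#'
#' Wave kinematics use `z`, the vertical position measured from the
#' still-water surface (`z = 0` at the surface, negative below). This is
#' the one conversion site between the ADCP height-above-seabed convention
#' and the wave-theory convention.
#'
#' @param height height above seabed (m), in `[0, water_depth]`.
#' @param water_depth water depth (m).
#' @return `z = height - water_depth` (m, `<= 0`).
#' @export
#' @examples
#' height_to_z(1.24, 22)   # near-bed bin
#' height_to_z(22, 22)     # surface
height_to_z <- function(height, water_depth) {
  if (any(height < 0) || any(height > water_depth))
    stop("height must lie within [0, water_depth]")
  height - water_depth
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("<velocity_field> ", x$provenance, "\n", sep = "")
  cat("  ", length(x$times), " times x ", length(x$heights), " heights, ",
      "cadence ", x$cadence, " s\n", sep = "")
  cat("  span ", format(x$times[1], "%Y-%m-%d %H:%M", tz = "UTC"), " .. ",
      format(x$times[length(x$times)], "%Y-%m-%d %H:%M", tz = "UTC"),
      " UTC\n", sep = "")
  cat("  heights ", min(x$heights), "-", max(x$heights),
      " m above seabed; missing ", sum(is.na(x$speed)), "/",
      length(x$speed), " samples\n", sep = "")
  invisible(x)
}

fmt_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

read_meta_comments <- function(path) {
  hdr <- readLines(path, n = 50L)
  hdr <- hdr[startsWith(hdr, "#")]
  out <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Read a velocity field from CSV
#'
#' Accepts the wide grid format written by [write_velocity_field()] (a
#' `time` column plus one column per height bin) or a long format with
#' `time`, `height` and `speed` columns. `#`-prefixed metadata comment
#' lines (`provenance`, `cadence`, `water_depth_ref`) are honoured.
#' Unparseable speed cells become explicit `NA` missing marks.
#'
#' @param path CSV file path.
#' @param dialect optional named character vector mapping the canonical
#'   column names `time`, `height`, `speed` to the names used in the file,
#'   e.g. `c(time = "timestamp_utc", height = "hab_m", speed = "spd")`.
#' @return A validated [velocity_field()].
#' @export
read_velocity_field <- function(path, dialect = NULL) {
  if (!file.exists(path))
    stop("read_velocity_field: no such file: ", path)
  meta <- read_meta_comments(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  nm <- function(canon) {
    if (!is.null(dialect) && canon %in% names(dialect)) dialect[[canon]] else canon
  }
  tcol <- nm("time")
  if (!(tcol %in% names(df)))
    stop("read_velocity_field: no '", tcol, "' column in ", path)
  times <- as.POSIXct(df[[tcol]], tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                     "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  long <- all(c(nm("height"), nm("speed")) %in% names(df))
  if (long) {
    h <- as.numeric(df[[nm("height")]])
    s <- suppressWarnings(as.numeric(df[[nm("speed")]]))
    heights <- sort(unique(h))
    ut <- unique(times)
    speed <- matrix(NA_real_, length(ut), length(heights))
    speed[cbind(match(times, ut), match(h, heights))] <- s
    times <- ut
  } else {
    hcols <- setdiff(names(df), tcol)
    heights <- suppressWarnings(as.numeric(sub("^h_", "", hcols)))
    if (anyNA(heights))
      stop("read_velocity_field: height columns must be numeric (or 'h_<m>'): ",
           paste(hcols[is.na(heights)], collapse = ", "))
    o <- order(heights)
    speed <- matrix(NA_real_, nrow(df), length(hcols))
    for (j in seq_along(o))
      speed[, j] <- suppressWarnings(as.numeric(df[[hcols[o[j]]]]))
    heights <- heights[o]
  }
  velocity_field(
    times, heights, speed,
    cadence = if (!is.null(meta$cadence)) as.numeric(meta$cadence) else 600,
    provenance = if (!is.null(meta$provenance)) meta$provenance else "external",
    water_depth_ref = if (!is.null(meta$water_depth_ref))
      suppressWarnings(as.numeric(meta$water_depth_ref)) else NA_real_)
}

#' Write a velocity field to CSV
#'
#' Wide grid format: `#` metadata comment lines (provenance, cadence,
#' water_depth_ref), then a header `time,h_<height>,...` and one row per
#' timestamp. Missing marks are serialized as empty cells. The file round
#' trips through [read_velocity_field()].
#'
#' @param field a [velocity_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path) {
  validate_velocity_field(field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# provenance: ", field$provenance),
               paste0("# cadence: ", format(field$cadence, scientific = FALSE)),
               paste0("# water_depth_ref: ", field$water_depth_ref)), con)
  df <- data.frame(time = fmt_iso(field$times), check.names = FALSE)
  for (j in seq_along(field$heights))
    df[[paste0("h_", field$heights[j])]] <- field$speed[, j]
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
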