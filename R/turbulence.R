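#' Decompose an instantaneous velocity series into mean and fluctuation
#'
#' Reynolds decomposition `u = u_bar + u'`: the series is cut into
#' consecutive averaging windows, each sample's fluctuation is its
#' deviation from the window mean. Fluctuations sum to zero within each
#' window by construction. A partial trailing window (fewer samples than
#' a full window) is dropped.
#'
#' @param series instantaneous speeds (m/s), uniformly sampled.
#' @param window averaging duration (s), default 600 (10-minute means).
#' @param cadence sampling interval (s), default 0.5 (2 Hz ADCP).
#' @return list with `u_mean` (one mean per complete window),
#'   `fluctuations` (u', one per retained sample), `window_index`
#'   (window id per retained sample) and `samples_per_window`.
#' @export
#' @examples
#' d <- decompose_velocity(c(1, 3, 2, 2), window = 1, cadence = 0.5)
#' d$u_mean          # 2 2
#' d$fluctuations    # -1 1 0 0
decompose_velocity <- function(series, window = 600, cadence = 0.5) {
  n_per <- floor(window / cadence)
  if (n_per < 2)
    stop("decompose_velocity: window must span at least 2 sampling intervals")
  n_win <- floor(length(series) / n_per)
  if (n_win < 1)
    stop("decompose_velocity: series shorter than one window (",
         n_per, " samples)")
  keep <- series[seq_len(n_win * n_per)]
  idx <- rep(seq_len(n_win), each = n_per)
  u_mean <- as.numeric(tapply(keep, idx, mean))
  list(u_mean = u_mean,
       fluctuations = keep - u_mean[idx],
       window_index = idx,
       samples_per_window = n_per)
}

#' Turbulence intensity
#'
#' The root-mean-square of the velocity fluctuations normalised by the
#' window-mean velocity: `I = RMS(u') / u_bar`. Undefined for
#' non-positive mean velocity.
#'
#' @param fluctuations velocity fluctuations u' (m/s).
#' @param u_mean window-mean velocity (m/s), > 0.
#' @return turbulence intensity I (dimensionless, >= 0).
#' @export
#' @examples
#' turbulence_intensity(c(-0.1, 0.1), u_mean = 0.2)  # 0.5
turbulence_intensity <- function(fluctuations, u_mean) {
  if (!is.finite(u_mean) || u_mean <= 0)
    stop("turbulence_intensity: u_mean must be > 0 (intensity undefined)")
  sqrt(mean(fluctuations^2)) / u_mean
}

#' Turbulence intensity profile from an instantaneous series
#'
#' Convenience wrapper: decomposes the series into windows and reports
#' per-window mean, RMS fluctuation and intensity.
#'
#' @inheritParams decompose_velocity
#' @return data.frame with one row per complete window: `u_mean`,
#'   `u_rms`, `intensity`.
#' @export
turbulence_summary <- function(series, window = 600, cadence = 0.5) {
  d <- decompose_velocity(series, window = window, cadence = cadence)
  u_rms <- as.numeric(tapply(d$fluctuations, d$window_index,
                             function(f) sqrt(mean(f^2))))
  data.frame(u_mean = d$u_mean, u_rms = u_rms,
             intensity = u_rms / d$u_mean)
}

#' Normalise heights above seabed by water depth
#'
#' Used to combine depth profiles from sites of different water depth on
#' a common dimensionless vertical coordinate (0 = seabed, 1 = surface).
#'
#' @param heights heights above seabed (m), within `[0, water_depth]`.
#' @param water_depth water depth (m), > 0.
#' @return `heights / water_depth` in `[0, 1]`.
#' @export
#' @examples
#' normalize_depth(18.75, 37.5)  # 0.5
normalize_depth <- function(heights, water_depth) {
  if (!is.finite(water_depth) || water_depth <= 0)
    stop("normalize_depth: water_depth must be > 0")
  if (any(heights < 0) || any(heights > water_depth))
    stop("normalize_depth: heights must lie within [0, water_depth]")
  heights / water_depth
}
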