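#' Specification for the synthetic Falmouth-bay-like data generator
#'
#' Collects the parameters of the seeded generator that emulates the
#' statistical character of the case-study measurement campaigns: a
#' vertically sheared tidal current with semidiurnal and spring-neap
#' modulation, an energetic winter sea state, depth-averaged turbulence
#' intensity, and a seasonal dissolved-oxygen cycle. Defaults are the
#' case-study values: long-run mean current 0.24 m/s at the surface and
#' 0.11 m/s near the seabed, spring-neap beat of the M2 (12.42 h) and S2
#' (12.00 h) constituents, bulk turbulence intensity 0.8, storm waves
#' H = 3.99 m / T = 7.4 s, annual-minimum DO 8.98 mg/L.
#'
#' @param duration record length (s); default 330 days.
#' @param cadence sampling interval (s); default 600 (10-min means).
#' @param heights heights above seabed (m); default 2-m bins from 1.24 m
#'   (the first ADCP bin) to 2 m below the surface.
#' @param water_depth water depth (m); default 30.
#' @param u_surface,u_seabed long-run mean current speed (m/s) at the
#'   surface and seabed; the shear profile interpolates linearly between
#'   them.
#' @param constituents data.frame with `period_s` and `amplitude`
#'   columns; the default M2 + S2 pair (relative amplitudes 1 and 0.3)
#'   produces the half-monthly spring-neap beat (~14.77 d).
#' @param noise_sd standard deviation of the multiplicative Gaussian
#'   sample noise (dimensionless); default 0.15, which places per-height
#'   maxima of the default run near the observed 0.35-0.69 m/s band.
#' @param intensity bulk turbulence intensity (default 0.8).
#' @param wave list `(H, T)`: the storm sea state (m, s).
#' @param do_cycle list `(min, max, min_day, noise_sd)`: annual DO cycle
#'   (mg/L); minimum on day-of-year `min_day` (default late August).
#' @param seed default integer seed for reproducibility.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration = 330 * 86400, cadence = 600,
                           heights = NULL, water_depth = 30,
                           u_surface = 0.24, u_seabed = 0.11,
                           constituents = data.frame(
                             period_s = c(12.42, 12.00) * 3600,
                             amplitude = c(1, 0.3)),
                           noise_sd = 0.15, intensity = 0.8,
                           wave = list(H = 3.99, T = 7.4),
                           do_cycle = list(min = 8.98, max = 10.5,
                                           min_day = 240, noise_sd = 0.1),
                           seed = 42L) {
  if (is.null(heights))
    heights <- seq(1.24, water_depth - 2, by = 2)
  if (duration <= 0 || cadence <= 0)
    stop("synthetic_spec: duration and cadence must be > 0")
  if (any(constituents$amplitude < 0))
    stop("synthetic_spec: constituent amplitudes must be >= 0")
  if (intensity < 0) stop("synthetic_spec: intensity must be >= 0")
  if (do_cycle$min > do_cycle$max)
    stop("synthetic_spec: do_cycle min must not exceed max")
  structure(list(duration = duration, cadence = cadence, heights = heights,
                 water_depth = water_depth, u_surface = u_surface,
                 u_seabed = u_seabed, constituents = constituents,
                 noise_sd = noise_sd, intensity = intensity, wave = wave,
                 do_cycle = do_cycle, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Linear shear profile of long-run mean current speed
#' @param spec a [synthetic_spec()].
#' @return mean speed (m/s) at each `spec$heights`.
#' @export
shear_profile <- function(spec) {
  frac <- spec$heights / spec$water_depth
  spec$u_seabed + (spec$u_surface - spec$u_seabed) * frac
}

#' Generate a synthetic external current-velocity field
#'
#' Produces an external [velocity_field()] with
#' `speed(t, h) = shear(h) * |m(t)| / mean|m| * max(0, 1 + noise)`,
#' where `m(t)` is the sum of the tidal constituents (semidiurnal
#' oscillation whose amplitude beats on the spring-neap cycle) and the
#' noise is iid Gaussian with sd `spec$noise_sd`. Rectified tidal
#' modulation is normalised by its realised mean so the long-run mean at
#' each height equals the configured shear profile.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @param t0 start time (POSIXct UTC).
#' @return an external [velocity_field()].
#' @export
#' @examples
#' f <- gen_current_field(synthetic_spec(duration = 2 * 86400))
#' f
gen_current_field <- function(spec, seed = spec$seed,
                              t0 = as.POSIXct("2010-09-16 00:00:00",
                                              tz = "UTC")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$cadence > min(spec$constituents$period_s) / 4)
    stop("gen_current_field: cadence ", spec$cadence,
         " s is too coarse for the fastest constituent (aliasing); ",
         "need cadence <= period/4")
  set.seed(seed)
  t <- seq(0, spec$duration - spec$cadence, by = spec$cadence)
  m <- rep(0, length(t))
  for (i in seq_len(nrow(spec$constituents)))
    m <- m + spec$constituents$amplitude[i] *
      cos(2 * pi * t / spec$constituents$period_s[i])
  m <- abs(m)
  mod <- if (mean(m) > 0) m / mean(m) else m + 1  # zero-amplitude tide
  shear <- shear_profile(spec)
  noise <- if (spec$noise_sd > 0) {
    matrix(pmax(0, 1 + stats::rnorm(length(t) * length(shear),
                                    sd = spec$noise_sd)),
           length(t), length(shear))
  } else {
    matrix(1, length(t), length(shear))
  }
  speed <- (mod %o% shear) * noise
  velocity_field(t0 + t, spec$heights, speed, cadence = spec$cadence,
                 provenance = "external",
                 water_depth_ref = spec$water_depth)
}

#' Generate an instantaneous turbulent velocity series
#'
#' Superimposes Gaussian fluctuations on a mean-velocity series so that
#' the fluctuation RMS equals `intensity` times the local mean:
#' `u(t) = u_bar(t) + N(0, intensity * u_bar(t))`. Feeding the result to
#' [turbulence_summary()] recovers the configured intensity to within
#' sampling error. Negative instantaneous excursions are kept (they
#' represent reversals relative to the mean; callers needing speeds
#' should take magnitudes).
#'
#' @param mean_series mean velocity per sample (m/s), >= 0.
#' @param intensity turbulence intensity, >= 0.
#' @param seed optional integer seed.
#' @return instantaneous velocity series, same length as `mean_series`.
#' @export
gen_turbulent_series <- function(mean_series, intensity, seed = NULL) {
  if (!is.finite(intensity) || intensity < 0)
    stop("gen_turbulent_series: intensity must be >= 0")
  if (any(mean_series < 0, na.rm = TRUE))
    stop("gen_turbulent_series: mean_series must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (intensity == 0) return(mean_series)
  mean_series + stats::rnorm(length(mean_series),
                             sd = intensity * mean_series)
}

#' Generate a synthetic seasonal dissolved-oxygen series
#'
#' Daily samples over one year following a sinusoidal annual cycle with
#' the configured minimum and maximum concentrations, the minimum falling
#' on `do_cycle$min_day`, plus optional Gaussian noise (clamped positive).
#' With zero noise the sampled minimum equals the configured minimum
#' exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @param year calendar year of the record.
#' @return a `do_series` data.frame (see [read_do_series()]).
#' @export
gen_do_series <- function(spec, seed = spec$seed, year = 2010) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cyc <- spec$do_cycle
  set.seed(seed)
  day <- 0:364
  mid <- (cyc$min + cyc$max) / 2
  amp <- (cyc$max - cyc$min) / 2
  conc <- mid - amp * cos(2 * pi * (day - cyc$min_day) / 365)
  if (!is.null(cyc$noise_sd) && cyc$noise_sd > 0)
    conc <- pmax(conc + stats::rnorm(length(conc), sd = cyc$noise_sd),
                 0.01)
  out <- data.frame(
    time = as.POSIXct(paste0(year, "-01-01"), tz = "UTC") + day * 86400,
    concentration = conc)
  class(out) <- c("do_series", "data.frame")
  out
}
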