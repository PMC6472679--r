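# small in-code fixtures shared across test files

make_field <- function(nt = 6, heights = c(1.24, 10, 20), speed = 0.2,
                       provenance = "external", cadence = 600,
                       water_depth_ref = 22) {
  tm <- as.POSIXct("2013-03-10 19:36:00", tz = "UTC") + cadence * (0:(nt - 1))
  sp <- if (is.matrix(speed)) speed else
    matrix(speed, nt, length(heights))
  velocity_field(tm, heights, sp, cadence = cadence,
                 provenance = provenance, water_depth_ref = water_depth_ref)
}

# independent bisection solver for the dispersion relation, used as an
# oracle against the package's damped fixed-point iteration
bisect_dispersion <- function(H, T, g = 9.81, tol = 1e-6) {
  L0 <- g * T^2 / (2 * pi)
  f <- function(lam) lam - L0 * tanh(2 * pi * H / lam)
  lo <- 1e-6 * L0
  hi <- 2 * L0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# brute-force longest-run oracle: checks every contiguous index window
brute_longest_run <- function(hit, cadence) {
  n <- length(hit)
  best <- 0
  for (i in seq_len(n)) for (j in i:n) {
    if (all(hit[i:j])) best <- max(best, j - i + 1)
  }
  best * cadence / 3600
}
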