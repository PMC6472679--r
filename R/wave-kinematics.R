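#' Solve the wave dispersion relation for wavelength
#'
#' Iteratively solves for the wavelength lambda of a sea state by damped
#' fixed-point iteration seeded at the deep-water wavelength
#' `gT^2/(2*pi)`.
#'
#' Two forms of the relation are available. `formula = "printed"`
#' (the default) solves
#' \deqn{\lambda = \frac{gT^2}{2\pi}\tanh\frac{2\pi H}{\lambda},}
#' with the wave height `H` inside the hyperbolic tangent; for the
#' Falmouth-bay maximum-annual storm (H = 3.99 m, T = 7.4 s) this yields
#' lambda = 44.0 m. `formula = "standard"` is the classical linear-theory
#' relation with the water depth `d` inside the tanh,
#' \eqn{\lambda = (gT^2/2\pi)\tanh(2\pi d/\lambda)}.
#'
#' @param H wave height (m), > 0. Used inside tanh by the `"printed"` form.
#' @param T wave period (s), > 0.
#' @param g gravitational acceleration (m/s^2), default 9.81.
#' @param tol convergence tolerance on lambda (m), default 1e-4.
#' @param max_iter maximum iterations, default 200.
#' @param formula `"printed"` (H inside tanh) or `"standard"` (d inside
#'   tanh).
#' @param d water depth (m); required when `formula = "standard"`.
#' @return wavelength lambda (m) with attributes `iterations` and
#'   `converged` (always `TRUE`; non-convergence is an error carrying the
#'   last iterate in its message).
#' @export
#' @examples
#' solve_dispersion(H = 3.99, T = 7.4)              # ~44.0 m
#' solve_dispersion(H = 3.99, T = 7.4, formula = "standard", d = 30)
solve_dispersion <- function(H, T, g = 9.81, tol = 1e-4, max_iter = 200,
                             formula = c("printed", "standard"), d = NULL) {
  formula <- match.arg(formula)
  if (!is.finite(H) || H <= 0) stop("solve_dispersion: H must be > 0")
  if (!is.finite(T) || T <= 0) stop("solve_dispersion: T must be > 0")
  if (formula == "standard") {
    if (is.null(d) || !is.finite(d) || d <= 0)
      stop("solve_dispersion: standard form needs water depth d > 0")
    inner <- d
  } else {
    inner <- H
  }
  L0 <- g * T^2 / (2 * pi)
  f <- function(lam) L0 * tanh(2 * pi * inner / lam)
  lam <- L0
  for (it in seq_len(max_iter)) {
    lam_new <- 0.5 * (lam + f(lam))     # damping factor 1/2
    if (abs(lam_new - lam) < tol) {
      return(structure(lam_new, iterations = it, converged = TRUE))
    }
    lam <- lam_new
  }
  stop("solve_dispersion: no convergence after ", max_iter,
       " iterations; last iterate lambda = ", format(lam), " m")
}

#' Classify water-depth regime of a sea state
#'
#' Deep-water waves occur when the water depth exceeds half the
#' wavelength (strict inequality: the boundary `d == lambda/2` is
#' classified `not_deep`).
#'
#' @param d water depth (m), > 0.
#' @param lambda wavelength (m), > 0.
#' @return `"deep"` or `"not_deep"`.
#' @export
classify_regime <- function(d, lambda) {
  if (!is.finite(d) || d <= 0) stop("classify_regime: d must be > 0")
  if (!is.finite(lambda) || lambda <= 0)
    stop("classify_regime: lambda must be > 0")
  if (d > lambda / 2) "deep" else "not_deep"
}

#' Construct a wave state
#'
#' Bundles a sea state (H, T, water depth) with its solved wavelength,
#' wave number `k = 2*pi/lambda` and depth-regime classification.
#'
#' @inheritParams solve_dispersion
#' @param d water depth (m), > 0.
#' @return list of class `wave_state` with fields `H`, `T`, `d`, `g`,
#'   `lambda`, `k`, `regime`.
#' @export
#' @examples
#' ws <- wave_state(H = 3.99, T = 7.4, d = 30)
#' ws$lambda   # 44.0 m
#' ws$regime   # "deep"
wave_state <- function(H, T, d, g = 9.81, tol = 1e-4, max_iter = 200,
                       formula = c("printed", "standard")) {
  formula <- match.arg(formula)
  if (!is.finite(d) || d <= 0) stop("wave_state: d must be > 0")
  lambda <- as.numeric(solve_dispersion(H, T, g = g, tol = tol,
                                        max_iter = max_iter,
                                        formula = formula, d = d))
  structure(list(H = H, T = T, d = d, g = g,
                 lambda = lambda, k = 2 * pi / lambda,
                 regime = classify_regime(d, lambda)),
            class = "wave_state")
}

#' @export
print.wave_state <- function(x, ...) {
  cat("<wave_state> H = ", x$H, " m, T = ", x$T, " s, d = ", x$d, " m\n",
      "  lambda = ", signif(x$lambda, 4), " m, k = ", signif(x$k, 4),
      " 1/m, regime = ", x$regime, "\n", sep = "")
  invisible(x)
}

#' Deep-water orbital velocity at a point
#'
#' Linear deep-water waves produce circular orbital motion with equal
#' horizontal and vertical velocity amplitudes:
#' \deqn{u = \frac{\pi H}{T} e^{kz}\cos\theta,\qquad
#'       w = \frac{\pi H}{T} e^{kz}\sin\theta,}
#' where `z <= 0` is the position below the still-water surface and
#' `theta` the wave phase. The magnitude `(pi*H/T)*exp(k*z)` is
#' phase-invariant and decays exponentially with depth.
#'
#' @param state a [wave_state()]; must be in the `deep` regime
#'   (shallow/intermediate elliptic kinematics are out of scope).
#' @param z vertical position (m) measured from the surface, `z <= 0`.
#' @param theta wave phase in degrees (default 0, the amplitude envelope).
#' @return named numeric `c(u = , w = )` in m/s.
#' @export
#' @examples
#' ws <- wave_state(3.99, 7.4, d = 30)
#' orbital_velocity(ws, z = 0)          # surface: u = pi*H/T ~ 1.69 m/s
orbital_velocity <- function(state, z, theta = 0) {
  stopifnot(inherits(state, "wave_state"))
  if (state$regime != "deep")
    stop("orbital_velocity: sea state is not deep water (d <= lambda/2); ",
         "shallow-water kinematics not implemented")
  if (any(z > 0)) stop("orbital_velocity: z must be <= 0 (below surface)")
  amp <- (pi * state$H / state$T) * exp(state$k * z)
  th <- theta * pi / 180
  c(u = amp * cos(th), w = amp * sin(th))
}

#' Wave orbital-velocity amplitude profile through the water column
#'
#' Evaluates the deep-water orbital amplitude `(pi*H/T)*exp(k*z)` at a set
#' of heights above the seabed, converting each to the depth coordinate
#' via [height_to_z()]. The amplitude is monotonically non-decreasing with
#' height above the seabed and equals `pi*H/T` at the surface.
#'
#' @param state a [wave_state()] in the `deep` regime.
#' @param heights heights above seabed (m), each within
#'   `[0, water_depth]`.
#' @param water_depth water depth (m); defaults to `state$d`.
#' @return numeric vector of orbital amplitudes (m/s), one per height.
#' @export
orbital_amplitude_profile <- function(state, heights, water_depth = state$d) {
  stopifnot(inherits(state, "wave_state"))
  if (state$regime != "deep")
    stop("orbital_amplitude_profile: sea state is not deep water")
  if (any(heights > water_depth))
    stop("orbital_amplitude_profile: height above the water surface")
  z <- height_to_z(heights, water_depth)
  (pi * state$H / state$T) * exp(state$k * z)
}
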