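#' Transfer-function coefficients for an SBCC design
#'
#' Linear external-to-internal flow transfer coefficients for a Sea Based
#' Container Culture container, as fitted in flume experiments for one
#' container design and angle of attack. The defaults are for "SBCC 1"
#' at a 90 degree angle of attack:
#'
#' * `m_cur = 0.2411` — internal mean-current velocity is ~24% of the
#'   external velocity;
#' * `m_turb = 0.8855` — internal turbulent fluctuation is ~89% of the
#'   external fluctuation;
#' * `n_cur = -0.4762` — biofouling coverage reduces internal current
#'   (e.g. 66% coverage: -31%);
#' * `n_turb = 0.1243` — biofouling coverage increases internal
#'   turbulence (33%/66% coverage: +4%/+8%);
#' * `I = 0.8` — bulk turbulence intensity, the depth-averaged maximum
#'   observed at the case-study sites;
#' * `c = 0` — the regressions were forced through the origin.
#'
#' Override any coefficient to represent a different container design.
#'
#' @param m_cur,m_turb velocity-magnitude transfer slopes (dimensionless).
#' @param n_cur,n_turb biofouling-coverage slopes (dimensionless, per unit
#'   coverage fraction).
#' @param I bulk turbulence intensity (dimensionless).
#' @param c intercept, fixed at 0.
#' @return list of class `transfer_coefficients`.
#' @export
#' @examples
#' transfer_coefficients()
transfer_coefficients <- function(m_cur = 0.2411, m_turb = 0.8855,
                                  n_cur = -0.4762, n_turb = 0.1243,
                                  I = 0.8, c = 0) {
  x <- list(m_cur = m_cur, m_turb = m_turb, n_cur = n_cur, n_turb = n_turb,
            I = I, c = c)
  if (any(!vapply(x, is.finite, logical(1))))
    stop("transfer_coefficients: all coefficients must be finite")
  if (I < 0) stop("transfer_coefficients: I must be >= 0")
  structure(x, class = "transfer_coefficients")
}

#' @export
print.transfer_coefficients <- function(x, ...) {
  cat("<transfer_coefficients>\n")
  cat(sprintf("  m_cur = %g  n_cur = %g\n", x$m_cur, x$n_cur))
  cat(sprintf("  m_turb = %g  n_turb = %g\n", x$m_turb, x$n_turb))
  cat(sprintf("  I = %g  c = %g\n", x$I, x$c))
  invisible(x)
}

#' Biofouling effect on internal flow
#'
#' Linear biofouling transfer `b = n * coverage` (intercept zero): the
#' fractional change of an internal flow quantity caused by biofouling
#' occluding a fraction of the container mesh. With the default
#' coefficients, coverage reduces mean internal current (`n_cur < 0`) and
#' increases internal turbulent fluctuations (`n_turb > 0`); at 33% and
#' 66% coverage the turbulence increase rounds to +4% and +8%.
#'
#' @param coverage biofouling coverage as a fraction in `[0, 1]`.
#' @param n transfer coefficient (e.g. `n_cur` or `n_turb` from
#'   [transfer_coefficients()]).
#' @return fractional change `b` (same sign as `n`).
#' @export
#' @examples
#' biofouling_effect(0.33, 0.1243)    # +0.041: ~+4% turbulence
#' biofouling_effect(0.66, -0.4762)   # -0.314: ~-31% current
biofouling_effect <- function(coverage, n) {
  if (any(!is.finite(coverage)) || any(coverage < 0) || any(coverage > 1))
    stop("biofouling_effect: coverage must be a fraction in [0, 1]")
  n * coverage
}

#' Predict internal velocity from external velocity
#'
#' The peak instantaneous internal velocity of an SBCC container under
#' external flow `u_ex`:
#' \deqn{u_{in} = u_{ex}\, m_{cur}(1 + b_{cur}) +
#'       u_{ex}\, I\, m_{turb}(1 + b_{turb}),}
#' where `b_cur = n_cur * coverage` and `b_turb = n_turb * coverage` are
#' the biofouling modifiers. The first term is the transferred mean
#' current; the second (included when `include_turbulence = TRUE`) is the
#' transferred turbulent fluctuation, with external fluctuation magnitude
#' taken as `I * u_ex`.
#'
#' @param u_ex external flow speed (m/s), >= 0; vectorised, `NA`
#'   propagates.
#' @param coeffs a [transfer_coefficients()].
#' @param coverage biofouling coverage fraction in `[0, 1]` (default 0,
#'   clean container).
#' @param include_turbulence add the turbulent-fluctuation term?
#' @return internal velocity `u_in` (m/s), same length as `u_ex`.
#' @export
#' @examples
#' internal_velocity(1)                              # 0.2411: ~24%
#' internal_velocity(1, include_turbulence = TRUE)   # + 0.8*0.8855
internal_velocity <- function(u_ex, coeffs = transfer_coefficients(),
                              coverage = 0, include_turbulence = FALSE) {
  stopifnot(inherits(coeffs, "transfer_coefficients"))
  if (any(u_ex < 0, na.rm = TRUE))
    stop("internal_velocity: u_ex must be >= 0")
  b_cur <- biofouling_effect(coverage, coeffs$n_cur)
  if (1 + b_cur < 0)
    stop("internal_velocity: coverage ", coverage, " drives the current ",
         "factor (1 + b_cur) negative - outside the linear model validity")
  u_in <- u_ex * coeffs$m_cur * (1 + b_cur) + coeffs$c
  if (include_turbulence) {
    b_turb <- biofouling_effect(coverage, coeffs$n_turb)
    u_in <- u_in + u_ex * coeffs$I * coeffs$m_turb * (1 + b_turb)
  }
  u_in
}

#' Apply the velocity transfer function to a whole field
#'
#' Element-wise [internal_velocity()] over an external
#' [velocity_field()], producing the predicted internal field. Missing
#' marks propagate. Applying the transfer to an already-internal field is
#' an error (double transfer).
#'
#' @param field an external [velocity_field()].
#' @inheritParams internal_velocity
#' @return a [velocity_field()] with `provenance = "internal"`.
#' @export
apply_transfer <- function(field, coeffs = transfer_coefficients(),
                           coverage = 0, include_turbulence = FALSE) {
  validate_velocity_field(field)
  if (field$provenance != "external")
    stop("apply_transfer: field is already internal (double transfer)")
  out <- field
  out$speed[] <- internal_velocity(field$speed, coeffs = coeffs,
                                   coverage = coverage,
                                   include_turbulence = include_turbulence)
  out$provenance <- "internal"
  validate_velocity_field(out)
  out
}
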