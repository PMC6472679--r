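#' Time constant of available dissolved oxygen in a container
#'
#' With no through-flow, a lobster consuming oxygen at rate `C` draws the
#' container's DO concentration down from the ambient seawater value to
#' the lowest acceptable concentration in
#' \deqn{t = \frac{V\,(DO_{sea} - DO_{lobster})}{C}.}
#' Units are enforced at the boundary (concentrations mg/L, volume L,
#' rate mg/s) so `t` emerges in seconds with no hidden conversion.
#'
#' @param V container volume (L), > 0.
#' @param DO_sea ambient seawater DO concentration (mg/L).
#' @param DO_lobster lowest acceptable DO concentration (mg/L), must be
#'   below `DO_sea`.
#' @param C oxygen consumption rate of the stocked lobster (mg/s), > 0.
#' @return time constant t (s).
#' @export
#' @examples
#' do_time_constant(V = 1.109, DO_sea = 8.98, DO_lobster = 6.4, C = 5e-5)
#' # ~57200 s ~ 15.9 h
do_time_constant <- function(V, DO_sea, DO_lobster, C) {
  if (!is.finite(V) || V <= 0) stop("do_time_constant: V must be > 0")
  if (!is.finite(C) || C <= 0) stop("do_time_constant: C must be > 0")
  if (!is.finite(DO_lobster) || DO_lobster <= 0)
    stop("do_time_constant: DO_lobster must be > 0")
  if (!is.finite(DO_sea) || DO_sea <= DO_lobster)
    stop("do_time_constant: DO_sea must exceed DO_lobster ",
         "(no oxygen headroom)")
  V * (DO_sea - DO_lobster) / C
}

#' Dissolved-oxygen velocity limit
#'
#' The minimum through-flow speed that replenishes a moored array of
#' containers before the oxygen headroom is consumed: `u_DO = L / t`,
#' where `L` is the along-flow length of the container array and `t` the
#' DO time constant from [do_time_constant()].
#'
#' @param L_array array length (m), > 0.
#' @param t DO time constant (s), > 0.
#' @return velocity limit u_DO (m/s).
#' @export
#' @examples
#' do_velocity_limit(97.6, 15.9 * 3600) * 1000   # ~1.70 mm/s
do_velocity_limit <- function(L_array, t) {
  if (!is.finite(L_array) || L_array <= 0)
    stop("do_velocity_limit: L_array must be > 0")
  if (!is.finite(t) || t <= 0) stop("do_velocity_limit: t must be > 0")
  L_array / t
}

#' Dissolved-oxygen budget for an SBCC array
#'
#' Bundles the supply/consumption budget parameters with the derived time
#' constant and velocity limit. Defaults are the Falmouth-bay case study:
#' annual-minimum seawater DO 8.98 mg/L, optimal-growth threshold
#' 6.4 mg/L, maximum consumption rate 5e-5 mg/s for a 150 g lobster, and
#' a 97.6 m container array. The default container volume of 1.109 L is
#' back-derived from the case study's 15.9 h time constant (the volume
#' itself is not an authoritative measured value); always set `V` for a
#' real container.
#'
#' @param DO_sea ambient seawater DO concentration (mg/L).
#' @param DO_lobster lowest acceptable DO concentration for optimal
#'   growth (mg/L).
#' @param C oxygen consumption rate (mg/s).
#' @param V container volume (L).
#' @param L_array array length (m).
#' @return list of class `do_budget` with the inputs plus derived
#'   `t` (s) and `u_DO` (m/s).
#' @export
#' @examples
#' b <- do_budget()
#' b$u_DO * 1000   # mm/s
do_budget <- function(DO_sea = 8.98, DO_lobster = 6.4, C = 5e-5,
                      V = 1.109, L_array = 97.6) {
  t <- do_time_constant(V = V, DO_sea = DO_sea, DO_lobster = DO_lobster,
                        C = C)
  structure(list(DO_sea = DO_sea, DO_lobster = DO_lobster, C = C, V = V,
                 L_array = L_array, t = t,
                 u_DO = do_velocity_limit(L_array, t)),
            class = "do_budget")
}

#' @export
print.do_budget <- function(x, ...) {
  cat("<do_budget>\n")
  cat(sprintf("  DO_sea = %g mg/L, DO_lobster = %g mg/L, C = %g mg/s\n",
              x$DO_sea, x$DO_lobster, x$C))
  cat(sprintf("  V = %g L, L_array = %g m\n", x$V, x$L_array))
  cat(sprintf("  t = %.3g h, u_DO = %.3g mm/s\n", x$t / 3600,
              x$u_DO * 1000))
  invisible(x)
}
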