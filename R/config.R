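#' Default run configuration (Falmouth-bay case study)
#'
#' The configuration consumed by [run_framework()]: where the External
#' Velocity Profile comes from (a CSV path or a synthetic-generator
#' spec), the transfer coefficients, the DO budget, the rearing limits
#' and the biofouling-coverage scenario grid. All defaults are the
#' Falmouth-bay case-study values.
#'
#' @param duration_days length of the synthetic record (days).
#' @param coverage biofouling-coverage scenario grid (fractions).
#' @param seed integer seed.
#' @return a nested configuration list.
#' @export
default_config <- function(duration_days = 330,
                           coverage = c(0, 0.33, 0.66), seed = 42L) {
  list(
    evp = list(path = NULL,
               synthetic = list(duration = duration_days * 86400)),
    coefficients = list(),
    do_budget = list(),
    limits = list(u_forage = 0.1, u_mobility = 0.27,
                  DO_survival = 4.5, DO_optimal = 6.4),
    scenarios = list(coverage = coverage,
                     mobility_with_turbulence = TRUE),
    output = list(dir = NULL),
    seed = as.integer(seed))
}

config_schema <- list(
  evp = c("path", "synthetic"),
  coefficients = c("m_cur", "m_turb", "n_cur", "n_turb", "I", "c"),
  do_budget = c("DO_sea", "DO_lobster", "C", "V", "L_array"),
  limits = c("u_forage", "u_mobility", "DO_survival", "DO_optimal"),
  scenarios = c("coverage", "mobility_with_turbulence"),
  output = c("dir"),
  seed = NULL)

#' Coverage values to fractions
#'
#' Configuration and command line accept biofouling coverage either as a
#' fraction in `[0, 1]` or as a percentage (a number greater than 1, or a
#' string with a `%` suffix); internally coverage is always a fraction.
#'
#' @param x numeric or character coverage values.
#' @return numeric fractions in `[0, 1]`.
#' @export
#' @examples
#' as_coverage(c("33%", "0.5", "66"))
as_coverage <- function(x) {
  if (is.character(x)) x <- as.numeric(sub("%$", "", trimws(x)))
  out <- ifelse(x > 1, x / 100, x)
  if (any(!is.finite(out)) || any(out < 0) || any(out > 1))
    stop("as_coverage: coverage must be in [0, 1] (or 0-100%)")
  out
}

#' Parse and validate a YAML run configuration
#'
#' Reads a YAML file, rejects unknown keys (naming the offender), fills
#' unspecified values with the Falmouth-bay defaults of
#' [default_config()], and normalises coverage values to fractions. An
#' empty file yields the all-defaults configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
parse_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  bad <- setdiff(names(user), names(config_schema))
  if (length(bad) > 0)
    stop("parse_config: unknown configuration key '", bad[1], "'")
  for (sec in names(user)) {
    if (sec == "seed") { cfg$seed <- as.integer(user$seed); next }
    sub_bad <- setdiff(names(user[[sec]]), config_schema[[sec]])
    if (length(sub_bad) > 0)
      stop("parse_config: unknown configuration key '", sec, ".",
           sub_bad[1], "'")
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  if (!is.null(cfg$scenarios$coverage))
    cfg$scenarios$coverage <- as_coverage(unlist(cfg$scenarios$coverage))
  cfg
}

#' Write a configuration list to YAML
#' @param config configuration list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
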