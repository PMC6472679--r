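#' Rearing flow-velocity and DO limits for European lobster
#'
#' Behavioural and oxygen-supply thresholds against which predicted
#' internal conditions are scored:
#'
#' * `u_forage` (default 0.1 m/s): foraging activity increases below this
#'   flow speed;
#' * `u_mobility` (default 0.27 m/s): mobility and olfactory sensing are
#'   severely impaired above this speed;
#' * `u_DO`: minimum through-flow keeping container DO above the
#'   optimal-growth concentration (from [do_budget()]);
#' * `DO_survival` (4.5 mg/L) and `DO_optimal` (6.4 mg/L): concentration
#'   thresholds for survival and optimal growth.
#'
#' @param u_forage foraging velocity limit (m/s).
#' @param u_mobility mobility velocity limit (m/s); must exceed
#'   `u_forage`.
#' @param u_DO DO velocity limit (m/s).
#' @param DO_survival,DO_optimal DO concentration limits (mg/L).
#' @return list of class `rearing_limits`.
#' @export
rearing_limits <- function(u_forage = 0.1, u_mobility = 0.27,
                           u_DO = do_budget()$u_DO,
                           DO_survival = 4.5, DO_optimal = 6.4) {
  vals <- c(u_forage, u_mobility, u_DO, DO_survival, DO_optimal)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("rearing_limits: all limits must be positive and finite")
  if (u_forage >= u_mobility)
    stop("rearing_limits: u_forage must be below u_mobility")
  structure(list(u_forage = u_forage, u_mobility = u_mobility, u_DO = u_DO,
                 DO_survival = DO_survival, DO_optimal = DO_optimal),
            class = "rearing_limits")
}

#' Percentage of time a series satisfies a limit condition
#'
#' The fraction of valid (non-missing) samples strictly above or strictly
#' below a limit, as a percentage. Ties at the limit count as
#' non-exceeding under either condition. Invariant to sample order.
#'
#' @param series flow speeds (m/s); `NA` marks missing samples, which are
#'   excluded from the denominator.
#' @param limit threshold (m/s).
#' @param condition `"above"` or `"below"` (strict inequality).
#' @return percentage in `[0, 100]`.
#' @export
#' @examples
#' percent_time(c(0.05, 0.2, 0.05, 0.3), 0.1, "below")  # 50
percent_time <- function(series, limit, condition = c("above", "below")) {
  condition <- match.arg(condition)
  ok <- !is.na(series)
  if (!any(ok)) stop("percent_time: all samples missing")
  hit <- if (condition == "above") series[ok] > limit else series[ok] < limit
  100 * sum(hit) / sum(ok)
}

#' Longest continuous period a series satisfies a limit condition
#'
#' The longest run of consecutive samples strictly above/below the limit,
#' expressed as a duration in hours (run length times the nominal
#' cadence). A missing sample terminates a run; if `times` are supplied,
#' a gap between consecutive samples exceeding `gap_factor * cadence`
#' also terminates the run (instrument deployment gaps must not be
#' counted as continuous exposure).
#'
#' @inheritParams percent_time
#' @param cadence nominal sampling interval (s).
#' @param times optional POSIXct sample times, used for gap detection.
#' @param gap_factor runs break across time gaps longer than
#'   `gap_factor * cadence` (default 1.5).
#' @return duration in hours; 0 if no sample satisfies the condition.
#' @export
#' @examples
#' longest_run(c(0.05, 0.05, 0.2, 0.05, 0.05, 0.05), 0.1, "below",
#'             cadence = 600)   # 3 samples * 600 s = 0.5 h
longest_run <- function(series, limit, condition = c("above", "below"),
                        cadence, times = NULL, gap_factor = 1.5) {
  condition <- match.arg(condition)
  if (missing(cadence) || !is.finite(cadence) || cadence <= 0)
    stop("longest_run: a positive nominal cadence (s) is required")
  hit <- if (condition == "above") series > limit else series < limit
  hit[is.na(hit)] <- FALSE
  if (!is.null(times)) {
    if (length(times) != length(series))
      stop("longest_run: times and series lengths differ")
    gap_after <- c(diff(as.numeric(times)) > gap_factor * cadence, FALSE)
  } else {
    gap_after <- rep(FALSE, length(series))
  }
  best <- 0L; run <- 0L
  for (i in seq_along(hit)) {
    run <- if (hit[i]) run + 1L else 0L
    if (run > best) best <- run
    if (gap_after[i]) run <- 0L
  }
  best * cadence / 3600
}

#' Depth-resolved exceedance report for an internal velocity field
#'
#' Scores each height bin of a predicted internal field against one limit
#' condition, reporting the percentage of valid time and the longest
#' continuous period satisfying it.
#'
#' @param internal an internal [velocity_field()].
#' @param limit threshold (m/s).
#' @param condition `"above"` or `"below"`.
#' @param limit_name label for the report rows.
#' @param gap_factor passed to [longest_run()].
#' @return data.frame with one row per height: `height`, `condition`,
#'   `limit`, `percent_time`, `longest_run_h`, `n_valid`, `n_missing`.
#' @export
evaluate_field <- function(internal, limit, condition = c("above", "below"),
                           limit_name = deparse(substitute(limit)),
                           gap_factor = 1.5) {
  condition <- match.arg(condition)
  validate_velocity_field(internal)
  if (internal$provenance != "internal")
    stop("evaluate_field: expected an internal (post-transfer) field")
  nh <- length(internal$heights)
  out <- data.frame(
    height = internal$heights,
    condition = paste(condition, limit_name),
    limit = limit,
    percent_time = NA_real_, longest_run_h = NA_real_,
    n_valid = NA_integer_, n_missing = NA_integer_)
  for (j in seq_len(nh)) {
    s <- internal$speed[, j]
    out$percent_time[j] <- percent_time(s, limit, condition)
    out$longest_run_h[j] <- longest_run(s, limit, condition,
                                        cadence = internal$cadence,
                                        times = internal$times,
                                        gap_factor = gap_factor)
    out$n_valid[j] <- sum(!is.na(s))
    out$n_missing[j] <- sum(is.na(s))
  }
  out
}

#' Run the full SBCC rearing-success evaluation framework
#'
#' Orchestrates the pipeline: obtain an External Velocity Profile (from a
#' file or the synthetic generator), derive the DO velocity limit from
#' the oxygen budget, transfer the EVP to Internal Velocity Profiles for
#' each biofouling-coverage scenario, and score the internal fields
#' against the rearing limits with depth-resolved exceedance statistics.
#'
#' Per scenario the report contains, for every height bin:
#' * percent/longest-run **below `u_DO`** using the current-only IVP
#'   (oxygen supply is driven by the mean flow);
#' * percent/longest-run **above `u_forage`** using the current-only IVP;
#' * percent/longest-run **above `u_mobility`** using the current-only
#'   IVP and, separately, the current-plus-turbulence IVP.
#'
#' @param config a configuration list from [parse_config()] /
#'   [default_config()], or a path to a YAML configuration file.
#' @param seed integer seed for the synthetic generator; overrides
#'   `config$seed` when given.
#' @return list of class `sbcc_report`: `report` (data.frame of
#'   statistics with columns `coverage`, `turbulence`, plus the
#'   [evaluate_field()] columns), `limits`, `budget`, `coefficients`,
#'   `evp`, `config`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_framework(default_config(duration_days = 15), seed = 1)
#' head(rep$report)
#' }
run_framework <- function(config = default_config(), seed = NULL) {
  if (is.character(config)) config <- parse_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)

  evp <- if (!is.null(config$evp$path)) {
    read_velocity_field(config$evp$path)
  } else {
    gen_current_field(do.call(synthetic_spec, config$evp$synthetic),
                      seed = config$seed)
  }
  if (evp$provenance != "external")
    stop("run_framework [evp]: input field must be external")

  coeffs <- do.call(transfer_coefficients, config$coefficients)
  budget <- do.call(do_budget, config$do_budget)
  limits <- rearing_limits(u_forage = config$limits$u_forage,
                           u_mobility = config$limits$u_mobility,
                           u_DO = budget$u_DO,
                           DO_survival = config$limits$DO_survival,
                           DO_optimal = config$limits$DO_optimal)

  rows <- list()
  for (cov in config$scenarios$coverage) {
    ivp_cur <- apply_transfer(evp, coeffs, coverage = cov,
                              include_turbulence = FALSE)
    ivp_turb <- apply_transfer(evp, coeffs, coverage = cov,
                               include_turbulence = TRUE)
    blocks <- list(
      cbind(turbulence = FALSE,
            evaluate_field(ivp_cur, limits$u_DO, "below", "u_DO")),
      cbind(turbulence = FALSE,
            evaluate_field(ivp_cur, limits$u_forage, "above", "u_forage")),
      cbind(turbulence = FALSE,
            evaluate_field(ivp_cur, limits$u_mobility, "above",
                           "u_mobility")))
    if (isTRUE(config$scenarios$mobility_with_turbulence))
      blocks <- c(blocks, list(
        cbind(turbulence = TRUE,
              evaluate_field(ivp_turb, limits$u_mobility, "above",
                             "u_mobility"))))
    rows[[length(rows) + 1]] <- cbind(coverage = cov, do.call(rbind, blocks))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, limits = limits, budget = budget,
                 coefficients = coeffs, evp = evp, config = config),
            class = "sbcc_report")
}

#' @export
print.sbcc_report <- function(x, ...) {
  cat("<sbcc_report>\n")
  cat("  EVP: ", length(x$evp$times), " times x ", length(x$evp$heights),
      " heights (", x$evp$provenance, ")\n", sep = "")
  cat(sprintf("  u_DO = %.3g mm/s, u_forage = %g m/s, u_mobility = %g m/s\n",
              x$limits$u_DO * 1000, x$limits$u_forage, x$limits$u_mobility))
  cat("  scenarios: coverage ",
      paste(unique(x$report$coverage), collapse = ", "), "\n", sep = "")
  cat("  report: ", nrow(x$report), " rows (height x condition x scenario)\n",
      sep = "")
  invisible(x)
}

#' Depth-profile plot of exceedance statistics
#'
#' Base-graphics depth profiles: one panel for percentage of time and one
#' for longest continuous period, one line per biofouling coverage, for a
#' chosen limit condition.
#'
#' @param x an `sbcc_report` from [run_framework()].
#' @param condition which condition to plot, e.g. `"below u_DO"`,
#'   `"above u_forage"`, `"above u_mobility"` (default: first present).
#' @param turbulence plot the turbulence-included variant?
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.sbcc_report <- function(x, condition = NULL, turbulence = FALSE, ...) {
  rep <- x$report[x$report$turbulence == turbulence, ]
  if (is.null(condition)) condition <- rep$condition[1]
  rep <- rep[rep$condition == condition, ]
  if (nrow(rep) == 0) stop("plot.sbcc_report: no rows for that condition")
  covs <- sort(unique(rep$coverage))
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (stat in c("percent_time", "longest_run_h")) {
    xlim <- range(rep[[stat]])
    graphics::plot(NA, xlim = xlim, ylim = range(rep$height),
                   xlab = if (stat == "percent_time") "% of time" else
                     "longest period (h)",
                   ylab = "height above seabed (m)", main = condition)
    for (i in seq_along(covs)) {
      r <- rep[rep$coverage == covs[i], ]
      graphics::lines(r[[stat]], r$height, col = i, lty = i)
    }
    graphics::legend("topright", legend = sprintf("%g%%", 100 * covs),
                     col = seq_along(covs), lty = seq_along(covs),
                     title = "biofouling", cex = 0.8)
  }
  invisible(x)
}

#' Write an exceedance report to CSV
#'
#' One row per height x scenario x condition, with a small `#` metadata
#' header recording the limits used.
#'
#' @param x an `sbcc_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "sbcc_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# u_DO: %.6g", x$limits$u_DO),
               sprintf("# u_forage: %g", x$limits$u_forage),
               sprintf("# u_mobility: %g", x$limits$u_mobility)), con)
  utils::write.table(x$report, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
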