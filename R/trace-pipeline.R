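# Displacement-to-force contraction pipeline.
#
# The instrument records platform deflection (micrometres) against time over
# a one-hour assay; force follows pointwise from the chip spring constant.
# Per-sample summaries (maximum force, lag, half-max time, plateau) feed the
# group statistics.

#' Displacement-versus-time trace
#'
#' @param times Times in seconds, strictly increasing, starting at >= 0.
#' @param deflections Platform deflections in micrometres, same length.
#' @param sample_id Sample label.
#' @param condition Condition (reagent) label.
#' @param max_duration Maximum allowed span in seconds (default 3600, the
#'   one-hour assay).
#' @return An object of class `displacement_trace`.
#' @export
displacement_trace <- function(times, deflections, sample_id = "S1",
                               condition = "control", max_duration = 3600) {
  .check_numeric_vector(times, "times", class = "clotforce_invalid_trace")
  .check_numeric_vector(deflections, "deflections",
                        class = "clotforce_invalid_trace")
  if (length(times) != length(deflections))
    cf_stop("times and deflections must have equal length",
            "clotforce_invalid_trace")
  if (length(times) > 1L && any(diff(times) <= 0))
    cf_stop("times must be strictly increasing", "clotforce_invalid_trace")
  if (length(times) && times[1L] < 0)
    cf_stop("times must start at or after 0", "clotforce_invalid_trace")
  if (length(times) && (times[length(times)] - times[1L]) > max_duration)
    cf_stop(sprintf("trace spans more than %g s", max_duration),
            "clotforce_invalid_trace")
  structure(list(times = times, deflections = deflections,
                 sample_id = sample_id, condition = condition),
            class = "displacement_trace")
}

#' Convert a displacement trace to a force trace
#'
#' Pointwise Hooke's-law transduction `F = k x`. Small negative deflections
#' (thermal drift, tracking jitter) are tolerated down to `neg_tolerance`
#' micrometres; anything below that is a data-quality error.
#'
#' @param trace A [displacement_trace()].
#' @param chip A [sensor_chip()].
#' @param neg_tolerance Most negative acceptable deflection in micrometres
#'   (default -1).
#' @return An object of class `force_trace` with forces in microNewtons.
#' @export
to_force_trace <- function(trace, chip, neg_tolerance = -1) {
  stopifnot(inherits(trace, "displacement_trace"),
            inherits(chip, "sensor_chip"))
  if (any(trace$deflections < neg_tolerance))
    cf_stop(sprintf("deflections below the %g um tolerance: bad trace data",
                    neg_tolerance),
            "clotforce_data_quality")
  structure(list(times = trace$times,
                 forces = chip$spring_constant_k * trace$deflections,
                 chip_k = chip$spring_constant_k,
                 sample_id = trace$sample_id,
                 condition = trace$condition),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %s/%s: %d points over %g s, k = %g N/m\n",
              x$condition, x$sample_id, length(x$times),
              if (length(x$times)) diff(range(x$times)) else 0, x$chip_k))
  invisible(x)
}

#' @export
plot.force_trace <- function(x, ...) {
  plot(x$times, x$forces, type = "l", xlab = "time (s)",
       ylab = "force (uN)",
       main = sprintf("%s / %s", x$condition, x$sample_id), ...)
  invisible(x)
}

# centered moving average; window given in seconds, converted to an odd
# number of samples from the median sampling interval. Returns the input
# unchanged for window <= 0.
.smooth_forces <- function(times, forces, smooth_window) {
  if (smooth_window <= 0 || length(forces) < 3L) return(forces)
  dt <- stats::median(diff(times))
  w <- max(1L, round(smooth_window / dt))
  if (w %% 2L == 0L) w <- w + 1L
  if (w <= 1L || w > length(forces)) return(forces)
  sm <- stats::filter(forces, rep(1 / w, w), sides = 2)
  as.numeric(sm)
}

#' Maximum contraction force of a trace
#'
#' Maximum of the moving-average-smoothed force series. Smoothing (default
#' 30 s centred window) suppresses single-sample noise spikes; `smooth_window
#' = 0` disables it and returns the raw maximum.
#'
#' @param ftrace A [force_trace()].
#' @param smooth_window Smoothing window in seconds (default 30; 0 disables).
#' @return Maximum force in microNewtons.
#' @export
max_contraction_force <- function(ftrace, smooth_window = 30) {
  stopifnot(inherits(ftrace, "force_trace"))
  if (length(ftrace$forces) < 2L)
    cf_stop("at least 2 samples are required", "clotforce_insufficient_data")
  sm <- .smooth_forces(ftrace$times, ftrace$forces, smooth_window)
  max(sm, na.rm = TRUE)
}

#' Contraction kinetics summary
#'
#' Summarises a force trace by its maximum force, lag time (first time the
#' force exceeds `lag_frac` of the maximum), time to half-maximum (first time
#' above `half_frac` of the maximum) and plateau force (mean of the final
#' `plateau_frac` of samples). If the trace never reaches half its maximum
#' above zero (e.g. a flat no-clot trace) the kinetic fields are `NA` and the
#' summary is flagged.
#'
#' @inheritParams max_contraction_force
#' @param lag_frac Lag threshold as a fraction of maximum (default 0.05).
#' @param half_frac Half-max threshold (default 0.5).
#' @param plateau_frac Fraction of final samples averaged for the plateau
#'   (default 0.1).
#' @return An object of class `contraction_summary`: list with `max_force`,
#'   `lag_time`, `time_to_half_max`, `plateau_force`, `flagged`.
#' @export
contraction_kinetics <- function(ftrace, smooth_window = 30, lag_frac = 0.05,
                                 half_frac = 0.5, plateau_frac = 0.1) {
  stopifnot(inherits(ftrace, "force_trace"))
  n <- length(ftrace$forces)
  if (n < 2L)
    cf_stop("at least 2 samples are required", "clotforce_insufficient_data")
  sm <- .smooth_forces(ftrace$times, ftrace$forces, smooth_window)
  ok <- !is.na(sm)
  fmax <- max(sm, na.rm = TRUE)
  n_pl <- max(1L, ceiling(plateau_frac * n))
  plateau <- mean(ftrace$forces[(n - n_pl + 1L):n])
  if (fmax <= 0) {
    out <- list(max_force = max(ftrace$forces), lag_time = NA_real_,
                time_to_half_max = NA_real_, plateau_force = plateau,
                flagged = TRUE)
    return(structure(out, class = "contraction_summary"))
  }
  first_above <- function(frac) {
    idx <- which(ok & sm > frac * fmax)
    if (length(idx)) ftrace$times[idx[1L]] else NA_real_
  }
  lag <- first_above(lag_frac)
  half <- first_above(half_frac)
  structure(list(max_force = fmax, lag_time = lag,
                 time_to_half_max = half, plateau_force = plateau,
                 flagged = is.na(half)),
            class = "contraction_summary")
}

#' @export
print.contraction_summary <- function(x, ...) {
  cat(sprintf(paste0("<contraction_summary> max %.1f uN, lag %.0f s, ",
                     "t1/2 %.0f s, plateau %.1f uN%s\n"),
              x$max_force, x$lag_time, x$time_to_half_max, x$plateau_force,
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' Per-sample maximum forces for a set of traces
#'
#' Converts each displacement trace with the chip constant and extracts its
#' maximum (smoothed) contraction force.
#'
#' @param traces A list of [displacement_trace()] objects (e.g. from
#'   [generate_condition_dataset()]).
#' @param chip A [sensor_chip()].
#' @param smooth_window Smoothing window in seconds (default 30).
#' @param statistic `"max"` (smoothed maximum, default) or `"plateau"` (mean
#'   of the final tenth of samples).
#' @return A data frame with columns `condition`, `sample_id`, `max_force`.
#' @export
extract_max_forces <- function(traces, chip, smooth_window = 30,
                               statistic = c("max", "plateau")) {
  statistic <- match.arg(statistic)
  rows <- lapply(traces, function(tr) {
    ft <- to_force_trace(tr, chip)
    val <- if (statistic == "max") {
      max_contraction_force(ft, smooth_window)
    } else {
      contraction_kinetics(ft, smooth_window)$plateau_force
    }
    data.frame(condition = tr$condition, sample_id = tr$sample_id,
               max_force = val, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
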