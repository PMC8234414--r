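# Synthetic data generation.
#
# No clot-contraction dataset is publicly deposited, so every pipeline input
# can be simulated here with the statistical structure the assay reports:
# sigmoidal contraction traces plateauing within the one-hour assay at
# condition-specific forces, nanoindenter calibration series linear to
# 96-99%, ELISA plates whose normalised pMLC ratios reproduce the reported
# percent changes, and blot lanes with configured relative intensities.

#' Default per-condition configuration
#'
#' One row per condition with the mean and SD of the maximum contraction
#' force (microNewtons), the pMLC percent effect versus control, and the
#' expected direction. Absolute force means are reported for control
#' (2958 +/- 373), U46619 (7337 +/- 1408) and Cpd7a (922 +/- 504); the
#' remaining means are back-computed from the reported percent changes under
#' the [percent_change()] convention (sildenafil +34.6%, PMA +41.6%, okadaic
#' acid +46.8%, ML7 -53.5%, K252d -63%, Y27632 -65%), with SDs set to the
#' control group's coefficient of variation times the back-computed mean.
#' pMLC effects: +40.9 (sildenafil), +41.3 (U46619), +30.5 (PMA), +30.7
#' (okadaic acid), -38.5 (Cpd7a), -42.8 (ML7), -39.8 (K252d), -46.0 (Y27632).
#'
#' @return Data frame with columns `condition`, `mean_max_force`,
#'   `sd_max_force`, `pmlc_effect`, `direction`.
#' @export
default_condition_configs <- function() {
  ctrl_mean <- 2958
  ctrl_sd <- 373
  cv <- ctrl_sd / ctrl_mean
  back <- function(effect) .mean_from_percent_change(effect, ctrl_mean)
  conds <- list(
    list("control",      ctrl_mean,    ctrl_sd,               0,    "none"),
    list("U46619",       7337,         1408,                  41.3, "up"),
    list("PMA",          back(41.6),   cv * back(41.6),       30.5, "up"),
    list("okadaic_acid", back(46.8),   cv * back(46.8),       30.7, "up"),
    list("sildenafil",   back(34.6),   cv * back(34.6),       40.9, "up"),
    list("Cpd7a",        922,          504,                  -38.5, "down"),
    list("ML7",          back(-53.5),  cv * back(-53.5),     -42.8, "down"),
    list("K252d",        back(-63),    cv * back(-63),       -39.8, "down"),
    list("Y27632",       back(-65),    cv * back(-65),       -46.0, "down"))
  data.frame(condition = vapply(conds, `[[`, character(1), 1L),
             mean_max_force = vapply(conds, `[[`, numeric(1), 2L),
             sd_max_force = vapply(conds, `[[`, numeric(1), 3L),
             pmlc_effect = vapply(conds, `[[`, numeric(1), 4L),
             direction = vapply(conds, `[[`, character(1), 5L),
             stringsAsFactors = FALSE)
}

#' Parameters of a synthetic contraction trace
#'
#' The deflection curve is a lagged logistic re-anchored to start at zero:
#' `x(t) = (F_inf / k) * (s((t - t_half)/tau) - s(-t_half/tau)) / (1 -
#' s(-t_half/tau))` with `s` the logistic function, plus Gaussian deflection
#' noise. Defaults: half-rise at 900 s, rise time constant 300 s, 0.2 um
#' noise, one-hour assay sampled every 5 s.
#'
#' @param plateau_force Plateau force `F_inf` in microNewtons (>= 0; 0 gives
#'   a flat no-clot trace).
#' @param midpoint_t Half-rise time in seconds (default 900).
#' @param rise_tau Logistic time constant in seconds (default 300).
#' @param noise_sd Deflection noise SD in micrometres (default 0.2).
#' @param duration Assay length in seconds (default 3600).
#' @param sampling_dt Sampling interval in seconds (default 5).
#' @return An object of class `trace_model`.
#' @export
trace_model <- function(plateau_force, midpoint_t = 900, rise_tau = 300,
                        noise_sd = 0.2, duration = 3600, sampling_dt = 5) {
  .check_scalar_number(plateau_force, "plateau_force", nonneg = TRUE)
  for (nm in c("midpoint_t", "rise_tau", "duration", "sampling_dt"))
    .check_scalar_number(get(nm), nm, positive = TRUE)
  .check_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (duration / sampling_dt < 100)
    cf_stop("duration / sampling_dt must give at least 100 points",
            "clotforce_invalid_input")
  structure(list(plateau_force = plateau_force, midpoint_t = midpoint_t,
                 rise_tau = rise_tau, noise_sd = noise_sd,
                 duration = duration, sampling_dt = sampling_dt),
            class = "trace_model")
}

# noiseless deflection curve of a trace model, in micrometres
.trace_mean_deflection <- function(model, chip, times) {
  if (model$plateau_force == 0) return(rep(0, length(times)))
  s0 <- stats::plogis(-model$midpoint_t / model$rise_tau)
  s <- stats::plogis((times - model$midpoint_t) / model$rise_tau)
  (model$plateau_force / chip$spring_constant_k) * (s - s0) / (1 - s0)
}

#' Generate one synthetic contraction trace
#'
#' @param model A [trace_model()].
#' @param chip A [sensor_chip()].
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   traces.
#' @param sample_id,condition Labels attached to the trace.
#' @return A [displacement_trace()].
#' @examples
#' tr <- generate_contraction_trace(trace_model(2958), sensor_chip(100), seed = 1)
#' @export
generate_contraction_trace <- function(model, chip, seed = NULL,
                                       sample_id = "S1",
                                       condition = "control") {
  stopifnot(inherits(model, "trace_model"), inherits(chip, "sensor_chip"))
  .with_seed(seed)
  times <- seq(0, model$duration, by = model$sampling_dt)
  x <- .trace_mean_deflection(model, chip, times)
  if (model$noise_sd > 0)
    x <- x + stats::rnorm(length(times), 0, model$noise_sd)
  displacement_trace(times, x, sample_id = sample_id, condition = condition,
                     max_duration = model$duration)
}

#' Generate a grouped synthetic condition dataset
#'
#' One trace per subject per condition. Each subject's plateau force is drawn
#' from a normal distribution with the condition's configured mean and SD,
#' truncated at zero (negative draws are rejected and redrawn); kinetics are
#' shared across subjects, only the plateau varies.
#'
#' @param configs Condition configuration data frame
#'   ([default_condition_configs()] or a subset).
#' @param n_subjects Subjects per condition (the assay used 5).
#' @param chip A [sensor_chip()].
#' @param seed Optional integer seed.
#' @param ... Further arguments passed to [trace_model()] (e.g. `noise_sd`).
#' @return A list of [displacement_trace()] objects, class
#'   `condition_dataset`, with attributes `configs`, `chip`, `seed`.
#' @export
generate_condition_dataset <- function(configs = default_condition_configs(),
                                       n_subjects = 5, chip = sensor_chip(100),
                                       seed = NULL, ...) {
  stopifnot(is.data.frame(configs), n_subjects >= 1)
  .with_seed(seed)
  traces <- list()
  for (i in seq_len(nrow(configs))) {
    mu <- configs$mean_max_force[i]
    sdv <- configs$sd_max_force[i]
    for (j in seq_len(n_subjects)) {
      plateau <- if (sdv == 0) mu else {
        repeat {
          p <- stats::rnorm(1, mu, sdv)
          if (p > 0) break
        }
        p
      }
      traces[[length(traces) + 1L]] <- generate_contraction_trace(
        trace_model(plateau, ...), chip, seed = NULL,
        sample_id = sprintf("S%02d", j), condition = configs$condition[i])
    }
  }
  structure(traces, class = "condition_dataset",
            configs = configs, chip = chip, seed = seed)
}

#' Generate a synthetic nanoindenter calibration series
#'
#' Evenly spaced deflections over the chip stroke with `force = k x` plus
#' Gaussian force noise. The default noise SD is 4% of the full-scale force
#' (`0.04 * k * max_stroke` microNewtons), which places the linearity score
#' of a 50-point series in the reported 96-99% band.
#'
#' @param chip A [sensor_chip()].
#' @param n_points Number of points (default 50, >= 3).
#' @param noise_sd_force Force noise SD in microNewtons; `NULL` (default)
#'   uses 4% of full scale.
#' @param seed Optional integer seed.
#' @return A [calibration_series()].
#' @export
generate_calibration_series <- function(chip, n_points = 50,
                                        noise_sd_force = NULL, seed = NULL) {
  stopifnot(inherits(chip, "sensor_chip"))
  if (n_points < 3L)
    cf_stop("at least 3 points are required", "clotforce_insufficient_data")
  .with_seed(seed)
  if (is.null(noise_sd_force))
    noise_sd_force <- 0.04 * chip$spring_constant_k * chip$max_stroke
  x <- seq(0, chip$max_stroke, length.out = n_points)
  f <- chip$spring_constant_k * x
  if (noise_sd_force > 0)
    f <- f + stats::rnorm(n_points, 0, noise_sd_force)
  calibration_series(x, f)
}

#' Generate a synthetic ELISA plate
#'
#' The control condition gets a pMLC/total-MLC ratio of 1; each other
#' condition's ratio is set so that at zero noise [phospho_percent_change()]
#' recovers exactly its configured `pmlc_effect` under the percent-change
#' convention. Well signals carry multiplicative log-normal noise of the
#' given coefficient of variation (mean-one noise factors).
#'
#' @param configs Condition configuration data frame (needs columns
#'   `condition`, `pmlc_effect`).
#' @param wells_per_condition Replicate wells per analyte and condition
#'   (default 8).
#' @param noise_cv Well-level coefficient of variation (default 0.05).
#' @param seed Optional integer seed.
#' @param total_signal Above-blank total-MLC signal in OD units (default 1).
#' @param blank_od Blank absorbance (default 0.05).
#' @param n_blank Number of blank wells (default 4).
#' @return An [elisa_plate()].
#' @export
generate_elisa_plate <- function(configs = default_condition_configs(),
                                 wells_per_condition = 8, noise_cv = 0.05,
                                 seed = NULL, total_signal = 1,
                                 blank_od = 0.05, n_blank = 4) {
  stopifnot(is.data.frame(configs), wells_per_condition >= 1)
  .check_scalar_number(noise_cv, "noise_cv", nonneg = TRUE)
  .with_seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) {
    if (noise_cv == 0) rep(1, n)
    else stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  rows <- list()
  add <- function(analyte, condition, od) {
    rows[[length(rows) + 1L]] <<- data.frame(
      well = sprintf("W%03d", length(rows) + seq_along(od)),
      analyte = analyte, condition = condition, od450 = od,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(configs))) {
    cond <- configs$condition[i]
    ratio <- if (cond == "control") 1
             else .mean_from_percent_change(configs$pmlc_effect[i], 1)
    nw <- wells_per_condition
    add("totalMLC", cond, blank_od + total_signal * noise(nw))
    add("pMLC", cond, blank_od + ratio * total_signal * noise(nw))
  }
  if (n_blank > 0)
    add("blank", "blank", blank_od * noise(n_blank))
  plate <- do.call(rbind, rows)
  plate$well <- sprintf("W%03d", seq_len(nrow(plate)))
  elisa_plate(plate)
}

#' Generate synthetic blot lanes
#'
#' One lane per condition, with the pMLC band intensity set to the
#' condition's configured pMLC ratio times a common baseline, a constant
#' total-MLC band, and a constant loading-control band, each with optional
#' multiplicative log-normal noise.
#'
#' @inheritParams generate_elisa_plate
#' @param baseline Baseline band intensity (arbitrary units, default 1000).
#' @return Named list of [blot_lane()] objects.
#' @export
generate_blot_lanes <- function(configs = default_condition_configs(),
                                noise_cv = 0, seed = NULL, baseline = 1000) {
  stopifnot(is.data.frame(configs))
  .with_seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function() {
    if (noise_cv == 0) 1
    else stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  lanes <- lapply(seq_len(nrow(configs)), function(i) {
    cond <- configs$condition[i]
    ratio <- if (cond == "control") 1
             else .mean_from_percent_change(configs$pmlc_effect[i], 1)
    blot_lane(cond,
              pmlc_intensity = baseline * ratio * noise(),
              total_mlc_intensity = baseline * noise(),
              loading_intensity = baseline * noise())
  })
  stats::setNames(lanes, configs$condition)
}

#' Final concentration after dilution
#'
#' `stock * vol_added / vol_total`, e.g. recalcification of citrated blood:
#' 6 uL of 100 mM calcium chloride into a 100 uL sample gives 6 mM.
#'
#' @param stock_concentration Stock concentration (any unit).
#' @param vol_added Volume of stock added.
#' @param vol_total Total final volume (>= `vol_added`).
#' @return Final concentration in the stock's units.
#' @examples
#' final_concentration(100, 6, 100) # 6
#' @export
final_concentration <- function(stock_concentration, vol_added, vol_total) {
  .check_scalar_number(stock_concentration, "stock_concentration",
                       nonneg = TRUE, class = "clotforce_domain_error")
  .check_scalar_number(vol_added, "vol_added", positive = TRUE,
                       class = "clotforce_domain_error")
  .check_scalar_number(vol_total, "vol_total", positive = TRUE,
                       class = "clotforce_domain_error")
  if (vol_added > vol_total)
    cf_stop("`vol_added` cannot exceed `vol_total`", "clotforce_domain_error")
  stock_concentration * vol_added / vol_total
}
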