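# Group summaries, the study's percent-change convention, and the
# force-versus-phosphorylation linear correlation.

#' Summary statistics for one condition group
#'
#' Mean, sample standard deviation (n - 1 denominator), median and IQR
#' (type-7 linear-interpolation quartiles). A single-value group gets sd and
#' IQR of 0 with `sd_flagged = TRUE`.
#'
#' @param values Numeric measurements (maximum forces in microNewtons, or
#'   normalised pMLC ratios), n >= 1.
#' @param condition Group label.
#' @return An object of class `condition_group`: list with `condition`,
#'   `values`, `n`, `mean`, `sd`, `median`, `iqr`, `sd_flagged`.
#' @examples
#' group_summary(c(1, 2, 3, 4, 5))
#' @export
group_summary <- function(values, condition = "group") {
  .check_numeric_vector(values, "values")
  n <- length(values)
  if (n < 1L)
    cf_stop("at least one value is required", "clotforce_insufficient_data")
  sd_flagged <- n < 2L
  structure(list(condition = condition, values = values, n = n,
                 mean = mean(values),
                 sd = if (sd_flagged) 0 else stats::sd(values),
                 median = stats::median(values),
                 iqr = if (sd_flagged) 0 else stats::IQR(values, type = 7),
                 sd_flagged = sd_flagged),
            class = "condition_group")
}

#' @export
print.condition_group <- function(x, ...) {
  cat(sprintf("<condition_group> %s: n = %d, mean = %.1f, sd = %.1f%s, median = %.1f, IQR = %.1f\n",
              x$condition, x$n, x$mean, x$sd,
              if (x$sd_flagged) " [single value]" else "", x$median, x$iqr))
  invisible(x)
}

#' Signed percent change between a treated and a control mean
#'
#' Uses the study's asymmetric convention: increases are expressed relative
#' to the *treated* mean, `+100 (treated - control) / treated`; decreases
#' relative to the *control* mean, `-100 (control - treated) / control`. This
#' is deliberate and non-standard -- it is the only reading consistent with
#' both reported force changes (7337 vs 2958 microNewtons printed as "60%
#' higher" and 922 vs 2958 printed as "69% lower") -- so results are
#' comparable with the reported percentages. Both percentages are bounded by
#' 100 in magnitude.
#'
#' @param treated_mean Treated-group mean (> 0).
#' @param control_mean Control-group mean (> 0).
#' @return Signed percent change.
#' @examples
#' percent_change(7337, 2958) # +59.7, rounds to 60
#' percent_change(922, 2958)  # -68.8, rounds to -69
#' @export
percent_change <- function(treated_mean, control_mean) {
  .check_scalar_number(treated_mean, "treated_mean", positive = TRUE,
                       class = "clotforce_domain_error")
  .check_scalar_number(control_mean, "control_mean", positive = TRUE,
                       class = "clotforce_domain_error")
  if (treated_mean >= control_mean) {
    100 * (treated_mean - control_mean) / treated_mean
  } else {
    -100 * (control_mean - treated_mean) / control_mean
  }
}

# inverse of percent_change with control fixed at `control`: the treated mean
# that reproduces a configured signed percent change.
.mean_from_percent_change <- function(effect, control) {
  if (effect >= 100)
    cf_stop("percent increase must be < 100 under this convention",
            "clotforce_domain_error")
  if (effect >= 0) control / (1 - effect / 100) else control * (1 + effect / 100)
}

#' Linear fit of phosphorylation on contraction force
#'
#' Ordinary least squares of per-condition mean normalised pMLC on
#' per-condition mean maximum contraction force, the relation summarised by
#' the assay's R-squared.
#'
#' @param force Per-condition mean forces (microNewtons), length >= 3.
#' @param pmlc Per-condition mean normalised pMLC values, same length.
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
fit_force_phospho <- function(force, pmlc) {
  .check_numeric_vector(force, "force")
  .check_numeric_vector(pmlc, "pmlc")
  if (length(force) != length(pmlc))
    cf_stop("force and pmlc must have equal length", "clotforce_invalid_input")
  if (length(force) < 3L)
    cf_stop("at least 3 conditions are required",
            "clotforce_insufficient_data")
  if (stats::var(force) == 0)
    cf_stop("zero variance in force", "clotforce_degenerate_input")
  fit <- stats::lm(pmlc ~ force)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((pmlc - mean(pmlc))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_points = length(force)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> pMLC = %.3g + %.3g * force, R^2 = %.3f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Condition summary table with percent changes versus control
#'
#' @param forces Data frame with columns `condition` and `max_force` (one row
#'   per sample), e.g. from [extract_max_forces()].
#' @param control Label of the control condition (default `"control"`).
#' @return A data frame with one row per condition: `condition`, `n`, `mean`,
#'   `sd`, `median`, `iqr`, `pct_change_vs_control`, `sd_flagged`. The control
#'   row has percent change 0.
#' @export
condition_table <- function(forces, control = "control") {
  if (!all(c("condition", "max_force") %in% names(forces)))
    cf_stop("`forces` must have columns condition and max_force",
            "clotforce_invalid_input")
  if (!control %in% forces$condition)
    cf_stop(sprintf("control condition '%s' not present", control),
            "clotforce_config_error")
  conds <- unique(forces$condition)
  conds <- c(control, setdiff(conds, control))
  groups <- lapply(conds, function(cc)
    group_summary(forces$max_force[forces$condition == cc], cc))
  ctrl_mean <- groups[[1L]]$mean
  rows <- lapply(groups, function(g) {
    data.frame(condition = g$condition, n = g$n, mean = g$mean, sd = g$sd,
               median = g$median, iqr = g$iqr,
               pct_change_vs_control = percent_change(g$mean, ctrl_mean),
               sd_flagged = g$sd_flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
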