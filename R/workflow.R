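# High-level workflow entry points binding the stages together: chip design,
# condition analysis, force-phosphorylation correlation and cascade
# prediction. Each can echo its inputs to disk with a reproducibility
# manifest.

#' Design report for a chip suspension
#'
#' From beam geometry, material and a target spring constant, computes the
#' shape factor, torsional constant, per-beam torsion stiffness, the
#' connection-arm length that meets the target, and the achieved spring
#' constant (round-trip check). The report can be written as YAML.
#'
#' @param length_L,thickness_a,width_b Beam dimensions in micrometres.
#' @param shear_modulus_G Shear modulus in pascals (default 50.9 GPa).
#' @param k_target Target platform spring constant in N/m (default 100).
#' @param beams_total Number of torsion beams (default 16).
#' @param out Optional YAML output path.
#' @return A list of class `ccs_design_report` with elements `geometry_um`,
#'   `shear_modulus_G`, `beta`, `J_m4`, `kappa_Nm_per_rad`, `arm_length_C_um`,
#'   `spring_constant_k`, `max_force_uN`, `warnings`.
#' @examples
#' ccs_design(680, 50, 10)
#' @export
ccs_design <- function(length_L, thickness_a, width_b,
                       shear_modulus_G = 50.9e9, k_target = 100,
                       beams_total = 16L, out = NULL) {
  geom <- beam_geometry(length_L, thickness_a, width_b)
  mat <- material(shear_modulus_G)
  C <- solve_arm_length(geom, mat, k_target, beams_total)
  design <- suspension_design(geom, mat, min(as.numeric(C), 2000),
                              beams_total = beams_total)
  k <- effective_spring_constant(design)
  chip <- sensor_chip(k)
  rep <- list(
    geometry_um = list(length_L = geom$length_L,
                       thickness_a = geom$thickness_a,
                       width_b = geom$width_b),
    shear_modulus_G = shear_modulus_G,
    beams_total = as.integer(beams_total),
    beta = beta_factor(geom),
    J_m4 = torsional_constant(geom),
    kappa_Nm_per_rad = beam_torsion_stiffness(geom, mat),
    arm_length_C_um = as.numeric(C),
    spring_constant_k = k,
    max_force_uN = force_from_displacement(chip, chip$max_stroke),
    warnings = if (isTRUE(attr(C, "exceeds_platform")))
      "arm length exceeds platform half-width" else character())
  class(rep) <- "ccs_design_report"
  if (!is.null(out)) yaml::write_yaml(unclass(rep), out)
  rep
}

#' @export
print.ccs_design_report <- function(x, ...) {
  cat("<ccs_design_report>\n")
  cat(sprintf("  beams: %d x %g x %g x %g um, G = %.3g Pa\n",
              x$beams_total, x$geometry_um$length_L,
              x$geometry_um$thickness_a, x$geometry_um$width_b,
              x$shear_modulus_G))
  cat(sprintf("  beta = %.4f, J = %.4g m^4, kappa = %.4g N m/rad\n",
              x$beta, x$J_m4, x$kappa_Nm_per_rad))
  cat(sprintf("  arm length C = %.1f um -> k = %.2f N/m (%.0f uN at full stroke)\n",
              x$arm_length_C_um, x$spring_constant_k, x$max_force_uN))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Analyse a set of contraction traces
#'
#' Converts every displacement trace to force, extracts per-sample maximum
#' contraction forces, and summarises per condition with percent changes
#' versus control. Optionally writes the summary CSV, per-sample forces CSV
#' and a manifest to `out_dir`.
#'
#' @param traces A list of [displacement_trace()] objects (e.g. from
#'   [generate_condition_dataset()] or [read_trace_csv()]).
#' @param chip A [sensor_chip()].
#' @param control Control condition label (default `"control"`).
#' @param smooth_window Smoothing window in seconds (default 30).
#' @param statistic `"max"` or `"plateau"` per-sample statistic.
#' @param out_dir Optional output directory.
#' @param seed Seed to record in the manifest (if the traces were generated).
#' @return A list with `table` (the [condition_table()]) and `forces` (the
#'   per-sample data frame).
#' @export
ccs_analyze <- function(traces, chip, control = "control", smooth_window = 30,
                        statistic = c("max", "plateau"), out_dir = NULL,
                        seed = NULL) {
  statistic <- match.arg(statistic)
  forces <- extract_max_forces(traces, chip, smooth_window, statistic)
  tab <- condition_table(forces, control = control)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    tab_path <- file.path(out_dir, "condition_summary.csv")
    forces_path <- file.path(out_dir, "sample_forces.csv")
    utils::write.csv(tab, tab_path, row.names = FALSE)
    utils::write.csv(forces, forces_path, row.names = FALSE)
    write_manifest(file.path(out_dir, "manifest.yaml"), seed = seed,
                   config = list(chip_k = chip$spring_constant_k,
                                 max_stroke = chip$max_stroke,
                                 control = control,
                                 smooth_window = smooth_window,
                                 statistic = statistic),
                   outputs = c(tab_path, forces_path))
  }
  list(table = tab, forces = forces)
}

#' Correlate contraction force with pMLC level across conditions
#'
#' Joins a per-condition force summary with a per-condition pMLC summary on
#' the condition label and fits pMLC on force by ordinary least squares.
#'
#' @param force_table Data frame with columns `condition`, `mean` (e.g.
#'   `ccs_analyze(...)$table`).
#' @param pmlc_table Data frame with columns `condition`, `pmlc_ratio` (e.g.
#'   [plate_summary()]).
#' @param out Optional CSV path for the merged scatter table.
#' @return A [fit_force_phospho()] result with an added `points` data frame.
#' @export
ccs_correlate <- function(force_table, pmlc_table, out = NULL) {
  if (!all(c("condition", "mean") %in% names(force_table)))
    cf_stop("`force_table` needs columns condition, mean",
            "clotforce_invalid_input")
  if (!all(c("condition", "pmlc_ratio") %in% names(pmlc_table)))
    cf_stop("`pmlc_table` needs columns condition, pmlc_ratio",
            "clotforce_invalid_input")
  shared <- intersect(force_table$condition, pmlc_table$condition)
  if (length(shared) < 3L)
    cf_stop("fewer than 3 shared conditions between the two tables",
            "clotforce_insufficient_data")
  pts <- merge(force_table[, c("condition", "mean")],
               pmlc_table[, c("condition", "pmlc_ratio")], by = "condition")
  names(pts)[names(pts) == "mean"] <- "mean_force"
  res <- fit_force_phospho(pts$mean_force, pts$pmlc_ratio)
  res$points <- pts
  if (!is.null(out)) utils::write.csv(pts, out, row.names = FALSE)
  res
}

#' Predict and tabulate perturbation directions
#'
#' Thin wrapper over [compare_predictions()] on the default cascade.
#'
#' @inheritParams compare_predictions
#' @return The comparison data frame (attribute `concordance`).
#' @export
ccs_predict_directions <- function(perturbations = default_perturbations(),
                                   observed = default_observed_directions()) {
  compare_predictions(build_default_network(), perturbations, observed)
}
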