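# Torsion-beam suspension model of the clot contraction sensor (CCS) chip.
#
# The sensor platform hangs from sixteen rectangular-section silicon torsion
# beams (four per side, joined pairwise by a rigid connection arm). Platelet
# contraction pulls the platform down by x micrometres; the beams twist by
# theta = x / C (small angles), storing torsional energy that resists with an
# effective linear spring constant k, so the measured force is F = k x.

#' Rectangular torsion-beam geometry
#'
#' Cross-section and length of one torsion beam. Dimensions are in
#' micrometres. By the usual convention for rectangular-section torsion the
#' thickness `a` is the larger side and the width `b` the smaller; inputs are
#' normalised so that `a >= b` on construction.
#'
#' @param length_L Beam length in micrometres.
#' @param thickness_a Cross-section thickness in micrometres (long side).
#' @param width_b Cross-section width in micrometres (short side).
#' @return An object of class `beam_geometry`.
#' @examples
#' beam_geometry(680, 50, 10)
#' @export
beam_geometry <- function(length_L, thickness_a, width_b) {
  for (nm in c("length_L", "thickness_a", "width_b"))
    .check_scalar_number(get(nm), nm, positive = TRUE,
                         class = "clotforce_invalid_geometry")
  if (thickness_a < width_b) {
    tmp <- thickness_a; thickness_a <- width_b; width_b <- tmp
  }
  structure(list(length_L = length_L, thickness_a = thickness_a,
                 width_b = width_b),
            class = "beam_geometry")
}

#' Beam material
#'
#' @param shear_modulus_G Shear modulus in pascals. Defaults to 50.9 GPa, a
#'   representative value for single-crystal silicon; silicon is anisotropic
#'   (roughly 50-80 GPa depending on crystal orientation), and the solved
#'   connection-arm length absorbs the choice.
#' @return An object of class `ccs_material`.
#' @export
material <- function(shear_modulus_G = 50.9e9) {
  .check_scalar_number(shear_modulus_G, "shear_modulus_G", positive = TRUE,
                       class = "clotforce_invalid_material")
  structure(list(shear_modulus_G = shear_modulus_G), class = "ccs_material")
}

#' Full platform suspension design
#'
#' Sixteen torsion beams (four arms of four beams) suspend the 4 mm sensor
#' platform; each arm's beams connect through a rigid connection arm of length
#' `arm_length_C`.
#'
#' @param beam A [beam_geometry()].
#' @param mat A [material()].
#' @param arm_length_C Connection-arm length in micrometres; must be positive
#'   and no larger than the platform half-width.
#' @param beams_total Total number of torsion beams (default 16).
#' @param arms Number of connection arms (default 4); `beams_total` must equal
#'   `4 * arms`.
#' @param platform_half_width Half the platform width in micrometres
#'   (default 2000 for the 4 mm platform).
#' @return An object of class `suspension_design`.
#' @export
suspension_design <- function(beam, mat, arm_length_C, beams_total = 16L,
                              arms = 4L, platform_half_width = 2000) {
  stopifnot(inherits(beam, "beam_geometry"), inherits(mat, "ccs_material"))
  .check_scalar_number(arm_length_C, "arm_length_C", positive = TRUE,
                       class = "clotforce_invalid_design")
  if (beams_total != 4L * arms)
    cf_stop("`beams_total` must equal 4 * arms", "clotforce_invalid_design")
  if (arm_length_C > platform_half_width)
    cf_stop("connection arm cannot exceed the platform half-width",
            "clotforce_invalid_design")
  structure(list(beam = beam, mat = mat, arm_length_C = arm_length_C,
                 beams_total = as.integer(beams_total),
                 arms = as.integer(arms),
                 platform_half_width = platform_half_width),
            class = "suspension_design")
}

#' Sensor chip as a linear spring
#'
#' @param spring_constant_k Platform spring constant in N/m.
#' @param max_stroke Nominal stroke (maximum deflection) in micrometres,
#'   default 100.
#' @return An object of class `sensor_chip`.
#' @examples
#' sensor_chip(100)
#' @export
sensor_chip <- function(spring_constant_k, max_stroke = 100) {
  .check_scalar_number(spring_constant_k, "spring_constant_k", positive = TRUE,
                       class = "clotforce_invalid_chip")
  .check_scalar_number(max_stroke, "max_stroke", positive = TRUE,
                       class = "clotforce_invalid_chip")
  structure(list(spring_constant_k = spring_constant_k,
                 max_stroke = max_stroke),
            class = "sensor_chip")
}

#' @export
print.sensor_chip <- function(x, ...) {
  cat(sprintf("<sensor_chip> k = %g N/m, stroke = %g um\n",
              x$spring_constant_k, x$max_stroke))
  invisible(x)
}

#' Nanoindenter calibration series
#'
#' Paired platform deflections (micrometres, strictly increasing) and measured
#' forces (microNewtons), as recorded when a calibrated nanoindenter pushes
#' the platform through its stroke.
#'
#' @param deflections Deflections in micrometres, strictly increasing, >= 0.
#' @param forces Forces in microNewtons, same length.
#' @return An object of class `calibration_series` (a data frame with columns
#'   `deflection_um`, `force_uN`).
#' @export
calibration_series <- function(deflections, forces) {
  .check_numeric_vector(deflections, "deflections",
                        class = "clotforce_invalid_calibration")
  .check_numeric_vector(forces, "forces",
                        class = "clotforce_invalid_calibration")
  if (length(deflections) != length(forces))
    cf_stop("deflections and forces must have equal length",
            "clotforce_invalid_calibration")
  if (length(deflections) < 3L)
    cf_stop("a calibration series needs at least 3 points",
            "clotforce_insufficient_data")
  if (any(diff(deflections) <= 0))
    cf_stop("deflections must be strictly increasing",
            "clotforce_invalid_calibration")
  if (any(deflections < 0))
    cf_stop("deflections must be non-negative",
            "clotforce_invalid_calibration")
  structure(data.frame(deflection_um = deflections, force_uN = forces),
            class = c("calibration_series", "data.frame"))
}

#' Shape factor for the torsional constant of a rectangular section
#'
#' For a rectangle of sides `a >= b`, the torsional constant is `J = beta a
#' b^3`. `beta` is computed from the closed-form approximation
#' `beta = 1/3 - 0.21 (b/a) (1 - (b/a)^4 / 12)`, which agrees with the
#' classical series solution to well under 0.5% over aspect ratios 1-10. It is
#' bounded in (0, 1/3] and increases with aspect ratio `a/b`, reaching the
#' thin-plate limit 1/3 as `a/b -> Inf`. For the chip's 50 x 10 um beams it
#' evaluates to 0.291.
#'
#' @param geom A [beam_geometry()].
#' @return The dimensionless shape factor.
#' @examples
#' beta_factor(beam_geometry(680, 50, 10)) # 0.291
#' @export
beta_factor <- function(geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  r <- geom$width_b / geom$thickness_a # b/a in (0, 1]
  1 / 3 - 0.21 * r * (1 - r^4 / 12)
}

#' Torsional constant of a rectangular beam cross-section
#'
#' `J = beta a b^3`, returned in m^4 (geometry given in micrometres).
#'
#' @inheritParams beta_factor
#' @return Torsional constant in m^4.
#' @export
torsional_constant <- function(geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  beta_factor(geom) * (geom$thickness_a * .UM) * (geom$width_b * .UM)^3
}

#' Torsion stiffness of one beam
#'
#' Torsion spring constant `kappa = G J / L` (N m / rad) relating torque to
#' twist angle through the angular form of Hooke's law, `tau = kappa theta`.
#'
#' @inheritParams beta_factor
#' @param mat A [material()].
#' @return Torsion stiffness in N m / rad.
#' @export
beam_torsion_stiffness <- function(geom, mat) {
  stopifnot(inherits(geom, "beam_geometry"), inherits(mat, "ccs_material"))
  mat$shear_modulus_G * torsional_constant(geom) / (geom$length_L * .UM)
}

#' Torque on a twisted beam
#'
#' `tau = kappa theta` for a beam of the given geometry and material.
#'
#' @inheritParams beam_torsion_stiffness
#' @param twist_theta Twist angle in radians.
#' @return A list with `twist_theta` (rad) and `torque_tau` (N m), class
#'   `torsion_beam_state`.
#' @export
torsion_beam_state <- function(geom, mat, twist_theta) {
  .check_scalar_number(twist_theta, "twist_theta")
  kappa <- beam_torsion_stiffness(geom, mat)
  structure(list(twist_theta = twist_theta,
                 torque_tau = kappa * twist_theta,
                 kappa = kappa),
            class = "torsion_beam_state")
}

#' Effective platform spring constant of the suspension
#'
#' Small-angle energy composition: a platform displacement `x` twists every
#' beam by `theta = x / C` (the arms and anchors are taken as perfectly
#' stiff), storing `U = n * kappa * theta^2 / 2`. Differentiating gives the
#' linear platform constant `k = n kappa / C^2`.
#'
#' @param design A [suspension_design()].
#' @return Spring constant in N/m.
#' @examples
#' d <- suspension_design(beam_geometry(680, 50, 10), material(), 417.4)
#' effective_spring_constant(d) # ~100 N/m
#' @export
effective_spring_constant <- function(design) {
  stopifnot(inherits(design, "suspension_design"))
  kappa <- beam_torsion_stiffness(design$beam, design$mat)
  design$beams_total * kappa / (design$arm_length_C * .UM)^2
}

#' Connection-arm length achieving a target spring constant
#'
#' Inverts the suspension composition: `C = sqrt(n kappa / k_target)`. If the
#' solution exceeds the platform half-width the value is still returned, with
#' a warning and attribute `exceeds_platform = TRUE`.
#'
#' @inheritParams beam_torsion_stiffness
#' @param k_target Target platform spring constant in N/m.
#' @param beams_total Number of torsion beams (default 16).
#' @param platform_half_width Platform half-width in micrometres (default 2000).
#' @return Arm length in micrometres (attribute `exceeds_platform`).
#' @export
solve_arm_length <- function(geom, mat, k_target, beams_total = 16L,
                             platform_half_width = 2000) {
  .check_scalar_number(k_target, "k_target", positive = TRUE,
                       class = "clotforce_domain_error")
  kappa <- beam_torsion_stiffness(geom, mat)
  C_m <- sqrt(beams_total * kappa / k_target)
  C_um <- C_m / .UM
  exceeds <- C_um > platform_half_width
  if (exceeds)
    warning(sprintf("solved arm length %.0f um exceeds the platform half-width (%g um)",
                    C_um, platform_half_width))
  structure(C_um, exceeds_platform = exceeds)
}

#' Force from platform displacement (Hooke's law)
#'
#' `F = k x`. With `k` in N/m and `x` in micrometres the product is directly
#' in microNewtons. Displacements beyond the chip stroke are transduced with a
#' warning (calibration hardware can overshoot); negative displacements are a
#' domain error.
#'
#' @param chip A [sensor_chip()].
#' @param x Displacement(s) in micrometres.
#' @return Force(s) in microNewtons.
#' @examples
#' force_from_displacement(sensor_chip(100), 100) # 10000 uN
#' @export
force_from_displacement <- function(chip, x) {
  stopifnot(inherits(chip, "sensor_chip"))
  .check_numeric_vector(x, "x", class = "clotforce_domain_error")
  if (any(x < 0))
    cf_stop("displacement must be non-negative", "clotforce_domain_error")
  if (any(x > chip$max_stroke))
    warning(sprintf("displacement beyond the %g um stroke", chip$max_stroke))
  chip$spring_constant_k * x
}

#' Displacement from force (inverse transduction)
#'
#' @inheritParams force_from_displacement
#' @param force Force(s) in microNewtons.
#' @return Displacement(s) in micrometres.
#' @export
displacement_from_force <- function(chip, force) {
  stopifnot(inherits(chip, "sensor_chip"))
  .check_numeric_vector(force, "force", class = "clotforce_domain_error")
  force / chip$spring_constant_k
}

#' Linearity score of a calibration series
#'
#' Quantifies how linear the measured force-deflection relation is, as a
#' percentage. The default metric is `100 * R^2` of the ordinary least-squares
#' fit of force on deflection. An alternative, `"max_residual"`, reports
#' `100 * (1 - max |residual| / full-scale force range)`.
#'
#' @param cal A [calibration_series()] (or data frame with columns
#'   `deflection_um`, `force_uN`).
#' @param metric `"r_squared"` (default) or `"max_residual"`.
#' @return Score in `[0, 100]`.
#' @export
linearity_score <- function(cal, metric = c("r_squared", "max_residual")) {
  metric <- match.arg(metric)
  if (!is.data.frame(cal) ||
      !all(c("deflection_um", "force_uN") %in% names(cal)))
    cf_stop("`cal` must have columns deflection_um and force_uN",
            "clotforce_invalid_calibration")
  d <- cal$deflection_um
  f <- cal$force_uN
  if (length(d) < 3L)
    cf_stop("at least 3 calibration points are required",
            "clotforce_insufficient_data")
  if (stats::var(d) == 0)
    cf_stop("zero variance in deflection", "clotforce_degenerate_input")
  fit <- stats::lm(f ~ d)
  if (metric == "r_squared") {
    ssr <- sum(stats::residuals(fit)^2)
    sst <- sum((f - mean(f))^2)
    if (sst == 0) return(0) # constant force: no linear association
    100 * (1 - ssr / sst)
  } else {
    rng <- diff(range(f))
    if (rng == 0) return(0)
    100 * (1 - max(abs(stats::residuals(fit))) / rng)
  }
}
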