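test_that("beta factor reproduces the chip value, limits and series oracle", {
  expect_equal(round(beta_factor(paper_beam()), 3), 0.291)
  # thin-plate limit
  expect_equal(beta_factor(beam_geometry(100, 1e6, 1)), 1 / 3,
               tolerance = 1e-5)
  # square section against the classical series solution
  expect_equal(beta_factor(beam_geometry(100, 20, 20)), 0.140577,
               tolerance = 0.001 / 0.1406)
  # bounded and monotone in aspect ratio
  aspects <- seq(1, 20, by = 0.5)
  betas <- vapply(aspects, function(r) beta_factor(beam_geometry(100, 10 * r, 10)),
                  numeric(1))
  expect_true(all(betas > 0 & betas <= 1 / 3))
  expect_true(all(diff(betas) > 0))
  # within 0.5% of the series solution for aspect ratios 1-10
  for (r in c(1, 2, 5, 10)) {
    expect_equal(beta_factor(beam_geometry(100, 10 * r, 10)), beta_series(r),
                 tolerance = 0.005)
  }
})

test_that("geometry is validated and normalised", {
  expect_error(beam_geometry(680, -50, 10), class = "clotforce_invalid_geometry")
  expect_error(beam_geometry(0, 50, 10), class = "clotforce_invalid_geometry")
  # a/b order is normalised so a >= b
  g <- beam_geometry(680, 10, 50)
  expect_equal(g$thickness_a, 50)
  expect_equal(g$width_b, 10)
  expect_equal(beta_factor(g), beta_factor(paper_beam()))
})

test_that("torsional constant follows J = beta a b^3 in m^4", {
  expect_equal(torsional_constant(paper_beam()), 1.456695e-20,
               tolerance = 1e-5)
  # degenerate cross-section
  expect_equal(torsional_constant(beam_geometry(100, 50, 1e-9)), 0,
               tolerance = 1e-40)
  # doubling b multiplies J by ~8 (beta shifts too)
  J1 <- torsional_constant(beam_geometry(680, 50, 10))
  J2 <- torsional_constant(beam_geometry(680, 50, 20))
  b1 <- beta_factor(beam_geometry(680, 50, 10))
  b2 <- beta_factor(beam_geometry(680, 50, 20))
  expect_equal(J2 / J1, 8 * b2 / b1, tolerance = 1e-12)
})

test_that("beam torsion stiffness is GJ/L with the expected scalings", {
  g <- paper_beam()
  m <- material(50.9e9)
  expect_equal(beam_torsion_stiffness(g, m), 1.090379e-06, tolerance = 1e-5)
  expect_equal(beam_torsion_stiffness(g, material(2 * 50.9e9)),
               2 * beam_torsion_stiffness(g, m), tolerance = 1e-12)
  expect_equal(beam_torsion_stiffness(beam_geometry(1360, 50, 10), m),
               beam_torsion_stiffness(g, m) / 2, tolerance = 1e-12)
  # torque state obeys tau = kappa * theta
  st <- torsion_beam_state(g, m, 0.01)
  expect_equal(st$torque_tau, st$kappa * 0.01, tolerance = 1e-15)
})

test_that("suspension composition gives ~100 N/m and scales as n/C^2", {
  g <- paper_beam(); m <- material()
  d <- suspension_design(g, m, 417.4)
  k <- effective_spring_constant(d)
  expect_equal(k, 100.1365, tolerance = 1e-4)
  expect_lt(abs(k - 100), 1)
  # quartering when C doubles
  d2 <- suspension_design(g, m, 2 * 417.4)
  expect_equal(effective_spring_constant(d2), k / 4, tolerance = 1e-12)
  # linear in beam count
  d8 <- suspension_design(g, m, 417.4, beams_total = 8L, arms = 2L)
  expect_equal(effective_spring_constant(d8), k / 2, tolerance = 1e-12)
  expect_error(suspension_design(g, m, 417.4, beams_total = 10L),
               class = "clotforce_invalid_design")
})

test_that("spring constant matches the strain-energy derivative and exact kinematics", {
  g <- paper_beam(); m <- material()
  C_um <- 417.4
  d <- suspension_design(g, m, C_um)
  k <- effective_spring_constant(d)
  kappa <- beam_torsion_stiffness(g, m)
  # numerical derivative of U(x) = n * kappa * (x/C)^2 / 2 at small x
  U <- function(x_m) 16 * 0.5 * kappa * (x_m / (C_um * 1e-6))^2
  h <- 1e-9
  x0 <- 1e-6
  k_num <- (U(x0 + h) - 2 * U(x0) + U(x0 - h)) / h^2
  expect_equal(k, k_num, tolerance = 1e-6)
  # exact kinematics theta = asin(x/C) converge to kx as x/C -> 0
  xC <- 0.01
  x_m <- xC * C_um * 1e-6
  theta <- asin(xC)
  F_exact <- 16 * kappa * theta / ((C_um * 1e-6) * cos(theta))
  expect_lt(abs(F_exact - k * x_m) / (k * x_m), 1e-4)
})

test_that("arm length solver inverts the spring constant", {
  g <- paper_beam(); m <- material()
  C <- solve_arm_length(g, m, 100)
  expect_equal(as.numeric(C), 417.68, tolerance = 1e-4)
  d <- suspension_design(g, m, as.numeric(C))
  expect_equal(effective_spring_constant(d), 100, tolerance = 1e-9)
  # low-stiffness chip still fits the platform
  C5 <- solve_arm_length(g, m, 5)
  expect_equal(as.numeric(C5), 1867.94, tolerance = 1e-4)
  expect_false(attr(C5, "exceeds_platform"))
  # limit: stiffer target, shorter arm
  expect_lt(as.numeric(solve_arm_length(g, m, 1e6)),
            as.numeric(solve_arm_length(g, m, 100)))
  expect_warning(solve_arm_length(g, m, 1), "half-width")
  expect_error(solve_arm_length(g, m, -5), class = "clotforce_domain_error")
})

test_that("Hooke's-law transduction hits the design point and round-trips", {
  chip <- default_chip()
  expect_equal(force_from_displacement(chip, 100), 10000)
  expect_equal(force_from_displacement(chip, 0), 0)
  expect_equal(force_from_displacement(sensor_chip(300), 10), 3000)
  # round trip to 1e-12 relative across chips
  for (k in c(5, 100, 300)) {
    ch <- sensor_chip(k)
    x <- c(0.013, 1, 42.42, 99.9)
    expect_equal(displacement_from_force(ch, force_from_displacement(ch, x)),
                 x, tolerance = 1e-12)
  }
  expect_error(force_from_displacement(chip, -1),
               class = "clotforce_domain_error")
  expect_warning(force_from_displacement(chip, 120), "stroke")
})

test_that("linearity score behaves on exact, constant and degenerate input", {
  x <- seq(0, 100, by = 10)
  exact <- calibration_series(x, 100 * x)
  expect_equal(linearity_score(exact), 100)
  expect_equal(linearity_score(exact, metric = "max_residual"), 100)
  const <- calibration_series(x, rep(500, length(x)))
  expect_equal(linearity_score(const), 0)
  expect_error(linearity_score(calibration_series(c(0, 1, 2), c(0, 1, 2))[1:2, ]),
               class = "clotforce_insufficient_data")
  expect_error(calibration_series(c(0, 1), c(0, 1)),
               class = "clotforce_insufficient_data")
  expect_error(calibration_series(c(0, 1, 1), c(0, 1, 2)),
               class = "clotforce_invalid_calibration")
})

test_that("linearity score equals 100 x squared Pearson correlation", {
  set.seed(11)
  for (i in 1:10) {
    x <- sort(runif(30, 0, 100))
    x <- x + seq_along(x) * 1e-6 # ensure strictly increasing
    f <- 100 * x + rnorm(30, 0, 300)
    cal <- calibration_series(x, f)
    expect_equal(linearity_score(cal), 100 * cor(x, f)^2, tolerance = 1e-12)
  }
})
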