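test_that("default condition configuration matches the reported study design", {
  cfg <- default_condition_configs()
  expect_equal(nrow(cfg), 9)
  get <- function(cc, col) cfg[[col]][cfg$condition == cc]
  expect_equal(get("control", "mean_max_force"), 2958)
  expect_equal(get("control", "sd_max_force"), 373)
  expect_equal(get("U46619", "mean_max_force"), 7337)
  expect_equal(get("U46619", "sd_max_force"), 1408)
  expect_equal(get("Cpd7a", "mean_max_force"), 922)
  expect_equal(get("Y27632", "pmlc_effect"), -46.0)
  # back-computed means invert the percent-change convention exactly
  expect_equal(percent_change(get("PMA", "mean_max_force"), 2958), 41.6,
               tolerance = 1e-12)
  expect_equal(percent_change(get("ML7", "mean_max_force"), 2958), -53.5,
               tolerance = 1e-12)
  expect_equal(percent_change(get("sildenafil", "mean_max_force"), 2958), 34.6,
               tolerance = 1e-12)
  expect_equal(percent_change(get("okadaic_acid", "mean_max_force"), 2958),
               46.8, tolerance = 1e-12)
  expect_equal(percent_change(get("K252d", "mean_max_force"), 2958), -63,
               tolerance = 1e-12)
  expect_equal(percent_change(get("Y27632", "mean_max_force"), 2958), -65,
               tolerance = 1e-12)
})

test_that("contraction traces are deterministic per seed and hit the closed form", {
  chip <- default_chip()
  model <- trace_model(2958)
  a <- generate_contraction_trace(model, chip, seed = 9)
  b <- generate_contraction_trace(model, chip, seed = 9)
  expect_identical(a$deflections, b$deflections)
  c2 <- generate_contraction_trace(model, chip, seed = 10)
  expect_false(identical(a$deflections, c2$deflections))
  # noiseless final deflection matches F_inf / k
  m0 <- trace_model(2958, noise_sd = 0)
  tr <- generate_contraction_trace(m0, chip)
  n <- length(tr$deflections)
  expect_equal(tr$deflections[n], 29.58, tolerance = 1e-3)
  expect_lt(abs(tr$deflections[1]), 1e-9) # starts at zero
  # oracle: full curve equals the independently written logistic form
  expect_equal(tr$deflections, logistic_deflection(tr$times, 2958, 100),
               tolerance = 1e-12)
  # no-calcium case: zero plateau gives a flat zero trace
  flat <- generate_contraction_trace(trace_model(0, noise_sd = 0), chip)
  expect_true(all(flat$deflections == 0))
})

test_that("condition datasets vary only the plateau and respect sd = 0", {
  chip <- default_chip()
  cfg <- data.frame(condition = "control", mean_max_force = 2958,
                    sd_max_force = 0, pmlc_effect = 0, direction = "none")
  ds <- generate_condition_dataset(cfg, n_subjects = 3, chip, seed = 1,
                                   noise_sd = 0)
  expect_length(ds, 3)
  expect_identical(ds[[1]]$deflections, ds[[2]]$deflections)
  # n = 5 mimics the study group size
  ds5 <- generate_condition_dataset(default_condition_configs()[1:2, ],
                                    n_subjects = 5, chip, seed = 2)
  expect_length(ds5, 10)
  expect_equal(sum(vapply(ds5, function(t) t$condition, "") == "control"), 5)
})

test_that("generate-convert-summarize recovers the control mean within CLT bounds", {
  chip <- default_chip()
  cfg <- default_condition_configs()[1, ] # control only
  ds <- generate_condition_dataset(cfg, n_subjects = 1000, chip, seed = 1)
  forces <- extract_max_forces(ds, chip)
  se <- 373 / sqrt(1000)
  expect_lt(abs(mean(forces$max_force) - 2958), 3 * se)
  # plateau statistic is unbiased too
  forces_pl <- extract_max_forces(ds, chip, statistic = "plateau")
  expect_lt(abs(mean(forces_pl$max_force) - 2958), 3 * se)
})

test_that("full pipeline round trip recovers every configured condition mean", {
  chip <- default_chip()
  cfg <- default_condition_configs()
  ds <- generate_condition_dataset(cfg, n_subjects = 250, chip, seed = 4)
  tab <- condition_table(extract_max_forces(ds, chip))
  for (i in seq_len(nrow(cfg))) {
    mu <- cfg$mean_max_force[i]
    se <- cfg$sd_max_force[i] / sqrt(250)
    got <- tab$mean[tab$condition == cfg$condition[i]]
    expect_lt(abs(got - mu), 3 * se + 0.01 * mu)
  }
  # recovered force direction matches the configured direction, which
  # matches the cascade prediction except for sildenafil
  preds <- compare_predictions()
  for (i in seq_len(nrow(cfg))) {
    cc <- cfg$condition[i]
    if (cc == "control") next
    pc <- tab$pct_change_vs_control[tab$condition == cc]
    expect_equal(if (pc > 0) "up" else "down", cfg$direction[i], label = cc)
    pred <- preds$predicted[preds$reagent == cc]
    if (cc == "sildenafil") expect_false(pred == cfg$direction[i])
    else expect_equal(pred, cfg$direction[i], label = cc)
  }
})

test_that("calibration series land in the reported linearity band", {
  chip <- default_chip()
  # zero noise -> perfectly linear
  expect_equal(linearity_score(generate_calibration_series(chip, 50, 0, 1)),
               100)
  # default noise: score >= 96 in at least 95% of seeds
  scores <- vapply(1:300, function(s)
    linearity_score(generate_calibration_series(chip, seed = s)), numeric(1))
  expect_gte(mean(scores >= 96), 0.95)
  expect_true(all(scores <= 100))
  # the low-stiffness chip is supported with the same relative noise
  s5 <- vapply(1:50, function(s)
    linearity_score(generate_calibration_series(sensor_chip(5), seed = s)),
    numeric(1))
  expect_gte(mean(s5 >= 96), 0.9)
})

test_that("elisa plates at moderate noise keep percent changes within 5 points", {
  configs <- default_condition_configs()
  dev <- vapply(1:100, function(s) {
    plate <- generate_elisa_plate(configs[configs$condition %in%
                                            c("control", "Y27632"), ],
                                  wells_per_condition = 8, noise_cv = 0.05,
                                  seed = s)
    abs(phospho_percent_change(plate, "Y27632") + 46)
  }, numeric(1))
  expect_gte(mean(dev <= 5), 0.95)
})

test_that("dilution arithmetic reproduces the recalcification step", {
  expect_equal(final_concentration(100, 6, 100), 6)
  expect_equal(final_concentration(100, 3, 100), 3)
  expect_equal(final_concentration(80, 50, 50), 80) # vol_added = vol_total
  expect_error(final_concentration(100, 120, 100),
               class = "clotforce_domain_error")
  expect_error(final_concentration(100, -5, 100),
               class = "clotforce_domain_error")
})
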