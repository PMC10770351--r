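test_that("load-stress conversion matches the 5 mm cord benchmarks", {
  # 4 kPa increments correspond to 32 g increments; 32 kPa to 256 g
  expect_equal(stress_to_grams(4e3), 32)
  expect_equal(stress_to_grams(32e3), 256)
  expect_equal(stress_to_grams(0), 0)
  expect_equal(grams_to_stress(256) / 1e3, 32, tolerance = 0.002)
  # exact inverse before rounding
  for (g in c(0, 1, 17.3, 256))
    expect_equal(stress_to_grams(grams_to_stress(g), exact = TRUE), g)
  expect_error(grams_to_stress(-1), "nonnegative")
  expect_error(grams_to_stress(10, cord_radius = 0), "cord_radius")
})

test_that("noiseless sweeps are recovered exactly by the calibration fit", {
  loads <- seq(0, 250, by = 25)
  sw <- as_taut_sweep(data.frame(load_g = loads,
                                 swv_mps = sqrt(1.932 + 0.125 * loads)))
  fit <- fit_squared_swv(sw)
  expect_equal(fit$slope, 0.125)
  expect_equal(fit$intercept, 1.932)
  expect_equal(fit$r2, 1.0)
  expect_equal(fit$baseline_swv, sqrt(1.932))
  # squared intercept of 3.108 equates to a baseline of 1.76 m/s
  sw2 <- as_taut_sweep(data.frame(load_g = loads,
                                  swv_mps = sqrt(3.108 + 0.058 * loads)))
  expect_equal(round(fit_squared_swv(sw2)$baseline_swv, 2), 1.76)
})

test_that("fit is equivariant under a constant shift of squared SWV", {
  sw <- generate_tension_sweep(sweep_spec(seed = 11))
  f1 <- fit_squared_swv(sw)
  sw2 <- sw
  sw2$swv_mps <- sqrt(sw$swv_mps^2 + 4)
  f2 <- fit_squared_swv(sw2)
  expect_equal(f2$slope, f1$slope)
  expect_equal(f2$intercept, f1$intercept + 4)
})

test_that("slope and intercept land inside their own 95% CIs at nominal rate", {
  hit_slope <- 0L
  hit_int <- 0L
  for (s in 1:500) {
    sw <- generate_tension_sweep(sweep_spec(loads = seq(0, 250, 25),
                                            replicates = 1, seed = s))
    ci <- confint(fit_squared_swv(sw)$lm)
    hit_slope <- hit_slope +
      (ci["load_g", 1] <= 0.053 && 0.053 <= ci["load_g", 2])
    hit_int <- hit_int +
      (ci["(Intercept)", 1] <= 12.658 && 12.658 <= ci["(Intercept)", 2])
  }
  expect_gte(hit_slope, 0.93 * 500)
  expect_gte(hit_int, 0.93 * 500)
})

test_that("prediction band has the textbook shape", {
  sw <- generate_tension_sweep(sweep_spec(seed = 3))
  fit <- fit_squared_swv(sw)
  loads <- seq(0, 250, by = 5)
  band <- prediction_band(fit, loads)
  # narrowest at the mean load, contains the fitted line everywhere
  widths <- band[, "upper"] - band[, "lower"]
  expect_equal(loads[which.min(widths)], loads[which.min(abs(loads - fit$mean_load))])
  expect_true(all(band[, "lower"] < band[, "fit"] &
                  band[, "fit"] < band[, "upper"]))
  # matches the stats::predict.lm prediction interval
  pl <- predict(fit, loads, interval = "prediction")
  expect_equal(unname(band[, "lower"]), pl[, 2], tolerance = 1e-10)
  expect_equal(unname(band[, "upper"]), pl[, 3], tolerance = 1e-10)
  expect_error(prediction_band(fit, 10, level = 1.2), "level")
})

test_that("tension inversion is the algebraic inverse with 0-clamping", {
  sw <- generate_tension_sweep(sweep_spec(noise_sd = 0, seed = 1))
  fit <- fit_squared_swv(sw)
  expect_equal(as.numeric(invert_tension(fit, fit$baseline_swv)), 0)
  tt <- c(10, 100, 250)
  v <- sqrt(fit$intercept + fit$slope * tt)
  expect_equal(as.numeric(invert_tension(fit, v)), tt)
  # a below-baseline speed clamps to zero and is flagged
  inv <- invert_tension(fit, fit$baseline_swv * 0.5)
  expect_equal(as.numeric(inv), 0)
  expect_true(attr(inv, "out_of_calibration"))
  # hand-computed inversion on the simulation-scale calibration
  fit$slope <- 0.058; fit$intercept <- 3.108
  expect_equal(as.numeric(invert_tension(fit, 4.16)), 244.786,
               tolerance = 1e-3)
  fit$slope <- -0.01
  expect_error(invert_tension(fit, 2), "non-invertible")
})

test_that("beta calibration inverts the model slope relation", {
  expect_equal(beta_for_slope(9.80665 / (1000 * pi * 25e-6) / 1000), 1)
  expect_equal(beta_for_slope(0.058), 0.46452, tolerance = 1e-4)
})

test_that("calibration requires three distinct loads", {
  expect_error(fit_squared_swv(data.frame(load_g = c(0, 0, 100, 100),
                                          swv_mps = c(1, 1.1, 2, 2.1))),
               "3 distinct loads")
})

test_that("model methods are coherent", {
  sw <- generate_tension_sweep(sweep_spec(seed = 5))
  fit <- fit_squared_swv(sw)
  expect_named(coef(fit), c("intercept", "slope"))
  expect_length(residuals(fit), fit$n)
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-12)
  expect_output(print(fit), "baseline SWV")
  expect_output(print(summary(fit)), "CI slope")
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$load_g, sw$load_g)
  # seeded simulate is reproducible
  expect_equal(simulate(fit, nsim = 1, seed = 9)[[1]], sims[[1]])
})
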