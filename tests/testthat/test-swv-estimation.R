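test_that("constructed translating pulses are recovered at their true speed", {
  for (speed in c(1.39, 2.0, 4.0)) {
    fld <- generate_translating_pulse(speed, sim_grid())
    est <- time_to_peak_swv(wavefront_trace(fld, signal = "displacement"))
    expect_equal(est$swv, speed, tolerance = 0.01)
  }
  # speed equivariance: doubling the construction speed doubles the estimate
  v1 <- time_to_peak_swv(wavefront_trace(
    generate_translating_pulse(1.5, sim_grid()), signal = "displacement"))$swv
  v2 <- time_to_peak_swv(wavefront_trace(
    generate_translating_pulse(3.0, sim_grid()), signal = "displacement"))$swv
  expect_equal(v2 / v1, 2, tolerance = 0.02)
})

test_that("peak times grow with distance for an outgoing simulated wave", {
  fld <- simulate_push(elastic_medium(), sim_grid(), push_beam())
  tr <- wavefront_trace(fld)
  expect_true(all(diff(tr$peak_time) > 0))
  expect_true(all(is.finite(tr$peak_time)))
  expect_equal(nrow(tr), 8)
})

test_that("time-to-peak fit is exact on a noiseless line", {
  tr <- data.frame(position = c(1, 2, 3) * 1e-3,
                   peak_time = c(0.5, 1.0, 1.5) * 1e-3)
  est <- time_to_peak_swv(tr)
  expect_equal(est$swv, 2.0)
  expect_equal(est$fit_r2, 1.0)
})

test_that("estimator is scale-equivariant and shift-invariant", {
  set.seed(42)
  tr <- data.frame(position = seq(1e-3, 3e-3, length.out = 7))
  tr$peak_time <- tr$position / 1.7 + rnorm(7, sd = 2e-5)
  v <- time_to_peak_swv(tr)$swv
  tr_scaled <- transform(tr, position = position * 3.5)
  expect_equal(time_to_peak_swv(tr_scaled)$swv, 3.5 * v)
  tr_shift <- transform(tr, peak_time = peak_time + 1e-3)
  expect_equal(time_to_peak_swv(tr_shift)$swv, v)
})

test_that("degenerate traces and fields raise the specified errors", {
  expect_error(time_to_peak_swv(data.frame(position = c(1e-3, 2e-3),
                                           peak_time = c(1e-3, 2e-3))),
               "insufficient data")
  expect_error(time_to_peak_swv(data.frame(position = c(1, 2, 3) * 1e-3,
                                           peak_time = rep(1e-3, 3))),
               "degenerate")
  zero <- generate_translating_pulse(1, sim_grid())
  zero$u[] <- 0
  expect_error(wavefront_trace(zero), "undefined peak.*offset")
  fld <- generate_translating_pulse(1, sim_grid())
  expect_error(wavefront_trace(fld, offsets = c(0.1, 0.2, 0.3)),
               "outside the grid")
  expect_error(wavefront_trace(fld, depth = 1), "depth")
  expect_error(wavefront_trace(fld, offsets = c(1e-3, 2e-3)),
               "at least 3")
})

test_that("time-to-peak agrees with a cross-correlation lag oracle within 5%", {
  for (sig in c(0, 16000)) {
    med <- elastic_medium(sigma = sig)
    fld <- simulate_push(med, sim_grid(), push_beam())
    ttp <- time_to_peak_swv(wavefront_trace(fld))$swv
    xc <- xcorr_swv_oracle(fld)
    expect_equal(ttp, xc, tolerance = 0.05)
  }
})
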