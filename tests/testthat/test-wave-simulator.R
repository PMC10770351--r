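# one shared zero-load simulation reused across several assertions
fld0 <- simulate_push(elastic_medium(), sim_grid(), push_beam())

test_that("stable timestep follows the 2D Courant bound", {
  med <- elastic_medium(mu = 1932.1, rho = 1000)   # c = 1.39 m/s
  g <- sim_grid()
  expect_equal(stable_timestep(med, g), 0.9 * 2e-4 / (1.39 * sqrt(2)),
               tolerance = 1e-6)
  g2 <- sim_grid(h = 2 * g$h)
  expect_equal(stable_timestep(med, g2), 2 * stable_timestep(med, g))
  g3 <- sim_grid(cfl_safety = 1e-6)
  expect_lt(stable_timestep(med, g3), 1e-9)
})

test_that("zero forcing produces an identically zero field", {
  f <- simulate_push(elastic_medium(), sim_grid(duration = 0.5e-3),
                     push_beam(intensity = 0))
  expect_true(all(f$u == 0))
})

test_that("field is finite, mirror-symmetric and decays into the sponge", {
  expect_true(all(is.finite(fld0$u)))
  expect_true(all(diff(fld0$t) > 0))
  nx <- length(fld0$x)
  expect_equal(fld0$u, fld0$u[nx:1, , ], tolerance = 1e-12)
  # displacement near the sponge edge is tiny relative to the focal region
  last <- fld0$u[, , dim(fld0$u)[3]]
  expect_lt(max(abs(last[c(1:5, nx - 4:0), ])), max(abs(fld0$u)) * 1e-3)
})

test_that("with damping and no forcing, energy does not grow after the push", {
  med <- elastic_medium(gamma = 50)
  g <- sim_grid(duration = 1.5e-3)
  f <- simulate_push(med, g, push_beam())
  # kinetic + elastic energy density summed over the grid
  en <- sapply(2:dim(f$u)[3], function(k) {
    du <- (f$u[, , k] - f$u[, , k - 1]) / f$dt
    ux <- diff(f$u[, , k])
    uz <- t(diff(t(f$u[, , k])))
    0.5 * med$rho * sum(du^2) +
      0.5 * med$mu * (sum(ux^2) + sum(uz^2)) / g$h^2
  })
  after <- which(f$t[-1] > 2 * f$beam$tau)
  expect_true(all(diff(en[after]) <= max(en) * 1e-9))
})

test_that("relaxed-cord SWV matches the analytic plane-wave speed within 5%", {
  est <- time_to_peak_swv(wavefront_trace(fld0))
  expect_equal(est$swv, sqrt(1932.1 / 1000), tolerance = 0.05)
  expect_gt(est$fit_r2, 0.99)
})

test_that("halving the grid spacing changes the SWV estimate by < 2%", {
  f2 <- simulate_push(elastic_medium(), sim_grid(h = 1e-4), push_beam())
  v1 <- time_to_peak_swv(wavefront_trace(fld0))$swv
  v2 <- time_to_peak_swv(wavefront_trace(f2))$swv
  expect_lt(abs(v1 - v2) / v2, 0.02)
})

test_that("tension speeds up the wave and squared SWV is linear in load", {
  sw <- run_load_sweep(elastic_medium(), sim_grid(), push_beam(),
                       loads = c(0, 64, 128, 192, 256))
  expect_true(all(diff(sw$swv_mps) > 0))            # strictly increasing
  fit <- fit_squared_swv(sw)
  expect_gt(fit$r2, 0.99)
  # ideal-membrane slope g0/(rho*pi*r^2*1000) = 0.1249 m^2 s^-2 g^-1
  expect_equal(fit$slope, 9.80665 / (1000 * pi * 5e-3^2 * 1000),
               tolerance = 0.1)
})

test_that("instability trips the divergence guard with the offending step", {
  g <- sim_grid(duration = 0.03)
  g$cfl_safety <- 3                                  # past the Courant bound
  expect_error(simulate_push(elastic_medium(), g, push_beam()),
               "diverged at step")
})

test_that("negative loads are rejected", {
  expect_error(run_load_sweep(elastic_medium(), sim_grid(), push_beam(),
                              loads = c(0, -5)), "nonnegative")
})
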