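test_that("noiseless sweeps reproduce the generating parameters exactly", {
  sw <- generate_tension_sweep(sweep_spec(noise_sd = 0))
  fit <- fit_squared_swv(sw)
  expect_equal(fit$slope, 0.053)
  expect_equal(fit$intercept, 12.658)
  expect_equal(fit$r2, 1)
  # default benchtop schedule: (0, 1, 5..250 by 5) x 3 replicates
  expect_equal(nrow(sw), 52 * 3)
  expect_equal(sort(unique(sw$load_g)), c(0, 1, seq(5, 250, 5)))
  # top-load SWV near 5.09 m/s by construction
  expect_equal(mean(sw$swv_mps[sw$load_g == 250]), 5.09, tolerance = 0.001)
})

test_that("sweep generation is a pure function of spec and seed", {
  s1 <- generate_tension_sweep(sweep_spec(seed = 123))
  s2 <- generate_tension_sweep(sweep_spec(seed = 123))
  s3 <- generate_tension_sweep(sweep_spec(seed = 124))
  expect_identical(s1, s2)
  expect_false(identical(s1$swv_mps, s3$swv_mps))
})

test_that("fitted slopes recover the generating slope across seeds", {
  slopes <- vapply(1:100, function(s) {
    fit_squared_swv(generate_tension_sweep(sweep_spec(seed = s)))$slope
  }, numeric(1))
  expect_true(all(abs(slopes - 0.053) / 0.053 < 0.10))
  # mean of fitted slopes within 2 Monte-Carlo SEs of the truth
  expect_lt(abs(mean(slopes) - 0.053), 2 * sd(slopes) / sqrt(length(slopes)))
})

test_that("case series generator is seeded and structurally valid", {
  a <- generate_case_series(series_spec(seed = 5))
  b <- generate_case_series(series_spec(seed = 5))
  expect_identical(a, b)
  expect_setequal(unique(a$case_id), LETTERS[1:6])
  expect_setequal(unique(a$checkpoint), c("PRE", "MID", "FULL"))
  expect_true(all(a$swv_mps > 0))
  # 3-6 images per checkpoint
  imgs <- aggregate(image_index ~ case_id + checkpoint, a, function(x)
    length(unique(x)))
  expect_true(all(imgs$image_index >= 3 & imgs$image_index <= 6))
  # the last third of cases carries excluded (high-curvature) FULLs
  curv <- aggregate(curvature_pct ~ case_id, a[a$checkpoint == "FULL", ],
                    mean)
  expect_true(all(curv$curvature_pct[curv$case_id %in% c("E", "F")] > 5))
})

test_that("published sub-sample counts fixture is honoured verbatim", {
  sp <- series_spec(fig_counts = series_fig_counts(), seed = 2)
  series <- generate_case_series(sp)
  one <- series[series$case_id == "A" & series$checkpoint %in% c("PRE", "MID"), ]
  counts <- aggregate(subsample_index ~ checkpoint + image_index, one, max)
  pre <- counts$subsample_index[counts$checkpoint == "PRE"]
  mid <- counts$subsample_index[counts$checkpoint == "MID"]
  expect_equal(pre, c(76, 60, 72, 84, 76))
  expect_equal(mid, c(116, 72, 64, 96, 112))
})

test_that("series spec guards its invariants", {
  expect_error(series_spec(pre_mean = 1.4, full_mean = 1.5), "PRE mean")
  expect_s3_class(series_spec(pre_mean = 1.4, full_mean = 1.5,
                              allow_overlap = TRUE), "series_spec")
  expect_error(sweep_spec(loads = c(-1, 0)), "nonnegative")
  expect_error(sweep_spec(noise_sd = -1), "noise_sd")
})

test_that("lognormal sub-sample noise preserves mean and spread roughly", {
  sp <- series_spec(family = "lognormal", seed = 31)
  series <- generate_case_series(sp)
  pre <- series$swv_mps[series$checkpoint == "PRE"]
  expect_equal(mean(pre), 2.3, tolerance = 0.05)
  expect_equal(sd(pre), 0.25, tolerance = 0.25)
})

test_that("translating pulse is an exact constant-velocity fixture", {
  fld <- generate_translating_pulse(2.0, sim_grid())
  tr <- wavefront_trace(fld, signal = "displacement",
                        offsets = seq(1e-3, 4e-3, 0.5e-3))
  est <- time_to_peak_swv(tr)
  expect_equal(est$swv, 2.0, tolerance = 0.01)
  expect_error(generate_translating_pulse(0, sim_grid()), "speed")
})
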