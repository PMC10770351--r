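test_that("acquisition pooling applies the fewer-than-30 discard rule", {
  expect_true(pool_acquisition(rnorm(29, 2))$discarded)
  p30 <- pool_acquisition(rnorm(30, 2))
  expect_false(p30$discarded)                  # exactly 30 is retained
  expect_equal(pool_acquisition(c(1, 2, 3), min_subsamples = 1)$median, 2)
  # out-of-plane sub-samples are dropped before counting
  p <- pool_acquisition(c(rep(2, 30), rep(9, 5)),
                        in_plane = rep(c(TRUE, FALSE), c(30, 5)))
  expect_false(p$discarded)
  expect_equal(p$median, 2)
  expect_equal(p$n, 30)
  p2 <- pool_acquisition(rep(2, 34), in_plane = rep(c(TRUE, FALSE), c(29, 5)))
  expect_true(p2$discarded)
  expect_match(p2$reason, "fewer than 30")
})

test_that("image classification is strictly above-threshold", {
  expect_equal(classify_image(1.80, 1.76), "stretched")
  expect_equal(classify_image(1.76, 1.76), "relaxed")   # tie goes to relaxed
  expect_equal(classify_image(1.39, 1.76), "relaxed")
  expect_equal(classify_image(c(2, 1), 1.5), c("stretched", "relaxed"))
})

test_that("diagnostic rates reproduce the confusion-matrix identities", {
  truth <- rep(c("stretched", "relaxed"), c(28, 27))
  pred <- truth
  pred[c(1:3, 29:32)] <- ifelse(truth[c(1:3, 29:32)] == "stretched",
                                "relaxed", "stretched")
  d <- diagnostic_accuracy(pred, truth)
  expect_equal(sum(d$confusion), 55)
  expect_equal(d$accuracy, 87.3)
  perfect <- diagnostic_accuracy(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_warning(d1 <- diagnostic_accuracy(rep("stretched", 3),
                                           rep("stretched", 3)),
                 "specificity undefined")
  expect_true(is.nan(d1$specificity))
  expect_error(diagnostic_accuracy(character(0), character(0)), "nonempty")
})

test_that("Welch test matches a numerical-integration oracle", {
  # textbook two-sample comparison with unequal n and variance
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6, 19.0, 21.7, 21.4)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1, 22.9, 30.5)
  got <- welch_t_test(a, b)
  ora <- welch_p_oracle(a, b)
  expect_equal(got$statistic, ora$t, tolerance = 1e-10)
  expect_equal(got$df, ora$df, tolerance = 1e-10)
  expect_equal(got$p_value, ora$p, tolerance = 1e-8)
})

test_that("Welch test invariances and degenerate cases", {
  x <- c(1.2, 1.5, 1.7, 2.0, 2.2)
  expect_equal(welch_t_test(x, x)$statistic, 0)
  expect_equal(welch_t_test(x, x)$p_value, 1)
  y <- c(2.5, 2.7, 3.0, 3.3)
  p0 <- welch_t_test(x, y)$p_value
  expect_equal(welch_t_test(x + 5, y + 5)$p_value, p0)     # common shift
  expect_equal(welch_t_test(y, x)$p_value, p0)             # relabel swap
  expect_error(welch_t_test(x, 1), "at least 2")
  expect_error(welch_t_test(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("separated PRE/POST sub-samples reach p < 0.001 per case", {
  series <- generate_case_series(series_spec(seed = 21))
  rep <- run_case_pipeline(series)
  ps <- sapply(rep$cases, function(cs) cs$welch$p_value)
  expect_true(all(ps < 0.001))
})

test_that("one-way ANOVA yields F = 0 for identical group means", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  out <- anova_oneway(g)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(anova_oneway(list(1:3)), "at least 2 groups")
  expect_error(anova_oneway(list(1:3, 5)), "at least 2 values")
})

test_that("two-group Tukey-Kramer equals sqrt(2) times the pooled t", {
  set.seed(2)
  a <- rnorm(8, 0); b <- rnorm(11, 1)
  tk <- tukey_kramer(list(a = a, b = b))
  t_pooled <- unname(stats::t.test(a, b, var.equal = TRUE)$statistic)
  expect_equal(tk$q, sqrt(2) * abs(t_pooled), tolerance = 1e-10)
})

test_that("Tukey-Kramer decisions agree with a permutation reference", {
  # five seeded datasets with clearly separated or clearly equal groups
  for (s in 1:5) {
    groups <- with_seed(s, list(
      g1 = rnorm(12, 0, 0.3),
      g2 = rnorm(9, 0, 0.3),          # same as g1: never significant
      g3 = rnorm(15, 3, 0.3)          # far away: always significant
    ))
    tk <- tukey_kramer(groups, alpha = 0.01)
    for (r in seq_len(nrow(tk))) {
      p_perm <- perm_p_oracle(groups[[tk$group1[r]]], groups[[tk$group2[r]]],
                              seed = 100 + s)
      expect_equal(tk$significant[r], p_perm < 0.01,
                   info = sprintf("seed %d pair %s-%s", s,
                                  tk$group1[r], tk$group2[r]))
    }
  }
})
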