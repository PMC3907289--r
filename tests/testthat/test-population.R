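test_that("population tables are reproducible and degenerate correctly", {
  p <- ner_parameters()
  spec <- population_spec(n_cells = 12, seed = 42, times_min = c(30, 240))
  c1 <- simulate_population(p, spec)
  c2 <- simulate_population(p, spec)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 12)
  expect_true(all(c1$lesion_dose_uM > 0))
  expect_true(all(c1$edu_240min > 0))

  # no variability: every cell identical
  spec0 <- population_spec(n_cells = 5, cv_factors = 0, cv_lesions = 0,
                           seed = 1, times_min = 30)
  c0 <- simulate_population(p, spec0)
  expect_equal(max(apply(c0[, -1], 2, sd)), 0)
  expect_error(population_spec(n_cells = 5, sources_enabled = "XPB",
                               seed = 1), "unknown")
})

test_that("lognormal draws preserve the mean and requested CV", {
  set.seed(9)
  x <- nercontrol:::rlnorm_mean_cv(1e4, 2.5, 0.32)
  expect_equal(mean(x), 2.5, tolerance = 3 * 0.32 / sqrt(1e4) * 2.5)
  expect_equal(cv_of(x), 0.32, tolerance = 3 * 0.32 / sqrt(2 * 1e4) * 3)
})

test_that("late EdU variability reflects the lesion dose distribution", {
  p <- ner_parameters()
  spec <- population_spec(n_cells = 200, seed = 7, times_min = c(30, 240))
  cells <- simulate_population(p, spec)
  # after repair completes, incorporated EdU is proportional to the dose
  expect_gt(cor(cells$edu_240min, cells$lesion_dose_uM), 0.99)
  expect_equal(cv_of(cells$edu_240min), cv_of(cells$lesion_dose_uM),
               tolerance = 0.03)
  # and its CV matches the generative dose CV within sampling error
  expect_equal(cv_of(cells$edu_240min), 0.32, tolerance = 0.05)
})

test_that("early repair-rate variability matches the propagated CV budget", {
  p <- ner_parameters()
  spec <- population_spec(n_cells = 1000, seed = 11, times_min = 30)
  cells <- simulate_population(p, spec)
  budget <- propagate_cv(response_coefficients(p), 0.25, 0.32)
  # the budget predicts the CV of the instantaneous repair rate
  expect_equal(cv_of(cells$rate_30min), budget$cv_rate, tolerance = 0.1)
})

test_that("accumulation is linear in expression level", {
  p <- ner_parameters()
  for (f in c("XPC", "XPA")) {
    spec <- population_spec(n_cells = 100, seed = 3, times_min = 30,
                            sources_enabled = f)
    cells <- simulate_population(p, spec)
    m <- lm(cells[[sprintf("acc_%s_30min", f)]] ~
              cells[[sprintf("conc_%s_uM", f)]])
    expect_gt(summary(m)$r.squared, 0.9)
  }
})

test_that("single-cell regression slopes agree with response coefficients", {
  p <- ner_parameters()
  rep30 <- response_coefficients(p)
  f <- names(which.max(rep30$R))
  spec <- population_spec(n_cells = 300, seed = 19, times_min = 30,
                          sources_enabled = f)
  cells <- simulate_population(p, spec)
  x <- cells[[sprintf("conc_%s_uM", f)]]
  y <- cells$rate_30min
  m <- lm(I(y / mean(y)) ~ I(x / mean(x)))
  slope <- coef(m)[2]
  se <- summary(m)$coefficients[2, 2]
  expect_lt(abs(slope - rep30$R[[f]]), 3 * se + 0.02)
})

test_that("bootstrap correlation is exact in degenerate cases and calibrated", {
  x <- 1:30
  r <- correlate(x, x, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$ci95, c(1, 1))
  set.seed(2)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(correlate(a, b, n_boot = 50, seed = 3)$r), 0.05)
  expect_error(correlate(1:5, rep(1, 5), seed = 1), "zero variance")

  # CI covers the generative correlation ~95% of the time
  rho <- 0.5
  covered <- 0L
  for (rep in 1:20) {
    set.seed(100 + rep)
    u <- rnorm(200)
    v <- rho * u + sqrt(1 - rho^2) * rnorm(200)
    ci <- correlate(u, v, n_boot = 400, seed = rep)$ci95
    if (rho >= ci[1] && rho <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 17L)
})

test_that("variance decomposition attributes most variability to lesions", {
  p <- ner_parameters()
  spec <- population_spec(n_cells = 150, seed = 23, times_min = 30)
  dec <- variance_decomposition(p, spec)
  dec30 <- dec[dec$time_min == 30, ]
  all_cv <- dec30$cv[dec30$source == "all"]
  singles <- dec30[!dec30$source %in% "all", ]
  # the lesion dose is the strongest single source
  expect_equal(singles$source[which.max(singles$cv)], "lesions")
  # each single source contributes less than the full model
  expect_true(all(singles$cv <= all_cv + 0.01))
  # independent sources combine roughly in quadrature
  expect_equal(sqrt(sum(singles$cv^2)), all_cv, tolerance = 0.15)
})

test_that("error-ellipse estimator recovers generative measurement error", {
  # noise-free channels: zero error, perfect correlation
  pairs0 <- generate_paired_measurements(200, 0.3, 0, seed = 5)
  ee0 <- error_ellipse(pairs0$channel1, pairs0$channel2)
  expect_equal(ee0$relative_error, 0, tolerance = 1e-9)
  expect_equal(ee0$r, 1, tolerance = 1e-12)

  # the two operating points reported for antibody validation
  pairs11 <- generate_paired_measurements(332, 0.3, 0.11, seed = 6)
  expect_equal(error_ellipse(pairs11$channel1, pairs11$channel2)$relative_error,
               11, tolerance = 2 / 11)
  pairs5 <- generate_paired_measurements(332, 0.3, 0.05, seed = 6)
  expect_equal(error_ellipse(pairs5$channel1, pairs5$channel2)$relative_error,
               5, tolerance = 2 / 5)
  # attribution option: single-channel noise variance doubles
  ee_s <- error_ellipse(pairs11$channel1, pairs11$channel2, "single")
  ee_e <- error_ellipse(pairs11$channel1, pairs11$channel2, "equal")
  expect_equal(ee_s$sd_log, sqrt(2) * ee_e$sd_log, tolerance = 1e-12)
  expect_error(error_ellipse(c(-1, 2:20), 1:20), "positive")
})
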