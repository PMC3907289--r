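test_that("first-order EdU fit recovers exact and noisy curves", {
  t <- seq(0, 4, 0.25)
  fit <- fit_first_order(t, 1 - exp(-0.58 * t))
  expect_equal(fit$lambda, 0.58, tolerance = 1e-6)
  expect_equal(fit$edu_max, 1, tolerance = 1e-6)
  expect_equal(fit$half_time, log(2) / 0.58, tolerance = 1e-6)
  expect_equal(fit$linear_slope, -0.58, tolerance = 1e-6)
  # weighted fit with SDs behaves the same on exact data
  fitw <- fit_first_order(t, 2 * (1 - exp(-0.3 * t)), sds = rep(0.05, length(t)))
  expect_equal(fitw$lambda, 0.3, tolerance = 1e-6)
  expect_error(fit_first_order(c(0, 1), c(0, 1)), ">= 3")
})

test_that("recovered first-order rate is unbiased over noisy replicates", {
  curves <- generate_edu_curves(0.58, 1, seq(0, 4, 0.5),
                                noise_spec("absolute", 0.05, 200, seed = 99))
  lam <- vapply(split(curves, curves$replicate), function(d) {
    fit_first_order(d$time_h, d$value)$lambda
  }, numeric(1))
  se <- sd(lam) / sqrt(length(lam))
  expect_lt(abs(mean(lam) - 0.58), 3 * se + 0.005)
})

test_that("negative log-likelihood matches a brute-force residual sum", {
  p <- ner_parameters()
  data <- small_bulk(p, times = seq(0, 240, 40))
  # model curves equal to the data means: zero
  expect_equal(negloglik(p, data), 0, tolerance = 1e-8)
  # independent accumulation of squared weighted residuals
  data2 <- data
  set.seed(3)
  data2$value <- data2$value + rnorm(nrow(data2), 0, data2$sd)
  pred <- nercontrol:::predict_dataset(p, data2)
  oracle <- 0
  for (i in seq_len(nrow(data2))) {
    oracle <- oracle + 0.5 * ((pred[i] - data2$value[i]) / data2$sd[i])^2
  }
  expect_equal(negloglik(p, data2), oracle, tolerance = 1e-12)
  # doubling every residual quadruples the value
  data3 <- data2
  data3$value <- pred + 2 * (data2$value - pred)
  expect_equal(negloglik(p, data3), 4 * negloglik(p, data2),
               tolerance = 1e-9)
  expect_error(negloglik(p, transform(data, sd = 0)), "SD")
})

test_that("model fitting recovers a generative binding constant", {
  p <- ner_parameters()
  data <- small_bulk(p, factors = "XPA", times = seq(0, 240, 30))
  fit <- fit_model(data, params = p, free = "kon.XPA.unwound",
                   n_starts = 3, spread = 3, seed = 5)
  expect_equal(unname(fit$estimates[["kon.XPA.unwound"]]), 1 / 0.147,
               tolerance = 0.02)
  # starting exactly at the truth: optimum not improved materially
  expect_lt(fit$nll, 1e-4)
  expect_error(fit_model(data, params = p, free = "kon.XPA.unwound",
                         n_starts = 2), "seed")
})

test_that("profile threshold crossings equal Wald bounds on a quadratic", {
  # linear-Gaussian surrogate: nll(theta) = (theta - mle)^2 / (2 se^2)
  mle <- 2.7
  se <- 0.31
  grid <- mle * 10^seq(-0.5, 0.5, length.out = 201)
  prof <- (grid - mle)^2 / (2 * se^2)
  ci <- nercontrol:::threshold_crossings(grid, prof, mle, 3.84 / 2)
  expect_equal(unname(ci["lower"]), mle - 1.96 * se, tolerance = 2e-3)
  expect_equal(unname(ci["upper"]), mle + 1.96 * se, tolerance = 2e-3)
})

test_that("profile likelihood identifies binding but only bounds catalysis", {
  p <- ner_parameters()
  data <- small_bulk(p, factors = "XPA", times = seq(0, 240, 40))
  fit <- fit_model(data, params = p, free = "kon.XPA.unwound",
                   n_starts = 1, seed = 2)
  prof <- profile_likelihood(data, fit, "kon.XPA.unwound",
                             lower = 0.5, upper = 2, n_grid = 11)
  # profile minimum coincides with the global MLE
  expect_equal(prof$grid[which.min(prof$nll)], prof$mle, tolerance = 0.1)
  expect_true(all(prof$nll >= prof$nll_min - 1e-6))
  expect_error(profile_likelihood(data, fit, "alpha"), "free")
  expect_error(profile_likelihood(data, fit, "kon.XPA.unwound", lower = 2),
               "bracket")

  # a fast catalytic rate (resynthesis) on noisy data: likelihood flat
  # above, rising below (practical non-identifiability from above)
  datan <- small_bulk(p, factors = "XPA", times = seq(0, 240, 40), sd = 0.05,
                      seed = 8)
  fitb <- fit_model(datan, params = p, free = "gamma", n_starts = 1, seed = 2)
  profb <- profile_likelihood(datan, fitb, "gamma", lower = 1e-3,
                              upper = 100, n_grid = 13)
  expect_equal(profb$verdict, "lower bound only")
})

test_that("prediction profile brackets the point prediction", {
  p <- ner_parameters()
  data <- small_bulk(p, factors = "XPA", times = seq(0, 240, 60), sd = 0.05,
                     seed = 21)
  fit <- fit_model(data, params = p, free = "kon.XPA.unwound",
                   n_starts = 1, seed = 4)
  pred <- prediction_profile(data, fit,
                             function(q) q$kon["XPA", "unwound"],
                             rel_range = 0.4, n_grid = 9)
  expect_true(pred$ci95["lower"] <= pred$point)
  expect_true(pred$ci95["upper"] >= pred$point)
  # consistency with the parameter's own profile: the prediction interval
  # of the identity predictor matches the profile interval direction-wise
  prof <- profile_likelihood(data, fit, "kon.XPA.unwound",
                             lower = 0.5, upper = 2, n_grid = 11)
  if (is.finite(prof$ci95["lower"]) && is.finite(pred$ci95["lower"])) {
    expect_equal(unname(pred$ci95["lower"]), unname(prof$ci95["lower"]),
                 tolerance = 0.15)
  }
})

test_that("profile confidence intervals cover the generative truth", {
  p <- ner_parameters()
  truth <- 1 / 0.147
  covered <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    data <- small_bulk(p, factors = "XPA", times = seq(0, 240, 40),
                       sd = 0.05, seed = 100 + r)
    fit <- fit_model(data, params = p, free = "kon.XPA.unwound",
                     n_starts = 1, seed = r)
    prof <- profile_likelihood(data, fit, "kon.XPA.unwound",
                               lower = 0.6, upper = 1 / 0.6, n_grid = 13)
    lo <- prof$ci95["lower"]; hi <- prof$ci95["upper"]
    if (is.na(lo)) lo <- -Inf
    if (is.na(hi)) hi <- Inf
    if (truth >= lo && truth <= hi) covered <- covered + 1L
  }
  expect_gte(covered, 17L)
})

test_that("datasets survive a CSV round trip", {
  p <- ner_parameters()
  d <- small_bulk(p, times = seq(0, 120, 60))
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path)
  expect_equal(d2$value, d$value)
  expect_equal(d2$time_min, d$time_min)
  expect_equal(d2$observable, d$observable)
  unlink(path)
  expect_error(read_dataset(write_dataset(data.frame(a = 1), path)),
               "columns")
  unlink(path)
})
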