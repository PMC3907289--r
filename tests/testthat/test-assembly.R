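test_that("chain construction matches the assembly schemes", {
  seq3 <- build_assembly_chain(assembly_scheme(3, "sequential"))
  expect_equal(seq3$state_labels, c("x0", "x1", "x2", "x3", "repaired"))
  expect_equal(nrow(seq3$generator), 5)

  rnd3 <- build_assembly_chain(assembly_scheme(3, "random"))
  expect_equal(nrow(rnd3$generator), 2^3 + 1)
  expect_true("xABC" %in% rnd3$state_labels)

  # generator structure: transient rows sum to zero, off-diagonals
  # non-negative, single absorbing state with an all-zero row
  for (chain in list(seq3, rnd3)) {
    Q <- chain$generator
    expect_equal(rowSums(Q), rep(0, nrow(Q)), tolerance = 1e-12)
    off <- Q
    diag(off) <- 0
    expect_true(all(off >= 0))
    expect_equal(Q[chain$absorbing, ], rep(0, ncol(Q)))
  }

  # with one component the assembly order is immaterial
  s1 <- build_assembly_chain(assembly_scheme(1, "sequential", 2, 0.5, 100))
  r1 <- build_assembly_chain(assembly_scheme(1, "random", 2, 0.5, 100))
  expect_equal(s1$generator, r1$generator)
})

test_that("invalid schemes are rejected", {
  expect_error(assembly_scheme(0, "random"), "n_components")
  expect_error(assembly_scheme(3, "random", k_on = -1), "k_on")
  expect_error(assembly_scheme(3, "random", k_off = -1), "k_off")
  expect_error(assembly_scheme(17, "random"), "state space")
  expect_error(assembly_scheme(3, "random", rho = 0), "rho")
  expect_error(completion_curve(assembly_scheme(2, "random"), c(3, 1, 2)),
               "non-decreasing")
})

test_that("mean repair times match closed forms and the recursion oracle", {
  # two-state closed form: 1/k + (1 + l/k)/rho
  for (pars in list(c(1, 1, 600), c(0.5, 2, 10), c(3, 0.1, 50))) {
    k <- pars[1]; l <- pars[2]; rho <- pars[3]
    closed <- 1 / k + (1 + l / k) / rho
    expect_equal(mean_repair_time(assembly_scheme(1, "random", k, l, rho)),
                 closed, tolerance = 1e-12)
    expect_equal(mean_repair_time(assembly_scheme(1, "sequential", k, l, rho)),
                 closed, tolerance = 1e-12)
  }
  # irreversible sequential: sum of independent exponential stages
  expect_equal(mean_repair_time(assembly_scheme(3, "sequential", 1, 0, 600)),
               3 / 1 + 1 / 600, tolerance = 1e-12)
  # subset-chain solve vs the independent birth-death recursion
  for (N in c(2, 5, 9)) {
    expect_equal(mean_repair_time(assembly_scheme(N, "random", 1, 1, 600)),
                 bd_mfpt_recursion(N, 1, 1, 600), tolerance = 1e-9)
  }
  # frozen reference: nine rapidly exchanging components produce an
  # hour-range mean repair time from minute-scale rates
  t9 <- mean_repair_time(assembly_scheme(9, "random", 1, 1, 600))
  expect_equal(t9, 68.3073015873, tolerance = 1e-9)
  expect_gt(t9, 50)
  expect_lt(t9, 90)
})

test_that("sequential and random mechanisms give similar mean times", {
  for (N in 1:10) {
    ts <- mean_repair_time(assembly_scheme(N, "sequential", 1, 1, 600))
    tr <- mean_repair_time(assembly_scheme(N, "random", 1, 1, 600))
    expect_lt(max(ts / tr, tr / ts), 3)
  }
})

test_that("completion curves behave and match the product-law oracle", {
  times <- seq(0, 30, 0.25)
  sch <- assembly_scheme(4, "random", 0.3, 0, 5000)
  F <- completion_curve(sch, times)
  expect_equal(F[1], 0)
  expect_true(all(F >= 0 & F <= 1))
  expect_true(all(diff(F) >= -1e-10))
  # near-instant catalysis: independent-site product law
  expect_equal(F, irreversible_completion(4, 0.3, times), tolerance = 2e-3)
  # reversible scheme tends to 1
  Frev <- completion_curve(assembly_scheme(3, "random", 1, 1, 600),
                           seq(0, 200, 2))
  expect_gt(Frev[length(Frev)], 0.999)
})

test_that("reversible completion is mono-exponential, irreversible sigmoid", {
  tmean <- mean_repair_time(assembly_scheme(9, "random", 1, 1, 600))
  times <- seq(0, 8 * tmean, length.out = 500)
  Frev <- completion_curve(assembly_scheme(9, "random", 1, 1, 600), times)
  fit <- fit_monoexponential(times, Frev)
  expect_lt(fit$rmse / fit$amplitude, 0.01)
  expect_equal(fit$tau, tmean, tolerance = 0.02)
  # irreversible curve has zero initial slope (sigmoid onset)
  Firr <- completion_curve(assembly_scheme(9, "random", 0.037, 0, 600), times)
  dt <- times[2] - times[1]
  expect_lt(Firr[2] / dt, 1e-6)          # initial slope ~ 0
  late <- which.max(diff(Firr))          # maximal slope away from t = 0
  expect_gt(late, 5)
})

test_that("mono-exponential fitting recovers exact curves", {
  times <- seq(0, 10, 0.25)
  tau <- 1.7241
  fit <- fit_monoexponential(times, 1 - exp(-times / tau))
  expect_equal(fit$tau, tau, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$linear_slope, -1 / tau, tolerance = 1e-6)
  fit2 <- fit_monoexponential(times, 0.4 * (1 - exp(-times / 2.5)))
  expect_equal(fit2$tau, 2.5, tolerance = 1e-6)
  expect_equal(fit2$amplitude, 0.4, tolerance = 1e-6)
  expect_error(fit_monoexponential(c(0, 1), c(0, 1)), ">= 3")
})

test_that("irreversible on-rate matching reproduces the reference regime", {
  # single component, near-instant catalysis: exponential matches
  # exponential, so k_irr is the reciprocal reference time constant
  tau_ref <- mean_repair_time(assembly_scheme(1, "random", 1, 1, 1e6))
  k1 <- match_irreversible_onrate(1, 1, 1, 1e6)
  expect_equal(k1, 1 / tau_ref, tolerance = 1e-4)
  # matched on-rate decreases with complex size at fixed reference rates
  ks <- vapply(2:7, function(N) match_irreversible_onrate(N, 1, 1, 600),
               numeric(1))
  expect_true(all(diff(ks) < 0))
  # both matching criteria agree on the order of magnitude for N = 9
  km <- match_irreversible_onrate(9, 1, 1, 600, method = "mean")
  expect_equal(km, 0.0414163, tolerance = 1e-4)
})

test_that("stochastic sampling is reproducible and consistent with MFPT", {
  sch <- assembly_scheme(3, "random", 1, 1, 600)
  s1 <- sample_repair_times(sch, 200, seed = 42)
  s2 <- sample_repair_times(sch, 200, seed = 42)
  expect_identical(s1, s2)

  n <- 4000
  x <- sample_repair_times(sch, n, seed = 7)
  mu <- mean_repair_time(sch)
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(n))

  # irreversible sequential: variance is the sum of stage variances
  schs <- assembly_scheme(3, "sequential", 2, 0, 10)
  y <- sample_repair_times(schs, 4000, seed = 11)
  var_theory <- 3 / 2^2 + 1 / 10^2
  # SE of a variance estimate, using the excess kurtosis (2) of a
  # three-fold exponential convolution
  se_var <- 2 * var_theory / sqrt(4000)
  expect_lt(abs(var(y) - var_theory), 3 * se_var)
})
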