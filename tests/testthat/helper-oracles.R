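# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (linear first-passage solve, matrix exponential,
# compiled ODE right-hand side).

# Mean first-passage time of the symmetric random assembly scheme reduced
# to a birth-death chain on the occupancy count, solved by the standard
# forward-elimination recursion T_j = a_j + b_j T_{j+1}.
bd_mfpt_recursion <- function(N, k, l, rho) {
  lam <- function(j) (N - j) * k
  mu <- function(j) j * l
  a <- numeric(N + 1)
  b <- numeric(N + 1)
  a[1] <- 1 / lam(0)
  b[1] <- 1
  if (N >= 2) {
    for (j in 1:(N - 1)) {
      d <- lam(j) + mu(j) - mu(j) * b[j]
      a[j + 1] <- (1 + mu(j) * a[j]) / d
      b[j + 1] <- lam(j) / d
    }
  }
  TN <- (1 + mu(N) * a[N]) / (mu(N) + rho - mu(N) * b[N])
  Tj <- TN
  for (j in (N - 1):0) Tj <- a[j + 1] + b[j + 1] * Tj
  Tj
}

# completion law for irreversible random assembly with instantaneous
# catalysis: N independent sites each filled with probability 1 - e^(-kt)
irreversible_completion <- function(N, k, times) (1 - exp(-k * times))^N

# reference parameter set reused across tests
ref_params <- function(...) ner_parameters(list(...))

# small noise-free bulk dataset (no FLIP) for fast fitting tests
small_bulk <- function(params, factors = c("XPC", "XPA"),
                       times = seq(0, 240, 30), seed = 1, sd = 0) {
  d <- generate_bulk_dataset(params,
                             noise_spec("relative", sd, 50, seed = seed),
                             acc_times = times, flip_factors = NULL)
  d[d$observable == "edu" | d$factor %in% factors, ]
}

cv_of <- function(x) stats::sd(x) / mean(x)
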