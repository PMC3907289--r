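#' Replicate-noise specification for synthetic bulk data
#'
#' @param kind \code{"relative"} (noise SD proportional to the signal) or
#'   \code{"absolute"}.
#' @param sd noise magnitude (relative fraction or absolute units).
#' @param n_replicates replicates averaged per time point.
#' @param seed integer seed (mandatory).
#' @return An object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(kind = c("relative", "absolute"), sd = 0.05,
                       n_replicates = 150, seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("'seed' is required")
  if (sd < 0) stop("'sd' must be >= 0")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  structure(list(kind = kind, sd = sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# Gaussian replicates around a noise-free curve; returns mean, empirical SD
replicate_noise <- function(truth, noise) {
  n <- noise$n_replicates
  scale <- if (noise$kind == "relative") {
    pmax(abs(truth), 0.05 * max(abs(truth), 1e-300))
  } else rep(1, length(truth))
  if (noise$sd == 0) {
    # exact curves; SD kept usable as a weight (1% of the curve maximum)
    return(data.frame(value = truth,
                      sd = rep(0.01 * max(abs(truth), 1e-12), length(truth)),
                      n = n))
  }
  if (n == 1) {
    return(data.frame(value = truth + stats::rnorm(length(truth), 0,
                                                   noise$sd * scale),
                      sd = noise$sd * scale, n = n))
  }
  reps <- matrix(stats::rnorm(n * length(truth), mean = rep(truth, each = n),
                              sd = rep(noise$sd * scale, each = n)),
                 nrow = n)
  data.frame(value = colMeans(reps), sd = apply(reps, 2, stats::sd), n = n)
}

#' Generate a synthetic bulk time-course dataset from the pathway model
#'
#' Simulates the model at \code{params} and emits a dataset in the
#' standard schema (see \code{\link{read_dataset}}) containing the
#' accumulation time courses of all seven factors, the EdU incorporation
#' curve, and FLIP curves per factor, each with Gaussian replicate noise;
#' the SD column is the empirical replicate SD (or the nominal SD when
#' \code{sd = 0}, so it stays usable as a weight).
#'
#' @param params generative parameter set.
#' @param noise a \code{\link{noise_spec}}.
#' @param acc_times accumulation/EdU time grid (minutes).
#' @param flip_times FLIP time grid (minutes since bleach; 5-s steps over
#'   5 min by default, matching the seconds-to-minutes dwell times).
#' @param flip_start bleach start time (minutes).
#' @param flip_factors factors for which FLIP curves are generated
#'   (default all seven; set \code{NULL} to skip FLIP).
#' @return Dataset data.frame.
#' @export
generate_bulk_dataset <- function(params, noise,
                                  acc_times = seq(0, 240, by = 10),
                                  flip_times = seq(0, 5, by = 5 / 60),
                                  flip_start = 30,
                                  flip_factors = ner_factors) {
  stopifnot(inherits(params, "ner_parameters"), inherits(noise, "noise_spec"))
  traj <- ner_simulate(params, sort(unique(c(0, acc_times))))
  set.seed(noise$seed)
  pieces <- list()
  for (f in ner_factors) {
    curve <- observe(traj, "accumulation", factor = f)
    curve <- curve[curve$time_min %in% acc_times, ]
    nn <- replicate_noise(curve$value, noise)
    pieces[[length(pieces) + 1L]] <-
      data.frame(observable = "accumulation", factor = f,
                 time_min = curve$time_min, nn)
  }
  edu <- observe(traj, "edu")
  edu <- edu[edu$time_min %in% acc_times, ]
  nn <- replicate_noise(edu$value, noise)
  pieces[[length(pieces) + 1L]] <-
    data.frame(observable = "edu", factor = NA, time_min = edu$time_min, nn)
  for (f in flip_factors) {
    curve <- flip_curve(params, flip_start, flip_times, f)
    nn <- replicate_noise(curve$value, noise)
    pieces[[length(pieces) + 1L]] <-
      data.frame(observable = "flip", factor = f,
                 time_min = curve$time_min, nn)
  }
  out <- do.call(rbind, pieces)
  # weights must stay strictly positive even where a curve is still zero
  out$sd <- pmax(out$sd, 0.01 * stats::median(out$sd))
  rownames(out) <- NULL
  out
}

#' Generate noisy first-order EdU incorporation curves
#'
#' Replicate single-exponential repair curves
#' \eqn{EdU_{max}(1 - e^{-\lambda t})} with additive Gaussian noise, as a
#' generative model for time-resolved repair-synthesis measurements.
#'
#' @param lambda first-order rate constant (h^-1).
#' @param edu_max saturation amplitude.
#' @param times time grid in hours.
#' @param noise a \code{\link{noise_spec}}; \code{n_replicates} is the
#'   number of independent curves.
#' @return data.frame with columns \code{replicate}, \code{time_h},
#'   \code{value}.
#' @examples
#' generate_edu_curves(0.58, 1, seq(0, 4, 0.5),
#'                     noise_spec("absolute", 0.05, 3, seed = 1))
#' @export
generate_edu_curves <- function(lambda, edu_max = 1, times = seq(0, 4, 0.5),
                                noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (lambda <= 0) stop("'lambda' must be > 0")
  truth <- edu_max * (1 - exp(-lambda * times))
  scale <- if (noise$kind == "relative") {
    pmax(abs(truth), 0.05 * max(abs(truth), 1e-300))
  } else rep(1, length(times))
  set.seed(noise$seed)
  do.call(rbind, lapply(seq_len(noise$n_replicates), function(r) {
    data.frame(replicate = r, time_h = times,
               value = truth + stats::rnorm(length(times), 0, noise$sd * scale))
  }))
}

#' Generate paired two-channel measurements of a variable signal
#'
#' Lognormal true signal (given CV) measured in two channels, each
#' multiplied by independent lognormal measurement noise of the given
#' relative error — the generative model behind the error-ellipse
#' estimator.
#'
#' @param n number of cells (>= 2).
#' @param signal_cv CV of the true signal distribution.
#' @param relative_error relative per-channel measurement error (e.g.
#'   0.11 for 11\%).
#' @param seed integer seed (mandatory).
#' @param mean_signal mean of the true signal (arbitrary units).
#' @return data.frame with columns \code{truth}, \code{channel1},
#'   \code{channel2}.
#' @examples
#' pairs <- generate_paired_measurements(332, 0.3, 0.11, seed = 1)
#' error_ellipse(pairs$channel1, pairs$channel2)$relative_error
#' @export
generate_paired_measurements <- function(n, signal_cv, relative_error, seed,
                                         mean_signal = 1) {
  if (missing(seed)) stop("'seed' is required")
  if (n < 2) stop("'n' must be >= 2")
  if (signal_cv < 0 || relative_error < 0) stop("CVs must be >= 0")
  set.seed(seed)
  truth <- rlnorm_mean_cv(n, mean_signal, signal_cv)
  data.frame(truth = truth,
             channel1 = truth * rlnorm_mean_cv(n, 1, relative_error),
             channel2 = truth * rlnorm_mean_cv(n, 1, relative_error))
}
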