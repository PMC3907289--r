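#' Fit first-order repair kinetics to an EdU time course
#'
#' Weighted least-squares fit of the single-exponential repair law
#' \eqn{EdU(t) = EdU_{max} (1 - e^{-\lambda t})} to a repair DNA synthesis
#' time course, with the linearised diagnostic slope of
#' \eqn{\log(1 - EdU/EdU_{max})} against time.
#'
#' @param times time points in hours.
#' @param values EdU incorporation (same arbitrary unit as the plateau).
#' @param sds optional standard deviations used as weights (1/sd^2).
#' @return An object of class \code{"edu_fit"}: \code{lambda} (h^-1),
#'   \code{edu_max}, \code{half_time} (h, = log(2)/lambda), \code{ci}
#'   (asymptotic 95\% intervals), \code{linear_slope}, \code{rmse}.
#' @examples
#' t <- seq(0, 4, 0.5)
#' fit_first_order(t, 1 - exp(-0.58 * t))
#' @export
fit_first_order <- function(times, values, sds = NULL) {
  if (length(times) < 3) stop("need >= 3 time points")
  dat <- data.frame(t = times, y = values)
  w <- if (is.null(sds)) rep(1, length(times)) else {
    if (any(sds <= 0)) stop("'sds' must be > 0 where supplied")
    1 / sds^2
  }
  fit <- minpack.lm::nlsLM(y ~ A * (1 - exp(-lambda * t)), data = dat,
                           start = list(A = max(values), lambda = 0.5),
                           weights = w, lower = c(1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- stats::coef(fit)
  lambda <- co[["lambda"]]; A <- co[["A"]]
  if (!is.finite(lambda) || lambda <= 0) {
    stop("first-order fit failed: non-positive rate constant")
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA_real_, lambda = NA_real_))
  frac <- values / A
  keep <- is.finite(frac) & frac < 0.99 & frac >= 0
  slope <- if (sum(keep) >= 2) {
    unname(stats::coef(stats::lm(log(1 - frac[keep]) ~ times[keep]))[2])
  } else NA_real_
  structure(list(
    lambda = lambda, edu_max = A, half_time = log(2) / lambda,
    ci = list(lambda = lambda + c(-1.96, 1.96) * se[["lambda"]],
              edu_max = A + c(-1.96, 1.96) * se[["A"]]),
    linear_slope = slope,
    rmse = sqrt(mean(stats::residuals(fit)^2)), fit = fit
  ), class = "edu_fit")
}

#' @export
print.edu_fit <- function(x, ...) {
  cat(sprintf("First-order repair fit: lambda = %.3f h^-1 (95%% CI %.3f-%.3f)\n",
              x$lambda, x$ci$lambda[1], x$ci$lambda[2]))
  cat(sprintf("  half-time = %.2f h, plateau = %.4g, rmse = %.3g\n",
              x$half_time, x$edu_max, x$rmse))
  invisible(x)
}

#' Read / write a bulk experiment dataset
#'
#' Datasets are tables of time-course observations with columns
#' \code{observable} (accumulation, edu, incised or flip), \code{factor}
#' (factor name or NA), \code{time_min}, \code{value}, \code{sd},
#' \code{n}. FLIP rows carry time in minutes since the bleach start.
#'
#' @param data dataset data.frame.
#' @param path CSV file path.
#' @return \code{read_dataset} returns the dataset data.frame.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observable", "factor", "time_min", "value", "sd", "n")
  if (!all(need %in% names(d))) {
    stop("dataset must have columns: ", paste(need, collapse = ", "))
  }
  d
}

# model predictions aligned to the rows of a dataset
predict_dataset <- function(params, data, flip_start = 30) {
  pred <- numeric(nrow(data))
  bulk <- data$observable != "flip"
  if (any(bulk)) {
    grid <- sort(unique(c(0, data$time_min[bulk])))
    traj <- ner_simulate(params, grid)
    for (grp in split(which(bulk), paste(data$observable[bulk],
                                         data$factor[bulk]))) {
      kind <- data$observable[grp[1]]
      fac <- data$factor[grp[1]]
      curve <- observe(traj, kind,
                       factor = if (kind == "accumulation") fac else NULL)
      pred[grp] <- curve$value[match(data$time_min[grp], curve$time_min)]
    }
  }
  for (grp in split(which(!bulk), data$factor[!bulk])) {
    ft <- sort(unique(c(0, data$time_min[grp])))
    curve <- flip_curve(params, flip_start, ft, data$factor[grp[1]])
    pred[grp] <- curve$value[match(data$time_min[grp], curve$time_min)]
  }
  pred
}

#' Gaussian negative log-likelihood of a parameter set
#'
#' One half the sum of squared standardised residuals,
#' \eqn{\frac12 \sum ((model - mean)/SD)^2}, over all dataset rows.
#'
#' @param params a \code{\link{ner_parameters}} object.
#' @param data a dataset (see \code{\link{read_dataset}}).
#' @param flip_start bleach start time used for FLIP rows (minutes).
#' @return Scalar negative log-likelihood (up to the constant term).
#' @export
negloglik <- function(params, data, flip_start = 30) {
  if (any(data$sd <= 0)) stop("dataset SD must be > 0 (used as weights)")
  pred <- predict_dataset(params, data, flip_start)
  0.5 * sum(((pred - data$value) / data$sd)^2)
}

param_get <- function(params, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) params[[name]]
  else if (parts[1] == "totals") params$totals[[parts[2]]]
  else params[[parts[1]]][parts[2], parts[3]]
}

param_set <- function(params, names, values) {
  apply_overrides(params, stats::setNames(as.list(values), names))
}

#' Maximum-likelihood fit of the NER model
#'
#' Multi-start local minimisation of \code{\link{negloglik}} over a
#' declared set of free parameters, in log10 parameter space with box
#' bounds. Starts are a Latin hypercube around the centre (the values in
#' \code{params}), spread multiplicatively by \code{spread}.
#'
#' @param data dataset to fit.
#' @param params base parameter set; also the multi-start centre. All
#'   parameters not listed in \code{free} stay fixed at these values.
#' @param free character vector of free parameter names in override
#'   notation, e.g. \code{c("kon.XPA.unwound", "kon.XPC.damaged")}.
#' @param n_starts number of optimisation starts (first start is the
#'   unperturbed centre).
#' @param spread multiplicative half-width of the start perturbations.
#' @param bounds multiplicative box bounds relative to the centre values.
#' @param seed integer seed for the start design (mandatory).
#' @param flip_start bleach start time for FLIP rows (minutes).
#' @return An object of class \code{"ner_fit"}: \code{params} (best-fit
#'   parameter set), \code{estimates} (named vector), \code{nll},
#'   \code{starts} (per-start log), \code{converged}, \code{free},
#'   \code{residuals} table.
#' @export
fit_model <- function(data, params = ner_parameters(), free, n_starts = 10,
                      spread = 3, bounds = c(1e-4, 1e4), seed,
                      flip_start = 30) {
  if (missing(seed)) stop("'seed' is required")
  if (missing(free) || length(free) == 0) stop("declare free parameters")
  center <- vapply(free, function(nm) param_get(params, nm), numeric(1))
  if (any(center <= 0)) stop("free parameters must be positive (log-scale fit)")
  lo <- log10(center * bounds[1]); hi <- log10(center * bounds[2])

  nll_log10 <- function(lp) {
    p <- param_set(params, free, 10^lp)
    tryCatch(negloglik(p, data, flip_start), error = function(e) 1e12)
  }
  set.seed(seed)
  starts <- matrix(log10(center), n_starts, length(free), byrow = TRUE)
  if (n_starts > 1) {
    u <- lhs::randomLHS(n_starts - 1, length(free))
    starts[-1, ] <- sweep(sweep(u * 2 - 1, 2, log10(spread), "*"), 2,
                          log10(center), "+")
  }
  runs <- lapply(seq_len(n_starts), function(i) {
    res <- tryCatch(
      stats::optim(starts[i, ], nll_log10, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 300, factr = 1e7)),
      error = function(e) list(par = starts[i, ], value = Inf, convergence = 99))
    list(start = 10^starts[i, ], par = 10^res$par, nll = res$value,
         converged = identical(res$convergence, 0L) || res$convergence == 0)
  })
  nlls <- vapply(runs, `[[`, numeric(1), "nll")
  if (all(!is.finite(nlls))) stop("all optimisation starts failed")
  best <- runs[[which.min(nlls)]]
  best_params <- param_set(params, free, best$par)
  pred <- predict_dataset(best_params, data, flip_start)
  structure(list(
    params = best_params,
    estimates = stats::setNames(best$par, free),
    nll = best$nll, free = free,
    starts = data.frame(
      start = I(lapply(runs, `[[`, "start")),
      nll = nlls,
      converged = vapply(runs, `[[`, logical(1), "converged")),
    converged = best$converged,
    residuals = cbind(data, model = pred,
                      weighted_residual = (pred - data$value) / data$sd),
    data = data, flip_start = flip_start
  ), class = "ner_fit")
}

#' @export
print.ner_fit <- function(x, ...) {
  cat("NER model fit:", length(x$free), "free parameter(s),",
      nrow(x$data), "observations\n")
  cat(sprintf("  nll = %.6g (%d/%d starts converged)\n", x$nll,
              sum(x$starts$converged), nrow(x$starts)))
  print(signif(x$estimates, 4))
  invisible(x)
}

#' Profile likelihood of one fitted parameter
#'
#' Re-optimises the remaining free parameters while stepping one parameter
#' over a grid, giving the profile negative log-likelihood and the 95\%
#' confidence interval where \eqn{2\,\Delta NLL \le 3.84} (chi-squared,
#' one degree of freedom). Flags practical non-identifiability when a
#' bound is not crossed inside the grid.
#'
#' @param data dataset used for the fit.
#' @param fit a \code{"ner_fit"} object.
#' @param parameter name of the profiled parameter (must be in
#'   \code{fit$free}).
#' @param lower,upper multiplicative grid range relative to the MLE.
#' @param n_grid number of grid points.
#' @return An object of class \code{"profile_curve"}: \code{parameter},
#'   \code{grid}, \code{nll}, \code{nll_min}, \code{ci95} (with NA for an
#'   uncrossed bound), \code{verdict} (one of "identifiable",
#'   "lower bound only", "upper bound only", "unbounded").
#' @export
profile_likelihood <- function(data, fit, parameter, lower = 0.1,
                               upper = 10, n_grid = 15) {
  stopifnot(inherits(fit, "ner_fit"))
  if (!parameter %in% fit$free) stop("'parameter' must be one of the fitted free parameters")
  if (lower >= 1 || upper <= 1) stop("grid must bracket the MLE (lower < 1 < upper)")
  mle <- fit$estimates[[parameter]]
  grid <- mle * 10^seq(log10(lower), log10(upper), length.out = n_grid)
  others <- setdiff(fit$free, parameter)
  prof <- vapply(grid, function(v) {
    pfix <- param_set(fit$params, parameter, v)
    if (length(others) == 0) {
      tryCatch(negloglik(pfix, data, fit$flip_start), error = function(e) NA_real_)
    } else {
      start <- log10(vapply(others, function(nm) param_get(fit$params, nm),
                            numeric(1)))
      obj <- function(lp) {
        p <- param_set(pfix, others, 10^lp)
        tryCatch(negloglik(p, data, fit$flip_start), error = function(e) 1e12)
      }
      tryCatch(stats::optim(start, obj, method = "L-BFGS-B",
                            lower = start - 4, upper = start + 4,
                            control = list(maxit = 200))$value,
               error = function(e) NA_real_)
    }
  }, numeric(1))
  nll_min <- min(c(prof, fit$nll), na.rm = TRUE)
  thr <- nll_min + 3.84 / 2
  ci <- threshold_crossings(grid, prof, mle, thr)
  verdict <- if (!is.na(ci[1]) && !is.na(ci[2])) "identifiable"
  else if (!is.na(ci[1])) "lower bound only"
  else if (!is.na(ci[2])) "upper bound only"
  else "unbounded"
  structure(list(parameter = parameter, grid = grid, nll = prof,
                 nll_min = nll_min, mle = mle, ci95 = ci, verdict = verdict),
            class = "profile_curve")
}

# interpolated crossings of the profile with the 95% threshold
threshold_crossings <- function(grid, prof, mle, thr) {
  ok <- is.finite(prof)
  g <- grid[ok]; p <- prof[ok]
  lower <- NA_real_; upper <- NA_real_
  cross <- function(i, j) {
    # linear interpolation in log-parameter space
    lg <- log(g)
    exp(lg[i] + (thr - p[i]) * (lg[j] - lg[i]) / (p[j] - p[i]))
  }
  left <- which(g <= mle & p > thr)
  if (length(left)) {
    i <- max(left)
    if (i < length(g)) lower <- cross(i, i + 1)
  }
  right <- which(g >= mle & p > thr)
  if (length(right)) {
    j <- min(right)
    if (j > 1) upper <- cross(j - 1, j)
  }
  c(lower = lower, upper = upper)
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("Profile likelihood for %s: MLE = %.4g, verdict: %s\n",
              x$parameter, x$mle, x$verdict))
  cat(sprintf("  95%% CI: [%s, %s]\n",
              format(x$ci95[1], digits = 4), format(x$ci95[2], digits = 4)))
  invisible(x)
}

#' Prediction profile likelihood of a derived quantity
#'
#' Confidence interval for a scalar prediction by constrained
#' re-optimisation along the prediction axis (penalty formulation): for
#' each target value c of the prediction, the free parameters are
#' re-optimised under a quadratic penalty pulling the prediction to c, and
#' the 95\% interval collects the c with \eqn{2\,\Delta NLL \le 3.84}.
#'
#' @param data dataset used for the fit.
#' @param fit a \code{"ner_fit"} object.
#' @param predictor function mapping a \code{ner_parameters} object to a
#'   scalar prediction.
#' @param rel_range half-width of the scanned prediction range, relative
#'   to max(|point prediction|, \code{abs_range}).
#' @param abs_range absolute floor for the scan half-width.
#' @param n_grid grid points along the prediction axis.
#' @param penalty penalty weight (in units of NLL per squared prediction
#'   mismatch, scaled by the grid step).
#' @return List with \code{point} (point prediction), \code{grid},
#'   \code{nll}, \code{ci95}.
#' @export
prediction_profile <- function(data, fit, predictor, rel_range = 0.5,
                               abs_range = 0.05, n_grid = 11,
                               penalty = NULL) {
  stopifnot(inherits(fit, "ner_fit"))
  point <- predictor(fit$params)
  half <- max(abs(point) * rel_range, abs_range)
  grid <- seq(point - half, point + half, length.out = n_grid)
  step <- grid[2] - grid[1]
  if (is.null(penalty)) penalty <- 100 / step^2
  start0 <- log10(fit$estimates)
  prof <- vapply(grid, function(cc) {
    obj <- function(lp) {
      p <- param_set(fit$params, fit$free, 10^lp)
      val <- tryCatch(negloglik(p, data, fit$flip_start) +
                        penalty * (predictor(p) - cc)^2,
                      error = function(e) 1e12)
      val
    }
    res <- tryCatch(stats::optim(start0, obj, method = "L-BFGS-B",
                                 lower = start0 - 3, upper = start0 + 3,
                                 control = list(maxit = 200)),
                    error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    p <- param_set(fit$params, fit$free, 10^res$par)
    tryCatch(negloglik(p, data, fit$flip_start), error = function(e) NA_real_)
  }, numeric(1))
  if (all(!is.finite(prof))) stop("prediction profile solve diverged at all grid points")
  nll_min <- min(c(prof, fit$nll), na.rm = TRUE)
  thr <- nll_min + 3.84 / 2
  ok <- is.finite(prof)
  g <- grid[ok]; pr <- prof[ok]
  if (min(pr) > thr) {
    return(list(point = point, grid = grid, nll = prof,
                ci95 = c(lower = NA_real_, upper = NA_real_)))
  }
  ctr <- which.min(pr)
  cross <- function(i, j) g[i] + (thr - pr[i]) * (g[j] - g[i]) / (pr[j] - pr[i])
  lower <- if (pr[1] > thr) {
    i <- max(which(seq_along(g) < ctr & pr > thr))
    cross(i, i + 1)
  } else g[1]
  upper <- if (pr[length(pr)] > thr) {
    j <- min(which(seq_along(g) > ctr & pr > thr))
    cross(j, j - 1)
  } else g[length(g)]
  list(point = point, grid = grid, nll = prof,
       ci95 = c(lower = lower, upper = upper))
}
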