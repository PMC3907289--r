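#' Specify a simulated cell population
#'
#' Cell-to-cell variability model: per-cell factor concentrations are
#' drawn from lognormal distributions with the reference means and given
#' CVs, and the per-cell lesion dose from a lognormal with CV
#' \code{cv_lesions} (or by resampling an empirical dose vector).
#' Lognormals are parameterised mean-preservingly: the arithmetic mean
#' equals the reference value exactly for any CV.
#'
#' @param n_cells number of cells (>= 2). Default 300 (several hundred
#'   cells, as in the damage-spot experiments).
#' @param cv_factors per-factor lognormal CVs (single value recycled;
#'   default 0.25, the typical width of expression distributions).
#' @param cv_lesions CV of the lesion dose (default 0.32, the width of
#'   the measured initial 6-4PP distribution).
#' @param times_min observation times in minutes.
#' @param seed integer seed (mandatory).
#' @param sources_enabled character vector naming the variable sources:
#'   any subset of the factor names and \code{"lesions"}. Everything else
#'   is held at its mean (used for variance decomposition).
#' @param dose_sample optional empirical lesion-dose vector resampled in
#'   place of the lognormal (values rescaled to mean \code{lesions0}).
#' @return An object of class \code{"population_spec"}.
#' @export
population_spec <- function(n_cells = 300, cv_factors = 0.25,
                            cv_lesions = 0.32, times_min = c(30, 240),
                            seed, sources_enabled = c(ner_factors, "lesions"),
                            dose_sample = NULL) {
  if (missing(seed)) stop("'seed' is required")
  if (n_cells < 2) stop("'n_cells' must be >= 2")
  if (any(cv_factors < 0) || cv_lesions < 0) stop("CVs must be >= 0")
  bad <- setdiff(sources_enabled, c(ner_factors, "lesions"))
  if (length(bad)) stop("unknown variability sources: ", paste(bad, collapse = ", "))
  structure(list(n_cells = as.integer(n_cells),
                 cv_factors = stats::setNames(rep_len(cv_factors, 7), ner_factors),
                 cv_lesions = cv_lesions, times_min = times_min,
                 seed = as.integer(seed), sources_enabled = sources_enabled,
                 dose_sample = dose_sample),
            class = "population_spec")
}

# lognormal with exact arithmetic mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a heterogeneous cell population
#'
#' Draws per-cell factor concentrations and lesion doses, solves the NER
#' model once per cell, and records factor accumulation and EdU
#' incorporation at the requested times.
#'
#' @param params reference (mean) parameter set.
#' @param spec a \code{\link{population_spec}}.
#' @return A data.frame (one row per cell) with columns \code{cell_id},
#'   \code{lesion_dose_uM}, \code{conc_<factor>_uM},
#'   \code{acc_<factor>_<t>min}, \code{edu_<t>min} and \code{rate_<t>min}
#'   (instantaneous repair-synthesis flux, local uM/min); cells whose
#'   integration failed are dropped with a warning (attribute
#'   \code{n_failed}).
#' @examples
#' \donttest{
#' cells <- simulate_population(ner_parameters(),
#'                              population_spec(n_cells = 20, seed = 1))
#' }
#' @export
simulate_population <- function(params, spec) {
  stopifnot(inherits(params, "ner_parameters"),
            inherits(spec, "population_spec"))
  n <- spec$n_cells
  set.seed(spec$seed)
  conc <- sapply(ner_factors, function(f) {
    cv <- if (f %in% spec$sources_enabled) spec$cv_factors[[f]] else 0
    rlnorm_mean_cv(n, params$totals[[f]], cv)
  })
  dose <- if ("lesions" %in% spec$sources_enabled) {
    if (!is.null(spec$dose_sample)) {
      sample(spec$dose_sample, n, replace = TRUE) *
        params$lesions0 / mean(spec$dose_sample)
    } else {
      rlnorm_mean_cv(n, params$lesions0, spec$cv_lesions)
    }
  } else rep(params$lesions0, n)

  grid <- sort(unique(c(0, spec$times_min)))
  rows <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    p <- params
    p$totals[] <- conc[i, ]
    p$lesions0 <- dose[i]
    traj <- tryCatch(ner_simulate(p, grid), error = function(e) NULL)
    if (is.null(traj)) {
      n_failed <- n_failed + 1L
      next
    }
    ti <- match(spec$times_min, traj$times)
    acc <- apply(traj$B, c(1, 2), sum)[ti, , drop = FALSE]
    flux <- synthesis_flux(traj)
    row <- c(cell_id = i, lesion_dose_uM = dose[i],
             stats::setNames(conc[i, ], paste0("conc_", ner_factors, "_uM")))
    for (j in seq_along(spec$times_min)) {
      t <- spec$times_min[j]
      row <- c(row,
               stats::setNames(acc[j, ], sprintf("acc_%s_%dmin", ner_factors, t)),
               stats::setNames(traj$edu[ti[j]], sprintf("edu_%dmin", t)),
               stats::setNames(flux[ti[j]], sprintf("rate_%dmin", t)))
    }
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (n_failed > 0) {
    warning(n_failed, " cell(s) dropped due to integration failure")
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "n_failed") <- n_failed
  out
}

#' Pearson correlation with bootstrap confidence bounds
#'
#' Pearson correlation coefficient with a non-parametric (percentile)
#' bootstrap 95\% confidence interval.
#'
#' @param x,y paired measurements (length >= 3).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed (mandatory).
#' @return List with \code{r} and \code{ci95}.
#' @examples
#' correlate(1:20, (1:20) + rnorm(20), seed = 1)
#' @export
correlate <- function(x, y, n_boot = 1000, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (length(x) != length(y) || length(x) < 3) {
    stop("'x' and 'y' must be paired with length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  r <- stats::cor(x, y)
  set.seed(seed)
  n <- length(x)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i])
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(r = r, ci95 = ci)
}

#' Decompose population variability by source
#'
#' Runs the population simulation with one variability source enabled at
#' a time (each factor individually, the lesion dose alone) plus an
#' all-sources run, and reports the CV of EdU incorporation at each
#' observation time per run.
#'
#' @param params reference parameter set.
#' @param spec a \code{\link{population_spec}}; its
#'   \code{sources_enabled} is overridden per run, everything else
#'   (including the seed) is reused.
#' @return data.frame with columns \code{source}, \code{time_min},
#'   \code{cv}.
#' @export
variance_decomposition <- function(params, spec) {
  stopifnot(inherits(spec, "population_spec"))
  sources <- c(as.list(ner_factors), list("lesions"),
               list(c(ner_factors, "lesions")))
  names(sources) <- c(ner_factors, "lesions", "all")
  out <- lapply(names(sources), function(nm) {
    sp <- spec
    sp$sources_enabled <- sources[[nm]]
    cells <- simulate_population(params, sp)
    data.frame(source = nm, time_min = spec$times_min,
               cv = vapply(spec$times_min, function(t) {
                 v <- cells[[sprintf("edu_%dmin", t)]]
                 stats::sd(v) / mean(v)
               }, numeric(1)))
  })
  do.call(rbind, out)
}

#' Relative measurement error from paired two-channel measurements
#'
#' Fits an error ellipse to log-transformed paired measurements of the
#' same quantity in two channels (e.g. GFP fluorescence versus antibody
#' staining). The variance along the minor principal axis is attributed
#' to measurement noise; under equal noise in both channels it equals the
#' per-channel log-scale noise variance, which is converted back to a
#' relative (lognormal CV) error. Optionally the whole minor-axis
#' variance can be attributed to a single channel.
#'
#' @param x,y paired positive measurements (n >= 10).
#' @param attribution \code{"equal"} (default) splits the noise equally
#'   between channels; \code{"single"} attributes it to one channel.
#' @return List with \code{relative_error} (percent), \code{r} (Pearson
#'   correlation of the log channels), \code{sd_log} (per-channel
#'   log-scale noise SD).
#' @examples
#' s <- exp(rnorm(200, 0, 0.3))
#' error_ellipse(s * exp(rnorm(200, 0, 0.1)), s * exp(rnorm(200, 0, 0.1)))
#' @export
error_ellipse <- function(x, y, attribution = c("equal", "single")) {
  attribution <- match.arg(attribution)
  if (length(x) != length(y) || length(x) < 10) {
    stop("need >= 10 paired measurements")
  }
  if (any(x <= 0) || any(y <= 0)) stop("measurements must be positive")
  lx <- log(x); ly <- log(y)
  S <- stats::cov(cbind(lx, ly))
  ev <- eigen(S, symmetric = TRUE)$values
  minor <- max(ev[2], 0)
  var_channel <- if (attribution == "equal") minor else 2 * minor
  sd_log <- sqrt(var_channel)
  list(relative_error = 100 * sqrt(exp(sd_log^2) - 1),
       r = stats::cor(lx, ly), sd_log = sd_log)
}
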