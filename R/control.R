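#' Instantaneous pathway rate at an evaluation time
#'
#' The repair-synthesis flux J_gamma (target \code{"repair_rate"}) or the
#' dual-incision flux J_beta (target \code{"incision_rate"}) at time
#' \code{t_eval}, computed from a fresh simulation.
#'
#' @param params a \code{\link{ner_parameters}} object.
#' @param target \code{"repair_rate"} or \code{"incision_rate"}.
#' @param t_eval evaluation time in minutes (> 0).
#' @return Flux in local uM min^-1.
#' @export
pathway_rate <- function(params, target = c("repair_rate", "incision_rate"),
                         t_eval = 30) {
  target <- match.arg(target)
  if (t_eval <= 0) stop("'t_eval' must be > 0")
  traj <- ner_simulate(params, seq(0, t_eval, length.out = 5))
  i <- length(traj$times)
  D <- traj$D[i, ]; B <- traj$B[i, , ]
  epsD <- 1e-10 * params$lesions0 + 1e-300
  th <- sweep(B, 2, D + epsD, "/")
  if (target == "repair_rate") {
    unname(params$gamma * D["incised"] *
             th["RPA", "incised"] * th["PCNA", "incised"])
  } else {
    unname(params$beta * D["unwound"] *
             prod(th[c("TFIIH", "XPG", "XPF", "XPA", "RPA"), "unwound"]))
  }
}

# repair-synthesis flux along an existing trajectory (vectorised over time)
synthesis_flux <- function(traj) {
  p <- traj$params
  epsD <- 1e-10 * p$lesions0 + 1e-300
  D3 <- traj$D[, "incised"]
  p$gamma * D3 * pmin(traj$B[, "RPA", "incised"] / (D3 + epsD), 1) *
    pmin(traj$B[, "PCNA", "incised"] / (D3 + epsD), 1)
}

#' Response coefficients of the repair (or incision) rate
#'
#' Logarithmic sensitivities \eqn{R_i = \partial \ln v / \partial \ln C_i}
#' of the pathway rate v to the nuclear concentration of each repair
#' factor, and to the initial lesion amount (\code{R_L}), by central
#' finite differences in log space with relative step \code{delta}. A
#' step-halving convergence check is recorded.
#'
#' @param params a \code{\link{ner_parameters}} object.
#' @param target rate definition, as in \code{\link{pathway_rate}}.
#' @param t_eval evaluation time in minutes.
#' @param delta relative finite-difference step (default 1\%).
#' @return An object of class \code{"response_report"}: \code{R} (named
#'   per-factor coefficients), \code{R_L}, \code{target}, \code{t_eval},
#'   \code{delta}, \code{convergence} (max relative change on step
#'   halving).
#' @examples
#' \donttest{
#' response_coefficients(ner_parameters())
#' }
#' @export
response_coefficients <- function(params,
                                  target = c("repair_rate", "incision_rate"),
                                  t_eval = 30, delta = 0.01) {
  target <- match.arg(target)
  if (t_eval <= 0) stop("'t_eval' must be > 0")
  log_rate <- function(p) {
    v <- pathway_rate(p, target, t_eval)
    if (!is.finite(v) || v <= 0) {
      stop("degenerate ", target, ": rate is zero or non-finite at t_eval")
    }
    log(v)
  }
  coef_one <- function(setter, d) {
    (log_rate(setter(1 + d)) - log_rate(setter(1 - d))) /
      (log(1 + d) - log(1 - d))
  }
  factor_setter <- function(f) function(s) {
    param_set(params, paste0("totals.", f), params$totals[[f]] * s)
  }
  lesion_setter <- function(s) {
    param_set(params, "lesions0", params$lesions0 * s)
  }
  R <- vapply(ner_factors, function(f) coef_one(factor_setter(f), delta),
              numeric(1))
  R_L <- coef_one(lesion_setter, delta)
  R_half <- vapply(ner_factors, function(f)
    coef_one(factor_setter(f), delta / 2), numeric(1))
  conv <- max(abs(R_half - R) / pmax(abs(R), 1e-6))
  structure(list(R = R, R_L = R_L, target = target, t_eval = t_eval,
                 delta = delta, convergence = conv),
            class = "response_report")
}

#' @export
print.response_report <- function(x, ...) {
  cat(sprintf("Response coefficients of the %s at t = %g min:\n",
              sub("_", " ", x$target), x$t_eval))
  print(round(x$R, 3))
  cat(sprintf("  R_L (lesions) = %.3f; step-halving change %.2g%%\n",
              x$R_L, 100 * x$convergence))
  invisible(x)
}

#' Rate response to finite concentration changes of one factor
#'
#' Pathway rate at \code{t_eval} with the nuclear concentration of one
#' factor scaled over a grid of fold changes, normalised to fold = 1
#' (knockdown/overexpression scan).
#'
#' @param params a \code{\link{ner_parameters}} object.
#' @param factor factor name.
#' @param folds positive fold changes (0 allowed as knockout limit).
#' @param target,t_eval as in \code{\link{pathway_rate}}.
#' @return data.frame with columns \code{fold} and \code{relative_rate}.
#' @export
perturbation_scan <- function(params, factor,
                              folds = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                              target = "repair_rate", t_eval = 30) {
  if (!factor %in% ner_factors) stop("unknown factor: ", factor)
  if (any(folds < 0)) stop("'folds' must be >= 0")
  rate_at <- function(fold) {
    p <- param_set(params, paste0("totals.", factor),
                   params$totals[[factor]] * fold)
    pathway_rate(p, target, t_eval)
  }
  v1 <- rate_at(1)
  data.frame(fold = folds,
             relative_rate = vapply(folds, rate_at, numeric(1)) / v1)
}

#' Propagate expression and lesion variability to the repair rate
#'
#' Law-of-propagation-of-uncertainty estimate of the coefficient of
#' variation of the repair rate across a cell population:
#' \deqn{CV_v^2 = \sum_i R_i^2 CV_i^2 + R_L^2 CV_L^2}
#' with the response coefficients from
#' \code{\link{response_coefficients}}.
#'
#' @param report a \code{"response_report"}.
#' @param cv_factors per-factor expression CVs; a single value is
#'   recycled.
#' @param cv_lesions CV of the initial lesion amount.
#' @return An object of class \code{"cv_budget"}: \code{cv_factors},
#'   \code{cv_lesions}, \code{cv_rate}, and the per-source contributions.
#' @examples
#' \donttest{
#' rep <- response_coefficients(ner_parameters())
#' propagate_cv(rep, 0.25, 0.32)
#' }
#' @export
propagate_cv <- function(report, cv_factors = 0.25, cv_lesions = 0.32) {
  stopifnot(inherits(report, "response_report"))
  if (any(cv_factors < 0) || cv_lesions < 0) stop("CVs must be >= 0")
  cvf <- rep_len(cv_factors, 7)
  names(cvf) <- ner_factors
  contrib <- c(report$R^2 * cvf^2, lesions = report$R_L^2 * cv_lesions^2)
  structure(list(cv_factors = cvf, cv_lesions = cv_lesions,
                 cv_rate = sqrt(sum(contrib)), contributions = contrib),
            class = "cv_budget")
}

#' @export
print.cv_budget <- function(x, ...) {
  cat(sprintf("Propagated repair-rate CV: %.3f\n", x$cv_rate))
  cat("  contributions (variance share):\n")
  print(round(x$contributions / sum(x$contributions), 3))
  invisible(x)
}
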