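#' Simulate the NER pathway model
#'
#' Integrates the balance equations for the five DNA repair intermediates
#' and the factor pools bound to them. Intermediates are interconverted by
#' the catalytic fluxes (unwinding J_alpha, dual incision J_beta, repair
#' synthesis J_gamma, re-chromatinization J_delta and re-annealing
#' J_epsilon), each proportional to the joint occupancy of the catalysing
#' factors on the source intermediate. Factors bind reversibly and
#' independently to the intermediates that carry a site for them; on a
#' state conversion each bound factor is carried over with probability
#' equal to its occupancy, returning to the free nuclear pool if the
#' target state has no site for it. Intermediates and bound pools are in
#' local damage-area concentrations; the free pools in nuclear
#' concentrations, coupled through the damage volume fraction phi.
#'
#' Integration uses the stiff solver lsoda on a compiled right-hand side,
#' relative tolerance 1e-8 and absolute tolerance 1e-10.
#'
#' @param params a \code{\link{ner_parameters}} object.
#' @param times increasing time grid in minutes, starting at 0.
#' @return An object of class \code{"ner_trajectory"}: list with
#'   \code{times}, matrix \code{D} (times x 5 intermediates, local uM),
#'   3-d array \code{B} (times x factor x state, local uM), matrix
#'   \code{free} (times x factor, nuclear uM), vector \code{edu}
#'   (cumulative repair synthesis, local uM) and \code{params}.
#' @examples
#' traj <- ner_simulate(ner_parameters(), seq(0, 240, 10))
#' traj$D[25, ]
#' @export
ner_simulate <- function(params, times) {
  stopifnot(inherits(params, "ner_parameters"))
  if (length(times) < 2 || times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing and start at 0")
  }
  y0 <- c(params$lesions0, rep(0, 4), rep(0, 20), 0)
  sol <- solve_checked(y0, times, "ner_derivs", params)
  as_trajectory(sol, params)
}

# lsoda solve that turns integrator breakdown into a clean error (with the
# solver's own diagnostics muffled, since the error carries the context)
solve_checked <- function(y0, times, func, params) {
  ws <- list()
  sol <- withCallingHandlers(
    deSolve::ode(y0, times, func = func, parms = pack_parameters(params),
                 dllname = "nercontrol", initfunc = "ner_init",
                 method = "lsoda", rtol = 1e-8, atol = 1e-10),
    warning = function(w) {
      ws[[length(ws) + 1L]] <<- w
      invokeRestart("muffleWarning")
    })
  if (attr(sol, "istate")[1] < 0) {
    stop("integrator failure at t = ", max(sol[, 1]),
         " min (partial trajectory discarded)", call. = FALSE)
  }
  for (w in ws) warning(w)
  sol
}

as_trajectory <- function(sol, params, labelled = FALSE) {
  nt <- nrow(sol)
  D <- sol[, 2:6, drop = FALSE]
  colnames(D) <- dna_states
  B <- array(0, dim = c(nt, 7, 5),
             dimnames = list(NULL, ner_factors, dna_states))
  Bm <- sol[, 7:26, drop = FALSE]
  for (j in seq_along(.pair_idx)) {
    fs <- arrayInd(.pair_idx[j], c(7, 5))
    B[, fs[1], fs[2]] <- Bm[, j]
  }
  neg <- min(0, min(D), min(B))
  if (neg < -1e-6 * max(params$lesions0, 1e-12)) {
    stop("negative concentrations beyond tolerance: ", neg)
  }
  free <- matrix(rep(params$totals, each = nt), nt, 7,
                 dimnames = list(NULL, ner_factors)) -
    params$phi * apply(B, c(1, 2), sum)
  out <- list(times = sol[, 1], D = D, B = B, free = free,
              edu = sol[, 27], params = params)
  if (labelled) {
    L <- array(0, dim = c(nt, 7, 5),
               dimnames = list(NULL, ner_factors, dna_states))
    Lm <- sol[, 28:47, drop = FALSE]
    for (j in seq_along(.pair_idx)) {
      fs <- arrayInd(.pair_idx[j], c(7, 5))
      L[, fs[1], fs[2]] <- Lm[, j]
    }
    out$labelled <- L
  }
  structure(out, class = "ner_trajectory")
}

#' @export
print.ner_trajectory <- function(x, ...) {
  cat(sprintf("NER trajectory: %d time points over [0, %g] min\n",
              length(x$times), max(x$times)))
  cat(sprintf("  repaired fraction at end: %.3f\n",
              x$D[length(x$times), "rechromatinized"] /
                max(x$params$lesions0, 1e-300)))
  invisible(x)
}

#' Observable time courses of a simulated trajectory
#'
#' Computes the measurement observables of the pathway model:
#' \describe{
#'   \item{accumulation}{total bound concentration of one factor at the
#'     damage site, summed over DNA states (local uM; what live-cell
#'     imaging of a tagged factor reports).}
#'   \item{edu}{cumulative repair DNA synthesis, the integral of the
#'     synthesis flux J_gamma (local uM; EdU incorporation).}
#'   \item{incised}{concentration of the lesion-excised intermediate as a
#'     fraction of the initial lesion amount.}
#'   \item{flip}{fluorescence loss in photobleaching: bound molecules of
#'     one factor present at \code{flip_start} are tracked as a labelled
#'     species that dissociates and is carried over with DNA-state
#'     conversions but cannot rebind; reported normalised to 1 at
#'     \code{flip_start}.}
#' }
#'
#' @param traj a \code{"ner_trajectory"} from \code{\link{ner_simulate}}.
#' @param kind one of \code{"accumulation"}, \code{"edu"},
#'   \code{"incised"}, \code{"flip"}.
#' @param factor factor name, required for accumulation and flip.
#' @param flip_start bleach start time in minutes (flip only); must lie in
#'   the trajectory's time range.
#' @param flip_times time grid (minutes since \code{flip_start}) on which
#'   the FLIP curve is returned; default 5-second steps over 5 minutes.
#' @param normalize for \code{kind = "edu"}: divide by the final plateau.
#' @return A data.frame with columns \code{time_min} and \code{value}.
#' @examples
#' traj <- ner_simulate(ner_parameters(), seq(0, 240, 10))
#' head(observe(traj, "accumulation", factor = "XPC"))
#' @export
observe <- function(traj, kind = c("accumulation", "edu", "incised", "flip"),
                    factor = NULL, flip_start = 30,
                    flip_times = seq(0, 5, by = 5 / 60), normalize = FALSE) {
  stopifnot(inherits(traj, "ner_trajectory"))
  kind <- match.arg(kind)
  times <- traj$times
  if (kind %in% c("accumulation", "flip")) {
    if (is.null(factor) || !factor %in% ner_factors) {
      stop("'factor' must be one of: ", paste(ner_factors, collapse = ", "))
    }
  }
  if (kind == "accumulation") {
    value <- rowSums(traj$B[, factor, , drop = FALSE][, 1, ])
    return(data.frame(time_min = times, value = value))
  }
  if (kind == "edu") {
    value <- traj$edu
    if (normalize) value <- value / max(value[length(value)], 1e-300)
    return(data.frame(time_min = times, value = value))
  }
  if (kind == "incised") {
    return(data.frame(time_min = times,
                      value = traj$D[, "incised"] /
                        max(traj$params$lesions0, 1e-300)))
  }
  # flip
  if (flip_start < min(times) || flip_start > max(times)) {
    stop("'flip_start' outside the trajectory time range")
  }
  flip_curve(traj$params, flip_start, flip_times, factor)
}

# integrate the extended system with labelled bound species from t0
flip_curve <- function(params, t0, flip_times, factor) {
  if (t0 <= 0) stop("'flip_start' must be > 0 (nothing is bound at t = 0)")
  pre <- ner_simulate(params, c(0, t0))
  i0 <- length(pre$times)
  B0 <- pre$B[i0, , ]
  y0 <- c(pre$D[i0, ], B0[.pair_idx], pre$edu[i0], B0[.pair_idx])
  sol <- solve_checked(y0, t0 + flip_times, "ner_flip_derivs", params)
  traj <- as_trajectory(sol, params, labelled = TRUE)
  lab <- rowSums(traj$labelled[, factor, , drop = FALSE][, 1, ])
  data.frame(time_min = flip_times,
             value = lab / max(lab[1], 1e-300))
}

#' EdU incorporation over a labelling window
#'
#' Integral of the repair-synthesis flux J_gamma over [t_start, t_end],
#' i.e. the amount of EdU incorporated when the label is present only
#' during that window. Additive over contiguous windows.
#'
#' @param params a \code{\link{ner_parameters}} object.
#' @param t_start,t_end window bounds in minutes, 0 <= t_start <= t_end.
#' @return Incorporated amount (local uM).
#' @examples
#' edu_window(ner_parameters(), 0, 60)
#' @export
edu_window <- function(params, t_start, t_end) {
  if (t_start < 0 || t_end < t_start) {
    stop("need 0 <= t_start <= t_end")
  }
  if (t_end == t_start) return(0)
  grid <- sort(unique(c(0, t_start, t_end)))
  traj <- ner_simulate(params, grid)
  edu_at <- function(tt) traj$edu[match(tt, traj$times)]
  unname(edu_at(t_end) - edu_at(t_start))
}
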