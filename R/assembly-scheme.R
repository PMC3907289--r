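#' Specify a repair-complex assembly scheme
#'
#' Defines the simplified ("cartoon") model of repair-complex formation: N
#' protein components associate reversibly at a lesion site, either in a
#' fixed order (\code{"sequential"}) or in any order (\code{"random"}), with
#' a common pseudo-first-order association rate \code{k_on}, a common
#' dissociation rate \code{k_off}, and a catalytic repair rate \code{rho}
#' once the complex is complete.
#'
#' @param n_components number of assembling components N (>= 1).
#' @param mechanism assembly order, \code{"sequential"} or \code{"random"}.
#' @param k_on pseudo-first-order association rate constant (min^-1).
#' @param k_off dissociation rate constant (min^-1); 0 gives irreversible
#'   assembly.
#' @param rho catalytic repair rate of the complete complex (min^-1).
#'   Default 600 min^-1 (10 s^-1).
#' @return An object of class \code{"assembly_scheme"}.
#' @examples
#' assembly_scheme(9, "random", k_on = 1, k_off = 1)
#' @export
assembly_scheme <- function(n_components, mechanism = c("sequential", "random"),
                            k_on = 1, k_off = 1, rho = 600) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(n_components) || length(n_components) != 1L ||
      n_components < 1 || n_components != round(n_components)) {
    stop("'n_components' must be a single integer >= 1")
  }
  if (k_on <= 0) stop("'k_on' must be > 0")
  if (k_off < 0) stop("'k_off' must be >= 0")
  if (rho <= 0) stop("'rho' must be > 0")
  if (mechanism == "random" && n_components > 16) {
    stop("random mechanism limited to n_components <= 16 (state space 2^N)")
  }
  structure(
    list(n_components = as.integer(n_components), mechanism = mechanism,
         k_on = k_on, k_off = k_off, rho = rho),
    class = "assembly_scheme"
  )
}

#' @export
print.assembly_scheme <- function(x, ...) {
  cat(sprintf("Assembly scheme: N = %d, %s mechanism\n", x$n_components,
              x$mechanism))
  cat(sprintf("  k_on = %g, k_off = %g, rho = %g (min^-1)\n",
              x$k_on, x$k_off, x$rho))
  invisible(x)
}

#' Build the continuous-time Markov chain of an assembly scheme
#'
#' Constructs the generator matrix of the assembly process. Sequential
#' schemes have N+2 states (empty site, 1..N components bound in order,
#' repaired); random schemes enumerate all 2^N occupancy subsets plus the
#' absorbing repaired state. The complete complex converts to the absorbing
#' state at rate \code{rho}; bound components dissociate at \code{k_off}
#' (in the sequential scheme only the outermost component can leave, so
#' that states remain assembly prefixes).
#'
#' @param scheme an \code{\link{assembly_scheme}}.
#' @return An object of class \code{"assembly_chain"}: list with
#'   \code{generator} (square rate matrix, min^-1), \code{state_labels},
#'   and \code{absorbing} (index of the repaired state).
#' @examples
#' chain <- build_assembly_chain(assembly_scheme(3, "sequential"))
#' chain$state_labels
#' @export
build_assembly_chain <- function(scheme) {
  stopifnot(inherits(scheme, "assembly_scheme"))
  N <- scheme$n_components
  k <- scheme$k_on; l <- scheme$k_off; rho <- scheme$rho

  if (scheme$mechanism == "sequential") {
    n <- N + 2L
    Q <- matrix(0, n, n)
    for (j in 0:N) {
      i <- j + 1L
      if (j < N) Q[i, i + 1L] <- k
      if (j > 0) Q[i, i - 1L] <- l
      if (j == N) Q[i, n] <- rho
    }
    labels <- c(paste0("x", 0:N), "repaired")
  } else {
    ns <- 2L^N
    n <- ns + 1L
    Q <- matrix(0, n, n)
    bits <- 2^(0:(N - 1))
    for (s in 0:(ns - 1L)) {
      i <- s + 1L
      occupied <- bitwAnd(s, bits) > 0
      for (b in seq_len(N)) {
        if (occupied[b]) Q[i, s - bits[b] + 1L] <- l
        else Q[i, s + bits[b] + 1L] <- k
      }
      if (all(occupied)) Q[i, n] <- rho
    }
    labels <- c(vapply(0:(ns - 1L), function(s) {
      occ <- which(bitwAnd(s, bits) > 0)
      if (length(occ) == 0) "x0" else paste0("x", paste(LETTERS[occ], collapse = ""))
    }, character(1)), "repaired")
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(generator = Q, state_labels = labels, absorbing = n),
            class = "assembly_chain")
}

#' Mean repair time of an assembly scheme
#'
#' Exact mean first-passage time from the empty assembly site to the
#' absorbing repaired state, obtained by solving the linear system
#' \eqn{-Q_T t = 1} on the transient part of the chain generator.
#'
#' @param scheme an \code{\link{assembly_scheme}}.
#' @return Mean repair time in minutes.
#' @examples
#' mean_repair_time(assembly_scheme(9, "random", 1, 1, 600)) # ~68 min
#' @export
mean_repair_time <- function(scheme) {
  chain <- build_assembly_chain(scheme)
  n <- chain$absorbing
  QT <- chain$generator[-n, -n, drop = FALSE]
  t <- tryCatch(solve(-QT, rep(1, n - 1L)),
                error = function(e) stop("no absorption: transient system singular (rho = 0?)"))
  if (!all(is.finite(t)) || t[1] <= 0) stop("no absorption: non-finite first-passage time")
  unname(t[1])
}

#' Completion curve (fraction of lesions repaired over time)
#'
#' Probability that the repair reaction has completed by each time point,
#' computed from the transient dynamics of the assembly chain. Uniform time
#' grids are propagated with a single matrix exponential of the generator
#' per step; non-uniform grids integrate the forward (master) equation.
#'
#' @param scheme an \code{\link{assembly_scheme}}.
#' @param times non-decreasing vector of times (minutes), >= 0.
#' @return Numeric vector of repaired fractions in [0, 1], non-decreasing.
#' @examples
#' completion_curve(assembly_scheme(3, "random"), seq(0, 60, 1))
#' @export
completion_curve <- function(scheme, times) {
  if (is.unsorted(times, strictly = FALSE)) stop("'times' must be non-decreasing")
  if (any(times < 0)) stop("'times' must be >= 0")
  chain <- build_assembly_chain(scheme)
  Q <- chain$generator
  n <- chain$absorbing
  p0 <- c(1, rep(0, n - 1L))

  dts <- diff(times)
  uniform <- length(times) >= 2 &&
    max(abs(dts - dts[1])) <= 1e-9 * max(dts[1], 1e-12)
  if (uniform && dts[1] > 0) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dts[1])))
    out <- numeric(length(times))
    p <- p0
    if (times[1] > 0) {
      p <- p %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * times[1])))
    }
    out[1] <- p[n]
    for (i in seq_along(times)[-1]) {
      p <- p %*% E
      out[i] <- p[n]
    }
  } else {
    out <- vapply(times, function(tt) {
      if (tt == 0) return(0)
      (p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * tt))))[n]
    }, numeric(1))
  }
  pmin(pmax(as.numeric(out), 0), 1)
}

#' Sample stochastic repair times of an assembly scheme
#'
#' Exact stochastic simulation (Gillespie algorithm) of the assembly chain,
#' returning the time to absorption for each realisation.
#'
#' @param scheme an \code{\link{assembly_scheme}}.
#' @param n_samples number of realisations (>= 1).
#' @param seed integer random seed (mandatory, for reproducibility).
#' @return Numeric vector of repair times (minutes).
#' @examples
#' x <- sample_repair_times(assembly_scheme(2, "random"), 100, seed = 1)
#' mean(x)
#' @export
sample_repair_times <- function(scheme, n_samples, seed) {
  stopifnot(inherits(scheme, "assembly_scheme"))
  if (missing(seed)) stop("'seed' is required")
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  chain <- build_assembly_chain(scheme)
  Q <- chain$generator
  n <- chain$absorbing
  rates <- lapply(seq_len(n - 1L), function(i) {
    r <- Q[i, ]; r[i] <- 0
    j <- which(r > 0)
    list(to = j, rate = r[j], total = sum(r[j]))
  })
  set.seed(seed)
  vapply(seq_len(n_samples), function(s) {
    t <- 0; i <- 1L
    while (i != n) {
      ri <- rates[[i]]
      t <- t + stats::rexp(1, ri$total)
      i <- if (length(ri$to) == 1L) ri$to else
        sample(ri$to, 1L, prob = ri$rate)
    }
    t
  }, numeric(1))
}
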