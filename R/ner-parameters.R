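#' @useDynLib nercontrol, .registration = TRUE
NULL

#' Core NER repair factors
#'
#' The seven repair factors represented explicitly in the pathway model:
#' the lesion-recognition factor XPC, the helicase complex TFIIH, the 3'
#' and 5' endonucleases XPG and ERCC1-XPF, the damage-verification factor
#' XPA, the single-strand binding protein RPA and the polymerase clamp
#' loader PCNA.
#' @export
ner_factors <- c("XPC", "TFIIH", "XPG", "XPF", "XPA", "RPA", "PCNA")

#' DNA repair intermediates
#'
#' The five DNA states of the pathway model, in pathway order: damaged
#' (lesion present, I), unwound (open complex, II), incised (lesion
#' excised, III), resynthesized (gap filled, IV) and rechromatinized
#' (restored chromatin, V).
#' @export
dna_states <- c("damaged", "unwound", "incised", "resynthesized",
                "rechromatinized")

# Reference dissociation constants K_D = koff/kon (uM) per factor x state.
# NA marks factor/state combinations with no binding site.
.kd_reference <- local({
  m <- matrix(NA_real_, 7, 5, dimnames = list(ner_factors, dna_states))
  m["XPC", ]   <- c(9.35,  0.864, 0.864, NA,    NA)
  m["TFIIH", ] <- c(0.052, 0.204, 0.204, NA,    NA)
  m["XPG", ]   <- c(NA,    0.395, 0.395, NA,    NA)
  m["XPF", ]   <- c(NA,    2.446, 2.446, NA,    NA)
  m["XPA", ]   <- c(NA,    0.147, 0.147, 0.236, NA)
  m["RPA", ]   <- c(NA,    1.222, 1.222, 1.167, 0.538)
  m["PCNA", ]  <- c(NA,    NA,    0.388, 0.605, 0.154)
  m
})

.permitted <- !is.na(.kd_reference)
# column-major order over the permitted factor x state pairs; must match
# the state layout of the compiled right-hand side (src/ner_rhs.c)
.pair_idx <- which(.permitted)

.totals_reference <- c(XPC = 1.0, TFIIH = 0.35, XPG = 0.104, XPF = 0.65,
                       XPA = 0.039, RPA = 0.325, PCNA = 0.4)

#' Reference parameter set of the NER pathway model
#'
#' Assembles the full kinetic parameter set: association and dissociation
#' rate constants for every permitted factor/DNA-state pair, the five
#' catalytic rate constants (alpha, DNA unwinding; beta, dual incision;
#' gamma, repair synthesis; delta, re-chromatinization; epsilon,
#' re-annealing of unwound DNA), nuclear factor concentrations, the damage
#' volume fraction phi and the initial local lesion concentration.
#'
#' Dissociation constants K_D = koff/kon default to the reference values
#' estimated for each factor/state pair (e.g. 9.35 uM for XPC on damaged
#' DNA, 0.147 uM for XPA on unwound DNA); the baseline dissociation rate is
#' koff = 1 min^-1 (dwell times of the order of one minute) with
#' kon = koff / K_D. Catalytic steps other than re-chromatinization are
#' fast (alpha = beta = gamma = 60 min^-1, i.e. 1 s^-1; epsilon = 1 min^-1;
#' delta = 0.05 min^-1). Factor concentrations default to a sub-saturating
#' regime in which accumulation at damage is approximately linear in
#' expression level and rate control is collectively distributed; see the
#' package vignette for how these were chosen.
#'
#' @param overrides named list of replacement values. Scalar fields
#'   (\code{alpha}, \code{beta}, \code{gamma}, \code{delta}, \code{epsilon},
#'   \code{phi}, \code{lesions0}) are named directly; per-pair rates as
#'   \code{"kon.XPA.unwound"} / \code{"koff.XPA.unwound"}; concentrations
#'   as \code{"totals.XPC"}; whole vectors/matrices as \code{totals},
#'   \code{kon}, \code{koff}.
#' @return An object of class \code{"ner_parameters"}: list with matrices
#'   \code{kon} (uM^-1 min^-1), \code{koff} (min^-1), logical
#'   \code{permitted}, scalars \code{alpha}..\code{epsilon} (min^-1),
#'   vector \code{totals} (uM), \code{phi}, \code{lesions0} (uM).
#' @examples
#' p <- ner_parameters()
#' kd(p)["XPA", "unwound"]
#' ner_parameters(list(alpha = 30, totals.XPC = 0.5))
#' @export
ner_parameters <- function(overrides = list()) {
  kon <- ifelse(.permitted, 1 / .kd_reference, NA_real_)
  koff <- ifelse(.permitted, 1, NA_real_)
  p <- list(kon = kon, koff = koff, permitted = .permitted,
            alpha = 60, beta = 60, gamma = 60, delta = 0.05, epsilon = 1,
            totals = .totals_reference, phi = 0.1, lesions0 = 0.1)
  class(p) <- "ner_parameters"
  if (length(overrides)) p <- apply_overrides(p, overrides)
  validate_ner_parameters(p)
  p
}

apply_overrides <- function(p, overrides) {
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("overrides must be a fully named list")
  }
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      if (!nm %in% c("kon", "koff", "totals", "alpha", "beta", "gamma",
                     "delta", "epsilon", "phi", "lesions0")) {
        stop("unknown parameter field: ", nm)
      }
      if (nm %in% c("kon", "koff")) {
        if (!identical(dim(val), dim(p[[nm]]))) stop(nm, ": wrong dimensions")
        if (any(!is.na(val[!p$permitted]))) {
          stop(nm, ": value supplied for a non-permitted factor/state pair")
        }
      }
      p[[nm]] <- val
    } else if (length(parts) == 2L && parts[1] == "totals") {
      if (!parts[2] %in% ner_factors) stop("unknown factor: ", parts[2])
      p$totals[parts[2]] <- val
    } else if (length(parts) == 3L && parts[1] %in% c("kon", "koff")) {
      f <- parts[2]; s <- parts[3]
      if (!f %in% ner_factors) stop("unknown factor: ", f)
      if (!s %in% dna_states) stop("unknown DNA state: ", s)
      if (!p$permitted[f, s]) {
        stop(sprintf("%s does not bind %s DNA: no such rate constant", f, s))
      }
      p[[parts[1]]][f, s] <- val
    } else {
      stop("cannot interpret override: ", nm)
    }
  }
  p
}

validate_ner_parameters <- function(p) {
  rates <- c(p$kon[p$permitted], p$koff[p$permitted],
             p$alpha, p$beta, p$gamma, p$delta, p$epsilon)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rate constants must be finite and >= 0")
  }
  if (any(p$totals < 0) || length(p$totals) != 7) {
    stop("'totals' must be 7 non-negative concentrations")
  }
  if (p$phi <= 0 || p$phi > 1) stop("'phi' must be in (0, 1]")
  if (p$lesions0 < 0) stop("'lesions0' must be >= 0")
  invisible(p)
}

#' Dissociation constants of a parameter set
#'
#' @param params a \code{\link{ner_parameters}} object.
#' @return Matrix of K_D = koff/kon (uM), NA where binding is not permitted.
#' @export
kd <- function(params) {
  stopifnot(inherits(params, "ner_parameters"))
  params$koff / params$kon
}

#' @export
print.ner_parameters <- function(x, ...) {
  cat("NER pathway parameter set\n")
  cat(sprintf("  catalytic (min^-1): alpha=%g beta=%g gamma=%g delta=%g epsilon=%g\n",
              x$alpha, x$beta, x$gamma, x$delta, x$epsilon))
  cat(sprintf("  phi = %g, lesions0 = %g uM\n", x$phi, x$lesions0))
  cat("  totals (uM):", paste(sprintf("%s=%g", names(x$totals), x$totals),
                              collapse = " "), "\n")
  cat("  K_D (uM):\n")
  print(round(kd(x), 4))
  invisible(x)
}

# flatten to the 54-element vector consumed by the compiled RHS
pack_parameters <- function(p) {
  c(p$kon[.pair_idx], p$koff[.pair_idx],
    p$alpha, p$beta, p$gamma, p$delta, p$epsilon,
    unname(p$totals), p$phi, p$lesions0)
}

#' Write / read a parameter set as JSON
#'
#' Serialises the full parameter set (nested factor-by-state rate maps,
#' catalytic block, concentrations, phi, lesions0) to a JSON file and back.
#'
#' @param params a \code{\link{ner_parameters}} object.
#' @param path file path.
#' @return \code{read_parameters} returns a \code{ner_parameters} object;
#'   \code{write_parameters} returns \code{path} invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "ner_parameters"))
  mat2map <- function(m) {
    lapply(stats::setNames(ner_factors, ner_factors), function(f) {
      v <- m[f, ]; as.list(v[!is.na(v)])
    })
  }
  obj <- list(kon = mat2map(params$kon), koff = mat2map(params$koff),
              catalytic = list(alpha = params$alpha, beta = params$beta,
                               gamma = params$gamma, delta = params$delta,
                               epsilon = params$epsilon),
              totals = as.list(params$totals),
              phi = params$phi, lesions0 = params$lesions0)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  map2mat <- function(map) {
    m <- matrix(NA_real_, 7, 5, dimnames = list(ner_factors, dna_states))
    for (f in names(map)) for (s in names(map[[f]])) m[f, s] <- map[[f]][[s]]
    m
  }
  ov <- list(kon = map2mat(obj$kon), koff = map2mat(obj$koff),
             alpha = obj$catalytic$alpha, beta = obj$catalytic$beta,
             gamma = obj$catalytic$gamma, delta = obj$catalytic$delta,
             epsilon = obj$catalytic$epsilon,
             totals = unlist(obj$totals)[ner_factors],
             phi = obj$phi, lesions0 = obj$lesions0)
  ner_parameters(ov)
}
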