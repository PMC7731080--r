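#' Phase system of a two-phase blood suspension
#'
#' Bundles the conductivities and volumetric fractions that describe whole
#' blood as a suspension of insulating inclusions (red cells, glucose) in a
#' conductive host (plasma).
#'
#' @param sigma_h Conductivity of the high-conductivity phase (plasma), S/m.
#' @param sigma_l Conductivity of the low-conductivity phase (red cells), S/m.
#'   Defaults to 0 (perfectly insulating inclusions).
#' @param k Volumetric fraction of red blood cells (hematocrit),
#'   dimensionless, in `[0, 1)`.
#' @param k_prime Volumetric fraction of glucose, dimensionless, >= 0.
#'
#' @return An object of class `phase_system`: a list with fields `sigma_h`,
#'   `sigma_l`, `k`, `k_prime`. The conductive (plasma) fraction
#'   `phi = 1 - k + k_prime` is available via [conductive_fraction()].
#'
#' @examples
#' ps <- phase_system(sigma_h = 1.5, k = 0.45)
#' conductive_fraction(ps$k, ps$k_prime)
#' @export
phase_system <- function(sigma_h, sigma_l = 0, k = 0, k_prime = 0) {
  stopifnot(is.numeric(sigma_h), length(sigma_h) == 1L,
            is.numeric(sigma_l), length(sigma_l) == 1L,
            is.numeric(k), length(k) == 1L,
            is.numeric(k_prime), length(k_prime) == 1L)
  if (!is.finite(sigma_h) || sigma_h <= 0)
    stop_validation("sigma_h must be a positive finite conductivity (S/m)")
  if (!is.finite(sigma_l) || sigma_l < 0 || sigma_l > sigma_h)
    stop_validation("sigma_l must satisfy 0 <= sigma_l <= sigma_h")
  if (!is.finite(k) || k < 0 || k >= 1)
    stop_validation("k (red-cell fraction) must lie in [0, 1)")
  if (!is.finite(k_prime) || k_prime < 0)
    stop_validation("k_prime (glucose fraction) must be non-negative")
  phi <- 1 - k + k_prime
  if (phi <= 0 || phi > 1)
    stop_validation(sprintf(
      "derived conductive fraction phi = 1 - k + k_prime = %g outside (0, 1]",
      phi))
  structure(list(sigma_h = sigma_h, sigma_l = sigma_l,
                 k = k, k_prime = k_prime),
            class = "phase_system")
}

#' @export
print.phase_system <- function(x, ...) {
  cat("Two-phase blood suspension\n")
  cat(sprintf("  sigma_h (plasma):    %g S/m\n", x$sigma_h))
  cat(sprintf("  sigma_l (red cells): %g S/m\n", x$sigma_l))
  cat(sprintf("  k  (red cells):      %g\n", x$k))
  cat(sprintf("  k' (glucose):        %g\n", x$k_prime))
  cat(sprintf("  phi (plasma, derived): %g\n",
              conductive_fraction(x$k, x$k_prime)))
  invisible(x)
}

#' Conductive (plasma) volume fraction
#'
#' Volume bookkeeping of the suspension: the plasma fraction phi satisfies
#' `phi - k_prime = 1 - k`, i.e. glucose displaces plasma volume while the
#' red-cell fraction is held fixed. With no glucose this reduces to the usual
#' `phi = 1 - k`.
#'
#' @param k Red-cell volume fraction, in `[0, 1)`.
#' @param k_prime Glucose volume fraction, >= 0.
#' @return `phi = 1 - k + k_prime`, guaranteed in `(0, 1]`.
#' @examples
#' conductive_fraction(0.45, 0)       # 0.55
#' conductive_fraction(0.45, 0.0040)  # 0.5540
#' @export
conductive_fraction <- function(k, k_prime = 0) {
  stopifnot(is.numeric(k), is.numeric(k_prime))
  if (any(!is.finite(k)) || any(k < 0) || any(k >= 1))
    stop_validation("k must lie in [0, 1)")
  if (any(!is.finite(k_prime)) || any(k_prime < 0))
    stop_validation("k_prime must be non-negative")
  phi <- 1 - k + k_prime
  if (any(phi <= 0) || any(phi > 1))
    stop_validation("phi = 1 - k + k_prime outside (0, 1]")
  phi
}

#' Effective conductivity for insulating spherical inclusions
#'
#' Closed-form Bruggeman asymmetric-medium result for insulating spherical
#' inclusions (`sigma_l = 0`) at volume fraction `k` in a host of
#' conductivity `sigma_h`:
#' \deqn{\sigma_m = (1 - k)^{3/2}\, \sigma_h.}
#'
#' @param sigma_h Host (plasma) conductivity, S/m, > 0.
#' @param k Inclusion volume fraction, in `[0, 1]`.
#' @return Effective conductivity sigma_m in S/m, in `[0, sigma_h]`.
#' @examples
#' effective_conductivity_insulating(1.5, 0.45)
#' @export
effective_conductivity_insulating <- function(sigma_h, k) {
  stopifnot(is.numeric(sigma_h), is.numeric(k))
  if (any(!is.finite(sigma_h)) || any(sigma_h <= 0))
    stop_validation("sigma_h must be positive")
  if (any(!is.finite(k)) || any(k < 0) || any(k > 1))
    stop_validation("k must lie in [0, 1]")
  (1 - k)^1.5 * sigma_h
}

#' Bruggeman asymmetric effective-medium conductivity
#'
#' Solves the Bruggeman asymmetric mixture equation for spherical grain
#' inclusions,
#' \deqn{\frac{\sigma_m - \sigma_l}{\sigma_m^{1/3}}
#'   = (1 - k)\,\frac{\sigma_h - \sigma_l}{\sigma_h^{1/3}},}
#' for the effective conductivity \eqn{\sigma_m} of a suspension of
#' low-conductivity inclusions (fraction `k`, conductivity `sigma_l`) in a
#' high-conductivity host (`sigma_h`). For `sigma_l = 0` the solution reduces
#' exactly to the closed form of [effective_conductivity_insulating()].
#'
#' The residual is continuous and monotone in sigma_m on `[sigma_l, sigma_h]`,
#' so a bracketed scalar root search is used (absolute tolerance `tol`,
#' at most `max_iter` iterations).
#'
#' @param sigma_h Host conductivity, S/m, > 0.
#' @param sigma_l Inclusion conductivity, S/m, `0 <= sigma_l <= sigma_h`.
#' @param k Inclusion volume fraction, `[0, 1)` (exactly 1 is allowed only
#'   with `sigma_l = 0`, where the exact limit sigma_m = 0 is returned).
#' @param tol Absolute tolerance on sigma_m, S/m.
#' @param max_iter Maximum root-search iterations.
#' @return The unique root sigma_m in `[sigma_l, sigma_h]`, S/m.
#' @examples
#' solve_bruggeman(1.0, 0, 0.3)       # equals (0.7)^1.5
#' solve_bruggeman(1.5, 0.3, 0.5)
#' @export
solve_bruggeman <- function(sigma_h, sigma_l = 0, k = 0,
                            tol = 1e-12, max_iter = 200L) {
  stopifnot(length(sigma_h) == 1L, length(sigma_l) == 1L, length(k) == 1L)
  if (!is.finite(sigma_h) || sigma_h <= 0)
    stop_validation("sigma_h must be positive")
  if (!is.finite(sigma_l) || sigma_l < 0 || sigma_l > sigma_h)
    stop_validation("sigma_l must satisfy 0 <= sigma_l <= sigma_h")
  if (!is.finite(k) || k < 0 || k > 1)
    stop_validation("k must lie in [0, 1]")
  if (k == 1) {
    if (sigma_l == 0) return(0)  # exact insulating limit, not solved
    stop_validation("k = 1 is only defined in the insulating limit sigma_l = 0")
  }
  if (sigma_l == sigma_h) return(sigma_h)  # identical phases
  rhs <- (1 - k) * (sigma_h - sigma_l) / sigma_h^(1/3)
  residual <- function(s) (s - sigma_l) / s^(1/3) - rhs
  # residual(sigma_l) <= 0 <= residual(sigma_h); monotone bracket
  sol <- tryCatch(
    stats::uniroot(residual, lower = max(sigma_l, .Machine$double.xmin),
                   upper = sigma_h, tol = tol, maxiter = max_iter,
                   extendInt = "no"),
    error = function(e) stop_convergence(sprintf(
      "Bruggeman root search failed on bracket [%g, %g]: %s",
      sigma_l, sigma_h, conditionMessage(e))))
  root <- min(max(sol$root, sigma_l), sigma_h)
  if (abs(residual(root)) > 1e-6 * max(1, abs(rhs)))
    stop_convergence(sprintf(
      "Bruggeman residual %.3e at returned root %.6g exceeds tolerance (bracket [%g, %g])",
      residual(root), root, sigma_l, sigma_h))
  root
}
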