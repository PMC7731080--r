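#' Five-coefficient rational impedance form
#'
#' The blood impedance magnitude admits an equivalent rational form in
#' frequency,
#' \deqn{|Z|(f) = \sqrt{\,b + \frac{(a + c f)^2}{f^2 (g + d f)^2}\,},}
#' where for physically mapped (complex) coefficient sets the squares are
#' read as squared moduli. The numerator/denominator pairs carry a gauge
#' redundancy: scaling all of `a, c, g, d` by a common factor leaves the
#' curve unchanged, so fitted sets are only identified up to that scale.
#'
#' @param a,b,c,d,g Coefficients (real for empirical fits, complex when
#'   mapped from physical parameters). `b` must have non-negative real part;
#'   `g` and `d` must not both be zero.
#' @param f_unit Frequency unit the coefficients expect: `"hz"` or `"khz"`.
#' @param z_unit Magnitude unit they produce: `"ohm"` or `"kohm"`.
#' @param ref_error_pct Optional named numeric vector of per-coefficient
#'   reference errors (%), carried for bundled published sets.
#' @return An object of class `rational_coefficients`.
#' @seealso [eval_rational()], [coeffs_from_physical()], [fit_rational()]
#' @export
rational_coefficients <- function(a, b, c, d, g,
                                  f_unit = c("hz", "khz"),
                                  z_unit = c("ohm", "kohm"),
                                  ref_error_pct = NULL) {
  f_unit <- match.arg(f_unit)
  z_unit <- match.arg(z_unit)
  vals <- c(a = a, b = b, c = c, d = d, g = g)
  if (any(!is.finite(Mod(vals))))
    stop_validation("all coefficients must be finite")
  if (Re(b) < 0)
    stop_validation("b must have non-negative real part (it equals R^2)")
  if (Mod(g) == 0 && Mod(d) == 0)
    stop_validation("g and d must not both be zero")
  structure(list(a = a, b = b, c = c, d = d, g = g,
                 f_unit = f_unit, z_unit = z_unit,
                 ref_error_pct = ref_error_pct),
            class = "rational_coefficients")
}

#' @export
print.rational_coefficients <- function(x, ...) {
  cat(sprintf("Rational impedance coefficients (f in %s, |Z| in %s)\n",
              x$f_unit, x$z_unit))
  for (nm in c("a", "b", "c", "d", "g")) {
    v <- x[[nm]]
    cat(sprintf("  %s = %s\n", nm,
                if (is.complex(v)) format(v, digits = 6)
                else format(v, digits = 6)))
  }
  fp <- pole_frequency(x)
  if (!is.na(fp))
    cat(sprintf("  denominator pole at f = %.6g %s\n", fp, x$f_unit))
  invisible(x)
}

#' Evaluate the rational impedance form
#'
#' @param coeffs A [rational_coefficients()] set.
#' @param f Frequencies, in `coeffs$f_unit`, > 0 (vectorized).
#' @param pole_guard For real coefficient sets, evaluation is refused when
#'   `|g + d f|` falls below this guard (proximity to the real denominator
#'   pole), in the coefficient units.
#' @return Impedance magnitudes in `coeffs$z_unit`, non-negative.
#' @examples
#' tb1 <- fixture_table1()
#' eval_rational(tb1, c(50, 100))  # kHz in, kOhm out
#' @export
eval_rational <- function(coeffs, f, pole_guard = 1e-12) {
  stopifnot(inherits(coeffs, "rational_coefficients"))
  if (any(!is.finite(f)) || any(f <= 0))
    stop_validation("f must be strictly positive")
  den <- Mod(coeffs$g + coeffs$d * f)
  is_real <- !is.complex(c(coeffs$a, coeffs$b, coeffs$c, coeffs$d, coeffs$g))
  if (is_real && any(den < pole_guard))
    stop_validation(sprintf(
      "evaluation within pole guard: |g + d f| = %.3e < %.3e near f = %g %s",
      min(den), pole_guard, f[which.min(den)], coeffs$f_unit))
  num <- Mod(coeffs$a + coeffs$c * f)
  sqrt(Re(coeffs$b) + num^2 / (f^2 * den^2))
}

#' Map physical blood parameters to rational coefficients
#'
#' Exact algebraic mapping of the physical forward model into the rational
#' form: `a = L`, `b = (L/A)^2 / (sigma_h^2 phi^3)` (the squared vessel
#' resistance), `c = -j 2 pi tau L`, `d = -j 4 pi^2 A eps_inf tau`,
#' `g = 2 pi A (eps_inf + delta_eps)`. [eval_rational()] on the result
#' reproduces [impedance_modulus()] identically (frequencies in Hz,
#' magnitudes in Ohm).
#'
#' @param params A [blood_model_params()].
#' @return A complex-valued [rational_coefficients()] with units (Hz, Ohm).
#' @export
coeffs_from_physical <- function(params) {
  stopifnot(inherits(params, "blood_model_params"))
  L <- params$geometry$L
  A <- params$geometry$A
  ph <- params$phases
  db <- params$debye
  phi <- conductive_fraction(ph$k, ph$k_prime)
  rational_coefficients(
    a = complex(real = L),
    b = complex(real = (L / A)^2 / (ph$sigma_h^2 * phi^3)),
    c = -2i * pi * db$tau * L,
    d = -4i * pi^2 * A * db$eps_inf * db$tau,
    g = complex(real = 2 * pi * A * (db$eps_inf + db$delta_eps)),
    f_unit = "hz", z_unit = "ohm"
  )
}

#' Per-point percent errors between model and experiment
#'
#' `e_i = 100 |model_i - experimental_i| / experimental_i`, the error
#' convention of published model-versus-data comparisons.
#'
#' @param model Numeric vector of modelled magnitudes.
#' @param experimental Numeric vector of experimental magnitudes, > 0,
#'   same length.
#' @return Numeric vector of percent errors, >= 0.
#' @examples
#' percent_errors(c(46.4, 97.9), c(49.0, 97.5))
#' @export
percent_errors <- function(model, experimental) {
  if (!is.numeric(model) || !is.numeric(experimental))
    stop_validation("model and experimental must be numeric")
  if (length(model) != length(experimental))
    stop_validation("model and experimental must have equal length")
  if (any(!is.finite(experimental)) || any(experimental <= 0))
    stop_validation("experimental magnitudes must be positive")
  100 * abs(model - experimental) / experimental
}

#' Real pole of the rational denominator
#'
#' The fitted denominator `g + d f` vanishes at `f* = -g/d`; when positive,
#' this pole bounds the model's validity band from below. Only defined for
#' real coefficient sets (physically mapped complex sets have no real pole).
#'
#' @param coeffs A [rational_coefficients()] set.
#' @return The pole frequency in `coeffs$f_unit`, or `NA_real_` when `d = 0`
#'   or the root is not positive.
#' @examples
#' pole_frequency(fixture_table1())  # just below the 50-100 kHz window
#' @export
pole_frequency <- function(coeffs) {
  stopifnot(inherits(coeffs, "rational_coefficients"))
  if (is.complex(c(coeffs$g, coeffs$d))) {
    if (Im(coeffs$g) != 0 || Im(coeffs$d) != 0) return(NA_real_)
  }
  g <- Re(coeffs$g); d <- Re(coeffs$d)
  if (d == 0) return(NA_real_)
  fstar <- -g / d
  if (fstar > 0) fstar else NA_real_
}

# Deterministic automatic initialization for fit_rational, gauge a = -1.
# Places the numerator zero just below the band (0.95 f_min), the denominator
# pole at 0.9 f_min, seeds b with the squared smallest magnitude, and sets the
# (g, d) scale by matching |Z| at the highest frequency (farthest from the
# seeded pole/zero, where the match is well conditioned).
auto_init_coeffs <- function(f, z) {
  fmin <- min(f); fmax <- max(f)
  zero0 <- 0.95 * fmin
  pole0 <- 0.9 * fmin
  c0 <- 1 / zero0                      # -a/c = zero0 with a = -1
  b0 <- min(z)^2
  z_at_fmax <- z[which.max(f)]
  target <- sqrt(max(z_at_fmax^2 - b0, (0.1 * z_at_fmax)^2))
  d0 <- abs(-1 + c0 * fmax) / (fmax * target * abs(fmax - pole0))
  g0 <- -d0 * pole0                    # pole -g0/d0 = pole0
  list(a = -1, b = b0, c = c0, d = d0, g = g0)
}

#' Fit the rational form to a measured spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' [minpack.lm::nls.lm()]) of the five-coefficient rational magnitude form
#' to a spectrum, minimizing the unweighted sum of squared magnitude
#' residuals. Because the form is invariant under a common rescaling of
#' `(a, c, g, d)`, one gauge constraint is imposed: by default `a` is fixed
#' at -1 (the published sign convention); alternatively `g` can be fixed at
#' 1. `b` is kept non-negative by an internal square-root parametrization.
#' The optimization is deterministic given the data, the initialization and
#' the gauge.
#'
#' @param spectrum An [eis_spectrum()] with at least 5 points.
#' @param init Optional [rational_coefficients()] initialization (real);
#'   rescaled into the requested gauge. Default: an automatic deterministic
#'   seed placing the numerator zero and denominator pole just below the
#'   frequency band.
#' @param gauge `"fix-a"` (a = -1, default) or `"fix-g"` (g = 1).
#' @param ftol,ptol Convergence tolerances on the relative change of the
#'   objective and parameters.
#' @param max_iter Iteration cap.
#' @return An object of class `eis_fit`: list with `coefficients`
#'   (gauge-fixed real [rational_coefficients()]), `fitted` (magnitudes at
#'   the data frequencies), `residual_pct`, `max_error_pct`,
#'   `mean_error_pct`, `converged`, `n_iter`, `objective`,
#'   `init_objective`, `gauge`, `pole` (frequency or `NA`),
#'   `pole_in_range` (flag: pole inside the data band), `message`.
#' @examples
#' tb2 <- fixture_table2()
#' fit <- fit_rational(tb2$experimental)
#' fit$max_error_pct
#' @export
fit_rational <- function(spectrum, init = NULL,
                         gauge = c("fix-a", "fix-g"),
                         ftol = 1e-12, ptol = 1e-12, max_iter = 500L) {
  stopifnot(inherits(spectrum, "eis_spectrum"))
  gauge <- match.arg(gauge)
  f <- spectrum$frequency
  z <- spectrum$z_mod
  if (length(f) < 5L)
    stop_validation("at least 5 spectrum points are needed to fit 4 free coefficients")

  start <- if (is.null(init)) {
    auto_init_coeffs(f, z)
  } else {
    stopifnot(inherits(init, "rational_coefficients"))
    if (is.complex(c(init$a, init$b, init$c, init$d, init$g)))
      stop_validation("initialization must be a real coefficient set")
    lam <- if (gauge == "fix-a") {
      if (init$a == 0) stop_validation("gauge fix-a needs init with a != 0")
      -1 / init$a
    } else {
      if (init$g == 0) stop_validation("gauge fix-g needs init with g != 0")
      1 / init$g
    }
    list(a = init$a * lam, b = Re(init$b), c = init$c * lam,
         d = init$d * lam, g = init$g * lam)
  }

  # free parameters: (sqrt(b), c, d, g) under fix-a; (a, sqrt(b), c, d) under fix-g
  unpack <- if (gauge == "fix-a") {
    function(p) list(a = -1, b = p[1]^2, c = p[2], d = p[3], g = p[4])
  } else {
    function(p) list(a = p[1], b = p[2]^2, c = p[3], d = p[4], g = 1)
  }
  p0 <- if (gauge == "fix-a") {
    c(sqrt(max(start$b, 0)), start$c, start$d, start$g)
  } else {
    c(start$a, sqrt(max(start$b, 0)), start$c, start$d)
  }

  model_fun <- function(p) {
    co <- unpack(p)
    sqrt(co$b + (co$a + co$c * f)^2 / (f^2 * (co$g + co$d * f)^2))
  }
  resid_fun <- function(p) model_fun(p) - z

  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(
      ftol = ftol, ptol = ptol, gtol = 0, maxiter = as.integer(max_iter)))

  co <- unpack(fit$par)
  coeffs <- rational_coefficients(co$a, co$b, co$c, co$d, co$g,
                                  f_unit = spectrum$f_unit,
                                  z_unit = spectrum$z_unit)
  fitted <- eval_rational(coeffs, f)
  errs <- percent_errors(fitted, z)
  converged <- fit$info %in% 1:3
  if (!converged)
    stop_convergence(sprintf(
      "rational fit did not converge after %d iterations (nls.lm info %d): %s",
      fit$niter, fit$info, fit$message))
  pole <- pole_frequency(coeffs)
  structure(list(
    coefficients = coeffs,
    fitted = fitted,
    residual_pct = errs,
    max_error_pct = max(errs),
    mean_error_pct = mean(errs),
    converged = converged,
    n_iter = fit$niter,
    objective = fit$deviance,
    init_objective = sum(resid_fun(p0)^2),
    gauge = if (gauge == "fix-a") "a fixed at -1" else "g fixed at 1",
    pole = pole,
    pole_in_range = !is.na(pole) && pole >= min(f) && pole <= max(f),
    message = fit$message
  ), class = "eis_fit")
}

#' @export
print.eis_fit <- function(x, ...) {
  cat("Rational impedance fit\n")
  cat(sprintf("  gauge: %s; converged in %d iterations\n", x$gauge, x$n_iter))
  print(x$coefficients)
  cat(sprintf("  residuals: max %.3g%%, mean %.3g%%\n",
              x$max_error_pct, x$mean_error_pct))
  if (isTRUE(x$pole_in_range))
    cat("  WARNING: fitted denominator pole lies inside the data band\n")
  invisible(x)
}

#' Flat key-value report of a fit
#'
#' @param fit An `eis_fit`.
#' @return A two-column data.frame (`key`, `value`) suitable for writing as
#'   plain text or CSV.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "eis_fit"))
  co <- fit$coefficients
  data.frame(
    key = c("a", "b", "c", "d", "g", "f_unit", "z_unit", "gauge",
            "max_error_pct", "mean_error_pct", "n_iter", "converged",
            "pole", "pole_in_range"),
    value = c(format(Re(co$a), digits = 10), format(Re(co$b), digits = 10),
              format(Re(co$c), digits = 10), format(Re(co$d), digits = 10),
              format(Re(co$g), digits = 10), co$f_unit, co$z_unit, fit$gauge,
              format(fit$max_error_pct, digits = 6),
              format(fit$mean_error_pct, digits = 6),
              fit$n_iter, fit$converged,
              format(fit$pole, digits = 8), fit$pole_in_range),
    stringsAsFactors = FALSE
  )
}
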