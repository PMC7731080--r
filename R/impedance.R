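#' Cylindrical vessel geometry
#'
#' Blood vessels are idealized as perfect cylinders of length `L` and
#' cross-sectional area `A`; with resistivity rho the DC resistance is
#' `R = L * rho / A` (second Ohm's law).
#'
#' @param L Vessel length, m, > 0.
#' @param A Cross-sectional area, m^2, > 0.
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(L, A) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop_validation("L must be a positive length (m)")
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop_validation("A must be a positive area (m^2)")
  structure(list(L = L, A = A), class = "vessel_geometry")
}

#' Debye relaxation parameters
#'
#' Single-time-constant dielectric relaxation: the permittivity falls from
#' its static value `eps_s = eps_inf + delta_eps` to `eps_inf` around the
#' characteristic frequency `1 / (2 pi tau)`.
#'
#' @param eps_inf High-frequency permittivity, F/m, > 0.
#' @param delta_eps Relaxation strength `eps_s - eps_inf`, F/m, > 0.
#' @param tau Relaxation time, s, > 0.
#' @return An object of class `debye_params` (with derived accessor `eps_s`
#'   available as `eps_inf + delta_eps`).
#' @export
debye_params <- function(eps_inf, delta_eps, tau) {
  v <- c(eps_inf, delta_eps, tau)
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    stop_validation("eps_inf, delta_eps and tau must all be strictly positive")
  structure(list(eps_inf = eps_inf, delta_eps = delta_eps, tau = tau),
            class = "debye_params")
}

#' Full physical parameter set of the blood impedance model
#'
#' @param geometry A [vessel_geometry()].
#' @param phases A [phase_system()].
#' @param debye A [debye_params()].
#' @return An object of class `blood_model_params`.
#' @seealso [default_blood_params()] for an illustrative parameter set.
#' @export
blood_model_params <- function(geometry, phases, debye) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(phases, "phase_system"),
            inherits(debye, "debye_params"))
  structure(list(geometry = geometry, phases = phases, debye = debye),
            class = "blood_model_params")
}

#' @export
print.blood_model_params <- function(x, ...) {
  cat("Blood impedance model parameters\n")
  cat(sprintf("  vessel: L = %g m, A = %g m^2\n", x$geometry$L, x$geometry$A))
  cat(sprintf("  phases: sigma_h = %g S/m, k = %g, k' = %g\n",
              x$phases$sigma_h, x$phases$k, x$phases$k_prime))
  cat(sprintf("  Debye:  eps_inf = %g F/m, delta_eps = %g F/m, tau = %g s\n",
              x$debye$eps_inf, x$debye$delta_eps, x$debye$tau))
  invisible(x)
}

#' Illustrative default blood parameters
#'
#' A physically plausible whole-blood parameter set for simulation and
#' testing: a 1 cm vessel segment of 1 mm^2 cross-section, plasma
#' conductivity 1.5 S/m, hematocrit 0.45, and a beta-dispersion-like Debye
#' relaxation placing the dispersive band across tens of kHz. These values
#' are illustrative defaults chosen by the package, not measured constants.
#'
#' @param k_prime Glucose volume fraction (default 0.0040, i.e. 4.0 mmol/L
#'   in the normalized mapping of [glucose_to_kprime()]).
#' @return A [blood_model_params()] object.
#' @export
default_blood_params <- function(k_prime = 0.0040) {
  blood_model_params(
    geometry = vessel_geometry(L = 0.01, A = 1e-6),
    phases = phase_system(sigma_h = 1.5, sigma_l = 0, k = 0.45,
                          k_prime = k_prime),
    debye = debye_params(eps_inf = 4.5e-9, delta_eps = 3.5e-7, tau = 2e-6)
  )
}

#' Vessel resistance of the blood suspension
#'
#' Resistance of the cylindrical vessel filled with the effective medium:
#' \deqn{R = \frac{L}{A\,\sigma_h\,\phi^{3/2}}, \qquad \phi = 1 - k + k',}
#' i.e. second Ohm's law `R = L rho / A` with the insulating-inclusion
#' Bruggeman resistivity `rho = 1 / (sigma_h phi^(3/2))`.
#'
#' @param geometry A [vessel_geometry()].
#' @param sigma_h Plasma conductivity, S/m.
#' @param k Red-cell volume fraction.
#' @param k_prime Glucose volume fraction.
#' @return Resistance in Ohm, strictly positive.
#' @examples
#' vessel_resistance(vessel_geometry(0.01, 1e-6), 1.5, 0.45, 0)
#' @export
vessel_resistance <- function(geometry, sigma_h, k, k_prime = 0) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (any(sigma_h <= 0)) stop_validation("sigma_h must be positive")
  phi <- conductive_fraction(k, k_prime)  # validates and guarantees phi > 0
  geometry$L / (geometry$A * sigma_h * phi^1.5)
}

#' Static capacitance of the vessel
#'
#' Parallel-plate-like capacitance of the cylindrical sample,
#' `C = A * eps / L`, equivalent to the relaxation identity `C = eps rho / R`
#' with `R = L rho / A`.
#'
#' @param geometry A [vessel_geometry()].
#' @param eps Permittivity, F/m, > 0 (a real static value).
#' @return Capacitance in F.
#' @export
static_capacitance <- function(geometry, eps) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (any(!is.finite(eps)) || any(eps <= 0))
    stop_validation("eps must be positive")
  geometry$A * eps / geometry$L
}

#' Debye complex permittivity
#'
#' \deqn{\varepsilon(\omega) = \varepsilon_\infty +
#'   \frac{\Delta\varepsilon}{1 - j\omega\tau}, \qquad \omega = 2\pi f.}
#' The real part decreases monotonically from the static value
#' `eps_s = eps_inf + delta_eps` at f = 0 to `eps_inf` at high frequency;
#' the imaginary part peaks at `omega tau = 1`.
#'
#' Note the sign convention `1 - j omega tau` in the denominator, giving a
#' positive imaginary part; only the modulus enters the impedance magnitude,
#' so the overall impedance is insensitive to this choice.
#'
#' @param f Frequency in Hz, >= 0 (vectorized).
#' @param debye A [debye_params()].
#' @return Complex permittivity, F/m.
#' @export
debye_permittivity <- function(f, debye) {
  stopifnot(inherits(debye, "debye_params"))
  if (any(!is.finite(f)) || any(f < 0))
    stop_validation("f must be non-negative and finite")
  omega <- 2 * pi * f
  debye$eps_inf + debye$delta_eps / (1 - 1i * omega * debye$tau)
}

#' Reactance magnitude of the vessel
#'
#' Capacitive reactance `chi = 1 / (2 pi f C)` with `C = A eps(f) / L` and
#' the Debye permittivity of [debye_permittivity()]:
#' \deqn{|\chi|(f) = \frac{|L(1 - j2\pi\tau f)|}
#'   {|2\pi A f\,(\varepsilon_\infty + \Delta\varepsilon
#'     - j2\pi\tau f\,\varepsilon_\infty)|}.}
#' Tends to `L / (2 pi A eps_s f)` as `tau -> 0` and to 0 as `f -> Inf`.
#'
#' @param f Frequency in Hz, > 0 (vectorized).
#' @param geometry A [vessel_geometry()].
#' @param debye A [debye_params()].
#' @return Reactance magnitude in Ohm.
#' @export
reactance <- function(f, geometry, debye) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(debye, "debye_params"))
  if (any(!is.finite(f)) || any(f <= 0))
    stop_validation("f must be strictly positive (reactance diverges at f = 0)")
  eps <- debye_permittivity(f, debye)
  Mod(geometry$L / (2 * pi * geometry$A * f * eps))
}

#' Impedance magnitude of the blood-filled vessel
#'
#' Full forward model: the modulus of the series combination of the
#' effective-medium resistance and the Debye capacitive reactance,
#' \deqn{|Z|(f) = \sqrt{R^2 + |\chi|^2(f)},}
#' with `R` from [vessel_resistance()] (glucose enters through the
#' conductive fraction `phi = 1 - k + k'`) and `|chi|` from [reactance()].
#' `|Z|` decreases towards the resistive floor `R` as frequency grows, and
#' decreases with glucose concentration at fixed frequency.
#'
#' @param f Frequency in Hz, > 0 (vectorized).
#' @param params A [blood_model_params()].
#' @return Impedance magnitude in Ohm.
#' @examples
#' p <- default_blood_params()
#' impedance_modulus(c(5e4, 1e5), p)
#' @export
impedance_modulus <- function(f, params) {
  stopifnot(inherits(params, "blood_model_params"))
  R <- vessel_resistance(params$geometry, params$phases$sigma_h,
                         params$phases$k, params$phases$k_prime)
  chi <- reactance(f, params$geometry, params$debye)
  sqrt(R^2 + chi^2)
}

#' Glucose concentration to volume fraction
#'
#' Maps a blood glucose concentration in mmol/L onto the dimensionless
#' glucose volume fraction `k_prime` of the phase system.
#'
#' @param conc Glucose concentration, mmol/L, >= 0 (vectorized).
#' @param mapping A [glucose_mapping()]. The default `"paper-normalized"`
#'   mode uses the dimensionless convention `k_prime = conc * 1e-3`, so the
#'   clinically normal span 4.0-6.8 mmol/L maps to 0.0040-0.0068. The
#'   `"physical"` mode computes a true volume fraction from the molar mass
#'   and mass density of glucose:
#'   `k_prime = conc*1e-3 * molar_mass / (mass_density * 1000)`.
#' @return Dimensionless glucose volume fraction(s).
#' @examples
#' glucose_to_kprime(4.0)                              # 0.0040
#' glucose_to_kprime(5.0, glucose_mapping("physical")) # ~5.85e-4
#' @export
glucose_to_kprime <- function(conc, mapping = glucose_mapping()) {
  stopifnot(inherits(mapping, "glucose_mapping"))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop_validation("glucose concentration must be non-negative")
  switch(mapping$mode,
    "paper-normalized" = conc * 1e-3,
    "physical" = conc * 1e-3 * mapping$molar_mass /
      (mapping$mass_density * 1000)
  )
}

#' Glucose concentration mapping
#'
#' @param mode `"paper-normalized"` (dimensionless convention,
#'   `k_prime = mmol/L * 1e-3`) or `"physical"` (true volume fraction from
#'   molar mass and density).
#' @param molar_mass Glucose molar mass, g/mol (default 180.16).
#' @param mass_density Glucose mass density, g/cm^3 (default 1.54).
#' @return An object of class `glucose_mapping`.
#' @export
glucose_mapping <- function(mode = c("paper-normalized", "physical"),
                            molar_mass = 180.16, mass_density = 1.54) {
  mode <- match.arg(mode)
  if (any(c(molar_mass, mass_density) <= 0))
    stop_validation("molar_mass and mass_density must be positive")
  structure(list(mode = mode, molar_mass = molar_mass,
                 mass_density = mass_density),
            class = "glucose_mapping")
}
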