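#' Published rational coefficients (hand-to-foot dataset)
#'
#' The five rational coefficients of the published least-squares fit to the
#' 50-100 kHz hand-to-foot whole-blood spectrum at 4.0 mmol/L glucose,
#' together with the per-coefficient reference errors reported alongside
#' them. Frequencies in kHz, magnitudes in kOhm.
#'
#' @return A [rational_coefficients()] set with `ref_error_pct` attached.
#' @export
fixture_table1 <- function() {
  rational_coefficients(
    a = -1.12600,
    b = +5.07358e-3,
    c = +2.60469e-2,
    d = -5.64804e-6,
    g = +2.45902e-4,
    f_unit = "khz", z_unit = "kohm",
    ref_error_pct = c(a = 4.0, b = 7.0, c = 4.0, d = 4.0, g = 4.0)
  )
}

#' Published model-versus-experiment comparison table
#'
#' The ten-row comparison between the rational-model impedance and the
#' experimental hand-to-foot magnitudes (kHz / kOhm), with the published
#' percent-error column, transcribed verbatim.
#'
#' @return A list with `numerical` and `experimental` (both
#'   [eis_spectrum()]s on the same ten-frequency grid) and `error_pct`
#'   (the printed error column).
#' @export
fixture_table2 <- function() {
  f <- c(50.0, 55.0, 60.0, 65.6, 70.0, 75.0, 80.0, 85.0, 96.0, 100.0)
  z_num <- c(97.9, 86.8, 78.7, 71.6, 66.9, 62.3, 58.3, 54.8, 48.0, 46.4)
  z_exp <- c(97.5, 87.5, 80.0, 70.0, 65.0, 60.0, 57.5, 56.2, 50.0, 49.0)
  err <- c(0.5, 0.8, 1.6, 2.2, 2.9, 3.8, 1.4, 2.6, 4.0, 5.2)
  list(
    numerical = eis_spectrum(f, z_num, f_unit = "khz", z_unit = "kohm",
                             meta = list(label = "model (published)",
                                         glucose_mmol_l = 4.0)),
    experimental = eis_spectrum(f, z_exp, f_unit = "khz", z_unit = "kohm",
                                meta = list(label = "experimental (published)",
                                            glucose_mmol_l = 4.0)),
    error_pct = err
  )
}

#' Published reference coefficients (second dataset)
#'
#' Coefficients reported for the same rational form fitted to a second
#' published dataset (4.1 mmol/L, different electrode arrangement). The
#' underlying spectrum was never printed, so these values are bundled as
#' reference constants only; no reproduction is attempted.
#'
#' @return A [rational_coefficients()] set with `ref_error_pct` attached.
#' @export
fixture_table3 <- function() {
  rational_coefficients(
    a = -71993.4,
    b = +2.46206,
    c = +5.84262e-2,
    d = +5.87295e-2,
    g = -72208.6,
    f_unit = "khz", z_unit = "kohm",
    ref_error_pct = c(a = 1.6, b = 3.4, c = 1.6, d = 1.6, g = 1.6)
  )
}

#' Multiplicative Gaussian noise model
#'
#' Measurement noise for simulated spectra: magnitudes are multiplied by
#' `(1 + eta)` with `eta ~ N(0, sd^2)` i.i.d. Impedance analyzers' error is
#' closer to relative than absolute, hence the multiplicative form.
#'
#' @param sd Relative standard deviation (dimensionless), >= 0; 0 disables
#'   noise. Default 0.01 (1%).
#' @param seed Integer RNG seed; every noisy draw is reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 0.01, seed = 1L) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop_validation("noise sd must be a non-negative number")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_validation("seed must be an integer")
  structure(list(kind = "multiplicative-gaussian", sd = sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Run expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so no hidden randomness leaks.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a (possibly noisy) impedance spectrum
#'
#' Evaluates a forward model — either physical [blood_model_params()] (Hz /
#' Ohm) or a [rational_coefficients()] set (its own units) — on a frequency
#' grid and applies the declared [noise_model()]. With `sd = 0` the exact
#' model curve is returned; equal seeds give identical output.
#'
#' @param source A [blood_model_params()] or [rational_coefficients()].
#' @param f_grid Frequencies, strictly increasing, > 0, in the source's
#'   frequency unit.
#' @param noise A [noise_model()]; default noiseless.
#' @param meta Extra metadata merged into the spectrum's `meta`.
#' @return An [eis_spectrum()].
#' @examples
#' s <- generate_spectrum(fixture_table1(), seq(50, 100, by = 5),
#'                        noise_model(sd = 0.01, seed = 42))
#' @export
generate_spectrum <- function(source, f_grid, noise = noise_model(sd = 0),
                              meta = list()) {
  stopifnot(inherits(noise, "noise_model"))
  if (inherits(source, "blood_model_params")) {
    z <- impedance_modulus(f_grid, source)
    f_unit <- "hz"; z_unit <- "ohm"
  } else if (inherits(source, "rational_coefficients")) {
    z <- eval_rational(source, f_grid)
    f_unit <- source$f_unit; z_unit <- source$z_unit
  } else {
    stop_validation("source must be blood_model_params or rational_coefficients")
  }
  if (noise$sd > 0) {
    eta <- with_local_seed(noise$seed,
                           stats::rnorm(length(f_grid), 0, noise$sd))
    z <- z * (1 + eta)
    if (any(z <= 0))
      stop_validation("noise draw produced a non-positive magnitude; lower sd")
  }
  eis_spectrum(f_grid, z, f_unit = f_unit, z_unit = z_unit,
               meta = c(meta, list(noise_kind = noise$kind,
                                   noise_sd = noise$sd,
                                   seed = noise$seed)))
}

#' Simulate a glucose sweep of impedance spectra
#'
#' One spectrum per glucose concentration: each concentration is mapped to
#' its glucose volume fraction via [glucose_to_kprime()], substituted into
#' the phase system, and the forward model evaluated on the grid. With zero
#' noise the magnitudes are strictly decreasing in concentration at every
#' frequency (more glucose raises the conductive fraction
#' `phi = 1 - k + k'`, lowering the resistance). Noisy sweeps draw one
#' independent noise vector per concentration from sub-seeds
#' `seed + 0, 1, 2, ...` in concentration order.
#'
#' @param params Baseline [blood_model_params()]; its `k_prime` is replaced
#'   per concentration.
#' @param concentrations Glucose concentrations, mmol/L, >= 0.
#' @param f_grid Frequency grid, Hz.
#' @param mapping A [glucose_mapping()]; default paper-normalized, so
#'   4.0-6.8 mmol/L spans k' = 0.0040-0.0068.
#' @param noise A [noise_model()]; default noiseless.
#' @return A named list of [eis_spectrum()]s, one per concentration, each
#'   tagged with `glucose_mmol_l` in its `meta`.
#' @examples
#' sweep <- generate_glucose_sweep(default_blood_params(),
#'                                 seq(4.0, 6.8, by = 0.4),
#'                                 seq(5e4, 1e5, length.out = 11))
#' @export
generate_glucose_sweep <- function(params, concentrations, f_grid,
                                   mapping = glucose_mapping(),
                                   noise = noise_model(sd = 0)) {
  stopifnot(inherits(params, "blood_model_params"),
            inherits(mapping, "glucose_mapping"),
            inherits(noise, "noise_model"))
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop_validation("concentrations must be non-negative")
  out <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    conc <- concentrations[i]
    kp <- glucose_to_kprime(conc, mapping)
    p_i <- blood_model_params(
      geometry = params$geometry,
      phases = phase_system(params$phases$sigma_h, params$phases$sigma_l,
                            params$phases$k, kp),
      debye = params$debye)
    n_i <- if (noise$sd > 0) {
      noise_model(sd = noise$sd, seed = noise$seed + i - 1L)
    } else noise
    out[[i]] <- generate_spectrum(p_i, f_grid, noise = n_i,
                                  meta = list(glucose_mmol_l = conc))
  }
  names(out) <- format(concentrations)
  out
}
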