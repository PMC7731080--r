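# Independent oracles, kept deliberately separate from the implementation.

# Plain bisection on the Bruggeman residual
# (s - sl)/s^(1/3) - (1 - k)(sh - sl)/sh^(1/3) over [sl, sh].
bisect_bruggeman <- function(sh, sl, k, iters = 200) {
  rhs <- (1 - k) * (sh - sl) / sh^(1/3)
  h <- function(s) (s - sl) / s^(1/3) - rhs
  lo <- max(sl, 1e-300); hi <- sh
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Rational magnitude from raw complex coefficients, written directly.
rational_mag_complex <- function(a, b, c, d, g, f) {
  sqrt(Re(b) + Mod(a + c * f)^2 / (f^2 * Mod(g + d * f)^2))
}

# Random valid physical parameter set, drawn from broad but physical ranges.
random_params <- function() {
  blood_model_params(
    geometry = vessel_geometry(L = runif(1, 1e-3, 0.1),
                               A = runif(1, 1e-8, 1e-4)),
    phases = phase_system(sigma_h = runif(1, 0.5, 2),
                          sigma_l = 0,
                          k = runif(1, 0.05, 0.6),
                          k_prime = runif(1, 0, 0.01)),
    debye = debye_params(eps_inf = runif(1, 1e-10, 1e-8),
                         delta_eps = runif(1, 1e-9, 1e-6),
                         tau = runif(1, 1e-8, 1e-5))
  )
}
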