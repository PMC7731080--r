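geom <- vessel_geometry(L = 0.01, A = 1e-6)

test_that("vessel resistance reduces to second Ohm's law and grows with hematocrit", {
  expect_equal(vessel_resistance(geom, 1.5, 0, 0), 0.01 / (1e-6 * 1.5),
               tolerance = 1e-12)                      # 6666.67 Ohm
  R45 <- vessel_resistance(geom, 1.5, 0.45, 0)
  expect_equal(R45, 0.01 / (1e-6 * 1.5 * 0.55^1.5), tolerance = 1e-12)
  expect_equal(R45, 16344.2, tolerance = 1e-5)
  expect_gt(vessel_resistance(geom, 1.5, 0.46, 0), R45)
  # glucose lowers resistance through phi = 1 - k + k'
  expect_lt(vessel_resistance(geom, 1.5, 0.45, 0.0068), R45)
  expect_error(vessel_resistance(geom, 1.5, 0.99, -0.5),
               class = "bloodEIS_validation_error")
})

test_that("static capacitance is the parallel-plate form and linear in area", {
  expect_equal(static_capacitance(geom, 8.85e-12), 8.85e-16, tolerance = 1e-15)
  g2 <- vessel_geometry(L = 0.01, A = 2e-6)
  expect_equal(static_capacitance(g2, 8.85e-12),
               2 * static_capacitance(geom, 8.85e-12))
  # C = eps * rho / R identity with R = L rho / A
  eps <- 3e-7; rho <- 2.5
  R <- geom$L * rho / geom$A
  expect_equal(static_capacitance(geom, eps), eps * rho / R, tolerance = 1e-12)
  expect_error(static_capacitance(geom, 0), class = "bloodEIS_validation_error")
})

test_that("Debye permittivity has the correct static, high-frequency and midpoint limits", {
  db <- debye_params(eps_inf = 4.5e-9, delta_eps = 3.5e-7, tau = 2e-6)
  eps0 <- debye_permittivity(0, db)
  expect_equal(Re(eps0), db$eps_inf + db$delta_eps)
  expect_equal(Im(eps0), 0)
  expect_equal(Re(debye_permittivity(1e12, db)), db$eps_inf,
               tolerance = 1e-6)
  # at omega*tau = 1: eps_inf + delta_eps (1 + j)/2
  f_mid <- 1 / (2 * pi * db$tau)
  expect_equal(debye_permittivity(f_mid, db),
               db$eps_inf + db$delta_eps * (1 + 1i) / 2, tolerance = 1e-12)
  # real part monotone non-increasing; imaginary peaks at omega*tau = 1
  f <- 10^seq(2, 8, length.out = 200)
  eps <- debye_permittivity(f, db)
  expect_true(all(diff(Re(eps)) <= 1e-20))
  expect_equal(f[which.max(Im(eps))], f_mid, tolerance = 0.05)
})

test_that("reactance follows 1/f scaling without relaxation and vanishes at high f", {
  db <- debye_params(eps_inf = 4.5e-9, delta_eps = 3.5e-7, tau = 1e-15)
  eps_s <- db$eps_inf + db$delta_eps
  f <- c(5e4, 1e5)
  chi <- reactance(f, geom, db)
  expect_equal(chi, geom$L / (2 * pi * geom$A * eps_s * f), tolerance = 1e-6)
  expect_equal(chi[1] / chi[2], 2, tolerance = 1e-6)
  db2 <- debye_params(eps_inf = 4.5e-9, delta_eps = 3.5e-7, tau = 2e-6)
  expect_lt(reactance(1e12, geom, db2), 1)  # -> 0 as f -> Inf (as L/(2 pi A eps_inf f))
  expect_error(reactance(0, geom, db2), class = "bloodEIS_validation_error")
})

test_that("impedance modulus approaches the resistive floor at high frequency", {
  p <- default_blood_params()
  R <- vessel_resistance(p$geometry, p$phases$sigma_h, p$phases$k,
                         p$phases$k_prime)
  expect_equal(impedance_modulus(1e12, p), R, tolerance = 1e-6)
  expect_true(all(impedance_modulus(c(5e4, 1e5), p) > R))
})

test_that("glucose concentration maps to volume fraction in both conventions", {
  expect_equal(glucose_to_kprime(4.0), 0.0040)
  expect_equal(glucose_to_kprime(6.8), 0.0068)
  expect_equal(glucose_to_kprime(5.0, glucose_mapping("physical")),
               5e-3 * 180.16 / 1540, tolerance = 1e-12)
  expect_equal(glucose_to_kprime(5.0, glucose_mapping("physical")),
               5.849e-4, tolerance = 1e-4)
  expect_error(glucose_to_kprime(-1), class = "bloodEIS_validation_error")
})

test_that("normalization is element-wise, invertible, and exact for unit scales", {
  s <- fixture_table2()$experimental
  expect_equal(normalize_spectrum(s, normalization_scales()), s)
  sc <- normalization_scales(Z_norm = 1000, f_norm = 50)
  n <- normalize_spectrum(s, sc)
  expect_equal(n$z_mod, s$z_mod / 1000)
  expect_equal(n$frequency, s$frequency / 50)
  expect_equal(denormalize_spectrum(n, sc)$z_mod, s$z_mod, tolerance = 1e-15)
  expect_equal(denormalize_spectrum(n, sc)$frequency, s$frequency,
               tolerance = 1e-15)
})
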