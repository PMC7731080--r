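test_that("rational form with the bundled coefficients reproduces the published rows", {
  tb1 <- fixture_table1()
  expect_equal(eval_rational(tb1, 100.0), 46.4, tolerance = 0.005)
  expect_equal(eval_rational(tb1, 85.0), 54.8, tolerance = 0.005)
  # degenerate reductions
  null_co <- rational_coefficients(0, 0, 0, 0, 1, "khz", "kohm")
  expect_equal(eval_rational(null_co, c(1, 10, 100)), rep(0, 3))
  static_co <- rational_coefficients(a = 2, b = 3, c = 0, d = 0, g = 4,
                                     "khz", "kohm")
  f <- c(1, 5, 50)
  expect_equal(eval_rational(static_co, f), sqrt(3 + 4 / (f^2 * 16)))
})

test_that("physically mapped coefficients reproduce the forward model exactly", {
  p <- default_blood_params()
  co <- coeffs_from_physical(p)
  expect_equal(Re(co$a), p$geometry$L)
  expect_equal(Re(co$b),
               vessel_resistance(p$geometry, p$phases$sigma_h,
                                 p$phases$k, p$phases$k_prime)^2,
               tolerance = 1e-14)
  # tau -> 0 limit: c and d vanish, g = 2 pi A eps_s
  p0 <- blood_model_params(p$geometry, p$phases,
                           debye_params(4.5e-9, 3.5e-7, 1e-300))
  co0 <- coeffs_from_physical(p0)
  expect_equal(Mod(co0$c), 0, tolerance = 1e-290)
  expect_equal(Mod(co0$d), 0, tolerance = 1e-290)
  expect_equal(Re(co0$g), 2 * pi * p$geometry$A * (4.5e-9 + 3.5e-7))
  # grid equivalence
  f <- seq(5e4, 1e5, length.out = 50)
  expect_equal(eval_rational(co, f), impedance_modulus(f, p),
               tolerance = 1e-13)
})

test_that("forward model and rational form agree on randomized parameter sets", {
  set.seed(20261002)
  for (trial in seq_len(1000)) {
    p <- random_params()
    co <- coeffs_from_physical(p)
    f <- sort(runif(50, 1e3, 1e6))
    z1 <- impedance_modulus(f, p)
    z2 <- eval_rational(co, f)
    expect_lt(max(abs(z1 - z2) / z1), 1e-12)
  }
})

test_that("percent errors match direct arithmetic and are zero only at identity", {
  expect_equal(percent_errors(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(percent_errors(46.4, 49.0), 100 * abs(46.4 - 49) / 49)
  expect_equal(percent_errors(46.4, 49.0), 5.31, tolerance = 1e-3)
  expect_equal(percent_errors(97.9, 97.5), 0.41, tolerance = 1e-2)
  expect_true(all(percent_errors(c(1.1, 0.9), c(1, 1)) > 0))
  expect_error(percent_errors(1:3, 1:2), class = "bloodEIS_validation_error")
})

test_that("pole frequency is the real denominator root when positive", {
  tb1 <- fixture_table1()
  expect_equal(pole_frequency(tb1), 2.45902e-4 / 5.64804e-6, tolerance = 1e-6)
  expect_equal(pole_frequency(tb1), 43.5, tolerance = 1e-3)
  expect_true(is.na(pole_frequency(
    rational_coefficients(1, 1, 1, 0, 1, "khz", "kohm"))))
  expect_true(is.na(pole_frequency(
    rational_coefficients(1, 1, 1, 2, 1, "khz", "kohm"))))  # same sign g, d
})

test_that("eval_rational is gauge invariant under common coefficient rescaling", {
  tb1 <- fixture_table1()
  f <- seq(50, 100, by = 2.5)
  base <- eval_rational(tb1, f)
  for (lam in c(-3, 0.01, 7)) {
    sc <- rational_coefficients(tb1$a * lam, tb1$b, tb1$c * lam,
                                tb1$d * lam, tb1$g * lam, "khz", "kohm")
    expect_equal(eval_rational(sc, f), base, tolerance = 1e-13)
  }
})

test_that("noiseless synthetic spectra give back the generating gauge invariants", {
  tb1 <- fixture_table1()
  f <- seq(50, 100, length.out = 25)
  s <- generate_spectrum(tb1, f)
  fit <- fit_rational(s)
  co <- fit$coefficients
  inv <- function(x) c(b = Re(x$b), a_over_g = Re(x$a) / Re(x$g),
                       c_over_d = Re(x$c) / Re(x$d),
                       zero = -Re(x$a) / Re(x$c), pole = -Re(x$g) / Re(x$d))
  expect_equal(inv(co), inv(tb1), tolerance = 1e-6)
  expect_true(fit$converged)
  # monotone improvement over the initialization
  expect_lte(fit$objective, fit$init_objective)
})

test_that("fit to the published experimental points beats the published worst-case error", {
  tb2 <- fixture_table2()
  fit <- fit_rational(tb2$experimental)
  expect_true(fit$converged)
  expect_lte(fit$max_error_pct, 5.2)
  expect_gte(fit$max_error_pct, fit$mean_error_pct)
  expect_true(all(fit$residual_pct >= 0))
})

test_that("fit is deterministic and respects a user-supplied initialization", {
  tb2 <- fixture_table2()
  f1 <- fit_rational(tb2$experimental)
  f2 <- fit_rational(tb2$experimental)
  expect_identical(f1$coefficients, f2$coefficients)
  # user init from the published set, rescaled into the gauge
  f3 <- fit_rational(tb2$experimental, init = fixture_table1())
  expect_true(f3$converged)
  expect_lte(f3$objective, f3$init_objective)
  expect_lte(f3$max_error_pct, 5.2)
  expect_error(fit_rational(eis_spectrum(1:4, c(4, 3, 2, 1),
                                         "khz", "kohm")),
               class = "bloodEIS_validation_error")
})

test_that("fitted curve from 1% noisy data stays within 3% of the noiseless truth", {
  tb1 <- fixture_table1()
  f <- fixture_table2()$numerical$frequency
  truth <- eval_rational(tb1, f)
  s <- generate_spectrum(tb1, f, noise_model(sd = 0.01, seed = 7))
  fit <- fit_rational(s)
  expect_true(fit$converged)
  rel <- abs(eval_rational(fit$coefficients, f) - truth) / truth
  expect_lt(max(rel), 0.03)
})

test_that("evaluation refuses real-coefficient poles inside the guard", {
  co <- rational_coefficients(a = -1, b = 1, c = 0.02, d = -1, g = 60,
                              "khz", "kohm")
  expect_error(eval_rational(co, 60, pole_guard = 1e-6),
               class = "bloodEIS_validation_error")
  expect_silent(eval_rational(co, 80))
})
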