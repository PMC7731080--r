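---
title: "Modelling whole-blood impedance spectra as a function of glucose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-blood impedance spectra as a function of glucose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodEIS)
```

## The physical model

`bloodEIS` models whole blood as a two-phase suspension: a conductive host
(plasma, conductivity $\sigma_h$) containing insulating inclusions — red
cells at volume fraction $k$ (the hematocrit) and glucose molecules at
volume fraction $k'$. Three layers compose the forward model.

**Effective conductivity.** The bulk conductivity $\sigma_m$ of the
suspension follows the Bruggeman asymmetric effective-medium equation for
spherical inclusions,
$$\frac{\sigma_m - \sigma_l}{\sigma_m^{1/3}}
  = (1-k)\,\frac{\sigma_h - \sigma_l}{\sigma_h^{1/3}},$$
solved by `solve_bruggeman()`. For perfectly insulating inclusions
($\sigma_l = 0$) the root has the closed form
$\sigma_m = (1-k)^{3/2}\sigma_h$ (`effective_conductivity_insulating()`),
and the solver is required (and tested) to agree with it to $10^{-10}$
relative. The residual is continuous and monotone on
$[\sigma_l, \sigma_h]$, so a bracketed scalar root search is used
(`stats::uniroot`, absolute tolerance $10^{-12}$ S/m, at most 200
iterations) — robustness was preferred over speed, since each solve is a
scalar problem. The degenerate corner $k = 1$, $\sigma_l = 0$ returns the
exact limit $\sigma_m = 0$ instead of being solved numerically.

**Volume bookkeeping.** Glucose is assumed to displace plasma volume while
the red-cell volume stays fixed, so the conductive fraction is
$\phi = 1 - k + k'$ (`conductive_fraction()`), constrained to $(0, 1]$.
A direct consequence — worth flagging because it is not obvious — is that
impedance *decreases* as glucose increases: larger $k'$ raises $\phi$ and
lowers the resistance. The package implements the relation as stated and
property-tests the monotonicity rather than reinterpreting the sign.

**Vessel impedance.** Blood vessels are idealized as perfect cylinders of
length $L$ and cross-section $A$ at constant temperature. The resistance is
$R = L / (A \sigma_h \phi^{3/2})$ (`vessel_resistance()`); the capacitance
is the parallel-plate form $C = A\varepsilon/L$ with a single-time-constant
Debye permittivity
$\varepsilon(\omega) = \varepsilon_\infty + \Delta\varepsilon/(1 - j\omega\tau)$,
$\omega = 2\pi f$ (`debye_permittivity()`), giving the reactance magnitude
$|\chi|(f)$ (`reactance()`) and finally
$|Z|(f) = \sqrt{R^2 + |\chi|^2}$ (`impedance_modulus()`). All physical
operations are in SI units (Hz, Ω, m, F/m); kHz/kΩ appear only in the
empirical-fit layer and file I/O, controlled by explicit unit tags.

## The rational form and its canonical reading

Substituting the Debye permittivity into the reactance shows that the
magnitude is exactly a five-coefficient rational form in frequency,
$$|Z|(f) = \sqrt{\,b + \frac{(a + c f)^2}{f^2\,(g + d f)^2}\,},$$
with the physical mapping $a = L$, $b = R^2 = (L/A)^2/(\sigma_h^2\phi^3)$,
$c = -j2\pi\tau L$, $d = -j4\pi^2 A \varepsilon_\infty \tau$,
$g = 2\pi A(\varepsilon_\infty + \Delta\varepsilon)$
(`coeffs_from_physical()`), squares read as squared moduli for complex
sets. Three reading choices deserve a note, because printed sources in this
area are typographically unreliable:

* The bracketing above is the only one that makes the rational form
  identical to $\sqrt{R^2 + \chi^2}$ with $b = R^2$ and
  $\chi = (a+cf)/(f(g+df))$; it also reproduces the bundled published
  model column from the bundled published coefficients to about 1% or
  better, while alternative bracketings are wrong by orders of magnitude.
* The angular frequency is the standard $\omega = 2\pi f$ — it is the only
  convention consistent with the $2\pi\tau$ and $4\pi^2$ factors in the
  coefficient mapping.
* The resistive term under the square root carries $(L/A)^2$, i.e. it
  equals $R^2$ exactly.

The package treats the agreement between `impedance_modulus()` and
`eval_rational(coeffs_from_physical(...))` as a machine-precision identity
and tests it at $10^{-12}$ relative over 1000 randomized parameter sets on
50-point grids — a deliberate dual-route check, since the two sides are
computed by independent code paths.

## Fitting: gauge, initialization, numerics

The rational form is unchanged when $(a, c, g, d)$ are scaled by a common
factor, so the five coefficients are only identified up to that gauge. The
fitter (`fit_rational()`, Levenberg–Marquardt via `minpack.lm::nls.lm`)
therefore imposes exactly one scale constraint — by default $a = -1$,
matching the sign convention of the bundled published set; $g = 1$ is
selectable. Recovery is asserted only on gauge-invariant quantities:
$b$, $a/g$, $c/d$, the numerator zero $-a/c$ and the denominator pole
$-g/d$.

Numerical choices:

* **Objective.** Unweighted sum of squared magnitude residuals
  (magnitude-only fitting; complex impedance fitting is out of scope).
* **Positivity of $b$.** $b$ equals a squared resistance; it is kept
  non-negative by an internal $b = s^2$ parametrization, which also keeps
  the square root defined throughout the search.
* **Initialization** (automatic, deterministic): the numerator zero is
  seeded at $0.95 f_{\min}$ and the pole at $0.9 f_{\min}$ — just below
  the measured band, where both landed for the bundled reference fit —
  and $b$ at $(\min|Z|)^2$. The $(g,d)$ scale is set by matching the
  measured magnitude at $f_{\max}$, the point farthest from the seeded
  pole and zero, where the match is well conditioned. (Matching at
  $f_{\min}$ would be degenerate: the seeded zero makes the numerator
  vanish there.)
* **Convergence.** Relative objective/parameter change below $10^{-12}$
  or 500 iterations; non-convergence raises a classed error with the
  optimizer's diagnostics, never a silent result. The objective at the
  returned coefficients never exceeds the objective at the
  initialization (tested).
* **Pole guard.** Real coefficient sets are refused evaluation where
  $|g + df| < 10^{-12}$ (in fit units); a fitted pole that lands inside
  the data band sets a warning flag (`pole_in_range`) rather than
  failing, since the fit may still interpolate acceptably.
* **Percent errors** are normalized by the experimental value,
  $e_i = 100\,|Z_{\mathrm{model},i} - Z_{\mathrm{exp},i}|/Z_{\mathrm{exp},i}$.
  Recomputing them from rounded published magnitudes reproduces the
  published error column only up to ~0.1 percentage points (0.41 vs a
  printed 0.5 at the low end of the band); the discrepancy is attributable
  to unrounded internals behind the published table and is documented, not
  "corrected".

The per-coefficient "error %" values attached to the bundled coefficient
sets are reproduced as reference constants only; their generating
definition is not a standard residual quantity and is not recomputed.

## Bundled reference data and the synthetic generator

Two published reference objects are bundled in code (`fixture_table1()`,
`fixture_table2()`): a five-coefficient fitted set (kHz/kΩ) and the
ten-row model-versus-experiment comparison it produced, for a hand-to-foot
whole-blood spectrum at 4.0 mmol/L glucose on a 50–100 kHz band. A second
published coefficient set (`fixture_table3()`) is bundled as constants
only — its underlying spectrum was never printed, so no reproduction is
attempted. Figure-level curves are deliberately *not* digitized: manual
curve extraction is the dominant acknowledged error source in this data
chain, and the transcribed table is the only fixture trustworthy to the
digit.

`generate_spectrum()` simulates measurements from either a physical
parameter set or a coefficient set, with multiplicative Gaussian noise
(magnitude × $(1+\eta)$, $\eta \sim N(0, \mathrm{sd}^2)$, default sd 0.01):
impedance analyzer error is closer to relative than absolute. Every noisy
draw requires an explicit seed, applied in a local RNG scope so the
caller's random stream is untouched; there is no hidden randomness in the
package. `generate_glucose_sweep()` produces one spectrum per
concentration; the default mapping (`glucose_mapping("paper-normalized")`)
is the dimensionless convention $k' = \mathrm{mmol/L} \times 10^{-3}$, so
the clinically normal span 4.0–6.8 mmol/L maps to $k' = 0.0040$–$0.0068$.
A `"physical"` mode computes a true volume fraction from glucose's molar
mass (180.16 g/mol) and density (1.54 g/cm³) instead — roughly a factor 8.5
smaller — for forward-simulation realism.

The baseline physical parameters (`default_blood_params()`) are
illustrative, chosen once for plausibility, not measured constants: a 1 cm
vessel segment of 1 mm² cross-section, plasma conductivity 1.5 S/m,
hematocrit 0.45, and a relaxation ($\varepsilon_\infty = 4.5$ nF/m,
$\Delta\varepsilon = 350$ nF/m, $\tau = 2$ µs) that places a dispersive,
tens-of-kΩ magnitude across the 50–100 kHz band, resembling the bundled
reference spectra in scale and shape.

**What passing tests do and do not show.** The synthetic generator
emulates the *model plus relative measurement noise*. It does not emulate
electrode–skin interface impedance, hematocrit variability, flow
dependence of conductivity, cell-membrane (multi-dispersion) effects, or
other blood constituents — all of which affect real spectra. Green
parameter-recovery and monotonicity tests therefore validate the
implementation and the identifiability of the rational form, not the
physiological accuracy of the model on real subjects.

## Known limitations

* Single-Debye permittivity only; no Cole–Cole or multi-dispersion
  relaxation. The model's own validity band is bounded above by membrane
  capacitance effects it ignores, and below by the fitted denominator
  pole (`pole_frequency()`, ≈43.5 kHz for the bundled set against a
  50–100 kHz band).
* Spherical inclusions only (no ellipsoidal depolarization factors), no
  percolation variants, no temperature dependence.
* The glucose sensitivity of $|Z|$ is small compared with the frequency
  dependence itself; in the default parameters a 4.0→6.8 mmol/L sweep
  moves the magnitude by only ~0.02%. Any practical estimator built on
  this model needs measurement precision at that level.
* The normalization scales that render spectra dimensionless
  (`normalization_scales()`) are user-supplied: the model fixes none of
  them numerically.

## Problem sizes used by the test suite

The suite runs in seconds: the oracle-equivalence property uses 1000
randomized parameter sets × 50-point grids; closed-form agreement uses a
30-point $(k, \sigma_h)$ grid; recovery tests use 25-point noiseless and
10-point noisy (sd 1%, fixed seed) spectra; monotonicity suites use grids
of 8–40 points. These sizes were chosen as comfortably sufficient for the
tolerances asserted, and are stated here so they can be scaled up by
anyone wanting stronger evidence.
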