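---
title: "Isothermal analysis of DSF binding studies: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isothermal analysis of DSF binding studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DSFbinding)
```

# The model and its assumptions

`DSFbinding` analyses thermal-shift binding studies under three assumptions:

1. **Reversible two-state unfolding.** The protein populates only folded (F)
   and unfolded (U) states, with
   $\Delta G_U(T) = \Delta H_{T_m}\,(1 - T/T_m) + \Delta C_p\,[(T - T_m) -
   T\ln(T/T_m)]$. The entropy at the midpoint is not an independent
   parameter: it is fixed by $\Delta G_U(T_m) = 0$. Written in this grouped
   form every term vanishes identically at $T = T_m$, so the midpoint
   condition holds to machine precision for any $\Delta C_p$.
2. **1:1 binding to the folded state only.** $K_d = [F][L]/[FL]$; binding of
   the unfolded state is not modelled. Free ligand follows the mass balance
   with the bindable pool taken as $[P]_0/(K_U+1)$; an exact three-species
   solution (`freeLigandExact()`, a quadratic with effective constant
   $K_d(1+K_U)$) is provided as a cross-check but deliberately not used in
   fitting, so that simulation and analysis share one convention.
3. **Fluorescence distinguishes folded from unfolded only.** The signal is a
   convex combination of two linear baselines weighted by the fraction
   unfolded; the folded--bound complex emits like folded--unbound.

The dissociation constant extracted at a temperature $T_{iso}$ is the
equilibrium constant *at that temperature*. It is expected to vary across
the scanned range, and it is not corrected for the temperature dependence of
binding enthalpy -- comparisons with, say, calorimetry at 20 degC must keep
this in mind.

# The pipeline

1. **Local fits** (`fitLocal`): each curve is fitted individually with six
   parameters (T_m, dH, two baseline slopes, two intercepts) at a fixed
   $\Delta C_p$. T_m is constrained to the analysis window and dH to
   (0, 1000] kcal/mol.
2. **Global fit** (`fitGlobal`): one least-squares problem over all curves;
   baseline slopes (and optionally $\Delta C_p$) are shared, everything else
   stays per-curve, initialized from the local fits (shared slopes from the
   median of the local slopes). Standard errors come from the square root of
   the covariance diagonal.
3. **Fraction unfolded** (`fuProfile`): evaluated per curve at chosen
   temperatures from the fitted (T_m, dH) and the study-level $\Delta C_p$.
   No ligand term appears here: the per-curve parameters already absorb the
   ligand effect.
4. **Isothermal binding fit** (`fitBindingIsothermal`,
   `scanTemperatures`): $f_u([L]_0) = K_U / (K_U + 1 + [L]_{free}/K_d)$ is
   fitted at each scanned temperature; the temperature with the smallest
   relative K_d error is selected (`Tsel`). On clean data that minimum sits
   near the apo melting temperature, which is also where a deliberately
   wrong $\Delta C_p$ does the least damage.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| analysis window | full grid | degC | select one transition; T_m is bounded by it |
| dCp (fixed) | 0 | kcal/(mol K) | common practice when no calorimetric value exists |
| dCp bounds (fitted) | [0, 20] | kcal/(mol K) | unfolding increases heat capacity; override allowed |
| dH bounds | (0, 1000] | kcal/mol | positivity is part of the model |
| binding-fit scales | log10 Kd in [-12, 0], log10 Ku in [-6, 6] | -- | conditioning; picomolar-to-molar coverage |
| isothermal weights | unweighted | -- | propagated fu errors are approximate (below) |

Concentrations are molar everywhere internally; the sample sheet accepts SI
suffixes (`"2mM"`, `"610nM"`). Temperatures are degC at every interface and
Kelvin inside all thermodynamic expressions. Baselines are evaluated on the
Celsius scale (intercept = signal extrapolated to 0 degC); the signal model
is scale-agnostic, so this is a convention, fixed once, not physics.

# The simulator: what it emulates, and what it does not

`simulateStudy()` builds each curve from the model above: apo
$\Delta G_U(T)$ from (TmApo, dHApo, dCpTrue), the ligand-free unfolding
constant at each temperature, free ligand from the mass balance with a
**temperature-independent K_d**, then the signal with linear baselines.
Noise is i.i.d. Gaussian with sigma equal to `noisePct` times the dynamic
range of the *whole noiseless study* (not per curve), seeded for bit
reproducibility. Defaults describe a realistic ratio-type study: apo T_m 50
degC, dH 120 kcal/mol, 14 two-fold dilutions from 2 mM plus an apo sample,
a 20--95 degC ramp at 0.5 degC steps, 2% noise.

What the simulator does **not** emulate -- and hence what a green round-trip
test does not establish robustness against:

* temperature dependence of K_d (binding enthalpy/heat capacity). One
  consequence: the T_m-shift model's known failure for tight (sub-uM)
  binders barely shows on simulated data, because that failure is driven
  mostly by the T dependence of binding that the simulator excludes.
* irreversible or kinetically controlled unfolding (heating-rate effects),
  multi-domain/multi-transition melts, aggregation;
* ligand autofluorescence or quenching, non-linear baselines, instrument
  drift.

Noiseless round trips are still not exact for ligand-containing curves: the
ligand-coupled $\Delta G$ is not exactly of two-state form, so compressing a
curve into per-curve (T_m, dH) carries an intrinsic model error of order
$10^{-3}$ in $f_u$, i.e. a few percent in K_d when P0 is comparable to K_d.
Choosing P0 below K_d (as recommended for real experiments) keeps the
noiseless round-trip error well under 1%.

# Numerical choices

* **Optimizer**: bounded trust-region nonlinear least squares via
  `nls(algorithm = "port")`, tolerance 1e-10, up to 5000 iterations. Fits
  that stop with "singular convergence" on numerically perfect data
  (residual variance below 1e-12 of the signal variance) are accepted as
  converged; where the optimizer's internal covariance factor degenerates,
  standard errors are recomputed from a central-difference Jacobian.
* **Local-fit initialization** by variable projection: given (T_m, dH,
  dCp), the signal model is linear in the four baseline parameters, so a
  coarse grid over (T_m, dH) with baselines solved by linear least squares
  locates the correct basin even for awkward shapes -- in particular cold
  denaturation, which appears at large $\Delta C_p$ and defeats the usual
  "baselines from the curve edges" heuristic. A smoothed-derivative
  extremum supplies one extra T_m candidate; failed fits are retried from
  T_m at window quantiles.
* **Fitting $\Delta C_p$**: the joint residual surface is a long shallow
  valley with spurious stops. The optimization starts at 0, as a cold start
  should, but proceeds as a profile continuation: fixed-$\Delta C_p$ global
  fits walked upward from 0 over a coarse grid select the basin, and the
  joint fit then releases $\Delta C_p$ from the profile minimizer. A single
  cold joint fit from 0 is demonstrably trapped (it can return ~1 when the
  truth is 12).
* **Free ligand**: the mass-balance root is evaluated in a cancellation-free
  arrangement (discriminant as a sum of positive terms, conjugate root form
  on the branch where subtraction would cancel). This is exact algebra on
  the same expression, required to reach ~1e-15 relative accuracy.
* **Error propagation** into $f_u$ uses the delta method on the marginal
  (T_m, dH) variances, ignoring their covariance. The covariance is often
  ill-conditioned in these fits; the resulting `fuErr` is therefore
  approximate, which is why the binding fit is unweighted by default.
* **Degenerate inputs**: flat curves (no transition) are flagged, not
  fitted; curves whose local fit yields no usable estimates are excluded
  from the global fit with a warning; a global fit whose T_m estimates pin
  at the window edge aborts the pipeline with a "no shift" status; a
  binding fit whose $f_u$ spread is below 0.02 is flagged "no shift
  detected"; estimates landing on a parameter bound are flagged and not
  counted as converged. Tsel ties resolve to the lower temperature (first
  minimum).

# Design decisions on open points

* **K_U is co-fitted** with K_d rather than fixed from the apo curve; the
  apo point initializes it ($K_U = f_u(0)/(1-f_u(0))$, clipped to
  [1e-4, 1e4]). Fixing it would propagate any apo-curve artefact directly
  into every K_d.
* **$\Delta C_p$ is strictly study-global** and bounded below by 0 by
  default (override via `dCpBounds`); per-curve heat-capacity changes are
  not modelled.
* **Replicates** are fitted as independent curves sharing their L0; no
  averaging before fitting, preserving the error structure.
* **Model 2's (Tm0, dH0) are fixed from the apo global fit** by default; a
  `coFit` flag releases them. Three free parameters on a dozen T_m points
  is fragile, and the apo fit knows both quantities better.
* The empirical single-site T_m interpolation (model 1) is implemented with
  the free-protein fraction from the exact 1:1 quadratic; its result always
  carries a caveat that it has no physico-chemical foundation and should
  not be reported as a binding affinity.
* The sample sheet is JSON (the only structured text format with a parser
  in the supported dependency set); the curve table is plain CSV with a
  `Temperature` column. Vendor exports are expected to be converted to this
  contract.

# Known limitations

* All results inherit the two-state, reversible, 1:1 assumptions; systems
  with irreversible unfolding can still give useful relative affinities,
  but the absolute numbers lean on cancellation, and heating-rate
  consistency between compared studies is essential.
* K_d values are per-temperature; extrapolation to other temperatures needs
  external information (e.g. a van 't Hoff analysis, out of scope here).
* The benchmark grid at full scale (all K_d x P0 decades x dCp x noise)
  is computationally heavy; the default reduced grid covers the structure
  of the full experiment and the full grid sits behind a CLI flag.
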