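---
title: "Models and methods for lamellar-phase SANS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for lamellar-phase SANS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellaR)
```

## Scope

lamellaR analyses reduced, absolute-scale SANS curves $I(q)$ from
lyotropic lamellar phases — stacks of surfactant bilayers of thickness
$\delta$ at repeat distance $d$, water gap $\bar d = d - \delta$,
membrane volume fraction $\phi$. It covers four connected tasks: fitting
the diffuse-plus-Bragg intensity model to individual curves; estimating
the bilayer thickness from the thin-sheet (Kratky–Porod) regime;
fitting the swelling law $d = \delta/\phi$ across a dilution series; and
converting geometry into elastic quantities (Caillé parameter,
undulation and electrostatic compression moduli). A synthetic generator
produces resolution-smeared, noisy curves with the same statistical
structure, so every estimator can be validated end-to-end.

## The intensity model

The scattered intensity is the sum of two contributions, each a
Lorentzian in $q$:

$$I(q) = \frac{A_z}{1 + q^2\xi_p^2}
       + \frac{A_B}{1 + (q-q_0)^2\xi_l^2} + b .$$

The first (diffuse) term describes in-plane concentration fluctuations
of amplitude $A_z$ (cm$^{-1}$) with correlation length $\xi_p$ (Å); it
decays monotonically and dominates disordered, dilute stacks. The
second (structured) term is the first-order Bragg peak of the periodic
stacking at $q_0$ (Å$^{-1}$) with interlamellar correlation length
$\xi_l$ (Å): larger $\xi_l$ means a sharper peak and longer-ranged
smectic order. At $q = q_0$ with $A_z = b = 0$ the model returns
exactly $A_B$. The flat background $b$ (default 0, optionally fitted)
represents incoherent scattering present in any real measurement; with
$b = 0$ the model is the plain five-parameter form. Well-ordered
charged or polymer-doped stacks can show a second-order reflection at
$2q_0$; the generator supports this through an optional
`second_order` attribute carrying its own amplitude and width, kept
outside the five-parameter fit model.

## Elastic relations

For a stack stabilised by thermal undulations, the inter-membrane
repulsion per unit area is

$$V(\bar d) = \frac{3\pi^2}{128}\frac{(k_BT)^2}{\kappa\,\bar d^{\,2}},$$

with $\kappa$ the bending modulus (J). The Caillé parameter, which
governs Bragg-peak lineshape broadening by layer-displacement
fluctuations, is in general

$$\eta = \frac{q_0^2\,k_BT}{8\pi\sqrt{\bar B K}},\qquad K=\kappa/d,$$

and in the Helfrich-dominated limit reduces to the purely geometric

$$\eta = m\,\pi^2\,(1-\delta/d)^2 = \tfrac{4}{3}\,(\bar d/d)^2,
\qquad m = \tfrac{4}{3\pi^2},$$

which under ideal swelling ($\bar d/d = 1-\phi$) gives
$\eta = \tfrac43(1-\phi)^2$: 1.20, 1.08, 0.85, 0.65 at
$\phi$ = 5, 10, 20, 30%. The package closes this loop internally: the
undulation compression modulus `helfrich_B()`,
$\bar B = d\,\partial^2V/\partial\bar d^{\,2}
 = \frac{9\pi^2}{64}(k_BT)^2 d/(\kappa\bar d^{\,4})$,
inserted into the general expression with $q_0 = 2\pi/d$, reproduces
the geometric form identically for any $\kappa$ — a strong unit- and
prefactor-consistency check that the tests exercise, alongside a
finite-difference oracle for the second derivative.

For salt-free charged stacks, `electrostatic_B()` implements the
counterion-only (Gouy–Chapman) limit: the osmotic pressure between
plates is $P = \pi k_BT/(2 l_B \bar d^{\,2})$, whence
$\bar B = \pi k_BT\,d/(l_B\bar d^{\,3})$, with the Bjerrum length
$l_B = 7$ Å for water. Only its sign, monotonicity and scaling are used
quantitatively: a reported compression-modulus column for the neutral
series cannot be reproduced without a stated $\kappa$, so the package
makes no attempt to, and covers the elastic stack with property tests
(trends, scalings, derivative consistency) instead.

## Thin-sheet form factor and thickness estimation

In the dilute, weak-interaction regime the bilayer scatters as a
randomly oriented thin sheet,

$$I(q) = \frac{2\pi\phi\,\Delta\rho^2\,\delta}{q^2}
         \exp\!\left(-\frac{q^2\delta^2}{12}\right),$$

with contrast $\Delta\rho = 6\times10^{10}$ cm$^{-2}$ by default (the
`slab_model` also records a nominal membrane volume
$V_A = 3\times10^{-7}$ cm$^3$ for traceability; the per-unit-volume
absolute intensity is already normalised through $\phi$). The form is
the Guinier expansion of the slab form factor and is quantitatively
valid for $q\delta \lesssim 2$; beyond that the true slab oscillations
deviate from the Gaussian tail, which is why `slab_intensity()`
documents the window and `estimate_thickness_kratky()` takes an
explicit regression window rather than using the full curve.

`estimate_thickness_kratky()` regresses $\ln(q^2I/\phi)$ on $q^2$ and
returns $\delta = \sqrt{-12\,s}$ from the slope $s$, with the standard
error propagated as $\sigma_\delta = 6\,\sigma_s/\delta$. The
$\phi$ normalisation removes the concentration dependence so windows
from different dilutions are comparable; the estimate is invariant
under intensity rescaling. A non-negative slope raises an error — it
signals non-lamellar scattering or a wrongly placed window rather than
a thickness of zero.

## Swelling-law fit

`fit_swelling()` regresses $d$ on $1/\phi$ **through the origin**: the
law $d = \delta/\phi$ has no intercept, so a free intercept would trade
slope against it and bias $\delta$; a free-intercept variant remains
available behind `intercept = TRUE` as a lever for diagnosing
non-ideal swelling. A single $(\phi, d)$ pair determines the slope
exactly (returned with an `NA` standard error); two or more distinct
$\phi$ give a standard error from the regression.

## Fitting machinery and numerical choices

`fit_nallet()` minimises weighted residuals with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`, non-negativity bounds on all
parameters), weights $1/\sigma^2$ when the curve carries uncertainties
and unweighted otherwise. Because the surface can have shallow or
multiple minima, the optimiser is multi-started: the supplied or
heuristic start plus five multiplicatively jittered copies
(factors uniform in $[0.8, 1.2]$, controlled by a seed), keeping the
lowest residual sum of squares.

When no starting values are given they are derived from the curve:
background from the median intensity of the top decade of $q$; the
diffuse term from a linearised Lorentzian fit
($1/I$ vs $q^2$) over the lowest decade; the Bragg position from peak
detection with $\xi_l \approx 2/\mathrm{FWHM}$. If no peak is detected
the Bragg term is frozen at zero — a flat curve therefore collapses
cleanly to pure background.

Parameter uncertainties come from the numerical Jacobian at the
optimum, inverted on the column-scaled (correlation-form) normal
matrix so that parameters differing by many orders of magnitude are
treated evenly. A parameter whose gradient column is numerically zero
relative to the largest (factor $10^{-8}$) is reported as
not-determined (`NA`, printed `"N.D."`): this is exactly the situation
of a vanishing-width Bragg term, whose correlation length and position
leave no imprint on the curve. For synthetic, background-free curves
the background should be excluded from the fit
(`fit_background = FALSE`): a free constant is perfectly collinear
with a vanishing-width Bragg Lorentzian, and removing it keeps $A_B$
identifiable in that degenerate corner.

`detect_bragg_peak()` searches $q^2I(q)$ for interior local maxima and
accepts the most prominent one whose topographic prominence (height
above the higher flanking minimum within a 15-point window) exceeds 3
times a robust local noise scale, estimated from the median absolute
second difference of $q^2I$ (for i.i.d. noise of sd $\sigma$ the second
difference has sd $\sqrt6\,\sigma$; the median makes the estimate
insensitive to the peak's own curvature). Strictly monotone curves have
no interior maxima, so the detector's specificity on diffuse-only
curves is structural, not statistical.

## What the synthetic generator emulates — and what it does not

`generate_nallet_curve()`/`generate_slab_curve()` compose the forward
model with (i) Gaussian $q$-resolution smearing and (ii) multiplicative
Gaussian noise. The defaults encode the measurement conditions of the
study this analysis targets: a 200-point logarithmic grid over
$q \in [0.002, 0.4]$ Å$^{-1}$; per-configuration resolution widths
$\{1, 2.8, 5\}\times10^{-3}$ Å$^{-1}$ assigned to the low/mid/high
thirds of the grid (three detector distances); 3% wavelength spread
(recorded, folded into the widths); 2% relative noise by default, with
per-point $\sigma = 0.02\,I$ reported, and all randomness behind one
integer seed (bit-reproducible, and the caller's RNG stream is left
untouched).

Smearing is computed by evaluating the *model function* at 41
Gauss-weighted nodes over $\pm4\sigma_q$ around each grid point — not
by convolving the sampled curve — so there are no interpolation
artefacts and no edge effects except where the kernel is truncated at
$q \le 0$. With a uniform kernel width this conserves the Porod
integral $\int q^2 I\,dq$ away from the grid edges (tested to 0.5%);
at a boundary between two configuration widths strict conservation
cannot hold, mirroring the seams of real multi-configuration
measurements. Smearing strictly broadens the Bragg peak, so a plain
model fitted to a smeared curve underestimates $\xi_l$ — the generator
sets a `resolution_warning` attribute when the kernel width at the
peak exceeds a fifth of the peak width.

What the generator does **not** emulate: Poisson counting statistics
(reduced absolute-scale data no longer carry counts, so a fractional
Gaussian model is the honest choice), inter-point correlations
introduced by real reduction software, beamstop/transmission effects,
multiple scattering, and any 2-D detector physics. Passing tests
therefore demonstrate estimator correctness under the stated noise
model, not robustness to every artefact of real spectrometer data.

`generate_dilution_series()` builds a series at distinct volume
fractions sharing one $\delta$, placing each Bragg peak at
$q_0 = 2\pi\phi/\delta$ and failing loudly (naming the offending
$\phi$) if a peak falls outside the instrument span.

## Batch pipeline

`run_pipeline()` chains the pieces per sample — read, fit, Bragg
spacing — then fits the swelling law across all peaked members and
computes each sample's Helfrich-limit $\eta$ from
$(\delta, d)$, taking $d$ from the fitted peak where present and from
$\delta/\phi$ otherwise. Per-sample failures become `failed:` rows
without stopping the batch. Reports are deterministic given inputs and
seed; `output_dir` writes a TSV table (not-determined uncertainties
rendered `N.D.`) and a JSON results file recording the seed.

## Conventions, defaults and problem sizes

* Units: $q$ in Å$^{-1}$, lengths in Å, intensities in cm$^{-1}$,
  $\kappa$ in J, $\bar B$ in Pa;
  $k_B = 1.380649\times10^{-23}$ J K$^{-1}$; default temperature
  293.15 K (samples equilibrated at 20 °C).
* $\phi$ is the **membrane** volume fraction throughout — the reading
  required by the swelling law and the ideal-swelling Caillé values.
* Validation errors name the offending field; divergent limits
  ($\bar d = 0$, $\phi = 0$, $q_0 = 0$) raise errors rather than
  returning `Inf`.
* Test and validation problem sizes: 200-point curves, 20-seed
  noise-coverage loops, 50-seed thickness Monte Carlo — sizes at which
  every stochastic check is stable under reasonable seed changes while
  the whole suite runs in seconds.

## Known limitations

* The two-Lorentzian intensity model is the dilute-phase description;
  it does not implement power-law Caillé lineshapes or finite-stack
  structure factors, so $\eta$ is derived from geometry, not from peak
  shape.
* Fits do not desmear: parameters from smeared curves carry resolution
  bias (chiefly $\xi_l$, downward). Fitting a smeared model is the
  natural extension point.
* The thin-sheet estimator relies on the caller choosing a window in
  the Guinier regime; it diagnoses (via $R^2$ and the sign of the
  slope) but does not automate that choice.
* The electrostatic compression modulus assumes the salt-free
  Gouy–Chapman limit; added salt would require a screened form.
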