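# lamellaR

Analysis of small-angle neutron scattering (SANS) from lyotropic
lamellar surfactant phases: model fitting, elastic (Caillé/Helfrich)
analysis, bilayer-thickness estimation and swelling-law fits, together
with a synthetic generator for resolution-smeared lamellar spectra.

## The scientific problem

A lamellar (L<sub>α</sub>) phase is a one-dimensional stack of
surfactant bilayers of thickness δ separated by solvent layers, with
repeat distance *d* and water gap *d̄* = *d* − δ. Reduced SANS curves
*I(q)* (absolute scale, cm⁻¹) from such phases carry two kinds of
information:

- **Structure.** The scattered intensity is modelled as the sum of a
  diffuse contribution from in-plane concentration fluctuations and a
  structured (Bragg) contribution from the periodic stacking:

  *I(q)* = *A*<sub>z</sub> / (1 + *q*²ξ<sub>p</sub>²) +
  *A*<sub>B</sub> / (1 + (*q* − *q*₀)²ξ<sub>l</sub>²) + *b*,

  with diffuse amplitude *A*<sub>z</sub>, in-plane correlation length
  ξ<sub>p</sub>, Bragg amplitude *A*<sub>B</sub>, interlamellar
  correlation length ξ<sub>l</sub>, peak position *q*₀ and a flat
  incoherent background *b*. The Bragg condition *d* = 2π/*q*₀ and the
  ideal swelling law *d* = δ/ϕ (ϕ the membrane volume fraction) link
  the fitted peak positions of a dilution series to the dry bilayer
  thickness.

- **Elasticity.** Layer-displacement fluctuations are summarised by the
  Caillé parameter η = *q*₀²*k*<sub>B</sub>*T* / (8π√(B̄K)), with layer
  compression modulus B̄ and smectic bending modulus *K* = κ/*d*. For a
  stack stabilised purely by Helfrich undulation repulsion,
  *V*(*d̄*) = 3π²(*k*<sub>B</sub>*T*)²/(128 κ*d̄*²), this reduces to the
  purely geometric η = (4/3)(1 − δ/*d*)². For salt-free charged stacks
  the electrostatic compression modulus
  B̄ = π*k*<sub>B</sub>*T d*/(*l*<sub>B</sub>*d̄*³) is provided
  (*l*<sub>B</sub> the Bjerrum length, 7 Å in water).

- **Bilayer form factor.** In the dilute thin-sheet regime,
  ln(*q*²*I*) is linear in *q*² with slope −δ²/12 (Kratky–Porod), giving
  a direct estimate of δ independent of the stacking.

## Worked example

Simulate a charged dilute lamellar sample (sharp Bragg peak at
*q*₀ = 0.0105 Å⁻¹), fit it, and derive the stack geometry and
elasticity:

```r
library(lamellaR)

p <- nallet_parameters(A_z = 102.15, xi_p = 55.37, A_B = 546.33,
                       xi_l = 628.84, q0 = 0.0105)
cur <- generate_nallet_curve(p, instrument_config(),
                             noise = noise_model(0.02, seed = 1),
                             label = "charged, phi = 5%")
fit <- fit_nallet(cur)
fit
#> <nallet_fit> (converged)  chi2_red = 6.82, 200 points in [0.002, 0.4] 1/A
#>   A_z (1/cm)         82.221 ± 2.2
#>   xi_p (A)           50.774 ± 0.668
#>   A_B (1/cm)         405.73 ± 7.82
#>   xi_l (A)           388.88 ± 8.93
#>   q0 (1/A)           0.010607 ± 3.4e-05
#>   background (1/cm)  0.0008165 ± 0.00484

bragg_spacing(fit$parameters$q0)
#> [1] 592.4  # repeat distance, Angstrom

caille_helfrich(membrane_geometry(delta = 30, d = 592.4))
#> [1] 1.20   # Caille parameter in the Helfrich limit
```

The peak position is recovered to 1%; the fitted ξ<sub>l</sub> (389 Å)
is smaller than the generating value (629 Å) because the simulated
curve is convolved with the instrument's Gaussian q-resolution, which
broadens the Bragg peak — the generator flags this with a
`resolution_warning` attribute, and fitting an unsmeared curve
(`instrument_config(resolution_sigmas = 0)`) recovers all five
parameters to machine precision. The elevated reduced χ² has the same
origin: the plain (unsmeared) model is fitted to a smeared curve.

For batch work, `run_pipeline()` fits a list of samples, derives *d*,
fits the swelling law across the series and reports η per sample, with
per-sample failures isolated; `read_curve()`/`write_curve()` handle
2–3-column ASCII spectra.

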