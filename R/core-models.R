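## Closed-form physics of lamellar stacks: intensity models, elastic
## relations and stack geometry. All functions are pure and vectorised
## over q where that makes sense.

#' Lamellar-phase scattered intensity (diffuse + Bragg)
#'
#' Evaluates the two-contribution lamellar intensity model: a
#' zero-centred Lorentzian for diffuse scattering from in-plane
#' concentration fluctuations, plus a Lorentzian centred at the Bragg
#' position for the structured scattering from the periodic stacking,
#' plus a flat incoherent background:
#' \deqn{I(q) = \frac{A_z}{1 + q^2 \xi_p^2} +
#'       \frac{A_B}{1 + (q - q_0)^2 \xi_l^2} + b.}
#'
#' With `A_B = 0` the curve decays monotonically (disordered, dilute
#' stacks); a large `A_B * xi_l` produces the sharp Bragg peak of a
#' well-ordered stack.
#'
#' @param q Scattering vector(s) (1/Angstrom), > 0.
#' @param params A [nallet_parameters()] object.
#' @return Intensity (1/cm), same length as `q`; always >= the
#'   background.
#' @examples
#' p <- nallet_parameters(A_z = 493.14, xi_p = 181.59, A_B = 62.55,
#'                        xi_l = 109.53, q0 = 0.06207)
#' nallet_intensity(c(0.01, 0.06207, 0.3), p)
#' @export
nallet_intensity <- function(q, params) {
  stopifnot(inherits(params, "nallet_parameters"))
  .check_num(q, "q", min = 0, strict_min = TRUE)
  params$A_z / (1 + (q * params$xi_p)^2) +
    params$A_B / (1 + ((q - params$q0) * params$xi_l)^2) +
    params$background
}

#' Thin-sheet (dilute bilayer) scattered intensity
#'
#' Absolute-scale intensity of randomly oriented, weakly interacting
#' bilayers of thickness `delta` in the thin-sheet (Kratky-Porod)
#' approximation:
#' \deqn{I(q) = \frac{2\pi \phi \Delta\rho^2 \delta}{q^2}
#'       \exp\!\left(-\frac{q^2\delta^2}{12}\right),}
#' so that \eqn{\ln(q^2 I)} is linear in \eqn{q^2} with slope exactly
#' \eqn{-\delta^2/12}. The approximation holds for \eqn{q\delta
#' \lesssim 2}; beyond that the Gaussian tail underestimates the true
#' slab form-factor oscillations.
#'
#' @param q Scattering vector(s) (1/Angstrom), > 0.
#' @param model A [slab_model()] object.
#' @return Intensity (1/cm). Scales linearly with `phi` and with
#'   `drho^2`.
#' @examples
#' slab_intensity(0.1, slab_model(phi = 0.05, delta = 32))
#' @export
slab_intensity <- function(q, model) {
  stopifnot(inherits(model, "slab_model"))
  .check_num(q, "q", min = 0, strict_min = TRUE)
  q_cm <- q / .A_to_cm                 # 1/A -> 1/cm
  delta_cm <- model$delta * .A_to_cm   # A -> cm
  2 * pi * model$phi * model$drho^2 * delta_cm / q_cm^2 *
    exp(-(q * model$delta)^2 / 12)
}

#' Helfrich undulation repulsion between stacked membranes
#'
#' Entropic interaction energy per unit area between adjacent fluid
#' membranes whose thermal undulations are confined by their neighbours:
#' \deqn{V(\bar d) = \frac{3\pi^2}{128}\,
#'       \frac{(k_B T)^2}{\kappa\,\bar d^{\,2}},}
#' with \eqn{\bar d = d - \delta} the water-gap thickness. Softer
#' membranes (smaller \eqn{\kappa}) undulate more and repel more
#' strongly.
#'
#' @param geometry A [membrane_geometry()] object with `dbar > 0`.
#' @param kappa Bending modulus (J), > 0.
#' @param temperature Absolute temperature (K).
#' @return Energy per unit area (J/m^2).
#' @export
helfrich_potential <- function(geometry, kappa, temperature = 293.15) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  .check_num(kappa, "kappa", min = 0, strict_min = TRUE, len = 1)
  .check_num(temperature, "temperature", min = 0, strict_min = TRUE, len = 1)
  if (geometry$dbar <= 0)
    .stopf("Helfrich potential diverges: water gap 'dbar' must be > 0")
  kT <- .kB * temperature
  dbar_m <- geometry$dbar * .A_to_m
  3 * pi^2 / 128 * kT^2 / (kappa * dbar_m^2)
}

#' Caille parameter in the Helfrich-dominated limit
#'
#' When the stack is stabilised purely by undulation repulsion the
#' Caille parameter depends only on geometry:
#' \deqn{\eta = m\,\pi^2 \left(1 - \delta/d\right)^2
#'            = \tfrac{4}{3}\,(\bar d/d)^2,}
#' with \eqn{m = 4/(3\pi^2)} (see [CAILLE_M]). Under the ideal swelling
#' law \eqn{d = \delta/\phi} this becomes \eqn{\eta =
#' \tfrac{4}{3}(1-\phi)^2}: layer-displacement fluctuations shrink as the
#' stack concentrates.
#'
#' @param geometry A [membrane_geometry()] object (`0 <= delta <= d`).
#' @return Dimensionless Caille parameter in \[0, 4/3\].
#' @examples
#' # ideal swelling at phi = 0.05
#' caille_helfrich(membrane_geometry(delta = 30, d = 30 / 0.05))
#' @export
caille_helfrich <- function(geometry) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  CAILLE_M * pi^2 * (geometry$dbar / geometry$d)^2
}

#' Caille parameter from elastic moduli
#'
#' The general smectic expression linking Bragg-peak lineshape broadening
#' to the stack's elastic constants:
#' \deqn{\eta = \frac{q_0^2\, k_B T}{8\pi \sqrt{\bar B K}},
#'       \qquad K = \kappa / d,}
#' where \eqn{\bar B} is the layer compression modulus (Pa) and
#' \eqn{K} the smectic bending modulus built from the single-membrane
#' bending modulus \eqn{\kappa} and the repeat distance `d`.
#'
#' @param q0 Bragg peak position (1/Angstrom), > 0.
#' @param elastic An [elastic_state()] with `kappa` (J) and `Bbar` (Pa).
#' @param d Repeat distance (Angstrom), > 0.
#' @param temperature Absolute temperature (K).
#' @return Dimensionless Caille parameter, > 0.
#' @export
caille_from_moduli <- function(q0, elastic, d, temperature = 293.15) {
  stopifnot(inherits(elastic, "elastic_state"))
  .check_num(q0, "q0", min = 0, strict_min = TRUE, len = 1)
  .check_num(d, "d", min = 0, strict_min = TRUE, len = 1)
  .check_num(temperature, "temperature", min = 0, strict_min = TRUE, len = 1)
  if (elastic$Bbar <= 0 || elastic$kappa <= 0)
    .stopf("Caille parameter diverges: moduli must be > 0")
  kT <- .kB * temperature
  q0_m <- q0 / .A_to_m                  # 1/A -> 1/m
  K <- elastic$kappa / (d * .A_to_m)    # J/m = N, smectic curvature modulus
  q0_m^2 * kT / (8 * pi * sqrt(elastic$Bbar * K))
}

#' Electrostatic layer compression modulus (salt-free)
#'
#' Compression modulus of a stack of weakly screened charged bilayers in
#' salt-free solvent, in the counterion-only (Gouy-Chapman) limit where
#' the inter-bilayer osmotic pressure is
#' \eqn{P = \pi k_B T / (2 l_B \bar d^{\,2})}:
#' \deqn{\bar B = d\,\frac{\partial^2 F}{\partial \bar d^{\,2}}
#'             = \frac{\pi\, k_B T\, d}{l_B\, \bar d^{\,3}},}
#' with \eqn{l_B} the Bjerrum length of the solvent (7 Angstrom for
#' water).
#'
#' @param geometry A [membrane_geometry()] object with `dbar > 0`.
#' @param elastic An [elastic_state()]; only its `bjerrum` field is used.
#' @param temperature Absolute temperature (K).
#' @return Compression modulus (Pa), strictly decreasing in `dbar`.
#' @export
electrostatic_B <- function(geometry, elastic = elastic_state(.kB * 293.15, 1),
                            temperature = 293.15) {
  stopifnot(inherits(geometry, "membrane_geometry"),
            inherits(elastic, "elastic_state"))
  .check_num(temperature, "temperature", min = 0, strict_min = TRUE, len = 1)
  if (geometry$dbar <= 0)
    .stopf("electrostatic compression modulus diverges: 'dbar' must be > 0")
  kT <- .kB * temperature
  pi * kT * (geometry$d * .A_to_m) /
    ((elastic$bjerrum * .A_to_m) * (geometry$dbar * .A_to_m)^3)
}

#' Helfrich layer compression modulus
#'
#' Compression modulus of an undulation-stabilised stack, obtained as
#' the second derivative of the Helfrich potential with respect to the
#' water gap, \eqn{\bar B = d\, \partial^2 V/\partial \bar d^{\,2}}:
#' \deqn{\bar B = \frac{9\pi^2}{64}\,
#'       \frac{(k_B T)^2\, d}{\kappa\, \bar d^{\,4}}.}
#' Used for trend and consistency checks of the neutral series.
#'
#' @inheritParams helfrich_potential
#' @return Compression modulus (Pa), scaling as \eqn{d/\bar d^{\,4}}.
#' @export
helfrich_B <- function(geometry, kappa, temperature = 293.15) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  .check_num(kappa, "kappa", min = 0, strict_min = TRUE, len = 1)
  .check_num(temperature, "temperature", min = 0, strict_min = TRUE, len = 1)
  if (geometry$dbar <= 0)
    .stopf("Helfrich compression modulus diverges: 'dbar' must be > 0")
  kT <- .kB * temperature
  9 * pi^2 / 64 * kT^2 * (geometry$d * .A_to_m) /
    (kappa * (geometry$dbar * .A_to_m)^4)
}

#' Ideal lamellar swelling law
#'
#' Repeat distance of an ideal lamellar stack of planar bilayers of
#' thickness `delta` at membrane volume fraction `phi`:
#' \eqn{d = \delta/\phi}.
#'
#' @param delta Bilayer thickness (Angstrom), > 0.
#' @param phi Membrane volume fraction, in (0, 1\].
#' @return Repeat distance (Angstrom), >= `delta`.
#' @examples
#' swelling_d(30, 0.05)  # 600 A
#' @export
swelling_d <- function(delta, phi) {
  .check_num(delta, "delta", min = 0, strict_min = TRUE)
  .check_num(phi, "phi", min = 0, strict_min = TRUE)
  if (any(phi > 1)) .stopf("'phi' must be <= 1")
  delta / phi
}

#' Repeat distance from the Bragg condition
#'
#' First-order Bragg condition for a one-dimensional periodic stack:
#' \eqn{d = 2\pi/q_0}. The function is an involution up to the 2-pi
#' factor: `bragg_spacing(bragg_spacing(d))` returns `d`.
#'
#' @param q0 First-order Bragg peak position (1/Angstrom), > 0.
#' @return Repeat distance (Angstrom).
#' @examples
#' bragg_spacing(0.0105)  # ~598 A
#' @export
bragg_spacing <- function(q0) {
  .check_num(q0, "q0", min = 0, strict_min = TRUE)
  2 * pi / q0
}
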