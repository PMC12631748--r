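#' @keywords internal
"_PACKAGE"

## Physical constants and unit conversions used throughout.
## Lengths are carried in Angstrom, q in 1/Angstrom, intensities in 1/cm,
## bending moduli in J, compression moduli in Pa, temperatures in K.
.kB <- 1.380649e-23        # Boltzmann constant, J/K
.A_to_m <- 1e-10           # Angstrom -> metre
.A_to_cm <- 1e-8           # Angstrom -> centimetre
.default_T <- 293.15       # sample equilibration temperature, K (20 C)

#' Caille prefactor for Helfrich-dominated stacks
#'
#' The dimensionless constant \eqn{m = 4/(3\pi^2)} entering the
#' Helfrich-limit expression for the Caille parameter,
#' \eqn{\eta = m \pi^2 (1 - \delta/d)^2}.
#'
#' @format A length-one numeric.
#' @export
CAILLE_M <- 4 / (3 * pi^2)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_num <- function(x, name, min = -Inf, strict_min = FALSE,
                       finite = TRUE, len = NULL) {
  if (!is.numeric(x)) .stopf("'%s' must be numeric", name)
  if (!is.null(len) && length(x) != len)
    .stopf("'%s' must have length %d", name, len)
  if (finite && any(!is.finite(x)))
    .stopf("'%s' must be finite", name)
  if (strict_min) {
    if (any(x <= min)) .stopf("'%s' must be > %g", name, min)
  } else if (any(x < min)) .stopf("'%s' must be >= %g", name, min)
  invisible(x)
}

#' Scattering curve container
#'
#' One reduced one-dimensional SANS spectrum on absolute scale: scattering
#' vector `q` (1/Angstrom, strictly increasing, positive), intensity
#' `I(q)` (1/cm, non-negative) and, optionally, one-standard-deviation
#' uncertainties.
#'
#' @param q Numeric vector of scattering vectors (1/Angstrom), strictly
#'   increasing and positive.
#' @param intensity Numeric vector of absolute intensities (1/cm),
#'   finite and non-negative, same length as `q`.
#' @param sigma Optional numeric vector of 1-sd uncertainties (1/cm),
#'   non-negative, same length as `q`.
#' @param label Free-text sample identifier.
#' @return An object of class `scattering_curve`: a list with elements
#'   `q`, `intensity`, `sigma` (possibly `NULL`) and `label`.
#' @examples
#' sc <- scattering_curve(q = c(0.01, 0.02, 0.05), intensity = c(9, 4, 1))
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, label = "") {
  .check_num(q, "q", min = 0, strict_min = TRUE)
  if (is.unsorted(q, strictly = TRUE))
    .stopf("'q' must be strictly increasing")
  .check_num(intensity, "intensity", min = 0, len = length(q))
  if (!is.null(sigma)) .check_num(sigma, "sigma", min = 0, len = length(q))
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
                 label = as.character(label)[1]),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %s: %d points, q in [%.4g, %.4g] 1/A%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  invisible(x)
}

#' Sample composition
#'
#' Composition variables defining one lamellar sample: membrane volume
#' fraction `phi`, co-surfactant/surfactant mass ratio `omega`,
#' charged-surfactant fraction `gamma`, telechelic-polymer fraction `psi`
#' and absolute temperature.
#'
#' @param phi Membrane volume fraction, in (0, 1).
#' @param omega Co-surfactant to surfactant mass ratio (default 1.26, the
#'   lamellar-phase composition studied here).
#' @param gamma Charged-surfactant fraction, in \[0, 1).
#' @param psi Telechelic-polymer fraction, in \[0, 1).
#' @param temperature Absolute temperature (K).
#' @return An object of class `sample_composition`.
#' @export
sample_composition <- function(phi, omega = 1.26, gamma = 0, psi = 0,
                               temperature = 293.15) {
  .check_num(phi, "phi", len = 1)
  if (phi <= 0 || phi >= 1) .stopf("'phi' must lie in (0, 1)")
  for (nm in c("gamma", "psi")) {
    v <- get(nm)
    .check_num(v, nm, len = 1)
    if (v < 0 || v >= 1) .stopf("'%s' must lie in [0, 1)", nm)
  }
  .check_num(omega, "omega", min = 0, len = 1)
  .check_num(temperature, "temperature", min = 0, strict_min = TRUE, len = 1)
  structure(list(phi = phi, omega = omega, gamma = gamma, psi = psi,
                 temperature = temperature),
            class = "sample_composition")
}

#' Nallet model parameters
#'
#' The parameter set of the lamellar-phase intensity model: a diffuse
#' (in-plane concentration fluctuation) Lorentzian of amplitude `A_z` and
#' correlation length `xi_p`, a Bragg Lorentzian of amplitude `A_B`,
#' interlamellar correlation length `xi_l` and peak position `q0`, plus a
#' flat incoherent `background`.
#'
#' @param A_z Diffuse-scattering amplitude (1/cm), >= 0.
#' @param xi_p In-plane concentration-fluctuation correlation length
#'   (Angstrom), >= 0.
#' @param A_B Bragg amplitude (1/cm), >= 0.
#' @param xi_l Interlamellar correlation length (Angstrom), >= 0.
#' @param q0 Bragg peak position (1/Angstrom), >= 0.
#' @param background Constant incoherent level (1/cm), >= 0; defaults to 0
#'   so the plain five-parameter model is preserved.
#' @return An object of class `nallet_parameters`.
#' @seealso [nallet_intensity()], [fit_nallet()]
#' @export
nallet_parameters <- function(A_z, xi_p, A_B, xi_l, q0, background = 0) {
  for (nm in c("A_z", "xi_p", "A_B", "xi_l", "q0", "background"))
    .check_num(get(nm), nm, min = 0, len = 1)
  structure(list(A_z = A_z, xi_p = xi_p, A_B = A_B, xi_l = xi_l,
                 q0 = q0, background = background),
            class = "nallet_parameters")
}

#' @export
print.nallet_parameters <- function(x, ...) {
  cat(sprintf(paste0("<nallet_parameters> A_z = %.4g 1/cm, xi_p = %.4g A, ",
                     "A_B = %.4g 1/cm, xi_l = %.4g A, q0 = %.5g 1/A, ",
                     "background = %.4g 1/cm\n"),
              x$A_z, x$xi_p, x$A_B, x$xi_l, x$q0, x$background))
  invisible(x)
}

#' Lamellar stack geometry
#'
#' Bilayer thickness `delta`, repeat distance `d` and the water-gap
#' thickness `dbar = d - delta` of a one-dimensional lamellar stack.
#'
#' @param delta Bilayer (dry) thickness (Angstrom), > 0.
#' @param d Lamellar repeat distance (Angstrom), >= `delta`.
#' @return An object of class `membrane_geometry` with fields `delta`,
#'   `d` and `dbar`.
#' @examples
#' membrane_geometry(delta = 30, d = swelling_d(30, 0.05))
#' @export
membrane_geometry <- function(delta, d) {
  .check_num(delta, "delta", min = 0, strict_min = TRUE, len = 1)
  .check_num(d, "d", len = 1)
  if (d < delta) .stopf("'d' (%g A) must be >= 'delta' (%g A)", d, delta)
  structure(list(delta = delta, d = d, dbar = d - delta),
            class = "membrane_geometry")
}

#' Membrane elastic state
#'
#' Elastic constants of the stack: bending modulus `kappa` (J), layer
#' compression modulus `Bbar` (Pa), Caille parameter `eta`
#' (dimensionless) and the solvent Bjerrum length (Angstrom, 7 A for
#' water at room temperature).
#'
#' @param kappa Membrane bending modulus (J), > 0.
#' @param Bbar Layer compression modulus (Pa), > 0.
#' @param eta Caille parameter, >= 0 (may be `NA` when not yet derived).
#' @param bjerrum Bjerrum length (Angstrom), > 0.
#' @return An object of class `elastic_state`.
#' @export
elastic_state <- function(kappa, Bbar, eta = NA_real_, bjerrum = 7) {
  .check_num(kappa, "kappa", min = 0, strict_min = TRUE, len = 1)
  .check_num(Bbar, "Bbar", min = 0, strict_min = TRUE, len = 1)
  if (!is.na(eta)) .check_num(eta, "eta", min = 0, len = 1)
  .check_num(bjerrum, "bjerrum", min = 0, strict_min = TRUE, len = 1)
  structure(list(kappa = kappa, Bbar = Bbar, eta = eta, bjerrum = bjerrum),
            class = "elastic_state")
}

#' Homogeneous-slab (thin sheet) scattering model
#'
#' Parameters of the dilute-bilayer form-factor model: membrane volume
#' fraction, bilayer thickness, scattering-length-density contrast and
#' the nominal membrane volume.
#'
#' @param phi Membrane volume fraction, > 0.
#' @param delta Bilayer thickness (Angstrom), > 0.
#' @param drho Scattering-length-density contrast (1/cm^2), default
#'   6e10.
#' @param V_A Membrane volume (cm^3), default 3e-7; carried for report
#'   traceability (the absolute-scale intensity per unit sample volume is
#'   already normalised through `phi`).
#' @return An object of class `slab_model`.
#' @seealso [slab_intensity()], [estimate_thickness_kratky()]
#' @export
slab_model <- function(phi, delta, drho = 6e10, V_A = 3e-7) {
  .check_num(phi, "phi", min = 0, strict_min = TRUE, len = 1)
  .check_num(delta, "delta", min = 0, strict_min = TRUE, len = 1)
  .check_num(drho, "drho", min = 0, strict_min = TRUE, len = 1)
  .check_num(V_A, "V_A", min = 0, strict_min = TRUE, len = 1)
  structure(list(phi = phi, delta = delta, drho = drho, V_A = V_A),
            class = "slab_model")
}
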