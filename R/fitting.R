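## Estimation stage: nonlinear Nallet fits, Kratky-Porod thickness
## regression, swelling-law fits and Porod-representation diagnostics.

## Evaluate `expr` under a fixed RNG state without disturbing the
## caller's stream.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.curve_window <- function(curve, q_window) {
  if (is.null(q_window)) return(seq_along(curve$q))
  stopifnot(length(q_window) == 2, q_window[1] < q_window[2])
  if (q_window[1] < min(curve$q) || q_window[2] > max(curve$q))
    .stopf("q_window [%g, %g] extends beyond the curve span [%g, %g]",
           q_window[1], q_window[2], min(curve$q), max(curve$q))
  which(curve$q >= q_window[1] & curve$q <= q_window[2])
}

.nallet_eval <- function(q, p) {
  p[["A_z"]] / (1 + (q * p[["xi_p"]])^2) +
    p[["A_B"]] / (1 + ((q - p[["q0"]]) * p[["xi_l"]])^2) +
    p[["background"]]
}

## Heuristic starting values when the caller supplies none: background
## from the high-q tail, diffuse Lorentzian linearised over the lowest
## decade of q, Bragg term seeded from the detected peak (frozen at zero
## when no peak is found).
.nallet_init <- function(curve) {
  q <- curve$q; I <- curve$intensity
  n <- length(q)
  bkg <- stats::median(I[q >= stats::quantile(q, 0.9)])
  low <- which(q <= min(q) * 10)
  if (length(low) < 3) low <- seq_len(min(5, n))
  Ilow <- pmax(I[low] - bkg, max(I) * 1e-6)
  fit <- try(stats::lm(I(1 / Ilow) ~ I(q[low]^2)), silent = TRUE)
  A_z <- max(I[1] - bkg, 0); xi_p <- 1 / q[ceiling(n / 4)]
  if (!inherits(fit, "try-error")) {
    cf <- unname(stats::coef(fit))
    if (is.finite(cf[1]) && cf[1] > 0) {
      A_z <- 1 / cf[1]
      if (is.finite(cf[2]) && cf[2] > 0) xi_p <- sqrt(cf[2] * A_z)
    }
  }
  peak <- if (n >= 20) detect_bragg_peak(curve) else NA_real_
  if (is.na(peak)) {
    A_B <- 0; xi_l <- 0; q0 <- 0; free_bragg <- FALSE
  } else {
    q0 <- peak
    i0 <- which.min(abs(q - q0))
    diffuse0 <- A_z / (1 + (q0 * xi_p)^2)
    A_B <- max(I[i0] - diffuse0 - bkg, max(I) * 1e-3)
    excess <- I - A_z / (1 + (q * xi_p)^2) - bkg
    above <- which(excess > A_B / 2)
    above <- above[abs(q[above] - q0) < q0]  # stay near the peak
    fwhm <- if (length(above) >= 2) diff(range(q[above])) else
      (q[min(i0 + 1, n)] - q[max(i0 - 1, 1)])
    xi_l <- 2 / max(fwhm, 1e-6)
    free_bragg <- TRUE
  }
  list(p = c(A_z = A_z, xi_p = xi_p, A_B = A_B, xi_l = xi_l, q0 = q0,
             background = max(bkg, 0)),
       free_bragg = free_bragg)
}

.num_jacobian <- function(fn, p) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- max(abs(p[j]), 1e-4) * 1e-6
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- max(p[j] - h, 0)
    J[, j] <- (fn(pp) - fn(pm)) / (pp[j] - pm[j])
  }
  J
}

#' Fit the Nallet model to a scattering curve
#'
#' Bounded (non-negative) nonlinear least squares of the lamellar
#' diffuse-plus-Bragg model ([nallet_intensity()]) using
#' Levenberg-Marquardt with multi-start: the starting point (supplied or
#' heuristic) plus `restarts` multiplicatively jittered copies, keeping
#' the lowest residual sum of squares. Points are weighted by
#' \eqn{1/\sigma^2} when the curve carries uncertainties.
#'
#' When no Bragg peak is detected and no starting values are supplied,
#' the Bragg term is frozen at zero and only the diffuse amplitude,
#' correlation length and background are fitted. Parameters whose
#' direction in the covariance matrix is numerically singular are
#' reported with an `NA` uncertainty, rendered as `"N.D."` (not
#' determined) in printed reports.
#'
#' @param curve A [scattering_curve()].
#' @param initial Optional [nallet_parameters()] starting values.
#' @param q_window Optional length-2 numeric fit range (1/Angstrom);
#'   default is the full curve.
#' @param restarts Number of jittered restarts (default 5).
#' @param jitter Relative half-width of the multiplicative start jitter
#'   (default 0.2, i.e. factors in \[0.8, 1.2\]).
#' @param fit_background Fit the flat incoherent background (default
#'   `TRUE`, appropriate for measured curves). Set `FALSE` to fix it at
#'   its starting value and fit the five model parameters only, e.g.
#'   for background-free synthetic curves where a free constant would
#'   be collinear with a vanishing-width Bragg term.
#' @param seed Integer seed controlling the restart jitter.
#' @return An object of class `nallet_fit`: list with `parameters`
#'   ([nallet_parameters()]), `uncertainties` (named numeric, `NA` =
#'   not determined), `chi2_reduced`, `q_window`, `converged`, `rss`.
#' @examples
#' p <- nallet_parameters(493.14, 181.59, 62.55, 109.53, 0.06207)
#' cur <- generate_nallet_curve(p, instrument_config(resolution_sigmas = 0))
#' fit_nallet(cur)$parameters
#' @export
fit_nallet <- function(curve, initial = NULL, q_window = NULL,
                       restarts = 5, jitter = 0.2, fit_background = TRUE,
                       seed = 42) {
  stopifnot(inherits(curve, "scattering_curve"))
  idx <- .curve_window(curve, q_window)
  if (length(idx) < 10)
    .stopf("need at least 10 points in the fit window, got %d", length(idx))
  q <- curve$q[idx]; I <- curve$intensity[idx]
  w <- if (!is.null(curve$sigma) && all(curve$sigma[idx] > 0))
    1 / curve$sigma[idx]^2 else rep(1, length(q))
  sw <- sqrt(w)

  if (is.null(initial)) {
    ini <- .nallet_init(curve)
    p0 <- ini$p; free_bragg <- ini$free_bragg
  } else {
    stopifnot(inherits(initial, "nallet_parameters"))
    p0 <- c(A_z = initial$A_z, xi_p = initial$xi_p, A_B = initial$A_B,
            xi_l = initial$xi_l, q0 = initial$q0,
            background = initial$background)
    free_bragg <- TRUE
  }
  free <- names(p0)
  if (!free_bragg) free <- setdiff(free, c("A_B", "xi_l", "q0"))
  if (!fit_background) free <- setdiff(free, "background")

  resid_fn <- function(pf) {
    p <- p0; p[free] <- pf
    sw * (.nallet_eval(q, p) - I)
  }

  starts <- .with_seed(seed, {
    c(list(p0[free]), lapply(seq_len(restarts), function(i) {
      p0[free] * stats::runif(length(free), 1 - jitter, 1 + jitter)
    }))
  })

  best <- NULL
  for (s in starts) {
    res <- try(minpack.lm::nls.lm(
      par = s, lower = rep(0, length(s)), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-12, ptol = 1e-12)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    .stopf("Nallet fit failed to converge from any of %d starts",
           length(starts))

  pf <- best$par
  p_hat <- p0; p_hat[free] <- pf
  rss <- best$deviance
  n <- length(q); npar <- length(free)
  dof <- max(n - npar, 1)
  s2 <- rss / dof
  chi2_red <- if (!is.null(curve$sigma)) rss / dof else s2

  ## covariance from the numerical Jacobian of the weighted residuals,
  ## inverted on the column-scaled (correlation) normal matrix so that
  ## parameters of very different magnitude are treated evenly; a
  ## parameter with numerically vanishing gradient, or lying in a
  ## singular direction, is flagged not-determined (NA)
  unc <- rep(NA_real_, length(p0)); names(unc) <- names(p0)
  J <- .num_jacobian(resid_fn, pf)
  JtJ <- crossprod(J)
  dsc <- sqrt(diag(JtJ))
  keep <- which(dsc > max(dsc) * 1e-8)
  if (length(keep)) {
    C <- JtJ[keep, keep, drop = FALSE] / outer(dsc[keep], dsc[keep])
    inv <- try(solve(C), silent = TRUE)
    if (!inherits(inv, "try-error")) {
      v <- s2 * diag(inv) / dsc[keep]^2
      unc_free <- rep(NA_real_, npar)
      ok <- which(is.finite(v) & v >= 0)
      unc_free[keep[ok]] <- sqrt(v[ok])
      unc[free] <- unc_free
    }
  }
  if (!free_bragg) unc[c("A_B", "xi_l", "q0")] <- NA_real_

  structure(list(
    parameters = nallet_parameters(p_hat[["A_z"]], p_hat[["xi_p"]],
                                   p_hat[["A_B"]], p_hat[["xi_l"]],
                                   p_hat[["q0"]], p_hat[["background"]]),
    uncertainties = unc,
    chi2_reduced = chi2_red,
    q_window = range(q),
    converged = best$info %in% 1:4,
    rss = rss,
    n_points = n),
    class = "nallet_fit")
}

#' @export
print.nallet_fit <- function(x, ...) {
  p <- x$parameters
  vals <- c(p$A_z, p$xi_p, p$A_B, p$xi_l, p$q0, p$background)
  u <- x$uncertainties
  fmt <- function(v, e) sprintf("%.5g %s", v,
                                if (is.na(e)) "± N.D." else
                                  sprintf("± %.3g", e))
  nm <- c("A_z (1/cm)", "xi_p (A)", "A_B (1/cm)", "xi_l (A)",
          "q0 (1/A)", "background (1/cm)")
  cat("<nallet_fit>", if (x$converged) "(converged)" else "(NOT converged)",
      sprintf(" chi2_red = %.3g, %d points in [%.4g, %.4g] 1/A\n",
              x$chi2_reduced, x$n_points, x$q_window[1], x$q_window[2]))
  for (i in seq_along(vals))
    cat(sprintf("  %-18s %s\n", nm[i], fmt(vals[i], u[i])))
  invisible(x)
}

#' Bilayer thickness from the Kratky-Porod regression
#'
#' Estimates the bilayer thickness from the thin-sheet regime of a
#' scattering curve: within the chosen window, \eqn{\ln(q^2 I/\phi)} is
#' regressed on \eqn{q^2}; the slope \eqn{s} of the line gives
#' \eqn{\delta = \sqrt{-12 s}}. Normalising by the volume fraction
#' removes the concentration dependence so that windows from different
#' dilutions are comparable. The estimate is scale invariant:
#' multiplying the intensity by a constant changes the intercept only.
#'
#' @param curve A [scattering_curve()] with positive intensities in the
#'   window.
#' @param phi Membrane volume fraction, > 0.
#' @param q_window Length-2 numeric regression window (1/Angstrom);
#'   should sit in the thin-sheet regime \eqn{q\delta \lesssim 2}.
#' @return An object of class `thickness_estimate`: list with `delta`
#'   (Angstrom), `delta_err` (propagated from the slope standard error),
#'   `q_window`, `r_squared`.
#' @examples
#' cur <- generate_slab_curve(slab_model(0.05, 32),
#'                            instrument_config(resolution_sigmas = 0))
#' estimate_thickness_kratky(cur, 0.05, c(0.063, 0.138))
#' @export
estimate_thickness_kratky <- function(curve, phi, q_window) {
  stopifnot(inherits(curve, "scattering_curve"))
  .check_num(phi, "phi", min = 0, strict_min = TRUE, len = 1)
  idx <- .curve_window(curve, q_window)
  if (length(idx) < 3)
    .stopf("need at least 3 points in the regression window, got %d",
           length(idx))
  q <- curve$q[idx]; I <- curve$intensity[idx]
  if (any(I <= 0))
    .stopf("intensities must be > 0 within the regression window")
  x <- q^2
  y <- log(x * I / phi)
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[["x"]]
  if (slope >= 0)
    .stopf(paste("non-negative Kratky-Porod slope: no thickness",
                 "determinable (non-lamellar scattering or wrong window)"))
  sm <- suppressWarnings(summary(fit))  # noise-free fits are exact
  slope_se <- sm$coefficients["x", "Std. Error"]
  delta <- sqrt(-12 * slope)
  structure(list(delta = delta,
                 delta_err = 6 * slope_se / delta,
                 q_window = range(q),
                 r_squared = sm$r.squared),
            class = "thickness_estimate")
}

#' @export
print.thickness_estimate <- function(x, ...) {
  cat(sprintf(
    "<thickness_estimate> delta = %.3f ± %.3f A (R^2 = %.5f, q in [%.4g, %.4g] 1/A)\n",
    x$delta, x$delta_err, x$r_squared, x$q_window[1], x$q_window[2]))
  invisible(x)
}

#' Fit the lamellar swelling law d = delta/phi
#'
#' Through-origin least squares of the repeat distance `d` on the
#' inverse volume fraction \eqn{1/\phi}; the slope is the dry bilayer
#' thickness \eqn{\delta}. The law has no intercept, so the default is a
#' regression through the origin; a free-intercept variant is available
#' for diagnostics. A single point determines the slope exactly (with no
#' standard error).
#'
#' @param points A data frame (or list coercible to one) with numeric
#'   columns `phi` (distinct, in (0, 1\]) and `d` (Angstrom).
#' @param intercept Fit a free intercept as a diagnostic (default
#'   `FALSE`, the physical law).
#' @return An object of class `swelling_fit`: list with `delta`
#'   (Angstrom), `delta_err` (standard error, `NA` when not estimable),
#'   `intercept` (0 unless requested), `points`.
#' @examples
#' fit_swelling(data.frame(phi = c(0.05, 0.1, 0.2, 0.3),
#'                         d = 30 / c(0.05, 0.1, 0.2, 0.3)))
#' @export
fit_swelling <- function(points, intercept = FALSE) {
  points <- as.data.frame(points)
  if (!all(c("phi", "d") %in% names(points)))
    .stopf("'points' must have columns 'phi' and 'd'")
  .check_num(points$phi, "phi", min = 0, strict_min = TRUE)
  if (any(points$phi > 1)) .stopf("'phi' must be <= 1")
  .check_num(points$d, "d", min = 0, strict_min = TRUE)
  if (nrow(points) < 1) .stopf("at least one (phi, d) point is required")
  if (anyDuplicated(points$phi)) .stopf("'phi' values must be distinct")
  x <- 1 / points$phi
  if (nrow(points) == 1 && !intercept) {
    return(structure(list(delta = points$d * points$phi,
                          delta_err = NA_real_, intercept = 0,
                          points = points), class = "swelling_fit"))
  }
  if (intercept) {
    if (nrow(points) < 2) .stopf("intercept fit needs >= 2 points")
    fit <- stats::lm(d ~ x, data = data.frame(x = x, d = points$d))
    cf <- suppressWarnings(summary(fit))$coefficients
    structure(list(delta = cf["x", "Estimate"],
                   delta_err = cf["x", "Std. Error"],
                   intercept = cf["(Intercept)", "Estimate"],
                   points = points), class = "swelling_fit")
  } else {
    fit <- stats::lm(d ~ 0 + x, data = data.frame(x = x, d = points$d))
    cf <- suppressWarnings(summary(fit))$coefficients
    se <- if (nrow(points) > 1) cf["x", "Std. Error"] else NA_real_
    structure(list(delta = cf["x", "Estimate"], delta_err = se,
                   intercept = 0, points = points), class = "swelling_fit")
  }
}

#' @export
print.swelling_fit <- function(x, ...) {
  cat(sprintf("<swelling_fit> delta = %.2f %s A (%d points)\n",
              x$delta,
              if (is.na(x$delta_err)) "± N.D." else
                sprintf("± %.2f", x$delta_err),
              nrow(x$points)))
  invisible(x)
}

#' Detect the first-order Bragg peak
#'
#' Searches \eqn{q^2 I(q)} for its most prominent interior local
#' maximum. Within a sliding window around each candidate, the
#' topographic prominence (height above the higher of the two flanking
#' minima) must exceed `prominence` times a robust local noise scale
#' estimated from the median absolute second difference of
#' \eqn{q^2 I}; strictly monotone curves have no interior maxima and
#' therefore never yield a peak. Absence of a peak is a valid result
#' (`NA`), mirroring dilute disordered stacks.
#'
#' @param curve A [scattering_curve()] with at least 20 points.
#' @param window Width (points) of the local prominence window.
#' @param prominence Required prominence in units of the local noise
#'   scale.
#' @return The peak position (1/Angstrom), or `NA_real_` when no
#'   sufficiently prominent maximum exists.
#' @export
detect_bragg_peak <- function(curve, window = 15, prominence = 3) {
  stopifnot(inherits(curve, "scattering_curve"))
  n <- length(curve$q)
  if (n < 20) .stopf("need at least 20 points, got %d", n)
  y <- curve$q^2 * curve$intensity
  cand <- which(diff(sign(diff(y))) < 0) + 1   # interior local maxima
  if (!length(cand)) return(NA_real_)
  half <- max(window %/% 2, 1)
  floor_scale <- 1e-9 * max(abs(y))
  score <- vapply(cand, function(i) {
    win <- max(1, i - half):min(n, i + half)
    left <- y[win[win < i]]; right <- y[win[win > i]]
    if (!length(left) || !length(right)) return(-Inf)
    prom <- y[i] - max(min(left), min(right))
    noise <- stats::mad(diff(y[win], differences = 2), center = 0) / sqrt(6)
    if (prom >= prominence * max(noise, floor_scale)) prom else -Inf
  }, numeric(1))
  if (all(!is.finite(score))) return(NA_real_)
  curve$q[cand[which.max(score)]]
}

#' Porod representation of a scattering curve
#'
#' Pointwise transform to \eqn{(q,\, q^2 I(q)/\phi)}, the natural
#' representation for bilayers: the \eqn{q^{-2}} thin-sheet decay is
#' flattened and the \eqn{\phi} normalisation makes form factors of
#' different dilutions directly comparable (they overlap at high q when
#' the bilayer is unchanged). The multiplication by \eqn{q^2} also
#' amplifies higher-order Bragg reflections.
#'
#' @param curve A [scattering_curve()].
#' @param phi Membrane volume fraction, > 0.
#' @return A data frame with columns `q` (1/Angstrom) and `value`
#'   (\eqn{q^2 I/\phi}).
#' @export
porod_representation <- function(curve, phi) {
  stopifnot(inherits(curve, "scattering_curve"))
  .check_num(phi, "phi", min = 0, strict_min = TRUE, len = 1)
  data.frame(q = curve$q, value = curve$q^2 * curve$intensity / phi)
}

#' High-q overlap metric between two transformed curves
#'
#' Quantifies how well two Porod-represented curves coincide above a
#' threshold: both are linearly interpolated onto the union of their q
#' grids within the common support above `q_threshold`, and the median
#' relative absolute difference
#' \eqn{\mathrm{median}\,|a-b|/\min(a,b)} is returned. The metric is
#' symmetric in its arguments; identical curves give 0 and a constant
#' ratio \eqn{1+r} gives \eqn{r}.
#'
#' @param curveA,curveB Data frames with columns `q` and `value`, as
#'   returned by [porod_representation()].
#' @param q_threshold Lower q bound of the comparison region
#'   (1/Angstrom).
#' @return Dimensionless median relative discrepancy.
#' @export
highq_overlap_metric <- function(curveA, curveB, q_threshold) {
  for (cu in list(curveA, curveB))
    if (!all(c("q", "value") %in% names(cu)))
      .stopf("curves must have columns 'q' and 'value'")
  .check_num(q_threshold, "q_threshold", len = 1)
  lo <- max(min(curveA$q), min(curveB$q), q_threshold)
  hi <- min(max(curveA$q), max(curveB$q))
  if (lo >= hi)
    .stopf("empty overlap region above q = %g", q_threshold)
  grid <- sort(unique(c(curveA$q, curveB$q)))
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2)
    .stopf("fewer than 2 shared points above q = %g", q_threshold)
  a <- stats::approx(curveA$q, curveA$value, xout = grid)$y
  b <- stats::approx(curveB$q, curveB$value, xout = grid)$y
  stats::median(abs(a - b) / pmin(a, b))
}
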