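## Readers/writers for reduced ASCII I(q) curves, the batch analysis
## pipeline and its report tables.

#' Read a reduced I(q) curve from ASCII
#'
#' Reads a 2- or 3-column whitespace- or comma-delimited file (`q`,
#' `I`, optional `sigma`), skipping `#` comment lines. Rows are sorted
#' by q when needed (with a notice); negative intensities are clipped to
#' zero with a warning, recording the policy in the message.
#'
#' @param path Path to the ASCII file.
#' @param q_unit `"A^-1"` (default) or `"nm^-1"`; nm^-1 input is
#'   converted to 1/Angstrom.
#' @param label Sample label (defaults to the file name).
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path, q_unit = c("A^-1", "nm^-1"),
                       label = basename(path)) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) .stopf("no data rows in %s", path)
  sep <- if (grepl(",", lines[1])) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           strip.white = TRUE)
  if (!ncol(tab) %in% 2:3)
    .stopf("expected 2 or 3 numeric columns in %s, found %d", path, ncol(tab))
  if (!all(vapply(tab, is.numeric, logical(1))))
    .stopf("non-numeric data in %s", path)
  q <- tab[[1]]
  if (q_unit == "nm^-1") q <- q / 10
  I <- tab[[2]]
  s <- if (ncol(tab) == 3) tab[[3]] else NULL
  if (is.unsorted(q, strictly = TRUE)) {
    message(sprintf("read_curve: q rows in %s were not sorted; sorting",
                    basename(path)))
    o <- order(q)
    q <- q[o]; I <- I[o]; if (!is.null(s)) s <- s[o]
  }
  if (any(I < 0)) {
    warning(sprintf("read_curve: %d negative intensities in %s clipped to zero",
                    sum(I < 0), basename(path)), call. = FALSE)
    I <- pmax(I, 0)
  }
  scattering_curve(q, I, sigma = s, label = label)
}

#' Write a curve as 3-column ASCII
#'
#' Writes `q I [sigma]` with a `#` header naming columns and units, 9
#' significant digits, so that [read_curve()] round-trips the values.
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  has_sigma <- !is.null(curve$sigma)
  header <- c(sprintf("# %s", curve$label),
              paste("# q(1/Angstrom) I(1/cm)",
                    if (has_sigma) "sigma(1/cm)" else ""))
  fmt <- function(x) formatC(x, digits = 9, format = "g")
  rows <- if (has_sigma)
    paste(fmt(curve$q), fmt(curve$intensity), fmt(curve$sigma))
  else paste(fmt(curve$q), fmt(curve$intensity))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a dilution series and its manifest
#'
#' Writes each member of a [generate_dilution_series()] result as a
#' 3-column ASCII curve plus a tab-separated `manifest.tsv` recording
#' composition and generator parameters for every file.
#'
#' @param series Result of [generate_dilution_series()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dilution_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(series), function(i) {
    m <- series[[i]]
    fn <- sprintf("curve_phi%03d.dat", round(1000 * m$composition$phi))
    write_curve(m$curve, file.path(dir, fn))
    data.frame(file = fn, phi = m$composition$phi,
               omega = m$composition$omega, gamma = m$composition$gamma,
               psi = m$composition$psi,
               temperature = m$composition$temperature,
               A_z = m$params$A_z, xi_p = m$params$xi_p,
               A_B = m$params$A_B, xi_l = m$params$xi_l,
               q0 = m$params$q0, background = m$params$background)
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

.nd <- function(x, digits = 4) {
  ifelse(is.na(x), "N.D.", formatC(x, digits = digits, format = "g"))
}

#' Run the lamellar analysis pipeline over a sample series
#'
#' For every sample: read (or take) its curve, fit the Nallet model,
#' derive the repeat distance from the fitted Bragg position, then fit
#' the swelling law \eqn{d = \delta/\phi} across all peaked members of
#' the series and compute each sample's Helfrich-limit Caille parameter
#' from its geometry. Per-sample failures are isolated and reported as
#' failed rows; the pipeline continues.
#'
#' @param samples A list; each element is a list with either `path`
#'   (ASCII curve file) or `curve` (a [scattering_curve()]), plus `phi`
#'   and optionally `label` and a `thickness_window` (length-2 q range
#'   for the Kratky-Porod estimate).
#' @param delta Known dry bilayer thickness (Angstrom); when `NULL`
#'   (default) the swelling-fit slope is used.
#' @param fit_options List of options forwarded to [fit_nallet()]
#'   (`q_window`, `restarts`, `jitter`).
#' @param seed Integer seed for the fit restarts; recorded in the
#'   output.
#' @param output_dir Optional directory; when given, writes
#'   `report.tsv` and `results.json` there.
#' @return An object of class `lamellar_report`: a data frame with one
#'   row per sample (fitted parameters with uncertainties, `d`, `eta`,
#'   `delta_kp` where a thickness window was given, `status`), with
#'   attributes `swelling` (the [fit_swelling()] result or `NULL`),
#'   `delta` (thickness used for `eta`) and `seed`.
#' @examples
#' series <- generate_dilution_series(
#'   delta = 30, phis = c(0.1, 0.2),
#'   peak_params = list(A_z = 100, xi_p = 50, A_B = 300, xi_l = 200))
#' run_pipeline(lapply(series, function(m)
#'   list(curve = m$curve, phi = m$composition$phi)))
#' @export
run_pipeline <- function(samples, delta = NULL, fit_options = list(),
                         seed = 42, output_dir = NULL) {
  if (!is.list(samples)) .stopf("'samples' must be a list")
  rows <- vector("list", length(samples))
  fits <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    rows[[i]] <- tryCatch({
      cur <- if (!is.null(s$curve)) s$curve else read_curve(s$path)
      lbl <- if (!is.null(s$label)) s$label else
        if (nzchar(cur$label)) cur$label else sprintf("sample%d", i)
      fit <- do.call(fit_nallet,
                     c(list(curve = cur, seed = seed), fit_options))
      fits[[i]] <- fit
      p <- fit$parameters; u <- fit$uncertainties
      has_peak <- p$A_B > 0 && p$q0 > 0 && p$xi_l > 0
      d <- if (has_peak) bragg_spacing(p$q0) else NA_real_
      dkp <- if (!is.null(s$thickness_window)) {
        tryCatch(estimate_thickness_kratky(cur, s$phi,
                                           s$thickness_window)$delta,
                 error = function(e) NA_real_)
      } else NA_real_
      data.frame(label = lbl, phi = s$phi,
                 A_z = p$A_z, A_z_err = u[["A_z"]],
                 xi_p = p$xi_p, xi_p_err = u[["xi_p"]],
                 A_B = p$A_B, A_B_err = u[["A_B"]],
                 xi_l = p$xi_l, xi_l_err = u[["xi_l"]],
                 q0 = p$q0, q0_err = u[["q0"]],
                 chi2_reduced = fit$chi2_reduced,
                 d = d, delta_kp = dkp, eta = NA_real_,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(label = sprintf("sample%d", i),
                 phi = if (!is.null(s$phi)) s$phi else NA_real_,
                 A_z = NA_real_, A_z_err = NA_real_, xi_p = NA_real_,
                 xi_p_err = NA_real_, A_B = NA_real_, A_B_err = NA_real_,
                 xi_l = NA_real_, xi_l_err = NA_real_, q0 = NA_real_,
                 q0_err = NA_real_, chi2_reduced = NA_real_, d = NA_real_,
                 delta_kp = NA_real_, eta = NA_real_,
                 status = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), phi = numeric(), A_z = numeric(),
               A_z_err = numeric(), xi_p = numeric(), xi_p_err = numeric(),
               A_B = numeric(), A_B_err = numeric(), xi_l = numeric(),
               xi_l_err = numeric(), q0 = numeric(), q0_err = numeric(),
               chi2_reduced = numeric(), d = numeric(),
               delta_kp = numeric(), eta = numeric(), status = character(),
               stringsAsFactors = FALSE)

  swell <- NULL
  peaked <- !is.na(report$d)
  if (sum(peaked) >= 1)
    swell <- fit_swelling(data.frame(phi = report$phi[peaked],
                                     d = report$d[peaked]))
  delta_used <- if (!is.null(delta)) delta else
    if (!is.null(swell)) swell$delta else NA_real_

  if (!is.na(delta_used) && nrow(report)) {
    for (i in seq_len(nrow(report))) {
      if (report$status[i] != "ok") next
      d_i <- if (!is.na(report$d[i])) report$d[i] else
        swelling_d(delta_used, report$phi[i])
      if (d_i >= delta_used)
        report$eta[i] <- caille_helfrich(membrane_geometry(delta_used, d_i))
    }
  }

  class(report) <- c("lamellar_report", "data.frame")
  attr(report, "swelling") <- swell
  attr(report, "delta") <- delta_used
  attr(report, "seed") <- seed

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- as.data.frame(report)
    for (nm in grep("_err$", names(out), value = TRUE))
      out[[nm]] <- .nd(out[[nm]])
    utils::write.table(out, file.path(output_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, delta = delta_used,
           swelling = if (is.null(swell)) NULL else
             list(delta = swell$delta, delta_err = swell$delta_err),
           samples = as.data.frame(report)),
      file.path(output_dir, "results.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

#' @export
print.lamellar_report <- function(x, ...) {
  cat(sprintf("<lamellar_report> %d sample(s), seed %d\n",
              nrow(x), attr(x, "seed")))
  sw <- attr(x, "swelling")
  if (!is.null(sw))
    cat(sprintf("  swelling law: delta = %.2f %s A\n", sw$delta,
                if (is.na(sw$delta_err)) "± N.D."
                else sprintf("± %.2f", sw$delta_err)))
  if (!nrow(x)) { cat("  (empty)\n"); return(invisible(x)) }
  disp <- data.frame(
    label = x$label, phi = x$phi,
    `A_z(1/cm)` = paste0(.nd(x$A_z), " ± ", .nd(x$A_z_err, 3)),
    `xi_p(A)` = paste0(.nd(x$xi_p), " ± ", .nd(x$xi_p_err, 3)),
    `A_B(1/cm)` = paste0(.nd(x$A_B), " ± ", .nd(x$A_B_err, 3)),
    `xi_l(A)` = paste0(.nd(x$xi_l), " ± ", .nd(x$xi_l_err, 3)),
    `q0(1/A)` = .nd(x$q0, 4),
    `d(A)` = .nd(x$d, 4), eta = .nd(x$eta, 3),
    status = x$status, check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}
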