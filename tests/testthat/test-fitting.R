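test_that("noise-free generated curves are refit to the generating
           parameters across all reference sets", {
  sets <- reference_sets()
  inst <- ideal_instrument()
  for (set_name in names(sets)) {
    tab <- sets[[set_name]]
    for (i in seq_len(nrow(tab))) {
      row <- tab[i, ]
      truth <- row_params(row)
      cur <- generate_nallet_curve(truth, inst)
      fit <- fit_nallet(cur, initial = jitter_params(truth, seed = 100 + i),
                        fit_background = FALSE, restarts = 2,
                        seed = 200 + i)
      checked <- if (row_degenerate(row)) c("A_z", "xi_p", "A_B") else
        c("A_z", "xi_p", "A_B", "xi_l", "q0")
      for (nm in checked) {
        expect_lt(abs(fit$parameters[[nm]] - truth[[nm]]) / truth[[nm]],
                  1e-3,
                  label = sprintf("%s[%d] %s relative error", set_name, i, nm))
      }
    }
  }
})

test_that("fitting is equivariant under intensity rescaling", {
  truth <- row_params(reference_sets()$charged[2, ])
  cur <- generate_nallet_curve(truth, ideal_instrument(),
                               noise_model(0.02, seed = 4))
  scaled <- scattering_curve(cur$q, 50 * cur$intensity, 50 * cur$sigma)
  f1 <- fit_nallet(cur, initial = jitter_params(truth, 7),
                   fit_background = FALSE, restarts = 2, seed = 1)
  f2 <- fit_nallet(scaled,
                   initial = jitter_params(truth, 7),  # same start shape
                   fit_background = FALSE, restarts = 2, seed = 1)
  expect_equal(f2$parameters$A_z / f1$parameters$A_z, 50, tolerance = 1e-3)
  expect_equal(f2$parameters$A_B / f1$parameters$A_B, 50, tolerance = 1e-3)
  expect_equal(f2$parameters$xi_p, f1$parameters$xi_p, tolerance = 1e-3)
  expect_equal(f2$parameters$xi_l, f1$parameters$xi_l, tolerance = 1e-3)
  expect_equal(f2$parameters$q0, f1$parameters$q0, tolerance = 1e-6)
})

test_that("a flat curve collapses to pure background with the Bragg
           uncertainties flagged not-determined", {
  q <- instrument_q_grid(instrument_config())
  flat <- scattering_curve(q, rep(0.5, length(q)))
  fit <- fit_nallet(flat)
  expect_lt(fit$parameters$A_z, 1e-6)
  expect_equal(fit$parameters$A_B, 0)
  expect_equal(fit$parameters$background, 0.5, tolerance = 1e-6)
  expect_true(all(is.na(fit$uncertainties[c("A_B", "xi_l", "q0")])))
})

test_that("fit_nallet refuses windows with too few points", {
  truth <- row_params(reference_sets()$charged[1, ])
  cur <- generate_nallet_curve(truth, ideal_instrument(n_points = 30))
  expect_error(fit_nallet(cur, q_window = c(0.0021, 0.004)), "10 points")
})

test_that("Kratky-Porod estimator is exact on noise-free thin-sheet
           curves and invariant to intensity scaling", {
  inst <- ideal_instrument()
  cur <- generate_slab_curve(slab_model(phi = 0.05, delta = 32), inst)
  est <- estimate_thickness_kratky(cur, 0.05, c(0.063, 0.138))
  expect_equal(est$delta, 32, tolerance = 1e-8)
  expect_gt(est$r_squared, 1 - 1e-10)
  scaled <- scattering_curve(cur$q, 7.3 * cur$intensity)
  est2 <- estimate_thickness_kratky(scaled, 0.05, c(0.063, 0.138))
  expect_equal(est2$delta, est$delta, tolerance = 1e-12)
})

test_that("Kratky-Porod estimator is unbiased at 2% noise", {
  inst <- ideal_instrument()
  deltas <- sapply(1:50, function(s) {
    cur <- generate_slab_curve(slab_model(phi = 0.05, delta = 32), inst,
                               noise_model(0.02, seed = s))
    estimate_thickness_kratky(cur, 0.05, c(0.063, 0.138))$delta
  })
  expect_lt(abs(mean(deltas) - 32) / 32, 0.02)
})

test_that("Kratky-Porod estimator signals a non-determinable thickness", {
  q <- seq(0.05, 0.2, length.out = 50)
  rising <- scattering_curve(q, exp(q^2 * 100) / q^2)
  expect_error(estimate_thickness_kratky(rising, 0.1, c(0.06, 0.19)),
               "no thickness")
})

test_that("swelling fit recovers the exact law and handles degenerate
           input sizes", {
  phis <- c(0.05, 0.1, 0.2, 0.3)
  exact <- fit_swelling(data.frame(phi = phis, d = 30 / phis))
  expect_equal(exact$delta, 30, tolerance = 1e-12)
  expect_equal(exact$delta_err, 0, tolerance = 1e-9)
  single <- fit_swelling(data.frame(phi = 0.1, d = 350))
  expect_equal(single$delta, 35)
  expect_true(is.na(single$delta_err))
  expect_error(fit_swelling(data.frame(phi = c(0.1, 0.1), d = c(300, 310))),
               "distinct")
})

test_that("swelling fit of the charged-series Bragg spacings yields a
           dry thickness of 30 +/- 1 A", {
  tab <- reference_sets()$charged
  fit <- fit_swelling(data.frame(phi = tab$phi, d = bragg_spacing(tab$q0)))
  expect_equal(fit$delta, 30.58192, tolerance = 1e-6)
  expect_equal(fit$delta_err, 0.7419128, tolerance = 1e-5)
  expect_lt(abs(fit$delta - 30), 1)
})

test_that("peak detection never fires on monotone diffuse-only curves", {
  inst <- ideal_instrument()
  for (A_z in c(10, 500, 14000)) {
    for (xi_p in c(30, 200, 1000)) {
      p <- nallet_parameters(A_z, xi_p, 0, 0, 0, background = 0.05)
      cur <- generate_nallet_curve(p, inst)
      expect_true(is.na(detect_bragg_peak(cur)),
                  label = sprintf("A_z=%g xi_p=%g", A_z, xi_p))
    }
  }
})

test_that("peak detection locates generated Bragg peaks within one grid
           step", {
  inst <- ideal_instrument()
  grid <- instrument_q_grid(inst)
  for (row in list(reference_sets()$charged[1, ],
                   reference_sets()$neutral[4, ])) {
    cur <- generate_nallet_curve(row_params(row), inst)
    found <- detect_bragg_peak(cur)
    step <- grid[which.min(abs(grid - row$q0)) + 1] -
      grid[which.min(abs(grid - row$q0))]
    expect_false(is.na(found))
    expect_lt(abs(found - row$q0), 1.5 * step)
  }
})

test_that("Porod representation flattens q^-2 decay and is
           phi-normalised", {
  q <- seq(0.01, 0.3, length.out = 60)
  cur <- scattering_curve(q, 1 / q^2)
  tr <- porod_representation(cur, 1)
  expect_equal(tr$value, rep(1, length(q)))
  # equal-delta slab curves at different phi transform identically
  inst <- ideal_instrument()
  c1 <- generate_slab_curve(slab_model(0.05, 32), inst)
  c2 <- generate_slab_curve(slab_model(0.10, 32), inst)
  t1 <- porod_representation(c1, 0.05)
  t2 <- porod_representation(c2, 0.10)
  expect_equal(t1$value, t2$value, tolerance = 1e-12)
})

test_that("Porod representation amplifies a second-order reflection", {
  p <- nallet_parameters(100, 50, 400, 300, 0.02)
  attr(p, "second_order") <- list(A_B = 60, xi_l = 300)
  cur <- generate_nallet_curve(p, ideal_instrument())
  tr <- porod_representation(cur, 0.1)
  near <- function(x, q, w = 0.002) which(abs(x - q) < w)
  # in the raw curve the second peak is ~15% of the first; after the
  # q^2 weighting the two reflections are comparable
  raw_ratio <- max(cur$intensity[near(cur$q, 0.04)]) /
    max(cur$intensity[near(cur$q, 0.02)])
  porod_ratio <- max(tr$value[near(tr$q, 0.04)]) /
    max(tr$value[near(tr$q, 0.02)])
  expect_gt(porod_ratio, 2.5 * raw_ratio)
})

test_that("high-q overlap metric is symmetric, zero for identical curves
           and equals a constant relative offset", {
  q <- seq(0.01, 0.3, length.out = 80)
  a <- data.frame(q = q, value = 5 + sin(10 * q))
  b <- data.frame(q = q, value = 1.10 * (5 + sin(10 * q)))
  expect_equal(highq_overlap_metric(a, a, 0.05), 0)
  expect_equal(highq_overlap_metric(a, b, 0.05), 0.10, tolerance = 1e-9)
  expect_equal(highq_overlap_metric(a, b, 0.05),
               highq_overlap_metric(b, a, 0.05))
  expect_error(highq_overlap_metric(a, b, 0.5), "overlap")
  # equal-delta slab curves at different dilutions overlap at high q
  inst <- ideal_instrument()
  t1 <- porod_representation(generate_slab_curve(slab_model(0.05, 32), inst),
                             0.05)
  t2 <- porod_representation(generate_slab_curve(slab_model(0.10, 32), inst),
                             0.10)
  expect_lt(highq_overlap_metric(t1, t2, 0.05), 0.01)
})
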