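# Published fitted parameter sets for the three dilution series of the
# TX100/TX35 lamellar system (neutral, charged Gamma = 1%, polymer-doped
# Psi = 10%), used as generator inputs for round-trip tests. xi_l values
# of ~1e-7 A mark rows where the Bragg correlation length was not
# determined (vanishing-width term, printed "± N.D."): for those rows
# the Bragg Lorentzian is numerically a constant and xi_l, q0 carry no
# information.
reference_sets <- function() {
  list(
    neutral = data.frame(
      phi = c(0.05, 0.10, 0.20, 0.30),
      A_z = c(14531.6, 2114, 760.77, 493.14),
      xi_p = c(1033.03, 337.43, 245.61, 181.59),
      A_B = c(11.31, 72.32, 50.51, 62.55),
      xi_l = c(2.43e-7, 79.48, 98.01, 109.53),
      q0 = c(0.0091, 0.1187, 0.04087, 0.06207)),
    charged = data.frame(
      phi = c(0.05, 0.10, 0.20, 0.30),
      A_z = c(102.15, 44.05, 21.76, 22.58),
      xi_p = c(55.37, 23.50, 29.99, 35.27),
      A_B = c(546.33, 326.93, 122.82, 72.31),
      xi_l = c(628.84, 381.38, 162.48, 133.66),
      q0 = c(0.0105, 0.0189, 0.0413, 0.0612)),
    polymer = data.frame(
      phi = c(0.05, 0.10, 0.20),
      A_z = c(722.82, 1123, 21.76),
      xi_p = c(161.06, 305.50, 29.99),
      A_B = c(3.44, 172.63, 144.75),
      xi_l = c(3.92e-9, 201.04, 226.81),
      q0 = c(0.01378, 0.02165, 0.04132)))
}

# Caille parameters reported for the neutral series under ideal swelling
reference_caille <- function() {
  data.frame(phi = c(0.05, 0.10, 0.20, 0.30),
             eta = c(1.20, 1.08, 0.85, 0.65))
}

row_params <- function(row) {
  nallet_parameters(A_z = row$A_z, xi_p = row$xi_p, A_B = row$A_B,
                    xi_l = row$xi_l, q0 = row$q0)
}

# a row is degenerate when its Bragg term has vanishing width
row_degenerate <- function(row) row$xi_l < 1e-3

jitter_params <- function(params, seed, amount = 0.2) {
  set.seed(seed)
  f <- stats::runif(5, 1 - amount, 1 + amount)
  nallet_parameters(params$A_z * f[1], params$xi_p * f[2],
                    params$A_B * f[3], params$xi_l * f[4],
                    params$q0 * f[5])
}

ideal_instrument <- function(n_points = 200)
  instrument_config(n_points = n_points, resolution_sigmas = 0)

trapz_q2I <- function(curve, lo = -Inf, hi = Inf) {
  k <- curve$q >= lo & curve$q <= hi
  q <- curve$q[k]
  y <- q^2 * curve$intensity[k]
  sum(diff(q) * (head(y, -1) + tail(y, -1)) / 2)
}
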