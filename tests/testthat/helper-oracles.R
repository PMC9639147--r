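# Shared fixtures and independent oracles used across the suite.

AU_FS <- 0.02418884

# Harmonic-oscillator wavefunction psi_n for frequency w centered at x0
# (atomic units), via the Hermite recursion.  Used for quadrature oracles.
ho_psi <- function(n, w, x0) {
  function(x) {
    q <- sqrt(w) * (x - x0)
    h0 <- rep(1, length(q)); h1 <- 2 * q
    h <- if (n == 0) h0 else if (n == 1) h1 else {
      for (k in 2:n) { h2 <- 2 * q * h1 - 2 * (k - 1) * h0; h0 <- h1; h1 <- h2 }
      h1
    }
    (w / pi)^0.25 / sqrt(2^n * factorial(n)) * h * exp(-q^2 / 2)
  }
}

# Quadrature oracles for the one-mode overlap and Q-element, independent of
# the package's ladder recursions.
quad_fc <- function(mode, v_g, v_e) {
  X <- mode$displacement / sqrt(mode$freq_g)
  L <- 30 / sqrt(min(mode$freq_g, mode$freq_e))
  stats::integrate(function(x)
    ho_psi(v_e, mode$freq_e, X)(x) * ho_psi(v_g, mode$freq_g, 0)(x),
    -L, L + X, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

quad_ht <- function(mode, v_g, v_e) {
  X <- mode$displacement / sqrt(mode$freq_g)
  L <- 30 / sqrt(min(mode$freq_g, mode$freq_e))
  stats::integrate(function(x)
    ho_psi(v_e, mode$freq_e, X)(x) * sqrt(mode$freq_g) * x *
      ho_psi(v_g, mode$freq_g, 0)(x),
    -L, L + X, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Brute-force 2-D quadrature by iterated adaptive 1-D integration
# (inner integral over y for each outer x node).
quad2d <- function(f, xl, xu, yl, yu, tol = 1e-11) {
  outer_f <- function(xv) vapply(xv, function(x)
    stats::integrate(function(y) f(x, y), yl, yu,
                     rel.tol = tol, abs.tol = tol)$value, numeric(1))
  stats::integrate(outer_f, xl, xu, rel.tol = tol, abs.tol = tol)$value
}

# A porphyrin-like two-mode test chromophore: visible gap, skeletal modes,
# weak electron-phonon coupling, transition dipole of order 1 a.u. with
# small Herzberg-Teller derivatives.
two_mode_model <- function() {
  vibronic_model(
    list(normal_mode(800, 800, sqrt(2 * 0.02)),
         normal_mode(1400, 1400, sqrt(2 * 0.03))),
    gap = 2.28, mu0 = c(0.8, 0.5, 0.2),
    dmu = cbind(c(0.03, 0.02, 0.01), c(0.01, 0.04, 0.02)))
}

one_mode_model <- function() {
  vibronic_model(list(normal_mode(800, 800, sqrt(2 * 0.02))),
                 gap = 2.28, mu0 = c(0.8, 0.5, 0.2),
                 dmu = matrix(c(0.03, 0.02, 0.01), 3, 1))
}

# Bare two-level system (no modes): ground + excited origin at `gap` (a.u.).
two_level_model <- function(gap = 0.2, mu = 1) {
  vibronic_model(list(), gap = gap, gap_unit = "au", mu0 = c(mu, 0, 0))
}

# Three-state open-system test model: |g0>, |e0>, |e1> with well-separated
# levels (0, 0.1, 0.12 hartree) so the quantum-jump dynamics is not
# AC-Stark sensitive.
three_state_model <- function() {
  m <- vibronic_model(
    list(normal_mode(0.02 / au$cm1_hartree, 0.02 / au$cm1_hartree, 0.3)),
    gap = 0.1, gap_unit = "au", mu0 = c(0.5, 0, 0),
    dmu = matrix(c(0.3, 0, 0), 3, 1))
  subset_states(m, c(1, 3, 4))
}

# Continuous-wave-like drive: a Gaussian envelope so wide it is flat over
# the whole run.
cw_pulse <- function(eps0, omega_au) {
  gaussian_pulse(eps0, sigma = 1e9, t0 = 0, omega = omega_au,
                 omega_unit = "au")
}

# The reference nonresonant study pulse: 5.14e5 V/m, sigma 256 fs,
# centred at 968 fs, carrier 2.04 eV (0.24 eV below the 0-0 line of the
# 2.28 eV test chromophores).
nonresonant_pulse <- function(sigma_fs = 256, t0_fs = 968)
  gaussian_pulse(5.14e5, sigma_fs, t0_fs, 2.04, amplitude_unit = "V/m")
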