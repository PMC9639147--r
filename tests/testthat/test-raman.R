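# Scattered-field coefficients, orientational averaging, cross-sections,
# and the sum-over-states oracle.

# hand-made trajectory with one excited intermediate of constant modulus
# oscillating at `omega_d`, on a two-level system
fake_trajectory <- function(model, T_au, dtau, amp, omega_d) {
  times <- seq(0, T_au, by = dtau)
  coefs <- rbind(rep(1 + 0i, length(times)),
                 amp * exp(-1i * omega_d * times))
  structure(list(times = times, coefs = coefs, surface = model$surface,
                 energy = model$energy, dt = dtau, stride = 1L,
                 stochastic = FALSE, jump_times = numeric(0)),
            class = "coef_trajectory")
}

test_that("no excited amplitude means no scattered signal on any channel", {
  m <- one_mode_model()
  p <- gaussian_pulse(0, 64, 242, 2.04)
  grid <- propagation_grid(300, 0.024, stride = 4)
  tr <- propagate_first_order(m, p, grid)
  b <- second_order_map(tr, m, 300, c(0.05, 0.09))
  expect_equal(max(Mod(b$B)), 0)
})

test_that("a constant-modulus intermediate gives a sinc line at energy conservation", {
  m <- two_level_model(gap = 0.1)
  wd <- 0.08
  win <- c(0.06, 0.10)
  widths <- vapply(c(4000, 8000), function(T_au) {
    tr <- fake_trajectory(m, T_au, 2, 0.01, wd)
    b <- second_order_map(tr, m, T_au * AU_FS, win, final_states = 1L,
                          pad = 16)
    prof <- Mod(b$B[, 1, 1, 1])
    pk <- which.max(prof)
    # centre at omega_S = omega_d (final state has E_N = 0)
    expect_lt(abs(b$omega[pk] - wd), b$omega[2] - b$omega[1])
    half <- which(prof >= prof[pk] / 2)
    (b$omega[max(half)] - b$omega[min(half)])
  }, numeric(1))
  # FWHM shrinks as 1/T
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.02)
})

test_that("cumulative Stokes signal is flat once the pulse is over", {
  m <- one_mode_model()
  p <- gaussian_pulse(5.14e5, 64, 242, 2.04, amplitude_unit = "V/m")
  grid <- propagation_grid(700, 0.024, stride = 4)
  s <- scattering_spectrum(m, p, grid, c(550, 625, 700))
  i800 <- which.min(abs(s$shift_cm1 - 800))
  v <- s$sigma[i800, ]
  expect_lt(abs(v[2] / v[1] - 1), 0.01)
  expect_lt(abs(v[3] / v[2] - 1), 0.01)
})

test_that("setup combination reduces correctly for structured tensors", {
  setup <- detection_setup()
  grid_shape <- c(2, 1, 1)
  mk_maps <- function(tensor) {
    lapply(1:3, function(e) {
      B <- array(0 + 0i, c(grid_shape, 3))
      for (l in 1:3) B[, , , l] <- tensor[l, e]
      list(omega = c(0.1, 0.2), t_obs = 1, final_states = 1L, B = B)
    })
  }
  b <- 0.7 - 0.2i
  iso <- combine_setup(mk_maps(diag(3) * b), setup)
  expect_equal(as.numeric(iso$P), rep(Mod(b)^2, 2), tolerance = 1e-12)
  zero <- combine_setup(mk_maps(matrix(0, 3, 3)), setup)
  expect_equal(max(zero$P), 0)
  expect_error(combine_setup(mk_maps(diag(3))[1:2], setup), "three")
})

test_that("invariant weights match the Monte-Carlo rotation average", {
  set.seed(7)
  A <- matrix(complex(real = stats::rnorm(9), imaginary = stats::rnorm(9)), 3, 3)
  an <- tdraman:::setup_combine_tensor(A, detection_setup())
  mc <- rotation_average_mc(A, 2e4)
  expect_equal(as.numeric(an), mc, tolerance = 5e-3)
})

test_that("cross-section rejects zero fluence and is nonnegative", {
  m <- one_mode_model()
  p <- gaussian_pulse(5.14e5, 64, 242, 2.04, amplitude_unit = "V/m")
  grid <- propagation_grid(500, 0.024, stride = 4)
  s <- scattering_spectrum(m, p, grid, c(300, 500))
  expect_true(all(s$sigma >= 0))
  expect_true(all(s$per_state >= 0))
  expect_equal(s$sigma, apply(s$per_state, c(1, 2), sum))
  tr <- propagate_first_order(m, p, grid)
  b <- second_order_map(tr, m, 500, c(0.05, 0.09))
  cmb <- combine_setup(list(b, b, b))
  expect_error(cross_section(cmb, gaussian_pulse(0, 64, 242, 2.04)),
               "fluence")
})

test_that("KHD polarizability is real off resonance and has simple-pole scaling", {
  m <- two_level_model(gap = 0.2, mu = 0.8)
  a1 <- khd_polarizability(m, omega_I = 0.1)[["1"]]
  expect_equal(max(abs(Im(a1))), 0)
  expect_equal(a1[1, 1], (0.8^2 / 0.1) + 0i)
  # doubling the detuning quarters |alpha|^2 exactly for one intermediate
  k1 <- khd_cross_section(m, omega_I = 0.2 - 0.02)
  k2 <- khd_cross_section(m, omega_I = 0.2 - 0.04)
  inv1 <- k1$cross_section / (k1$omega_S^3 * (0.2 - 0.02))
  inv2 <- k2$cross_section / (k2$omega_S^3 * (0.2 - 0.04))
  expect_equal(inv1 / inv2, 4, tolerance = 1e-10)
  expect_error(khd_polarizability(m, omega_I = 0.2), "pole")
})

test_that("peak integrals are additive and reject empty bands", {
  m <- one_mode_model()
  p <- gaussian_pulse(5.14e5, 64, 242, 2.04, amplitude_unit = "V/m")
  grid <- propagation_grid(500, 0.024, stride = 4)
  s <- scattering_spectrum(m, p, grid, 500)
  # split the band exactly at a grid point: trapezoids partition the union
  cut <- s$shift_cm1[which.min(abs(s$shift_cm1 - 800))]
  i1 <- peak_integral(s, c(500, cut))$integral
  i2 <- peak_integral(s, c(cut, 1100))$integral
  iu <- peak_integral(s, c(500, 1100))$integral
  expect_equal(i1 + i2, iu, tolerance = 1e-12)
  s0 <- s; s0$sigma[] <- 0
  expect_equal(peak_integral(s0, c(500, 1100))$integral, 0)
  expect_error(peak_integral(s, c(5000, 6000)), "empty band")
})

test_that("spectrum averaging is exact for degenerate inputs and checks grids", {
  m <- one_mode_model()
  p <- gaussian_pulse(5.14e5, 64, 242, 2.04, amplitude_unit = "V/m")
  grid <- propagation_grid(400, 0.024, stride = 4)
  s <- scattering_spectrum(m, p, grid, 400)
  one <- average_spectra(list(s))
  expect_equal(one$sigma, s$sigma)
  three <- average_spectra(list(s, s, s))
  expect_equal(three$sigma, s$sigma)
  expect_equal(max(three$se), 0)
  s2 <- scattering_spectrum(m, p, grid, 350)
  expect_error(average_spectra(list(s, s2)), "mismatched")
})

test_that("band integrals of small and large SSE ensembles agree within errors", {
  m <- three_state_model()
  p <- cw_pulse(2e-3, m$energy[3])
  grid <- propagation_grid(20000 * AU_FS, 0.25 * AU_FS, stride = 200)
  ch <- data.frame(source = 3, target = 2, rate = 2e-4)
  win_ev <- (m$energy[3] + c(-0.02, 0.02)) * au$hartree_eV
  run <- function(n, seed) {
    sp <- sse_spectrum_ensemble(m, p, grid, 20000 * AU_FS, ch,
                                n_traj = n, seed = seed,
                                shift_window_cm1 = au_to_cm1(c(-0.02, 0.02)))
    band <- range(sp$shift_cm1)
    tot <- peak_integral(sp, band)$integral
    semat <- sp$se
    w <- sp$omega
    se_band <- sqrt(sum((diff(w) * (semat[-1, 1] + semat[-nrow(semat), 1]) / 2)^2))
    c(tot, se_band)
  }
  a <- run(8, seed = 21)
  b <- run(16, seed = 22)
  expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2) + 1e-12)
})
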