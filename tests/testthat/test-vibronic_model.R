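# Vibronic basis, FC/HT integrals and transition-dipole assembly.

test_that("basis truncation gives the zero state plus one fundamental per mode", {
  modes108 <- replicate(108, normal_mode(1000, 1000, 0.1), simplify = FALSE)
  expect_equal(nrow(build_basis(modes108, 1L)), 109L)
  expect_equal(nrow(build_basis(list(), 1L)), 1L)
  b2 <- build_basis(list(normal_mode(800, 800, 0.1),
                         normal_mode(1400, 1400, 0.1)), 1L)
  expect_equal(nrow(b2), 3L)
  expect_equal(b2[1, ], c(0L, 0L))       # zero state first
  expect_equal(b2[2, ], c(1L, 0L))       # then mode-index order
  expect_equal(b2[3, ], c(0L, 1L))
  expect_error(build_basis(list(normal_mode(800, 800, 0)), -1L), "max_quanta")
})

test_that("basis energies are referenced to the global ground vibronic state", {
  m <- two_mode_model()
  expect_equal(m$energy[1], 0)
  expect_true(all(m$energy >= 0))
  expect_equal(m$energy[2], cm1_to_au(800))
  expect_equal(m$energy[3], cm1_to_au(1400))
  # excited origin above the ground origin
  expect_gt(origin_energy(m), max(m$energy[m$surface == "g"]))
  expect_error(vibronic_model(list(), gap = -1, gap_unit = "au",
                              mu0 = c(1, 0, 0)), "origin")
})

test_that("FC integrals reproduce closed-form displaced-oscillator limits", {
  m0 <- normal_mode(800, 800, 0)
  expect_equal(fc_integral(m0, 0, 0), 1)
  d <- 0.5
  md <- normal_mode(800, 800, d)
  expect_equal(fc_integral(md, 0, 0)^2, exp(-d^2 / 2), tolerance = 1e-12)
  expect_equal((fc_integral(md, 0, 1) / fc_integral(md, 0, 0))^2, d^2 / 2,
               tolerance = 1e-12)
})

test_that("FC and HT integrals agree with numerical quadrature", {
  for (m in list(normal_mode(800, 950, 0.37), normal_mode(1400, 1200, -0.6),
                 normal_mode(300, 300, 1.1))) {
    for (vg in 0:3) for (ve in 0:3)
      expect_equal(fc_integral(m, vg, ve), quad_fc(m, vg, ve),
                   tolerance = 1e-10)
    for (vg in 0:2) for (ve in 0:3)
      expect_equal(ht_integral(m, vg, ve), quad_ht(m, vg, ve),
                   tolerance = 1e-10)
  }
})

test_that("HT element at zero displacement follows the ladder rule", {
  m0 <- normal_mode(800, 800, 0)
  expect_equal(ht_integral(m0, 0, 0), 0)
  expect_equal(abs(ht_integral(m0, 0, 1)), 1 / sqrt(2), tolerance = 1e-12)
})

test_that("quanta beyond the recursion depth raise an explicit error", {
  m <- normal_mode(800, 800, 0.3)
  expect_error(fc_integral(m, 0, 500), "recursion depth")
  expect_error(fc_integral(m, -1, 0), ">= 0")
})

test_that("FC sum rule converges monotonically to one from below", {
  m <- normal_mode(800, 950, 0.8)
  sums <- vapply(c(2, 5, 10, 20, 40), function(ME)
    sum(vapply(0:ME, function(ve) fc_integral(m, 0, ve)^2, numeric(1))),
    numeric(1))
  expect_true(all(diff(sums) >= -1e-14))
  expect_true(all(sums <= 1 + 1e-12))
  expect_equal(sums[length(sums)], 1, tolerance = 1e-10)
})

test_that("dipole matrix is symmetric with zero same-surface blocks", {
  m <- two_mode_model()
  ns <- m$n_per_surface
  for (a in 1:3) {
    D <- m$D[[a]]
    expect_equal(D, t(D))
    expect_true(all(D[1:ns, 1:ns] == 0))
    expect_true(all(D[ns + 1:ns, ns + 1:ns] == 0))
  }
})

test_that("pure-FC models scale every element by mu0; pure-HT obeys the selection rule", {
  modes <- list(normal_mode(900, 1000, 0.4))
  mfc <- vibronic_model(modes, gap = 2, mu0 = c(0.7, 0.1, -0.2))
  ns <- mfc$n_per_surface
  fcprod <- outer(0:1, 0:1, Vectorize(function(ve, vg)
    fc_integral(modes[[1]], vg, ve)))
  for (a in 1:3)
    expect_equal(mfc$D[[a]][ns + 1:ns, 1:ns], mfc$mu0[a] * fcprod,
                 tolerance = 1e-12)
  # mu0 = 0, one HT derivative, zero displacement: only 0 <-> 1 transitions
  modes0 <- list(normal_mode(900, 900, 0))
  mht <- vibronic_model(modes0, gap = 2, mu0 = c(0, 0, 0),
                        dmu = matrix(c(0.3, 0, 0), 3, 1))
  blk <- mht$D[[1]][3:4, 1:2]
  expect_equal(blk[1, 1], 0)      # 0 -> 0 forbidden
  expect_equal(blk[2, 2], 0)      # 1 -> 1 forbidden
  expect_equal(abs(blk[2, 1]), 0.3 / sqrt(2), tolerance = 1e-12)
  expect_equal(abs(blk[1, 2]), 0.3 / sqrt(2), tolerance = 1e-12)
})

test_that("assembled two-mode dipole elements match brute-force 2-D quadrature", {
  modes <- list(normal_mode(800, 900, 0.45), normal_mode(1400, 1300, -0.3))
  mu0 <- c(0.6, -0.2, 0.3)
  dmu <- cbind(c(0.10, 0.05, -0.02), c(-0.04, 0.08, 0.03))
  m <- vibronic_model(modes, gap = 2.1, mu0 = mu0, dmu = dmu)
  ns <- m$n_per_surface
  w1 <- modes[[1]]$freq_g; w2 <- modes[[2]]$freq_g
  X1 <- modes[[1]]$displacement / sqrt(w1)
  X2 <- modes[[2]]$displacement / sqrt(w2)
  L1 <- 12 / sqrt(w1); L2 <- 12 / sqrt(w2)
  quanta <- m$quanta
  for (a in 2:3) {   # the x component is covered by the deeper check below
    for (ie in 1:ns) for (ig in 1:ns) {
      ve <- quanta[ie, ]; vg <- quanta[ig, ]
      f <- function(x, y) {
        mu_q <- mu0[a] + dmu[a, 1] * sqrt(w1) * x + dmu[a, 2] * sqrt(w2) * y
        mu_q *
          ho_psi(ve[1], modes[[1]]$freq_e, X1)(x) *
          ho_psi(ve[2], modes[[2]]$freq_e, X2)(y) *
          ho_psi(vg[1], w1, 0)(x) * ho_psi(vg[2], w2, 0)(y)
      }
      ref <- quad2d(f, -L1, L1 + X1, -L2, L2 + X2)
      expect_lt(abs(m$D[[a]][ns + ie, ig] - ref), 1e-8)
    }
  }
})

test_that("imported integral tables override the analytic computation", {
  modes <- list(normal_mode(800, 800, 0.4))
  fc <- matrix(c(0.9, 0.1, -0.1, 0.85), 2, 2)
  ht <- array(c(0.05, 0.6, 0.6, 0.1), c(2, 2, 1))
  m <- vibronic_model(modes, gap = 2, mu0 = c(1, 0, 0),
                      dmu = matrix(c(0.2, 0, 0), 3, 1),
                      fc_table = fc, ht_table = ht)
  expect_equal(m$D[[1]][3:4, 1:2], 1 * fc + 0.2 * ht[, , 1])
  expect_error(vibronic_model(modes, gap = 2, mu0 = c(1, 0, 0),
                              fc_table = matrix(1, 3, 3)), "dimensions")
})

test_that("dimension mismatch between modes and derivatives is rejected", {
  expect_error(vibronic_model(list(normal_mode(800, 800, 0)), gap = 2,
                              mu0 = c(1, 0, 0), dmu = matrix(0, 3, 2)),
               "mismatch")
})

test_that("synthesized models are reproducible and honour their spec", {
  a <- synthesize_model(n_modes = 3, seed = 42)
  b <- synthesize_model(n_modes = 3, seed = 42)
  expect_identical(a, b)
  d <- synthesize_model(n_modes = 3, seed = 43)
  expect_false(identical(a, d))
  expect_equal(length(a$energy), 2 * 4)
  # requested Huang-Rhys window respected: S = d^2/2
  S <- vapply(a$modes, function(m) m$displacement^2 / 2, numeric(1))
  expect_true(all(S >= 0.005 & S <= 0.05))
  m1 <- synthesize_model(n_modes = 1, huang_rhys_range = c(0.04, 0.04), seed = 1)
  expect_equal(m1$modes[[1]]$displacement^2 / 2, 0.04, tolerance = 1e-12)
  expect_error(synthesize_model(freq_range_cm1 = c(500, 100)), "range")
})
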