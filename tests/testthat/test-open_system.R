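# Quantum-jump trajectories, decay channels and the Lindblad oracle.

test_that("decay channels connect every fundamental to its surface origin", {
  m <- two_mode_model()
  ch <- decay_channels(m, lifetime_ps = 1.8)
  expect_equal(nrow(ch), 4L)                     # 2 fundamentals per surface
  expect_equal(sort(ch$source), c(2L, 3L, 5L, 6L))
  expect_equal(ch$target[ch$source %in% c(2, 3)], c(1L, 1L))
  expect_equal(ch$target[ch$source %in% c(5, 6)], c(4L, 4L))
  expect_equal(ch$rate, rep(1 / (1.8e3 / AU_FS), 4), tolerance = 1e-12)
  che <- decay_channels(m, surfaces = "excited")
  expect_true(all(m$surface[che$source] == "e"))
})

test_that("zero decay rates reproduce the closed-system trajectory exactly", {
  m <- three_state_model()
  p <- cw_pulse(2e-3, m$energy[3])
  grid <- propagation_grid(3000 * AU_FS, 0.25 * AU_FS, stride = 100)
  ch0 <- data.frame(source = 3, target = 2, rate = 0)
  t_sse <- propagate_sse(m, p, grid, ch0, seed = 5)
  t_cls <- suppressWarnings(propagate_first_order(m, p, grid))
  expect_identical(t_sse$coefs, t_cls$coefs)
  expect_length(t_sse$jump_times, 0)
})

test_that("a jump collapses onto the normalized target state", {
  m <- three_state_model()
  ch <- data.frame(source = 3, target = 2, rate = 5e-3)
  p0 <- cw_pulse(0, 0.1)
  grid <- propagation_grid(2000 * AU_FS, 0.5 * AU_FS, stride = 1)
  tr <- propagate_sse(m, p0, grid, ch, seed = 7, init_state = 3)
  expect_gt(length(tr$jump_times), 0)
  i_after <- which(tr$times >= tr$jump_times[1])[1]
  expect_equal(sum(Mod(tr$coefs[, i_after])^2), 1, tolerance = 1e-12)
  expect_equal(Mod(tr$coefs[3, i_after]), 0)
  expect_equal(Mod(tr$coefs[2, i_after]), 1, tolerance = 1e-12)
})

test_that("too coarse a step for the jump probability is refused", {
  m <- three_state_model()
  ch <- data.frame(source = 3, target = 2, rate = 0.5)
  p0 <- cw_pulse(0, 0.1)
  grid <- propagation_grid(100 * AU_FS, 0.5 * AU_FS, stride = 10)
  expect_error(propagate_sse(m, p0, grid, ch, seed = 1, init_state = 3),
               "reduce dt")
})

test_that("Lindblad propagation reduces to the pure-state projector when closed", {
  m <- three_state_model()
  # field-free superposition: the exact closed-system projector is analytic
  ch0 <- data.frame(source = 3, target = 2, rate = 0)
  p0 <- cw_pulse(0, 0.1)
  grid <- propagation_grid(500 * AU_FS, 0.02 * AU_FS, stride = 2500)
  c0 <- rep(1, 3) / sqrt(3)
  dm <- propagate_lindblad(m, p0, grid, ch0, rho0 = (c0 %o% c0) + 0i)
  for (i in seq_along(dm$times)) {
    ph <- exp(-1i * m$energy * dm$times[i])
    proj <- (c0 * ph) %*% Conj(t(c0 * ph))
    expect_lt(max(Mod(dm$rho[, , i] - proj)), 1e-8)
  }
  # with the field on, it matches the closed-system run to discretization
  p <- cw_pulse(2e-3, m$energy[3])
  grid2 <- propagation_grid(3000 * AU_FS, 0.05 * AU_FS, stride = 6000)
  dm2 <- propagate_lindblad(m, p, grid2, ch0)
  tr <- propagate_first_order(m, p, grid2)
  for (i in seq_along(dm2$times)) {
    proj <- tr$coefs[, i] %*% Conj(t(tr$coefs[, i]))
    expect_lt(max(Mod(dm2$rho[, , i] - proj)), 5e-4)
  }
  # trace conserved
  trs <- vapply(seq_along(dm2$times), function(i)
    Re(sum(diag(dm2$rho[, , i]))), numeric(1))
  expect_lt(max(abs(trs - 1)), 1e-8)
})

test_that("field-free Lindblad decay follows the exponential closed form", {
  m <- three_state_model()
  G <- 1e-3
  ch <- data.frame(source = 3, target = 2, rate = G)
  p0 <- cw_pulse(0, 0.1)
  grid <- propagation_grid(4000 * AU_FS, 0.5 * AU_FS, stride = 100)
  rho0 <- matrix(0 + 0i, 3, 3); rho0[3, 3] <- 1
  dm <- propagate_lindblad(m, p0, grid, ch, rho0 = rho0)
  pop <- lindblad_populations(dm)
  expect_equal(pop[3, ], exp(-G * dm$times), tolerance = 1e-6)
  expect_equal(pop[2, ], 1 - exp(-G * dm$times), tolerance = 1e-6)
})

test_that("ensemble population statistics behave and reject mismatched grids", {
  m <- three_state_model()
  p <- cw_pulse(2e-3, m$energy[3])
  grid <- propagation_grid(2000 * AU_FS, 0.25 * AU_FS, stride = 400)
  ch0 <- data.frame(source = 3, target = 2, rate = 0)
  trs <- run_sse_ensemble(m, p, grid, ch0, n_traj = 3, seed = 1)
  ep <- ensemble_populations(trs)
  # deterministic (no-decay) ensemble: identical members, zero SE
  expect_equal(max(ep$se), 0)
  expect_equal(ep$mean, populations(trs[[1]]))
  expect_error(ensemble_populations(trs[1]), "at least 2")
  grid2 <- propagation_grid(2000 * AU_FS, 0.25 * AU_FS, stride = 200)
  tr2 <- propagate_sse(m, p, grid2, ch0, seed = 4)
  expect_error(ensemble_populations(list(trs[[1]], tr2)), "mismatched")
})

test_that("ensembles are reproducible from the master seed", {
  m <- three_state_model()
  p <- cw_pulse(2e-3, m$energy[3])
  grid <- propagation_grid(2000 * AU_FS, 0.25 * AU_FS, stride = 400)
  ch <- data.frame(source = 3, target = 2, rate = 2e-4)
  e1 <- run_sse_ensemble(m, p, grid, ch, n_traj = 4, seed = 99)
  e2 <- run_sse_ensemble(m, p, grid, ch, n_traj = 4, seed = 99)
  expect_identical(lapply(e1, `[[`, "coefs"), lapply(e2, `[[`, "coefs"))
})
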