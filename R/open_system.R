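# Vibrational relaxation: stochastic Schroedinger equation with quantum
# jumps, and the dense Lindblad master-equation propagator used as its
# independent oracle.

#' Vibrational decay channels
#'
#' One channel per vibronic state with at least one vibrational quantum:
#' the state decays to the lowest vibronic level of its own electronic
#' surface with rate `1 / lifetime` (a single shared phenomenological
#' lifetime by default; per-channel rates may be supplied).
#'
#' @param model a [vibronic_model()].
#' @param lifetime_ps shared vibrational lifetime (picoseconds).
#' @param surfaces which surfaces relax: `"both"` (default), `"excited"`
#'   or `"ground"`.
#' @param rates optional explicit per-channel rates (a.u.), overriding the
#'   lifetime.
#' @return data frame with columns `source`, `target` (state indices) and
#'   `rate` (a.u.).
#' @export
decay_channels <- function(model, lifetime_ps = 1.8,
                           surfaces = c("both", "excited", "ground"),
                           rates = NULL) {
  surfaces <- match.arg(surfaces)
  nq <- rowSums(model$state_quanta)
  sel <- nq > 0
  if (surfaces == "excited") sel <- sel & model$surface == "e"
  if (surfaces == "ground")  sel <- sel & model$surface == "g"
  src <- which(sel)
  tgt <- vapply(src, function(i) {
    cand <- which(model$surface == model$surface[i])
    cand[which.min(model$energy[cand])]
  }, integer(1))
  if (is.null(rates)) {
    if (lifetime_ps <= 0) stop("decay_channels: lifetime must be > 0")
    rates <- rep(1 / fs_to_au(lifetime_ps * 1000), length(src))
  }
  if (length(rates) != length(src) || any(rates < 0))
    stop("decay_channels: need one non-negative rate per channel")
  ok <- src != tgt
  data.frame(source = src[ok], target = tgt[ok], rate = rates[ok])
}

#' Propagate one stochastic Schroedinger trajectory
#'
#' Quantum-jump unravelling of vibrational relaxation.  Each step applies
#' the deterministic two-step evolution with the amplitude-damping factors
#' `exp(-Gamma_q dt / 2)` on the decaying states, renormalizes, and draws a
#' Monte-Carlo jump with probability `p_q = Gamma_q |c_source|^2 dt` per
#' channel; on a jump the wave function is replaced by the (normalized)
#' jump-operator image, i.e. the pure target state.  Averaged over
#' trajectories this converges to the Lindblad master equation (see
#' [propagate_lindblad()]), which the test suite verifies.
#'
#' @inheritParams propagate_first_order
#' @param channels a [decay_channels()] data frame.
#' @param seed integer seed for this trajectory's noise realization.
#' @param jump_tol error if the total per-step jump probability exceeds
#'   this (demands a smaller dt).
#' @return A `coef_trajectory` with the jump log (`jump_times`,
#'   `jump_channels`).
#' @export
propagate_sse <- function(model, pulse, grid, channels, seed,
                          init_state = 1L, jump_tol = 0.1) {
  check_stability(model, grid)
  Nb <- length(model$energy)
  if (any(channels$source < 1 | channels$source > Nb |
            channels$target < 1 | channels$target > Nb))
    stop("propagate_sse: channel state index out of range")
  c0 <- complex(Nb); c0[init_state] <- 1 + 0i
  set.seed(seed)
  res <- cpp_propagate(model$energy, direction_matrix(model, pulse$pol),
                       sample_field(pulse, grid), grid$dt, grid$stride, c0,
                       as.integer(channels$source) - 1L,
                       as.integer(channels$target) - 1L,
                       channels$rate, TRUE, jump_tol)
  new_trajectory(res, model, pulse, grid, stochastic = TRUE, seed = seed)
}

#' Run a reproducible SSE trajectory ensemble
#'
#' Per-trajectory seeds are derived deterministically from the master seed
#' (a fixed draw of `n_traj` integers), so ensembles are reproducible and
#' could be computed in any order.
#'
#' @inheritParams propagate_sse
#' @param n_traj number of trajectories (>= 1).
#' @param seed master seed.
#' @return list of `coef_trajectory` objects.
#' @export
run_sse_ensemble <- function(model, pulse, grid, channels, n_traj, seed) {
  if (n_traj < 1) stop("run_sse_ensemble: n_traj must be >= 1")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_traj)
  lapply(seeds, function(s)
    propagate_sse(model, pulse, grid, channels, seed = s))
}

#' Propagate the Lindblad master equation (oracle)
#'
#' Deterministic dense density-matrix propagation (classic RK4) with the
#' same decay channels as the quantum-jump trajectories; the trajectory
#' average of [propagate_sse()] converges to this result.
#'
#' @inheritParams propagate_sse
#' @param rho0 initial density matrix (default: pure `init_state`).
#' @param trace_tol error if `|tr rho - 1|` exceeds this at any step.
#' @return A `density_trajectory`: stored times and a `Nb x Nb x n_stored`
#'   complex array.
#' @export
propagate_lindblad <- function(model, pulse, grid, channels,
                               init_state = 1L, rho0 = NULL,
                               trace_tol = 1e-6) {
  Nb <- length(model$energy)
  if (is.null(rho0)) {
    rho0 <- matrix(0 + 0i, Nb, Nb)
    rho0[init_state, init_state] <- 1 + 0i
  }
  res <- cpp_lindblad(model$energy, direction_matrix(model, pulse$pol),
                      sample_field(pulse, grid), grid$dt, grid$stride,
                      as.integer(channels$source) - 1L,
                      as.integer(channels$target) - 1L,
                      channels$rate, rho0, trace_tol)
  structure(list(times = as.numeric(res$times), rho = res$rho,
                 surface = model$surface, energy = model$energy),
            class = "density_trajectory")
}

#' Diagonal populations of a density trajectory
#' @param dm a `density_trajectory`.
#' @return matrix of real populations, states x stored times.
#' @export
lindblad_populations <- function(dm) {
  nt <- length(dm$times)
  vapply(seq_len(nt), function(i) Re(diag(dm$rho[, , i])),
         numeric(dim(dm$rho)[1]))
}

#' Ensemble-averaged populations with standard errors
#'
#' @param trajectories list of `coef_trajectory` objects on identical
#'   grids (at least 2).
#' @return list with `times`, `mean` (states x times) and `se` (standard
#'   error of the mean).
#' @export
ensemble_populations <- function(trajectories) {
  if (length(trajectories) < 2L)
    stop("ensemble_populations: need at least 2 trajectories")
  t0 <- trajectories[[1]]$times
  for (tr in trajectories)
    if (length(tr$times) != length(t0) || any(tr$times != t0))
      stop("ensemble_populations: trajectories stored on mismatched grids")
  pops <- lapply(trajectories, populations)
  M <- length(pops)
  mean_p <- Reduce(`+`, pops) / M
  var_p <- Reduce(`+`, lapply(pops, function(p) (p - mean_p)^2)) / (M - 1)
  list(times = t0, mean = mean_p, se = sqrt(var_p / M))
}
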