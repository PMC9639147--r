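# Real-time propagation of the vibronic coefficients under the incident
# pulse with the second-order Euler (two-step) integrator.

#' Propagation grid
#'
#' @param duration_fs total propagation time (fs).
#' @param dt_fs time step (fs); the default 0.024 fs is 1 a.u. of
#'   time within rounding and resolves optical carriers up to several eV.
#' @param stride store every `stride`-th step.
#' @return An object of class `propagation_grid`.
#' @export
propagation_grid <- function(duration_fs, dt_fs = 0.024, stride = 1L) {
  if (dt_fs <= 0) stop("propagation_grid: dt must be > 0")
  if (stride < 1) stop("propagation_grid: stride must be >= 1")
  dt <- fs_to_au(dt_fs)
  nsteps <- as.integer(round(fs_to_au(duration_fs) / dt))
  if (nsteps < 1) stop("propagation_grid: duration shorter than one step")
  structure(list(dt = dt, nsteps = nsteps, stride = as.integer(stride)),
            class = "propagation_grid")
}

# field scalar sampled on the step grid t_m = m dt, m = 0..nsteps
sample_field <- function(pulse, grid) {
  field_scalar(pulse, seq(0, grid$nsteps) * grid$dt)
}

# the two-step scheme is only stable for |E_max| dt < 1; refuse clearly
# unstable grids before wasting a run
check_stability <- function(model, grid) {
  x <- max(abs(model$energy)) * grid$dt
  if (x >= 1)
    stop(sprintf(
      "propagation: |E_max| * dt = %.2f >= 1; the second-order Euler scheme is unstable, reduce dt",
      x))
  invisible(x)
}

# -(mu . pol): real interaction matrix for a unit field along `pol`
direction_matrix <- function(model, pol) {
  pol <- pol / sqrt(sum(pol^2))
  -(pol[1] * model$D[[1]] + pol[2] * model$D[[2]] + pol[3] * model$D[[3]])
}

#' Interaction operator at a time
#'
#' The light-matter coupling `V(t) = -mu . eps(t)` contracted on the
#' vibronic basis; Hermitian (real symmetric), zero whenever the field is
#' zero.
#'
#' @param model a [vibronic_model()].
#' @param pulse a pulse object.
#' @param t time (atomic units).
#' @return real symmetric matrix on the vibronic basis (a.u.).
#' @export
interaction_element <- function(model, pulse, t) {
  e <- field_at(pulse, t)
  -(e[1] * model$D[[1]] + e[2] * model$D[[2]] + e[3] * model$D[[3]])
}

new_trajectory <- function(res, model, pulse, grid, stochastic,
                           seed = NA_integer_) {
  structure(list(
    times = res$times, coefs = res$coefs,
    surface = model$surface, energy = model$energy,
    dt = grid$dt, stride = grid$stride,
    pulse = pulse, model_hash = config_hash(model),
    stochastic = stochastic, seed = seed,
    jump_times = res$jump_times, jump_channels = res$jump_channels,
    norm_drift = res$norm_drift
  ), class = "coef_trajectory")
}

#' Propagate the first-order vibronic coefficients
#'
#' Advances the coefficient vector with the two-step second-order Euler
#' scheme `c(t + dt) = c(t - dt) - 2 i dt H(t) c(t)` (midpoint start step)
#' under `H(t) = H0 + V(t)`.  Coefficients carry their full phases
#' `exp(-i E_J t)`; no rotating frame is used, because the scattered-field
#' Fourier stage needs absolute phases.  In the weak-field regime the
#' excited-surface amplitudes are the first-order perturbative wave
#' function.
#'
#' @param model a [vibronic_model()] (dipoles assembled).
#' @param pulse a pulse object; its polarization sets the field direction.
#' @param grid a [propagation_grid()].
#' @param init_state index of the initial basis state (default: the global
#'   ground vibronic state, index 1).
#' @param norm_tol warn if the closed-system norm drifts by more than this.
#' @return A `coef_trajectory`: stored times (a.u.), complex coefficients
#'   (`Nb x n_stored`), and metadata.
#' @export
propagate_first_order <- function(model, pulse, grid, init_state = 1L,
                                  norm_tol = 1e-6) {
  check_stability(model, grid)
  Nb <- length(model$energy)
  c0 <- complex(Nb); c0[init_state] <- 1 + 0i
  res <- cpp_propagate(model$energy, direction_matrix(model, pulse$pol),
                       sample_field(pulse, grid), grid$dt, grid$stride, c0,
                       integer(0), integer(0), numeric(0),
                       FALSE, 0.1)
  if (res$norm_drift > norm_tol)
    warning(sprintf(
      "propagate_first_order: norm drift %.2e exceeds %.1e; reduce dt",
      res$norm_drift, norm_tol))
  new_trajectory(res, model, pulse, grid, stochastic = FALSE)
}

#' State populations of a trajectory
#'
#' @param trajectory a `coef_trajectory`.
#' @return matrix `|c_J(t)|^2`, states x stored times.
#' @export
populations <- function(trajectory) {
  Mod(trajectory$coefs)^2
}

#' @export
print.coef_trajectory <- function(x, ...) {
  cat(sprintf(
    "<coef_trajectory> %d states, %d stored times (0..%.1f fs)%s\n",
    nrow(x$coefs), length(x$times), au_to_fs(max(x$times)),
    if (x$stochastic) sprintf(", SSE with %d jumps", length(x$jump_times))
    else ""))
  invisible(x)
}
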