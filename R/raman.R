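# Scattered-field stage: cumulative second-order coefficients by windowed
# FFT of the first-order trajectory, isotropic orientational averaging via
# rotational invariants, cumulative time-dependent cross-sections, and the
# Kramers-Heisenberg-Dirac sum-over-states oracle.

#' Detection setup (illumination-detection geometry)
#'
#' The scattered-field tensor `B^{lambda eta}` transforms under molecular
#' rotations like the polarizability tensor, so the isotropic orientational
#' average of any detected intensity is a fixed combination of its three
#' rotational invariants: `|Tr B|^2`, the antisymmetric norm
#' `sum |B^a_ij|^2` and the symmetric-traceless norm
#' `sum |B^s_ij|^2 - |Tr B|^2 / 3`.  The default geometry - incident
#' linear polarization perpendicular to the detection direction, unpolarized
#' detection at 90 degrees - carries the classic weights
#' `(1/9, 1/6, 7/30)` (the `45 a^2 + 7 gamma^2` rule extended to complex,
#' possibly antisymmetric tensors); they are validated against a
#' Monte-Carlo rotation average in the test suite.
#'
#' @param geometry geometry name; only `"perpendicular_unpolarized"` is
#'   built in, or `"custom"` with explicit `weights`.
#' @param weights for `"custom"`: nonnegative weights of
#'   `(|Tr|^2, antisymmetric, symmetric-traceless)` in that order.
#' @return An object of class `detection_setup`.
#' @export
detection_setup <- function(geometry = c("perpendicular_unpolarized", "custom"),
                            weights = NULL) {
  geometry <- match.arg(geometry)
  if (geometry == "perpendicular_unpolarized") {
    weights <- c(tr = 1 / 9, anti = 1 / 6, sym = 7 / 30)
  } else {
    if (length(weights) != 3L || any(weights < 0))
      stop("detection_setup: need 3 nonnegative weights")
    names(weights) <- c("tr", "anti", "sym")
  }
  structure(list(geometry = geometry, weights = weights),
            class = "detection_setup")
}

# invariant combination for one 3x3 complex tensor
setup_combine_tensor <- function(A, setup) {
  w <- setup$weights
  tr2 <- Mod(A[1, 1] + A[2, 2] + A[3, 3])^2
  S <- (A + t(A)) / 2
  An <- (A - t(A)) / 2
  sym2 <- sum(Mod(S)^2) - tr2 / 3
  anti2 <- sum(Mod(An)^2)
  w["tr"] * tr2 + w["anti"] * anti2 + w["sym"] * sym2
}

#' Monte-Carlo rotational average of the detected intensity (oracle)
#'
#' Brute-force isotropic average of the detected intensity for the default
#' geometry (incident polarization along the lab z axis, detection along x,
#' both scattered projections summed) over uniformly random molecular
#' orientations.  Orientations are drawn as uniform quaternions; each draw
#' is augmented by the 24 rotations of the octahedral group (an exact
#' subgroup stratification of SO(3) that keeps the orientation distribution
#' uniform while strongly reducing the Monte-Carlo variance).
#'
#' @param A complex 3x3 tensor in the molecular frame.
#' @param n_orient total number of orientations (rounded up to a multiple
#'   of 24).
#' @return the averaged intensity (scalar).
#' @export
rotation_average_mc <- function(A, n_orient = 1e5) {
  # the 24 proper signed permutation matrices (rotation group of the cube)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  octa <- list()
  for (p in perms) for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    M <- matrix(0, 3, 3)
    M[cbind(1:3, p)] <- c(s1, s2, s3)
    if (abs(det(M) - 1) < 1e-12) octa[[length(octa) + 1L]] <- M
  }
  nq <- ceiling(n_orient / 24)
  u1 <- stats::runif(nq); u2 <- stats::runif(nq); u3 <- stats::runif(nq)
  q <- cbind(sqrt(1 - u1) * sin(2 * pi * u2), sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3), sqrt(u1) * cos(2 * pi * u3))
  tot <- 0
  for (i in seq_len(nq)) {
    w <- q[i, 4]; x <- q[i, 1]; y <- q[i, 2]; z <- q[i, 3]
    R <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
      2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
      2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
      3, 3, byrow = TRUE)
    for (f in octa) {
      Rf <- f %*% R
      Al <- Rf %*% A %*% t(Rf)
      tot <- tot + Mod(Al[3, 3])^2 + Mod(Al[2, 3])^2
    }
  }
  tot / (24 * nq)
}

#' Second-order (scattered-field) coefficient map
#'
#' Builds the cumulative scattered-field coefficients
#' `B_N^lambda(omega_S, t_obs)` from a stored first-order trajectory: for
#' each ground-surface final state `N` the integrand
#' `sum_J <N|mu_lambda|J> c_J(t') exp(i (E_N + omega_S) t')` is windowed by
#' the Heaviside function `Theta(t_obs - t')` and transformed over `t'` by
#' a zero-padded FFT, so all scattered frequencies are obtained at once.
#' Only excited-surface intermediates contribute (the dipole matrix has no
#' same-surface elements), so `B` vanishes identically while the pulse has
#' created no excited-surface amplitude.
#'
#' @param trajectory a `coef_trajectory` (full-phase convention of
#'   [propagate_first_order()]).
#' @param model the [vibronic_model()] the trajectory was computed with.
#' @param observation_times_fs observation times (fs); snapped to the
#'   stored grid, all within the run.
#' @param omega_window scattered-frequency window `c(min, max)` in hartree.
#' @param final_states indices of final states (default: every
#'   ground-surface basis state).
#' @param pad zero-padding factor of the FFT (frequency resolution
#'   `2 pi / (pad * T)`).
#' @return list with `omega` (a.u.), `t_obs` (a.u.), `final_states` and the
#'   complex array `B` of dimension `n_omega x n_tobs x n_states x 3`
#'   (last index: scattered polarization lambda = x, y, z).
#' @export
second_order_map <- function(trajectory, model, observation_times_fs,
                             omega_window, final_states = NULL, pad = 8) {
  tt <- trajectory$times
  dtau <- tt[2] - tt[1]
  nm <- length(tt)
  t_obs <- fs_to_au(observation_times_fs)
  if (any(t_obs > tt[nm] + dtau))
    stop("second_order_map: observation time beyond the trajectory")
  iobs <- vapply(t_obs, function(x) which.min(abs(tt - x)), integer(1))
  if (is.null(final_states)) final_states <- which(trajectory$surface == "g")

  P <- 2^ceiling(log2(pad * nm))
  omega_all <- 2 * pi * (seq_len(P) - 1) / (P * dtau)
  sel <- which(omega_all >= omega_window[1] & omega_all <= omega_window[2])
  if (length(sel) == 0) stop("second_order_map: empty frequency window")

  B <- array(0 + 0i, c(length(sel), length(iobs), length(final_states), 3L))
  for (s in seq_along(final_states)) {
    N <- final_states[s]
    phase <- exp(1i * trajectory$energy[N] * tt)
    for (a in 1:3) {
      row <- model$D[[a]][N, ]
      if (all(row == 0)) next
      g <- as.vector(row %*% trajectory$coefs) * phase
      for (io in seq_along(iobs)) {
        gw <- complex(P)
        gw[seq_len(iobs[io])] <- g[seq_len(iobs[io])]
        B[, io, s, a] <- dtau * stats::fft(gw, inverse = TRUE)[sel]
      }
    }
  }
  list(omega = omega_all[sel], t_obs = tt[iobs],
       final_states = final_states, B = B)
}

#' Combine polarization components for a detection setup
#'
#' Takes the three maps of [second_order_map()] computed with the incident
#' field along x, y and z, treats `B^{lambda eta}` as a 3x3 tensor per
#' `(N, omega_S, t_obs)`, and combines its rotational invariants with the
#' weights of the chosen geometry, yielding the isotropically averaged
#' populations `P_N(omega_S, t_obs)`.
#'
#' @param maps list of three [second_order_map()] results (incident
#'   polarization x, y, z, in that order), on identical grids.
#' @param setup a [detection_setup()].
#' @return list with `omega`, `t_obs`, `final_states` and the real
#'   nonnegative array `P` (`n_omega x n_tobs x n_states`).
#' @export
combine_setup <- function(maps, setup = detection_setup()) {
  if (length(maps) != 3L)
    stop("combine_setup: need the three incident-polarization maps (x, y, z)")
  m1 <- maps[[1]]
  for (m in maps[-1])
    if (length(m$omega) != length(m1$omega) ||
          !isTRUE(all.equal(m$t_obs, m1$t_obs)))
      stop("combine_setup: maps on mismatched grids")
  w <- setup$weights
  dims <- dim(m1$B)[1:3]
  slice <- function(map, l) array(map$B[, , , l], dims)
  tr <- array(0 + 0i, dims)
  sym2 <- array(0, dims)
  anti2 <- array(0, dims)
  for (l in 1:3) tr <- tr + slice(maps[[l]], l)
  for (l in 1:3) for (e in 1:3) {
    ble <- slice(maps[[e]], l)   # B_{lambda eta}
    bel <- slice(maps[[l]], e)   # B_{eta lambda}
    sym2 <- sym2 + Mod((ble + bel) / 2)^2
    anti2 <- anti2 + Mod((ble - bel) / 2)^2
  }
  P <- w["tr"] * Mod(tr)^2 + w["anti"] * anti2 +
    w["sym"] * (sym2 - Mod(tr)^2 / 3)
  P[P < 0] <- 0   # clip tiny negative round-off
  list(omega = m1$omega, t_obs = m1$t_obs,
       final_states = m1$final_states, P = P)
}

#' Cumulative time-dependent scattering cross-section
#'
#' Converts the isotropically averaged second-order populations into the
#' cumulative differential cross-section per unit scattered frequency and
#' solid angle,
#' `sigma(omega_S; t_obs) = omega_I omega_S^3 / (4 pi^2 c^3) * sum_N
#' P_N(omega_S, t_obs) / F`, with `F` the incident fluence.  The
#' `omega_I omega_S^3 / c^4` frequency dependence and the overall constant
#' are fixed by requiring the quasi-CW limit to reproduce the
#' Kramers-Heisenberg-Dirac spontaneous-Raman cross-section
#' ([khd_cross_section()]), which the test suite checks.
#'
#' @param combined result of [combine_setup()].
#' @param pulse the incident pulse (for fluence and the Raman-shift axis).
#' @param omega_I incident carrier frequency (a.u.); defaults to the
#'   pulse's.
#' @return An object of class `spectrum_series`: `omega` (a.u.),
#'   `shift_cm1` (Raman shift), `t_obs`, per-state array `per_state` and
#'   total matrix `sigma` (`n_omega x n_tobs`), all in atomic units of
#'   cross-section per unit frequency per steradian.
#' @export
cross_section <- function(combined, pulse, omega_I = NULL) {
  F <- fluence(pulse)
  if (!is.finite(F) || F <= 0)
    stop("cross_section: zero-fluence pulse gives an undefined cross-section")
  if (is.null(omega_I)) omega_I <- pulse$omega
  pref <- omega_I * combined$omega^3 / (4 * pi^2 * au$c_au^3) / F
  per_state <- combined$P * array(pref, dim(combined$P))
  sigma <- apply(per_state, c(1, 2), sum)
  structure(list(
    omega = combined$omega,
    shift_cm1 = au_to_cm1(omega_I - combined$omega),
    t_obs = combined$t_obs,
    final_states = combined$final_states,
    per_state = per_state,
    sigma = matrix(sigma, length(combined$omega)),
    omega_I = omega_I, fluence = F
  ), class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf(
    "<spectrum_series> %d frequencies (shift %.0f..%.0f cm-1), %d observation times\n",
    length(x$omega), min(x$shift_cm1), max(x$shift_cm1), length(x$t_obs)))
  invisible(x)
}

#' Kramers-Heisenberg-Dirac sum-over-states cross-section (CW oracle)
#'
#' Continuous-wave spontaneous Raman cross-sections per final vibronic
#' state from the resonant-term transition polarizability
#' `alpha^N_{lambda eta} = sum_J mu_lambda^{NJ} mu_eta^{J0} /
#' (E_J - E_0 - omega_I - i gamma)` over excited-surface intermediates,
#' combined with the same rotational-invariant weights and
#' `omega_I omega_S^3 / c^4` prefactor as [cross_section()].  Serves as
#' the time-independent oracle for the quasi-CW limit of the time-domain
#' pipeline.
#'
#' @param model a [vibronic_model()].
#' @param omega_I incident frequency (a.u.).
#' @param damping homogeneous damping `gamma` (a.u.); must be positive
#'   when `omega_I` is at resonance with an intermediate.
#' @param setup a [detection_setup()].
#' @param init_state initial vibronic state index (default ground).
#' @return data frame: final state index, Raman shift (cm^-1), scattered
#'   frequency (a.u.) and line-integrated differential cross-section
#'   (a.u. / sr).
#' @export
khd_cross_section <- function(model, omega_I, damping = 0,
                              setup = detection_setup(), init_state = 1L) {
  alphas <- khd_polarizability(model, omega_I, damping, init_state)
  out <- lapply(names(alphas), function(nm) {
    N <- as.integer(nm)
    omega_S <- omega_I - (model$energy[N] - model$energy[init_state])
    if (omega_S <= 0) return(NULL)
    data.frame(
      state = N,
      shift_cm1 = au_to_cm1(model$energy[N] - model$energy[init_state]),
      omega_S = omega_S,
      cross_section = omega_I * omega_S^3 / au$c_au^4 *
        as.numeric(setup_combine_tensor(alphas[[nm]], setup)))
  })
  do.call(rbind, out)
}

#' @rdname khd_cross_section
#' @return `khd_polarizability` returns the complex 3x3 transition
#'   polarizability tensor per ground-surface final state (a named list,
#'   names = state indices); real when the damping vanishes off resonance.
#' @export
khd_polarizability <- function(model, omega_I, damping = 0, init_state = 1L) {
  exc <- which(model$surface == "e")
  det <- model$energy[exc] - model$energy[init_state] - omega_I
  if (any(abs(det) < 1e-12) && damping <= 0)
    stop("khd_polarizability: omega_I at a pole requires damping > 0")
  finals <- which(model$surface == "g")
  out <- lapply(finals, function(N) {
    alpha <- matrix(0 + 0i, 3, 3)
    for (l in 1:3) for (e in 1:3)
      alpha[l, e] <- sum(model$D[[l]][N, exc] * model$D[[e]][exc, init_state] /
                           (det - 1i * damping))
    alpha
  })
  names(out) <- finals
  out
}

#' Integrate a spectral band as a function of observation time
#'
#' Trapezoidal integral of the cross-section over a Raman-shift band, per
#' observation time (the cumulative band intensity).
#'
#' @param spectrum a `spectrum_series`.
#' @param band_cm1 Raman-shift band `c(lo, hi)` in cm^-1.
#' @return data frame with `t_obs_fs` and `integral` (a.u. / sr).
#' @export
peak_integral <- function(spectrum, band_cm1) {
  idx <- which(spectrum$shift_cm1 >= band_cm1[1] &
                 spectrum$shift_cm1 <= band_cm1[2])
  if (length(idx) < 2L)
    stop("peak_integral: empty band (no grid points in the requested range)")
  idx <- idx[order(spectrum$omega[idx])]
  w <- spectrum$omega[idx]
  vals <- vapply(seq_along(spectrum$t_obs), function(io) {
    y <- spectrum$sigma[idx, io]
    sum(diff(w) * (y[-1] + y[-length(y)]) / 2)
  }, numeric(1))
  data.frame(t_obs_fs = au_to_fs(spectrum$t_obs), integral = vals)
}

#' Average spectra over stochastic realizations
#'
#' Pointwise mean (and standard error) of a list of `spectrum_series`
#' computed from independent SSE trajectories.
#'
#' @param spectra list of `spectrum_series` on identical grids.
#' @return a `spectrum_series` whose `sigma` is the mean; the element `se`
#'   holds the standard error of the mean (zero for a single input).
#' @export
average_spectra <- function(spectra) {
  s1 <- spectra[[1]]
  for (s in spectra[-1])
    if (length(s$omega) != length(s1$omega) ||
          !isTRUE(all.equal(s$t_obs, s1$t_obs)))
      stop("average_spectra: spectra on mismatched grids")
  M <- length(spectra)
  tot <- Reduce(`+`, lapply(spectra, `[[`, "sigma")) / M
  per <- Reduce(`+`, lapply(spectra, `[[`, "per_state")) / M
  se <- if (M > 1) {
    v <- Reduce(`+`, lapply(spectra, function(s) (s$sigma - tot)^2)) / (M - 1)
    sqrt(v / M)
  } else tot * 0
  out <- s1
  out$sigma <- tot
  out$per_state <- per
  out$se <- se
  out$n_averaged <- M
  out
}

#' Full time-resolved scattering spectrum of a model under a pulse
#'
#' Convenience pipeline: propagates the first-order coefficients for the
#' three incident-field directions (x, y, z), builds the scattered-field
#' maps, combines them for the detection setup and returns the cumulative
#' cross-section.  With `channels` set, one quantum-jump (SSE) realization
#' is computed instead of the closed-system dynamics (three independent
#' noise streams, one per field direction, derived from `seed`).
#'
#' @inheritParams propagate_first_order
#' @inheritParams second_order_map
#' @param shift_window_cm1 Raman-shift window of the output spectrum.
#' @param setup a [detection_setup()].
#' @param channels optional [decay_channels()] for an SSE realization.
#' @param seed seed for the SSE noise (required with `channels`).
#' @return a `spectrum_series`.
#' @export
scattering_spectrum <- function(model, pulse, grid, observation_times_fs,
                                shift_window_cm1 = NULL,
                                setup = detection_setup(), pad = 8,
                                channels = NULL, seed = NULL) {
  omega_I <- pulse$omega
  if (is.null(shift_window_cm1)) {
    emax <- max(model$energy[model$surface == "g"])
    shift_window_cm1 <- c(-300, au_to_cm1(emax) + 500)
  }
  omega_window <- omega_I - rev(cm1_to_au(shift_window_cm1))
  if (omega_window[1] < 0) omega_window[1] <- 0
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (!is.null(channels)) {
    if (is.null(seed)) stop("scattering_spectrum: SSE realization needs a seed")
    set.seed(seed)
    dir_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  }
  maps <- lapply(1:3, function(k) {
    p <- with_polarization(pulse, dirs[[k]])
    tr <- if (is.null(channels))
      propagate_first_order(model, p, grid)
    else
      propagate_sse(model, p, grid, channels, seed = dir_seeds[k])
    second_order_map(tr, model, observation_times_fs, omega_window, pad = pad)
  })
  cross_section(combine_setup(maps, setup), pulse, omega_I = omega_I)
}

#' Ensemble-averaged SSE scattering spectrum
#'
#' Runs `n_traj` independent quantum-jump realizations of
#' [scattering_spectrum()] and averages the resulting cross-sections
#' (the trajectory average that converges to the Lindblad result).
#'
#' @inheritParams scattering_spectrum
#' @param n_traj number of trajectories.
#' @param seed master seed (per-trajectory seeds derived deterministically).
#' @return a `spectrum_series` with standard errors.
#' @export
sse_spectrum_ensemble <- function(model, pulse, grid, observation_times_fs,
                                  channels, n_traj, seed,
                                  shift_window_cm1 = NULL,
                                  setup = detection_setup(), pad = 8) {
  if (n_traj < 1) stop("sse_spectrum_ensemble: n_traj must be >= 1")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_traj)
  spectra <- lapply(seeds, function(s)
    scattering_spectrum(model, pulse, grid, observation_times_fs,
                        shift_window_cm1 = shift_window_cm1, setup = setup,
                        pad = pad, channels = channels, seed = s))
  average_spectra(spectra)
}
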