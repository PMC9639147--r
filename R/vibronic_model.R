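# Vibronic model: two Born-Oppenheimer electronic surfaces dressed with
# harmonic vibrational levels, and the Franck-Condon / Herzberg-Teller
# transition dipole matrix between them.

.MAX_FC_QUANTA <- 120L

#' Define a normal mode
#'
#' A harmonic normal mode shared by the two electronic surfaces, with
#' possibly different frequencies on each surface and a dimensionless
#' displacement `d` between the surface minima along the mode.  The
#' Huang-Rhys factor of the mode is `S = d^2 / 2`.
#'
#' Dimensionless coordinates are referenced to the ground-surface
#' oscillator: `Q = sqrt(omega_g) x` with `hbar = m = 1`.
#'
#' @param freq_g ground-surface harmonic frequency.
#' @param freq_e excited-surface harmonic frequency (defaults to `freq_g`).
#' @param displacement dimensionless displacement `d` between the minima.
#' @param unit `"cm-1"` (default) or `"au"` for the input frequencies.
#' @return An object of class `normal_mode` (frequencies stored in hartree).
#' @export
normal_mode <- function(freq_g, freq_e = freq_g, displacement = 0,
                        unit = c("cm-1", "au")) {
  unit <- match.arg(unit)
  if (unit == "cm-1") {
    freq_g <- cm1_to_au(freq_g)
    freq_e <- cm1_to_au(freq_e)
  }
  if (!is.finite(freq_g) || !is.finite(freq_e) || freq_g <= 0 || freq_e <= 0)
    stop("normal_mode: frequencies must be strictly positive and finite")
  if (!is.finite(displacement))
    stop("normal_mode: displacement must be finite")
  structure(list(freq_g = freq_g, freq_e = freq_e,
                 displacement = displacement),
            class = "normal_mode")
}

# Overlap table <m_e | n_g> for a pair of displaced, possibly distorted
# harmonic oscillators, by the two ladder-operator recursions (exact for
# harmonic states).  Rows: excited quanta 0..max_e; cols: ground 0..max_g.
fc_mode_table <- function(mode, max_e, max_g) {
  if (max_e < 0 || max_g < 0) stop("fc_mode_table: quanta must be >= 0")
  if (max_e > .MAX_FC_QUANTA || max_g > .MAX_FC_QUANTA)
    stop("fc_mode_table: requested quanta exceed the implemented recursion depth (",
         .MAX_FC_QUANTA, ")")
  wg <- mode$freq_g; we <- mode$freq_e
  X  <- mode$displacement / sqrt(wg)   # cartesian-like displacement, x units
  r  <- sqrt(wg / we)
  I  <- matrix(0, max_e + 1L, max_g + 1L)
  I[1, 1] <- sqrt(2 * sqrt(wg * we) / (wg + we)) *
    exp(-wg * we * X^2 / (2 * (wg + we)))
  # row m = 0, stepping n up (terms in sqrt(m) vanish):
  #   I(m, n+1) = [ sqrt(m) I(m-1,n) + sqrt(we/2) X I(m,n)
  #                 - (1/2)(1/r - r) sqrt(n) I(m,n-1) ] / ((1/2)(1/r+r) sqrt(n+1))
  cu <- 0.5 * (1 / r + r)
  cd <- 0.5 * (1 / r - r)
  if (max_g >= 1) {
    for (n in 0:(max_g - 1L)) {
      lower <- if (n >= 1) cd * sqrt(n) * I[1, n] else 0
      I[1, n + 2L] <- (sqrt(we / 2) * X * I[1, n + 1L] - lower) /
        (cu * sqrt(n + 1))
    }
  }
  # step m up for every n:
  #   I(m+1, n) = [ sqrt(n) I(m,n-1) - sqrt(wg/2) X I(m,n)
  #                 - (1/2)(r - 1/r) sqrt(m) I(m-1,n) ] / ((1/2)(r+1/r) sqrt(m+1))
  if (max_e >= 1) {
    for (m in 0:(max_e - 1L)) {
      for (n in 0:max_g) {
        t1 <- if (n >= 1) sqrt(n) * I[m + 1L, n] else 0
        t3 <- if (m >= 1) -cd * sqrt(m) * I[m, n + 1L] else 0
        I[m + 2L, n + 1L] <- (t1 - sqrt(wg / 2) * X * I[m + 1L, n + 1L] - t3) /
          (cu * sqrt(m + 1))
      }
    }
  }
  I
}

#' Franck-Condon and Herzberg-Teller one-mode integrals
#'
#' `fc_integral` returns the overlap `<v_e | v_g>` of the harmonic
#' vibrational states of the two surfaces along one mode (displaced and,
#' if the two frequencies differ, distorted).  `ht_integral` returns the
#' matrix element `<v_e | Q | v_g>` of the dimensionless ground-surface
#' normal coordinate, obtained by the ladder decomposition
#' `Q |n> = (sqrt(n) |n-1> + sqrt(n+1) |n+1>) / sqrt(2)` so that it reuses
#' the overlap recursion and is exact for harmonic states.
#'
#' @param mode a [normal_mode()].
#' @param v_g,v_e vibrational quanta (non-negative integers) on the ground
#'   and excited surface.
#' @return a real scalar.
#' @export
fc_integral <- function(mode, v_g, v_e) {
  if (v_g < 0 || v_e < 0) stop("fc_integral: quanta must be >= 0")
  fc_mode_table(mode, v_e, v_g)[v_e + 1L, v_g + 1L]
}

#' @rdname fc_integral
#' @export
ht_integral <- function(mode, v_g, v_e) {
  if (v_g < 0 || v_e < 0) stop("ht_integral: quanta must be >= 0")
  I <- fc_mode_table(mode, v_e, v_g + 1L)
  lower <- if (v_g >= 1) sqrt(v_g) * I[v_e + 1L, v_g] else 0
  (lower + sqrt(v_g + 1) * I[v_e + 1L, v_g + 2L]) / sqrt(2)
}

#' Enumerate the vibronic basis of one surface
#'
#' Returns the quanta vectors of all vibrational states with total quanta
#' up to `max_quanta`.  The default truncation (`max_quanta = 1`) is the
#' zero-quanta state plus one single-quantum fundamental per mode, so
#' `n_modes + 1` states per surface.  Ordering is deterministic: the zero
#' state first, then states of increasing total quanta in mode-index order.
#'
#' @param modes list of [normal_mode()] objects (may be empty).
#' @param max_quanta maximum total number of quanta per state (>= 1 for the
#'   default truncation; larger values are used for sum-rule checks).
#' @return integer matrix with one row per state and one column per mode.
#' @export
build_basis <- function(modes, max_quanta = 1L) {
  if (max_quanta < 0) stop("build_basis: max_quanta must be >= 0")
  n <- length(modes)
  if (n == 0L) return(matrix(0L, 1L, 0L))
  acc <- list(rep(0L, n))
  prev <- list(rep(0L, n))
  total <- 1L
  while (total <= max_quanta) {
    nxt <- list()
    for (v in prev) {
      # add one quantum to mode k >= last incremented mode, lexicographic
      last <- if (sum(v) == 0L) 1L else max(which(v > 0L))
      for (k in last:n) {
        w <- v
        w[k] <- w[k] + 1L
        nxt[[length(nxt) + 1L]] <- w
      }
    }
    nxt <- unique(nxt)
    acc <- c(acc, nxt)
    prev <- nxt
    total <- total + 1L
  }
  do.call(rbind, acc)
}

#' Construct a vibronic model
#'
#' Assembles the full model: two electronic surfaces (`g`, `e`) dressed
#' with the vibrational basis of [build_basis()], state energies referenced
#' so the global ground vibronic state has energy exactly zero, and the
#' transition dipole matrix of [assemble_dipoles()].  Transition dipoles
#' between states of the same surface are identically zero.
#'
#' @param modes list of [normal_mode()] objects.
#' @param gap adiabatic electronic energy gap between the surface origins.
#' @param mu0 electronic transition dipole 3-vector at the equilibrium
#'   geometry (atomic units).
#' @param dmu `3 x n_modes` matrix of transition-dipole derivatives with
#'   respect to the dimensionless normal coordinates (Herzberg-Teller
#'   terms); defaults to all zero.
#' @param gap_unit `"eV"` (default) or `"au"`.
#' @param max_quanta total-quanta truncation of the basis per surface.
#' @param fc_table,ht_table optional externally computed integral tables
#'   overriding the analytic per-mode computation: `fc_table` is an
#'   `n_e x n_g` matrix of multi-mode overlaps `<v_e|v_g>` and `ht_table`
#'   an `n_e x n_g x n_modes` array of `<v_e|Q_k|v_g>` elements, indexed by
#'   the basis ordering of this constructor (used to import e.g.
#'   Duschinsky-mixed adiabatic-Hessian integrals).
#' @return An object of class `vibronic_model`.
#' @export
vibronic_model <- function(modes, gap, mu0, dmu = NULL,
                           gap_unit = c("eV", "au"), max_quanta = 1L,
                           fc_table = NULL, ht_table = NULL) {
  gap_unit <- match.arg(gap_unit)
  if (gap_unit == "eV") gap <- ev_to_au(gap)
  if (!is.finite(gap) || gap <= 0)
    stop("vibronic_model: excited origin must lie above the ground origin")
  n <- length(modes)
  if (is.null(dmu)) dmu <- matrix(0, 3, max(n, 0L))
  dmu <- as.matrix(dmu)
  if (n > 0 && (nrow(dmu) != 3L || ncol(dmu) != n))
    stop("vibronic_model: dmu must be a 3 x n_modes matrix ",
         "(dimension mismatch between modes and derivative list)")
  mu0 <- as.numeric(mu0)
  if (length(mu0) != 3L || any(!is.finite(mu0)))
    stop("vibronic_model: mu0 must be a finite 3-vector")
  if (any(!is.finite(dmu)))
    stop("vibronic_model: dmu must be finite")

  quanta <- build_basis(modes, max_quanta)
  ns <- nrow(quanta)
  wg <- vapply(modes, `[[`, numeric(1), "freq_g")
  we <- vapply(modes, `[[`, numeric(1), "freq_e")
  zpe_shift <- if (n > 0) sum(we - wg) / 2 else 0
  e_g <- as.numeric(quanta %*% wg)
  e_e <- gap + zpe_shift + as.numeric(quanta %*% we)

  model <- structure(list(
    modes = modes, n_modes = n, gap = gap,
    quanta = quanta, n_per_surface = ns,
    surface = rep(c("g", "e"), each = ns),
    energy = c(e_g, e_e),
    state_quanta = rbind(quanta, quanta),
    mu0 = mu0, dmu = dmu,
    fc_table = fc_table, ht_table = ht_table
  ), class = "vibronic_model")
  assemble_dipoles(model)
}

#' Assemble the vibronic transition dipole matrix
#'
#' Fills the 3-component dipole matrix on the vibronic basis:
#' the element between an excited-surface state `|v_e>` and a
#' ground-surface state `|v_g>` is
#' `mu0 * prod_k <v_e,k|v_g,k>` plus the Herzberg-Teller sum
#' `sum_k dmu_k * <v_e,k|Q_k|v_g,k> * prod_{j != k} <v_e,j|v_g,j>`.
#' Same-surface elements are identically zero and the matrix is symmetric.
#' If the model carries imported `fc_table`/`ht_table` integrals these are
#' used verbatim instead of the analytic per-mode products.
#'
#' @param model a [vibronic_model()].
#' @return the model with a `D` field: a list of three `Nb x Nb` dipole
#'   component matrices (x, y, z).
#' @export
assemble_dipoles <- function(model) {
  ns <- model$n_per_surface
  n  <- model$n_modes
  quanta <- model$quanta
  maxq <- if (n > 0) max(quanta) else 0L

  if (is.null(model$fc_table)) {
    # per-mode overlap and Q-element tables (HT needs ground quanta + 1)
    fc <- lapply(model$modes, fc_mode_table, max_e = maxq, max_g = maxq + 1L)
    ht <- vector("list", n)
    for (k in seq_len(n)) {
      I <- fc[[k]]
      tab <- matrix(0, maxq + 1L, maxq + 1L)
      for (m in 0:maxq) for (ng in 0:maxq) {
        lower <- if (ng >= 1) sqrt(ng) * I[m + 1L, ng] else 0
        tab[m + 1L, ng + 1L] <- (lower + sqrt(ng + 1) * I[m + 1L, ng + 2L]) / sqrt(2)
      }
      ht[[k]] <- tab
    }
    FC <- matrix(1, ns, ns)   # [e_state, g_state] multi-mode overlap
    HT <- array(0, c(ns, ns, max(n, 1L)))
    for (a in seq_len(ns)) for (b in seq_len(ns)) {
      if (n == 0) next
      f <- vapply(seq_len(n), function(k)
        fc[[k]][quanta[a, k] + 1L, quanta[b, k] + 1L], numeric(1))
      FC[a, b] <- prod(f)
      for (k in seq_len(n)) {
        others <- if (n > 1) prod(f[-k]) else 1
        HT[a, b, k] <- ht[[k]][quanta[a, k] + 1L, quanta[b, k] + 1L] * others
      }
    }
  } else {
    FC <- model$fc_table
    if (!all(dim(FC) == c(ns, ns)))
      stop("assemble_dipoles: imported fc_table has wrong dimensions")
    HT <- model$ht_table
    if (is.null(HT)) HT <- array(0, c(ns, ns, max(n, 1L)))
    if (!all(dim(HT)[1:2] == c(ns, ns)) || (n > 0 && dim(HT)[3] != n))
      stop("assemble_dipoles: imported ht_table has wrong dimensions")
  }

  Nb <- 2L * ns
  D <- lapply(1:3, function(a) matrix(0, Nb, Nb))
  for (a in 1:3) {
    blk <- model$mu0[a] * FC
    for (k in seq_len(n)) blk <- blk + model$dmu[a, k] * HT[, , k]
    # rows: excited states (indices ns+1..2ns), cols: ground (1..ns)
    D[[a]][ns + seq_len(ns), seq_len(ns)] <- blk
    D[[a]][seq_len(ns), ns + seq_len(ns)] <- t(blk)
  }
  model$D <- D
  model
}

#' Keep a subset of vibronic basis states
#'
#' Truncates the model to the selected basis states (indices into the full
#' basis, ground block first).  Useful for building small few-state test
#' systems.  The global energy reference is kept.
#'
#' @param model a [vibronic_model()].
#' @param keep integer indices of states to keep.
#' @return the truncated model.
#' @export
subset_states <- function(model, keep) {
  keep <- sort(unique(as.integer(keep)))
  if (any(keep < 1L | keep > length(model$energy)))
    stop("subset_states: index out of range")
  model$surface <- model$surface[keep]
  model$energy <- model$energy[keep]
  model$state_quanta <- model$state_quanta[keep, , drop = FALSE]
  model$D <- lapply(model$D, function(m) m[keep, keep, drop = FALSE])
  model$subset <- keep
  model
}

#' Generate a synthetic vibronic model
#'
#' Draws a random but reproducible model molecule: mode frequencies uniform
#' in a range, Huang-Rhys factors uniform in a range (displacement
#' `d = sqrt(2 S)`), mild excited-surface frequency changes, a transition
#' dipole of given magnitude with a random orientation, and random
#' Herzberg-Teller derivative vectors.  Defaults emulate a porphyrin-like
#' chromophore: visible electronic gap, mid-infrared skeletal modes, weak
#' electron-phonon coupling and a transition dipole of order 1 a.u.
#'
#' @param n_modes number of normal modes.
#' @param freq_range_cm1 range of ground-surface frequencies (cm^-1).
#' @param huang_rhys_range range of Huang-Rhys factors S.
#' @param freq_change_range range of excited/ground frequency ratios.
#' @param gap_eV adiabatic electronic gap (eV).
#' @param mu0_norm magnitude of the equilibrium transition dipole (a.u.).
#' @param dmu_norm magnitude of each Herzberg-Teller derivative vector
#'   (a.u. per dimensionless coordinate).
#' @param max_quanta basis truncation (see [build_basis()]).
#' @param seed integer seed; the same seed yields the identical model.
#' @return A [vibronic_model()].
#' @export
synthesize_model <- function(n_modes = 2,
                             freq_range_cm1 = c(150, 1600),
                             huang_rhys_range = c(0.005, 0.05),
                             freq_change_range = c(0.97, 1.03),
                             gap_eV = 2.28,
                             mu0_norm = 1.0,
                             dmu_norm = 0.05,
                             max_quanta = 1L,
                             seed = 1L) {
  chk <- function(r, what) {
    if (length(r) != 2L || any(!is.finite(r)) || r[2] < r[1] || r[2] <= 0)
      stop("synthesize_model: empty or invalid ", what, " range")
  }
  chk(freq_range_cm1, "frequency")
  chk(huang_rhys_range, "Huang-Rhys")
  chk(freq_change_range, "frequency-change")
  if (n_modes < 0) stop("synthesize_model: n_modes must be >= 0")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  wg <- sort(stats::runif(n_modes, freq_range_cm1[1], freq_range_cm1[2]))
  ratio <- stats::runif(n_modes, freq_change_range[1], freq_change_range[2])
  S <- stats::runif(n_modes, huang_rhys_range[1], huang_rhys_range[2])
  modes <- lapply(seq_len(n_modes), function(k)
    normal_mode(wg[k], wg[k] * ratio[k], sqrt(2 * S[k]), unit = "cm-1"))

  rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  mu0 <- mu0_norm * rand_unit()
  dmu <- if (n_modes > 0)
    vapply(seq_len(n_modes), function(k) dmu_norm * rand_unit(), numeric(3))
  else matrix(0, 3, 0)
  dmu <- matrix(dmu, nrow = 3)

  vibronic_model(modes, gap = gap_eV, mu0 = mu0, dmu = dmu,
                 max_quanta = max_quanta)
}

#' @export
print.vibronic_model <- function(x, ...) {
  cat("<vibronic_model>\n")
  cat("  modes:", x$n_modes,
      if (x$n_modes > 0)
        paste0("(", paste(sprintf("%.0f", au_to_cm1(
          vapply(x$modes, `[[`, numeric(1), "freq_g"))), collapse = ", "),
          " cm-1)") else "", "\n")
  cat("  states:", length(x$energy),
      sprintf("(adiabatic gap %.3f eV, 0-0 line %.3f eV)\n",
              x$gap * au$hartree_eV,
              (x$energy[match("e", x$surface)]) * au$hartree_eV))
  invisible(x)
}

# Energy of the excited-surface vibronic origin (the 0-0 line), a.u.
#' Energy of the excited-surface vibronic origin (0-0 transition), hartree
#' @param model a [vibronic_model()].
#' @export
origin_energy <- function(model) {
  model$energy[match("e", model$surface)]
}
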