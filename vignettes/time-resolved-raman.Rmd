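---
title: "Time-resolved spontaneous Raman and fluorescence from vibronic wavepacket dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved spontaneous Raman and fluorescence from vibronic wavepacket dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`tdraman` simulates spontaneous Raman scattering and fluorescence of a
molecule in the time domain.  The molecule is described by two
Born-Oppenheimer electronic surfaces, ground `g` and excited `e`, each
dressed with harmonic vibrational levels.  In the default truncation each
surface carries the zero-quanta vibronic state plus one single-quantum
fundamental per normal mode, i.e. `n_modes + 1` states per surface; higher
quanta can be requested (`max_quanta`) for convergence checks such as the
Franck-Condon sum rule.  Energies are stored in hartree and re-referenced
so that the global ground vibronic state sits at exactly zero; this fixes
the otherwise arbitrary phase convention of the propagation.

Light-matter coupling enters through the vibronic transition dipole
matrix.  For an excited-surface state `|v_e>` and a ground-surface state
`|v_g>`,

```
mu(v_e, v_g) = mu0 * prod_k <v_e,k | v_g,k>
             + sum_k (dmu/dQ_k) <v_e,k | Q_k | v_g,k> prod_{j!=k} <v_e,j | v_g,j>
```

the first term being the Franck-Condon (FC) contribution of the
equilibrium electronic dipole `mu0` and the second the Herzberg-Teller
(HT) correction, linear in the dimensionless normal coordinates.  Dipole
elements between states of the same surface are identically zero (no IR
transitions), and the matrix is real symmetric.

The one-dimensional overlaps `<m_e|n_g>` of displaced (and possibly
frequency-changed) harmonic oscillators are evaluated analytically with
two ladder-operator recursions seeded by the closed-form `<0|0>` overlap;
`<m_e|Q|n_g>` follows from the ladder decomposition
`Q|n> = (sqrt(n)|n-1> + sqrt(n+1)|n+1>)/sqrt(2)`.  Both are exact for
harmonic states; the test suite checks them against direct numerical
quadrature of the wavefunction products to 1e-10 and the assembled
two-mode dipole elements against brute-force 2-D quadrature to 1e-8.
Multi-mode integrals are per-mode products (parallel-mode approximation).
Duschinsky-mixed integrals computed by external vibronic codes can be
imported verbatim through the `[fc_table]`/`[ht_table]` sections of the
model file; imported HT integrals must follow the same convention used
here, i.e. derivatives along the *ground-surface* dimensionless normal
coordinates (`hbar = m = omega_g` absorbed), since the producing code's
choice of coordinates is not otherwise detectable.

## Conventions

* Units: atomic units internally; inputs in cm^-1 (frequencies), eV
  (electronic energies, carriers), fs (times), V/m or a.u. (fields), with
  1 hartree = 27.2114 eV, 1 a.u. time = 0.02418884 fs, 1 a.u. field =
  5.142e11 V/m.  The benchmark amplitude 5.14e5 V/m is thus ~1e-6 a.u.,
  deep in the perturbative regime.
* The Gaussian pulse is
  `eps0 exp(-(t-t0)^2/(2 sigma^2)) cos(omega (t-t0) + phase)`; the carrier
  phase at the envelope centre is zero by default (peak field at `t0`) and
  exposed as a parameter.  For envelopes much longer than the optical
  period the Raman observables are phase-insensitive, which the suite
  verifies to 1e-4.
* Fluence is `F = (c/4 pi) * int eps(t)^2 dt` (Gaussian electromagnetic
  conventions; the carrier's `cos^2` supplies the cycle-average 1/2 inside
  the integral).  For `omega sigma >> 1` the integral equals
  `eps0^2 sigma sqrt(pi)/2`.

## Propagation

The coefficients of the vibronic expansion are advanced with the
two-step second-order Euler scheme

```
c(t + dt) = c(t - dt) - 2 i dt [H0 + V(t)] c(t)
```

started with a single midpoint (RK2) step.  The exact finite-difference
stencil of this family is not uniquely fixed by its name; the two-step
(leapfrog) form was chosen because it is the standard member used with
real-time coefficient propagation, it is strictly norm-stable for
`|E_max| dt < 1`, and its measured convergence order is verified to be
2.0 in the suite.  Coefficients carry full phases `exp(-i E_J t)` (no
rotating frame, no interaction picture) because the scattered-field
Fourier stage needs absolute phases.

Two numerical properties of the stencil matter in practice:

* **Stability**: the scheme is unstable for `|E_max| dt >= 1`;
  propagators refuse such grids.
* **Dispersion**: a state of energy `E` effectively oscillates at
  `E (1 + (E dt)^2 / 6)`.  At the default `dt = 0.024 fs` (~1 a.u.) and
  visible energies (~0.084 hartree) the shift is ~1e-4 hartree.  This is
  negligible against nonresonant detunings (~0.01 hartree) but matters in
  two situations: (i) exactly resonant narrow-band driving, where the
  pulse bandwidth `1/sigma` can be comparable to the shift - resonant
  runs therefore use `dt = 0.25 a.u.` or less so that
  `sigma * E^3 dt^2 / 6 << 1`; and (ii) comparisons against the RK4
  Lindblad oracle, which carries different (much smaller) dispersion.

The default time step 0.024 fs, pulse widths 256/496-512 fs, centre
968 fs, amplitude 5.14e5 V/m, carrier 2.04 eV (nonresonant, 0.24 eV below
the 0-0 line) or on the 0-0 line (resonant), vibrational lifetime 1.8 ps
and 50-trajectory ensembles are the reference study conditions of the
simulator; the test suite and the acceptance script run them unchanged on
few-mode synthetic chromophores (see below), with run lengths of
2.4-4.8 ps (1e5-8e5 steps).

## Vibrational relaxation: quantum jumps and the Lindblad oracle

Relaxation of the vibronic fundamentals toward the lowest level of their
own surface is modelled with a Markovian stochastic Schroedinger equation
realized by the quantum-jump algorithm.  Each step applies (a) the
deterministic two-step evolution with exact per-step amplitude damping
`exp(-Gamma_q dt/2)` on each decaying state - with the damping of the
two-step history handled consistently,
`c(t+dt) = e^{-2 D dt} c(t-dt) - 2 i dt e^{-D dt} H(t) c(t)`, which keeps
the scheme's parasitic mode damped - and (b) a Monte-Carlo jump drawn
with probability `p_q = Gamma_q |c_q|^2 dt / ||c||^2` per channel; on a
jump the wave function collapses onto the pure target state (the
normalized jump-operator image) and the integrator restarts.  The
no-jump evolution runs *unnormalized*; the physical (normalized) state is
taken at storage time.  An earlier variant that renormalized every step
was rejected because forcing the single-slice norm to one corrupts the
two-step solution at O((E dt)^2) per step and biases the ensemble;
with the present scheme a 200-trajectory ensemble agrees with the dense
RK4 Lindblad propagator within 3 standard errors (plus a <=5e-3
discretization allowance where the ensemble variance vanishes), the
field-free ensemble survival reproduces `exp(-Gamma t)`, and the
jump-time distribution passes a Kolmogorov-Smirnov test against the
exponential law.

Whether ground-surface fundamentals also relax is configurable
(`surfaces = "both"` by default, or `"excited"`/`"ground"`): in the
nonresonant weak-field regime the choice is immaterial because
ground-surface fundamentals hold no first-order population, and the
suite verifies that relaxation leaves the nonresonant Stokes integral
unchanged to well below 0.5%.

Ensembles derive per-trajectory seeds (and, inside each trajectory, one
seed per incident-field direction) deterministically from a master seed,
so runs are reproducible and order-independent.

## From trajectories to spectra

For every ground-surface final state `N`, scattered polarization
`lambda` and incident polarization `eta`, the cumulative scattered-field
coefficient is the windowed Fourier transform of the first-order
trajectory,

```
B_N^{lambda eta}(omega_S, t_obs) =
  dt' * sum_{t' <= t_obs} [sum_J mu_lambda^{NJ} c_J^{(1),eta}(t')]
        exp(i (E_N + omega_S) t')
```

evaluated for all `omega_S` at once by a zero-padded FFT (default padding
x8; frequency resolution `2 pi / (pad * T)`); the Heaviside window is the
truncation of the series at `t_obs`.  The sign of `omega_S` in the
exponent is fixed operationally by requiring Stokes lines at
`omega_I - omega_k`, which the suite asserts to within one grid element.
Only excited-surface intermediates contribute because the dipole matrix
has no same-surface elements.

The nine `(lambda, eta)` components form a 3x3 tensor per
`(N, omega_S, t_obs)` that transforms under molecular rotations like the
polarizability tensor.  The isotropic orientational average of the
detected intensity is therefore a fixed combination of its rotational
invariants; for the default geometry (linear incident polarization
perpendicular to the detection direction, unpolarized detection) the
weights are `1/9` on `|Tr B|^2`, `1/6` on the antisymmetric norm and
`7/30` on the symmetric-traceless norm - the classic `45a^2 + 7gamma^2`
rule extended to complex, possibly antisymmetric tensors.  They are
validated against a brute-force Monte-Carlo rotation average (1e5
uniform orientations, stratified over the octahedral subgroup) to 0.5%.

The cumulative cross-section per unit scattered frequency and solid
angle is

```
sigma(omega_S; t_obs) = omega_I omega_S^3 / (4 pi^2 c^3)
                        * sum_N P_N(omega_S, t_obs) / F
```

The density-of-states and scattered-field-amplitude substitutions behind
the prefactor are not independently observable; their product is fixed,
together with the fluence convention, by requiring the quasi-CW limit to
reproduce the Kramers-Heisenberg-Dirac (KHD) spontaneous-Raman
differential cross-section with its `omega_I omega_S^3 / c^4` frequency
dependence.  The package ships the resonant-term KHD sum over states as
an independent oracle, and the suite checks per-line agreement of the
time-domain pipeline with it to 5% (2% observed, dominated by integrator
dispersion on the detuning).

In resonance, Raman and fluorescence both emerge from the same
second-order coefficients and overlap spectrally; no attempt is made to
decompose them.  The qualitative signatures are verified instead: in
nonresonance the cumulative band integral plateaus once the pulse is
over and is invariant (to 1%) to doubling the pulse width at fixed
amplitude, while in resonance it keeps growing after the pulse peak and
a doubled pulse width roughly quadruples the late-time signal
(excited-state population scales with the pulse area squared).

## The synthetic chromophores

The generator (`synthesize_model`) draws porphyrin-like model molecules:
a visible electronic gap (default 2.28 eV), mid-infrared skeletal modes
(150-1600 cm^-1), weak electron-phonon coupling (Huang-Rhys factors
0.005-0.05, displacements `d = sqrt(2S)`), mild excited-surface frequency
changes (+-3%), a transition dipole of order 1 a.u. with random
orientation and HT derivatives of order 0.05 a.u.  These values are
typical of rigid aromatic chromophores.  Fixed two- and one-mode
instances (modes at 800 and 1400 cm^-1) are used for the
reference-condition runs so that band integrals are well separated from
the Rayleigh line.

What the generator deliberately does **not** emulate: Duschinsky
rotation between surfaces (import real vibronic data for that),
anharmonicity, more than one excited electronic state, thermally
populated initial states (hence no anti-Stokes), electronic/radiative
decay and pure dephasing.  Passing tests on these models therefore
validate the dynamics, the scattered-field bookkeeping and the
statistics of the relaxation model - not the spectroscopic accuracy of
any particular real molecule.

## Degenerate and edge inputs

* Zero field: the ground state is stationary and every scattered channel
  is identically zero.
* Zero-amplitude pulses have zero fluence; the cross-section is
  undefined and requested as an error.
* Empty mode lists give a clean two-level system (used for the Rabi and
  convergence checks).
* Tabulated pulses are zero outside their grid; non-finite field values
  are rejected.
* Observation times are snapped to the stored grid and refused beyond
  the run.

## Known limitations

* The resonant-term-only two-photon amplitude limits quantitative
  accuracy far below resonance (long-wavelength excitation), as does the
  single excited surface.
* The leapfrog dispersion makes exactly-resonant narrow-band runs
  dt-sensitive (see above); halving dt quarters the effect.
* Trajectory archives are plain CSV (small runs) rather than a binary
  container, keeping the package free of compiled I/O dependencies.
* The cumulative signal before the pulse has fully decayed contains the
  finite-window sinc broadening of any persistent amplitude; linewidths
  shrink as `1/t_obs` until the process is exhausted.
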