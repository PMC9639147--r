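Package: tdraman
Title: Time-Resolved Spontaneous Raman and Fluorescence from Vibronic
    Wavepacket Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates time-resolved spontaneous Raman scattering and
    fluorescence of molecules in the time domain.  A vibronic wave function
    (two Born-Oppenheimer electronic surfaces dressed with harmonic
    vibrational levels, Franck-Condon and Herzberg-Teller transition
    dipoles) is propagated in real time under an arbitrary laser pulse with
    a second-order Euler integrator.  Second-order (scattered-field)
    coefficients are accumulated by a windowed fast Fourier transform,
    combined into rotational invariants for an isotropic orientational
    average, and turned into a cumulative time-dependent scattering
    cross-section.  Vibrational relaxation is treated with the stochastic
    Schroedinger equation (quantum-jump trajectories); a dense Lindblad
    master-equation propagator and a Kramers-Heisenberg-Dirac
    sum-over-states polarizability serve as built-in independent
    cross-checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
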