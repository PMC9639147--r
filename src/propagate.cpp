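// Real-time propagation cores: second-order Euler (leapfrog) integration of
// the vibronic coefficients under H0 + V(t), the stochastic Schroedinger
// equation with quantum jumps, and a dense Lindblad RK4 propagator used as
// an independent oracle.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

// H(t) c = E % c + eps * (M c), M real, column-major.
static inline void apply_h(const double* E, const double* M, double eps,
                           const cplx* c, cplx* h, int n) {
  for (int i = 0; i < n; ++i) h[i] = E[i] * c[i];
  if (eps != 0.0) {
    for (int j = 0; j < n; ++j) {
      const cplx cj = eps * c[j];
      if (cj == cplx(0.0, 0.0)) continue;
      const double* col = M + (size_t)n * j;
      for (int i = 0; i < n; ++i) h[i] += col[i] * cj;
    }
  }
}

// One RK2 (midpoint) step from c at time index n to n+1; used to start and
// to restart the two-step scheme after a quantum jump.
static inline void rk2_step(const double* E, const double* M,
                            double f0, double f1, double dt,
                            const cplx* c, cplx* out, cplx* tmp, int n) {
  const cplx mi(0.0, -1.0);
  apply_h(E, M, f0, c, out, n);                 // out = H(t0) c
  for (int i = 0; i < n; ++i) tmp[i] = c[i] + (dt / 2.0) * mi * out[i];
  apply_h(E, M, 0.5 * (f0 + f1), tmp, out, n);  // out = H(t_half) c_half
  for (int i = 0; i < n; ++i) out[i] = c[i] + dt * mi * out[i];
}

// [[Rcpp::export]]
List cpp_propagate(NumericVector energies, NumericMatrix M,
                   NumericVector field, double dt, int stride,
                   ComplexVector c0,
                   IntegerVector src, IntegerVector tgt, NumericVector rates,
                   bool stochastic, double jump_tol) {
  const int n = energies.size();
  const int nsteps = field.size() - 1;   // field sampled at t_m = m * dt
  const int nchan = src.size();
  if (M.nrow() != n || M.ncol() != n) stop("cpp_propagate: M dimension mismatch");
  if (c0.size() != n) stop("cpp_propagate: c0 dimension mismatch");

  const double* E = REAL(energies);
  const double* Mp = REAL(M);
  const double* F = REAL(field);

  std::vector<cplx> cur(n), prev(n), nxt(n), tmp(n);
  for (int i = 0; i < n; ++i)
    cur[i] = cplx(COMPLEX(c0)[i].r, COMPLEX(c0)[i].i);

  // per-step amplitude damping factors for the no-jump SSE evolution
  std::vector<double> damp(nchan);
  for (int q = 0; q < nchan; ++q) damp[q] = std::exp(-0.5 * rates[q] * dt);

  bool any_decay = false;
  for (int q = 0; q < nchan; ++q) if (rates[q] > 0.0) any_decay = true;

  const int nstored = nsteps / stride + 1;
  ComplexMatrix coefs(n, nstored);
  NumericVector times(nstored);
  std::vector<double> jtimes;
  std::vector<int> jchan;
  double norm_drift = 0.0;

  // The no-jump evolution runs unnormalized (leapfrog for H(t), exact
  // exponential amplitude damping per step); the physical state is the
  // normalized vector, so coefficients are normalized at storage time only.
  int istore = 0;
  auto store = [&](int step, const std::vector<cplx>& c) {
    if (step % stride == 0 && istore < nstored) {
      times[istore] = step * dt;
      double s = 1.0;
      if (any_decay) {
        double nrm = 0.0;
        for (int i = 0; i < n; ++i) nrm += std::norm(c[i]);
        s = 1.0 / std::sqrt(nrm);
      }
      for (int i = 0; i < n; ++i) {
        coefs(i, istore).r = s * c[i].real();
        coefs(i, istore).i = s * c[i].imag();
      }
      ++istore;
    }
  };

  // Quantum-jump bookkeeping on the freshly advanced vector `c`: damp the
  // decaying amplitudes, draw a jump with probability
  // Gamma_q |c_src|^2 dt / ||c||^2, and on a jump collapse onto the pure
  // target state (the normalized jump-operator image).  Returns true if a
  // jump occurred (the two-step scheme is then restarted).
  auto sse_update = [&](std::vector<cplx>& c, int step) -> bool {
    for (int q = 0; q < nchan; ++q) c[src[q]] *= damp[q];
    double nrm2 = 0.0;
    for (int i = 0; i < n; ++i) nrm2 += std::norm(c[i]);
    double ptot = 0.0;
    for (int q = 0; q < nchan; ++q)
      ptot += rates[q] * std::norm(c[src[q]]) * dt / nrm2;
    if (ptot > jump_tol)
      stop("propagate_sse: total jump probability per step exceeds %f; reduce dt",
           jump_tol);
    if (ptot > 0.0 && unif_rand() < ptot) {
      double u = unif_rand() * ptot, acc = 0.0;
      int pick = nchan - 1;
      for (int q = 0; q < nchan; ++q) {
        acc += rates[q] * std::norm(c[src[q]]) * dt / nrm2;
        if (u <= acc) { pick = q; break; }
      }
      std::fill(c.begin(), c.end(), cplx(0.0, 0.0));
      c[tgt[pick]] = cplx(1.0, 0.0);
      jtimes.push_back(step * dt);
      jchan.push_back(pick + 1);
      return true;
    }
    return false;
  };

  store(0, cur);
  bool restart = true;
  int step = 0;
  while (step < nsteps) {
    if (restart) {
      rk2_step(E, Mp, F[step], F[step + 1], dt, cur.data(), nxt.data(),
               tmp.data(), n);
      restart = false;
    } else {
      // c(t+dt) = c(t-dt) - 2 i dt H(t) c(t); with amplitude damping the
      // history terms carry the decay of their time lag:
      // c(t+dt) = e^{-2 D dt} c(t-dt) - 2 i dt e^{-D dt} H(t) c(t),
      // realized as one extra damping of c(t-dt) here plus the common
      // e^{-D dt} factor applied after the step (sse_update).
      if (stochastic && any_decay)
        for (int q = 0; q < nchan; ++q) prev[src[q]] *= damp[q];
      apply_h(E, Mp, F[step], cur.data(), tmp.data(), n);
      const cplx f(0.0, -2.0 * dt);
      for (int i = 0; i < n; ++i) nxt[i] = prev[i] + f * tmp[i];
    }
    ++step;
    if (stochastic && any_decay) {
      if (sse_update(nxt, step)) restart = true;
    } else {
      double nrm = 0.0;
      for (int i = 0; i < n; ++i) nrm += std::norm(nxt[i]);
      norm_drift = std::max(norm_drift, std::fabs(std::sqrt(nrm) - 1.0));
    }
    prev.swap(cur);
    cur.swap(nxt);
    store(step, cur);
  }

  return List::create(
    _["times"] = times, _["coefs"] = coefs,
    _["jump_times"] = NumericVector(jtimes.begin(), jtimes.end()),
    _["jump_channels"] = IntegerVector(jchan.begin(), jchan.end()),
    _["norm_drift"] = norm_drift);
}

// [[Rcpp::export]]
List cpp_lindblad(arma::vec energies, arma::mat M, arma::vec field,
                  double dt, int stride,
                  arma::ivec src, arma::ivec tgt, arma::vec rates,
                  arma::cx_mat rho0, double trace_tol) {
  const int n = energies.n_elem;
  const int nsteps = field.n_elem - 1;
  const int nchan = src.n_elem;
  const arma::cx_double I(0.0, 1.0);

  arma::mat H0 = arma::diagmat(energies);
  auto deriv = [&](const arma::cx_mat& rho, double eps) -> arma::cx_mat {
    arma::mat H = H0 + eps * M;
    arma::cx_mat d = -I * (H * rho - rho * H);
    for (int q = 0; q < nchan; ++q) {
      const int s = src[q], t = tgt[q];
      const double g = rates[q];
      d(t, t) += g * rho(s, s);
      d.row(s) -= 0.5 * g * rho.row(s);
      d.col(s) -= 0.5 * g * rho.col(s);
    }
    return d;
  };

  const int nstored = nsteps / stride + 1;
  arma::cx_cube out(n, n, nstored);
  arma::vec times(nstored);
  arma::cx_mat rho = rho0;
  int istore = 0;
  for (int step = 0; step <= nsteps; ++step) {
    if (step % stride == 0 && istore < nstored) {
      out.slice(istore) = rho;
      times[istore] = step * dt;
      ++istore;
    }
    if (step == nsteps) break;
    const double f0 = field[step], f1 = field[step + 1];
    const double fh = 0.5 * (f0 + f1);
    arma::cx_mat k1 = deriv(rho, f0);
    arma::cx_mat k2 = deriv(rho + 0.5 * dt * k1, fh);
    arma::cx_mat k3 = deriv(rho + 0.5 * dt * k2, fh);
    arma::cx_mat k4 = deriv(rho + dt * k3, f1);
    rho += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    double tr = std::abs(arma::trace(rho).real() - 1.0);
    if (tr > trace_tol)
      stop("propagate_lindblad: trace drift %g exceeds tolerance; reduce dt", tr);
  }

  return List::create(_["times"] = times, _["rho"] = out);
}
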