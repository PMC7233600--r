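#include <Rcpp.h>
using namespace Rcpp;

// Discrete-map update of coupled Kuramoto populations.
//
// theta0: initial phases (all oscillators, concatenated by population)
// omega:  per-oscillator phase increment per iteration
// pop:    0-based population index per oscillator
// kappa_int: internal all-to-all coupling, applied in mean-field form
//            kappa_int * R_k * sin(psi_k - theta)  (= kappa/N * full sum)
// edges:  matrix with columns (src, tgt, n, m, kappa); each row adds, to
//         every oscillator h of population tgt,
//         kappa * M_src * sin(n * psi_src - m * theta_h)
// n_iter: iterations; the order parameter of each population is recorded at
//         every iteration before the update
//
// All drive terms on a population share its members' phase harmonics
// (m = 1 or 2), so they are folded into one complex coefficient per
// harmonic: sum_e a_e sin(phi_e - m theta) = Im(C_m e^{-i m theta}) with
// C_m = sum_e a_e e^{i phi_e}. The internal mean-field term joins C_1.
// [[Rcpp::export]]
List kuramoto_core(NumericVector theta0, NumericVector omega,
                   IntegerVector pop, int npop, double kappa_int,
                   NumericMatrix edges, int n_iter, bool save_phases) {
  int N = theta0.size();
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<int> popc(pop.begin(), pop.end());
  std::vector<int> npc(npop, 0);
  for (int i = 0; i < N; ++i) npc[popc[i]]++;

  int ne = edges.nrow();
  for (int e = 0; e < ne; ++e) {
    int m = (int)edges(e, 3);
    if (m < 1 || m > 2)
      stop("only target-phase multipliers 1 and 2 are supported");
  }

  NumericMatrix M(npop, n_iter), psi(npop, n_iter);
  NumericMatrix phases;
  if (save_phases) phases = NumericMatrix(N, n_iter);

  std::vector<double> sr(npop), si(npop), R(npop), P(npop);
  // per population: complex drive coefficients for harmonics m = 1, 2
  std::vector<double> c1r(npop), c1i(npop), c2r(npop), c2i(npop);

  for (int t = 0; t < n_iter; ++t) {
    std::fill(sr.begin(), sr.end(), 0.0);
    std::fill(si.begin(), si.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      sr[popc[i]] += std::cos(theta[i]);
      si[popc[i]] += std::sin(theta[i]);
    }
    for (int k = 0; k < npop; ++k) {
      double re = sr[k] / npc[k], im = si[k] / npc[k];
      R[k] = std::sqrt(re * re + im * im);
      P[k] = std::atan2(im, re);
      M(k, t) = R[k];
      psi(k, t) = P[k];
      // internal mean-field term: kappa_int * R_k * sin(psi_k - theta)
      c1r[k] = kappa_int * re;
      c1i[k] = kappa_int * im;
      c2r[k] = 0.0;
      c2i[k] = 0.0;
    }
    for (int e = 0; e < ne; ++e) {
      int src = (int)edges(e, 0), tgt = (int)edges(e, 1);
      double n = edges(e, 2);
      int m = (int)edges(e, 3);
      double a = edges(e, 4) * R[src];
      double phi = n * P[src];
      if (m == 1) {
        c1r[tgt] += a * std::cos(phi);
        c1i[tgt] += a * std::sin(phi);
      } else {
        c2r[tgt] += a * std::cos(phi);
        c2i[tgt] += a * std::sin(phi);
      }
    }
    if (save_phases)
      for (int i = 0; i < N; ++i) phases(i, t) = theta[i];
    for (int i = 0; i < N; ++i) {
      int k = popc[i];
      double s1 = std::sin(theta[i]), co1 = std::cos(theta[i]);
      // Im(C1 e^{-i theta}) = c1i*cos(theta) - c1r*sin(theta)
      double d = omega[i] + c1i[k] * co1 - c1r[k] * s1;
      if (c2r[k] != 0.0 || c2i[k] != 0.0) {
        double s2 = 2.0 * s1 * co1;            // sin(2 theta)
        double co2 = co1 * co1 - s1 * s1;      // cos(2 theta)
        d += c2i[k] * co2 - c2r[k] * s2;
      }
      theta[i] += d;
    }
  }
  List out = List::create(Named("M") = M, Named("psi") = psi);
  if (save_phases) out["phases"] = phases;
  return out;
}
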