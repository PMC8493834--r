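#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form propagation of the factorized gating system over a sequence
// of constant-voltage pieces (steps; ramps and sampled waveforms are
// zero-order-hold subdivided upstream). At fixed voltage the activation
// chain (C1a, Oa) is an affine linear system solved by eigendecomposition
// and the availability gate h relaxes mono-exponentially, so propagation
// is exact; this mirrors the reference R implementation and exists for the
// inference inner loop, where millions of trace evaluations occur.
//
// piece_v:   command voltage per piece (mV)
// piece_dur: duration per piece (ms)
// piece_n:   number of output samples in the piece
// piece_t0:  local time of the piece's first output sample (ms)
// piece_reset: 1 -> reset state to the holding steady state at piece start
// [[Rcpp::export(name = ".sim_O_cpp")]]
NumericVector sim_O_cpp(NumericVector p, NumericVector piece_v,
                        NumericVector piece_dur, IntegerVector piece_n,
                        NumericVector piece_t0, IntegerVector piece_reset,
                        double dt, double holding, double v_off) {
  const int np = piece_v.size();
  int ntot = 0;
  for (int k = 0; k < np; ++k) ntot += piece_n[k];
  NumericVector out(ntot);

  // holding-potential steady state
  double x1 = 0.0, x2 = 0.0, xh = 1.0; // C1a, Oa, h
  double h1 = 0.0, h2 = 0.0, hh = 1.0;
  {
    double V = holding - v_off;
    double a1 = p[0] * std::exp(p[1] * V), b1 = p[2] * std::exp(-p[3] * V);
    double bh = p[4] * std::exp(p[5] * V), ah = p[6] * std::exp(-p[7] * V);
    double a2 = p[8] * std::exp(p[9] * V), b2 = p[10] * std::exp(-p[11] * V);
    double det = a1 * b2 + b1 * b2 + a1 * a2;
    h1 = a1 * b2 / det; h2 = a1 * a2 / det; hh = ah / (ah + bh);
    x1 = h1; x2 = h2; xh = hh;
  }

  int pos = 0;
  for (int k = 0; k < np; ++k) {
    if (piece_reset[k]) { x1 = h1; x2 = h2; xh = hh; }
    double V = piece_v[k] - v_off;
    double a1 = p[0] * std::exp(p[1] * V), b1 = p[2] * std::exp(-p[3] * V);
    double bh = p[4] * std::exp(p[5] * V), ah = p[6] * std::exp(-p[7] * V);
    double a2 = p[8] * std::exp(p[9] * V), b2 = p[10] * std::exp(-p[11] * V);
    double A11 = -(a1 + a2 + b1), A12 = b2 - a1, A21 = a2, A22 = -b2;
    double det = a1 * b2 + b1 * b2 + a1 * a2;
    double xi1 = a1 * b2 / det, xi2 = a1 * a2 / det;
    double hinf = ah / (ah + bh), tauh = 1.0 / (ah + bh);
    double d1 = x1 - xi1, d2 = x2 - xi2, dh = xh - hinf;
    double tr = A11 + A22;
    double disc = tr * tr - 4.0 * det;
    double sq = disc > 0 ? std::sqrt(disc) : 0.0;
    const int nq = piece_n[k];
    const double t0 = piece_t0[k], dur = piece_dur[k];

    if (sq > 1e-10 * std::max(std::fabs(tr), 1.0)) {
      double l1 = (tr + sq) / 2.0, l2 = (tr - sq) / 2.0;
      double v11, v12, v21, v22;
      if (std::fabs(A12) >= std::fabs(A21)) {
        if (std::fabs(A12) < 1e-300) { v11 = 1; v12 = 0; v21 = 0; v22 = 1; }
        else { v11 = A12; v12 = l1 - A11; v21 = A12; v22 = l2 - A11; }
      } else { v11 = l1 - A22; v12 = A21; v21 = l2 - A22; v22 = A21; }
      double dd = v11 * v22 - v21 * v12;
      double al1 = (d1 * v22 - d2 * v21) / dd;
      double al2 = (v11 * d2 - v12 * d1) / dd;
      for (int j = 0; j < nq; ++j) {
        double t = t0 + j * dt;
        double e1 = std::exp(l1 * t), e2 = std::exp(l2 * t);
        double Oa = xi2 + al1 * v12 * e1 + al2 * v22 * e2;
        double h = hinf + dh * std::exp(-t / tauh);
        out[pos + j] = Oa * h;
      }
      double e1 = std::exp(l1 * dur), e2 = std::exp(l2 * dur);
      x1 = xi1 + al1 * v11 * e1 + al2 * v21 * e2;
      x2 = xi2 + al1 * v12 * e1 + al2 * v22 * e2;
    } else {
      double l = tr / 2.0;
      double g1 = (A11 - l) * d1 + A12 * d2;
      double g2 = A21 * d1 + (A22 - l) * d2;
      for (int j = 0; j < nq; ++j) {
        double t = t0 + j * dt;
        double el = std::exp(l * t);
        double Oa = xi2 + el * (d2 + t * g2);
        double h = hinf + dh * std::exp(-t / tauh);
        out[pos + j] = Oa * h;
      }
      double el = std::exp(l * dur);
      x1 = xi1 + el * (d1 + dur * g1);
      x2 = xi2 + el * (d2 + dur * g2);
    }
    xh = hinf + dh * std::exp(-dur / tauh);
    pos += nq;
  }
  return out;
}
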