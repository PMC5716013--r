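#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One-occurrence-per-sequence (OOPS) motif EM.
//
// Sequences are integer vectors with codes 0..3 = A,C,G,T and 4 = masked.
// Windows containing a masked base are excluded from the site posterior.
// theta is W x 4 (rows = motif positions), bg a length-4 background.
//
// The tracked objective is the OOPS log-likelihood ratio against the
// background-only model:
//   LLR = sum_i log( (1/n_i) * sum_o prod_w theta[w, x_{o+w}] / bg[x_{o+w}] )
// which EM increases monotonically.

// [[Rcpp::export]]
List cpp_em_oops(List seqs, int W, NumericMatrix theta0, NumericVector bg,
                 int max_iter, double tol, double pseudo_frac) {
  if (W < 1 || W > 64) stop("motif width must be between 1 and 64");
  const int nseq = seqs.size();
  std::vector<std::vector<int>> x(nseq);
  std::vector<int> noff(nseq);
  for (int i = 0; i < nseq; ++i) {
    IntegerVector v = seqs[i];
    x[i].assign(v.begin(), v.end());
    noff[i] = (int)x[i].size() - W + 1;
    if (noff[i] < 1) stop("sequence shorter than motif width");
  }
  NumericMatrix theta(clone(theta0));
  std::vector<double> lbg(4);
  for (int a = 0; a < 4; ++a) lbg[a] = std::log(bg[a]);

  std::vector<double> llr_trace;
  double prev = R_NegInf;
  NumericMatrix counts(W, 4);
  std::vector<std::vector<double>> post(nseq);
  int it = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    // log-odds of theta vs background per (position, base)
    double lth[64][4];
    for (int w = 0; w < W; ++w)
      for (int a = 0; a < 4; ++a)
        lth[w][a] = std::log(theta(w, a)) - lbg[a];

    double llr = 0.0;
    std::fill(counts.begin(), counts.end(), 0.0);
    for (int i = 0; i < nseq; ++i) {
      const std::vector<int>& s = x[i];
      int L = noff[i];
      std::vector<double>& z = post[i];
      z.assign(L, R_NegInf);
      double mx = R_NegInf;
      for (int o = 0; o < L; ++o) {
        double sc = 0.0;
        bool ok = true;
        for (int w = 0; w < W; ++w) {
          int a = s[o + w];
          if (a > 3) { ok = false; break; }
          sc += lth[w][a];
        }
        if (ok) { z[o] = sc; if (sc > mx) mx = sc; }
      }
      if (!std::isfinite(mx)) stop("sequence fully masked");
      double tot = 0.0;
      int nvalid = 0;
      for (int o = 0; o < L; ++o)
        if (std::isfinite(z[o])) { tot += std::exp(z[o] - mx); ++nvalid; }
      llr += mx + std::log(tot) - std::log((double)nvalid);
      // E-step responsibilities and expected counts
      for (int o = 0; o < L; ++o) {
        if (!std::isfinite(z[o])) { z[o] = 0.0; continue; }
        double zo = std::exp(z[o] - mx) / tot;
        z[o] = zo;
        if (zo > 0)
          for (int w = 0; w < W; ++w) counts(w, s[o + w]) += zo;
      }
    }
    llr_trace.push_back(llr);
    if (std::isfinite(prev) && llr - prev < tol) { converged = true; break; }
    prev = llr;

    // M-step with pseudocount pseudo_frac * bg per cell
    for (int w = 0; w < W; ++w) {
      double rs = 0.0;
      for (int a = 0; a < 4; ++a) rs += counts(w, a) + pseudo_frac * bg[a];
      for (int a = 0; a < 4; ++a)
        theta(w, a) = (counts(w, a) + pseudo_frac * bg[a]) / rs;
    }
  }

  // MAP site per sequence from the last posterior
  IntegerVector offsets(nseq);
  for (int i = 0; i < nseq; ++i) {
    int besto = 0; double bz = -1.0;
    for (int o = 0; o < noff[i]; ++o)
      if (post[i][o] > bz) { bz = post[i][o]; besto = o; }
    offsets[i] = besto + 1;  // 1-based
  }

  return List::create(_["theta"] = theta,
                      _["offsets"] = offsets,
                      _["llr"] = llr_trace.back(),
                      _["llr_trace"] = NumericVector(llr_trace.begin(), llr_trace.end()),
                      _["iterations"] = std::min(it, max_iter),
                      _["converged"] = converged);
}
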