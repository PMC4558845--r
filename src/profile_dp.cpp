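// Forward and Viterbi dynamic programming for a lean local profile HMM
// (match/insert/delete core states, uniform local entry/exit, background
// N/C flanks scoring zero in log-odds space).  All scores are log2 odds
// against the background model.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log2(2^a + 2^b)
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// [[Rcpp::export(name = ".profile_dp_cpp")]]
List profile_dp_cpp(NumericMatrix mesc,   // M x 20 match emission log2-odds
                    NumericMatrix ltr,    // M x 7 log2 transitions: MM MI MD IM II DM DD
                    IntegerVector x,      // target residues 1..20, 0 = unknown
                    double entry,         // log2 P(B -> M_k), uniform
                    double exit_) {       // log2 P(M_k -> E), uniform
  const int M = mesc.nrow();
  const int L = x.size();

  std::vector<double> fM(M + 1, NEG_INF), fI(M + 1, NEG_INF), fD(M + 1, NEG_INF);
  std::vector<double> pM(M + 1), pI(M + 1), pD(M + 1);
  double fTot = NEG_INF;

  // Viterbi arrays + traceback
  std::vector<double> vM((L + 1) * (M + 1), NEG_INF),
      vI((L + 1) * (M + 1), NEG_INF), vD((L + 1) * (M + 1), NEG_INF);
  // traceback codes: 0 none/B, 1 M, 2 I, 3 D
  std::vector<signed char> tbM((L + 1) * (M + 1), 0),
      tbI((L + 1) * (M + 1), 0), tbD((L + 1) * (M + 1), 0);
  double vBest = NEG_INF;
  int bestI = -1, bestK = -1;

  auto idx = [M](int i, int k) { return i * (M + 1) + k; };

  for (int i = 1; i <= L; ++i) {
    std::swap(pM, fM); std::swap(pI, fI); std::swap(pD, fD);
    std::fill(fM.begin(), fM.end(), NEG_INF);
    std::fill(fI.begin(), fI.end(), NEG_INF);
    std::fill(fD.begin(), fD.end(), NEG_INF);
    const int xi = x[i - 1];
    for (int k = 1; k <= M; ++k) {
      const double e = (xi >= 1 && xi <= 20) ? mesc(k - 1, xi - 1) : 0.0;
      // forward: into M_k from B, M_{k-1}, I_{k-1}, D_{k-1}
      double a = entry;                                   // fresh local start
      if (k > 1) {
        a = lse2(a, pM[k - 1] + ltr(k - 2, 0));
        a = lse2(a, pI[k - 1] + ltr(k - 2, 3));
        a = lse2(a, pD[k - 1] + ltr(k - 2, 5));
      }
      fM[k] = e + a;
      // insert after column k (emits background: zero odds)
      fI[k] = lse2(pM[k] + ltr(k - 1, 1), pI[k] + ltr(k - 1, 4));
      // delete of column k (silent; same-row recursion over k)
      if (k > 1)
        fD[k] = lse2(fM[k - 1] + ltr(k - 2, 2), fD[k - 1] + ltr(k - 2, 6));

      // Viterbi mirrors
      double vm = entry; signed char tb = 0;
      if (k > 1) {
        double c1 = vM[idx(i - 1, k - 1)] + ltr(k - 2, 0);
        double c2 = vI[idx(i - 1, k - 1)] + ltr(k - 2, 3);
        double c3 = vD[idx(i - 1, k - 1)] + ltr(k - 2, 5);
        if (c1 > vm) { vm = c1; tb = 1; }
        if (c2 > vm) { vm = c2; tb = 2; }
        if (c3 > vm) { vm = c3; tb = 3; }
      }
      vM[idx(i, k)] = e + vm; tbM[idx(i, k)] = tb;
      double i1 = vM[idx(i - 1, k)] + ltr(k - 1, 1);
      double i2 = vI[idx(i - 1, k)] + ltr(k - 1, 4);
      vI[idx(i, k)] = i1 > i2 ? i1 : i2; tbI[idx(i, k)] = i1 > i2 ? 1 : 2;
      if (k > 1) {
        double d1 = vM[idx(i, k - 1)] + ltr(k - 2, 2);
        double d2 = vD[idx(i, k - 1)] + ltr(k - 2, 6);
        vD[idx(i, k)] = d1 > d2 ? d1 : d2; tbD[idx(i, k)] = d1 > d2 ? 1 : 3;
      }
      // local exit from M_k
      fTot = lse2(fTot, fM[k] + exit_);
      double ve = vM[idx(i, k)] + exit_;
      if (ve > vBest) { vBest = ve; bestI = i; bestK = k; }
    }
  }

  // Viterbi traceback over match states.
  // Predecessors: M(i,k) <- {B | M/I/D at (i-1,k-1)}; I(i,k) <- {M/I at
  // (i-1,k)}; D(i,k) <- {M/D at (i,k-1)}.
  std::vector<int> path_i, path_k;
  if (bestI > 0) {
    int i = bestI, k = bestK; signed char st = 1;  // start in M
    while (i >= 1 && k >= 1) {
      if (st == 1) {
        path_i.push_back(i); path_k.push_back(k);
        signed char prev = tbM[idx(i, k)];
        if (prev == 0) break;          // local entry
        st = prev; --i; --k;
      } else if (st == 2) {
        st = tbI[idx(i, k)]; --i;
      } else {
        st = tbD[idx(i, k)]; --k;
      }
    }
  }
  std::reverse(path_i.begin(), path_i.end());
  std::reverse(path_k.begin(), path_k.end());

  return List::create(_["forward_bits"] = fTot,
                      _["viterbi_bits"] = vBest,
                      _["path_i"] = wrap(path_i),
                      _["path_k"] = wrap(path_k));
}
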