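// Minimum-free-energy RNA secondary structure by dynamic programming
// (Zuker-style) under a nearest-neighbour model: stacking energies for
// adjacent base pairs, logarithmic hairpin/bulge/internal loop penalties,
// and an affine multiloop term. Energy parameters are passed in from R so
// the R-side structure evaluator and this DP share one parameter set.
//
// Conventions: sequence in the DNA alphabet (T == U); canonical pairs are
// AT, TA, CG, GC, GT, TG; hairpin loops have >= 3 unpaired bases; interior
// loops in the search are bounded by maxloop total unpaired bases.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = 1e9;

struct Params {
  std::vector<double> stack; // 6x6, row-major, 1-based types 1..6 -> 0..5
  double hairpin_a, hairpin_b;   // H(n) = hairpin_a + hairpin_b * log(n/3)
  double bulge1;                 // bulge of size 1
  double bulge_a, bulge_b;       // B(n>=2) = bulge_a + bulge_b * log(n/2)
  double internal_a, internal_b; // I(n) = internal_a + internal_b * log(n/2)
  double internal_asym, internal_asym_max;
  double ml_close, ml_branch;    // multiloop a, b (c = 0 per unpaired base)
  int maxloop;
  int min_hairpin;
};

static int base_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': case 'U': return 3;
  default: return -1;
  }
}

// pair types: 1 CG, 2 GC, 3 GT, 4 TG, 5 AT, 6 TA, 0 none
static int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

static double hairpin_e(int n, const Params& P) {
  return P.hairpin_a + P.hairpin_b * std::log((double)n / 3.0);
}

static double bulge_e(int n, const Params& P) {
  if (n == 1) return P.bulge1;
  return P.bulge_a + P.bulge_b * std::log((double)n / 2.0);
}

static double internal_e(int n1, int n2, const Params& P) {
  int n = n1 + n2;
  double asym = P.internal_asym * std::abs(n1 - n2);
  if (asym > P.internal_asym_max) asym = P.internal_asym_max;
  return P.internal_a + P.internal_b * std::log((double)n / 2.0) + asym;
}

// loop energy for pair (i,j) enclosing pair (k,l) with n1, n2 unpaired
static double two_loop_e(int t_out, int t_in, int n1, int n2, const Params& P) {
  if (n1 == 0 && n2 == 0) return P.stack[(t_out - 1) * 6 + (t_in - 1)];
  if (n1 == 0 || n2 == 0) return bulge_e(n1 + n2, P);
  return internal_e(n1, n2, P);
}

class Folder {
public:
  Folder(const std::string& seq, const Params& P) : P_(P) {
    n_ = (int)seq.size();
    b_.resize(n_);
    for (int i = 0; i < n_; ++i) b_[i] = base_idx(seq[i]);
    V_.assign((size_t)n_ * n_, INF);
    WM_.assign((size_t)n_ * n_, INF);
    W_.assign(n_ + 1, 0.0);
    pt_.assign(n_, -1);
  }

  double& V(int i, int j) { return V_[(size_t)i * n_ + j]; }
  double& WM(int i, int j) { return WM_[(size_t)i * n_ + j]; }

  void fill() {
    for (int span = P_.min_hairpin + 1; span < n_; ++span) {
      for (int i = 0; i + span < n_; ++i) {
        int j = i + span;
        computeV(i, j);
        computeWM(i, j);
      }
    }
    // exterior loop
    for (int j = 0; j < n_; ++j) {
      double best = (j > 0) ? W_[j] : 0.0; // W_ index shifted: W_[j+1] = best over 0..j
      for (int i = 0; i <= j; ++i) {
        double v = V(i, j);
        if (v >= INF) continue;
        double cand = (i > 0 ? W_[i] : 0.0) + v;
        if (cand < best) best = cand;
      }
      W_[j + 1] = std::min(best, W_[j]);
    }
  }

  double mfe() const { return n_ ? W_[n_] : 0.0; }

  void traceback() {
    if (n_ == 0) return;
    traceW(n_ - 1);
  }

  std::string dotbracket() const {
    std::string s(n_, '.');
    for (int i = 0; i < n_; ++i)
      if (pt_[i] > i) { s[i] = '('; s[pt_[i]] = ')'; }
    return s;
  }

private:
  int n_;
  Params P_;
  std::vector<int> b_;
  std::vector<double> V_, WM_, W_;
  std::vector<int> pt_;

  void computeV(int i, int j) {
    int t = pair_type(b_[i], b_[j]);
    if (t == 0) return;
    int loop = j - i - 1;
    if (loop < P_.min_hairpin) return;
    double best = hairpin_e(loop, P_);
    // interior (stack / bulge / internal)
    int maxk = std::min(j - 1, i + P_.maxloop + 1);
    for (int k = i + 1; k <= maxk; ++k) {
      int n1 = k - i - 1;
      for (int l = j - 1; l > k; --l) {
        int n2 = j - l - 1;
        if (n1 + n2 > P_.maxloop) break;
        double vin = V(k, l);
        if (vin >= INF) continue;
        int t_in = pair_type(b_[k], b_[l]);
        double cand = vin + two_loop_e(t, t_in, n1, n2, P_);
        if (cand < best) best = cand;
      }
    }
    // multiloop: >= 2 branches inside
    for (int k = i + 1; k < j - 1; ++k) {
      double a = WM(i + 1, k), b = WM(k + 1, j - 1);
      if (a >= INF || b >= INF) continue;
      double cand = P_.ml_close + P_.ml_branch + a + b;
      if (cand < best) best = cand;
    }
    V(i, j) = best;
  }

  void computeWM(int i, int j) {
    double best = INF;
    double v = V(i, j);
    if (v < INF) best = v + P_.ml_branch;
    if (j - 1 >= i) best = std::min(best, WM(i, j - 1));
    if (i + 1 <= j) best = std::min(best, WM(i + 1, j));
    for (int k = i; k < j; ++k) {
      double a = WM(i, k), b = WM(k + 1, j);
      if (a >= INF || b >= INF) continue;
      if (a + b < best) best = a + b;
    }
    WM(i, j) = best;
  }

  static bool near(double a, double b) { return std::fabs(a - b) < 1e-7; }

  void traceW(int j) {
    while (j >= 0) {
      if (near(W_[j + 1], W_[j])) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j && !found; ++i) {
        double v = V(i, j);
        if (v >= INF) continue;
        if (near(W_[j + 1], (i > 0 ? W_[i] : 0.0) + v)) {
          traceV(i, j);
          j = i - 1;
          found = true;
        }
      }
      if (!found) --j; // numerical safety; should not happen
    }
  }

  void traceV(int i, int j) {
    pt_[i] = j; pt_[j] = i;
    int t = pair_type(b_[i], b_[j]);
    int loop = j - i - 1;
    double e = V(i, j);
    if (near(e, hairpin_e(loop, P_))) return;
    int maxk = std::min(j - 1, i + P_.maxloop + 1);
    for (int k = i + 1; k <= maxk; ++k) {
      int n1 = k - i - 1;
      for (int l = j - 1; l > k; --l) {
        int n2 = j - l - 1;
        if (n1 + n2 > P_.maxloop) break;
        double vin = V(k, l);
        if (vin >= INF) continue;
        int t_in = pair_type(b_[k], b_[l]);
        if (near(e, vin + two_loop_e(t, t_in, n1, n2, P_))) {
          traceV(k, l);
          return;
        }
      }
    }
    for (int k = i + 1; k < j - 1; ++k) {
      double a = WM(i + 1, k), b = WM(k + 1, j - 1);
      if (a >= INF || b >= INF) continue;
      if (near(e, P_.ml_close + P_.ml_branch + a + b)) {
        traceWM(i + 1, k);
        traceWM(k + 1, j - 1);
        return;
      }
    }
  }

  void traceWM(int i, int j) {
    double e = WM(i, j);
    if (e >= INF) return;
    double v = V(i, j);
    if (v < INF && near(e, v + P_.ml_branch)) { traceV(i, j); return; }
    if (j - 1 >= i && near(e, WM(i, j - 1))) { traceWM(i, j - 1); return; }
    if (i + 1 <= j && near(e, WM(i + 1, j))) { traceWM(i + 1, j); return; }
    for (int k = i; k < j; ++k) {
      double a = WM(i, k), b = WM(k + 1, j);
      if (a >= INF || b >= INF) continue;
      if (near(e, a + b)) { traceWM(i, k); traceWM(k + 1, j); return; }
    }
  }
};

// [[Rcpp::export(name = ".rnafold_cpp")]]
List rnafold_cpp(std::string seq, NumericMatrix stack, List loop_params) {
  Params P;
  P.stack.assign(36, 0.0);
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j)
      P.stack[i * 6 + j] = stack(i, j);
  P.hairpin_a = as<double>(loop_params["hairpin_a"]);
  P.hairpin_b = as<double>(loop_params["hairpin_b"]);
  P.bulge1 = as<double>(loop_params["bulge1"]);
  P.bulge_a = as<double>(loop_params["bulge_a"]);
  P.bulge_b = as<double>(loop_params["bulge_b"]);
  P.internal_a = as<double>(loop_params["internal_a"]);
  P.internal_b = as<double>(loop_params["internal_b"]);
  P.internal_asym = as<double>(loop_params["internal_asym"]);
  P.internal_asym_max = as<double>(loop_params["internal_asym_max"]);
  P.ml_close = as<double>(loop_params["ml_close"]);
  P.ml_branch = as<double>(loop_params["ml_branch"]);
  P.maxloop = as<int>(loop_params["maxloop"]);
  P.min_hairpin = as<int>(loop_params["min_hairpin"]);

  for (size_t k = 0; k < seq.size(); ++k) {
    if (base_idx(seq[k]) < 0) stop("invalid base in sequence");
  }

  Folder f(seq, P);
  f.fill();
  f.traceback();
  return List::create(_["structure"] = f.dotbracket(), _["mfe"] = f.mfe());
}
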