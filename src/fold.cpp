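// Minimum-free-energy RNA secondary structure by dynamic programming:
// non-crossing pairs (AU/GC/GU only), a nearest-neighbor stacked-pair
// energy approximation, logarithmic hairpin-loop penalties, length-capped
// interior/bulge loops and a flat multibranch penalty.  Energies in
// kcal/mol.  This is a deliberately simple energy model: the downstream
// filter consumes only the MFE threshold and the pair table.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double INF = 1e9;
static const int MIN_HAIRPIN = 3;     // minimum unpaired bases in a hairpin
static const int MAX_INTERIOR = 30;   // cap on interior/bulge unpaired bases
static const double MULTI_CLOSE = 3.4;  // multibranch closing penalty
static const double MULTI_BRANCH = 0.4; // per-branch penalty
static const double MULTI_UNPAIRED = 0.1;

static inline int baseIndex(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': case 'U': return 3;
  default: return -1;
  }
}

// pair strengths; a stack of two pairs contributes -(s1+s2)/2
static double pairStrength(int a, int b) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2.2;  // A:U
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3.3;  // G:C
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1.4;  // G:U
  return 0.0;
}

static inline double hairpinE(int size) {
  return 4.5 + 1.6 * std::log((double)size / MIN_HAIRPIN);
}

static inline double interiorE(int unpaired) {
  return 1.8 + 0.4 * unpaired;
}

struct Fold {
  int n;
  std::vector<int> b;
  std::vector<double> V, WM;
  std::vector<double> W;
  std::vector<int> pair;

  double& v(int i, int j) { return V[(size_t)i * n + j]; }
  double& wm(int i, int j) { return WM[(size_t)i * n + j]; }
  double strength(int i, int j) { return pairStrength(b[i], b[j]); }
  bool canPair(int i, int j) { return strength(i, j) > 0.0; }

  void fill() {
    V.assign((size_t)n * n, INF);
    WM.assign((size_t)n * n, INF);
    for (int len = 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        // --- V ---
        if (canPair(i, j) && j - i - 1 >= MIN_HAIRPIN) {
          double e = hairpinE(j - i - 1);
          // stack
          if (j - i - 3 >= MIN_HAIRPIN + 0 && canPair(i + 1, j - 1) &&
              v(i + 1, j - 1) < INF)
            e = std::min(e, v(i + 1, j - 1) -
                              0.5 * (strength(i, j) + strength(i + 1, j - 1)));
          // interior / bulge
          for (int p = i + 1; p <= std::min(i + MAX_INTERIOR + 1, j - 2); ++p) {
            for (int q = j - 1; q > p; --q) {
              int u = (p - i - 1) + (j - q - 1);
              if (u == 0) continue;          // that is the stack case
              if (u > MAX_INTERIOR) break;   // q too small already
              if (v(p, q) < INF)
                e = std::min(e, v(p, q) + interiorE(u));
            }
          }
          // multibranch: at least two branches inside
          for (int k = i + 1; k < j - 1; ++k) {
            if (wm(i + 1, k) < INF && wm(k + 1, j - 1) < INF)
              e = std::min(e, wm(i + 1, k) + wm(k + 1, j - 1) + MULTI_CLOSE);
          }
          v(i, j) = e;
        }
        // --- WM ---
        double m = INF;
        if (v(i, j) < INF) m = std::min(m, v(i, j) + MULTI_BRANCH);
        if (i + 1 <= j && wm(i + 1, j) < INF)
          m = std::min(m, wm(i + 1, j) + MULTI_UNPAIRED);
        if (i <= j - 1 && wm(i, j - 1) < INF)
          m = std::min(m, wm(i, j - 1) + MULTI_UNPAIRED);
        for (int k = i; k < j; ++k) {
          if (wm(i, k) < INF && wm(k + 1, j) < INF)
            m = std::min(m, wm(i, k) + wm(k + 1, j));
        }
        wm(i, j) = m;
      }
    }
    W.assign(n + 1, 0.0);
    for (int j = 1; j <= n; ++j) {
      W[j] = W[j - 1];
      for (int i = 1; i <= j; ++i) {
        if (v(i - 1, j - 1) < INF)
          W[j] = std::min(W[j], W[i - 1] + v(i - 1, j - 1));
      }
    }
  }

  void traceV(int i, int j) {
    pair[i] = j + 1;  // 1-based partners
    pair[j] = i + 1;
    double e = v(i, j);
    const double tol = 1e-7;
    if (std::fabs(e - hairpinE(j - i - 1)) < tol) return;
    if (canPair(i + 1, j - 1) && v(i + 1, j - 1) < INF &&
        std::fabs(e - (v(i + 1, j - 1) -
                       0.5 * (strength(i, j) + strength(i + 1, j - 1)))) < tol) {
      traceV(i + 1, j - 1);
      return;
    }
    for (int p = i + 1; p <= std::min(i + MAX_INTERIOR + 1, j - 2); ++p) {
      for (int q = j - 1; q > p; --q) {
        int u = (p - i - 1) + (j - q - 1);
        if (u == 0) continue;
        if (u > MAX_INTERIOR) break;
        if (v(p, q) < INF && std::fabs(e - (v(p, q) + interiorE(u))) < tol) {
          traceV(p, q);
          return;
        }
      }
    }
    for (int k = i + 1; k < j - 1; ++k) {
      if (wm(i + 1, k) < INF && wm(k + 1, j - 1) < INF &&
          std::fabs(e - (wm(i + 1, k) + wm(k + 1, j - 1) + MULTI_CLOSE)) < tol) {
        traceWM(i + 1, k);
        traceWM(k + 1, j - 1);
        return;
      }
    }
    Rcpp::stop("fold traceback failed (V)");
  }

  void traceWM(int i, int j) {
    double e = wm(i, j);
    const double tol = 1e-7;
    if (v(i, j) < INF && std::fabs(e - (v(i, j) + MULTI_BRANCH)) < tol) {
      traceV(i, j);
      return;
    }
    if (i + 1 <= j && wm(i + 1, j) < INF &&
        std::fabs(e - (wm(i + 1, j) + MULTI_UNPAIRED)) < tol) {
      traceWM(i + 1, j);
      return;
    }
    if (i <= j - 1 && wm(i, j - 1) < INF &&
        std::fabs(e - (wm(i, j - 1) + MULTI_UNPAIRED)) < tol) {
      traceWM(i, j - 1);
      return;
    }
    for (int k = i; k < j; ++k) {
      if (wm(i, k) < INF && wm(k + 1, j) < INF &&
          std::fabs(e - (wm(i, k) + wm(k + 1, j))) < tol) {
        traceWM(i, k);
        traceWM(k + 1, j);
        return;
      }
    }
    Rcpp::stop("fold traceback failed (WM)");
  }

  void traceback() {
    pair.assign(n, 0);
    const double tol = 1e-7;
    int j = n;
    while (j > 0) {
      if (std::fabs(W[j] - W[j - 1]) < tol) {
        --j;
        continue;
      }
      bool found = false;
      for (int i = 1; i <= j; ++i) {
        if (v(i - 1, j - 1) < INF &&
            std::fabs(W[j] - (W[i - 1] + v(i - 1, j - 1))) < tol) {
          traceV(i - 1, j - 1);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) Rcpp::stop("fold traceback failed (W)");
    }
  }
};

// [[Rcpp::export(name = ".foldEnergyCpp")]]
List foldEnergyCpp(std::string seq) {
  Fold f;
  f.n = (int)seq.size();
  f.b.resize(f.n);
  for (int i = 0; i < f.n; ++i) {
    int bi = baseIndex(seq[i]);
    if (bi < 0) stop("sequence contains non-ACGT characters");
    f.b[i] = bi;
  }
  if (f.n < 2) {
    return List::create(_["pairs"] = IntegerVector(f.n, 0), _["mfe"] = 0.0);
  }
  f.fill();
  f.traceback();
  double mfe = f.W[f.n];
  return List::create(_["pairs"] = IntegerVector(f.pair.begin(), f.pair.end()),
                      _["mfe"] = mfe);
}
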