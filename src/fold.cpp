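// Zuker-style minimum-free-energy folding of short RNA windows.
//
// Energy model (tables supplied from R so the R-side structure scorer and
// this DP share one set of constants):
//   - nearest-neighbour stacking over the six admissible pair types,
//   - hairpin / bulge / interior loop size penalties (pre-extrapolated
//     vectors, 1-based by loop size),
//   - linear multiloop penalty (close + per-branch + per-unpaired).
// Lonely pairs are allowed, minimum hairpin loop is 3 nt, bulge/interior
// loops are capped at `maxLoop` total unpaired nucleotides.
//
// Traceback is deterministic: options are examined in a fixed order
// (pairing before unpaired, stacking before larger loops, 5'-most branch
// first) and the first option within 1e-6 of the optimum is taken.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-6;

// base codes: A=0, C=1, G=2, U=3; pair types 0..5 = AU UA CG GC GU UG, -1 none
static inline int pairType(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Model {
  NumericMatrix stack;          // 6x6
  NumericVector hairpin, bulge, interior;  // 1-based by size (index 0 = size 1)
  double mlClose, mlBranch, mlUnpaired;
  int maxLoop;
  double loopE(int size, const NumericVector& tab) const {
    return tab[size - 1];
  }
};

class Folder {
public:
  std::vector<int> s;
  int n;
  Model m;
  std::vector<std::vector<double> > V, WM, WM2;
  std::vector<double> W;

  Folder(const std::vector<int>& seq, const Model& mod) : s(seq), m(mod) {
    n = (int)s.size();
  }

  // energy of the two-pair loop closed by (i,j) with inner pair (k,l)
  double twoLoop(int i, int j, int k, int l) const {
    int up5 = k - i - 1, up3 = j - l - 1;
    if (up5 + up3 > m.maxLoop) return INF;
    int pt = pairType(s[i], s[j]), ptin = pairType(s[k], s[l]);
    if (pt < 0 || ptin < 0) return INF;
    if (up5 == 0 && up3 == 0) return m.stack(pt, ptin);
    if (up5 == 0 || up3 == 0) return m.loopE(up5 + up3, m.bulge);
    return m.loopE(up5 + up3, m.interior);
  }

  void fill() {
    V.assign(n, std::vector<double>(n, INF));
    WM.assign(n, std::vector<double>(n, INF));
    WM2.assign(n, std::vector<double>(n, INF));
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        int pt = pairType(s[i], s[j]);
        if (pt >= 0) {
          double best = m.loopE(j - i - 1, m.hairpin);
          // stack / bulge / interior
          for (int k = i + 1; k <= j - 5 && k - i - 1 <= m.maxLoop; ++k) {
            for (int l = j - 1; l >= k + 4; --l) {
              if ((k - i - 1) + (j - l - 1) > m.maxLoop) break;
              if (V[k][l] >= INF) continue;
              double e = twoLoop(i, j, k, l);
              if (e < INF && e + V[k][l] < best) best = e + V[k][l];
            }
          }
          // multiloop closed by (i,j)
          if (j - i >= 6 && WM2[i + 1][j - 1] < INF) {
            double e = m.mlClose + m.mlBranch + WM2[i + 1][j - 1];
            if (e < best) best = e;
          }
          V[i][j] = best;
        }
        // WM / WM2 (multiloop interiors)
        double wm = INF;
        if (V[i][j] < INF) wm = V[i][j] + m.mlBranch;
        if (WM[i + 1][j] < INF) wm = std::min(wm, WM[i + 1][j] + m.mlUnpaired);
        if (WM[i][j - 1] < INF) wm = std::min(wm, WM[i][j - 1] + m.mlUnpaired);
        double wm2 = INF;
        for (int k = i; k < j; ++k) {
          if (WM[i][k] < INF && WM[k + 1][j] < INF) {
            double e = WM[i][k] + WM[k + 1][j];
            if (e < wm2) wm2 = e;
            if (e < wm) wm = e;
          }
        }
        WM[i][j] = wm;
        WM2[i][j] = wm2;
      }
    }
    // external loop
    W.assign(n + 1, 0.0);  // W[j+1] = best for prefix 0..j
    for (int j = 0; j < n; ++j) {
      double best = W[j];  // j unpaired
      for (int i = 0; i + 4 <= j; ++i) {
        if (V[i][j] < INF) {
          double e = (i > 0 ? W[i] : 0.0) + V[i][j];
          if (e < best) best = e;
        }
      }
      W[j + 1] = best;
    }
  }

  std::vector<int> pairs;

  void tracebackV(int i, int j) {
    double target = V[i][j];
    pairs[i] = j + 1; pairs[j] = i + 1;  // 1-based
    // stack/interior/bulge, stacking examined first via k ascending, l desc
    for (int k = i + 1; k <= j - 5 && k - i - 1 <= m.maxLoop; ++k) {
      for (int l = j - 1; l >= k + 4; --l) {
        if ((k - i - 1) + (j - l - 1) > m.maxLoop) break;
        if (V[k][l] >= INF) continue;
        double e = twoLoop(i, j, k, l);
        if (e < INF && std::fabs(e + V[k][l] - target) < EPS) {
          tracebackV(k, l);
          return;
        }
      }
    }
    if (j - i >= 6 && WM2[i + 1][j - 1] < INF &&
        std::fabs(m.mlClose + m.mlBranch + WM2[i + 1][j - 1] - target) < EPS) {
      tracebackWM2(i + 1, j - 1);
      return;
    }
    // hairpin: nothing further to trace
  }

  void tracebackWM2(int i, int j) {
    double target = WM2[i][j];
    for (int k = i; k < j; ++k) {
      if (WM[i][k] < INF && WM[k + 1][j] < INF &&
          std::fabs(WM[i][k] + WM[k + 1][j] - target) < EPS) {
        tracebackWM(i, k);
        tracebackWM(k + 1, j);
        return;
      }
    }
  }

  void tracebackWM(int i, int j) {
    double target = WM[i][j];
    if (V[i][j] < INF && std::fabs(V[i][j] + m.mlBranch - target) < EPS) {
      tracebackV(i, j);
      return;
    }
    if (i + 1 <= j && WM[i + 1][j] < INF &&
        std::fabs(WM[i + 1][j] + m.mlUnpaired - target) < EPS) {
      tracebackWM(i + 1, j);
      return;
    }
    if (i <= j - 1 && WM[i][j - 1] < INF &&
        std::fabs(WM[i][j - 1] + m.mlUnpaired - target) < EPS) {
      tracebackWM(i, j - 1);
      return;
    }
    for (int k = i; k < j; ++k) {
      if (WM[i][k] < INF && WM[k + 1][j] < INF &&
          std::fabs(WM[i][k] + WM[k + 1][j] - target) < EPS) {
        tracebackWM(i, k);
        tracebackWM(k + 1, j);
        return;
      }
    }
  }

  void traceback() {
    pairs.assign(n, 0);
    int j = n - 1;
    while (j >= 4) {
      // pairing preferred over leaving j unpaired; 5'-most partner first
      bool found = false;
      for (int i = 0; i + 4 <= j; ++i) {
        if (V[i][j] < INF &&
            std::fabs((i > 0 ? W[i] : 0.0) + V[i][j] - W[j + 1]) < EPS) {
          tracebackV(i, j);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) --j;
    }
  }
};

// [[Rcpp::export(name = ".foldMFE_cpp")]]
List foldMFE_cpp(IntegerVector seq, NumericMatrix stack,
                 NumericVector hairpin, NumericVector bulge,
                 NumericVector interior, double mlClose, double mlBranch,
                 double mlUnpaired, int maxLoop) {
  Model m{stack, hairpin, bulge, interior, mlClose, mlBranch, mlUnpaired,
          maxLoop};
  std::vector<int> s(seq.begin(), seq.end());
  Folder f(s, m);
  int n = f.n;
  if (n < 5) {
    return List::create(_["energy"] = 0.0,
                        _["pairs"] = IntegerVector(n, 0));
  }
  f.fill();
  double e = f.W[n];
  if (e >= -EPS) {  // nothing better than fully unpaired
    return List::create(_["energy"] = 0.0,
                        _["pairs"] = IntegerVector(n, 0));
  }
  f.traceback();
  return List::create(_["energy"] = e,
                      _["pairs"] = IntegerVector(f.pairs.begin(),
                                                 f.pairs.end()));
}
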