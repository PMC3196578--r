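// Minimum-free-energy hairpin folding under a simple additive energy model:
// pair energies GC -3, AU -2, GU -1 (kcal/mol), hairpin loops >= 3 nt,
// +1 kcal/mol per unpaired nt in interior loops and bulges, multiloop and
// exterior unpaired bases free, no pseudoknots.  Two-matrix Zuker-style DP
// so that the DP optimum equals the structural energy an enumeration oracle
// assigns.  Interior loops are capped at `max_interior` unpaired nt per side.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const int INF = 100000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return 4;
  }
}

// energy of pair (a,b); INF if not pairable
static inline int pair_energy(int a, int b, bool allow_gu) {
  if (a > 3 || b > 3) return INF;
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2; // A:U
  if (allow_gu && ((a == 2 && b == 3) || (a == 3 && b == 2))) return -1; // G:U
  return INF;
}

struct Fold {
  int n;
  std::vector<int> code;
  std::vector<int> V, WM;
  std::vector<int> W;
  bool allow_gu;
  int maxint;

  int &v(int i, int j) { return V[(size_t) i * n + j]; }
  int &wm(int i, int j) { return WM[(size_t) i * n + j]; }
  int ep(int i, int j) { return pair_energy(code[i], code[j], allow_gu); }

  void run() {
    V.assign((size_t) n * n, INF);
    WM.assign((size_t) n * n, INF);
    for (int len = 4; len < n; ++len) {
      for (int i = 0; i + len < n; ++i) {
        int j = i + len;
        int e = ep(i, j);
        if (e < INF) {
          int best = 0; // hairpin loop (>= 3 nt guaranteed by len >= 4)
          // interior loop / bulge / stack
          int pmax = std::min(j - 1, i + 1 + maxint);
          for (int p = i + 1; p <= pmax; ++p) {
            int l1 = p - i - 1;
            int qmin = std::max(p + 4, j - 1 - maxint);
            for (int q = j - 1; q >= qmin; --q) {
              int cell = v(p, q);
              if (cell >= INF) continue;
              int l2 = j - q - 1;
              int cand = cell + l1 + l2;
              if (cand < best) best = cand;
            }
          }
          // multiloop: at least two branches inside
          for (int k = i + 1; k < j - 1; ++k) {
            int a = wm(i + 1, k), b = wm(k + 1, j - 1);
            if (a < INF && b < INF && a + b < best) best = a + b;
          }
          v(i, j) = e + best;
        }
        // WM: >= 1 branch, unpaired free
        int w = v(i, j);
        if (len >= 5) {
          w = std::min(w, wm(i + 1, j));
          w = std::min(w, wm(i, j - 1));
          for (int k = i + 4; k + 1 + 4 <= j; ++k) {
            int a = wm(i, k), b = wm(k + 1, j);
            if (a < INF && b < INF) w = std::min(w, a + b);
          }
        }
        wm(i, j) = w;
      }
    }
    W.assign(n, 0);
    for (int j = 0; j < n; ++j) {
      int best = (j > 0) ? W[j - 1] : 0;
      for (int i = 0; i + 4 <= j; ++i) {
        if (v(i, j) < INF) {
          int cand = ((i > 0) ? W[i - 1] : 0) + v(i, j);
          if (cand < best) best = cand;
        }
      }
      W[j] = std::min(best, 0);
    }
  }

  std::string structure;
  void trace_v(int i, int j) {
    structure[i] = '('; structure[j] = ')';
    int target = v(i, j) - ep(i, j);
    if (target == 0) return; // hairpin
    int pmax = std::min(j - 1, i + 1 + maxint);
    for (int p = i + 1; p <= pmax; ++p) {
      int l1 = p - i - 1;
      int qmin = std::max(p + 4, j - 1 - maxint);
      for (int q = j - 1; q >= qmin; --q) {
        if (v(p, q) < INF && v(p, q) + l1 + (j - q - 1) == target) {
          trace_v(p, q); return;
        }
      }
    }
    for (int k = i + 1; k < j - 1; ++k) {
      int a = wm(i + 1, k), b = wm(k + 1, j - 1);
      if (a < INF && b < INF && a + b == target) {
        trace_wm(i + 1, k); trace_wm(k + 1, j - 1); return;
      }
    }
  }
  void trace_wm(int i, int j) {
    int t = wm(i, j);
    if (t == v(i, j)) { trace_v(i, j); return; }
    if (j - i >= 5) {
      if (t == wm(i + 1, j)) { trace_wm(i + 1, j); return; }
      if (t == wm(i, j - 1)) { trace_wm(i, j - 1); return; }
      for (int k = i + 4; k + 1 + 4 <= j; ++k) {
        int a = wm(i, k), b = wm(k + 1, j);
        if (a < INF && b < INF && a + b == t) {
          trace_wm(i, k); trace_wm(k + 1, j); return;
        }
      }
    }
  }
  void trace_w() {
    structure.assign(n, '.');
    int j = n - 1;
    while (j >= 0) {
      if (W[j] == 0) break;
      if (j > 0 && W[j] == W[j - 1]) { --j; continue; }
      bool found = false;
      for (int i = 0; i + 4 <= j; ++i) {
        if (v(i, j) < INF &&
            ((i > 0) ? W[i - 1] : 0) + v(i, j) == W[j]) {
          trace_v(i, j);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) break;
    }
  }
};

// [[Rcpp::export]]
List cpp_fold(std::string seq, bool allow_gu, int max_interior) {
  Fold f;
  f.n = (int) seq.size();
  f.allow_gu = allow_gu;
  f.maxint = max_interior;
  f.code.resize(f.n);
  for (int i = 0; i < f.n; ++i) f.code[i] = base_code(seq[i]);
  if (f.n < 5) {
    return List::create(_["structure"] = std::string(f.n, '.'),
                        _["mfe"] = 0.0);
  }
  f.run();
  f.trace_w();
  double mfe = (double) std::min(0, f.W[f.n - 1]);
  return List::create(_["structure"] = f.structure, _["mfe"] = mfe);
}
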