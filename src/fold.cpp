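#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
using namespace Rcpp;

// Secondary-structure prediction by Nussinov-style interval dynamic
// programming with stacking energies: a base pair contributes energy only
// when stacked on an adjacent pair (GC -3, AU -2, GU -1 kcal/mol per
// stacked pair); lone pairs contribute 0.  Hairpin loops are >= min_loop nt.
// Pseudoknot-free by construction.  Deterministic traceback (fixed decision
// order) so the same sequence always yields the same dot-bracket string.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': case 'U': return 3;
  default: return -1;
  }
}

static inline bool can_pair(int a, int b) {
  // AU, GC, GU and their mirrors
  return (a + b == 3) || (a == 2 && b == 3) || (a == 3 && b == 2);
}

static inline double stack_energy(int a, int b) {
  // energy credited to pair (a,b) when stacked on an adjacent pair
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return -3.0;   // GC
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2.0;   // AU
  return -1.0;                                                 // GU
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) stop("non-ACGTU character at position %d", i + 1);
    s[i] = c;
  }
  if (n == 0) return List::create(_["structure"] = "", _["energy"] = 0.0);

  const double INF = 1e9;
  // W[i][j]: best (minimum) energy on [i, j]; V[i][j]: best with (i,j) paired
  std::vector<std::vector<double> > W(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // V(i,j): (i,j) paired
      if (can_pair(s[i], s[j]) && j - i - 1 >= min_loop) {
        double best = W[i + 1][j - 1];             // closing pair, unstacked
        if (j - i - 1 > min_loop && can_pair(s[i + 1], s[j - 1]) &&
            V[i + 1][j - 1] < INF) {
          double st = stack_energy(s[i], s[j]) + V[i + 1][j - 1];
          if (st < best) best = st;
        }
        V[i][j] = best;
      }
      // W(i,j)
      double w = W[i + 1][j];                      // i unpaired
      double w2 = W[i][j - 1];                     // j unpaired
      if (w2 < w) w = w2;
      if (V[i][j] < w) w = V[i][j];
      for (int k = i; k < j; ++k) {                // bifurcation
        double b = W[i][k] + W[k + 1][j];
        if (b < w) w = b;
      }
      W[i][j] = w;
    }
  }

  // traceback
  std::string db(n, '.');
  const double EPS = 1e-9;
  // state 0: interpret as W interval, state 1: as V interval
  std::stack<std::array<int, 3> > st;
  st.push({0, n - 1, 0});
  while (!st.empty()) {
    std::array<int, 3> f = st.top();
    st.pop();
    int i = f[0], j = f[1], mode = f[2];
    if (i >= j) continue;
    if (mode == 1) {
      db[i] = '(';
      db[j] = ')';
      if (j - i - 1 > min_loop && can_pair(s[i + 1], s[j - 1]) &&
          V[i + 1][j - 1] < INF &&
          std::abs(V[i][j] - (stack_energy(s[i], s[j]) + V[i + 1][j - 1])) < EPS) {
        st.push({i + 1, j - 1, 1});
      } else {
        st.push({i + 1, j - 1, 0});
      }
      continue;
    }
    double w = W[i][j];
    if (std::abs(w) < EPS && V[i][j] > -EPS) {
      // nothing scored on this interval; leave unpaired (deterministic)
      continue;
    }
    if (V[i][j] < INF && std::abs(w - V[i][j]) < EPS) {
      st.push({i, j, 1});
    } else if (std::abs(w - W[i + 1][j]) < EPS) {
      st.push({i + 1, j, 0});
    } else if (std::abs(w - W[i][j - 1]) < EPS) {
      st.push({i, j - 1, 0});
    } else {
      for (int k = i; k < j; ++k) {
        if (std::abs(w - (W[i][k] + W[k + 1][j])) < EPS) {
          st.push({i, k, 0});
          st.push({k + 1, j, 0});
          break;
        }
      }
    }
  }

  return List::create(_["structure"] = db, _["energy"] = W[0][n - 1]);
}
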