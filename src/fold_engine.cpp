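// Minimum-free-energy RNA secondary structure under a nearest-neighbour
// stacking model: Watson-Crick + G:U pairs, stacking energies for the 36
// ordered pair stacks, length-dependent hairpin/bulge/internal loop
// penalties (tables to 30 nt, logarithmic extrapolation beyond), affine
// multiloop cost, minimum hairpin loop 3, interior loops capped at
// max_interior unpaired nt, no pseudoknots, no dangles.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-6;
static const double LOG_EXTRAP = 1.75 * 0.6163; // Jacobson-Stockmayer, 37 C

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// pair-type index into the stack table rows/cols:
// 0 AT, 1 CG, 2 GC, 3 GT, 4 TA, 5 TG (alphabetical, matching the R table)
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 0) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Params {
  std::vector<double> stack;   // 6x6 row-major [outer*6 + inner]
  std::vector<double> hairpin, bulge, internal_;
  double ml_init, ml_branch, ml_unpaired;
  int max_interior;
  double loop_e(const std::vector<double>& tab, int n) const {
    int m = (int)tab.size();
    if (n <= 0) return INF;
    if (n <= m) {
      double v = tab[n - 1];
      return ISNAN(v) ? INF : v;
    }
    return tab[m - 1] + LOG_EXTRAP * std::log((double)n / m);
  }
  double hairpin_e(int n) const { return n < 3 ? INF : loop_e(hairpin, n); }
  double bulge_e(int n) const { return loop_e(bulge, n); }
  double internal_e(int n) const { return loop_e(internal_, n); }
};

class Folder {
public:
  Folder(const std::string& seq, const Params& p) : s(seq), par(p), n(seq.size()) {
    code.resize(n);
    for (int i = 0; i < n; ++i) code[i] = base_code(s[i]);
    V.assign((size_t)n * n, INF);
    M.assign((size_t)n * n, INF);
    M1.assign((size_t)n * n, INF);
    W.assign(n + 1, 0.0);
  }

  inline double& at(std::vector<double>& m, int i, int j) {
    return m[(size_t)i * n + j];
  }
  inline double get(std::vector<double>& m, int i, int j) {
    return (i < 0 || j < 0 || i >= n || j >= n || i > j) ? INF : m[(size_t)i * n + j];
  }
  inline bool can_pair(int i, int j) {
    return j - i - 1 >= 3 && code[i] >= 0 && code[j] >= 0 &&
           pair_type(code[i], code[j]) >= 0;
  }
  inline double stack_e(int i, int j, int k, int l) {
    int a = pair_type(code[i], code[j]), b = pair_type(code[k], code[l]);
    return par.stack[(size_t)a * 6 + b];
  }
  double interior_e(int i, int j, int k, int l) {
    int n1 = k - i - 1, n2 = j - l - 1;
    if (n1 == 0 && n2 == 0) return stack_e(i, j, k, l);
    if (n1 == 0 || n2 == 0) return par.bulge_e(n1 + n2);
    return par.internal_e(n1 + n2);
  }

  void fill() {
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // V
        if (can_pair(i, j)) {
          double best = par.hairpin_e(j - i - 1);
          int kmax = std::min(i + 1 + par.max_interior, j - 1);
          for (int k = i + 1; k <= kmax; ++k) {
            int lmin = std::max(k + 4, j - 1 - (par.max_interior - (k - i - 1)));
            for (int l = j - 1; l >= lmin; --l) {
              double v = get(V, k, l);
              if (v >= INF) continue;
              double e = interior_e(i, j, k, l) + v;
              if (e < best) best = e;
            }
          }
          // multiloop: (i,j) closes >= 2 inner helices
          for (int u = i + 2; u <= j - 3; ++u) {
            double a = get(M, i + 1, u), b = get(M1, u + 1, j - 1);
            if (a >= INF || b >= INF) continue;
            double e = par.ml_init + par.ml_branch + a + b;
            if (e < best) best = e;
          }
          at(V, i, j) = best;
        }
        // M1: rightmost helix starts at i
        {
          double best = INF;
          double v = get(V, i, j);
          if (v < INF) best = v + par.ml_branch;
          double m1 = get(M1, i, j - 1);
          if (m1 < INF && m1 + par.ml_unpaired < best) best = m1 + par.ml_unpaired;
          at(M1, i, j) = best;
        }
        // M: >= 1 helix somewhere in [i, j]
        {
          double best = INF;
          double v = get(V, i, j);
          if (v < INF) best = v + par.ml_branch;
          double a = get(M, i + 1, j);
          if (a < INF && a + par.ml_unpaired < best) best = a + par.ml_unpaired;
          double b = get(M, i, j - 1);
          if (b < INF && b + par.ml_unpaired < best) best = b + par.ml_unpaired;
          for (int u = i + 1; u <= j; ++u) {
            double x = get(M, i, u - 1), y = get(M1, u, j);
            if (x >= INF || y >= INF) continue;
            if (x + y < best) best = x + y;
          }
          at(M, i, j) = best;
        }
      }
    }
    // external loop
    for (int j = 0; j < n; ++j) {
      double best = j > 0 ? W[j] : 0.0;  // W[j] is prefix [0, j-1]; j unpaired
      if (j == 0) best = 0.0; else best = W[j];
      for (int i = 0; i <= j - 4; ++i) {
        double v = get(V, i, j);
        if (v >= INF) continue;
        double e = (i > 0 ? W[i] : 0.0) + v;
        if (e < best) best = e;
      }
      W[j + 1] = best;
    }
  }

  std::string traceback() {
    std::string db(n, '.');
    // external
    int j = n - 1;
    while (j >= 0) {
      if (std::fabs(W[j + 1] - W[j]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j - 4 && !found; ++i) {
        double v = get(V, i, j);
        if (v >= INF) continue;
        if (std::fabs(W[j + 1] - ((i > 0 ? W[i] : 0.0) + v)) < EPS) {
          trace_V(i, j, db);
          j = i - 1;
          found = true;
        }
      }
      if (!found) { --j; }  // numerical safety; should not happen
    }
    return db;
  }

private:
  void trace_V(int i, int j, std::string& db) {
    db[i] = '('; db[j] = ')';
    double target = get(V, i, j);
    if (std::fabs(target - par.hairpin_e(j - i - 1)) < EPS) return;
    int kmax = std::min(i + 1 + par.max_interior, j - 1);
    for (int k = i + 1; k <= kmax; ++k) {
      int lmin = std::max(k + 4, j - 1 - (par.max_interior - (k - i - 1)));
      for (int l = j - 1; l >= lmin; --l) {
        double v = get(V, k, l);
        if (v >= INF) continue;
        if (std::fabs(target - (interior_e(i, j, k, l) + v)) < EPS) {
          trace_V(k, l, db);
          return;
        }
      }
    }
    for (int u = i + 2; u <= j - 3; ++u) {
      double a = get(M, i + 1, u), b = get(M1, u + 1, j - 1);
      if (a >= INF || b >= INF) continue;
      if (std::fabs(target - (par.ml_init + par.ml_branch + a + b)) < EPS) {
        trace_M(i + 1, u, db);
        trace_M1(u + 1, j - 1, db);
        return;
      }
    }
  }
  void trace_M(int i, int j, std::string& db) {
    while (i <= j) {
      double target = get(M, i, j);
      double v = get(V, i, j);
      if (v < INF && std::fabs(target - (v + par.ml_branch)) < EPS) {
        trace_V(i, j, db); return;
      }
      double a = get(M, i + 1, j);
      if (a < INF && std::fabs(target - (a + par.ml_unpaired)) < EPS) { ++i; continue; }
      double b = get(M, i, j - 1);
      if (b < INF && std::fabs(target - (b + par.ml_unpaired)) < EPS) { --j; continue; }
      for (int u = i + 1; u <= j; ++u) {
        double x = get(M, i, u - 1), y = get(M1, u, j);
        if (x >= INF || y >= INF) continue;
        if (std::fabs(target - (x + y)) < EPS) {
          trace_M(i, u - 1, db);
          trace_M1(u, j, db);
          return;
        }
      }
      return;  // numerical safety
    }
  }
  void trace_M1(int i, int j, std::string& db) {
    while (i <= j) {
      double target = get(M1, i, j);
      double v = get(V, i, j);
      if (v < INF && std::fabs(target - (v + par.ml_branch)) < EPS) {
        trace_V(i, j, db); return;
      }
      --j;
    }
  }

  std::string s;
  const Params& par;
  int n;
  std::vector<int> code;
  std::vector<double> V, M, M1;
public:
  std::vector<double> W;
};

// [[Rcpp::export(name = ".fold_engine_cpp")]]
List fold_engine_cpp(std::string seq, NumericMatrix stack,
                     NumericVector hairpin, NumericVector bulge,
                     NumericVector internal, double ml_init,
                     double ml_branch, double ml_unpaired,
                     int max_interior) {
  int n = seq.size();
  if (n < 8) stop("sequence too short to fold (< 8 nt)");
  if (n > 5000) stop("sequence too long for the built-in folder (> 5000 nt)");
  Params p;
  p.stack.assign(36, 0.0);
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      p.stack[(size_t)a * 6 + b] = stack(a, b);
  p.hairpin.assign(hairpin.begin(), hairpin.end());
  p.bulge.assign(bulge.begin(), bulge.end());
  p.internal_.assign(internal.begin(), internal.end());
  p.ml_init = ml_init; p.ml_branch = ml_branch; p.ml_unpaired = ml_unpaired;
  p.max_interior = max_interior;

  Folder f(seq, p);
  f.fill();
  double mfe = f.W[n];
  if (mfe > 0) mfe = 0;  // open chain is always available at zero
  std::string db = f.traceback();
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
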