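#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Minimum-energy pseudoknot-free secondary structure under a simple
// additive model: each base pair contributes its stacking-free pair
// energy (GC -3.0, AU -2.0, GU -1.0 kcal/mol) and every hairpin loop
// closure costs +4.0 kcal/mol. Interior loops, bulges and multiloops
// carry no penalty. Minimum hairpin loop size is 3 unpaired bases,
// enforced as j - i > MINLOOP for any pair (i, j).

static const double INF = 1e9;
static const double LOOP_PENALTY = 4.0;
static const int MINLOOP = 3;

static inline double pair_energy(char a, char b) {
  // sequence is normalised to RNA upper case upstream
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return INF;
}

struct FoldDP {
  int n;
  const std::string &s;
  std::vector<double> V;   // V[i*n+j]: min energy on [i,j] with (i,j) paired
  std::vector<double> WP;  // WP[i*n+j]: min energy on [i,j] with >=1 pair
  FoldDP(const std::string &seq) : n((int)seq.size()), s(seq),
      V(n * n, INF), WP(n * n, INF) {
    for (int span = MINLOOP + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        double e = pair_energy(s[i], s[j]);
        if (e < INF / 2) {
          double interior = LOOP_PENALTY; // hairpin closure
          if (j - 1 - (i + 1) > MINLOOP) {
            double win = WP[(i + 1) * n + (j - 1)];
            if (win < interior) interior = win;
          }
          V[i * n + j] = e + interior;
        }
        double best = V[i * n + j];
        if (WP[(i + 1) * n + j] < best) best = WP[(i + 1) * n + j];
        if (WP[i * n + (j - 1)] < best) best = WP[i * n + (j - 1)];
        for (int k = i + 1; k < j; ++k) {
          double a = WP[i * n + k], b = WP[(k + 1) * n + j];
          if (a < INF / 2 && b < INF / 2 && a + b < best) best = a + b;
        }
        WP[i * n + j] = best;
      }
    }
  }

  void trace_WP(int i, int j, std::string &db) {
    if (j <= i) return;
    double w = WP[i * n + j];
    if (w >= INF / 2) return; // no pairs: leave dots
    const double eps = 1e-7;
    if (std::abs(V[i * n + j] - w) < eps) { trace_V(i, j, db); return; }
    if (std::abs(WP[(i + 1) * n + j] - w) < eps) { trace_WP(i + 1, j, db); return; }
    if (std::abs(WP[i * n + (j - 1)] - w) < eps) { trace_WP(i, j - 1, db); return; }
    for (int k = i + 1; k < j; ++k) {
      double a = WP[i * n + k], b = WP[(k + 1) * n + j];
      if (a < INF / 2 && b < INF / 2 && std::abs(a + b - w) < eps) {
        trace_WP(i, k, db); trace_WP(k + 1, j, db); return;
      }
    }
    Rcpp::stop("fold traceback failed (WP)");
  }

  void trace_V(int i, int j, std::string &db) {
    db[i] = '('; db[j] = ')';
    double e = pair_energy(s[i], s[j]);
    double target = V[i * n + j] - e;
    const double eps = 1e-7;
    if (std::abs(target - LOOP_PENALTY) < eps) return; // hairpin loop inside
    trace_WP(i + 1, j - 1, db);
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq) {
  int n = (int)seq.size();
  std::string db(n, '.');
  if (n <= MINLOOP + 1) {
    return List::create(_["structure"] = db, _["mfe"] = 0.0);
  }
  FoldDP dp(seq);
  double mfe = dp.WP[0 * n + (n - 1)];
  if (mfe >= 0) {
    // empty structure is optimal (or no pair possible)
    return List::create(_["structure"] = std::string(n, '.'),
                        _["mfe"] = 0.0);
  }
  dp.trace_WP(0, n - 1, db);
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}

// [[Rcpp::export(name = ".duplex_energy_cpp")]]
double duplex_energy_cpp(std::string a, std::string b) {
  // energy of an ungapped duplex: a aligned antiparallel against b
  // (b given 5'->3'; position i of a pairs with position n-1-i of b)
  int n = (int)std::min(a.size(), b.size());
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    double p = pair_energy(a[i], b[b.size() - 1 - i]);
    if (p < INF / 2) e += p;
  }
  return e;
}
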