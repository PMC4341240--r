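#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand over nested
// (pseudoknot-free) structures.  Loop-based energy model:
//   - stacking energies for adjacent base pairs (6x6 table over
//     AU/UA/GC/CG/GU/UG, outer x inner),
//   - fixed terminal (hairpin) loop penalty,
//   - bulge: open + per-nt, internal loop: open + per-nt (both sides),
//   - multiloop: closing penalty + per-branch penalty (closing pair
//     counts as a branch), unpaired bases free,
//   - minimum hairpin loop size, interior loop size capped per side.
// All constants come from R (fold_energy_params()) so the enumeration
// oracle in the test suite can share them.

static const double INF = 1e9;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

// pair types: 0 AU, 1 UA, 2 GC, 3 CG, 4 GU, 5 UG; -1 unpairable
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Params {
  double stack[6][6];
  double hairpin, bulge_open, bulge_per, internal_open, internal_per;
  double multi_close, multi_branch;
  int min_loop, max_interior;
};

static inline double loop_energy(const Params &P, int l1, int l2,
                                 int pt_out, int pt_in) {
  if (l1 == 0 && l2 == 0) return P.stack[pt_out][pt_in];
  if (l1 == 0 || l2 == 0) return P.bulge_open + P.bulge_per * (l1 + l2);
  return P.internal_open + P.internal_per * (l1 + l2);
}

// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(std::string seq, List params) {
  int n = (int) seq.size();
  if (n < 1) stop("empty sequence");

  Params P;
  NumericMatrix st = params["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) P.stack[a][b] = st(a, b);
  P.hairpin = as<double>(params["hairpin"]);
  P.bulge_open = as<double>(params["bulge_open"]);
  P.bulge_per = as<double>(params["bulge_per"]);
  P.internal_open = as<double>(params["internal_open"]);
  P.internal_per = as<double>(params["internal_per"]);
  P.multi_close = as<double>(params["multi_close"]);
  P.multi_branch = as<double>(params["multi_branch"]);
  P.min_loop = as<int>(params["min_loop"]);
  P.max_interior = as<int>(params["max_interior"]);

  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) {
    b[i] = base_code(seq[i]);
    if (b[i] < 0) stop("non-ACGU(T) character at position %d", i + 1);
  }

  // 0-based indices; V[i][j], WM[i][j] for i<=j
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > WM(n, std::vector<double>(n, INF));

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int pt = pair_type(b[i], b[j]);
      if (pt >= 0 && j - i - 1 >= P.min_loop) {
        double best = P.hairpin;  // hairpin closure
        // interior: inner pair (k,l)
        int kmax = std::min(j - 2, i + 1 + P.max_interior);
        for (int k = i + 1; k <= kmax; ++k) {
          int l1 = k - i - 1;
          int lmin = std::max(k + 1, j - 1 - P.max_interior);
          for (int l = j - 1; l >= lmin; --l) {
            if (V[k][l] >= INF) continue;
            int pt2 = pair_type(b[k], b[l]);
            double e = V[k][l] + loop_energy(P, l1, j - l - 1, pt, pt2);
            if (e < best) best = e;
          }
        }
        // multiloop: >= 2 branches inside
        for (int k = i + 2; k <= j - 2; ++k) {
          if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
          double e = P.multi_close + P.multi_branch +
            WM[i + 1][k] + WM[k + 1][j - 1];
          if (e < best) best = e;
        }
        V[i][j] = best;
      }
      // WM: at least one branch in [i, j], unpaired free
      double wm = INF;
      if (V[i][j] < INF) wm = V[i][j] + P.multi_branch;
      if (WM[i + 1][j] < wm && i + 1 <= j) wm = WM[i + 1][j];
      if (j - 1 >= i && WM[i][j - 1] < wm) wm = WM[i][j - 1];
      for (int k = i + 1; k < j; ++k) {
        if (WM[i][k] >= INF || WM[k + 1][j] >= INF) continue;
        double e = WM[i][k] + WM[k + 1][j];
        if (e < wm) wm = e;
      }
      WM[i][j] = wm;
    }
  }

  // exterior
  std::vector<double> W(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    double best = W[j - 1];
    for (int i = 1; i <= j; ++i) {
      if (V[i - 1][j - 1] >= INF) continue;
      double e = W[i - 1] + V[i - 1][j - 1];
      if (e < best) best = e;
    }
    W[j] = best;
  }
  double mfe = W[n];

  // traceback
  const double EPS = 1e-7;
  std::vector<int> partner(n, -1);
  struct Task { int type; int i; int j; };  // 0 = V, 1 = WM
  std::vector<Task> stack_t;

  {
    int j = n;
    while (j > 0) {
      if (std::fabs(W[j] - W[j - 1]) < EPS) { --j; continue; }
      int found = -1;
      for (int i = 1; i <= j; ++i) {
        if (V[i - 1][j - 1] < INF &&
            std::fabs(W[i - 1] + V[i - 1][j - 1] - W[j]) < EPS) { found = i; break; }
      }
      if (found < 0) { --j; continue; }
      stack_t.push_back({0, found - 1, j - 1});
      j = found - 1;
    }
  }

  while (!stack_t.empty()) {
    Task t = stack_t.back(); stack_t.pop_back();
    int i = t.i, j = t.j;
    if (t.type == 0) {
      partner[i] = j; partner[j] = i;
      double v = V[i][j];
      if (std::fabs(v - P.hairpin) < EPS) continue;
      int pt = pair_type(b[i], b[j]);
      bool done = false;
      int kmax = std::min(j - 2, i + 1 + P.max_interior);
      for (int k = i + 1; k <= kmax && !done; ++k) {
        int lmin = std::max(k + 1, j - 1 - P.max_interior);
        for (int l = j - 1; l >= lmin; --l) {
          if (V[k][l] >= INF) continue;
          int pt2 = pair_type(b[k], b[l]);
          if (std::fabs(V[k][l] + loop_energy(P, k - i - 1, j - l - 1, pt, pt2) - v) < EPS) {
            stack_t.push_back({0, k, l}); done = true; break;
          }
        }
      }
      if (done) continue;
      for (int k = i + 2; k <= j - 2; ++k) {
        if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
        if (std::fabs(P.multi_close + P.multi_branch + WM[i + 1][k] + WM[k + 1][j - 1] - v) < EPS) {
          stack_t.push_back({1, i + 1, k});
          stack_t.push_back({1, k + 1, j - 1});
          done = true; break;
        }
      }
    } else {
      double wm = WM[i][j];
      if (V[i][j] < INF && std::fabs(V[i][j] + P.multi_branch - wm) < EPS) {
        stack_t.push_back({0, i, j}); continue;
      }
      if (i + 1 <= j && std::fabs(WM[i + 1][j] - wm) < EPS) {
        stack_t.push_back({1, i + 1, j}); continue;
      }
      if (j - 1 >= i && std::fabs(WM[i][j - 1] - wm) < EPS) {
        stack_t.push_back({1, i, j - 1}); continue;
      }
      for (int k = i + 1; k < j; ++k) {
        if (WM[i][k] >= INF || WM[k + 1][j] >= INF) continue;
        if (std::fabs(WM[i][k] + WM[k + 1][j] - wm) < EPS) {
          stack_t.push_back({1, i, k});
          stack_t.push_back({1, k + 1, j});
          break;
        }
      }
    }
  }

  std::string db(n, '.');
  IntegerVector part(n);
  for (int i = 0; i < n; ++i) {
    if (partner[i] >= 0) db[i] = (partner[i] > i) ? '(' : ')';
    part[i] = partner[i] + 1;  // 1-based, 0 = unpaired
  }

  return List::create(_["structure"] = db, _["mfe"] = mfe, _["partner"] = part);
}
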