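#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Minimum-free-energy secondary structure by Zuker-style dynamic programming.
// Energy model: published nearest-neighbor stacking energies for Watson-Crick
// and G:U pairs (6x6 table passed from R), loop penalties linear in loop size.
// Pseudoknot-free; hairpin loops of at least `minloop` unpaired bases; internal
// and bulge loops capped at `maxloop` total unpaired bases.

static const double INF = 1e9;
static const double EPS = 1e-6;

// pair-type index: AU=0 UA=1 CG=2 GC=3 GU=4 UG=5 (DNA spelling, T==U)
static inline int ptype(char a, char b) {
  if (a == 'A' && b == 'T') return 0;
  if (a == 'T' && b == 'A') return 1;
  if (a == 'C' && b == 'G') return 2;
  if (a == 'G' && b == 'C') return 3;
  if (a == 'G' && b == 'T') return 4;
  if (a == 'T' && b == 'G') return 5;
  return -1;
}

struct FoldCtx {
  int n, minloop, maxloop;
  const std::string* s;
  std::vector<double> V, WM;
  std::vector<double> W;
  double stk[6][6];
  double ha, hb, ia, ib, ma, mb, mc;
  inline double& v(int i, int j) { return V[(size_t)i * n + j]; }
  inline double& wm(int i, int j) { return WM[(size_t)i * n + j]; }
  inline int pt(int i, int j) const { return ptype((*s)[i], (*s)[j]); }
};

static double calcV(FoldCtx& C, int i, int j);

static double calcWM(FoldCtx& C, int i, int j) {
  if (i > j) return INF;
  return C.wm(i, j);
}

// fill order: by increasing span
static void fill_tables(FoldCtx& C) {
  int n = C.n;
  for (int span = 1; span <= n - 1; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // --- V(i,j)
      double best = INF;
      int pt_ij = C.pt(i, j);
      if (pt_ij >= 0 && j - i - 1 >= C.minloop) {
        // hairpin
        best = C.ha + C.hb * (j - i - 1);
        // stack / internal / bulge
        for (int p = i + 1; p <= std::min(i + C.maxloop + 1, j - 2); ++p) {
          int n1 = p - i - 1;
          for (int q = j - 1; q > p; --q) {
            int n2 = j - q - 1;
            if (n1 + n2 > C.maxloop) break;
            double vin = C.v(p, q);
            if (vin >= INF) continue;
            double e;
            if (n1 == 0 && n2 == 0) {
              e = vin + C.stk[pt_ij][C.pt(p, q)];
            } else {
              e = vin + C.ia + C.ib * (n1 + n2);
            }
            if (e < best) best = e;
          }
        }
        // multiloop: >= 2 branches in i+1..j-1
        for (int k = i + 2; k <= j - 2; ++k) {
          double a = calcWM(C, i + 1, k), b = calcWM(C, k + 1, j - 1);
          if (a >= INF || b >= INF) continue;
          double e = C.ma + C.mb + a + b;
          if (e < best) best = e;
        }
      }
      C.v(i, j) = best;
      // --- WM(i,j): >=1 branch inside a multiloop
      double w = INF;
      if (C.v(i, j) < INF) w = C.v(i, j) + C.mb;
      if (i + 1 <= j) {
        double e = calcWM(C, i + 1, j);
        if (e < INF) w = std::min(w, e + C.mc);
        e = calcWM(C, i, j - 1);
        if (e < INF) w = std::min(w, e + C.mc);
      }
      for (int k = i; k < j; ++k) {
        double a = calcWM(C, i, k), b = calcWM(C, k + 1, j);
        if (a < INF && b < INF) w = std::min(w, a + b);
      }
      C.wm(i, j) = w;
    }
    // single bases: WM(i,i) handled below
  }
}

static void traceV(FoldCtx& C, int i, int j, std::string& db);

static void traceWM(FoldCtx& C, int i, int j, std::string& db) {
  if (i > j) return;
  double w = C.wm(i, j);
  if (C.v(i, j) < INF && std::fabs(w - (C.v(i, j) + C.mb)) < EPS) {
    traceV(C, i, j, db);
    return;
  }
  if (i + 1 <= j && C.wm(i + 1, j) < INF &&
      std::fabs(w - (C.wm(i + 1, j) + C.mc)) < EPS) {
    traceWM(C, i + 1, j, db);
    return;
  }
  if (i <= j - 1 && C.wm(i, j - 1) < INF &&
      std::fabs(w - (C.wm(i, j - 1) + C.mc)) < EPS) {
    traceWM(C, i, j - 1, db);
    return;
  }
  for (int k = i; k < j; ++k) {
    double a = C.wm(i, k), b = C.wm(k + 1, j);
    if (a < INF && b < INF && std::fabs(w - (a + b)) < EPS) {
      traceWM(C, i, k, db);
      traceWM(C, k + 1, j, db);
      return;
    }
  }
  Rcpp::stop("internal traceback failure (WM)");
}

static void traceV(FoldCtx& C, int i, int j, std::string& db) {
  db[i] = '(';
  db[j] = ')';
  double v = C.v(i, j);
  int pt_ij = C.pt(i, j);
  // hairpin?
  if (std::fabs(v - (C.ha + C.hb * (j - i - 1))) < EPS) return;
  for (int p = i + 1; p <= std::min(i + C.maxloop + 1, j - 2); ++p) {
    int n1 = p - i - 1;
    for (int q = j - 1; q > p; --q) {
      int n2 = j - q - 1;
      if (n1 + n2 > C.maxloop) break;
      double vin = C.v(p, q);
      if (vin >= INF) continue;
      double e = (n1 == 0 && n2 == 0)
        ? vin + C.stk[pt_ij][C.pt(p, q)]
        : vin + C.ia + C.ib * (n1 + n2);
      if (std::fabs(v - e) < EPS) {
        traceV(C, p, q, db);
        return;
      }
    }
  }
  for (int k = i + 2; k <= j - 2; ++k) {
    double a = C.wm(i + 1, k), b = C.wm(k + 1, j - 1);
    if (a >= INF || b >= INF) continue;
    if (std::fabs(v - (C.ma + C.mb + a + b)) < EPS) {
      traceWM(C, i + 1, k, db);
      traceWM(C, k + 1, j - 1, db);
      return;
    }
  }
  Rcpp::stop("internal traceback failure (V)");
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, NumericMatrix stack_table,
                  double hairpin_a, double hairpin_b,
                  double internal_a, double internal_b,
                  double multi_a, double multi_b, double multi_c,
                  int minloop, int maxloop) {
  int n = (int)seq.size();
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);
  FoldCtx C;
  C.n = n; C.s = &seq; C.minloop = minloop; C.maxloop = maxloop;
  C.ha = hairpin_a; C.hb = hairpin_b;
  C.ia = internal_a; C.ib = internal_b;
  C.ma = multi_a; C.mb = multi_b; C.mc = multi_c;
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      C.stk[a][b] = stack_table(a, b);
  C.V.assign((size_t)n * n, INF);
  C.WM.assign((size_t)n * n, INF);
  fill_tables(C);

  // external region: W[j] = best energy of prefix 0..j, unpaired bases free
  std::vector<double> W(n, 0.0);
  std::vector<int> pair_i(n, -1);
  for (int j = 0; j < n; ++j) {
    double best = (j > 0) ? W[j - 1] : 0.0;
    int argi = -1;
    for (int i = 0; i <= j - C.minloop - 1; ++i) {
      double vij = C.v(i, j);
      if (vij >= INF) continue;
      double e = (i > 0 ? W[i - 1] : 0.0) + vij;
      if (e < best - 1e-12) { best = e; argi = i; }
    }
    W[j] = best;
    pair_i[j] = argi;
  }

  std::string db(n, '.');
  int j = n - 1;
  while (j >= 0) {
    if (pair_i[j] >= 0 &&
        std::fabs(W[j] - ((pair_i[j] > 0 ? W[pair_i[j] - 1] : 0.0) +
                          C.v(pair_i[j], j))) < EPS) {
      int i = pair_i[j];
      traceV(C, i, j, db);
      j = i - 1;
    } else {
      --j;
    }
  }
  return List::create(_["structure"] = db, _["mfe"] = W[n - 1]);
}
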