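#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand with a simplified
// Turner-style nearest-neighbor model: stacking terms for the six canonical
// pairs (AU, UA, CG, GC, GU, UG), length-dependent hairpin/bulge/internal
// loop penalties and an affine multibranch term.  All energies are integer
// tenths of kcal/mol so that an independent re-evaluation of the reported
// structure reproduces the MFE exactly.

static const int INF = 100000000;

// base codes: A=0, C=1, G=2, U=3
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0; // AU
  if (a == 3 && b == 0) return 1; // UA
  if (a == 1 && b == 2) return 2; // CG
  if (a == 2 && b == 1) return 3; // GC
  if (a == 2 && b == 3) return 4; // GU
  if (a == 3 && b == 2) return 5; // UG
  return -1;
}

struct FoldParams {
  IntegerMatrix stack;       // 6x6, tenths kcal/mol
  IntegerVector hairpin;     // index = loop length
  IntegerVector bulge;       // index = loop length
  IntegerVector internal_;   // index = total unpaired
  int ml_a, ml_b, ml_c;
  int min_hairpin;
  int max_interior;
};

class Folder {
public:
  std::vector<int> s;
  int n;
  FoldParams p;
  std::vector<std::vector<int>> V, WM;
  std::vector<int> W;

  Folder(const std::vector<int>& seq, const FoldParams& par) : s(seq), p(par) {
    n = (int)s.size();
    V.assign(n, std::vector<int>(n, INF));
    WM.assign(n, std::vector<int>(n, INF));
    W.assign(n + 1, 0);
  }

  int loop_energy(int i, int j, int k, int l) {
    // interior loop / bulge / stack between pairs (i,j) and (k,l), i<k<l<j
    int u1 = k - i - 1, u2 = j - l - 1;
    if (u1 == 0 && u2 == 0) {
      return p.stack(pair_type(s[i], s[j]), pair_type(s[k], s[l]));
    }
    int tot = u1 + u2;
    if (tot > p.max_interior) return INF;
    if (u1 == 0 || u2 == 0) {
      if (tot >= p.bulge.size()) return INF;
      return p.bulge[tot];
    }
    if (tot >= p.internal_.size()) return INF;
    return p.internal_[tot];
  }

  void fill() {
    for (int j = 0; j < n; ++j) {
      for (int i = j - 1; i >= 0; --i) {
        // V(i,j)
        int pt = pair_type(s[i], s[j]);
        if (pt >= 0 && j - i - 1 >= p.min_hairpin) {
          int best = INF;
          int hl = j - i - 1;
          if (hl < p.hairpin.size() && p.hairpin[hl] < best) best = p.hairpin[hl];
          // stack / bulge / interior
          for (int k = i + 1; k < j; ++k) {
            int u1 = k - i - 1;
            if (u1 > p.max_interior) break;
            for (int l = j - 1; l > k; --l) {
              int u2 = j - l - 1;
              if (u1 + u2 > p.max_interior) break;
              if (V[k][l] >= INF) continue;
              int le = loop_energy(i, j, k, l);
              if (le >= INF) continue;
              int e = le + V[k][l];
              if (e < best) best = e;
            }
          }
          // multibranch closing: a + WM(i+1,k) + WM(k+1,j-1), >= 2 branches
          for (int k = i + 2; k < j - 1; ++k) {
            if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
            int e = p.ml_a + WM[i + 1][k] + WM[k + 1][j - 1];
            if (e < best) best = e;
          }
          V[i][j] = best;
        }
        // WM(i,j): >= 1 branch inside a multiloop
        int wm = INF;
        if (V[i][j] < INF) wm = std::min(wm, V[i][j] + p.ml_b);
        if (i + 1 <= j && WM[i + 1][j] < INF) wm = std::min(wm, WM[i + 1][j] + p.ml_c);
        if (j - 1 >= i && WM[i][j - 1] < INF) wm = std::min(wm, WM[i][j - 1] + p.ml_c);
        for (int k = i + 1; k < j; ++k) {
          if (WM[i][k - 1] < INF && WM[k][j] < INF)
            wm = std::min(wm, WM[i][k - 1] + WM[k][j]);
        }
        WM[i][j] = wm;
      }
    }
    // exterior
    for (int j = 1; j <= n; ++j) {
      W[j] = W[j - 1];
      for (int i = 1; i <= j; ++i) {
        if (V[i - 1][j - 1] < INF)
          W[j] = std::min(W[j], W[i - 1] + V[i - 1][j - 1]);
      }
    }
  }

  void traceV(int i, int j, std::string& db) {
    db[i] = '(';
    db[j] = ')';
    int hl = j - i - 1;
    if (hl < p.hairpin.size() && V[i][j] == p.hairpin[hl]) return;
    for (int k = i + 1; k < j; ++k) {
      int u1 = k - i - 1;
      if (u1 > p.max_interior) break;
      for (int l = j - 1; l > k; --l) {
        int u2 = j - l - 1;
        if (u1 + u2 > p.max_interior) break;
        if (V[k][l] >= INF) continue;
        int le = loop_energy(i, j, k, l);
        if (le >= INF) continue;
        if (V[i][j] == le + V[k][l]) { traceV(k, l, db); return; }
      }
    }
    for (int k = i + 2; k < j - 1; ++k) {
      if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
      if (V[i][j] == p.ml_a + WM[i + 1][k] + WM[k + 1][j - 1]) {
        traceWM(i + 1, k, db);
        traceWM(k + 1, j - 1, db);
        return;
      }
    }
    Rcpp::stop("traceback failure in V");
  }

  void traceWM(int i, int j, std::string& db) {
    if (V[i][j] < INF && WM[i][j] == V[i][j] + p.ml_b) { traceV(i, j, db); return; }
    if (i + 1 <= j && WM[i + 1][j] < INF && WM[i][j] == WM[i + 1][j] + p.ml_c) {
      traceWM(i + 1, j, db); return;
    }
    if (j - 1 >= i && WM[i][j - 1] < INF && WM[i][j] == WM[i][j - 1] + p.ml_c) {
      traceWM(i, j - 1, db); return;
    }
    for (int k = i + 1; k < j; ++k) {
      if (WM[i][k - 1] < INF && WM[k][j] < INF &&
          WM[i][j] == WM[i][k - 1] + WM[k][j]) {
        traceWM(i, k - 1, db);
        traceWM(k, j, db);
        return;
      }
    }
    Rcpp::stop("traceback failure in WM");
  }

  std::string traceback() {
    std::string db(n, '.');
    int j = n;
    while (j > 0) {
      if (W[j] == W[j - 1]) { --j; continue; }
      bool found = false;
      for (int i = 1; i <= j; ++i) {
        if (V[i - 1][j - 1] < INF && W[j] == W[i - 1] + V[i - 1][j - 1]) {
          traceV(i - 1, j - 1, db);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) Rcpp::stop("traceback failure in W");
    }
    return db;
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector codes, IntegerMatrix stack,
                  IntegerVector hairpin, IntegerVector bulge,
                  IntegerVector internal_loop,
                  int ml_a, int ml_b, int ml_c,
                  int min_hairpin, int max_interior) {
  FoldParams p{stack, hairpin, bulge, internal_loop,
               ml_a, ml_b, ml_c, min_hairpin, max_interior};
  std::vector<int> s(codes.begin(), codes.end());
  Folder f(s, p);
  f.fill();
  std::string db = f.traceback();
  return List::create(_["structure"] = db,
                      _["mfe_tenths"] = f.W[f.n]);
}

// Affine-gap (Gotoh) global alignment path between two profiles given a
// precomputed column-pair score matrix M (rows = columns of profile A,
// cols = columns of profile B).  Maximization; gap_open is the cost of the
// first gap column, gap_ext of each subsequent one (both >= 0).
// Deterministic tie-breaking: diagonal preferred, then gap in B, then in A.
// [[Rcpp::export(name = ".gotoh_path_cpp")]]
List gotoh_path_cpp(NumericMatrix M, double gap_open, double gap_ext) {
  int la = M.nrow(), lb = M.ncol();
  const double NEG = -1e18;
  NumericMatrix Sm(la + 1, lb + 1), Ga(la + 1, lb + 1), Gb(la + 1, lb + 1);
  // backpointers: state entered FROM (0 = Sm, 1 = Ga, 2 = Gb)
  IntegerMatrix Bs(la + 1, lb + 1), Bga(la + 1, lb + 1), Bgb(la + 1, lb + 1);
  Sm(0, 0) = 0; Ga(0, 0) = NEG; Gb(0, 0) = NEG;
  for (int i = 1; i <= la; ++i) {
    Sm(i, 0) = NEG;
    Gb(i, 0) = -gap_open - gap_ext * (i - 1);
    Bgb(i, 0) = (i == 1) ? 0 : 2;
    Ga(i, 0) = NEG;
  }
  for (int j = 1; j <= lb; ++j) {
    Sm(0, j) = NEG;
    Ga(0, j) = -gap_open - gap_ext * (j - 1);
    Bga(0, j) = (j == 1) ? 0 : 1;
    Gb(0, j) = NEG;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      // Sm: diagonal step; prefer Sm, then Gb, then Ga on ties
      double best = Sm(i - 1, j - 1); int bs = 0;
      if (Gb(i - 1, j - 1) > best) { best = Gb(i - 1, j - 1); bs = 2; }
      if (Ga(i - 1, j - 1) > best) { best = Ga(i - 1, j - 1); bs = 1; }
      Sm(i, j) = best + M(i - 1, j - 1);
      Bs(i, j) = bs;
      // Ga: gap in A consuming B column j
      double open_from = Sm(i, j - 1); int ba = 0;
      if (Gb(i, j - 1) > open_from) { open_from = Gb(i, j - 1); ba = 2; }
      double ext = Ga(i, j - 1) - gap_ext;
      if (open_from - gap_open >= ext) {
        Ga(i, j) = open_from - gap_open; Bga(i, j) = ba;
      } else {
        Ga(i, j) = ext; Bga(i, j) = 1;
      }
      // Gb: gap in B consuming A column i
      double open_from_b = Sm(i - 1, j); int bb = 0;
      if (Ga(i - 1, j) > open_from_b) { open_from_b = Ga(i - 1, j); bb = 1; }
      double extb = Gb(i - 1, j) - gap_ext;
      if (open_from_b - gap_open >= extb) {
        Gb(i, j) = open_from_b - gap_open; Bgb(i, j) = bb;
      } else {
        Gb(i, j) = extb; Bgb(i, j) = 2;
      }
    }
  }
  double fin = Sm(la, lb); int state = 0;
  if (Gb(la, lb) > fin) { fin = Gb(la, lb); state = 2; }
  if (Ga(la, lb) > fin) { fin = Ga(la, lb); state = 1; }
  std::vector<int> ai, bi;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      state = Bs(i, j);
      --i; --j;
    } else if (state == 1) {
      ai.push_back(0); bi.push_back(j);
      state = Bga(i, j);
      --j;
    } else {
      ai.push_back(i); bi.push_back(0);
      state = Bgb(i, j);
      --i;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = fin);
}
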