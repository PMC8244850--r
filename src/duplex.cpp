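#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Optimal intermolecular duplex between two short strands under the
// nearest-neighbor stacking model with bulge/internal interruptions.
// Strand 1 is read 5'->3', strand 2 is read 5'->3'; pairing is antiparallel
// so successive pairs consume strand 1 forward and strand 2 backward.
// Energies in integer tenths of kcal/mol; dH is accumulated along the
// dG-optimal pairing.

static const int INF = 100000000;

static inline int pair_type2(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// [[Rcpp::export(name = ".duplex_cpp")]]
List duplex_cpp(IntegerVector s1, IntegerVector s2,
                IntegerMatrix stack_dg, IntegerMatrix stack_dh,
                IntegerVector bulge, IntegerVector internal_loop,
                int init_dg, int init_dh, int max_interior) {
  int n1 = s1.size(), n2 = s2.size();
  // E[i][j]: best stack/loop sum for a duplex whose 5'-most pair (on strand 1)
  // is some (i0,j0) and whose current terminal pair is (i,j).
  std::vector<std::vector<int>> E(n1, std::vector<int>(n2, INF));
  std::vector<std::vector<int>> H(n1, std::vector<int>(n2, 0));
  std::vector<std::vector<std::pair<int,int>>> from(
      n1, std::vector<std::pair<int,int>>(n2, {-1, -1}));
  for (int i = 0; i < n1; ++i) {
    for (int j = n2 - 1; j >= 0; --j) {
      int pt = pair_type2(s1[i], s2[j]);
      if (pt < 0) continue;
      E[i][j] = 0;  // duplex starting at this pair
      H[i][j] = 0;
      for (int ip = 0; ip < i; ++ip) {
        for (int jp = n2 - 1; jp > j; --jp) {
          if (E[ip][jp] >= INF) continue;
          int ptp = pair_type2(s1[ip], s2[jp]);
          int u1 = i - ip - 1, u2 = jp - j - 1;
          int cost, dh = 0;
          if (u1 == 0 && u2 == 0) {
            cost = stack_dg(ptp, pt);
            dh = stack_dh(ptp, pt);
          } else if (u1 + u2 > max_interior) {
            continue;
          } else if (u1 == 0 || u2 == 0) {
            if (u1 + u2 >= bulge.size()) continue;
            cost = bulge[u1 + u2];
          } else {
            if (u1 + u2 >= internal_loop.size()) continue;
            cost = internal_loop[u1 + u2];
          }
          if (E[ip][jp] + cost < E[i][j]) {
            E[i][j] = E[ip][jp] + cost;
            H[i][j] = H[ip][jp] + dh;
            from[i][j] = {ip, jp};
          }
        }
      }
    }
  }
  int best = INF, bi = -1, bj = -1;
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j)
      if (E[i][j] < best) { best = E[i][j]; bi = i; bj = j; }
  if (best >= INF) {
    return List::create(_["dg_tenths"] = NA_INTEGER,
                        _["dh_tenths"] = NA_INTEGER,
                        _["pairs1"] = IntegerVector(0),
                        _["pairs2"] = IntegerVector(0));
  }
  // prefer the duplex reaching furthest toward the strand-1 3' end among ties
  for (int i = n1 - 1; i >= 0 && bi < n1; --i) {
    for (int j = 0; j < n2; ++j) {
      if (E[i][j] == best) { bi = i; bj = j; i = -1; break; }
    }
  }
  std::vector<int> p1, p2;
  int ci = bi, cj = bj;
  while (ci >= 0) {
    p1.push_back(ci + 1);
    p2.push_back(cj + 1);
    auto pr = from[ci][cj];
    ci = pr.first; cj = pr.second;
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["dg_tenths"] = best + init_dg,
                      _["dh_tenths"] = H[bi][bj] + init_dh,
                      _["pairs1"] = wrap(p1),
                      _["pairs2"] = wrap(p2));
}
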