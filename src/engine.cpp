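// Event-driven (Gillespie) kernel for the lattice cell-sorting dynamics.
//
// Edges of the periodic square lattice are indexed e = 2*s + d with
// s = row*L + col (row-major, 0-based) and d = 0 (right neighbour) or
// d = 1 (down neighbour).  A complete binary sum tree over the per-edge
// switch rates gives O(log E) sampling and O(log E) updates; internal
// nodes are always recomputed as the exact sum of their children, and the
// whole tree is additionally rebuilt from freshly computed rates every
// `refreshEvery` switches because individual rates span many orders of
// magnitude (exp of +-8*max|beta|).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

class Engine {
public:
  int L, N, nSites, nEdges, nLeaves;
  std::vector<int> type;   // per site, row-major
  std::vector<int> nbr;    // 4 per site: up, down, left, right
  std::vector<double> beta; // N*N, column-major (symmetric)
  std::vector<double> tree; // size 2*nLeaves, leaves at [nLeaves, ...)
  long long d;             // homotypic contact count, maintained exactly

  Engine(const IntegerMatrix& types, const NumericMatrix& b)
    : L(types.nrow()), N(b.nrow()), nSites(L * L), nEdges(2 * L * L) {
    if (types.ncol() != L) stop("types matrix must be square");
    type.resize(nSites);
    for (int r = 0; r < L; ++r)
      for (int c = 0; c < L; ++c)
        type[r * L + c] = types(r, c);
    beta.assign(b.begin(), b.end());
    nbr.resize(4 * nSites);
    for (int r = 0; r < L; ++r) {
      for (int c = 0; c < L; ++c) {
        int s = r * L + c;
        nbr[4 * s + 0] = ((r - 1 + L) % L) * L + c;
        nbr[4 * s + 1] = ((r + 1) % L) * L + c;
        nbr[4 * s + 2] = r * L + (c - 1 + L) % L;
        nbr[4 * s + 3] = r * L + (c + 1) % L;
      }
    }
    nLeaves = 1;
    while (nLeaves < nEdges) nLeaves <<= 1;
    tree.assign(2 * nLeaves, 0.0);
    rebuild();
    computeD();
  }

  inline double B(int i, int j) const { return beta[i + N * j]; }

  inline int edgeOther(int e) const {
    int s = e >> 1;
    return (e & 1) ? nbr[4 * s + 1] : nbr[4 * s + 3];
  }

  double edgeRate(int e) const {
    int x = e >> 1, y = edgeOther(e);
    int tx = type[x], ty = type[y];
    if (tx == ty) return 0.0;
    double ex = 0.0;
    for (int k = 0; k < 4; ++k) ex += B(tx, type[nbr[4 * x + k]]);
    for (int k = 0; k < 4; ++k) ex += B(ty, type[nbr[4 * y + k]]);
    return std::exp(-ex);
  }

  void setLeaf(int e, double v) {
    int i = nLeaves + e;
    tree[i] = v;
    for (i >>= 1; i >= 1; i >>= 1) tree[i] = tree[2 * i] + tree[2 * i + 1];
  }

  void rebuild() {
    for (int e = 0; e < nEdges; ++e) tree[nLeaves + e] = edgeRate(e);
    for (int e = nEdges; e < nLeaves; ++e) tree[nLeaves + e] = 0.0;
    for (int i = nLeaves - 1; i >= 1; --i)
      tree[i] = tree[2 * i] + tree[2 * i + 1];
  }

  void computeD() {
    long long dd = 0;
    for (int s = 0; s < nSites; ++s) {
      if (type[s] == type[nbr[4 * s + 1]]) ++dd; // down edge
      if (type[s] == type[nbr[4 * s + 3]]) ++dd; // right edge
    }
    d = dd;
  }

  int sample(double u) const {
    int i = 1;
    while (i < nLeaves) {
      if (u < tree[2 * i]) i = 2 * i;
      else { u -= tree[2 * i]; i = 2 * i + 1; }
    }
    int e = i - nLeaves;
    if (tree[i] <= 0.0) { // floating-point edge case: walk to a live event
      for (int k = 1; k <= nEdges; ++k) {
        int cand = (e + k) % nEdges;
        if (tree[nLeaves + cand] > 0.0) return cand;
      }
    }
    return e;
  }

  void applySwitch(int e) {
    int x = e >> 1, y = edgeOther(e);
    int tx = type[x], ty = type[y];
    int before = 0, after = 0;
    for (int k = 0; k < 4; ++k) {
      int z = nbr[4 * x + k];
      if (z == y) continue;
      if (type[z] == tx) ++before;
      if (type[z] == ty) ++after;
    }
    for (int k = 0; k < 4; ++k) {
      int z = nbr[4 * y + k];
      if (z == x) continue;
      if (type[z] == ty) ++before;
      if (type[z] == tx) ++after;
    }
    d += after - before;
    type[x] = ty;
    type[y] = tx;
    // rates change only for edges incident to {x, y} or their neighbours
    int sites[10];
    int ns = 0;
    sites[ns++] = x;
    sites[ns++] = y;
    for (int k = 0; k < 4; ++k) {
      int z = nbr[4 * x + k];
      bool dup = false;
      for (int j = 0; j < ns; ++j) if (sites[j] == z) { dup = true; break; }
      if (!dup) sites[ns++] = z;
    }
    for (int k = 0; k < 4; ++k) {
      int z = nbr[4 * y + k];
      bool dup = false;
      for (int j = 0; j < ns; ++j) if (sites[j] == z) { dup = true; break; }
      if (!dup) sites[ns++] = z;
    }
    int edges[40];
    int ne = 0;
    for (int j = 0; j < ns; ++j) {
      int s = sites[j];
      edges[ne++] = 2 * s;                 // right edge of s
      edges[ne++] = 2 * s + 1;             // down edge of s
      edges[ne++] = 2 * nbr[4 * s + 2];    // right edge of left neighbour
      edges[ne++] = 2 * nbr[4 * s + 0] + 1; // down edge of up neighbour
    }
    std::sort(edges, edges + ne);
    ne = (int)(std::unique(edges, edges + ne) - edges);
    for (int j = 0; j < ne; ++j) setLeaf(edges[j], edgeRate(edges[j]));
  }
};

} // namespace

// [[Rcpp::export(name = ".dmm_run")]]
List dmm_run(IntegerMatrix types, NumericMatrix beta, double nSwitches,
             int stride, bool recordWaiting, int refreshEvery) {
  Engine eng(types, beta);
  long long n = (long long)nSwitches;
  if (n < 0) stop("nSwitches must be nonnegative");

  std::vector<double> recIdx, recD, waits;
  recIdx.reserve(stride > 0 ? (size_t)(n / stride + 2) : 2);
  recD.reserve(recIdx.capacity());
  if (recordWaiting) waits.reserve((size_t)n);
  recIdx.push_back(0.0);
  recD.push_back((double)eng.d);

  for (long long t = 1; t <= n; ++t) {
    double total = eng.tree[1];
    if (!(total > 0.0))
      stop("frozen state: total switch rate is not positive");
    double u = unif_rand() * total;         // pair first,
    int e = eng.sample(u);
    double w = -std::log(unif_rand()) / total; // then waiting time
    eng.applySwitch(e);
    if (recordWaiting) waits.push_back(w);
    if (refreshEvery > 0 && (t % refreshEvery) == 0) eng.rebuild();
    if ((stride > 0 && (t % stride) == 0) || t == n) {
      recIdx.push_back((double)t);
      recD.push_back((double)eng.d);
    }
    if ((t & 0xFFFFF) == 0) checkUserInterrupt();
  }

  IntegerMatrix outTypes(eng.L, eng.L);
  for (int r = 0; r < eng.L; ++r)
    for (int c = 0; c < eng.L; ++c)
      outTypes(r, c) = eng.type[r * eng.L + c];
  NumericVector rates(eng.nEdges);
  for (int e = 0; e < eng.nEdges; ++e) rates[e] = eng.tree[eng.nLeaves + e];

  return List::create(
    _["switch_index"] = NumericVector(recIdx.begin(), recIdx.end()),
    _["d"] = NumericVector(recD.begin(), recD.end()),
    _["waiting_times"] = recordWaiting
      ? NumericVector(waits.begin(), waits.end()) : NumericVector(0),
    _["types"] = outTypes,
    _["edge_rates"] = rates,
    _["total_rate"] = eng.tree[1]);
}

// [[Rcpp::export(name = ".dmm_edge_rates")]]
NumericVector dmm_edge_rates(IntegerMatrix types, NumericMatrix beta) {
  Engine eng(types, beta);
  NumericVector rates(eng.nEdges);
  for (int e = 0; e < eng.nEdges; ++e) rates[e] = eng.tree[eng.nLeaves + e];
  return rates;
}
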