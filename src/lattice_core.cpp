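#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Uniform-grid spatial hash used by the Gabriel graph construction.
struct BinGrid {
  double cell;
  double lo[3];
  int dims[3];
  std::vector< std::vector<int> > bins;

  BinGrid(const NumericMatrix& pos, double cell_size) : cell(cell_size) {
    const int n = pos.nrow();
    double hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], pos(i, d));
        hi[d] = std::max(hi[d], pos(i, d));
      }
    int nb = 1;
    for (int d = 0; d < 3; ++d) {
      dims[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
      nb *= dims[d];
    }
    bins.resize(nb);
    for (int i = 0; i < n; ++i) bins[index_of(pos, i)].push_back(i);
  }

  int index_of(const NumericMatrix& pos, int i) const {
    int ix[3];
    for (int d = 0; d < 3; ++d) {
      ix[d] = (int)std::floor((pos(i, d) - lo[d]) / cell);
      if (ix[d] < 0) ix[d] = 0;
      if (ix[d] >= dims[d]) ix[d] = dims[d] - 1;
    }
    return ix[0] + dims[0] * (ix[1] + dims[1] * ix[2]);
  }

  // all points within radius r of point i (excluding i), via 27-neighborhood
  void neighbors_within(const NumericMatrix& pos, int i, double r,
                        std::vector<int>& out) const {
    out.clear();
    const double r2 = r * r;
    int ix[3];
    for (int d = 0; d < 3; ++d) {
      ix[d] = (int)std::floor((pos(i, d) - lo[d]) / cell);
      if (ix[d] < 0) ix[d] = 0;
      if (ix[d] >= dims[d]) ix[d] = dims[d] - 1;
    }
    int reach = (int)std::ceil(r / cell);
    for (int dz = -reach; dz <= reach; ++dz) {
      int z = ix[2] + dz; if (z < 0 || z >= dims[2]) continue;
      for (int dy = -reach; dy <= reach; ++dy) {
        int y = ix[1] + dy; if (y < 0 || y >= dims[1]) continue;
        for (int dx = -reach; dx <= reach; ++dx) {
          int x = ix[0] + dx; if (x < 0 || x >= dims[0]) continue;
          const std::vector<int>& b = bins[x + dims[0] * (y + dims[1] * z)];
          for (size_t k = 0; k < b.size(); ++k) {
            int j = b[k];
            if (j == i) continue;
            double d2 = 0;
            for (int d = 0; d < 3; ++d) {
              double dd = pos(i, d) - pos(j, d);
              d2 += dd * dd;
            }
            if (d2 <= r2) out.push_back(j);
          }
        }
      }
    }
  }
};

// Gabriel graph: edge (i,j) iff no third point lies inside (or on, within tol)
// the sphere having segment ij as diameter.  Closed-ball ties are excluded so
// the unjittered cubic grid yields exactly the 6 face neighbors.  Candidate
// edges are capped at length r_max.
// [[Rcpp::export]]
List gabriel_edges_cpp(NumericMatrix pos, double bin_size, double r_max,
                       double tol) {
  const int n = pos.nrow();
  BinGrid grid(pos, bin_size);
  std::vector<int> ei, ej;
  std::vector<int> cand, interf;
  const double r_max2 = r_max * r_max;

  for (int i = 0; i < n; ++i) {
    grid.neighbors_within(pos, i, r_max, cand);
    std::vector<int> cand_i(cand);  // copy: `cand` reused below
    for (size_t a = 0; a < cand_i.size(); ++a) {
      int j = cand_i[a];
      if (j <= i) continue;
      double d2 = 0;
      double mid[3];
      for (int d = 0; d < 3; ++d) {
        double dd = pos(i, d) - pos(j, d);
        d2 += dd * dd;
        mid[d] = 0.5 * (pos(i, d) + pos(j, d));
      }
      if (d2 > r_max2) continue;
      const double rad2 = 0.25 * d2;
      // any point inside the closed diametral ball kills the edge;
      // such a point is within distance |ij| of i, hence among cand_i
      bool ok = true;
      for (size_t b = 0; b < cand_i.size() && ok; ++b) {
        int k = cand_i[b];
        if (k == j) continue;
        double dk2 = 0;
        for (int d = 0; d < 3; ++d) {
          double dd = pos(k, d) - mid[d];
          dk2 += dd * dd;
        }
        if (dk2 <= rad2 + tol) ok = false;
      }
      if (ok) { ei.push_back(i + 1); ej.push_back(j + 1); }
    }
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej));
}

// All unordered point pairs closer than `cutoff` (1-based indices).
// [[Rcpp::export]]
List close_pairs_cpp(NumericMatrix pos, double bin_size, double cutoff) {
  const int n = pos.nrow();
  BinGrid grid(pos, bin_size);
  std::vector<int> ei, ej;
  std::vector<double> ed;
  std::vector<int> cand;
  for (int i = 0; i < n; ++i) {
    grid.neighbors_within(pos, i, cutoff, cand);
    for (size_t a = 0; a < cand.size(); ++a) {
      int j = cand[a];
      if (j <= i) continue;
      double d2 = 0;
      for (int d = 0; d < 3; ++d) {
        double dd = pos(i, d) - pos(j, d);
        d2 += dd * dd;
      }
      ei.push_back(i + 1);
      ej.push_back(j + 1);
      ed.push_back(std::sqrt(d2));
    }
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej),
                      _["d"] = wrap(ed));
}

// Breadth-first search for the nearest site satisfying `target`.  Sites
// with traversable = FALSE may terminate a search (when they are targets)
// but are never expanded; with traversable all-TRUE this is the plain
// occupancy-blind hop distance.  Distances are hop counts; search stops
// after level `cap`.  Deterministic: queue is FIFO, adjacency lists are
// stored sorted, and among targets at the minimal level the smallest site
// index wins.  Returns dist = -1 when nothing is found.
// adj_ptr: 0-based offsets of length n+1; adj_idx: 1-based site ids.
// [[Rcpp::export]]
List bfs_nearest_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                     LogicalVector target, int start, int cap,
                     bool want_path, LogicalVector traversable) {
  const int n = adj_ptr.size() - 1;
  if (start < 1 || start > n) stop("site index out of range");
  const bool use_trav = traversable.size() == n;
  std::vector<int> dist(n, -1), parent(n, -1);
  std::queue<int> q;
  const int s = start - 1;
  dist[s] = 0;
  q.push(s);
  int found = -1, found_level = -1;
  while (!q.empty()) {
    int v = q.front(); q.pop();
    if (found_level >= 0 && dist[v] >= found_level) break;
    if (dist[v] >= cap) continue;
    for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e) {
      int w = adj_idx[e] - 1;
      if (dist[w] >= 0) continue;
      dist[w] = dist[v] + 1;
      parent[w] = v;
      if (target[w]) {
        if (found_level < 0) found_level = dist[w];
        if (dist[w] == found_level && (found < 0 || w < found)) found = w;
      }
      if (!use_trav || traversable[w]) q.push(w);
    }
  }
  if (target[s]) { found = s; found_level = 0; }  // degenerate query
  if (found < 0)
    return List::create(_["dist"] = -1, _["site"] = NA_INTEGER,
                        _["path"] = IntegerVector(0));
  IntegerVector path(0);
  if (want_path) {
    std::vector<int> rev;
    for (int v = found; v >= 0; v = parent[v]) {
      rev.push_back(v + 1);
      if (v == s) break;
    }
    std::reverse(rev.begin(), rev.end());
    path = wrap(rev);
  }
  return List::create(_["dist"] = found_level, _["site"] = found + 1,
                      _["path"] = path);
}

// Flood fill of the free (unoccupied) site set from the given seed sites:
// marks the free region connected to the medium boundary.  Free sites left
// unmarked are interior holes (lysed regions) enclosed by the spheroid.
// [[Rcpp::export]]
LogicalVector exterior_free_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                                LogicalVector free_site,
                                IntegerVector seeds) {
  const int n = adj_ptr.size() - 1;
  LogicalVector out(n, false);
  std::queue<int> q;
  for (int k = 0; k < seeds.size(); ++k) {
    int s = seeds[k] - 1;
    if (free_site[s] && !out[s]) { out[s] = true; q.push(s); }
  }
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e) {
      int w = adj_idx[e] - 1;
      if (free_site[w] && !out[w]) { out[w] = true; q.push(w); }
    }
  }
  return out;
}

// Hop distances from `start` to every site (capped); -1 beyond the cap.
// [[Rcpp::export]]
IntegerVector bfs_distances_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                                int start, int cap) {
  const int n = adj_ptr.size() - 1;
  if (start < 1 || start > n) stop("site index out of range");
  std::vector<int> dist(n, -1);
  std::queue<int> q;
  dist[start - 1] = 0;
  q.push(start - 1);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    if (dist[v] >= cap) continue;
    for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e) {
      int w = adj_idx[e] - 1;
      if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
  }
  return wrap(dist);
}
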