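#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

// Vietoris-Rips persistent homology by boundary-matrix reduction over Z/2.
//
// Simplices are enumerated explicitly (edges, triangles, tetrahedra) with
// filtration value = longest pairwise distance, and columns are reduced with
// the standard "add earlier column with the same pivot" algorithm.  H0 is
// handled separately by a union-find pass over the sorted edges, which also
// marks the edges that create 1-cycles.  This is adequate for the cloud
// sizes met here (a few hundred points at dimension 1, small fixtures at
// dimension 2); it is not meant to compete with specialised libraries.

namespace {

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra == rb) return false;
    parent[ra] = rb;
    return true;
  }
};

// symmetric difference of two sorted int vectors (Z/2 column addition)
std::vector<int> symdiff(const std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

struct Bar { int dim; double birth; double death; };

// Reduce columns (boundaries of (k+1)-simplices expressed in k-simplex row
// indices, already sorted by filtration) and emit finite k-dimensional bars.
// row_filt: filtration value of each k-simplex (row), col_filt: of columns.
// creator_rows: on exit, rows never used as a pivot (potential (k+1)-cycle
// creators are the *columns* that reduce to zero; their indices are pushed
// into zero_cols).
void reduce_columns(std::vector<std::vector<int> >& cols,
                    const std::vector<double>& col_filt,
                    const std::vector<double>& row_filt,
                    std::vector<char>& row_paired,
                    std::vector<int>& zero_cols,
                    int dim, std::vector<Bar>& bars) {
  std::unordered_map<int, int> pivot_owner; // row -> column index
  for (size_t j = 0; j < cols.size(); ++j) {
    std::vector<int>& col = cols[j];
    while (!col.empty()) {
      int piv = col.back();
      std::unordered_map<int, int>::iterator it = pivot_owner.find(piv);
      if (it == pivot_owner.end()) break;
      col = symdiff(col, cols[it->second]);
    }
    if (col.empty()) {
      zero_cols.push_back((int)j);
    } else {
      int piv = col.back();
      pivot_owner[piv] = (int)j;
      row_paired[piv] = 1;
      double b = row_filt[piv], d = col_filt[j];
      if (d > b) bars.push_back(Bar{dim, b, d});
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".rips_persistence_cpp")]]
DataFrame rips_persistence_cpp(NumericMatrix dist, int max_dim, double threshold) {
  const int n = dist.nrow();
  std::vector<Bar> bars;
  const double inf = R_PosInf;

  // ---- edges, sorted by (filtration, i, j) ----
  struct Edge { double w; int i, j; };
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = dist(i, j);
      if (w <= threshold) edges.push_back(Edge{w, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int ne = (int)edges.size();

  // ---- H0 via union-find; edges that close a cycle are H1 creators ----
  UnionFind uf(n);
  std::vector<char> edge_creates_cycle(ne, 0);
  int components = n;
  for (int e = 0; e < ne; ++e) {
    if (uf.unite(edges[e].i, edges[e].j)) {
      bars.push_back(Bar{0, 0.0, edges[e].w});
      --components;
    } else {
      edge_creates_cycle[e] = 1;
    }
  }
  for (int c = 0; c < components; ++c) bars.push_back(Bar{0, 0.0, inf});

  std::vector<char> edge_paired(ne, 0);

  if (max_dim >= 1 && ne > 0) {
    // edge index lookup by vertex pair
    std::unordered_map<long long, int> edge_id;
    edge_id.reserve((size_t)ne * 2);
    for (int e = 0; e < ne; ++e)
      edge_id[(long long)edges[e].i * n + edges[e].j] = e;
    std::vector<double> edge_filt(ne);
    for (int e = 0; e < ne; ++e) edge_filt[e] = edges[e].w;

    // ---- triangles ----
    struct Tri { double w; int a, b, c; }; // a<b<c vertex ids
    std::vector<Tri> tris;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dij = dist(i, j);
        if (dij > threshold) continue;
        for (int k = j + 1; k < n; ++k) {
          double w = std::max(dij, std::max(dist(i, k), dist(j, k)));
          if (w <= threshold) tris.push_back(Tri{w, i, j, k});
        }
      }
    std::sort(tris.begin(), tris.end(), [](const Tri& a, const Tri& b) {
      if (a.w != b.w) return a.w < b.w;
      if (a.a != b.a) return a.a < b.a;
      if (a.b != b.b) return a.b < b.b;
      return a.c < b.c;
    });
    const int nt = (int)tris.size();

    std::vector<std::vector<int> > tcols(nt);
    std::vector<double> tri_filt(nt);
    for (int t = 0; t < nt; ++t) {
      const Tri& tr = tris[t];
      std::vector<int> col(3);
      col[0] = edge_id[(long long)tr.a * n + tr.b];
      col[1] = edge_id[(long long)tr.a * n + tr.c];
      col[2] = edge_id[(long long)tr.b * n + tr.c];
      std::sort(col.begin(), col.end());
      tcols[t] = col;
      tri_filt[t] = tr.w;
    }
    std::vector<int> tri_zero_cols;
    reduce_columns(tcols, tri_filt, edge_filt, edge_paired, tri_zero_cols, 1, bars);

    // unpaired cycle-creating edges: infinite H1 bars (within the threshold)
    for (int e = 0; e < ne; ++e)
      if (edge_creates_cycle[e] && !edge_paired[e])
        bars.push_back(Bar{1, edges[e].w, inf});

    if (max_dim >= 2 && nt > 0) {
      // triangle index lookup
      std::unordered_map<long long, int> tri_id;
      tri_id.reserve((size_t)nt * 2);
      for (int t = 0; t < nt; ++t) {
        const Tri& tr = tris[t];
        tri_id[((long long)tr.a * n + tr.b) * n + tr.c] = t;
      }
      // ---- tetrahedra ----
      struct Tet { double w; int a, b, c, d; };
      std::vector<Tet> tets;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          if (dist(i, j) > threshold) continue;
          for (int k = j + 1; k < n; ++k) {
            double w3 = std::max(dist(i, j), std::max(dist(i, k), dist(j, k)));
            if (w3 > threshold) continue;
            for (int l = k + 1; l < n; ++l) {
              double w = std::max(w3, std::max(dist(i, l),
                           std::max(dist(j, l), dist(k, l))));
              if (w <= threshold) tets.push_back(Tet{w, i, j, k, l});
            }
          }
        }
      std::sort(tets.begin(), tets.end(), [](const Tet& a, const Tet& b) {
        if (a.w != b.w) return a.w < b.w;
        if (a.a != b.a) return a.a < b.a;
        if (a.b != b.b) return a.b < b.b;
        if (a.c != b.c) return a.c < b.c;
        return a.d < b.d;
      });
      const int nq = (int)tets.size();
      std::vector<std::vector<int> > qcols(nq);
      std::vector<double> tet_filt(nq);
      std::vector<char> tri_paired(nt, 0);
      for (int q = 0; q < nq; ++q) {
        const Tet& te = tets[q];
        std::vector<int> col(4);
        col[0] = tri_id[((long long)te.a * n + te.b) * n + te.c];
        col[1] = tri_id[((long long)te.a * n + te.b) * n + te.d];
        col[2] = tri_id[((long long)te.a * n + te.c) * n + te.d];
        col[3] = tri_id[((long long)te.b * n + te.c) * n + te.d];
        std::sort(col.begin(), col.end());
        qcols[q] = col;
        tet_filt[q] = te.w;
      }
      std::vector<int> tet_zero_cols;
      reduce_columns(qcols, tet_filt, tri_filt, tri_paired, tet_zero_cols, 2, bars);
      // infinite H2 bars: zero-reduced triangle columns never paired by a tet
      std::vector<char> tri_is_cycle(nt, 0);
      for (size_t z = 0; z < tri_zero_cols.size(); ++z)
        tri_is_cycle[tri_zero_cols[z]] = 1;
      for (int t = 0; t < nt; ++t)
        if (tri_is_cycle[t] && !tri_paired[t])
          bars.push_back(Bar{2, tri_filt[t], inf});
    }
  }

  const int nb = (int)bars.size();
  IntegerVector dim(nb);
  NumericVector birth(nb), death(nb);
  for (int b = 0; b < nb; ++b) {
    dim[b] = bars[b].dim; birth[b] = bars[b].birth; death[b] = bars[b].death;
  }
  return DataFrame::create(_["dimension"] = dim, _["birth"] = birth,
                           _["death"] = death);
}
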