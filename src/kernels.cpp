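#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared cell-list helper (non-periodic). Cells of size cs over the bbox of
// pts; linear cell index -> chained point list via head/next arrays.
// ---------------------------------------------------------------------------
struct CellList {
  double lo[3];
  double cs;
  int nd[3];
  std::vector<int> head; // cell -> first point (-1 none)
  std::vector<int> nxt;  // point -> next point in cell

  void build(const NumericMatrix &pts, double cell_size) {
    int n = pts.nrow();
    cs = cell_size;
    for (int d = 0; d < 3; ++d) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int i = 0; i < n; ++i) {
        double v = pts(i, d);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      lo[d] = mn;
      nd[d] = std::max(1, (int)std::floor((mx - mn) / cs) + 1);
    }
    head.assign((size_t)nd[0] * nd[1] * nd[2], -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(pts(i, 0), pts(i, 1), pts(i, 2));
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int clampi(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  inline int cell_of(double x, double y, double z) const {
    int i = clampi((int)std::floor((x - lo[0]) / cs), nd[0]);
    int j = clampi((int)std::floor((y - lo[1]) / cs), nd[1]);
    int k = clampi((int)std::floor((z - lo[2]) / cs), nd[2]);
    return (k * nd[1] + j) * nd[0] + i;
  }
};

// ---------------------------------------------------------------------------
// k-nearest neighbours of the first n_query points among all rows of pts.
// Neighbour search expands cell shells until k neighbours are guaranteed.
// Returns 1-based indices, self excluded.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix pts, int n_query, int k, double cell_size) {
  int n = pts.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  CellList cl;
  cl.build(pts, cell_size);
  IntegerMatrix out(n_query, k);
  std::vector<int> cand;
  std::vector<double> cd;
  for (int q = 0; q < n_query; ++q) {
    double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
    int ci = (int)std::floor((x - cl.lo[0]) / cl.cs);
    int cj = (int)std::floor((y - cl.lo[1]) / cl.cs);
    int ck = (int)std::floor((z - cl.lo[2]) / cl.cs);
    int ring = 1;
    for (;; ++ring) {
      cand.clear();
      cd.clear();
      for (int dk = -ring; dk <= ring; ++dk) {
        int kk = ck + dk;
        if (kk < 0 || kk >= cl.nd[2]) continue;
        for (int dj = -ring; dj <= ring; ++dj) {
          int jj = cj + dj;
          if (jj < 0 || jj >= cl.nd[1]) continue;
          for (int di = -ring; di <= ring; ++di) {
            int ii = ci + di;
            if (ii < 0 || ii >= cl.nd[0]) continue;
            int c = (kk * cl.nd[1] + jj) * cl.nd[0] + ii;
            for (int p = cl.head[c]; p != -1; p = cl.nxt[p]) {
              if (p == q) continue;
              double dx = pts(p, 0) - x, dy = pts(p, 1) - y, dz = pts(p, 2) - z;
              double d2 = dx * dx + dy * dy + dz * dz;
              cand.push_back(p);
              cd.push_back(d2);
            }
          }
        }
      }
      // enough candidates and the kth best is inside the guaranteed radius?
      if ((int)cand.size() >= k) {
        std::vector<int> ord(cand.size());
        for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
        std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                          [&](int a, int b) { return cd[a] < cd[b]; });
        double safe = ring * cl.cs; // closest possible point outside the ring
        if (std::sqrt(cd[ord[k - 1]]) <= safe ||
            (ring >= cl.nd[0] && ring >= cl.nd[1] && ring >= cl.nd[2])) {
          for (int i = 0; i < k; ++i) out(q, i) = cand[ord[i]] + 1;
          break;
        }
      } else if (ring >= cl.nd[0] && ring >= cl.nd[1] && ring >= cl.nd[2]) {
        stop("cpp_knn: fewer candidates than k");
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Nearest row of pts for every row of query (1-based).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_nearest(NumericMatrix query, NumericMatrix pts,
                          double cell_size) {
  CellList cl;
  cl.build(pts, cell_size);
  int m = query.nrow();
  IntegerVector out(m);
  for (int q = 0; q < m; ++q) {
    double x = query(q, 0), y = query(q, 1), z = query(q, 2);
    int ci = (int)std::floor((x - cl.lo[0]) / cl.cs);
    int cj = (int)std::floor((y - cl.lo[1]) / cl.cs);
    int ck = (int)std::floor((z - cl.lo[2]) / cl.cs);
    int best = -1;
    double bd2 = R_PosInf;
    for (int ring = 0;; ++ring) {
      bool any_cell = false;
      for (int dk = -ring; dk <= ring; ++dk) {
        int kk = ck + dk;
        if (kk < 0 || kk >= cl.nd[2]) continue;
        for (int dj = -ring; dj <= ring; ++dj) {
          int jj = cj + dj;
          if (jj < 0 || jj >= cl.nd[1]) continue;
          for (int di = -ring; di <= ring; ++di) {
            if (ring > 0 && std::abs(di) != ring && std::abs(dj) != ring &&
                std::abs(dk) != ring)
              continue; // shell only
            int ii = ci + di;
            if (ii < 0 || ii >= cl.nd[0]) continue;
            any_cell = true;
            int c = (kk * cl.nd[1] + jj) * cl.nd[0] + ii;
            for (int p = cl.head[c]; p != -1; p = cl.nxt[p]) {
              double dx = pts(p, 0) - x, dy = pts(p, 1) - y, dz = pts(p, 2) - z;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < bd2) { bd2 = d2; best = p; }
            }
          }
        }
      }
      double safe = ring * cl.cs;
      if (best >= 0 && std::sqrt(bd2) <= safe) break;
      if (!any_cell && ring > cl.nd[0] + cl.nd[1] + cl.nd[2]) break;
    }
    out[q] = best + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mean of vals rows over pts within radius of each query row; rows with no
// neighbour are left at zero (caller falls back to nearest point).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_radius_mean(NumericMatrix query, NumericMatrix pts,
                              NumericMatrix vals, double radius) {
  CellList cl;
  cl.build(pts, radius);
  int m = query.nrow(), nv = vals.ncol();
  NumericMatrix out(m, nv);
  double r2 = radius * radius;
  for (int q = 0; q < m; ++q) {
    double x = query(q, 0), y = query(q, 1), z = query(q, 2);
    int ci = (int)std::floor((x - cl.lo[0]) / cl.cs);
    int cj = (int)std::floor((y - cl.lo[1]) / cl.cs);
    int ck = (int)std::floor((z - cl.lo[2]) / cl.cs);
    int cnt = 0;
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = ck + dk;
      if (kk < 0 || kk >= cl.nd[2]) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = cj + dj;
        if (jj < 0 || jj >= cl.nd[1]) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = ci + di;
          if (ii < 0 || ii >= cl.nd[0]) continue;
          int c = (kk * cl.nd[1] + jj) * cl.nd[0] + ii;
          for (int p = cl.head[c]; p != -1; p = cl.nxt[p]) {
            double dx = pts(p, 0) - x, dy = pts(p, 1) - y, dz = pts(p, 2) - z;
            if (dx * dx + dy * dy + dz * dz <= r2) {
              for (int v = 0; v < nv; ++v) out(q, v) += vals(p, v);
              ++cnt;
            }
          }
        }
      }
    }
    if (cnt > 0)
      for (int v = 0; v < nv; ++v) out(q, v) /= cnt;
  }
  return out;
}

// ---------------------------------------------------------------------------
// All pairs (i<j) within cutoff; box lengths > 0 enable minimum-image
// distances in that dimension. Returns E x 2 matrix of 1-based indices.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix pts, double cutoff,
                               NumericVector box) {
  int n = pts.nrow();
  double L[3];
  bool per[3];
  for (int d = 0; d < 3; ++d) {
    L[d] = box[d];
    per[d] = box[d] > 0;
  }
  // wrapped copies for cell binning
  std::vector<double> w(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = pts(i, d);
      if (per[d]) v = v - L[d] * std::floor(v / L[d]);
      w[3 * (size_t)i + d] = v;
    }
  int nd[3];
  double cs[3];
  for (int d = 0; d < 3; ++d) {
    if (per[d]) {
      nd[d] = std::max(1, (int)std::floor(L[d] / cutoff));
      cs[d] = L[d] / nd[d];
    } else {
      double mn = R_PosInf, mx = R_NegInf;
      for (int i = 0; i < n; ++i) {
        mn = std::min(mn, w[3 * (size_t)i + d]);
        mx = std::max(mx, w[3 * (size_t)i + d]);
      }
      nd[d] = std::max(1, (int)std::floor((mx - mn) / cutoff) + 1);
      cs[d] = cutoff;
      L[d] = mn; // reuse as origin for non-periodic dims
    }
  }
  std::vector<int> head((size_t)nd[0] * nd[1] * nd[2], -1), nxt(n, -1),
      ijk(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      double v = w[3 * (size_t)i + d];
      int idx = per[d] ? (int)std::floor(v / cs[d])
                       : (int)std::floor((v - L[d]) / cs[d]);
      if (idx >= nd[d]) idx = nd[d] - 1;
      if (idx < 0) idx = 0;
      c[d] = idx;
      ijk[3 * (size_t)i + d] = idx;
    }
    int cc = (c[2] * nd[1] + c[1]) * nd[0] + c[0];
    nxt[i] = head[cc];
    head[cc] = i;
  }
  double cut2 = cutoff * cutoff;
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    int ci = ijk[3 * (size_t)i], cj = ijk[3 * (size_t)i + 1],
        ck = ijk[3 * (size_t)i + 2];
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = ck + dk;
      if (per[2]) kk = (kk + nd[2]) % nd[2];
      else if (kk < 0 || kk >= nd[2]) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = cj + dj;
        if (per[1]) jj = (jj + nd[1]) % nd[1];
        else if (jj < 0 || jj >= nd[1]) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = ci + di;
          if (per[0]) ii = (ii + nd[0]) % nd[0];
          else if (ii < 0 || ii >= nd[0]) continue;
          int c = (kk * nd[1] + jj) * nd[0] + ii;
          for (int p = head[c]; p != -1; p = nxt[p]) {
            if (p <= i) continue;
            double d2 = 0;
            for (int d = 0; d < 3; ++d) {
              double dd = w[3 * (size_t)p + d] - w[3 * (size_t)i + d];
              if (per[d]) dd -= box[d] * std::round(dd / box[d]);
              d2 += dd * dd;
            }
            if (d2 <= cut2) {
              // guard against double counting through wrapped small grids
              bool dup = false;
              for (size_t e = ei.size(); e-- > 0;) {
                if (ei[e] != i + 1) break;
                if (ej[e] == p + 1) { dup = true; break; }
              }
              if (!dup) { ei.push_back(i + 1); ej.push_back(p + 1); }
            }
          }
        }
      }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t e = 0; e < ei.size(); ++e) {
    out(e, 0) = ei[e];
    out(e, 1) = ej[e];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Splat oriented normals onto a periodic grid with a Gaussian kernel.
// Returns c(Vx, Vy, Vz) as one vector of length 3 * n1*n2*n3.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_splat(NumericMatrix points, NumericMatrix normals,
                        IntegerVector dims, NumericVector off,
                        NumericVector h, double sigma, double rcut) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  size_t ntot = (size_t)n1 * n2 * n3;
  NumericVector out(3 * ntot);
  int n = points.nrow();
  int span[3];
  for (int d = 0; d < 3; ++d) span[d] = (int)std::ceil(rcut / h[d]);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double rc2 = rcut * rcut;
  for (int p = 0; p < n; ++p) {
    double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    int ci = (int)std::round((px - off[0]) / h[0]);
    int cj = (int)std::round((py - off[1]) / h[1]);
    int ck = (int)std::round((pz - off[2]) / h[2]);
    for (int dk = -span[2]; dk <= span[2]; ++dk) {
      int kk = ((ck + dk) % n3 + n3) % n3;
      double z = off[2] + (ck + dk) * h[2];
      double dz = z - pz;
      for (int dj = -span[1]; dj <= span[1]; ++dj) {
        int jj = ((cj + dj) % n2 + n2) % n2;
        double y = off[1] + (cj + dj) * h[1];
        double dy = y - py;
        for (int di = -span[0]; di <= span[0]; ++di) {
          int ii = ((ci + di) % n1 + n1) % n1;
          double x = off[0] + (ci + di) * h[0];
          double dx = x - px;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > rc2) continue;
          double wgt = std::exp(-d2 * inv2s2);
          size_t node = ((size_t)kk * n2 + jj) * n1 + ii;
          out[node] += wgt * normals(p, 0);
          out[ntot + node] += wgt * normals(p, 1);
          out[2 * ntot + node] += wgt * normals(p, 2);
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra over a periodic scalar grid. Cells 0..n-1 in each
// dimension; node values wrap, node positions do not (so the mesh spans
// [off, off + n*h] with an open seam at the periodic faces). Triangles are
// oriented with their normal pointing toward field > iso.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector off, NumericVector h, double iso) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  // padded (unwrapped) node index space
  int64_t p1 = n1 + 1, p2 = n2 + 1;
  auto val = [&](int i, int j, int k) -> double {
    int ii = i % n1, jj = j % n2, kk = k % n3;
    return field[((size_t)kk * n2 + jj) * n1 + ii] - iso;
  };
  auto nodeid = [&](int i, int j, int k) -> int64_t {
    return ((int64_t)k * p2 + j) * p1 + i;
  };
  static const int corner[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                   {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  double cpos[8][3], cval[8];
  int64_t cid[8];
  auto edge_vertex = [&](int a, int b) -> int {
    int64_t ia = cid[a], ib = cid[b];
    uint64_t key = ia < ib ? ((uint64_t)ia << 32) ^ (uint64_t)ib
                           : ((uint64_t)ib << 32) ^ (uint64_t)ia;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double va = cval[a], vb = cval[b];
    double t = va / (va - vb);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    double x = cpos[a][0] + t * (cpos[b][0] - cpos[a][0]);
    double y = cpos[a][1] + t * (cpos[b][1] - cpos[a][1]);
    double z = cpos[a][2] + t * (cpos[b][2] - cpos[a][2]);
    int id = (int)vx.size();
    vx.push_back(x);
    vy.push_back(y);
    vz.push_back(z);
    edge_vert[key] = id;
    return id;
  };
  auto emit = [&](int e0, int e1, int e2, const int *tc) {
    // orient: normal toward positive field
    double ax = vx[e1] - vx[e0], ay = vy[e1] - vy[e0], az = vz[e1] - vz[e0];
    double bx = vx[e2] - vx[e0], by = vy[e2] - vy[e0], bz = vz[e2] - vz[e0];
    double nx = ay * bz - az * by, ny = az * bx - ax * bz,
           nz = ax * by - ay * bx;
    double cx = (vx[e0] + vx[e1] + vx[e2]) / 3.0,
           cy = (vy[e0] + vy[e1] + vy[e2]) / 3.0,
           cz = (vz[e0] + vz[e1] + vz[e2]) / 3.0;
    double s = 0;
    for (int q = 0; q < 4; ++q) {
      int c = tc[q];
      s += cval[c] * ((cpos[c][0] - cx) * nx + (cpos[c][1] - cy) * ny +
                      (cpos[c][2] - cz) * nz);
    }
    if (s >= 0) {
      tri.push_back(e0 + 1);
      tri.push_back(e1 + 1);
      tri.push_back(e2 + 1);
    } else {
      tri.push_back(e0 + 1);
      tri.push_back(e2 + 1);
      tri.push_back(e1 + 1);
    }
  };

  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        bool anyp = false, anyn = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner[c][0], jj = j + corner[c][1],
              kk = k + corner[c][2];
          cval[c] = val(ii, jj, kk);
          if (cval[c] > 0) anyp = true;
          else anyn = true;
          cpos[c][0] = off[0] + ii * h[0];
          cpos[c][1] = off[1] + jj * h[1];
          cpos[c][2] = off[2] + kk * h[2];
          cid[c] = nodeid(ii, jj, kk);
        }
        if (!anyp || !anyn) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tc = tets[t];
          int pos[4], neg[4], np = 0, nn = 0;
          for (int q = 0; q < 4; ++q) {
            if (cval[tc[q]] > 0) pos[np++] = tc[q];
            else neg[nn++] = tc[q];
          }
          if (np == 0 || np == 4) continue;
          if (np == 1) {
            int a = pos[0];
            int e0 = edge_vertex(a, neg[0]), e1 = edge_vertex(a, neg[1]),
                e2 = edge_vertex(a, neg[2]);
            emit(e0, e1, e2, tc);
          } else if (np == 3) {
            int a = neg[0];
            int e0 = edge_vertex(a, pos[0]), e1 = edge_vertex(a, pos[1]),
                e2 = edge_vertex(a, pos[2]);
            emit(e0, e1, e2, tc);
          } else {
            // quad: edges (p0,n0),(p0,n1),(p1,n1),(p1,n0)
            int e00 = edge_vertex(pos[0], neg[0]),
                e01 = edge_vertex(pos[0], neg[1]),
                e11 = edge_vertex(pos[1], neg[1]),
                e10 = edge_vertex(pos[1], neg[0]);
            emit(e00, e01, e11, tc);
            emit(e00, e11, e10, tc);
          }
        }
      }

  int nv = vx.size(), nt = tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  IntegerMatrix F(nt, 3);
  for (int t = 0; t < nt; ++t) {
    F(t, 0) = tri[3 * t];
    F(t, 1) = tri[3 * t + 1];
    F(t, 2) = tri[3 * t + 2];
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// ---------------------------------------------------------------------------
// Long-edge pattern subdivision: split every edge longer than max_edge at its
// midpoint, re-tessellating each triangle by its number of marked edges;
// repeat until no long edges remain (or max_pass).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_subdivide(NumericMatrix vertices, IntegerMatrix triangles,
                   double max_edge, int max_pass) {
  std::vector<double> vx, vy, vz;
  int nv0 = vertices.nrow();
  vx.reserve(nv0 * 4);
  vy.reserve(nv0 * 4);
  vz.reserve(nv0 * 4);
  for (int i = 0; i < nv0; ++i) {
    vx.push_back(vertices(i, 0));
    vy.push_back(vertices(i, 1));
    vz.push_back(vertices(i, 2));
  }
  std::vector<int> tri;
  tri.reserve((size_t)triangles.nrow() * 12);
  for (int t = 0; t < triangles.nrow(); ++t) {
    tri.push_back(triangles(t, 0) - 1);
    tri.push_back(triangles(t, 1) - 1);
    tri.push_back(triangles(t, 2) - 1);
  }
  double me2 = max_edge * max_edge;
  auto len2 = [&](int a, int b) {
    double dx = vx[a] - vx[b], dy = vy[a] - vy[b], dz = vz[a] - vz[b];
    return dx * dx + dy * dy + dz * dz;
  };
  for (int pass = 0; pass < max_pass; ++pass) {
    std::unordered_map<uint64_t, int> mid;
    auto midpoint = [&](int a, int b) -> int {
      uint64_t key = a < b ? ((uint64_t)a << 32) | (uint64_t)b
                           : ((uint64_t)b << 32) | (uint64_t)a;
      auto it = mid.find(key);
      if (it != mid.end()) return it->second;
      int id = (int)vx.size();
      vx.push_back(0.5 * (vx[a] + vx[b]));
      vy.push_back(0.5 * (vy[a] + vy[b]));
      vz.push_back(0.5 * (vz[a] + vz[b]));
      mid[key] = id;
      return id;
    };
    std::vector<int> out;
    out.reserve(tri.size() * 2);
    bool any = false;
    size_t nt = tri.size() / 3;
    for (size_t t = 0; t < nt; ++t) {
      int v0 = tri[3 * t], v1 = tri[3 * t + 1], v2 = tri[3 * t + 2];
      bool m0 = len2(v0, v1) > me2, m1 = len2(v1, v2) > me2,
           m2 = len2(v2, v0) > me2;
      int nm = (int)m0 + m1 + m2;
      if (nm == 0) {
        out.push_back(v0);
        out.push_back(v1);
        out.push_back(v2);
        continue;
      }
      any = true;
      if (nm == 3) {
        int a = midpoint(v0, v1), b = midpoint(v1, v2), c = midpoint(v2, v0);
        int q[12] = {v0, a, c, a, v1, b, c, b, v2, a, b, c};
        out.insert(out.end(), q, q + 12);
      } else if (nm == 1) {
        // rotate so the marked edge is (v0,v1)
        if (m1) { int tmp = v0; v0 = v1; v1 = v2; v2 = tmp; }
        else if (m2) { int tmp = v0; v0 = v2; v2 = v1; v1 = tmp; }
        int a = midpoint(v0, v1);
        int q[6] = {v0, a, v2, a, v1, v2};
        out.insert(out.end(), q, q + 6);
      } else {
        // rotate so the two marked edges are (v0,v1) and (v1,v2); the
        // marked pair shares one vertex which must land on v1
        if (m0 && m2) { int tmp = v0; v0 = v2; v2 = v1; v1 = tmp; }
        else if (m1 && m2) { int tmp = v0; v0 = v1; v1 = v2; v2 = tmp; }
        int a = midpoint(v0, v1), b = midpoint(v1, v2);
        int q[9] = {a, v1, b, v0, a, b, v0, b, v2};
        out.insert(out.end(), q, q + 9);
      }
    }
    tri.swap(out);
    if (!any) break;
  }
  int nv = vx.size(), nt = tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  IntegerMatrix F(nt, 3);
  for (int t = 0; t < nt; ++t) {
    F(t, 0) = tri[3 * t] + 1;
    F(t, 1) = tri[3 * t + 1] + 1;
    F(t, 2) = tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// ---------------------------------------------------------------------------
// Open-boundary flags: edges with a single incident triangle mark their
// vertices and incident triangles as boundary.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_mesh_boundary(IntegerMatrix triangles, int nv) {
  int nt = triangles.nrow();
  std::unordered_map<uint64_t, int> cnt;
  cnt.reserve((size_t)nt * 3);
  for (int t = 0; t < nt; ++t) {
    for (int e = 0; e < 3; ++e) {
      int a = triangles(t, e), b = triangles(t, (e + 1) % 3);
      uint64_t key = a < b ? ((uint64_t)a << 32) | (uint64_t)b
                           : ((uint64_t)b << 32) | (uint64_t)a;
      ++cnt[key];
    }
  }
  LogicalVector vflag(nv), tflag(nt);
  for (int t = 0; t < nt; ++t) {
    for (int e = 0; e < 3; ++e) {
      int a = triangles(t, e), b = triangles(t, (e + 1) % 3);
      uint64_t key = a < b ? ((uint64_t)a << 32) | (uint64_t)b
                           : ((uint64_t)b << 32) | (uint64_t)a;
      if (cnt[key] == 1) {
        tflag[t] = true;
        vflag[a - 1] = true;
        vflag[b - 1] = true;
      }
    }
  }
  return List::create(_["vertices"] = vflag, _["triangles"] = tflag);
}

// ---------------------------------------------------------------------------
// Greedy short-edge collapse: edges shorter than min_edge are collapsed to
// their midpoint (shortest first, each vertex at most once per pass);
// boundary vertices are never moved. Degenerate triangles are dropped.
// With target_nv > 0 collapsing stops once the vertex count reaches it,
// which pins the mean edge length of the relaxed mesh.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_collapse(NumericMatrix vertices, IntegerMatrix triangles,
                  LogicalVector boundary, double min_edge, int max_pass,
                  int target_nv = 0) {
  int nv = vertices.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) {
    X[i] = vertices(i, 0);
    Y[i] = vertices(i, 1);
    Z[i] = vertices(i, 2);
  }
  std::vector<int> tri;
  for (int t = 0; t < triangles.nrow(); ++t) {
    tri.push_back(triangles(t, 0) - 1);
    tri.push_back(triangles(t, 1) - 1);
    tri.push_back(triangles(t, 2) - 1);
  }
  std::vector<char> bnd(nv);
  for (int i = 0; i < nv; ++i) bnd[i] = boundary[i] ? 1 : 0;
  double me2 = min_edge * min_edge;
  int live = nv;
  for (int pass = 0; pass < max_pass; ++pass) {
    if (target_nv > 0 && live <= target_nv) break;
    size_t nt = tri.size() / 3;
    // collect unique short edges; lengths are quantized so that the greedy
    // order is robust to last-bit floating-point noise (keeps the whole
    // remesh equivariant under rigid motions of the input)
    std::vector<std::pair<int64_t, std::pair<int, int> > > cand;
    std::unordered_map<uint64_t, char> seen;
    for (size_t t = 0; t < nt; ++t) {
      for (int e = 0; e < 3; ++e) {
        int a = tri[3 * t + e], b = tri[3 * t + (e + 1) % 3];
        if (bnd[a] || bnd[b]) continue;
        double dx = X[a] - X[b], dy = Y[a] - Y[b], dz = Z[a] - Z[b];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 >= me2) continue;
        uint64_t key = a < b ? ((uint64_t)a << 32) | (uint64_t)b
                             : ((uint64_t)b << 32) | (uint64_t)a;
        if (seen.count(key)) continue;
        seen[key] = 1;
        cand.push_back({(int64_t)std::llround(d2 * 1e8), {a, b}});
      }
    }
    if (cand.empty()) break;
    std::sort(cand.begin(), cand.end());
    std::vector<int> remap(nv);
    for (int i = 0; i < nv; ++i) remap[i] = i;
    std::vector<char> touched(nv, 0);
    bool any = false;
    for (auto &c : cand) {
      if (target_nv > 0 && live <= target_nv) break;
      int a = c.second.first, b = c.second.second;
      if (touched[a] || touched[b]) continue;
      X[a] = 0.5 * (X[a] + X[b]);
      Y[a] = 0.5 * (Y[a] + Y[b]);
      Z[a] = 0.5 * (Z[a] + Z[b]);
      remap[b] = a;
      touched[a] = touched[b] = 1;
      --live;
      any = true;
    }
    if (!any) break;
    std::vector<int> out;
    out.reserve(tri.size());
    for (size_t t = 0; t < nt; ++t) {
      int a = remap[tri[3 * t]], b = remap[tri[3 * t + 1]],
          c = remap[tri[3 * t + 2]];
      if (a == b || b == c || a == c) continue;
      out.push_back(a);
      out.push_back(b);
      out.push_back(c);
    }
    tri.swap(out);
  }
  // compact vertex indexing
  std::vector<int> used(nv, -1);
  int nu = 0;
  for (size_t i = 0; i < tri.size(); ++i) {
    if (used[tri[i]] < 0) used[tri[i]] = nu++;
  }
  NumericMatrix V(nu, 3);
  for (int i = 0; i < nv; ++i) {
    if (used[i] >= 0) {
      V(used[i], 0) = X[i];
      V(used[i], 1) = Y[i];
      V(used[i], 2) = Z[i];
    }
  }
  size_t nt = tri.size() / 3;
  IntegerMatrix F(nt, 3);
  for (size_t t = 0; t < nt; ++t) {
    F(t, 0) = used[tri[3 * t]] + 1;
    F(t, 1) = used[tri[3 * t + 1]] + 1;
    F(t, 2) = used[tri[3 * t + 2]] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// ---------------------------------------------------------------------------
// Tangential area-weighted Laplacian relaxation (CVT-style smoothing).
// Boundary vertices stay fixed; displacement is projected onto the local
// tangent plane so the shape (and total area) is preserved.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_smooth(NumericMatrix vertices, IntegerMatrix triangles,
                         LogicalVector boundary, int n_iter, double lambda) {
  int nv = vertices.nrow(), nt = triangles.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) {
    X[i] = vertices(i, 0);
    Y[i] = vertices(i, 1);
    Z[i] = vertices(i, 2);
  }
  std::vector<double> wsum(nv), cx(nv), cy(nv), cz(nv), nxv(nv), nyv(nv),
      nzv(nv);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(wsum.begin(), wsum.end(), 0.0);
    std::fill(cx.begin(), cx.end(), 0.0);
    std::fill(cy.begin(), cy.end(), 0.0);
    std::fill(cz.begin(), cz.end(), 0.0);
    std::fill(nxv.begin(), nxv.end(), 0.0);
    std::fill(nyv.begin(), nyv.end(), 0.0);
    std::fill(nzv.begin(), nzv.end(), 0.0);
    for (int t = 0; t < nt; ++t) {
      int a = triangles(t, 0) - 1, b = triangles(t, 1) - 1,
          c = triangles(t, 2) - 1;
      double ux = X[b] - X[a], uy = Y[b] - Y[a], uz = Z[b] - Z[a];
      double vx2 = X[c] - X[a], vy2 = Y[c] - Y[a], vz2 = Z[c] - Z[a];
      double nx = uy * vz2 - uz * vy2, ny = uz * vx2 - ux * vz2,
             nz = ux * vy2 - uy * vx2;
      double area = 0.5 * std::sqrt(nx * nx + ny * ny + nz * nz);
      double mx = (X[a] + X[b] + X[c]) / 3.0, my = (Y[a] + Y[b] + Y[c]) / 3.0,
             mz = (Z[a] + Z[b] + Z[c]) / 3.0;
      int vs[3] = {a, b, c};
      for (int q = 0; q < 3; ++q) {
        int v = vs[q];
        wsum[v] += area;
        cx[v] += area * mx;
        cy[v] += area * my;
        cz[v] += area * mz;
        nxv[v] += nx;
        nyv[v] += ny;
        nzv[v] += nz;
      }
    }
    for (int v = 0; v < nv; ++v) {
      if (boundary[v] || wsum[v] <= 0) continue;
      double dx = cx[v] / wsum[v] - X[v], dy = cy[v] / wsum[v] - Y[v],
             dz = cz[v] / wsum[v] - Z[v];
      double nn = std::sqrt(nxv[v] * nxv[v] + nyv[v] * nyv[v] +
                            nzv[v] * nzv[v]);
      if (nn > 1e-12) {
        double nx = nxv[v] / nn, ny = nyv[v] / nn, nz = nzv[v] / nn;
        double dn = dx * nx + dy * ny + dz * nz;
        dx -= dn * nx;
        dy -= dn * ny;
        dz -= dn * nz;
      }
      X[v] += lambda * dx;
      Y[v] += lambda * dy;
      Z[v] += lambda * dz;
    }
  }
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = X[i];
    V(i, 1) = Y[i];
    V(i, 2) = Z[i];
  }
  return V;
}

// ---------------------------------------------------------------------------
// Per-tile winning-bead arbitration. A bead touches every tile whose midpoint
// lies within its VdW radius of the bead's projected footprint centre; among
// touching beads the most solvent-proximal one (largest height score) wins.
// Ties within 1e-6 A go to the smaller radius, then the smaller residue id.
// Returns the 1-based winning bead index per tile (0 = untouched).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_assign_tiles(NumericMatrix mid, NumericMatrix foot,
                               NumericVector radius, NumericVector score,
                               IntegerVector resid) {
  int nt = mid.nrow(), nb = foot.nrow();
  double rmax = 0;
  for (int b = 0; b < nb; ++b) rmax = std::max(rmax, radius[b]);
  if (rmax <= 0) rmax = 1.0;
  CellList cl;
  cl.build(mid, rmax);
  IntegerVector win(nt);
  std::vector<double> bscore(nt), brad(nt);
  std::vector<int> bres(nt);
  const double tol = 1e-6;
  for (int b = 0; b < nb; ++b) {
    double x = foot(b, 0), y = foot(b, 1), z = foot(b, 2);
    double r = radius[b], r2 = r * r;
    int i0 = (int)std::floor((x - r - cl.lo[0]) / cl.cs),
        i1 = (int)std::floor((x + r - cl.lo[0]) / cl.cs);
    int j0 = (int)std::floor((y - r - cl.lo[1]) / cl.cs),
        j1 = (int)std::floor((y + r - cl.lo[1]) / cl.cs);
    int k0 = (int)std::floor((z - r - cl.lo[2]) / cl.cs),
        k1 = (int)std::floor((z + r - cl.lo[2]) / cl.cs);
    i0 = cl.clampi(i0, cl.nd[0]); i1 = cl.clampi(i1, cl.nd[0]);
    j0 = cl.clampi(j0, cl.nd[1]); j1 = cl.clampi(j1, cl.nd[1]);
    k0 = cl.clampi(k0, cl.nd[2]); k1 = cl.clampi(k1, cl.nd[2]);
    for (int kk = k0; kk <= k1; ++kk)
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) {
          int c = (kk * cl.nd[1] + jj) * cl.nd[0] + ii;
          for (int t = cl.head[c]; t != -1; t = cl.nxt[t]) {
            double dx = mid(t, 0) - x, dy = mid(t, 1) - y, dz = mid(t, 2) - z;
            if (dx * dx + dy * dy + dz * dz > r2) continue;
            if (win[t] == 0) {
              win[t] = b + 1;
              bscore[t] = score[b];
              brad[t] = r;
              bres[t] = resid[b];
            } else {
              double ds = score[b] - bscore[t];
              bool better = false;
              if (ds > tol) better = true;
              else if (ds >= -tol) {
                if (r < brad[t] - 1e-9) better = true;
                else if (std::abs(r - brad[t]) <= 1e-9 && resid[b] < bres[t])
                  better = true;
              }
              if (better) {
                win[t] = b + 1;
                bscore[t] = score[b];
                brad[t] = r;
                bres[t] = resid[b];
              }
            }
          }
        }
  }
  return win;
}
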