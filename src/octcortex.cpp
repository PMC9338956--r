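#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// reflect index into [0, n) (symmetric border: -1 -> 0, n -> n-1)
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2D convolution of a slice with a sparse kernel given as tap offsets
// (dy, dx) and weights; same-size output, reflective border.
// [[Rcpp::export]]
NumericMatrix conv2_sparse(NumericMatrix img, IntegerVector dy,
                           IntegerVector dx, NumericVector w) {
  const int nr = img.nrow(), nc = img.ncol(), nt = w.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = 0; t < nt; ++t) {
        int ii = i + dy[t], jj = j + dx[t];
        if (ii < 0 || ii >= nr) ii = reflect(ii, nr);
        if (jj < 0 || jj >= nc) jj = reflect(jj, nc);
        s += w[t] * img(ii, jj);
      }
      out(i, j) = s;
    }
  }
  return out;
}

// 26-connected component labeling of a 3D logical array, dims (ny, nx, nz).
// Two-pass union-find; labels are 1..K in first-voxel order.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  std::vector<int> parent(1, 0); // parent[0] unused

  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < ny; ++i) {
        R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * ny + i;
        if (!mask[idx]) continue;
        int best = 0;
        // scan the 13 already-visited neighbors (26-connectivity, causal half)
        for (int dk = -1; dk <= 0; ++dk) {
          int kk = k + dk; if (kk < 0) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= nx) continue;
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di; if (ii < 0 || ii >= ny) continue;
              if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
              R_xlen_t nb = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * ny + ii;
              int l = lab[nb];
              if (l > 0) {
                if (best == 0) best = l; else unite(best, l);
              }
            }
          }
        }
        if (best == 0) {
          parent.push_back(++next);
          lab[idx] = next;
        } else {
          lab[idx] = find(best);
        }
      }
    }
  }
  // relabel roots to consecutive 1..K in order of first appearance
  std::vector<int> remap(next + 1, 0);
  int K = 0;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    int l = lab[idx];
    if (l == 0) continue;
    int r = find(l);
    if (remap[r] == 0) remap[r] = ++K;
    lab[idx] = remap[r];
  }
  lab.attr("n_components") = K;
  return lab;
}

// For each row of `query` (n x 3), distance to (and index of) the nearest
// row of `ref` (m x 3). If self = true, query and ref are the same set and
// a point is not its own neighbor.
// [[Rcpp::export]]
List nn_brute(NumericMatrix query, NumericMatrix ref, bool self) {
  const int n = query.nrow(), m = ref.nrow();
  NumericVector d(n);
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = NA_INTEGER;
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < m; ++j) {
      if (self && j == i) continue;
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bj = j + 1; }
    }
    d[i] = std::sqrt(best);
    idx[i] = bj;
  }
  return List::create(_["dist"] = d, _["index"] = idx);
}
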