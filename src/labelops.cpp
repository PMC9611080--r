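#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// One simultaneous 6-neighbourhood consistency sweep.
// A voxel with no in-grid 6-neighbour sharing its label is reassigned to the
// modal label of its in-grid neighbours (ties -> smallest label id).
// Decisions are taken on the input state; returns new labels + change count.
// [[Rcpp::export]]
List cpp_cleanup_pass(IntegerVector labels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(labels);
  int changed = 0;
  int nb[6];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        int own = labels[i];
        int nn = 0;
        if (x > 0)      nb[nn++] = labels[i - 1];
        if (x < nx - 1) nb[nn++] = labels[i + 1];
        if (y > 0)      nb[nn++] = labels[i - nx];
        if (y < ny - 1) nb[nn++] = labels[i + nx];
        if (z > 0)      nb[nn++] = labels[i - nx * ny];
        if (z < nz - 1) nb[nn++] = labels[i + nx * ny];
        bool supported = false;
        for (int k = 0; k < nn; ++k) if (nb[k] == own) { supported = true; break; }
        if (supported || nn == 0) continue;
        // modal neighbour label, ties toward the smallest id
        int best = -1, bestCount = 0;
        for (int k = 0; k < nn; ++k) {
          int v = nb[k], c = 0;
          for (int m = 0; m < nn; ++m) if (nb[m] == v) ++c;
          if (c > bestCount || (c == bestCount && v < best)) {
            best = v; bestCount = c;
          }
        }
        if (best != own) { out[i] = best; ++changed; }
      }
  return List::create(_["labels"] = out, _["changed"] = changed);
}

// Labels of non-ambient voxels that have an in-grid ambient (0) 6-neighbour.
// [[Rcpp::export]]
IntegerVector cpp_surface_labels(IntegerVector labels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<bool> seen(65536, false);
  std::vector<int> found;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        int own = labels[i];
        if (own == 0 || seen[own]) continue;
        bool amb =
          (x > 0      && labels[i - 1] == 0) ||
          (x < nx - 1 && labels[i + 1] == 0) ||
          (y > 0      && labels[i - nx] == 0) ||
          (y < ny - 1 && labels[i + nx] == 0) ||
          (z > 0      && labels[i - nx * ny] == 0) ||
          (z < nz - 1 && labels[i + nx * ny] == 0);
        if (amb) { seen[own] = true; found.push_back(own); }
      }
  return wrap(found);
}

// Number of 6-connected components of a given label.
// [[Rcpp::export]]
int cpp_n_components(IntegerVector labels, IntegerVector dims, int id) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> visited(n, 0);
  int ncomp = 0;
  std::queue<int> q;
  for (size_t start = 0; start < n; ++start) {
    if (labels[start] != id || visited[start]) continue;
    ++ncomp;
    visited[start] = 1;
    q.push((int)start);
    while (!q.empty()) {
      int i = q.front(); q.pop();
      int z = i / (nx * ny), r = i % (nx * ny), y = r / nx, x = r % nx;
      const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (!visited[j] && labels[j] == id) { visited[j] = 1; q.push(j); }
      }
    }
  }
  return ncomp;
}
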