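// Isosurface extraction from a binary voxel mask by marching tetrahedra:
// the table-free member of the marching-cubes family.  Mask values sit at
// voxel centres (nodes); each cell of 8 nodes is split into 6 tetrahedra
// sharing the main diagonal, a decomposition that keeps face diagonals
// consistent between neighbouring cells, so the triangulated iso-0.5
// surface is watertight.  The mask is conceptually padded with zeros, so
// structures touching the grid boundary are still closed.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

// cube corner offsets, corner id 0..7
const int CX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};
// 6-tet decomposition around the 0-6 diagonal
const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tets(LogicalVector mask, IntegerVector dims,
                       NumericVector pitch) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double hx = pitch[0], hy = pitch[1], hz = pitch[2];
  // padded node grid: node (i,j,k) in [0, n+2) maps to voxel (i-1, j-1, k-1)
  int mx = nx + 2, my = ny + 2, mz = nz + 2;
  auto node_val = [&](int i, int j, int k) -> int {
    int vx = i - 1, vy = j - 1, vz = k - 1;
    if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
      return 0;
    return mask[vx + (R_xlen_t)nx * (vy + (R_xlen_t)ny * vz)] ? 1 : 0;
  };
  auto node_pos = [&](int i, int j, int k, double* p) {
    p[0] = (i - 0.5) * hx; p[1] = (j - 0.5) * hy; p[2] = (k - 0.5) * hz;
  };
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> verts;   // x,y,z triples
  std::vector<int> tris;       // 1-based vertex index triples
  uint64_t NN = (uint64_t)mx * my * mz;

  auto edge_vertex = [&](uint64_t a, uint64_t b, const double* pa,
                         const double* pb) -> int {
    uint64_t lo = std::min(a, b), hi = std::max(a, b);
    uint64_t key = lo * NN + hi;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)(verts.size() / 3) + 1;
    verts.push_back(0.5 * (pa[0] + pb[0]));
    verts.push_back(0.5 * (pa[1] + pb[1]));
    verts.push_back(0.5 * (pa[2] + pb[2]));
    vmap.emplace(key, id);
    return id;
  };

  int cvals[8];
  uint64_t cid[8];
  double cpos[8][3];
  for (int k = 0; k < mz - 1; ++k)
    for (int j = 0; j < my - 1; ++j)
      for (int i = 0; i < mx - 1; ++i) {
        int any1 = 0, all1 = 1;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CX[c], jj = j + CY[c], kk = k + CZ[c];
          cvals[c] = node_val(ii, jj, kk);
          any1 |= cvals[c]; all1 &= cvals[c];
          cid[c] = (uint64_t)ii + (uint64_t)mx * (jj + (uint64_t)my * kk);
          node_pos(ii, jj, kk, cpos[c]);
        }
        if (!any1 || all1) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in[4], nin = 0, nout = 0, outi[4];
          for (int v = 0; v < 4; ++v) {
            if (cvals[T[v]]) in[nin++] = T[v]; else outi[nout++] = T[v];
          }
          if (nin == 0 || nin == 4) continue;
          int vid[4]; int nv = 0;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : outi[0];
            const int* others = (nin == 1) ? outi : in;
            for (int v = 0; v < 3; ++v)
              vid[nv++] = edge_vertex(cid[apex], cid[others[v]],
                                      cpos[apex], cpos[others[v]]);
          } else {  // 2 in / 2 out: quad over the four cut edges
            // order: (in0,out0), (in0,out1), (in1,out1), (in1,out0)
            vid[nv++] = edge_vertex(cid[in[0]], cid[outi[0]], cpos[in[0]], cpos[outi[0]]);
            vid[nv++] = edge_vertex(cid[in[0]], cid[outi[1]], cpos[in[0]], cpos[outi[1]]);
            vid[nv++] = edge_vertex(cid[in[1]], cid[outi[1]], cpos[in[1]], cpos[outi[1]]);
            vid[nv++] = edge_vertex(cid[in[1]], cid[outi[0]], cpos[in[1]], cpos[outi[0]]);
          }
          // inside centroid, used to orient triangles outward
          double cx = 0, cy = 0, cz2 = 0;
          for (int v = 0; v < nin; ++v) {
            cx += cpos[in[v]][0]; cy += cpos[in[v]][1]; cz2 += cpos[in[v]][2];
          }
          cx /= nin; cy /= nin; cz2 /= nin;
          auto emit = [&](int a, int b, int c) {
            const double* pa = &verts[(a - 1) * 3];
            const double* pb = &verts[(b - 1) * 3];
            const double* pc = &verts[(c - 1) * 3];
            double u[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
            double v[3] = {pc[0] - pa[0], pc[1] - pa[1], pc[2] - pa[2]};
            double nrm[3] = {u[1] * v[2] - u[2] * v[1],
                             u[2] * v[0] - u[0] * v[2],
                             u[0] * v[1] - u[1] * v[0]};
            double gx = (pa[0] + pb[0] + pc[0]) / 3 - cx;
            double gy = (pa[1] + pb[1] + pc[1]) / 3 - cy;
            double gz = (pa[2] + pb[2] + pc[2]) / 3 - cz2;
            if (nrm[0] * gx + nrm[1] * gy + nrm[2] * gz < 0) std::swap(b, c);
            tris.push_back(a); tris.push_back(b); tris.push_back(c);
          };
          if (nv == 3) emit(vid[0], vid[1], vid[2]);
          else { emit(vid[0], vid[1], vid[2]); emit(vid[0], vid[2], vid[3]); }
        }
      }
  int nV = (int)(verts.size() / 3), nF = (int)(tris.size() / 3);
  NumericMatrix V(nV, 3);
  IntegerMatrix F(nF, 3);
  for (int v = 0; v < nV; ++v)
    for (int c = 0; c < 3; ++c) V(v, c) = verts[v * 3 + c];
  for (int f = 0; f < nF; ++f)
    for (int c = 0; c < 3; ++c) F(f, c) = tris[f * 3 + c];
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Uniform Laplacian smoothing: each vertex moves a fraction lambda toward
// the mean of its mesh neighbours; vertex and face counts are untouched.
// [[Rcpp::export]]
NumericMatrix cpp_smooth_mesh(NumericMatrix V, IntegerMatrix F, int iters,
                              double lambda) {
  int nV = V.nrow(), nF = F.nrow();
  std::vector<std::vector<int>> adj(nV);
  for (int f = 0; f < nF; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int v = 0; v < nV; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  NumericMatrix cur = clone(V);
  for (int it = 0; it < iters; ++it) {
    NumericMatrix nxt = clone(cur);
    for (int v = 0; v < nV; ++v) {
      if (adj[v].empty()) continue;
      double mx = 0, my = 0, mz = 0;
      for (int u : adj[v]) { mx += cur(u, 0); my += cur(u, 1); mz += cur(u, 2); }
      double inv = 1.0 / adj[v].size();
      nxt(v, 0) = cur(v, 0) + lambda * (mx * inv - cur(v, 0));
      nxt(v, 1) = cur(v, 1) + lambda * (my * inv - cur(v, 1));
      nxt(v, 2) = cur(v, 2) + lambda * (mz * inv - cur(v, 2));
    }
    cur = nxt;
  }
  return cur;
}
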