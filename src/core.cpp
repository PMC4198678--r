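#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Cube corner c (0..7) sits at offset (c&1, (c>>1)&1, (c>>2)&1) from the
// cell's lower voxel.  Edge ids 0..11: x-edges 0..3 based at corners
// {0,2,4,6}, y-edges 4..7 based at {0,1,4,5}, z-edges 8..11 based at
// {0,1,2,3}.  R/mc-table.R uses the identical enumeration.
static const int EDGE_BASE[12] = {0, 2, 4, 6, 0, 1, 4, 5, 0, 1, 2, 3};
static const int EDGE_AXIS[12] = {0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2};

// [[Rcpp::export(name = ".mc_core")]]
List mc_core(NumericVector field, IntegerVector dims, double iso,
             IntegerVector cell_lo, IntegerVector cell_hi,
             IntegerVector labels, IntegerVector tab_off,
             IntegerVector tab_edges) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t sx = 1, sy = nx, sz = (int64_t)nx * ny;

  std::unordered_map<int64_t, int> vmap;
  std::vector<double> vx, vy, vz;   // interpolation parameters per vertex
  std::vector<int> vlab;
  std::vector<int> tri;             // 0-based vertex indices

  double corner[8];
  int64_t cidx[8];

  for (int k = cell_lo[2]; k <= cell_hi[2]; ++k) {
    for (int j = cell_lo[1]; j <= cell_hi[1]; ++j) {
      for (int i = cell_lo[0]; i <= cell_hi[0]; ++i) {
        int64_t base = i * sx + j * sy + k * sz;
        int config = 0;
        for (int c = 0; c < 8; ++c) {
          int64_t id = base + (c & 1) * sx + ((c >> 1) & 1) * sy +
                       ((c >> 2) & 1) * sz;
          cidx[c] = id;
          corner[c] = field[id];
          if (corner[c] > iso) config |= (1 << c);
        }
        if (config == 0 || config == 255) continue;
        for (int t = tab_off[config]; t < tab_off[config + 1]; ++t) {
          int e = tab_edges[t];
          int bc = EDGE_BASE[e];
          int axis = EDGE_AXIS[e];
          int oc = bc | (1 << axis);   // other corner of the edge
          int bi = i + (bc & 1), bj = j + ((bc >> 1) & 1),
              bk = k + ((bc >> 2) & 1);
          int64_t key = ((int64_t)bi + (int64_t)bj * nx +
                         (int64_t)bk * nx * ny) * 3 + axis;
          auto it = vmap.find(key);
          int vid;
          if (it == vmap.end()) {
            double v0 = corner[bc], v1 = corner[oc];
            double tt = (v1 == v0) ? 0.5 : (iso - v0) / (v1 - v0);
            // keep vertices strictly off cell corners so a corner value
            // exactly equal to iso cannot collapse triangles to zero area
            if (tt < 1e-6) tt = 1e-6;
            if (tt > 1.0 - 1e-6) tt = 1.0 - 1e-6;
            double px = bi, py = bj, pz = bk;
            if (axis == 0) px += tt;
            else if (axis == 1) py += tt;
            else pz += tt;
            int inside = (v0 > iso) ? bc : oc;  // solid-side endpoint
            vid = (int)vx.size();
            vx.push_back(px); vy.push_back(py); vz.push_back(pz);
            vlab.push_back(labels.size() ? labels[cidx[inside]] : 0);
            vmap.emplace(key, vid);
          } else {
            vid = it->second;
          }
          tri.push_back(vid);
        }
      }
    }
  }

  int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  IntegerVector VL(nv);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v];
    VL[v] = vlab[v];
  }
  int nt = (int)tri.size() / 3;
  IntegerMatrix F(nt, 3);
  for (int t = 0; t < nt; ++t) {
    F(t, 0) = tri[3 * t] + 1;
    F(t, 1) = tri[3 * t + 1] + 1;
    F(t, 2) = tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F,
                      _["vertex_labels"] = VL);
}

// Point-in-mesh occupancy by +x ray-casting parity, one ray per (j,k) row.
// Watertightness is checked on the R side before calling.
// [[Rcpp::export(name = ".voxelize_core")]]
LogicalVector voxelize_core(NumericMatrix V, IntegerMatrix F,
                            IntegerVector dims, NumericVector spacing,
                            NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nt = F.nrow();
  LogicalVector occ((int64_t)nx * ny * nz);
  // rays are offset infinitesimally off the voxel-centre lattice so that
  // mesh edges lying exactly on lattice lines (ubiquitous for voxel-derived
  // meshes) cannot graze the ray; only points within ~1e-6 voxel of the
  // surface could be affected
  const double ey = 0.7548776662466927 * 1e-6 * spacing[1];
  const double ez = 0.5698402909980532 * 1e-6 * spacing[2];
  std::vector<double> xs;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2] + ez;
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1] + ey;
      xs.clear();
      for (int t = 0; t < nt; ++t) {
        int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
        double ay = V(a, 1) - py, az = V(a, 2) - pz;
        double by = V(b, 1) - py, bz = V(b, 2) - pz;
        double cy = V(c, 1) - py, cz = V(c, 2) - pz;
        // signed areas of projected edges (2D cross products)
        double d0 = ay * bz - az * by;
        double d1 = by * cz - bz * cy;
        double d2 = cy * az - cz * ay;
        bool pos = (d0 > 0) && (d1 > 0) && (d2 > 0);
        bool neg = (d0 < 0) && (d1 < 0) && (d2 < 0);
        if (!pos && !neg) continue;   // ray misses or grazes triangle
        double s = d0 + d1 + d2;
        double xhit = (d1 * V(a, 0) + d2 * V(b, 0) + d0 * V(c, 0)) / s;
        xs.push_back(xhit);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      int64_t rowbase = (int64_t)j * nx + (int64_t)k * nx * ny;
      for (int i = 0; i < nx; ++i) {
        double px = origin[0] + i * spacing[0];
        // parity of crossings strictly below px
        size_t n = std::lower_bound(xs.begin(), xs.end(), px) - xs.begin();
        if (n & 1) occ[rowbase + i] = true;
      }
    }
  }
  return occ;
}

// Nearest voxel with label 0 to (i,j,k) (0-based), expanding-shell search.
// Returns 0-based (i,j,k) or (-1,-1,-1) if the whole volume is occupied.
// [[Rcpp::export(name = ".nearest_free_voxel")]]
IntegerVector nearest_free_voxel(IntegerVector labels, IntegerVector dims,
                                 int i0, int j0, int k0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t sy = nx, sz = (int64_t)nx * ny;
  int rmax = std::max(std::max(nx, ny), nz);
  double best = R_PosInf;
  int bi = -1, bj = -1, bk = -1;
  for (int r = 0; r <= rmax; ++r) {
    if (best < (double)r * r) break;   // cannot improve beyond this shell
    int klo = std::max(0, k0 - r), khi = std::min(nz - 1, k0 + r);
    for (int k = klo; k <= khi; ++k) {
      int jlo = std::max(0, j0 - r), jhi = std::min(ny - 1, j0 + r);
      for (int j = jlo; j <= jhi; ++j) {
        bool onshell_jk = (std::abs(k - k0) == r) || (std::abs(j - j0) == r);
        int ilo = std::max(0, i0 - r), ihi = std::min(nx - 1, i0 + r);
        for (int i = ilo; i <= ihi; ++i) {
          if (!onshell_jk && std::abs(i - i0) != r) continue;
          if (labels[i + j * sy + k * sz] != 0) continue;
          double d = (double)(i - i0) * (i - i0) +
                     (double)(j - j0) * (j - j0) +
                     (double)(k - k0) * (k - k0);
          if (d < best) { best = d; bi = i; bj = j; bk = k; }
        }
      }
    }
  }
  return IntegerVector::create(bi, bj, bk);
}
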