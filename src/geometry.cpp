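#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra isosurface extraction.
//
// The scalar field lives on voxel centers. The lattice is padded with one
// virtual layer of zero-valued nodes on every side so that any support
// touching the grid boundary is capped and the resulting surface is closed.
// Each lattice cube is split into 6 tetrahedra (Kuhn split around the main
// diagonal); the split is consistent across shared cube faces, and within a
// tetrahedron the iso-contour is unambiguous, so the mesh is watertight by
// construction. Iso-vertices are keyed by the lattice edge they sit on and
// shared between all incident tetrahedra (vertex welding by construction).
// ---------------------------------------------------------------------------

// corner bit encoding: bit0 = +x, bit1 = +y, bit2 = +z
static const int KUHN_PERMS[6][2] = {
  {1, 2}, {1, 4}, {2, 1}, {2, 4}, {4, 1}, {4, 2}
};

// [[Rcpp::export]]
List mt_isosurface_cpp(NumericVector field, IntegerVector dims,
                       NumericVector origin, NumericVector spacing,
                       double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = REAL(field);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  // padded node index in 0..n+1 per axis; outside the stored field -> 0
  auto val = [&](int i, int j, int k) -> double {
    if (i < 1 || j < 1 || k < 1 || i > nx || j > ny || k > nz) return 0.0;
    return f[(size_t)(i - 1) +
             (size_t)nx * ((size_t)(j - 1) + (size_t)ny * (size_t)(k - 1))];
  };
  auto node_id = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)(nx + 2) *
           ((uint64_t)j + (uint64_t)(ny + 2) * (uint64_t)k);
  };

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> V;   // x,y,z triples
  std::vector<int> F;      // 1-based vertex index triples

  // world position of padded node
  auto npos = [&](int i, int j, int k, double *p) {
    p[0] = ox + (i - 1) * sx;
    p[1] = oy + (j - 1) * sy;
    p[2] = oz + (k - 1) * sz;
  };

  // vertex on the lattice edge (na-node, nb-node); canonical order by id
  auto edge_vert = [&](int ai, int aj, int ak, double va,
                       int bi, int bj, int bk, double vb) -> int {
    uint64_t ida = node_id(ai, aj, ak), idb = node_id(bi, bj, bk);
    if (ida > idb) {
      std::swap(ida, idb);
      std::swap(ai, bi); std::swap(aj, bj); std::swap(ak, bk);
      std::swap(va, vb);
    }
    uint64_t key = (ida << 32) | idb;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double pa[3], pb[3];
    npos(ai, aj, ak, pa);
    npos(bi, bj, bk, pb);
    double t = (level - va) / (vb - va);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int idx = (int)(V.size() / 3) + 1;
    V.push_back(pa[0] + t * (pb[0] - pa[0]));
    V.push_back(pa[1] + t * (pb[1] - pa[1]));
    V.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex.emplace(key, idx);
    return idx;
  };

  // emit a triangle oriented so its normal points from inside to outside
  auto emit = [&](int v0, int v1, int v2,
                  const double *pin, const double *pout) {
    const double *a = &V[(size_t)(v0 - 1) * 3];
    const double *b = &V[(size_t)(v1 - 1) * 3];
    const double *c = &V[(size_t)(v2 - 1) * 3];
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double w[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double n[3] = {u[1] * w[2] - u[2] * w[1],
                   u[2] * w[0] - u[0] * w[2],
                   u[0] * w[1] - u[1] * w[0]};
    double d[3] = {pout[0] - pin[0], pout[1] - pin[1], pout[2] - pin[2]};
    double dot = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
    if (dot < 0) std::swap(v1, v2);
    F.push_back(v0); F.push_back(v1); F.push_back(v2);
  };

  int ci[4], cj[4], ck[4];
  double cv[4];
  for (int k = 0; k <= nz; ++k) {
    for (int j = 0; j <= ny; ++j) {
      for (int i = 0; i <= nx; ++i) {
        // cube spanning padded nodes (i..i+1, j..j+1, k..k+1)
        double cube[8];
        int n_in = 0;
        for (int c = 0; c < 8; ++c) {
          cube[c] = val(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          if (cube[c] > level) ++n_in;
        }
        if (n_in == 0 || n_in == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int a = KUHN_PERMS[t][0], b = KUHN_PERMS[t][1];
          const int corners[4] = {0, a, a | b, 7};
          bool inside[4];
          int tin = 0;
          for (int c = 0; c < 4; ++c) {
            const int cc = corners[c];
            ci[c] = i + (cc & 1);
            cj[c] = j + ((cc >> 1) & 1);
            ck[c] = k + ((cc >> 2) & 1);
            cv[c] = cube[cc];
            inside[c] = cv[c] > level;
            if (inside[c]) ++tin;
          }
          if (tin == 0 || tin == 4) continue;
          // centroids of inside/outside corners for orientation
          double pin[3] = {0, 0, 0}, pout[3] = {0, 0, 0}, pp[3];
          for (int c = 0; c < 4; ++c) {
            npos(ci[c], cj[c], ck[c], pp);
            double *dst = inside[c] ? pin : pout;
            dst[0] += pp[0]; dst[1] += pp[1]; dst[2] += pp[2];
          }
          const double win = 1.0 / tin, wout = 1.0 / (4 - tin);
          for (int c = 0; c < 3; ++c) { pin[c] *= win; pout[c] *= wout; }
          if (tin == 1 || tin == 3) {
            const bool lone_in = (tin == 1);
            int s = -1, o[3], no = 0;
            for (int c = 0; c < 4; ++c) {
              if (inside[c] == lone_in) s = c; else o[no++] = c;
            }
            int v0 = edge_vert(ci[s], cj[s], ck[s], cv[s],
                               ci[o[0]], cj[o[0]], ck[o[0]], cv[o[0]]);
            int v1 = edge_vert(ci[s], cj[s], ck[s], cv[s],
                               ci[o[1]], cj[o[1]], ck[o[1]], cv[o[1]]);
            int v2 = edge_vert(ci[s], cj[s], ck[s], cv[s],
                               ci[o[2]], cj[o[2]], ck[o[2]], cv[o[2]]);
            emit(v0, v1, v2, pin, pout);
          } else {
            int in_[2], out_[2], a2 = 0, b2 = 0;
            for (int c = 0; c < 4; ++c) {
              if (inside[c]) in_[a2++] = c; else out_[b2++] = c;
            }
            // quad perimeter: (i0,o0) (i0,o1) (i1,o1) (i1,o0)
            int q0 = edge_vert(ci[in_[0]], cj[in_[0]], ck[in_[0]], cv[in_[0]],
                               ci[out_[0]], cj[out_[0]], ck[out_[0]], cv[out_[0]]);
            int q1 = edge_vert(ci[in_[0]], cj[in_[0]], ck[in_[0]], cv[in_[0]],
                               ci[out_[1]], cj[out_[1]], ck[out_[1]], cv[out_[1]]);
            int q2 = edge_vert(ci[in_[1]], cj[in_[1]], ck[in_[1]], cv[in_[1]],
                               ci[out_[1]], cj[out_[1]], ck[out_[1]], cv[out_[1]]);
            int q3 = edge_vert(ci[in_[1]], cj[in_[1]], ck[in_[1]], cv[in_[1]],
                               ci[out_[0]], cj[out_[0]], ck[out_[0]], cv[out_[0]]);
            emit(q0, q1, q2, pin, pout);
            emit(q0, q2, q3, pin, pout);
          }
        }
      }
    }
  }

  const int nv = (int)(V.size() / 3), nf = (int)(F.size() / 3);
  NumericMatrix verts(nv, 3);
  IntegerMatrix faces(nf, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = V[(size_t)v * 3];
    verts(v, 1) = V[(size_t)v * 3 + 1];
    verts(v, 2) = V[(size_t)v * 3 + 2];
  }
  for (int t = 0; t < nf; ++t) {
    faces(t, 0) = F[(size_t)t * 3];
    faces(t, 1) = F[(size_t)t * 3 + 1];
    faces(t, 2) = F[(size_t)t * 3 + 2];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// ---------------------------------------------------------------------------
// Parity ray-cast voxelization: a voxel is occupied iff a +x ray through
// (a deterministically jittered copy of) its center crosses the mesh an odd
// number of times before reaching it. The fixed sub-voxel jitter keeps rays
// off triangle edges and vertices, the classic degenerate cases.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector voxelize_raycast_cpp(NumericMatrix verts, IntegerMatrix faces,
                                   IntegerVector dims, NumericVector origin,
                                   NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // deterministic irrational-fraction jitter, < 1/4 voxel
  const double ey = 0.2132486540518586 * sy;
  const double ez = 0.1770326903534802 * sz;

  const int nrays = ny * nz;
  std::vector<std::vector<double>> hits(nrays);

  const int nf = faces.nrow();
  for (int t = 0; t < nf; ++t) {
    const int a = faces(t, 0) - 1, b = faces(t, 1) - 1, c = faces(t, 2) - 1;
    const double ay = verts(a, 1), az = verts(a, 2), ax = verts(a, 0);
    const double by = verts(b, 1), bz = verts(b, 2), bx = verts(b, 0);
    const double cy = verts(c, 1), cz = verts(c, 2), cx = verts(c, 0);
    const double ymin = std::min(ay, std::min(by, cy));
    const double ymax = std::max(ay, std::max(by, cy));
    const double zmin = std::min(az, std::min(bz, cz));
    const double zmax = std::max(az, std::max(bz, cz));
    int j0 = (int)std::ceil((ymin - oy - ey) / sy);
    int j1 = (int)std::floor((ymax - oy - ey) / sy);
    int k0 = (int)std::ceil((zmin - oz - ez) / sz);
    int k1 = (int)std::floor((zmax - oz - ez) / sz);
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    const double d1y = by - ay, d1z = bz - az;
    const double d2y = cy - ay, d2z = cz - az;
    const double det = d1y * d2z - d2y * d1z;
    if (std::fabs(det) < 1e-300) continue;  // projection-degenerate triangle
    const double inv = 1.0 / det;
    for (int k = k0; k <= k1; ++k) {
      const double pz = oz + k * sz + ez - az;
      for (int j = j0; j <= j1; ++j) {
        const double py = oy + j * sy + ey - ay;
        const double u = (py * d2z - d2y * pz) * inv;
        const double v = (d1y * pz - py * d1z) * inv;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        hits[j + (size_t)ny * k].push_back(
          ax + u * (bx - ax) + v * (cx - ax));
      }
    }
  }

  IntegerVector out((size_t)nx * ny * nz);
  std::fill(out.begin(), out.end(), 0);
  int *o = INTEGER(out);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      std::vector<double> &xs = hits[j + (size_t)ny * k];
      if (xs.empty()) continue;
      if (xs.size() % 2 != 0)
        stop("ray parity failure at ray (%d, %d): %d crossings "
             "(is the mesh watertight?)", j + 1, k + 1, (int)xs.size());
      std::sort(xs.begin(), xs.end());
      for (size_t m = 0; m + 1 < xs.size(); m += 2) {
        const double x0 = xs[m], x1 = xs[m + 1];
        int i0 = (int)std::ceil((x0 - ox) / sx);
        while (ox + i0 * sx <= x0) ++i0;
        int i1 = (int)std::floor((x1 - ox) / sx);
        while (ox + i1 * sx >= x1) --i1;
        if (i0 < 0) i0 = 0;
        if (i1 > nx - 1) i1 = nx - 1;
        for (int i = i0; i <= i1; ++i)
          o[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = 1;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling on a binary 3D mask (6- or 26-connectivity).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  const int *m = INTEGER(mask);
  IntegerVector labels(n);
  std::fill(labels.begin(), labels.end(), 0);
  int *lab = INTEGER(labels);

  std::vector<int> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back(di);
        offs.push_back(dj);
        offs.push_back(dk);
      }

  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t p = stack.back();
      stack.pop_back();
      const int i = (int)(p % nx);
      const int j = (int)((p / nx) % ny);
      const int k = (int)(p / ((size_t)nx * ny));
      for (size_t q = 0; q < offs.size(); q += 3) {
        const int ii = i + offs[q], jj = j + offs[q + 1], kk = k + offs[q + 2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        const size_t pp = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
        if (m[pp] && !lab[pp]) {
          lab[pp] = next;
          stack.push_back(pp);
        }
      }
    }
  }
  return labels;
}
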