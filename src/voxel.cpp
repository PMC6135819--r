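#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Voxel grids are passed as IntegerVector with a dim attribute (d1, d2, d3),
// column-major as in R. Linear index = i + d1*(j + d2*k), 0-based here.

static inline int lin(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

// offsets for 6- and 26-connectivity
static const int OFF6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(IntegerVector vox, int connectivity) {
  IntegerVector dim = vox.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  IntegerVector lab(vox.size(), 0);
  lab.attr("dim") = dim;

  std::vector<std::array<int,3>> offs;
  if (connectivity == 6) {
    for (auto &o : OFF6) offs.push_back({o[0], o[1], o[2]});
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c)
          if (a || b || c) offs.push_back({a, b, c});
  }

  int next = 0;
  std::queue<std::array<int,3>> q;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int p = lin(i, j, k, d1, d2);
        if (vox[p] == 0 || lab[p] != 0) continue;
        ++next;
        lab[p] = next;
        q.push({i, j, k});
        while (!q.empty()) {
          auto v = q.front(); q.pop();
          for (auto &o : offs) {
            int ni = v[0] + o[0], nj = v[1] + o[1], nk = v[2] + o[2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d1 || nj >= d2 || nk >= d3)
              continue;
            int np = lin(ni, nj, nk, d1, d2);
            if (vox[np] != 0 && lab[np] == 0) {
              lab[np] = next;
              q.push({ni, nj, nk});
            }
          }
        }
      }
  return lab;
}

// Fill background regions not connected to the grid border (internal cavities).
// Background connectivity is 6 (complement of 26-connected foreground).
// [[Rcpp::export(name = ".fill_cavities")]]
IntegerVector fill_cavities(IntegerVector vox) {
  IntegerVector dim = vox.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<uint8_t> outside(vox.size(), 0);
  std::queue<std::array<int,3>> q;
  // seed from all border background voxels
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        if (i != 0 && j != 0 && k != 0 && i != d1-1 && j != d2-1 && k != d3-1)
          continue;
        int p = lin(i, j, k, d1, d2);
        if (vox[p] == 0 && !outside[p]) {
          outside[p] = 1;
          q.push({i, j, k});
        }
      }
  while (!q.empty()) {
    auto v = q.front(); q.pop();
    for (auto &o : OFF6) {
      int ni = v[0] + o[0], nj = v[1] + o[1], nk = v[2] + o[2];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= d1 || nj >= d2 || nk >= d3)
        continue;
      int np = lin(ni, nj, nk, d1, d2);
      if (vox[np] == 0 && !outside[np]) {
        outside[np] = 1;
        q.push({ni, nj, nk});
      }
    }
  }
  IntegerVector out(vox.size());
  out.attr("dim") = dim;
  for (int p = 0; p < (int)vox.size(); ++p)
    out[p] = (vox[p] != 0 || !outside[p]) ? 1 : 0;
  return out;
}

// Repair critical configurations so the binary image is well-composed
// (its boundary is a 2-manifold).  Critical patterns (Latecki):
//  C1: a 2x2 axis-aligned square with foreground on one diagonal only;
//  C2: a 2x2x2 block whose foreground (or background) is exactly one pair of
//      antipodal corners.
// Repair flips background voxels to foreground; iterate until clean.
// [[Rcpp::export(name = ".well_compose")]]
IntegerVector well_compose(IntegerVector voxin, int max_pass = 50) {
  IntegerVector dim = voxin.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  IntegerVector vox = clone(voxin);
  for (int pass = 0; pass < max_pass; ++pass) {
    bool changed = false;
    // C1 squares in the three axis planes
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          // squares with low corner (i,j,k) in planes (i,j), (i,k), (j,k)
          for (int pl = 0; pl < 3; ++pl) {
            int a1 = 0, a2 = 0, b1 = 0, b2 = 0, c1 = 0, c2 = 0;
            if (pl == 0) { a1 = 1; b2 = 1; }        // vary i and j
            else if (pl == 1) { a1 = 1; c2 = 1; }   // vary i and k
            else { b1 = 1; c2 = 1; }                // vary j and k
            int i2 = i + a1 + a2, j2 = j + b1 + b2, k2 = k + c1 + c2;
            if (i + a1 >= d1 || j + b1 >= d2 || k + c1 >= d3) continue;
            if (i + a2 >= d1 || j + b2 >= d2 || k + c2 >= d3) continue;
            (void)i2; (void)j2; (void)k2;
            int p00 = lin(i, j, k, d1, d2);
            int p10 = lin(i + a1, j + b1, k + c1, d1, d2);
            int p01 = lin(i + a2, j + b2, k + c2, d1, d2);
            int p11 = lin(i + a1 + a2, j + b1 + b2, k + c1 + c2, d1, d2);
            bool f00 = vox[p00] != 0, f10 = vox[p10] != 0;
            bool f01 = vox[p01] != 0, f11 = vox[p11] != 0;
            if (f00 && f11 && !f10 && !f01) { vox[p10] = 1; changed = true; }
            else if (f10 && f01 && !f00 && !f11) { vox[p00] = 1; changed = true; }
          }
        }
    // C2 blocks
    for (int k = 0; k + 1 < d3; ++k)
      for (int j = 0; j + 1 < d2; ++j)
        for (int i = 0; i + 1 < d1; ++i) {
          int idx[8]; bool fg[8]; int nfg = 0;
          for (int c = 0; c < 8; ++c) {
            int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
            idx[c] = lin(ii, jj, kk, d1, d2);
            fg[c] = vox[idx[c]] != 0;
            if (fg[c]) ++nfg;
          }
          // antipodal corner pairs: (c, 7-c)
          if (nfg == 2) {
            for (int c = 0; c < 4; ++c)
              if (fg[c] && fg[7 - c]) { vox[idx[c ^ 1]] = 1; changed = true; }
          } else if (nfg == 6) {
            for (int c = 0; c < 4; ++c)
              if (!fg[c] && !fg[7 - c]) { vox[idx[c]] = 1; changed = true; }
          }
        }
    if (!changed) break;
  }
  return vox;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra over the voxel corner lattice.
// Each voxel (cell) is split into 6 tetrahedra around the main diagonal
// (Kuhn decomposition); the decomposition is consistent across shared faces.
// Cell corner c (0..7) has offset ((c&1), (c>>1)&1, (c>>2)&1); corner value =
// the voxel value of the cell itself sampled at corners? No: we march on the
// *dual* grid: sample points are voxel centers, cells connect 2x2x2 blocks of
// voxel centers.  Vertex positions are midpoints of crossing edges, in voxel
// center coordinates (voxel center of (i,j,k) sits at (i+0.5, j+0.5, k+0.5)
// in index space; the caller shifts/scales to physical units).
// ---------------------------------------------------------------------------

// 6 Kuhn tetrahedra: corner index paths 0 -> axis -> axis -> 7
static const int TETS[6][4] = {
  {0, 1, 3, 7},  // x, y, z
  {0, 1, 5, 7},  // x, z, y
  {0, 2, 3, 7},  // y, x, z
  {0, 2, 6, 7},  // y, z, x
  {0, 4, 5, 7},  // z, x, y
  {0, 4, 6, 7}   // z, y, x
};

struct MeshAcc {
  std::unordered_map<uint64_t, int> vkey;   // edge key -> vertex id
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int edge_vertex(MeshAcc &m, uint64_t ka, uint64_t kb,
                       const double *pa, const double *pb) {
  uint64_t lo = ka < kb ? ka : kb, hi = ka < kb ? kb : ka;
  uint64_t key = lo * 2000000011ULL + hi;
  auto it = m.vkey.find(key);
  if (it != m.vkey.end()) return it->second;
  int id = (int)m.vx.size();
  m.vkey.emplace(key, id);
  m.vx.push_back(0.5 * (pa[0] + pb[0]));
  m.vy.push_back(0.5 * (pa[1] + pb[1]));
  m.vz.push_back(0.5 * (pa[2] + pb[2]));
  return id;
}

static void emit_tri(MeshAcc &m, int a, int b, int c,
                     const double *fgdir) {
  // orient so normal points along fgdir (from foreground toward background)
  double ux = m.vx[b] - m.vx[a], uy = m.vy[b] - m.vy[a], uz = m.vz[b] - m.vz[a];
  double wx = m.vx[c] - m.vx[a], wy = m.vy[c] - m.vy[a], wz = m.vz[c] - m.vz[a];
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  double d = nx * fgdir[0] + ny * fgdir[1] + nz * fgdir[2];
  if (d >= 0) { m.f0.push_back(a); m.f1.push_back(b); m.f2.push_back(c); }
  else        { m.f0.push_back(a); m.f1.push_back(c); m.f2.push_back(b); }
}

// [[Rcpp::export(name = ".marching_tetrahedra")]]
List marching_tetrahedra(IntegerVector vox) {
  IntegerVector dim = vox.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  MeshAcc m;
  double P[8][3]; uint64_t K[8]; int val[8];
  for (int k = 0; k + 1 < d3; ++k)
    for (int j = 0; j + 1 < d2; ++j)
      for (int i = 0; i + 1 < d1; ++i) {
        int sum = 0;
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          val[c] = vox[lin(ii, jj, kk, d1, d2)] != 0;
          sum += val[c];
          P[c][0] = ii + 0.5; P[c][1] = jj + 0.5; P[c][2] = kk + 0.5;
          K[c] = (uint64_t)lin(ii, jj, kk, d1, d2);
        }
        if (sum == 0 || sum == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int fgc[4], bgc[4], nf = 0, nb = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[T[c]]) fgc[nf++] = T[c]; else bgc[nb++] = T[c];
          }
          if (nf == 0 || nf == 4) continue;
          // direction foreground centroid -> background centroid
          double fgdir[3];
          for (int a = 0; a < 3; ++a) {
            double fsum = 0, bsum = 0;
            for (int c = 0; c < nf; ++c) fsum += P[fgc[c]][a];
            for (int c = 0; c < nb; ++c) bsum += P[bgc[c]][a];
            fgdir[a] = bsum / nb - fsum / nf;
          }
          if (nf == 1) {
            int a = edge_vertex(m, K[fgc[0]], K[bgc[0]], P[fgc[0]], P[bgc[0]]);
            int b = edge_vertex(m, K[fgc[0]], K[bgc[1]], P[fgc[0]], P[bgc[1]]);
            int c = edge_vertex(m, K[fgc[0]], K[bgc[2]], P[fgc[0]], P[bgc[2]]);
            emit_tri(m, a, b, c, fgdir);
          } else if (nf == 3) {
            int a = edge_vertex(m, K[bgc[0]], K[fgc[0]], P[bgc[0]], P[fgc[0]]);
            int b = edge_vertex(m, K[bgc[0]], K[fgc[1]], P[bgc[0]], P[fgc[1]]);
            int c = edge_vertex(m, K[bgc[0]], K[fgc[2]], P[bgc[0]], P[fgc[2]]);
            emit_tri(m, a, b, c, fgdir);
          } else {
            // 2-2: quad m(a0,b0) m(a0,b1) m(a1,b1) m(a1,b0)
            int q0 = edge_vertex(m, K[fgc[0]], K[bgc[0]], P[fgc[0]], P[bgc[0]]);
            int q1 = edge_vertex(m, K[fgc[0]], K[bgc[1]], P[fgc[0]], P[bgc[1]]);
            int q2 = edge_vertex(m, K[fgc[1]], K[bgc[1]], P[fgc[1]], P[bgc[1]]);
            int q3 = edge_vertex(m, K[fgc[1]], K[bgc[0]], P[fgc[1]], P[bgc[0]]);
            emit_tri(m, q0, q1, q2, fgdir);
            emit_tri(m, q0, q2, q3, fgdir);
          }
        }
      }
  int nv = (int)m.vx.size(), nf = (int)m.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = m.vx[v]; V(v, 1) = m.vy[v]; V(v, 2) = m.vz[v];
  }
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = m.f0[f] + 1; F(f, 1) = m.f1[f] + 1; F(f, 2) = m.f2[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Simple-point test for the (26, 6) connectivity pair (Bertrand/Malandain):
// a foreground voxel p is simple iff
//   - the foreground of N26*(p) has exactly one 26-component, and
//   - the background of N18(p) has exactly one 6-component that is
//     6-adjacent to p.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".is_simple_point")]]
bool is_simple_point(IntegerVector vox, int i, int j, int k) {
  // i, j, k are 1-based from R; convert
  --i; --j; --k;
  IntegerVector dim = vox.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int nb[27];  // neighborhood values, index (a+1) + 3*(b+1) + 9*(c+1)
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        int ii = i + a, jj = j + b, kk = k + c;
        int v = 0;
        if (ii >= 0 && jj >= 0 && kk >= 0 && ii < d1 && jj < d2 && kk < d3)
          v = vox[lin(ii, jj, kk, d1, d2)] != 0;
        nb[(a + 1) + 3 * (b + 1) + 9 * (c + 1)] = v;
      }
  auto at = [&](int a, int b, int c) { return nb[(a+1) + 3*(b+1) + 9*(c+1)]; };
  // --- foreground 26-components in N26* (center excluded) ---
  int lab[27]; for (int t = 0; t < 27; ++t) lab[t] = 0;
  int ncomp_fg = 0;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        int t = (a+1) + 3*(b+1) + 9*(c+1);
        if (!nb[t] || lab[t]) continue;
        ++ncomp_fg;
        // BFS within neighborhood
        std::queue<std::array<int,3>> q;
        lab[t] = ncomp_fg; q.push({a, b, c});
        while (!q.empty()) {
          auto v = q.front(); q.pop();
          for (int dc = -1; dc <= 1; ++dc)
            for (int db = -1; db <= 1; ++db)
              for (int da = -1; da <= 1; ++da) {
                if (!da && !db && !dc) continue;
                int na = v[0] + da, nbb = v[1] + db, nc = v[2] + dc;
                if (na < -1 || nbb < -1 || nc < -1 || na > 1 || nbb > 1 || nc > 1)
                  continue;
                if (na == 0 && nbb == 0 && nc == 0) continue;
                int nt = (na+1) + 3*(nbb+1) + 9*(nc+1);
                if (nb[nt] && !lab[nt]) { lab[nt] = ncomp_fg; q.push({na, nbb, nc}); }
              }
        }
      }
  if (ncomp_fg != 1) return false;
  // --- background 6-components in N18 that touch a face neighbor ---
  int blab[27]; for (int t = 0; t < 27; ++t) blab[t] = 0;
  int ncomp_bg = 0;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        int man = std::abs(a) + std::abs(b) + std::abs(c);
        if (man == 0 || man == 3) continue;       // N18 only
        int t = (a+1) + 3*(b+1) + 9*(c+1);
        if (nb[t] || blab[t]) continue;
        if (man != 1) continue;                   // seed only from face neighbors
        ++ncomp_bg;
        std::queue<std::array<int,3>> q;
        blab[t] = ncomp_bg; q.push({a, b, c});
        while (!q.empty()) {
          auto v = q.front(); q.pop();
          static const int O6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
          for (auto &o : O6) {
            int na = v[0]+o[0], nbb = v[1]+o[1], nc = v[2]+o[2];
            if (na < -1 || nbb < -1 || nc < -1 || na > 1 || nbb > 1 || nc > 1)
              continue;
            int man2 = std::abs(na) + std::abs(nbb) + std::abs(nc);
            if (man2 == 0 || man2 == 3) continue;
            int nt = (na+1) + 3*(nbb+1) + 9*(nc+1);
            if (!nb[nt] && !blab[nt]) { blab[nt] = ncomp_bg; q.push({na, nbb, nc}); }
          }
        }
      }
  (void)at;
  return ncomp_bg == 1;
}
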