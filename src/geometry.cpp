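#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection against a whole mesh.
// Vertices are V x 3, triangles F x 3 with 1-based indices (R convention).
// For each ray the nearest hit with strictly positive ray parameter is kept;
// exact ties on the parameter go to the lowest triangle index (ascending scan
// with strict '<'). Degenerate triangles (|det| <= eps) are skipped.

static const double MT_EPS = 1e-12;
static const double BARY_TOL = 1e-9;

// [[Rcpp::export]]
List cpp_ray_mesh(NumericMatrix origins, NumericMatrix dirs,
                  NumericMatrix V, IntegerMatrix F) {
  const int K = dirs.nrow(), nf = F.nrow();
  const bool one_origin = origins.nrow() == 1;
  NumericVector t_out(K, NA_REAL);
  IntegerVector tri_out(K, NA_INTEGER);
  NumericMatrix pts(K, 3);
  std::fill(pts.begin(), pts.end(), NA_REAL);

  for (int k = 0; k < K; ++k) {
    const int ko = one_origin ? 0 : k;
    const double ox = origins(ko, 0), oy = origins(ko, 1), oz = origins(ko, 2);
    const double dx = dirs(k, 0), dy = dirs(k, 1), dz = dirs(k, 2);
    double best_t = R_PosInf;
    int best_tri = -1;

    for (int f = 0; f < nf; ++f) {
      const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
      const double ax = V(i0, 0), ay = V(i0, 1), az = V(i0, 2);
      const double e1x = V(i1, 0) - ax, e1y = V(i1, 1) - ay, e1z = V(i1, 2) - az;
      const double e2x = V(i2, 0) - ax, e2y = V(i2, 1) - ay, e2z = V(i2, 2) - az;
      // p = dir x e2
      const double px = dy * e2z - dz * e2y;
      const double py = dz * e2x - dx * e2z;
      const double pz = dx * e2y - dy * e2x;
      const double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) <= MT_EPS) continue;
      const double inv = 1.0 / det;
      const double tx = ox - ax, ty = oy - ay, tz = oz - az;
      const double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -BARY_TOL || u > 1.0 + BARY_TOL) continue;
      // q = t x e1
      const double qx = ty * e1z - tz * e1y;
      const double qy = tz * e1x - tx * e1z;
      const double qz = tx * e1y - ty * e1x;
      const double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -BARY_TOL || u + v > 1.0 + BARY_TOL) continue;
      const double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t <= MT_EPS) continue;
      if (t < best_t) { best_t = t; best_tri = f; }
    }
    if (best_tri >= 0) {
      t_out[k] = best_t;
      tri_out[k] = best_tri + 1;
      pts(k, 0) = ox + best_t * dx;
      pts(k, 1) = oy + best_t * dy;
      pts(k, 2) = oz + best_t * dz;
    }
  }
  return List::create(_["t"] = t_out, _["triangle"] = tri_out, _["point"] = pts);
}

// Number of intersections with t > 0 per ray (for ray-parity inside tests).
// [[Rcpp::export]]
IntegerVector cpp_ray_mesh_count(NumericMatrix origins, NumericMatrix dirs,
                                 NumericMatrix V, IntegerMatrix F) {
  const int K = dirs.nrow(), nf = F.nrow();
  const bool one_origin = origins.nrow() == 1;
  IntegerVector cnt(K, 0);
  for (int k = 0; k < K; ++k) {
    const int ko = one_origin ? 0 : k;
    const double ox = origins(ko, 0), oy = origins(ko, 1), oz = origins(ko, 2);
    const double dx = dirs(k, 0), dy = dirs(k, 1), dz = dirs(k, 2);
    for (int f = 0; f < nf; ++f) {
      const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
      const double ax = V(i0, 0), ay = V(i0, 1), az = V(i0, 2);
      const double e1x = V(i1, 0) - ax, e1y = V(i1, 1) - ay, e1z = V(i1, 2) - az;
      const double e2x = V(i2, 0) - ax, e2y = V(i2, 1) - ay, e2z = V(i2, 2) - az;
      const double px = dy * e2z - dz * e2y;
      const double py = dz * e2x - dx * e2z;
      const double pz = dx * e2y - dy * e2x;
      const double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) <= MT_EPS) continue;
      const double inv = 1.0 / det;
      const double tx = ox - ax, ty = oy - ay, tz = oz - az;
      const double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -BARY_TOL || u > 1.0 + BARY_TOL) continue;
      const double qx = ty * e1z - tz * e1y;
      const double qy = tz * e1x - tx * e1z;
      const double qz = tx * e1y - ty * e1x;
      const double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -BARY_TOL || u + v > 1.0 + BARY_TOL) continue;
      const double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t > MT_EPS) cnt[k] += 1;
    }
  }
  return cnt;
}

// Nearest mesh vertex per query point: returns 1-based index and distance.
// [[Rcpp::export]]
List cpp_nearest_vertex(NumericMatrix P, NumericMatrix V) {
  const int K = P.nrow(), n = V.nrow();
  IntegerVector idx(K);
  NumericVector dist(K);
  for (int k = 0; k < K; ++k) {
    const double x = P(k, 0), y = P(k, 1), z = P(k, 2);
    double best = R_PosInf;
    int bi = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = V(i, 0) - x, dy = V(i, 1) - y, dz = V(i, 2) - z;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = i; }
    }
    idx[k] = bi + 1;
    dist[k] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

static inline int64_t cell_key(int cx, int cy, int cz) {
  // pack three signed cell coordinates into one key (21 bits each)
  const int64_t B = 1 << 20;
  return ((int64_t)(cx + B) << 42) | ((int64_t)(cy + B) << 21) | (int64_t)(cz + B);
}

// Inter-shell proximity penalty: sum over unordered pairs of distinct shells,
// over vertex pairs closer than T, of (T - distance). Exact radius-T search
// via a uniform grid hash with cell size T.
// P: (sum of shell sizes) x 3, shell: integer label per row.
// [[Rcpp::export]]
double cpp_penalty_g(NumericMatrix P, IntegerVector shell, double T) {
  const int n = P.nrow();
  std::unordered_multimap<int64_t, int> grid;
  grid.reserve(n * 2);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(P(i, 0) / T);
    cy[i] = (int)std::floor(P(i, 1) / T);
    cz[i] = (int)std::floor(P(i, 2) / T);
    grid.emplace(cell_key(cx[i], cy[i], cz[i]), i);
  }
  const double T2 = T * T;
  // enumerate each unordered cell pair once: the same cell (j > i) plus the
  // 13 neighbour offsets in the lexicographically positive half-space
  static const int HO[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0}, {1, -1, 0}, {1, 0, 1},
    {1, 0, -1}, {0, 1, 1}, {0, 1, -1}, {1, 1, 1}, {1, 1, -1}, {1, -1, 1},
    {1, -1, -1}};
  double g = 0.0;
  for (int i = 0; i < n; ++i) {
    const double x = P(i, 0), y = P(i, 1), z = P(i, 2);
    {
      auto range = grid.equal_range(cell_key(cx[i], cy[i], cz[i]));
      for (auto it = range.first; it != range.second; ++it) {
        const int j = it->second;
        if (j <= i || shell[j] == shell[i]) continue;
        const double dx = P(j, 0) - x, dy = P(j, 1) - y, dz = P(j, 2) - z;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < T2) g += T - std::sqrt(d2);
      }
    }
    for (int o = 0; o < 13; ++o) {
      auto range = grid.equal_range(cell_key(cx[i] + HO[o][0], cy[i] + HO[o][1],
                                             cz[i] + HO[o][2]));
      for (auto it = range.first; it != range.second; ++it) {
        const int j = it->second;
        if (shell[j] == shell[i]) continue;
        const double dx = P(j, 0) - x, dy = P(j, 1) - y, dz = P(j, 2) - z;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < T2) g += T - std::sqrt(d2);
      }
    }
  }
  return g;
}

// Raytracing specialization for star-shaped meshes with all rays sharing one
// origin (the star centre): triangles are pruned by an angular cone around
// the triangle centroid whose aperture bounds the triangle's angular extent
// from the origin. A pruned miss falls back to the full scan, so results are
// identical to cpp_ray_mesh for a shared origin.
// [[Rcpp::export]]
List cpp_ray_mesh_star(NumericVector origin, NumericMatrix dirs,
                       NumericMatrix V, IntegerMatrix F) {
  const int K = dirs.nrow(), nf = F.nrow();
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // per-triangle centroid direction and cone cosine bound
  std::vector<double> cxd(nf), cyd(nf), czd(nf), cosb(nf);
  for (int f = 0; f < nf; ++f) {
    double ux[3], uy[3], uz[3];
    for (int k = 0; k < 3; ++k) {
      const int i = F(f, k) - 1;
      double vx = V(i, 0) - ox, vy = V(i, 1) - oy, vz = V(i, 2) - oz;
      const double n = std::sqrt(vx * vx + vy * vy + vz * vz);
      if (n > 0) { vx /= n; vy /= n; vz /= n; }
      ux[k] = vx; uy[k] = vy; uz[k] = vz;
    }
    double cx = ux[0] + ux[1] + ux[2];
    double cy = uy[0] + uy[1] + uy[2];
    double cz = uz[0] + uz[1] + uz[2];
    const double cn = std::sqrt(cx * cx + cy * cy + cz * cz);
    if (cn > 0) { cx /= cn; cy /= cn; cz /= cn; }
    double mind = 1.0;
    for (int k = 0; k < 3; ++k) {
      const double d = cx * ux[k] + cy * uy[k] + cz * uz[k];
      if (d < mind) mind = d;
    }
    cxd[f] = cx; cyd[f] = cy; czd[f] = cz;
    // widen the cone slightly; exactness is restored by the fallback scan
    cosb[f] = mind - 1e-6 - 0.25 * (1.0 - mind);
  }

  NumericVector t_out(K, NA_REAL);
  IntegerVector tri_out(K, NA_INTEGER);
  NumericMatrix pts(K, 3);
  std::fill(pts.begin(), pts.end(), NA_REAL);

  for (int k = 0; k < K; ++k) {
    const double dx = dirs(k, 0), dy = dirs(k, 1), dz = dirs(k, 2);
    double best_t = R_PosInf;
    int best_tri = -1;
    for (int pass = 0; pass < 2 && best_tri < 0; ++pass) {
      for (int f = 0; f < nf; ++f) {
        if (pass == 0) {
          const double ca = dx * cxd[f] + dy * cyd[f] + dz * czd[f];
          if (ca < cosb[f]) continue;
        }
        const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
        const double ax = V(i0, 0), ay = V(i0, 1), az = V(i0, 2);
        const double e1x = V(i1, 0) - ax, e1y = V(i1, 1) - ay, e1z = V(i1, 2) - az;
        const double e2x = V(i2, 0) - ax, e2y = V(i2, 1) - ay, e2z = V(i2, 2) - az;
        const double px = dy * e2z - dz * e2y;
        const double py = dz * e2x - dx * e2z;
        const double pz = dx * e2y - dy * e2x;
        const double det = e1x * px + e1y * py + e1z * pz;
        if (std::fabs(det) <= MT_EPS) continue;
        const double inv = 1.0 / det;
        const double tx = ox - ax, ty = oy - ay, tz = oz - az;
        const double u = (tx * px + ty * py + tz * pz) * inv;
        if (u < -BARY_TOL || u > 1.0 + BARY_TOL) continue;
        const double qx = ty * e1z - tz * e1y;
        const double qy = tz * e1x - tx * e1z;
        const double qz = tx * e1y - ty * e1x;
        const double v = (dx * qx + dy * qy + dz * qz) * inv;
        if (v < -BARY_TOL || u + v > 1.0 + BARY_TOL) continue;
        const double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
        if (t <= MT_EPS) continue;
        if (t < best_t || (t == best_t && f + 1 < best_tri)) {
          best_t = t; best_tri = f;
        }
      }
    }
    if (best_tri >= 0) {
      t_out[k] = best_t;
      tri_out[k] = best_tri + 1;
      pts(k, 0) = ox + best_t * dx;
      pts(k, 1) = oy + best_t * dy;
      pts(k, 2) = oz + best_t * dz;
    }
  }
  return List::create(_["t"] = t_out, _["triangle"] = tri_out, _["point"] = pts);
}
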