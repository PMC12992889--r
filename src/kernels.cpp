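#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Ball structuring-element offsets in voxel units for a radius given in mm,
// under (possibly anisotropic) voxel spacing.
static void ball_offsets(double radius_mm, const double *sp,
                         std::vector<int> &dx, std::vector<int> &dy,
                         std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  if (radius_mm <= 0) { dx.push_back(0); dy.push_back(0); dz.push_back(0); return; }
  int rx = (int)std::floor(radius_mm / sp[0]);
  int ry = (int)std::floor(radius_mm / sp[1]);
  int rz = (int)std::floor(radius_mm / sp[2]);
  double r2 = radius_mm * radius_mm;
  for (int k = -rz; k <= rz; ++k)
    for (int j = -ry; j <= ry; ++j)
      for (int i = -rx; i <= rx; ++i) {
        double d2 = i * sp[0] * i * sp[0] + j * sp[1] * j * sp[1] +
                    k * sp[2] * k * sp[2];
        if (d2 <= r2) { dx.push_back(i); dy.push_back(j); dz.push_back(k); }
      }
}

// Iterative threshold-descent ordering of in-mask voxels.
//
// Seed = in-mask voxels at the in-mask HU maximum (step 0). The inclusion
// threshold then descends by hu_step; at each step the not-yet-included
// in-mask voxels at or above the threshold join with the current step index,
// after which one morphological closing (ball of closing_radius_mm, physical
// units) of the included region is applied, clipped to the mask; voxels
// closed in receive the same step index. The closing is maintained
// incrementally: the dilation D of the included set only ever grows, and a
// voxel can newly satisfy "ball(v) subset of D" only if it lies within one
// radius of the voxels D just gained.
//
// Returns 0-based step index per voxel (-1 outside mask) and the cumulative
// included count at the end of each step.
// [[Rcpp::export]]
List cpp_threshold_descent(NumericVector vol, LogicalVector mask,
                           IntegerVector dim, NumericVector spacing,
                           double closing_radius_mm, double hu_step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double sp[3] = { spacing[0], spacing[1], spacing[2] };
  const bool do_close = closing_radius_mm > 0;

  std::vector<int> bx, by, bz;
  ball_offsets(closing_radius_mm, sp, bx, by, bz);
  const size_t nb = bx.size();

  // in-mask voxels sorted by descending HU
  std::vector<R_xlen_t> mv;
  mv.reserve(1024);
  for (R_xlen_t v = 0; v < n; ++v) if (mask[v]) mv.push_back(v);
  const R_xlen_t nmask = (R_xlen_t)mv.size();
  if (nmask == 0) stop("mask is empty");
  std::sort(mv.begin(), mv.end(), [&](R_xlen_t a, R_xlen_t b) {
    return vol[a] > vol[b];
  });
  const double hu_max = vol[mv.front()];

  IntegerVector step_idx(n, -1);
  std::vector<char> inD(do_close ? (size_t)n : 0, 0);
  std::vector<int> cand_stamp(do_close ? (size_t)n : 0, -1);
  std::vector<R_xlen_t> newD, cands;
  std::vector<int> cum;
  cum.reserve(256);

  R_xlen_t ptr = 0;       // next position in the sorted order
  R_xlen_t n_inc = 0;
  int step = 0;
  double thr = hu_max;

  auto dilate_from = [&](R_xlen_t v, bool collect) {
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
    for (size_t b = 0; b < nb; ++b) {
      int xx = x + bx[b], yy = y + by[b], zz = z + bz[b];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * yy + (R_xlen_t)nx * ny * zz;
      if (!inD[w]) { inD[w] = 1; if (collect) newD.push_back(w); }
    }
  };

  while (true) {
    // threshold additions for this step
    newD.clear();
    std::vector<R_xlen_t> added;
    while (ptr < nmask && vol[mv[ptr]] >= thr) {
      R_xlen_t v = mv[ptr++];
      if (step_idx[v] >= 0) continue;  // closed in at an earlier step
      step_idx[v] = step;
      ++n_inc;
      if (do_close) dilate_from(v, true);
      added.push_back(v);
    }

    if (do_close && !newD.empty()) {
      // candidate voxels: within one ball radius of the dilation's growth
      cands.clear();
      for (size_t q = 0; q < newD.size(); ++q) {
        R_xlen_t w = newD[q];
        int x = (int)(w % nx), y = (int)((w / nx) % ny), z = (int)(w / ((R_xlen_t)nx * ny));
        for (size_t b = 0; b < nb; ++b) {
          int xx = x + bx[b], yy = y + by[b], zz = z + bz[b];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          R_xlen_t c = (R_xlen_t)xx + (R_xlen_t)nx * yy + (R_xlen_t)nx * ny * zz;
          if (!mask[c] || step_idx[c] >= 0 || cand_stamp[c] == step) continue;
          cand_stamp[c] = step;
          cands.push_back(c);
        }
      }
      // erosion test against the dilation as it stands after the additions
      std::vector<R_xlen_t> closed_in;
      for (size_t q = 0; q < cands.size(); ++q) {
        R_xlen_t c = cands[q];
        int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((R_xlen_t)nx * ny));
        bool ok = true;
        for (size_t b = 0; b < nb && ok; ++b) {
          int xx = x + bx[b], yy = y + by[b], zz = z + bz[b];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) { ok = false; break; }
          R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * yy + (R_xlen_t)nx * ny * zz;
          if (!inD[w]) ok = false;
        }
        if (ok) closed_in.push_back(c);
      }
      for (size_t q = 0; q < closed_in.size(); ++q) {
        R_xlen_t c = closed_in[q];
        step_idx[c] = step;
        ++n_inc;
        dilate_from(c, false);  // keep D = dilation(included) for later steps
      }
    }

    cum.push_back((int)n_inc);
    if (n_inc >= nmask) break;
    thr -= hu_step;
    ++step;
    if (step > 100000000) stop("threshold descent failed to terminate");
  }

  return List::create(_["step"] = step_idx,
                      _["cum_count"] = IntegerVector(cum.begin(), cum.end()),
                      _["n_mask"] = (double)nmask);
}

static inline double sample_trilinear(const double *vol, int nx, int ny, int nz,
                                      double x, double y, double z, bool &ok) {
  // x,y,z in continuous voxel coordinates (voxel centre i at i + 0.5)
  double fx = x - 0.5, fy = y - 0.5, fz = z - 0.5;
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  if (i0 < -1 || i0 >= nx || j0 < -1 || j0 >= ny || k0 < -1 || k0 >= nz) {
    ok = false; return 0.0;
  }
  ok = true;
  double acc = 0.0, wsum = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
        double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
        acc += w * vol[(R_xlen_t)i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k];
        wsum += w;
      }
  if (wsum <= 0) { ok = false; return 0.0; }
  return acc / wsum;
}

// Masked maximum-intensity projection by ray casting.
//
// The view frame is (u = image column, t = ray direction, v = image row);
// a world point is p = center_mm + R %*% c(u, t, v). With R = identity the
// ray direction is the volume's anteroposterior (second) axis, i.e. the
// baseline AP view. HU are sampled trilinearly; the region mask is sampled
// nearest-neighbour and gates each ray sample, so the projection over a
// union of regions is exactly the pixelwise maximum of the per-region
// projections. Pixels whose ray never meets the mask return NA.
// [[Rcpp::export]]
NumericMatrix cpp_render_mip(NumericVector vol, LogicalVector mask,
                             IntegerVector dim, NumericVector spacing,
                             NumericMatrix rot, NumericVector center_mm,
                             int out_size, double side_mm,
                             double ray_len_mm, double ray_step_mm,
                             NumericVector bbox_lo, NumericVector bbox_hi) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double *V = REAL(vol);
  const int *M = LOGICAL(mask);
  NumericMatrix out(out_size, out_size);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double R00 = rot(0, 0), R01 = rot(0, 1), R02 = rot(0, 2);
  const double R10 = rot(1, 0), R11 = rot(1, 1), R12 = rot(1, 2);
  const double R20 = rot(2, 0), R21 = rot(2, 1), R22 = rot(2, 2);
  const int nt = std::max(1, (int)std::ceil(ray_len_mm / ray_step_mm));

  // mask bounding box transformed into the view frame (u, t, v): rays only
  // need to be sampled where they can meet the mask
  double ulo = 1e30, uhi = -1e30, tlo = 1e30, thi = -1e30,
         vlo = 1e30, vhi = -1e30;
  for (int c = 0; c < 8; ++c) {
    double px = ((c & 1) ? bbox_hi[0] : bbox_lo[0]) - center_mm[0];
    double py = ((c & 2) ? bbox_hi[1] : bbox_lo[1]) - center_mm[1];
    double pz = ((c & 4) ? bbox_hi[2] : bbox_lo[2]) - center_mm[2];
    double uu = R00 * px + R10 * py + R20 * pz;   // R^T (p - center)
    double tt = R01 * px + R11 * py + R21 * pz;
    double vv = R02 * px + R12 * py + R22 * pz;
    ulo = std::min(ulo, uu); uhi = std::max(uhi, uu);
    tlo = std::min(tlo, tt); thi = std::max(thi, tt);
    vlo = std::min(vlo, vv); vhi = std::max(vhi, vv);
  }
  const double margin = ray_step_mm + std::max(sx, std::max(sy, sz));
  ulo -= margin; uhi += margin; tlo -= margin; thi += margin;
  vlo -= margin; vhi += margin;

  for (int col = 0; col < out_size; ++col) {
    double u = (col + 0.5) / out_size * side_mm - side_mm / 2.0;
    if (u < ulo || u > uhi) continue;
    for (int row = 0; row < out_size; ++row) {
      double v = (row + 0.5) / out_size * side_mm - side_mm / 2.0;
      if (v < vlo || v > vhi) continue;
      double best = NA_REAL;
      bool hit = false;
      for (int it = 0; it < nt; ++it) {
        double t = -ray_len_mm / 2.0 + (it + 0.5) * ray_step_mm;
        if (t < tlo || t > thi) continue;
        double px = center_mm[0] + R00 * u + R01 * t + R02 * v;
        double py = center_mm[1] + R10 * u + R11 * t + R12 * v;
        double pz = center_mm[2] + R20 * u + R21 * t + R22 * v;
        // continuous voxel coordinates
        double cx = px / sx, cy = py / sy, cz = pz / sz;
        int ix = (int)std::floor(cx), iy = (int)std::floor(cy), iz = (int)std::floor(cz);
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) continue;
        if (!M[(R_xlen_t)ix + (R_xlen_t)nx * iy + (R_xlen_t)nx * ny * iz]) continue;
        bool ok;
        double s = sample_trilinear(V, nx, ny, nz, cx, cy, cz, ok);
        if (!ok) continue;
        if (!hit || s > best) { best = s; hit = true; }
      }
      if (hit) out(row, col) = best;  // row = image vertical, col = horizontal
    }
  }
  return out;
}

// Grayscale dilation restricted to a target region: each target voxel takes
// the maximum of the source volume over a ball of the given physical radius.
// Voxels outside the target are returned unchanged.
// [[Rcpp::export]]
NumericVector cpp_gray_dilate_in(NumericVector vol, LogicalVector target,
                                 IntegerVector dim, NumericVector spacing,
                                 double radius_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sp[3] = { spacing[0], spacing[1], spacing[2] };
  std::vector<int> bx, by, bz;
  ball_offsets(radius_mm, sp, bx, by, bz);
  const size_t nb = bx.size();
  NumericVector out = clone(vol);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!target[v]) continue;
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
    double best = vol[v];
    for (size_t b = 0; b < nb; ++b) {
      int xx = x + bx[b], yy = y + by[b], zz = z + bz[b];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      double s = vol[(R_xlen_t)xx + (R_xlen_t)nx * yy + (R_xlen_t)nx * ny * zz];
      if (s > best) best = s;
    }
    out[v] = best;
  }
  return out;
}

// Distance from grid points to a line segment, thresholded at a radius:
// returns logical vector marking voxels whose centre lies within radius_mm
// of the segment p0-p1 (all in mm). Used to rasterise vessel capsules.
// [[Rcpp::export]]
LogicalVector cpp_capsule_mask(IntegerVector dim, NumericVector spacing,
                               NumericVector p0, NumericVector p1,
                               double radius_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  double dx = p1[0] - p0[0], dy = p1[1] - p0[1], dz = p1[2] - p0[2];
  double L2 = dx * dx + dy * dy + dz * dz;
  // bounding box in voxel indices
  double lo[3] = { std::min(p0[0], p1[0]) - radius_mm,
                   std::min(p0[1], p1[1]) - radius_mm,
                   std::min(p0[2], p1[2]) - radius_mm };
  double hi[3] = { std::max(p0[0], p1[0]) + radius_mm,
                   std::max(p0[1], p1[1]) + radius_mm,
                   std::max(p0[2], p1[2]) + radius_mm };
  int i0 = std::max(0, (int)std::floor(lo[0] / sx - 0.5));
  int i1 = std::min(nx - 1, (int)std::ceil(hi[0] / sx - 0.5));
  int j0 = std::max(0, (int)std::floor(lo[1] / sy - 0.5));
  int j1 = std::min(ny - 1, (int)std::ceil(hi[1] / sy - 0.5));
  int k0 = std::max(0, (int)std::floor(lo[2] / sz - 0.5));
  int k1 = std::min(nz - 1, (int)std::ceil(hi[2] / sz - 0.5));
  double r2 = radius_mm * radius_mm;
  for (int k = k0; k <= k1; ++k)
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double px = (i + 0.5) * sx, py = (j + 0.5) * sy, pz = (k + 0.5) * sz;
        double wx = px - p0[0], wy = py - p0[1], wz = pz - p0[2];
        double tt = L2 > 0 ? (wx * dx + wy * dy + wz * dz) / L2 : 0.0;
        if (tt < 0) tt = 0; else if (tt > 1) tt = 1;
        double qx = wx - tt * dx, qy = wy - tt * dy, qz = wz - tt * dz;
        if (qx * qx + qy * qy + qz * qz <= r2)
          out[(R_xlen_t)i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k] = true;
      }
  return out;
}

// In-place Adam update with optional coupled L2 weight decay. w, m, v are
// modified in place (the caller owns them exclusively during training);
// avoids allocating six full-size temporaries per step in R.
// [[Rcpp::export]]
void cpp_adam_step(NumericVector w, NumericVector g, NumericVector m,
                   NumericVector v, double lr, int t, double weight_decay,
                   double beta1, double beta2, double eps) {
  const R_xlen_t n = w.size();
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  double *W = REAL(w), *G = REAL(g), *M = REAL(m), *V = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = G[i] + weight_decay * W[i];
    M[i] = beta1 * M[i] + (1 - beta1) * gi;
    V[i] = beta2 * V[i] + (1 - beta2) * gi * gi;
    W[i] -= lr * (M[i] / c1) / (std::sqrt(V[i] / c2) + eps);
  }
}
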