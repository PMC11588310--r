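#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// All volumes are R arrays laid out (z, y, x), column-major:
// linear index = z + nz*(y + ny*x), 0-based here, 1-based at the R boundary.

// Separable 1D convolution along one axis with border renormalization
// (kernel weights falling outside the grid are dropped and the remaining
// weights rescaled to sum to one, so a constant image stays constant).
// [[Rcpp::export]]
NumericVector conv_axis_3d(NumericVector vol, IntegerVector dim, int axis,
                           NumericVector kernel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int K = kernel.size(), half = K / 2;
  NumericVector out(vol.size());
  const int st[3] = {1, nz, nz * ny};
  const int len = dim[axis];
  int a1, a2;
  if (axis == 0)      { a1 = 1; a2 = 2; }
  else if (axis == 1) { a1 = 0; a2 = 2; }
  else                { a1 = 0; a2 = 1; }
  const int d1 = dim[a1], d2 = dim[a2], s1 = st[a1], s2 = st[a2], sa = st[axis];
  for (int i2 = 0; i2 < d2; ++i2) {
    for (int i1 = 0; i1 < d1; ++i1) {
      const int base = i1 * s1 + i2 * s2;
      for (int t = 0; t < len; ++t) {
        const int jlo = std::max(-half, -t);
        const int jhi = std::min(half, len - 1 - t);
        double acc = 0.0, w = 0.0;
        for (int j = jlo; j <= jhi; ++j) {
          const double kv = kernel[half + j];
          acc += kv * vol[base + (t + j) * sa];
          w += kv;
        }
        out[base + t * sa] = (w > 0) ? acc / w : 0.0;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Strict local maxima over the 26-neighborhood; plateaus resolved by keeping
// the lowest linear index. Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector local_maxima_3d(NumericVector vol, IntegerVector dim,
                              double threshold, LogicalVector mask) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const bool use_mask = (mask.size() == vol.size());
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const int i = z + nz * (y + ny * x);
        const double v = vol[i];
        if (!(v > threshold)) continue;
        if (use_mask && !mask[i]) continue;
        bool ismax = true;
        for (int ddx = -1; ddx <= 1 && ismax; ++ddx) {
          const int xx = x + ddx;
          if (xx < 0 || xx >= nx) continue;
          for (int ddy = -1; ddy <= 1 && ismax; ++ddy) {
            const int yy = y + ddy;
            if (yy < 0 || yy >= ny) continue;
            for (int ddz = -1; ddz <= 1 && ismax; ++ddz) {
              const int zz = z + ddz;
              if (zz < 0 || zz >= nz) continue;
              const int j = zz + nz * (yy + ny * xx);
              if (j == i) continue;
              if (vol[j] > v || (vol[j] == v && j < i)) ismax = false;
            }
          }
        }
        if (ismax) hits.push_back(i + 1);
      }
    }
  }
  return wrap(hits);
}

// Seeded region growing on the enhanced response. Each seed claims the
// 6-connected component of voxels with response >= growth_fraction * its own
// peak; voxels claimed by several seeds go to the physically nearer peak,
// exact ties to the lower seed id (seeds are passed in id order).
// [[Rcpp::export]]
IntegerVector grow_blobs_3d(NumericVector enh, IntegerVector dim,
                            IntegerVector seeds, double growth_fraction,
                            NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  IntegerVector owner(n, 0);
  std::vector<double> bestd(n, 0.0);
  std::vector<int> stamp(n, 0);
  std::vector<int> queue;
  queue.reserve(4096);
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const int ns = seeds.size();
  for (int s = 0; s < ns; ++s) {
    const int sid = s + 1;
    const int s0 = seeds[s] - 1;
    const double peak = enh[s0];
    if (!(peak > 0)) continue;
    const double thr = growth_fraction * peak;
    const int sz = s0 % nz, sy = (s0 / nz) % ny, sx = s0 / (nz * ny);
    queue.clear();
    queue.push_back(s0);
    stamp[s0] = sid;
    size_t head = 0;
    while (head < queue.size()) {
      const int i = queue[head++];
      const int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
      const double ddz = (z - sz) * dz, ddy = (y - sy) * dy, ddx = (x - sx) * dx;
      const double d = ddz * ddz + ddy * ddy + ddx * ddx;
      if (owner[i] == 0 || d < bestd[i] - 1e-12) {
        owner[i] = sid;
        bestd[i] = d;
      }
      if (z > 0      && stamp[i - 1]       != sid && enh[i - 1]       >= thr) { stamp[i - 1]       = sid; queue.push_back(i - 1); }
      if (z < nz - 1 && stamp[i + 1]       != sid && enh[i + 1]       >= thr) { stamp[i + 1]       = sid; queue.push_back(i + 1); }
      if (y > 0      && stamp[i - nz]      != sid && enh[i - nz]      >= thr) { stamp[i - nz]      = sid; queue.push_back(i - nz); }
      if (y < ny - 1 && stamp[i + nz]      != sid && enh[i + nz]      >= thr) { stamp[i + nz]      = sid; queue.push_back(i + nz); }
      if (x > 0      && stamp[i - nz * ny] != sid && enh[i - nz * ny] >= thr) { stamp[i - nz * ny] = sid; queue.push_back(i - nz * ny); }
      if (x < nx - 1 && stamp[i + nz * ny] != sid && enh[i + nz * ny] >= thr) { stamp[i + nz * ny] = sid; queue.push_back(i + nz * ny); }
    }
  }
  owner.attr("dim") = dim;
  return owner;
}

// 6-connected component labeling of a logical mask.
// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> queue;
  int next = 0;
  for (int i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0] != 0) continue;
    ++next;
    queue.clear();
    queue.push_back(i0);
    lab[i0] = next;
    size_t head = 0;
    while (head < queue.size()) {
      const int i = queue[head++];
      const int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
      const int nb[6] = {
        z > 0 ? i - 1 : -1, z < nz - 1 ? i + 1 : -1,
        y > 0 ? i - nz : -1, y < ny - 1 ? i + nz : -1,
        x > 0 ? i - nz * ny : -1, x < nx - 1 ? i + nz * ny : -1};
      for (int k = 0; k < 6; ++k) {
        const int j = nb[k];
        if (j >= 0 && mask[j] && lab[j] == 0) {
          lab[j] = next;
          queue.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Fill interior holes: background voxels not 6-connected to the border
// become foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  std::vector<char> outside(n, 0);
  std::vector<int> queue;
  queue.reserve(4096);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 && x != 0 && x != nx - 1)
          continue;
        const int i = z + nz * (y + ny * x);
        if (!mask[i] && !outside[i]) {
          outside[i] = 1;
          queue.push_back(i);
        }
      }
    }
  }
  size_t head = 0;
  while (head < queue.size()) {
    const int i = queue[head++];
    const int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    const int nb[6] = {
      z > 0 ? i - 1 : -1, z < nz - 1 ? i + 1 : -1,
      y > 0 ? i - nz : -1, y < ny - 1 ? i + nz : -1,
      x > 0 ? i - nz * ny : -1, x < nx - 1 ? i + nz * ny : -1};
    for (int k = 0; k < 6; ++k) {
      const int j = nb[k];
      if (j >= 0 && !mask[j] && !outside[j]) {
        outside[j] = 1;
        queue.push_back(j);
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dim;
  return out;
}

// Binary dilation (op = 1) or erosion (op = 2) with the 6-neighbor cross
// structuring element, iterated.
// [[Rcpp::export]]
LogicalVector morph_binary_3d(LogicalVector mask, IntegerVector dim, int op,
                              int iter) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  std::vector<char> cur(n), nxt(n);
  for (int i = 0; i < n; ++i) cur[i] = mask[i] ? 1 : 0;
  for (int it = 0; it < iter; ++it) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) {
          const int i = z + nz * (y + ny * x);
          char v = cur[i];
          char agg = v;
          const int nb[6] = {
            z > 0 ? i - 1 : -1, z < nz - 1 ? i + 1 : -1,
            y > 0 ? i - nz : -1, y < ny - 1 ? i + nz : -1,
            x > 0 ? i - nz * ny : -1, x < nx - 1 ? i + nz * ny : -1};
          if (op == 1) {  // dilate
            for (int k = 0; k < 6 && !agg; ++k)
              if (nb[k] >= 0 && cur[nb[k]]) agg = 1;
          } else {        // erode (out-of-bounds treated as background)
            for (int k = 0; k < 6 && agg; ++k)
              if (nb[k] < 0 || !cur[nb[k]]) agg = 0;
          }
          nxt[i] = agg;
        }
      }
    }
    std::swap(cur, nxt);
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cur[i] != 0;
  out.attr("dim") = dim;
  return out;
}
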