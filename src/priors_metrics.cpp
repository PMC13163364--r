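// Low-level kernels for the appearance prior (contour-band geometry,
// neighbourhood intensity responses) and the surface-distance metrics.
// Volumes are passed as flat vectors in R array order with dim (D, H, W),
// i.e. linear index v = z + D*y + D*H*x, axis order (z, y, x).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int D, int H) {
  return z + D * (y + H * x);
}

// Per-slice contour-band labels. For each slice z with a non-empty reference
// mask, every in-plane pixel gets band = ceil(d / thickness) where d is the
// unsigned Euclidean distance (in-plane voxel units) to the nearest boundary
// pixel of the mask; d = 0 maps to band 1 and bands are capped at n_bands.
// Slices with an empty reference mask are left unassigned (label 0).
// Boundary pixel: foreground with a 4-adjacent background neighbour
// (pixels on the slice edge count their missing neighbours as background).
// [[Rcpp::export]]
IntegerVector cpp_band_partition(IntegerVector mask, IntegerVector dims,
                                 int n_bands, double thickness) {
  const int D = dims[0], H = dims[1], W = dims[2];
  IntegerVector out(mask.size());
  std::vector<int> by, bx;
  for (int z = 0; z < D; ++z) {
    by.clear(); bx.clear();
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        if (!mask[idx3(z, y, x, D, H)]) continue;
        bool edge = (y == 0) || (y == H - 1) || (x == 0) || (x == W - 1);
        if (!edge) {
          edge = !mask[idx3(z, y - 1, x, D, H)] || !mask[idx3(z, y + 1, x, D, H)] ||
                 !mask[idx3(z, y, x - 1, D, H)] || !mask[idx3(z, y, x + 1, D, H)];
        }
        if (edge) { by.push_back(y); bx.push_back(x); }
      }
    if (by.empty()) continue;  // unassigned slice
    const int nb = (int)by.size();
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        double best = 1e30;
        for (int k = 0; k < nb; ++k) {
          const double dy = y - by[k], dx = x - bx[k];
          const double d2 = dy * dy + dx * dx;
          if (d2 < best) best = d2;
        }
        const double d = std::sqrt(best);
        int band = (int)std::ceil(d / thickness);
        if (band < 1) band = 1;
        if (band > n_bands) band = n_bands;
        out[idx3(z, y, x, D, H)] = band;
      }
  }
  out.attr("dim") = dims;
  return out;
}

// Neighbourhood intensity response: for each banded voxel, the sum of
// quantized intensities over same-band voxels within in-plane Chebyshev
// `radius` on slices z-1, z, z+1 (clipped at the volume faces), plus the
// number of contributing voxels. Unassigned voxels get phi = count = 0.
// [[Rcpp::export]]
List cpp_phi(IntegerVector vol, IntegerVector bands, IntegerVector dims,
             int radius) {
  const int D = dims[0], H = dims[1], W = dims[2];
  IntegerVector phi(vol.size()), cnt(vol.size());
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      for (int z = 0; z < D; ++z) {
        const int v = idx3(z, y, x, D, H);
        const int b = bands[v];
        if (b == 0) continue;
        int s = 0, n = 0;
        const int z0 = std::max(0, z - 1), z1 = std::min(D - 1, z + 1);
        const int y0 = std::max(0, y - radius), y1 = std::min(H - 1, y + radius);
        const int x0 = std::max(0, x - radius), x1 = std::min(W - 1, x + radius);
        for (int xi = x0; xi <= x1; ++xi)
          for (int yi = y0; yi <= y1; ++yi)
            for (int zi = z0; zi <= z1; ++zi) {
              const int u = idx3(zi, yi, xi, D, H);
              if (bands[u] == b) { s += vol[u]; ++n; }
            }
        phi[v] = s; cnt[v] = n;
      }
  phi.attr("dim") = dims;
  cnt.attr("dim") = dims;
  return List::create(_["phi"] = phi, _["count"] = cnt);
}

// Pooled symmetric surface distances in mm. Boundary voxel: foreground with
// at least one face-adjacent background neighbour (volume faces count as
// background). Returns, unsorted, the nearest-boundary distance from every
// boundary voxel of `pred` to the boundary of `ref` and vice versa.
static void boundary_voxels(const IntegerVector& m, int D, int H, int W,
                            std::vector<int>& bz, std::vector<int>& by,
                            std::vector<int>& bx) {
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      for (int z = 0; z < D; ++z) {
        if (!m[idx3(z, y, x, D, H)]) continue;
        bool b = (z == 0) || (z == D - 1) || (y == 0) || (y == H - 1) ||
                 (x == 0) || (x == W - 1);
        if (!b) {
          b = !m[idx3(z - 1, y, x, D, H)] || !m[idx3(z + 1, y, x, D, H)] ||
              !m[idx3(z, y - 1, x, D, H)] || !m[idx3(z, y + 1, x, D, H)] ||
              !m[idx3(z, y, x - 1, D, H)] || !m[idx3(z, y, x + 1, D, H)];
        }
        if (b) { bz.push_back(z); by.push_back(y); bx.push_back(x); }
      }
}

static void directed_distances(const std::vector<int>& az, const std::vector<int>& ay,
                               const std::vector<int>& ax,
                               const std::vector<int>& bz, const std::vector<int>& by,
                               const std::vector<int>& bx,
                               double sz, double sy, double sx,
                               std::vector<double>& out) {
  const int na = (int)az.size(), nb = (int)bz.size();
  for (int i = 0; i < na; ++i) {
    double best = 1e300;
    for (int j = 0; j < nb; ++j) {
      const double dz = (az[i] - bz[j]) * sz;
      const double dy = (ay[i] - by[j]) * sy;
      const double dx = (ax[i] - bx[j]) * sx;
      const double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    out.push_back(std::sqrt(best));
  }
}

// [[Rcpp::export]]
NumericVector cpp_surface_distances(IntegerVector pred, IntegerVector ref,
                                    IntegerVector dims, NumericVector spacing) {
  const int D = dims[0], H = dims[1], W = dims[2];
  std::vector<int> pz, py, px, rz, ry, rx;
  boundary_voxels(pred, D, H, W, pz, py, px);
  boundary_voxels(ref, D, H, W, rz, ry, rx);
  if (pz.empty() || rz.empty())
    stop("undefined surface distance: empty mask");
  std::vector<double> d;
  d.reserve(pz.size() + rz.size());
  directed_distances(pz, py, px, rz, ry, rx, spacing[0], spacing[1], spacing[2], d);
  directed_distances(rz, ry, rx, pz, py, px, spacing[0], spacing[1], spacing[2], d);
  return wrap(d);
}

// Number of face-connected foreground components (6-connectivity).
// [[Rcpp::export]]
int cpp_n_components(IntegerVector mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int n = D * H * W;
  std::vector<uint8_t> seen(n, 0);
  int ncomp = 0;
  std::queue<int> q;
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  for (int v0 = 0; v0 < n; ++v0) {
    if (!mask[v0] || seen[v0]) continue;
    ++ncomp;
    seen[v0] = 1;
    q.push(v0);
    while (!q.empty()) {
      const int v = q.front(); q.pop();
      const int z = v % D, y = (v / D) % H, x = v / (D * H);
      for (int k = 0; k < 6; ++k) {
        const int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= D || yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        const int u = idx3(zz, yy, xx, D, H);
        if (mask[u] && !seen[u]) { seen[u] = 1; q.push(u); }
      }
    }
  }
  return ncomp;
}
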