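// Dense 3D image utilities: separable Gaussian smoothing (reflective
// boundaries), ball erosion, 26-connected component labeling, hole filling
// and supersampled analytic-shape occupancy.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect(int q, int n) {
  if (n == 1) return 0;
  while (q < 0 || q >= n) {
    if (q < 0) q = -q - 1;
    if (q >= n) q = 2 * n - 1 - q;
  }
  return q;
}

static std::vector<double> gkern(double sigma) {
  if (sigma <= 0.0) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cppGaussBlur3D(NumericVector vol, IntegerVector dims,
                             NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> a(REAL(vol), REAL(vol) + nvox), b(nvox);
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    std::vector<double> k = gkern(sigma[ax]);
    int r = ((int)k.size() - 1) / 2;
    if (r == 0) continue;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int q[3] = {x, y, z};
          size_t base = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int qt = reflect(q[ax] + t, n[ax]);
            acc += k[t + r] * a[base + ((size_t)qt - q[ax]) * stride[ax]];
          }
          b[base] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(Dimension(nx, ny, nz));
  std::copy(a.begin(), a.end(), REAL(out));
  return out;
}

// [[Rcpp::export]]
IntegerVector cppErodeBall(IntegerVector mask, IntegerVector dims,
                           NumericVector radiusVox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double rx = radiusVox[0], ry = radiusVox[1], rz = radiusVox[2];
  // offsets of the voxelized ellipsoidal structuring element
  std::vector<int> ox, oy, oz;
  int mx = (int)std::floor(rx), my = (int)std::floor(ry),
      mz = (int)std::floor(rz);
  for (int dz = -mz; dz <= mz; ++dz)
    for (int dy = -my; dy <= my; ++dy)
      for (int dx = -mx; dx <= mx; ++dx) {
        double v = 0.0;
        if (rx > 0) v += (double)dx * dx / (rx * rx);
        else if (dx != 0) continue;
        if (ry > 0) v += (double)dy * dy / (ry * ry);
        else if (dy != 0) continue;
        if (rz > 0) v += (double)dz * dz / (rz * rz);
        else if (dz != 0) continue;
        if (v <= 1.0 + 1e-12) { ox.push_back(dx); oy.push_back(dy); oz.push_back(dz); }
      }
  IntegerVector out(Dimension(nx, ny, nz));
  const int *m = INTEGER(mask);
  int *o = INTEGER(out);
  size_t nofs = ox.size();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t j = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        if (!m[j]) { o[j] = 0; continue; }
        int keep = 1;
        for (size_t t = 0; t < nofs; ++t) {
          int xx = x + ox[t], yy = y + oy[t], zz = z + oz[t];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz ||
              !m[(size_t)xx + (size_t)nx * (yy + (size_t)ny * zz)]) {
            keep = 0; break;
          }
        }
        o[j] = keep;
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector cppLabelComponents(IntegerVector mask, IntegerVector dims,
                                 int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector out(Dimension(nx, ny, nz));
  int *lab = INTEGER(out);
  const int *m = INTEGER(mask);
  std::fill(lab, lab + nvox, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t seed = 0; seed < nvox; ++seed) {
    if (!m[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      size_t j = stack.back(); stack.pop_back();
      int x = (int)(j % nx), y = (int)((j / nx) % ny), z = (int)(j / ((size_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            size_t jj = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
            if (m[jj] && !lab[jj]) { lab[jj] = next; stack.push_back(jj); }
          }
    }
  }
  return out;
}

// fill internal cavities: background is flooded 6-connected from the array
// border; unreached background voxels are holes and get filled
// [[Rcpp::export]]
IntegerVector cppFillHoles(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  const int *m = INTEGER(mask);
  std::vector<char> outside(nvox, 0);
  std::vector<size_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1 && z != 0 &&
            z != nz - 1)
          continue;
        size_t j = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        if (!m[j] && !outside[j]) { outside[j] = 1; stack.push_back(j); }
      }
  const int DX[6] = {1, -1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DZ[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    size_t j = stack.back(); stack.pop_back();
    int x = (int)(j % nx), y = (int)((j / nx) % ny), z = (int)(j / ((size_t)nx * ny));
    for (int t = 0; t < 6; ++t) {
      int xx = x + DX[t], yy = y + DY[t], zz = z + DZ[t];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      size_t jj = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
      if (!m[jj] && !outside[jj]) { outside[jj] = 1; stack.push_back(jj); }
    }
  }
  IntegerVector out(Dimension(nx, ny, nz));
  int *o = INTEGER(out);
  for (size_t j = 0; j < nvox; ++j) o[j] = (m[j] || !outside[j]) ? 1 : 0;
  return out;
}

// fractional occupancy of a sphere (type 0) or ellipsoid (type 1) on the
// grid, each voxel subdivided into ss^3 sample points
// [[Rcpp::export]]
NumericVector cppShapeOccupancy(IntegerVector dims, NumericVector spacing,
                                NumericVector origin, int type,
                                NumericVector center, NumericVector semi,
                                int ss) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(Dimension(nx, ny, nz));
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ax = semi[0], ay = (type == 0) ? semi[0] : semi[1],
         az = (type == 0) ? semi[0] : semi[2];
  // bounding voxel range (one voxel margin)
  int lo[3], hi[3];
  double cc[3] = {center[0], center[1], center[2]};
  double aa[3] = {ax, ay, az};
  double sp[3] = {sx, sy, sz};
  int nn[3] = {nx, ny, nz};
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::max(0, (int)std::floor((cc[d] - aa[d] - origin[d]) / sp[d]) - 1);
    hi[d] = std::min(nn[d] - 1,
                     (int)std::ceil((cc[d] + aa[d] - origin[d]) / sp[d]) + 1);
  }
  std::vector<double> off(ss);
  for (int a = 0; a < ss; ++a) off[a] = ((a + 0.5) / ss - 0.5);
  double inv = 1.0 / ((double)ss * ss * ss);
  for (int z = lo[2]; z <= hi[2]; ++z)
    for (int y = lo[1]; y <= hi[1]; ++y)
      for (int x = lo[0]; x <= hi[0]; ++x) {
        double wx = origin[0] + x * sx, wy = origin[1] + y * sy,
               wz = origin[2] + z * sz;
        int cnt = 0;
        for (int c = 0; c < ss; ++c) {
          double pz = (wz + off[c] * sz - cc[2]) / az;
          double pz2 = pz * pz;
          if (pz2 > 1.0) continue;
          for (int b = 0; b < ss; ++b) {
            double py = (wy + off[b] * sy - cc[1]) / ay;
            double pyz = pz2 + py * py;
            if (pyz > 1.0) continue;
            for (int a = 0; a < ss; ++a) {
              double px = (wx + off[a] * sx - cc[0]) / ax;
              if (pyz + px * px <= 1.0) ++cnt;
            }
          }
        }
        if (cnt)
          out[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = cnt * inv;
      }
  return out;
}
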