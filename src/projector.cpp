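// Rotation-based attenuated parallel-beam projector and OSEM.
//
// Volumes are nx x ny x nz double arrays (x fastest, R column-major order).
// For projection angle theta the volume is resampled on a grid rotated by
// theta about the z axis (bilinear, out-of-field treated as zero) and summed
// along +y, which is the detector direction.  Attenuation uses the standard
// half-voxel self-attenuation convention: the factor for a voxel is
// exp(-dl * (mu/2 + sum of mu over voxels between it and the detector)).
// The back projector is the exact adjoint (same interpolation weights,
// scatter instead of gather), so OSEM with one subset is plain MLEM for the
// matrix this operator defines.
//
// Internally volumes are held z-fastest (v[z + nz*(x + nx*y)]) so that the
// per-voxel work of the in-plane rotation runs as contiguous vector
// operations over z.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static std::vector<double> gaussKernel(double sigma) {
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

// separable blur of one nu x nv slab, zero boundary; the convolution matrix
// is symmetric, so this blur is its own adjoint
static void blur2d(double *p, int nu, int nv, const std::vector<double> &k,
                   std::vector<double> &tmp) {
  int r = ((int)k.size() - 1) / 2;
  if (r == 0) return;
  tmp.assign((size_t)nu * nv, 0.0);
  for (int v = 0; v < nv; ++v)
    for (int u = 0; u < nu; ++u) {
      double acc = 0.0;
      int lo = std::max(-r, -u), hi = std::min(r, nu - 1 - u);
      for (int t = lo; t <= hi; ++t) acc += k[t + r] * p[(u + t) + nu * v];
      tmp[u + (size_t)nu * v] = acc;
    }
  for (int v = 0; v < nv; ++v)
    for (int u = 0; u < nu; ++u) {
      double acc = 0.0;
      int lo = std::max(-r, -v), hi = std::min(r, nv - 1 - v);
      for (int t = lo; t <= hi; ++t) acc += k[t + r] * tmp[u + (size_t)nu * (v + t)];
      p[u + (size_t)nu * v] = acc;
    }
}

// x-fastest (R order) <-> z-fastest internal layout
static void toZ(const double *in, double *out, int nx, int ny, int nz) {
  size_t nxy = (size_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t i0 = (size_t)x + (size_t)nx * y;
      double *o = out + (size_t)nz * i0;
      for (int z = 0; z < nz; ++z) o[z] = in[i0 + nxy * z];
    }
}

static void fromZ(const double *in, double *out, int nx, int ny, int nz) {
  size_t nxy = (size_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t i0 = (size_t)x + (size_t)nx * y;
      const double *p = in + (size_t)nz * i0;
      for (int z = 0; z < nz; ++z) out[i0 + nxy * z] = p[z];
    }
}

struct RotPlan {
  std::vector<int> s00, s10, s01, s11;        // source 2D index or -1
  std::vector<double> w00, w10, w01, w11;
  void build(int nx, int ny, double theta) {
    int n = nx * ny;
    s00.assign(n, -1); s10.assign(n, -1); s01.assign(n, -1); s11.assign(n, -1);
    w00.assign(n, 0.0); w10.assign(n, 0.0); w01.assign(n, 0.0); w11.assign(n, 0.0);
    double ct = std::cos(theta), st = std::sin(theta);
    double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
    for (int yo = 0; yo < ny; ++yo)
      for (int xo = 0; xo < nx; ++xo) {
        double dx = xo - cx, dy = yo - cy;
        double xs = ct * dx + st * dy + cx;
        double ys = -st * dx + ct * dy + cy;
        int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        double fx = xs - x0, fy = ys - y0;
        int i = xo + nx * yo;
        if (x0 >= 0 && x0 < nx && y0 >= 0 && y0 < ny) {
          s00[i] = x0 + nx * y0; w00[i] = (1 - fx) * (1 - fy);
        }
        if (x0 + 1 >= 0 && x0 + 1 < nx && y0 >= 0 && y0 < ny) {
          s10[i] = x0 + 1 + nx * y0; w10[i] = fx * (1 - fy);
        }
        if (x0 >= 0 && x0 < nx && y0 + 1 >= 0 && y0 + 1 < ny) {
          s01[i] = x0 + nx * (y0 + 1); w01[i] = (1 - fx) * fy;
        }
        if (x0 + 1 >= 0 && x0 + 1 < nx && y0 + 1 >= 0 && y0 + 1 < ny) {
          s11[i] = x0 + 1 + nx * (y0 + 1); w11[i] = fx * fy;
        }
      }
  }
};

// gather-rotate a z-fast volume; only slices [z0, z1) are produced
static void rotGatherZ(const RotPlan &P, const double *in, double *out,
                       int nxy, int nz, int z0, int z1) {
  int len = z1 - z0;
  for (int i = 0; i < nxy; ++i) {
    double *o = out + (size_t)nz * i + z0;
    std::memset(o, 0, sizeof(double) * len);
    if (P.s00[i] >= 0) {
      const double *p = in + (size_t)nz * P.s00[i] + z0;
      double w = P.w00[i];
      for (int z = 0; z < len; ++z) o[z] += w * p[z];
    }
    if (P.s10[i] >= 0) {
      const double *p = in + (size_t)nz * P.s10[i] + z0;
      double w = P.w10[i];
      for (int z = 0; z < len; ++z) o[z] += w * p[z];
    }
    if (P.s01[i] >= 0) {
      const double *p = in + (size_t)nz * P.s01[i] + z0;
      double w = P.w01[i];
      for (int z = 0; z < len; ++z) o[z] += w * p[z];
    }
    if (P.s11[i] >= 0) {
      const double *p = in + (size_t)nz * P.s11[i] + z0;
      double w = P.w11[i];
      for (int z = 0; z < len; ++z) o[z] += w * p[z];
    }
  }
}

// exact adjoint of rotGatherZ: accumulate into out
static void rotScatterZ(const RotPlan &P, const double *in, double *out,
                        int nxy, int nz, int z0, int z1) {
  int len = z1 - z0;
  for (int i = 0; i < nxy; ++i) {
    const double *p = in + (size_t)nz * i + z0;
    if (P.s00[i] >= 0) {
      double *o = out + (size_t)nz * P.s00[i] + z0;
      double w = P.w00[i];
      for (int z = 0; z < len; ++z) o[z] += w * p[z];
    }
    if (P.s10[i] >= 0) {
      double *o = out + (size_t)nz * P.s10[i] + z0;
      double w = P.w10[i];
      for (int z = 0; z < len; ++z) o[z] += w * p[z];
    }
    if (P.s01[i] >= 0) {
      double *o = out + (size_t)nz * P.s01[i] + z0;
      double w = P.w01[i];
      for (int z = 0; z < len; ++z) o[z] += w * p[z];
    }
    if (P.s11[i] >= 0) {
      double *o = out + (size_t)nz * P.s11[i] + z0;
      double w = P.w11[i];
      for (int z = 0; z < len; ++z) o[z] += w * p[z];
    }
  }
}

// fused gather-rotate of column i from a z-fast volume into tmp[0..len)
static inline void gatherCol(const RotPlan &P, const double *in, int i,
                             int nz, int z0, int z1, double *tmp) {
  int len = z1 - z0;
  int s00 = P.s00[i], s10 = P.s10[i], s01 = P.s01[i], s11 = P.s11[i];
  if (s00 >= 0 && s10 >= 0 && s01 >= 0 && s11 >= 0) {
    const double *p00 = in + (size_t)nz * s00 + z0;
    const double *p10 = in + (size_t)nz * s10 + z0;
    const double *p01 = in + (size_t)nz * s01 + z0;
    const double *p11 = in + (size_t)nz * s11 + z0;
    double w00 = P.w00[i], w10 = P.w10[i], w01 = P.w01[i], w11 = P.w11[i];
    for (int z = 0; z < len; ++z)
      tmp[z] = w00 * p00[z] + w10 * p10[z] + w01 * p01[z] + w11 * p11[z];
    return;
  }
  std::memset(tmp, 0, sizeof(double) * len);
  if (s00 >= 0) {
    const double *p = in + (size_t)nz * s00 + z0;
    double w = P.w00[i];
    for (int z = 0; z < len; ++z) tmp[z] += w * p[z];
  }
  if (s10 >= 0) {
    const double *p = in + (size_t)nz * s10 + z0;
    double w = P.w10[i];
    for (int z = 0; z < len; ++z) tmp[z] += w * p[z];
  }
  if (s01 >= 0) {
    const double *p = in + (size_t)nz * s01 + z0;
    double w = P.w01[i];
    for (int z = 0; z < len; ++z) tmp[z] += w * p[z];
  }
  if (s11 >= 0) {
    const double *p = in + (size_t)nz * s11 + z0;
    double w = P.w11[i];
    for (int z = 0; z < len; ++z) tmp[z] += w * p[z];
  }
}

// fused forward projection: rotate, attenuate and sum along y in one pass
static void fwdFused(const RotPlan &P, const double *volZ, const double *att,
                     double *projZ, int nx, int ny, int nz, int z0, int z1,
                     double *tmp) {
  std::memset(projZ, 0, sizeof(double) * (size_t)nz * nx);
  int len = z1 - z0;
  for (int yo = 0; yo < ny; ++yo)
    for (int xo = 0; xo < nx; ++xo) {
      int i = xo + nx * yo;
      gatherCol(P, volZ, i, nz, z0, z1, tmp);
      double *p = projZ + (size_t)nz * xo + z0;
      if (att) {
        const double *a = att + (size_t)nz * i + z0;
        for (int z = 0; z < len; ++z) p[z] += tmp[z] * a[z];
      } else {
        for (int z = 0; z < len; ++z) p[z] += tmp[z];
      }
    }
}

// fused backprojection (exact adjoint of fwdFused): expand along y with the
// attenuation weights and scatter-rotate, accumulating into accZ
static void bpFused(const RotPlan &P, const double *projZ, const double *att,
                    double *accZ, int nx, int ny, int nz, int z0, int z1,
                    double *tmp) {
  int len = z1 - z0;
  for (int yo = 0; yo < ny; ++yo)
    for (int xo = 0; xo < nx; ++xo) {
      int i = xo + nx * yo;
      int s00 = P.s00[i], s10 = P.s10[i], s01 = P.s01[i], s11 = P.s11[i];
      if (s00 < 0 && s10 < 0 && s01 < 0 && s11 < 0) continue;
      const double *p = projZ + (size_t)nz * xo + z0;
      if (att) {
        const double *a = att + (size_t)nz * i + z0;
        for (int z = 0; z < len; ++z) tmp[z] = p[z] * a[z];
      } else {
        std::memcpy(tmp, p, sizeof(double) * len);
      }
      if (s00 >= 0) {
        double *o = accZ + (size_t)nz * s00 + z0;
        double w = P.w00[i];
        for (int z = 0; z < len; ++z) o[z] += w * tmp[z];
      }
      if (s10 >= 0) {
        double *o = accZ + (size_t)nz * s10 + z0;
        double w = P.w10[i];
        for (int z = 0; z < len; ++z) o[z] += w * tmp[z];
      }
      if (s01 >= 0) {
        double *o = accZ + (size_t)nz * s01 + z0;
        double w = P.w01[i];
        for (int z = 0; z < len; ++z) o[z] += w * tmp[z];
      }
      if (s11 >= 0) {
        double *o = accZ + (size_t)nz * s11 + z0;
        double w = P.w11[i];
        for (int z = 0; z < len; ++z) o[z] += w * tmp[z];
      }
    }
}

// attenuation factors from a rotated z-fast mu volume; detector at large y
static void attFromMuZ(const double *muRot, double *att, int nx, int ny,
                       int nz, double dl, int z0, int z1,
                       std::vector<double> &cum) {
  cum.assign((size_t)nz * nx, 0.0);
  for (int y = ny - 1; y >= 0; --y)
    for (int x = 0; x < nx; ++x) {
      const double *m = muRot + (size_t)nz * ((size_t)x + (size_t)nx * y);
      double *a = att + (size_t)nz * ((size_t)x + (size_t)nx * y);
      double *c = cum.data() + (size_t)nz * x;
      for (int z = z0; z < z1; ++z) {
        a[z] = std::exp(-dl * (c[z] + 0.5 * m[z]));
        c[z] += m[z];
      }
    }
}

// forward projection of a rotated z-fast volume into projZ (z-fast slab,
// pz[z + nz*x]); att may be NULL
static void sumYZ(const double *buf, const double *att, double *projZ,
                  int nx, int ny, int nz, int z0, int z1) {
  std::memset(projZ, 0, sizeof(double) * (size_t)nz * nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const double *v = buf + (size_t)nz * ((size_t)x + (size_t)nx * y);
      double *p = projZ + (size_t)nz * x;
      if (att) {
        const double *a = att + (size_t)nz * ((size_t)x + (size_t)nx * y);
        for (int z = z0; z < z1; ++z) p[z] += v[z] * a[z];
      } else {
        for (int z = z0; z < z1; ++z) p[z] += v[z];
      }
    }
}

// expand projZ along y weighted by att into buf (z-fast)
static void expandYZ(const double *projZ, const double *att, double *buf,
                     int nx, int ny, int nz, int z0, int z1) {
  int len = z1 - z0;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double *v = buf + (size_t)nz * ((size_t)x + (size_t)nx * y);
      const double *p = projZ + (size_t)nz * x;
      std::memset(v + z0, 0, sizeof(double) * len);
      if (att) {
        const double *a = att + (size_t)nz * ((size_t)x + (size_t)nx * y);
        for (int z = z0; z < z1; ++z) v[z] = p[z] * a[z];
      } else {
        for (int z = z0; z < z1; ++z) v[z] = p[z];
      }
    }
}

// slab transposes between internal (z fastest) and external (u fastest)
static void slabOut(const double *projZ, double *proj, int nx, int nz) {
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) proj[x + (size_t)nx * z] = projZ[z + (size_t)nz * x];
}

static void slabIn(const double *proj, double *projZ, int nx, int nz) {
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) projZ[z + (size_t)nz * x] = proj[x + (size_t)nx * z];
}

// [[Rcpp::export]]
NumericVector cppForwardProject(NumericVector vol, NumericVector mu,
                                IntegerVector dims, NumericVector angles,
                                double dl, double psfSigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2], na = angles.size();
  size_t nvox = (size_t)nx * ny * nz;
  int nxy = nx * ny;
  bool useAtt = (size_t)mu.size() == nvox;
  NumericVector out(Dimension(nx, nz, na));
  std::vector<double> volZ(nvox), muZ, buf(nvox), attv, muRot, cum;
  std::vector<double> projZ((size_t)nz * nx), tmp2;
  toZ(REAL(vol), volZ.data(), nx, ny, nz);
  if (useAtt) {
    muZ.resize(nvox); attv.resize(nvox); muRot.resize(nvox);
    toZ(REAL(mu), muZ.data(), nx, ny, nz);
  }
  std::vector<double> kern = gaussKernel(psfSigma);
  RotPlan P;
  for (int a = 0; a < na; ++a) {
    P.build(nx, ny, angles[a]);
    const double *attp = NULL;
    if (useAtt) {
      rotGatherZ(P, muZ.data(), muRot.data(), nxy, nz, 0, nz);
      attFromMuZ(muRot.data(), attv.data(), nx, ny, nz, dl, 0, nz, cum);
      attp = attv.data();
    }
    rotGatherZ(P, volZ.data(), buf.data(), nxy, nz, 0, nz);
    sumYZ(buf.data(), attp, projZ.data(), nx, ny, nz, 0, nz);
    double *proj = REAL(out) + (size_t)nx * nz * a;
    slabOut(projZ.data(), proj, nx, nz);
    blur2d(proj, nx, nz, kern, tmp2);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cppBackProject(NumericVector proj, NumericVector mu,
                             IntegerVector dims, NumericVector angles,
                             double dl, double psfSigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2], na = angles.size();
  size_t nvox = (size_t)nx * ny * nz;
  int nxy = nx * ny;
  bool useAtt = (size_t)mu.size() == nvox;
  std::vector<double> acc(nvox, 0.0), buf(nvox), muZ, attv, muRot, cum;
  std::vector<double> projZ((size_t)nz * nx), slab((size_t)nx * nz), tmp2;
  if (useAtt) {
    muZ.resize(nvox); attv.resize(nvox); muRot.resize(nvox);
    toZ(REAL(mu), muZ.data(), nx, ny, nz);
  }
  std::vector<double> kern = gaussKernel(psfSigma);
  RotPlan P;
  for (int a = 0; a < na; ++a) {
    P.build(nx, ny, angles[a]);
    const double *attp = NULL;
    if (useAtt) {
      rotGatherZ(P, muZ.data(), muRot.data(), nxy, nz, 0, nz);
      attFromMuZ(muRot.data(), attv.data(), nx, ny, nz, dl, 0, nz, cum);
      attp = attv.data();
    }
    std::memcpy(slab.data(), REAL(proj) + (size_t)nx * nz * a,
                sizeof(double) * (size_t)nx * nz);
    blur2d(slab.data(), nx, nz, kern, tmp2);
    slabIn(slab.data(), projZ.data(), nx, nz);
    expandYZ(projZ.data(), attp, buf.data(), nx, ny, nz, 0, nz);
    rotScatterZ(P, buf.data(), acc.data(), nxy, nz, 0, nz);
  }
  NumericVector out(Dimension(nx, ny, nz));
  fromZ(acc.data(), REAL(out), nx, ny, nz);
  return out;
}

// [[Rcpp::export]]
List cppOsem(NumericVector proj, NumericVector scatter, NumericVector mu,
             IntegerVector dims, NumericVector angles, double dl,
             double psfSigma, int iterations, int subsets,
             bool keepIterates) {
  int nx = dims[0], ny = dims[1], nz = dims[2], na = angles.size();
  int nxy = nx * ny;
  size_t nvox = (size_t)nxy * nz, nbin = (size_t)nx * nz;
  bool useAtt = (size_t)mu.size() == nvox;
  if (na % subsets != 0)
    stop("number of subsets (%d) must divide the number of angles (%d)",
         subsets, na);
  const double *y = REAL(proj);
  for (size_t i = 0; i < nbin * (size_t)na; ++i)
    if (y[i] < 0.0) stop("negative counts in projection data");
  bool useScat = (size_t)scatter.size() == nbin * (size_t)na;
  const double eps = 1e-12;

  std::vector<double> kern = gaussKernel(psfSigma);
  int blurR = ((int)kern.size() - 1) / 2;

  // axial crop: slices carrying attenuation or counts, padded by the blur
  int z0 = 0, z1 = nz;
  if (useAtt) {
    std::vector<char> has(nz, 0);
    for (int z = 0; z < nz; ++z) {
      const double *m = REAL(mu) + (size_t)nxy * z;
      for (int i = 0; i < nxy; ++i)
        if (m[i] > 0.0) { has[z] = 1; break; }
      if (!has[z])
        for (int a = 0; a < na && !has[z]; ++a) {
          const double *p = y + nbin * (size_t)a + (size_t)nx * z;
          for (int x = 0; x < nx; ++x)
            if (p[x] > 0.0) { has[z] = 1; break; }
        }
    }
    z0 = nz; z1 = 0;
    for (int z = 0; z < nz; ++z)
      if (has[z]) { z0 = std::min(z0, z); z1 = std::max(z1, z + 1); }
    if (z0 >= z1) { z0 = 0; z1 = nz; }
    z0 = std::max(0, z0 - blurR - 1);
    z1 = std::min(nz, z1 + blurR + 1);
  }

  std::vector<RotPlan> plans(na);
  for (int a = 0; a < na; ++a) plans[a].build(nx, ny, angles[a]);

  std::vector<double> muZ, muRot, attv, cum;
  if (useAtt) {
    muZ.resize(nvox); muRot.resize(nvox);
    toZ(REAL(mu), muZ.data(), nx, ny, nz);
  }
  bool cacheAtt = useAtt && (double)nvox * na * 8.0 < 6e8;
  std::vector<double> attCache;
  if (cacheAtt) {
    attCache.assign(nvox * (size_t)na, 0.0);
    for (int a = 0; a < na; ++a) {
      rotGatherZ(plans[a], muZ.data(), muRot.data(), nxy, nz, z0, z1);
      attFromMuZ(muRot.data(), attCache.data() + nvox * (size_t)a,
                 nx, ny, nz, dl, z0, z1, cum);
    }
  } else if (useAtt) {
    attv.resize(nvox);
  }
  auto attFor = [&](int a) -> const double * {
    if (!useAtt) return (const double *)NULL;
    if (cacheAtt) return attCache.data() + nvox * (size_t)a;
    rotGatherZ(plans[a], muZ.data(), muRot.data(), nxy, nz, z0, z1);
    attFromMuZ(muRot.data(), attv.data(), nx, ny, nz, dl, z0, z1, cum);
    return attv.data();
  };

  std::vector<double> projZ((size_t)nz * nx), slab(nbin), tmp2;
  std::vector<double> col(nz);

  // subset sensitivity images: A_s^T 1 (blur of ones, then adjoint)
  std::vector<std::vector<double> > sens(subsets,
                                         std::vector<double>(nvox, 0.0));
  for (int s = 0; s < subsets; ++s) {
    for (int a = s; a < na; a += subsets) {
      std::fill(slab.begin(), slab.end(), 1.0);
      blur2d(slab.data(), nx, nz, kern, tmp2);
      slabIn(slab.data(), projZ.data(), nx, nz);
      bpFused(plans[a], projZ.data(), attFor(a), sens[s].data(),
              nx, ny, nz, z0, z1, col.data());
    }
    double mx = 0.0;
    for (size_t i = 0; i < nvox; ++i) mx = std::max(mx, sens[s][i]);
    if (mx <= 0.0) stop("all-zero sensitivity in subset %d", s + 1);
  }

  // initial estimate: ones on the body support (z-fast layout)
  std::vector<double> x(nvox, 0.0);
  {
    std::vector<double> suppZ;
    const double *muzp = NULL;
    if (useAtt) muzp = muZ.data();
    for (size_t i = 0; i < nvox; ++i) {
      bool body = !useAtt || muzp[i] > 0.0;
      double stot = 0.0;
      for (int s = 0; s < subsets; ++s) stot += sens[s][i];
      if (body && stot > 0.0) x[i] = 1.0;
    }
  }

  std::vector<double> num(nvox), ratio(nbin);
  List iterates(keepIterates ? iterations : 0);
  for (int it = 0; it < iterations; ++it) {
    for (int s = 0; s < subsets; ++s) {
      std::fill(num.begin(), num.end(), 0.0);
      for (int a = s; a < na; a += subsets) {
        const double *att = attFor(a);
        fwdFused(plans[a], x.data(), att, projZ.data(), nx, ny, nz, z0, z1,
                 col.data());
        slabOut(projZ.data(), slab.data(), nx, nz);
        blur2d(slab.data(), nx, nz, kern, tmp2);
        const double *ya = y + nbin * (size_t)a;
        const double *sa = useScat ? REAL(scatter) + nbin * (size_t)a : NULL;
        for (size_t i = 0; i < nbin; ++i) {
          double f = slab[i] + (sa ? sa[i] : 0.0);
          ratio[i] = ya[i] / (f + eps);
        }
        std::memcpy(slab.data(), ratio.data(), sizeof(double) * nbin);
        blur2d(slab.data(), nx, nz, kern, tmp2);
        slabIn(slab.data(), projZ.data(), nx, nz);
        bpFused(plans[a], projZ.data(), att, num.data(), nx, ny, nz, z0, z1,
                col.data());
      }
      for (size_t i = 0; i < nvox; ++i)
        if (sens[s][i] > 0.0) x[i] *= num[i] / sens[s][i];
    }
    if (keepIterates) {
      NumericVector xi(Dimension(nx, ny, nz));
      fromZ(x.data(), REAL(xi), nx, ny, nz);
      iterates[it] = xi;
    }
  }
  NumericVector out(Dimension(nx, ny, nz));
  fromZ(x.data(), REAL(out), nx, ny, nz);
  return List::create(_["image"] = out, _["iterates"] = iterates);
}

// [[Rcpp::export]]
NumericVector cppBlurProjections(NumericVector proj, IntegerVector dims,
                                 double sigma) {
  int nu = dims[0], nv = dims[1], na = dims[2];
  NumericVector out = clone(proj);
  std::vector<double> kern = gaussKernel(sigma);
  std::vector<double> tmp2;
  for (int a = 0; a < na; ++a)
    blur2d(REAL(out) + (size_t)nu * nv * a, nu, nv, kern, tmp2);
  return out;
}
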