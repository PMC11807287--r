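// Attenuated parallel-beam SPECT projector with distance-dependent Gaussian
// collimator-detector response, per-energy-group attenuation scaling, per-group
// energy-window detection weights and an optional broad-Gaussian scatter
// surrogate.  The forward and back operators are exact adjoints of each other:
// rotation uses bilinear gather in the forward direction and the transposed
// scatter in the backward direction; all blur kernels are symmetric and
// applied with zero padding; attenuation is a diagonal (self-adjoint) factor.
//
// Volume layout follows R arrays: dim = (nx, ny, nz), x fastest.  Rays travel
// along +x in the rotated frame; the detector lies on the +x side.  Projection
// bins are (u, v) = (rotated y, z).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct RotPlan {
  // bilinear gather weights per in-plane output point (xo, yo), shared by z
  std::vector<int> i0, j0;      // lower-left source indices, -1 when outside
  std::vector<double> wx, wy;   // fractional offsets
  int nx, ny;
};

const int OUTSIDE = -1000000;  // sentinel: rotated point falls off the grid

RotPlan make_plan(int nx, int ny, double theta) {
  RotPlan p;
  p.nx = nx; p.ny = ny;
  p.i0.assign((size_t)nx * ny, OUTSIDE);
  p.j0.assign((size_t)nx * ny, OUTSIDE);
  p.wx.assign((size_t)nx * ny, 0.0);
  p.wy.assign((size_t)nx * ny, 0.0);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double c = std::cos(theta), s = std::sin(theta);
  for (int yo = 0; yo < ny; ++yo) {
    for (int xo = 0; xo < nx; ++xo) {
      const double dx = xo - cx, dy = yo - cy;
      const double xs = cx + c * dx - s * dy;
      const double ys = cy + s * dx + c * dy;
      const size_t q = (size_t)yo * nx + xo;
      const int i = (int)std::floor(xs), j = (int)std::floor(ys);
      if (i < -1 || i > nx - 1 || j < -1 || j > ny - 1) continue;
      p.i0[q] = i; p.j0[q] = j;
      p.wx[q] = xs - i; p.wy[q] = ys - j;
    }
  }
  return p;
}

// gather-rotate every z-slice of vol into out (both nx*ny*nz)
void rotate_gather(const double* vol, double* out, const RotPlan& p, int nz) {
  const int nx = p.nx, ny = p.ny;
  const size_t npl = (size_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    const double* src = vol + npl * z;
    double* dst = out + npl * z;
    for (size_t q = 0; q < npl; ++q) {
      const int i = p.i0[q], j = p.j0[q];
      if (i == OUTSIDE) { dst[q] = 0.0; continue; }
      const double wx = p.wx[q], wy = p.wy[q];
      double acc = 0.0;
      if (i >= 0 && j >= 0)           acc += (1 - wx) * (1 - wy) * src[(size_t)j * nx + i];
      if (i + 1 < nx && j >= 0)       acc += wx * (1 - wy) * src[(size_t)j * nx + i + 1];
      if (i >= 0 && j + 1 < ny)       acc += (1 - wx) * wy * src[(size_t)(j + 1) * nx + i];
      if (i + 1 < nx && j + 1 < ny)   acc += wx * wy * src[(size_t)(j + 1) * nx + i + 1];
      dst[q] = acc;
    }
  }
}

// accumulating gather (used as the adjoint of rotate_scatter)
void rotate_gather_accum(const double* vol, double* out, const RotPlan& p,
                         int nz) {
  const int nx = p.nx, ny = p.ny;
  const size_t npl = (size_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    const double* src = vol + npl * z;
    double* dst = out + npl * z;
    for (size_t q = 0; q < npl; ++q) {
      const int i = p.i0[q], j = p.j0[q];
      if (i == OUTSIDE) continue;
      const double wx = p.wx[q], wy = p.wy[q];
      double acc = 0.0;
      if (i >= 0 && j >= 0)           acc += (1 - wx) * (1 - wy) * src[(size_t)j * nx + i];
      if (i + 1 < nx && j >= 0)       acc += wx * (1 - wy) * src[(size_t)j * nx + i + 1];
      if (i >= 0 && j + 1 < ny)       acc += (1 - wx) * wy * src[(size_t)(j + 1) * nx + i];
      if (i + 1 < nx && j + 1 < ny)   acc += wx * wy * src[(size_t)(j + 1) * nx + i + 1];
      dst[q] += acc;
    }
  }
}

// exact adjoint of rotate_gather: scatter rotated-frame values back.
// Also used directly (with the opposite-angle plan) as the mass-conserving
// forward rotation of activity: each voxel splats its content onto the
// bilinear neighbourhood of its rotated position, so total activity is
// preserved exactly for interior voxels.
void rotate_scatter(const double* rot, double* out, const RotPlan& p, int nz) {
  const int nx = p.nx, ny = p.ny;
  const size_t npl = (size_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    const double* src = rot + npl * z;
    double* dst = out + npl * z;
    for (size_t q = 0; q < npl; ++q) {
      const int i = p.i0[q], j = p.j0[q];
      if (i == OUTSIDE) continue;
      const double v = src[q];
      if (v == 0.0) continue;
      const double wx = p.wx[q], wy = p.wy[q];
      if (i >= 0 && j >= 0)         dst[(size_t)j * nx + i]           += (1 - wx) * (1 - wy) * v;
      if (i + 1 < nx && j >= 0)     dst[(size_t)j * nx + i + 1]       += wx * (1 - wy) * v;
      if (i >= 0 && j + 1 < ny)     dst[(size_t)(j + 1) * nx + i]     += (1 - wx) * wy * v;
      if (i + 1 < nx && j + 1 < ny) dst[(size_t)(j + 1) * nx + i + 1] += wx * wy * v;
    }
  }
}

// separable symmetric 2D convolution of an n1 x n2 image, zero padded;
// written as shifted axpy passes so every inner loop is contiguous
void conv_dim1(const std::vector<double>& in, std::vector<double>& out,
               int n1, int n2, const std::vector<double>& ker) {
  const int h = ((int)ker.size() - 1) / 2;
  if (h == 0) { out = in; for (auto& v : out) v *= ker[0]; return; }
  std::fill(out.begin(), out.end(), 0.0);
  for (int j = 0; j < n2; ++j) {
    const double* src = &in[(size_t)j * n1];
    double* dst = &out[(size_t)j * n1];
    for (int d = -h; d <= h; ++d) {
      const double w = ker[d + h];
      const int i0 = std::max(0, -d), i1 = n1 - 1 - std::max(0, d);
      const double* s = src + i0 + d;
      double* o = dst + i0;
      for (int i = i0; i <= i1; ++i) *o++ += w * *s++;
    }
  }
}

void conv_dim2(const std::vector<double>& in, std::vector<double>& out,
               int n1, int n2, const std::vector<double>& ker) {
  const int h = ((int)ker.size() - 1) / 2;
  if (h == 0) { out = in; for (auto& v : out) v *= ker[0]; return; }
  std::fill(out.begin(), out.end(), 0.0);
  for (int j = 0; j < n2; ++j) {
    double* dst = &out[(size_t)j * n1];
    const int k0 = std::max(0, j - h), k1 = std::min(n2 - 1, j + h);
    for (int k = k0; k <= k1; ++k) {
      const double w = ker[k - j + h];
      const double* src = &in[(size_t)k * n1];
      for (int i = 0; i < n1; ++i) dst[i] += w * src[i];
    }
  }
}

void blur2d(const std::vector<double>& in, std::vector<double>& out,
            std::vector<double>& scratch, int n1, int n2,
            const std::vector<double>& ker) {
  if (ker.size() == 1 && ker[0] == 1.0) { out = in; return; }
  conv_dim1(in, scratch, n1, n2, ker);
  conv_dim2(scratch, out, n1, n2, ker);
}

std::vector<std::vector<double>> as_kernels(List blurKernels) {
  std::vector<std::vector<double>> ks;
  for (int b = 0; b < blurKernels.size(); ++b) {
    NumericVector k = blurKernels[b];
    ks.emplace_back(k.begin(), k.end());
  }
  return ks;
}

// attenuation path sums toward the detector (+x): A(x) = dx_cm * (0.5*mu(x) +
// sum_{x' > x} mu(x')), per (y, z) column
void path_sums(const double* mu, double* A, int nx, int ny, int nz, double dx_cm) {
  const size_t npl = (size_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      const double* m = mu + npl * z + (size_t)y * nx;
      double* a = A + npl * z + (size_t)y * nx;
      double tail = 0.0;
      for (int x = nx - 1; x >= 0; --x) {
        a[x] = dx_cm * (0.5 * m[x] + tail);
        tail += m[x];
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_forward_project(List acts, NumericVector muS, NumericVector muB,
                                  IntegerVector dims, double voxel_mm,
                                  NumericVector angles,
                                  NumericVector sSoft, NumericVector sBone,
                                  NumericMatrix winW, List blurKernels,
                                  IntegerVector bandOfX,
                                  NumericVector scatterKernel,
                                  NumericVector scatterFrac) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const int nA = angles.size(), nG = sSoft.size(), nW = winW.ncol();
  const int nM = acts.size();
  const int nB = blurKernels.size();
  const size_t npix = (size_t)ny * nz;
  const double dx_cm = voxel_mm / 10.0;

  std::vector<const double*> actp(nM);
  for (int m = 0; m < nM; ++m) {
    NumericVector a = acts[m];
    if ((size_t)a.size() != nvox) stop("activity map has wrong size");
    actp[m] = REAL(a);
  }
  auto kers = as_kernels(blurKernels);
  std::vector<double> sker(scatterKernel.begin(), scatterKernel.end());

  NumericVector out((size_t)npix * nA * nW * nM);  // (u,v,angle,window,map)
  std::vector<double> rotS(nvox), rotB(nvox), AS(nvox), AB(nvox), att(nvox);
  std::vector<std::vector<double>> rotA(nM, std::vector<double>(nvox));
  std::vector<std::vector<double>> band(nB, std::vector<double>(npix));
  std::vector<double> gsum(npix), tmp(npix), scratch(npix);
  // prim[m][w]
  std::vector<std::vector<std::vector<double>>> prim(
      nM, std::vector<std::vector<double>>(nW, std::vector<double>(npix)));

  for (int a = 0; a < nA; ++a) {
    RotPlan plan = make_plan(nx, ny, angles[a]);        // gather plan (mu)
    RotPlan planS = make_plan(nx, ny, -angles[a]);      // splat plan (activity)
    rotate_gather(REAL(muS), rotS.data(), plan, nz);
    rotate_gather(REAL(muB), rotB.data(), plan, nz);
    for (int m = 0; m < nM; ++m) {
      std::fill(rotA[m].begin(), rotA[m].end(), 0.0);
      rotate_scatter(actp[m], rotA[m].data(), planS, nz);
    }
    path_sums(rotS.data(), AS.data(), nx, ny, nz, dx_cm);
    path_sums(rotB.data(), AB.data(), nx, ny, nz, dx_cm);
    for (int m = 0; m < nM; ++m)
      for (int w = 0; w < nW; ++w)
        std::fill(prim[m][w].begin(), prim[m][w].end(), 0.0);

    for (int g = 0; g < nG; ++g) {
      const double ss = sSoft[g], sb = sBone[g];
      for (size_t q = 0; q < nvox; ++q)
        att[q] = std::exp(-ss * AS[q] - sb * AB[q]);
      for (int m = 0; m < nM; ++m) {
        for (int b = 0; b < nB; ++b) std::fill(band[b].begin(), band[b].end(), 0.0);
        const double* A0 = rotA[m].data();
        for (int z = 0; z < nz; ++z) {
          for (int y = 0; y < ny; ++y) {
            const size_t base = (size_t)z * nx * ny + (size_t)y * nx;
            const size_t pix = (size_t)z * ny + y;
            for (int x = 0; x < nx; ++x) {
              const double v = A0[base + x];
              if (v != 0.0) band[bandOfX[x]][pix] += v * att[base + x];
            }
          }
        }
        std::fill(gsum.begin(), gsum.end(), 0.0);
        for (int b = 0; b < nB; ++b) {
          blur2d(band[b], tmp, scratch, ny, nz, kers[b]);
          for (size_t q = 0; q < npix; ++q) gsum[q] += tmp[q];
        }
        for (int w = 0; w < nW; ++w) {
          const double ww = winW(g, w);
          if (ww == 0.0) continue;
          for (size_t q = 0; q < npix; ++q) prim[m][w][q] += ww * gsum[q];
        }
      }
    }
    // scatter surrogate and write-out
    for (int m = 0; m < nM; ++m) {
      for (int w = 0; w < nW; ++w) {
        double* dst = REAL(out) +
          (((size_t)m * nW + w) * nA + a) * npix;
        const double sf = scatterFrac[w];
        if (sf != 0.0) {
          blur2d(prim[m][w], tmp, scratch, ny, nz, sker);
          for (size_t q = 0; q < npix; ++q) dst[q] = prim[m][w][q] + sf * tmp[q];
        } else {
          std::copy(prim[m][w].begin(), prim[m][w].end(), dst);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_back_project(List projs, IntegerVector dims,
                               NumericVector muS, NumericVector muB,
                               double voxel_mm, NumericVector angles,
                               NumericVector sSoft, NumericVector sBone,
                               NumericMatrix winW, List blurKernels,
                               IntegerVector bandOfX,
                               NumericVector scatterKernel,
                               NumericVector scatterFrac) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const int nA = angles.size(), nG = sSoft.size(), nW = winW.ncol();
  const int nB = blurKernels.size();
  const int nM = projs.size();
  const size_t npix = (size_t)ny * nz;
  const double dx_cm = voxel_mm / 10.0;

  std::vector<const double*> projp(nM);
  for (int m = 0; m < nM; ++m) {
    NumericVector pv = projs[m];
    if ((size_t)pv.size() != npix * nA * nW) stop("projection array has wrong size");
    projp[m] = REAL(pv);
  }
  auto kers = as_kernels(blurKernels);
  std::vector<double> sker(scatterKernel.begin(), scatterKernel.end());

  NumericVector out(nvox * nM);  // (x,y,z,map)
  std::vector<double> rotS(nvox), rotB(nvox), AS(nvox), AB(nvox), att(nvox);
  std::vector<std::vector<double>> rotcube(nM, std::vector<double>(nvox));
  std::vector<std::vector<std::vector<double>>> tw(
      nM, std::vector<std::vector<double>>(nW, std::vector<double>(npix)));
  std::vector<double> gimg(npix), tmp(npix), scratch(npix);
  std::vector<std::vector<double>> bband(nB, std::vector<double>(npix));

  for (int a = 0; a < nA; ++a) {
    RotPlan plan = make_plan(nx, ny, angles[a]);        // gather plan (mu)
    RotPlan planS = make_plan(nx, ny, -angles[a]);      // adjoint of the splat
    rotate_gather(REAL(muS), rotS.data(), plan, nz);
    rotate_gather(REAL(muB), rotB.data(), plan, nz);
    path_sums(rotS.data(), AS.data(), nx, ny, nz, dx_cm);
    path_sums(rotB.data(), AB.data(), nx, ny, nz, dx_cm);

    for (int m = 0; m < nM; ++m) {
      for (int w = 0; w < nW; ++w) {
        const double* src = projp[m] + ((size_t)w * nA + a) * npix;
        const double sf = scatterFrac[w];
        if (sf != 0.0) {
          std::vector<double> in(src, src + npix);
          blur2d(in, tmp, scratch, ny, nz, sker);
          for (size_t q = 0; q < npix; ++q) tw[m][w][q] = src[q] + sf * tmp[q];
        } else {
          std::copy(src, src + npix, tw[m][w].begin());
        }
      }
      std::fill(rotcube[m].begin(), rotcube[m].end(), 0.0);
    }

    for (int g = 0; g < nG; ++g) {
      const double ss = sSoft[g], sb = sBone[g];
      for (size_t q = 0; q < nvox; ++q)
        att[q] = std::exp(-ss * AS[q] - sb * AB[q]);
      for (int m = 0; m < nM; ++m) {
        std::fill(gimg.begin(), gimg.end(), 0.0);
        for (int w = 0; w < nW; ++w) {
          const double ww = winW(g, w);
          if (ww == 0.0) continue;
          for (size_t q = 0; q < npix; ++q) gimg[q] += ww * tw[m][w][q];
        }
        for (int b = 0; b < nB; ++b)
          blur2d(gimg, bband[b], scratch, ny, nz, kers[b]);
        double* rc = rotcube[m].data();
        for (int z = 0; z < nz; ++z) {
          for (int y = 0; y < ny; ++y) {
            const size_t base = (size_t)z * nx * ny + (size_t)y * nx;
            const size_t pix = (size_t)z * ny + y;
            for (int x = 0; x < nx; ++x)
              rc[base + x] += att[base + x] * bband[bandOfX[x]][pix];
          }
        }
      }
    }
    for (int m = 0; m < nM; ++m)
      rotate_gather_accum(rotcube[m].data(), REAL(out) + nvox * m, planS, nz);
  }
  return out;
}
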