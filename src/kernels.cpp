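#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample a 3D volume (column-major, dims nx,ny,nz) at fractional 0-based voxel
// coordinates. Trilinear or nearest-neighbour; points outside the support get
// `fill`. Points within half a voxel of the border clamp to the border value,
// matching edge-value extension.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dim,
                          NumericMatrix pts, double fill, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  const long sxy = (long)nx * ny;
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) {
      out[p] = fill;
      continue;
    }
    if (nearest) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      i = std::min(std::max(i, 0), nx - 1);
      j = std::min(std::max(j, 0), ny - 1);
      k = std::min(std::max(k, 0), nz - 1);
      out[p] = v[i + (long)j * nx + (long)k * sxy];
      continue;
    }
    // clamp into [0, n-1] so border voxels extend by half a voxel
    if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1 && nx > 1) i0--;
    if (j0 == ny - 1 && ny > 1) j0--;
    if (k0 == nz - 1 && nz > 1) k0--;
    int i1 = std::min(i0 + 1, nx - 1);
    int j1 = std::min(j0 + 1, ny - 1);
    int k1 = std::min(k0 + 1, nz - 1);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = v[i0 + (long)j0 * nx + (long)k0 * sxy];
    double c100 = v[i1 + (long)j0 * nx + (long)k0 * sxy];
    double c010 = v[i0 + (long)j1 * nx + (long)k0 * sxy];
    double c110 = v[i1 + (long)j1 * nx + (long)k0 * sxy];
    double c001 = v[i0 + (long)j0 * nx + (long)k1 * sxy];
    double c101 = v[i1 + (long)j0 * nx + (long)k1 * sxy];
    double c011 = v[i0 + (long)j1 * nx + (long)k1 * sxy];
    double c111 = v[i1 + (long)j1 * nx + (long)k1 * sxy];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

static void conv1d_axis(const double *in, double *out, int nx, int ny, int nz,
                        const std::vector<double> &ker, int axis) {
  const int r = (int)(ker.size() - 1) / 2;
  const long sxy = (long)nx * ny;
  const int n[3] = {nx, ny, nz};
  const long stride[3] = {1, nx, sxy};
  const long st = stride[axis];
  const int len = n[axis];
  // iterate over all lines along `axis`
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int pos[3] = {i, j, k};
        if (pos[axis] != 0) continue; // line anchor only
        long base = i + (long)j * nx + (long)k * sxy;
        for (int t = 0; t < len; ++t) {
          double acc = 0.0;
          for (int q = -r; q <= r; ++q) {
            int s = t + q;
            if (s < 0) s = -s;               // reflect
            if (s >= len) s = 2 * len - 2 - s;
            if (s < 0) s = 0;
            acc += ker[q + r] * in[base + (long)s * st];
          }
          out[base + (long)t * st] = acc;
        }
      }
    }
  }
}

// Separable Gaussian smoothing with reflecting boundaries; sigma per axis in
// voxel units (sigma <= 0 skips that axis).
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long ntot = (long)nx * ny * nz;
  NumericVector a(clone(vol));
  NumericVector b(ntot);
  double *pa = a.begin(), *pb = b.begin();
  bool in_a = true;
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int q = -r; q <= r; ++q) {
      ker[q + r] = std::exp(-0.5 * q * q / (s * s));
      sum += ker[q + r];
    }
    for (auto &w : ker) w /= sum;
    if (in_a) conv1d_axis(pa, pb, nx, ny, nz, ker, axis);
    else      conv1d_axis(pb, pa, nx, ny, nz, ker, axis);
    in_a = !in_a;
  }
  NumericVector out = in_a ? a : b;
  out.attr("dim") = dim;
  return out;
}

// Per-axis second differences along each axis: returns the bending energy
// sum(D2a u)^2 over axes for one field component.
// [[Rcpp::export]]
double cpp_bending_value(NumericVector comp, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sxy = (long)nx * ny;
  const double *u = comp.begin();
  double acc = 0.0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const long base = (long)j * nx + (long)k * sxy;
      for (int i = 0; i < nx; ++i) {
        const long p = base + i;
        if (i > 0 && i < nx - 1) {
          double d = u[p - 1] - 2 * u[p] + u[p + 1];
          acc += d * d;
        }
        if (j > 0 && j < ny - 1) {
          double d = u[p - nx] - 2 * u[p] + u[p + nx];
          acc += d * d;
        }
        if (k > 0 && k < nz - 1) {
          double d = u[p - sxy] - 2 * u[p] + u[p + sxy];
          acc += d * d;
        }
      }
    }
  }
  return acc;
}

// Gradient of cpp_bending_value wrt the component: sum over axes of
// D2a^T D2a u (second-difference operator applied twice, zero beyond edges).
// [[Rcpp::export]]
NumericVector cpp_bending_grad(NumericVector comp, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sxy = (long)nx * ny;
  const long ntot = sxy * nz;
  const double *u = comp.begin();
  std::vector<double> d2(ntot, 0.0);
  NumericVector out(ntot);
  double *o = out.begin();
  // axis x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const long base = (long)j * nx + (long)k * sxy;
      for (int i = 1; i < nx - 1; ++i) {
        const long p = base + i;
        d2[p] = u[p - 1] - 2 * u[p] + u[p + 1];
      }
      d2[base] = 0; d2[base + nx - 1] = 0;
      for (int i = 1; i < nx - 1; ++i) {
        const long p = base + i;
        double v = 2.0 * d2[p];
        o[p] -= 2.0 * v;
        o[p - 1] += v;
        o[p + 1] += v;
      }
    }
  // axis y
  std::fill(d2.begin(), d2.end(), 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < ny - 1; ++j) {
      const long base = (long)j * nx + (long)k * sxy;
      for (int i = 0; i < nx; ++i) {
        const long p = base + i;
        d2[p] = u[p - nx] - 2 * u[p] + u[p + nx];
      }
    }
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < ny - 1; ++j) {
      const long base = (long)j * nx + (long)k * sxy;
      for (int i = 0; i < nx; ++i) {
        const long p = base + i;
        double v = 2.0 * d2[p];
        o[p] -= 2.0 * v;
        o[p - nx] += v;
        o[p + nx] += v;
      }
    }
  // axis z
  std::fill(d2.begin(), d2.end(), 0.0);
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j) {
      const long base = (long)j * nx + (long)k * sxy;
      for (int i = 0; i < nx; ++i) {
        const long p = base + i;
        d2[p] = u[p - sxy] - 2 * u[p] + u[p + sxy];
      }
    }
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j) {
      const long base = (long)j * nx + (long)k * sxy;
      for (int i = 0; i < nx; ++i) {
        const long p = base + i;
        double v = 2.0 * d2[p];
        o[p] -= 2.0 * v;
        o[p - sxy] += v;
        o[p + sxy] += v;
      }
    }
  return out;
}

// Warp K channels through the displacement u (mm, npx x 3) on the grid they
// all share: channel values are sampled at voxel + u/spacing with one weight
// computation per voxel. Returns an npx x K matrix.
// [[Rcpp::export]]
NumericMatrix cpp_warp_multi(List vols, IntegerVector dim, NumericMatrix u,
                             NumericVector spacing, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sxy = (long)nx * ny;
  const long npx = sxy * nz;
  const int K = vols.size();
  std::vector<const double*> v(K);
  for (int c = 0; c < K; ++c) {
    NumericVector vv = vols[c];
    v[c] = vv.begin();
  }
  NumericMatrix out(npx, K);
  const double isx = 1.0 / spacing[0], isy = 1.0 / spacing[1],
               isz = 1.0 / spacing[2];
  for (long p = 0; p < npx; ++p) {
    const int k0i = (int)(p / sxy);
    const long rem = p - (long)k0i * sxy;
    const int j0i = (int)(rem / nx);
    const int i0i = (int)(rem - (long)j0i * nx);
    double x = i0i + u(p, 0) * isx;
    double y = j0i + u(p, 1) * isy;
    double z = k0i + u(p, 2) * isz;
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) {
      for (int c = 0; c < K; ++c) out(p, c) = fill;
      continue;
    }
    if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    int i0 = (int)x, j0 = (int)y, k0 = (int)z;
    if (i0 == nx - 1 && nx > 1) i0--;
    if (j0 == ny - 1 && ny > 1) j0--;
    if (k0 == nz - 1 && nz > 1) k0--;
    const int i1 = std::min(i0 + 1, nx - 1);
    const int j1 = std::min(j0 + 1, ny - 1);
    const int k1 = std::min(k0 + 1, nz - 1);
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    const long b000 = i0 + (long)j0 * nx + (long)k0 * sxy;
    const long b100 = i1 + (long)j0 * nx + (long)k0 * sxy;
    const long b010 = i0 + (long)j1 * nx + (long)k0 * sxy;
    const long b110 = i1 + (long)j1 * nx + (long)k0 * sxy;
    const long b001 = i0 + (long)j0 * nx + (long)k1 * sxy;
    const long b101 = i1 + (long)j0 * nx + (long)k1 * sxy;
    const long b011 = i0 + (long)j1 * nx + (long)k1 * sxy;
    const long b111 = i1 + (long)j1 * nx + (long)k1 * sxy;
    const double w000 = (1 - fx) * (1 - fy) * (1 - fz);
    const double w100 = fx * (1 - fy) * (1 - fz);
    const double w010 = (1 - fx) * fy * (1 - fz);
    const double w110 = fx * fy * (1 - fz);
    const double w001 = (1 - fx) * (1 - fy) * fz;
    const double w101 = fx * (1 - fy) * fz;
    const double w011 = (1 - fx) * fy * fz;
    const double w111 = fx * fy * fz;
    for (int c = 0; c < K; ++c) {
      const double *vc = v[c];
      out(p, c) = w000 * vc[b000] + w100 * vc[b100] + w010 * vc[b010] +
        w110 * vc[b110] + w001 * vc[b001] + w101 * vc[b101] +
        w011 * vc[b011] + w111 * vc[b111];
    }
  }
  return out;
}
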