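#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hot loops for volume resampling and phantom rendering.  Volumes are
// stored as R arrays dim (nx, ny, nz), element [i, j, k] (1-based in R)
// living at 0-based voxel coordinate (i-1, j-1, k-1); voxel centres sit
// at integer coordinates.  Samples outside the grid evaluate to zero.

static inline double sample_trilinear(const double *v, int nx, int ny, int nz,
                                      double x, double y, double z) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy < 2; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx < 2; ++dx) {
        int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * v[(size_t)xi + (size_t)nx * ((size_t)yi + (size_t)ny * zi)];
      }
    }
  }
  return acc;
}

static inline double sample_nearest(const double *v, int nx, int ny, int nz,
                                    double x, double y, double z) {
  long xi = std::lround(x), yi = std::lround(y), zi = std::lround(z);
  if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) return 0.0;
  return v[(size_t)xi + (size_t)nx * ((size_t)yi + (size_t)ny * zi)];
}

// Interpolate vol at arbitrary points (n x 3 matrix of 0-based voxel coords).
// [[Rcpp::export]]
NumericVector interp_points_cpp(NumericVector vol, IntegerVector dims,
                                NumericMatrix pts, bool nearest = false) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = nearest
      ? sample_nearest(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2))
      : sample_trilinear(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  }
  return out;
}

// Affine resampling: out voxel x (0-based) takes the value of the input
// volume at A %*% x + b.  Used for all rotations/shifts.
// [[Rcpp::export]]
NumericVector affine_interp_cpp(NumericVector vol, IntegerVector din,
                                IntegerVector dout, NumericMatrix A,
                                NumericVector b, bool nearest = false) {
  int nx = din[0], ny = din[1], nz = din[2];
  int ox = dout[0], oy = dout[1], oz = dout[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *v = REAL(vol);
  double *o = REAL(out);
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  size_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      double cx = a01 * j + a02 * k + b[0];
      double cy = a11 * j + a12 * k + b[1];
      double cz = a21 * j + a22 * k + b[2];
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = a00 * i + cx, y = a10 * i + cy, z = a20 * i + cz;
        o[idx] = nearest ? sample_nearest(v, nx, ny, nz, x, y, z)
                         : sample_trilinear(v, nx, ny, nz, x, y, z);
      }
    }
  }
  return out;
}

// Sum of isotropic Gaussian blobs, each truncated at cutoff_sigmas.
// centers: n x 3 (0-based voxel coords), sigma/amp per blob (voxels).
// [[Rcpp::export]]
NumericVector render_blobs_cpp(IntegerVector dims, NumericMatrix centers,
                               NumericVector sigma, NumericVector amp,
                               double cutoff_sigmas = 4.0) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  for (int bi = 0; bi < centers.nrow(); ++bi) {
    double cx = centers(bi, 0), cy = centers(bi, 1), cz = centers(bi, 2);
    double s = sigma[bi], a = amp[bi];
    double inv2s2 = 1.0 / (2.0 * s * s);
    double r = cutoff_sigmas * s;
    int x0 = std::max(0, (int)std::ceil(cx - r)), x1 = std::min(nx - 1, (int)std::floor(cx + r));
    int y0 = std::max(0, (int)std::ceil(cy - r)), y1 = std::min(ny - 1, (int)std::floor(cy + r));
    int z0 = std::max(0, (int)std::ceil(cz - r)), z1 = std::min(nz - 1, (int)std::floor(cz + r));
    for (int k = z0; k <= z1; ++k) {
      double dz2 = (k - cz) * (k - cz);
      for (int j = y0; j <= y1; ++j) {
        double dyz2 = dz2 + (j - cy) * (j - cy);
        for (int i = x0; i <= x1; ++i) {
          double d2 = dyz2 + (i - cx) * (i - cx);
          o[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] += a * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return out;
}
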