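#include <Rcpp.h>
using namespace Rcpp;

// Line integral of a density grid along a fixed direction, one ray per point.
//
// For each row of `points` (physical coordinates of a voxel centre), steps
// backwards from the point against `dir` (unit vector) in increments of
// `step`, sampling the density grid by nearest neighbour at segment
// midpoints, until the sample leaves the grid bounding box.  Air (density 0)
// outside the body contributes nothing, so the result is the material path
// length from the entry surface to the point.
//
// [[Rcpp::export]]
NumericVector ray_line_integral(NumericVector dens, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix points, NumericVector dir,
                                double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // bounding box spans half a voxel beyond the outermost voxel centres
  const double lo0 = origin[0] - 0.5 * sx, hi0 = origin[0] + (nx - 0.5) * sx;
  const double lo1 = origin[1] - 0.5 * sy, hi1 = origin[1] + (ny - 0.5) * sy;
  const double lo2 = origin[2] - 0.5 * sz, hi2 = origin[2] + (nz - 0.5) * sz;
  const double dx = dir[0], dy = dir[1], dz = dir[2];
  const int n = points.nrow();
  // generous cap: grid diagonal over step size
  const double diag = (hi0 - lo0) + (hi1 - lo1) + (hi2 - lo2);
  const int kmax = (int)(diag / step) + 2;

  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double sum = 0.0;
    for (int k = 0; k < kmax; ++k) {
      // midpoint of the k-th backward segment
      const double t = (k + 0.5) * step;
      const double x = px - t * dx, y = py - t * dy, z = pz - t * dz;
      if (x < lo0 || x > hi0 || y < lo1 || y > hi1 || z < lo2 || z > hi2)
        break;
      int ix = (int)std::lround((x - origin[0]) / sx);
      int iy = (int)std::lround((y - origin[1]) / sy);
      int iz = (int)std::lround((z - origin[2]) / sz);
      if (ix < 0) ix = 0; else if (ix >= nx) ix = nx - 1;
      if (iy < 0) iy = 0; else if (iy >= ny) iy = ny - 1;
      if (iz < 0) iz = 0; else if (iz >= nz) iz = nz - 1;
      sum += dens[ix + (size_t)nx * (iy + (size_t)ny * iz)] * step;
    }
    out[i] = sum;
  }
  return out;
}
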