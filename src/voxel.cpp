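#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Solvent-excluded-surface volume on a voxel grid.
//
// Let U be the union of atom spheres inflated by the probe radius
// (radius r_i + probe). The SES is the erosion of U by the probe: a point x
// belongs to the SES iff no allowed probe center (a point outside U) lies
// within the probe radius of x.
//
// The grid realisation keeps, per voxel, the exact signed distance
//   g(x) = min_i (|x - c_i| - (r_i + probe))
// (negative inside U), evaluated only in a band around the surface. A voxel
// x is occupied when g(x) < 0 and blocked when some lattice point c
// satisfies |x - c| + max(-g(c), 0) <= probe: lattice points outside U block
// within the full probe radius, lattice points just inside block with their
// residual reach, which places the effective blocking front on the true
// (sub-voxel) surface of U instead of on voxel centers. Returns the number
// of occupied, unblocked voxels.
//
// The caller must pad the grid so U stays clear of the grid boundary.
// [[Rcpp::export]]
double cpp_ses_voxel_count(NumericMatrix coords, NumericVector radii,
                           double probe, double spacing,
                           NumericVector origin, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(ntot, INF);

  auto idx = [&](int x, int y, int z) -> R_xlen_t {
    return ((R_xlen_t)z * ny + y) * nx + x;
  };

  // signed distance to the inflated union, exact within a band wide enough
  // to cover every potential blocking source (g < probe) and the interior
  // band (g > -probe - 2h); deeper voxels keep g from whatever sphere
  // stamped them, which is <= the band floor and only used as "inside"
  const int natom = coords.nrow();
  for (int a = 0; a < natom; ++a) {
    const double R = radii[a] + probe;
    const double reach = R + probe + 2 * spacing;
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    int x0 = std::max(0, (int)std::floor((cx - reach - origin[0]) / spacing));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + reach - origin[0]) / spacing));
    int y0 = std::max(0, (int)std::floor((cy - reach - origin[1]) / spacing));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + reach - origin[1]) / spacing));
    int z0 = std::max(0, (int)std::floor((cz - reach - origin[2]) / spacing));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + reach - origin[2]) / spacing));
    const double reach2 = reach * reach;
    for (int z = z0; z <= z1; ++z) {
      const double dz = origin[2] + z * spacing - cz, dz2 = dz * dz;
      for (int y = y0; y <= y1; ++y) {
        const double dy = origin[1] + y * spacing - cy, d2yz = dz2 + dy * dy;
        if (d2yz > reach2) continue;
        for (int x = x0; x <= x1; ++x) {
          const double dx = origin[0] + x * spacing - cx;
          const double d2 = d2yz + dx * dx;
          if (d2 > reach2) continue;
          const double v = std::sqrt(d2) - R;
          R_xlen_t k = idx(x, y, z);
          if (v < g[k]) g[k] = v;
        }
      }
    }
  }

  // blocking: sources are lattice points with residual reach
  // rad = probe - max(-g, 0) > 0, i.e. -probe < g (outside sources block with
  // the full probe radius; unstamped far-outside voxels are irrelevant
  // because everything within probe of the mask lies inside the band)
  std::vector<unsigned char> blocked(ntot, 0);
  const int pr = (int)std::ceil(probe / spacing) + 1;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double gc = g[idx(x, y, z)];
        if (!std::isfinite(gc) || gc >= probe) continue;
        const double rad = (gc < 0.0) ? probe + gc : probe;
        if (rad < 0.0) continue;
        const double rad2 = rad * rad;
        const int r0 = (int)std::ceil(rad / spacing);
        for (int dz = -std::min(r0, pr); dz <= std::min(r0, pr); ++dz) {
          const int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          const double fz = dz * spacing, fz2 = fz * fz;
          if (fz2 > rad2) continue;
          for (int dy = -r0; dy <= r0; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            const double fy = dy * spacing, f2 = fz2 + fy * fy;
            if (f2 > rad2) continue;
            for (int dx = -r0; dx <= r0; ++dx) {
              const int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              const double fx = dx * spacing;
              if (f2 + fx * fx <= rad2) blocked[idx(xx, yy, zz)] = 1;
            }
          }
        }
      }

  double count = 0.0;
  for (R_xlen_t i = 0; i < ntot; ++i)
    if (g[i] < 0.0 && !blocked[i]) count += 1.0;
  return count;
}
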