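// Local wall-normal estimation on staircase voxel boundaries: the normal at
// a solid-adjacent fluid node is the normalised negative sum of offset
// vectors to all solid voxels within a cubic window, pointing into the
// fluid. Out-of-domain voxels follow the face boundary conditions:
// periodic wrap, mirror at symmetry faces, solid beyond no-slip walls.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// faces: (x-,x+,y-,y+,z-,z+) with 0 periodic, 1 no-slip (solid), 2 symmetry
// nodes: 1-based linear indices of boundary-adjacent fluid nodes
// [[Rcpp::export]]
NumericMatrix wall_normals_cpp(IntegerVector labels, IntegerVector dims,
                               IntegerVector nodes, int rn,
                               IntegerVector faces) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int* lab = INTEGER(labels);
  const int nn = nodes.size();
  NumericMatrix out(nn, 3);
  const int n3[3] = {nx, ny, nz};
  for (int k = 0; k < nn; ++k) {
    const R_xlen_t c = (R_xlen_t)nodes[k] - 1;
    const int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
    double sx = 0, sy = 0, sz = 0;
    double bx = 0, by = 0, bz = 0;       // nearest-link fallback
    double bestd = 1e30;
    for (int dz = -rn; dz <= rn; ++dz)
      for (int dy = -rn; dy <= rn; ++dy)
        for (int dx = -rn; dx <= rn; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int p[3] = {x + dx, y + dy, z + dz};
          bool solid = false, skip = false;
          for (int a = 0; a < 3; ++a) {
            if (p[a] >= 0 && p[a] < n3[a]) continue;
            const int face = 2 * a + (p[a] < 0 ? 0 : 1);
            const int code = faces[face];
            if (code == 0) p[a] = (p[a] + n3[a]) % n3[a];
            else if (code == 2) p[a] = (p[a] < 0) ? (-p[a] - 1) : (2 * n3[a] - p[a] - 1);
            else solid = true;
            if (p[a] < 0 || p[a] >= n3[a]) skip = true;  // window beyond mirror
          }
          if (skip) continue;
          if (!solid) {
            const R_xlen_t cc = (R_xlen_t)p[0] + (R_xlen_t)nx * (p[1] + (R_xlen_t)ny * p[2]);
            solid = lab[cc] != 0;
          }
          if (solid) {
            sx -= dx; sy -= dy; sz -= dz;
            const double d = dx * dx + dy * dy + dz * dz;
            if (d < bestd) { bestd = d; bx = -dx; by = -dy; bz = -dz; }
          }
        }
    double nrm = std::sqrt(sx * sx + sy * sy + sz * sz);
    if (nrm < 1e-12) { sx = bx; sy = by; sz = bz; nrm = std::sqrt(sx*sx+sy*sy+sz*sz); }
    if (nrm < 1e-12) { sx = 1; sy = 0; sz = 0; nrm = 1; }
    out(k, 0) = sx / nrm; out(k, 1) = sy / nrm; out(k, 2) = sz / nrm;
  }
  return out;
}
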