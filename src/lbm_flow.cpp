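// D3Q19 two-relaxation-time lattice Boltzmann solver for steady Stokes-regime
// perfusion flow in voxelized pore geometries.
//
// Conventions: volumes are column-major R arrays indexed [x, y, z] with x
// fastest; lattice units (dx = dt = 1, initial density 1). The symmetric
// (even) part of the populations relaxes at s1 (sets the viscosity,
// nu = cs^2 (1/s1 - 1/2)), the antisymmetric (odd) part at s2; with
// s2 = 8(2 - s1)/(8 - s1) the magic combination (1/s1 - 1/2)(1/s2 - 1/2)
// equals 3/16 and halfway bounce-back walls sit midway between nodes.
// The body force enters through an equilibrium-velocity shift
// du = F/(rho s2); the hydrodynamic velocity is (j + F/2)/rho.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const int CX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int CY[19] = {0, 0, 0, 1,-1, 0, 0, 1, 1,-1,-1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int CZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1, 1,-1,-1, 1, 1,-1,-1};
static const double W[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36};

static int opposite(int q) {
  for (int p = 0; p < 19; ++p)
    if (CX[p] == -CX[q] && CY[p] == -CY[q] && CZ[p] == -CZ[q]) return p;
  return 0;
}
static int mirror_axis(int q, int axis) {
  int tx = CX[q], ty = CY[q], tz = CZ[q];
  if (axis == 0) tx = -tx; else if (axis == 1) ty = -ty; else tz = -tz;
  for (int p = 0; p < 19; ++p)
    if (CX[p] == tx && CY[p] == ty && CZ[p] == tz) return p;
  return 0;
}

// Face boundary codes: 0 periodic, 1 no-slip wall (halfway bounce-back),
// 2 symmetry (halfway specular reflection). faces = (x-,x+,y-,y+,z-,z+).
// [[Rcpp::export]]
List run_flow_cpp(IntegerVector labels, IntegerVector dims,
                  double s1, double s2, NumericVector force,
                  IntegerVector faces, double tol, int max_steps,
                  int window, Nullable<NumericVector> f_init) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  const int* lab = INTEGER(labels);

  // fluid node index map
  std::vector<int> fid(ncell, -1);
  std::vector<int> fx, fy, fz;
  int nf = 0;
  for (R_xlen_t c = 0; c < ncell; ++c) if (lab[c] == 0) ++nf;
  fx.reserve(nf); fy.reserve(nf); fz.reserve(nf);
  {
    int k = 0;
    R_xlen_t c = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++c)
          if (lab[c] == 0) { fid[c] = k++; fx.push_back(x); fy.push_back(y); fz.push_back(z); }
  }
  if (nf == 0) stop("no fluid nodes in the volume");

  int OPP[19], MIR[3][19];
  for (int q = 0; q < 19; ++q) {
    OPP[q] = opposite(q);
    for (int a = 0; a < 3; ++a) MIR[a][q] = mirror_axis(q, a);
  }

  // Pull-streaming source table: for fluid node i, direction q, the
  // population streamed in is f_old[src_dir][src_node].
  std::vector<int32_t> srcN((size_t)nf * 19);
  std::vector<int8_t> srcQ((size_t)nf * 19);
  for (int i = 0; i < nf; ++i) {
    for (int q = 0; q < 19; ++q) {
      int qq = q;
      int x = fx[i] - CX[q], y = fy[i] - CY[q], z = fz[i] - CZ[q];
      bool bb = false;
      // resolve each axis independently (corner-safe for the face set used)
      int pos[3] = {x, y, z};
      const int n3[3] = {nx, ny, nz};
      for (int a = 0; a < 3 && !bb; ++a) {
        if (pos[a] >= 0 && pos[a] < n3[a]) continue;
        int face = 2 * a + (pos[a] < 0 ? 0 : 1);
        int code = faces[face];
        if (code == 0) {            // periodic wrap
          pos[a] = (pos[a] + n3[a]) % n3[a];
        } else if (code == 2) {     // specular mirror halfway outside face
          qq = MIR[a][qq];
          pos[a] = (pos[a] < 0) ? 0 : n3[a] - 1;
        } else {                    // no-slip: halfway bounce-back
          bb = true;
        }
      }
      R_xlen_t cidx = bb ? -1 :
        (R_xlen_t)pos[0] + (R_xlen_t)nx * (pos[1] + (R_xlen_t)ny * pos[2]);
      if (bb || lab[cidx] != 0) {   // solid neighbour: bounce back on self
        srcN[(size_t)q * nf + i] = i;
        srcQ[(size_t)q * nf + i] = (int8_t)OPP[q];
      } else {
        srcN[(size_t)q * nf + i] = fid[cidx];
        srcQ[(size_t)q * nf + i] = (int8_t)qq;
      }
    }
  }

  const double Fx = force[0], Fy = force[1], Fz = force[2];
  const double hs1 = s1, hs2 = s2;

  std::vector<double> fA((size_t)nf * 19), fB((size_t)nf * 19);
  if (f_init.isNotNull()) {
    NumericVector fi(f_init);
    if ((R_xlen_t)fi.size() != (R_xlen_t)nf * 19) stop("f_init has wrong length");
    std::copy(fi.begin(), fi.end(), fA.begin());
  } else {
    for (int q = 0; q < 19; ++q)
      std::fill(fA.begin() + (size_t)q * nf, fA.begin() + (size_t)(q + 1) * nf, W[q]);
  }

  std::vector<double> ux(nf, 0.0), uy(nf, 0.0), uz(nf, 0.0);
  std::vector<double> ux0(nf, 0.0), uy0(nf, 0.0), uz0(nf, 0.0);
  std::vector<double> mass_trace;
  int pairs[9][2];
  {
    int k = 0;
    bool used[19] = {false};
    used[0] = true;
    for (int q = 1; q < 19; ++q) if (!used[q]) {
      pairs[k][0] = q; pairs[k][1] = OPP[q];
      used[q] = used[OPP[q]] = true; ++k;
    }
  }

  double *cur = fA.data(), *nxt = fB.data();
  int step = 0;
  bool converged = false;
  double last_delta = NA_REAL;

  // cache-blocked, node-vectorized update: per block, gather one direction
  // at a time (nearly sequential reads), then run the TRT collision as
  // SIMD-friendly loops over the block. For a (q, opp q) pair the even and
  // odd equilibrium parts have closed forms
  //   e+ = w rho (1 + 4.5 (c.u)^2 - 1.5 u^2),  e- = 3 w rho (c.u).
  const int B = 1024;
  std::vector<double> buf((size_t)19 * B);
  std::vector<double> rho(B), jxv(B), jyv(B), jzv(B),
      vxv(B), vyv(B), vzv(B), usq(B);

  for (step = 1; step <= max_steps; ++step) {
    for (int i0 = 0; i0 < nf; i0 += B) {
      const int nb = std::min(B, nf - i0);
      for (int q = 0; q < 19; ++q) {
        const int32_t* sn = srcN.data() + (size_t)q * nf + i0;
        const int8_t* sq = srcQ.data() + (size_t)q * nf + i0;
        double* b = buf.data() + (size_t)q * B;
        for (int j = 0; j < nb; ++j)
          b[j] = cur[(size_t)sq[j] * nf + sn[j]];
      }
      for (int j = 0; j < nb; ++j) {
        rho[j] = buf[j]; jxv[j] = 0.0; jyv[j] = 0.0; jzv[j] = 0.0;
      }
      for (int q = 1; q < 19; ++q) {
        const double* b = buf.data() + (size_t)q * B;
        const double cx = CX[q], cy = CY[q], cz = CZ[q];
        for (int j = 0; j < nb; ++j) {
          rho[j] += b[j];
          jxv[j] += cx * b[j]; jyv[j] += cy * b[j]; jzv[j] += cz * b[j];
        }
      }
      for (int j = 0; j < nb; ++j) {
        const double ir = 1.0 / rho[j];
        vxv[j] = (jxv[j] + Fx / hs2) * ir;
        vyv[j] = (jyv[j] + Fy / hs2) * ir;
        vzv[j] = (jzv[j] + Fz / hs2) * ir;
        usq[j] = vxv[j] * vxv[j] + vyv[j] * vyv[j] + vzv[j] * vzv[j];
      }
      {
        double* b0 = buf.data();
        for (int j = 0; j < nb; ++j) {
          const double feq0 = W[0] * rho[j] * (1.0 - 1.5 * usq[j]);
          b0[j] -= hs1 * (b0[j] - feq0);
        }
      }
      for (int k = 0; k < 9; ++k) {
        const int q = pairs[k][0], p = pairs[k][1];
        double* bq = buf.data() + (size_t)q * B;
        double* bp = buf.data() + (size_t)p * B;
        const double cx = CX[q], cy = CY[q], cz = CZ[q], w = W[q];
        for (int j = 0; j < nb; ++j) {
          const double cu = cx * vxv[j] + cy * vyv[j] + cz * vzv[j];
          const double es = w * rho[j] * (1.0 + 4.5 * cu * cu - 1.5 * usq[j]);
          const double ea = 3.0 * w * rho[j] * cu;
          const double fs = 0.5 * (bq[j] + bp[j]), fa = 0.5 * (bq[j] - bp[j]);
          const double ds = hs1 * (fs - es), da = hs2 * (fa - ea);
          bq[j] -= ds + da;
          bp[j] -= ds - da;
        }
      }
      for (int j = 0; j < nb; ++j) {
        const int i = i0 + j;
        const double ir = 1.0 / rho[j];
        ux[i] = (jxv[j] + 0.5 * Fx) * ir;
        uy[i] = (jyv[j] + 0.5 * Fy) * ir;
        uz[i] = (jzv[j] + 0.5 * Fz) * ir;
      }
      for (int q = 0; q < 19; ++q) {
        double* out = nxt + (size_t)q * nf + i0;
        const double* b = buf.data() + (size_t)q * B;
        for (int j = 0; j < nb; ++j) out[j] = b[j];
      }
    }
    std::swap(cur, nxt);

    if (step % window == 0) {
      double num = 0.0, den = 0.0, mass = 0.0;
      for (int i = 0; i < nf; ++i) {
        const double dx = ux[i] - ux0[i], dy = uy[i] - uy0[i], dz = uz[i] - uz0[i];
        num += dx * dx + dy * dy + dz * dz;
        den += ux[i] * ux[i] + uy[i] * uy[i] + uz[i] * uz[i];
      }
      for (int q = 0; q < 19; ++q) {
        const double* fq = cur + (size_t)q * nf;
        for (int i = 0; i < nf; ++i) mass += fq[i];
      }
      mass_trace.push_back(mass);
      std::copy(ux.begin(), ux.end(), ux0.begin());
      std::copy(uy.begin(), uy.end(), uy0.begin());
      std::copy(uz.begin(), uz.end(), uz0.begin());
      last_delta = (den > 0.0) ? std::sqrt(num / den) : std::sqrt(num);
      if (!std::isfinite(mass)) stop("flow solver diverged at step %d", step);
      if (step > window && last_delta < tol) { converged = true; break; }
      Rcpp::checkUserInterrupt();
    }
  }
  if (step > max_steps) step = max_steps;

  // one extra streaming pass (no collision): the stress tensor must be
  // evaluated from pre-collision non-equilibrium populations
  for (int i = 0; i < nf; ++i)
    for (int q = 0; q < 19; ++q)
      nxt[(size_t)q * nf + i] =
        cur[(size_t)srcQ[(size_t)q * nf + i] * nf + srcN[(size_t)q * nf + i]];
  std::swap(cur, nxt);

  NumericVector Ux(nf), Uy(nf), Uz(nf), Rho(nf), Fout((R_xlen_t)nf * 19);
  for (int i = 0; i < nf; ++i) {
    Ux[i] = ux[i]; Uy[i] = uy[i]; Uz[i] = uz[i];
    double r = 0.0;
    for (int q = 0; q < 19; ++q) r += cur[(size_t)q * nf + i];
    Rho[i] = r;
  }
  std::copy(cur, cur + (size_t)nf * 19, Fout.begin());
  IntegerVector fidx(nf);
  for (int i = 0; i < nf; ++i)
    fidx[i] = fx[i] + nx * (fy[i] + ny * fz[i]) + 1; // 1-based cell index

  return List::create(
    _["ux"] = Ux, _["uy"] = Uy, _["uz"] = Uz, _["rho"] = Rho,
    _["f"] = Fout, _["fluid_index"] = fidx, _["steps"] = step,
    _["converged"] = converged, _["delta"] = last_delta,
    _["mass_trace"] = NumericVector(mass_trace.begin(), mass_trace.end()));
}

// Deviatoric viscous stress from the second moment of the non-equilibrium
// populations: sigma_ab = -(1 - s1/2) sum_q f^neq_q c_qa c_qb (lattice
// units). Returns 6 columns (xx, yy, zz, xy, xz, yz) per fluid node.
// [[Rcpp::export]]
NumericMatrix stress_from_populations_cpp(NumericVector f, int nf,
                                          NumericVector force, double s1,
                                          double s2) {
  NumericMatrix out(nf, 6);
  const double Fx = force[0], Fy = force[1], Fz = force[2];
  const double pref = -(1.0 - 0.5 * s1);
  for (int i = 0; i < nf; ++i) {
    double fq[19], rho = 0.0, jx = 0.0, jy = 0.0, jz = 0.0;
    for (int q = 0; q < 19; ++q) {
      fq[q] = f[(R_xlen_t)q * nf + i];
      rho += fq[q];
      jx += fq[q] * CX[q]; jy += fq[q] * CY[q]; jz += fq[q] * CZ[q];
    }
    const double inv_rho = 1.0 / rho;
    const double vx = (jx + 0.5 * Fx) * inv_rho;
    const double vy = (jy + 0.5 * Fy) * inv_rho;
    const double vz = (jz + 0.5 * Fz) * inv_rho;
    const double usq = vx * vx + vy * vy + vz * vz;
    double pxx = 0, pyy = 0, pzz = 0, pxy = 0, pxz = 0, pyz = 0;
    for (int q = 0; q < 19; ++q) {
      const double cu = CX[q] * vx + CY[q] * vy + CZ[q] * vz;
      const double feq = W[q] * rho * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * usq);
      const double fn = fq[q] - feq;
      pxx += fn * CX[q] * CX[q]; pyy += fn * CY[q] * CY[q]; pzz += fn * CZ[q] * CZ[q];
      pxy += fn * CX[q] * CY[q]; pxz += fn * CX[q] * CZ[q]; pyz += fn * CY[q] * CZ[q];
    }
    // remove the trace: the isotropic part is pressure, not viscous stress
    const double tr3 = (pxx + pyy + pzz) / 3.0;
    out(i, 0) = pref * (pxx - tr3);
    out(i, 1) = pref * (pyy - tr3);
    out(i, 2) = pref * (pzz - tr3);
    out(i, 3) = pref * pxy;
    out(i, 4) = pref * pxz;
    out(i, 5) = pref * pyz;
  }
  return out;
}
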