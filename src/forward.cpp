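#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Discretized first-Born forward model on translation-invariant kernels.
//
// In a homogeneous slab the excitation fluence from the line source and the
// detector Green's function depend only on displacements from the source
// line / detector pixel, so one Monte Carlo kernel pair serves every stage
// position (block-convolutional structure).
//
//   frame(s, d, y) = sum_v O(v) * Phi(x_v - x_s, z_v) *
//                             Grn(x_s + off_d - x_v, y_d - y_v, z_v) * h^3
//
// phi2d:  (nkx x nz) excitation kernel, row cx_phi (1-based) is dx = 0.
// g3d:    (ngx x ngy x nz) emission kernel, centre (cgx, cgy) is
//         (dx, dy) = (0, 0).
// ovox:   nonzero fluorophore voxels, columns x, y, z (mm, voxel centres),
//         value.
// Lookups are nearest-bin at the kernel resolution h.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector born_forward_stack(NumericMatrix phi2d, int cx_phi,
                                 NumericVector g3d, IntegerVector gdims,
                                 int cgx, int cgy, double h,
                                 NumericMatrix ovox,
                                 NumericVector stage_x,
                                 NumericVector offsets,
                                 NumericVector ydet,
                                 double phi_floor = 0.0) {
  const int nkx = phi2d.nrow(), nzp = phi2d.ncol();
  const int ngx = gdims[0], ngy = gdims[1], ngz = gdims[2];
  const int ns = stage_x.size(), nd = offsets.size(), nyd = ydet.size();
  const int no = ovox.nrow();
  const double vol = h * h * h;
  const double *GG = g3d.begin();

  NumericVector out((R_xlen_t)ns * nd * nyd);  // dims (ns, nd, nyd)
  double *O = out.begin();

  for (int o = 0; o < no; ++o) {
    const double xo = ovox(o, 0), yo = ovox(o, 1), zo = ovox(o, 2);
    const double val = ovox(o, 3) * vol;
    const int iz = (int)std::floor(zo / h);
    if (iz < 0 || iz >= nzp || iz >= ngz) continue;
    for (int s = 0; s < ns; ++s) {
      const int ixp = (int)std::lround((xo - stage_x[s]) / h) + (cx_phi - 1);
      if (ixp < 0 || ixp >= nkx) continue;
      const double phi = phi2d(ixp, iz);
      if (phi <= phi_floor) continue;
      const double contrib = val * phi;
      for (int d = 0; d < nd; ++d) {
        const double xd = stage_x[s] + offsets[d];
        const int igx = (int)std::lround((xd - xo) / h) + (cgx - 1);
        if (igx < 0 || igx >= ngx) continue;
        const R_xlen_t base = (R_xlen_t)igx + (R_xlen_t)ngx * (R_xlen_t)ngy * iz;
        const R_xlen_t row_s = (R_xlen_t)s + (R_xlen_t)ns * d;
        for (int y = 0; y < nyd; ++y) {
          const int igy = (int)std::lround((ydet[y] - yo) / h) + (cgy - 1);
          if (igy < 0 || igy >= ngy) continue;
          const double gv = GG[base + (R_xlen_t)ngx * igy];
          if (gv > 0)
            O[row_s + (R_xlen_t)ns * nd * y] += contrib * gv;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ns, nd, nyd);
  return out;
}

// ---------------------------------------------------------------------------
// Sparse assembly of the weighted sensitivity matrix in invariant-y mode.
//
// Rows are (stage position, detector offset) pairs ordered offset-fastest;
// columns are x-z voxels ordered x-fastest (col = ix + nx * iz, 0-based).
// W[(s,d), (ix,iz)] = Phi(ix - sx_s, iz) * Grn(ix - (sx_s + off_d), iz) * h^3
// Entries below floor_rel * max(W) are dropped (MC shot-noise floor).
// Returns 1-based triplets for Matrix::sparseMatrix().
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List assemble_w_conv(NumericMatrix phi2d, int cx_phi,
                     NumericMatrix g2d, int cx_g,
                     int nx, int nz, double h,
                     IntegerVector stage_ix,   // 0-based source voxel index
                     IntegerVector offset_iv,  // offset in voxels
                     double floor_rel = 1e-6) {
  const int nkx = phi2d.nrow(), ngx = g2d.nrow();
  const int ns = stage_ix.size(), nd = offset_iv.size();
  const double vol = h * h * h;

  // pass 1: global maximum entry
  double wmax = 0.0;
  for (int s = 0; s < ns; ++s) {
    for (int d = 0; d < nd; ++d) {
      const int sx = stage_ix[s], dx = stage_ix[s] + offset_iv[d];
      for (int iz = 0; iz < nz; ++iz) {
        for (int ix = 0; ix < nx; ++ix) {
          const int ip = ix - sx + (cx_phi - 1);
          if (ip < 0 || ip >= nkx) continue;
          const int ig = ix - dx + (cx_g - 1);
          if (ig < 0 || ig >= ngx) continue;
          const double v = phi2d(ip, iz) * g2d(ig, iz);
          if (v > wmax) wmax = v;
        }
      }
    }
  }
  const double floor_abs = floor_rel * wmax;

  std::vector<int> ri, ci;
  std::vector<double> xv;
  ri.reserve(1 << 20); ci.reserve(1 << 20); xv.reserve(1 << 20);
  for (int s = 0; s < ns; ++s) {
    for (int d = 0; d < nd; ++d) {
      const int row = s * nd + d;  // offset-fastest
      const int sx = stage_ix[s], dx = stage_ix[s] + offset_iv[d];
      for (int iz = 0; iz < nz; ++iz) {
        for (int ix = 0; ix < nx; ++ix) {
          const int ip = ix - sx + (cx_phi - 1);
          if (ip < 0 || ip >= nkx) continue;
          const int ig = ix - dx + (cx_g - 1);
          if (ig < 0 || ig >= ngx) continue;
          const double v = phi2d(ip, iz) * g2d(ig, iz);
          if (v > floor_abs) {
            ri.push_back(row + 1);
            ci.push_back(ix + nx * iz + 1);
            xv.push_back(v * vol);
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["x"] = wrap(xv), _["nrow"] = ns * nd,
                      _["ncol"] = nx * nz, _["max"] = wmax * vol);
}
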