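#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All stencils are second-order central differences on the unit lattice with
// replicate-edge (zero-gradient) boundaries.  Arrays are R 3D arrays in
// column-major order: index = i + nx*(j + ny*k).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
List cpp_gradient(NumericVector f, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector gx(n), gy(n), gz(n);
  for (int k = 0; k < nz; ++k) {
    const int kp = clampi(k + 1, 0, nz - 1), km = clampi(k - 1, 0, nz - 1);
    for (int j = 0; j < ny; ++j) {
      const int jp = clampi(j + 1, 0, ny - 1), jm = clampi(j - 1, 0, ny - 1);
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      const R_xlen_t bjp = (R_xlen_t)nx * (jp + (R_xlen_t)ny * k);
      const R_xlen_t bjm = (R_xlen_t)nx * (jm + (R_xlen_t)ny * k);
      const R_xlen_t bkp = (R_xlen_t)nx * (j + (R_xlen_t)ny * kp);
      const R_xlen_t bkm = (R_xlen_t)nx * (j + (R_xlen_t)ny * km);
      for (int i = 0; i < nx; ++i) {
        const int ip = clampi(i + 1, 0, nx - 1), im = clampi(i - 1, 0, nx - 1);
        gx[base + i] = 0.5 * (f[base + ip] - f[base + im]);
        gy[base + i] = 0.5 * (f[bjp + i] - f[bjm + i]);
        gz[base + i] = 0.5 * (f[bkp + i] - f[bkm + i]);
      }
    }
  }
  return List::create(_["x"] = gx, _["y"] = gy, _["z"] = gz);
}

// [[Rcpp::export]]
NumericVector cpp_laplacian(NumericVector f, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (int k = 0; k < nz; ++k) {
    const int kp = clampi(k + 1, 0, nz - 1), km = clampi(k - 1, 0, nz - 1);
    for (int j = 0; j < ny; ++j) {
      const int jp = clampi(j + 1, 0, ny - 1), jm = clampi(j - 1, 0, ny - 1);
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      const R_xlen_t bjp = (R_xlen_t)nx * (jp + (R_xlen_t)ny * k);
      const R_xlen_t bjm = (R_xlen_t)nx * (jm + (R_xlen_t)ny * k);
      const R_xlen_t bkp = (R_xlen_t)nx * (j + (R_xlen_t)ny * kp);
      const R_xlen_t bkm = (R_xlen_t)nx * (j + (R_xlen_t)ny * km);
      for (int i = 0; i < nx; ++i) {
        const int ip = clampi(i + 1, 0, nx - 1), im = clampi(i - 1, 0, nx - 1);
        out[base + i] = f[base + ip] + f[base + im] + f[bjp + i] + f[bjm + i] +
                        f[bkp + i] + f[bkm + i] - 6.0 * f[base + i];
      }
    }
  }
  return out;
}

static inline double wprime(double p) {
  // derivative of the double-well W(p) = p^2 (p-1)^2
  return 2.0 * p * (p - 1.0) * (2.0 * p - 1.0);
}

struct Box { int x0, x1, y0, y1, z0, z1; };

// tight bounding box of {phi > thresh}, expanded by `pad`, clamped to grid
static Box supportBox(const std::vector<double> &f, int nx, int ny, int nz,
                      double thresh, int pad) {
  Box b = {nx, -1, ny, -1, nz, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i)
        if (f[base + i] > thresh) {
          if (i < b.x0) b.x0 = i;
          if (i > b.x1) b.x1 = i;
          if (j < b.y0) b.y0 = j;
          if (j > b.y1) b.y1 = j;
          if (k < b.z0) b.z0 = k;
          if (k > b.z1) b.z1 = k;
        }
    }
  if (b.x1 < 0) { b = {0, nx - 1, 0, ny - 1, 0, nz - 1}; return b; }
  b.x0 = clampi(b.x0 - pad, 0, nx - 1); b.x1 = clampi(b.x1 + pad, 0, nx - 1);
  b.y0 = clampi(b.y0 - pad, 0, ny - 1); b.y1 = clampi(b.y1 + pad, 0, ny - 1);
  b.z0 = clampi(b.z0 - pad, 0, nz - 1); b.z1 = clampi(b.z1 + pad, 0, nz - 1);
  return b;
}

// Advective update of all cell fields over `nsteps` explicit Euler steps:
//   phi_i <- phi_i - (h/tau) * (F_ten + F_rep + F_vol + F_atr) . grad(phi_i)
// with the force terms of the overdamped model.  Everything is in lattice
// units; `targetVol` are prescribed volumes in lattice units.  The update is
// synchronous (all forces evaluated on the fields at the start of a step).
// Work is restricted to per-cell support bounding boxes (refreshed
// periodically and padded generously against interface motion, which is
// sub-voxel per step under the CFL-like stability of the scheme).
// Returns the updated fields, their final volumes, and the step at which a
// non-finite value was first produced (0 if none; the update then stopped).
// [[Rcpp::export]]
List cpp_evolve(List fields, NumericVector eggshell, IntegerVector dims,
                NumericMatrix sigma, NumericVector targetVol,
                double gamma, double ccoef, double ge, double g,
                double M, double gradEps, double maskThresh,
                double tau, double h, int nsteps, double volCap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int nc = fields.size();
  const int boxRefresh = 30, boxPad = 6;   // pad >= boxRefresh * max speed
  std::vector<std::vector<double>> phi(nc), phinew(nc);
  for (int c = 0; c < nc; ++c) {
    NumericVector f = fields[c];
    phi[c].assign(f.begin(), f.end());
    phinew[c] = phi[c];
  }
  std::vector<double> egg2(n);
  for (R_xlen_t v = 0; v < n; ++v) egg2[v] = eggshell[v] * eggshell[v];

  std::vector<std::vector<double>> gx(nc), gy(nc), gz(nc);
  for (int c = 0; c < nc; ++c) {
    gx[c].assign(n, 0.0); gy[c].assign(n, 0.0); gz[c].assign(n, 0.0);
  }
  std::vector<double> S2(n, 0.0), vol(nc);
  std::vector<Box> box(nc);
  int badStep = 0;

  for (int s = 0; s < nsteps && badStep == 0; ++s) {
    if (s % boxRefresh == 0)
      for (int c = 0; c < nc; ++c) {
        // zero the old gradient region before the box can move
        const Box &ob = box[c];
        if (s > 0)
          for (int k = ob.z0; k <= ob.z1; ++k)
            for (int j = ob.y0; j <= ob.y1; ++j) {
              const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
              std::fill(gx[c].begin() + base + ob.x0, gx[c].begin() + base + ob.x1 + 1, 0.0);
              std::fill(gy[c].begin() + base + ob.x0, gy[c].begin() + base + ob.x1 + 1, 0.0);
              std::fill(gz[c].begin() + base + ob.x0, gz[c].begin() + base + ob.x1 + 1, 0.0);
            }
        box[c] = supportBox(phi[c], nx, ny, nz, 1e-7, boxPad);
      }

    // per-step precomputation within boxes: gradients, volumes, S2
    for (int c = 0; c < nc; ++c) {
      const std::vector<double> &f = phi[c];
      const Box &b = box[c];
      double vsum = 0.0;
      for (int k = b.z0; k <= b.z1; ++k) {
        const int kp = clampi(k + 1, 0, nz - 1), km = clampi(k - 1, 0, nz - 1);
        for (int j = b.y0; j <= b.y1; ++j) {
          const int jp = clampi(j + 1, 0, ny - 1), jm = clampi(j - 1, 0, ny - 1);
          const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          const R_xlen_t bjp = (R_xlen_t)nx * (jp + (R_xlen_t)ny * k);
          const R_xlen_t bjm = (R_xlen_t)nx * (jm + (R_xlen_t)ny * k);
          const R_xlen_t bkp = (R_xlen_t)nx * (j + (R_xlen_t)ny * kp);
          const R_xlen_t bkm = (R_xlen_t)nx * (j + (R_xlen_t)ny * km);
          for (int i = b.x0; i <= b.x1; ++i) {
            const int ip = clampi(i + 1, 0, nx - 1), im = clampi(i - 1, 0, nx - 1);
            const R_xlen_t v = base + i;
            gx[c][v] = 0.5 * (f[base + ip] - f[base + im]);
            gy[c][v] = 0.5 * (f[bjp + i] - f[bjm + i]);
            gz[c][v] = 0.5 * (f[bkp + i] - f[bkm + i]);
            vsum += f[v];
          }
        }
      }
      vol[c] = vsum;
    }
    if (nc > 1)
      for (int c = 0; c < nc; ++c) {
        const Box &b = box[c];
        const std::vector<double> &f = phi[c];
        for (int k = b.z0; k <= b.z1; ++k)
          for (int j = b.y0; j <= b.y1; ++j) {
            const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            for (int i = b.x0; i <= b.x1; ++i)
              S2[base + i] += f[base + i] * f[base + i];
          }
      }

    for (int c = 0; c < nc; ++c) {
      const std::vector<double> &f = phi[c];
      std::vector<double> &fn = phinew[c];
      const Box &b = box[c];
      double dvol = M * (vol[c] - targetVol[c]);
      if (dvol > volCap) dvol = volCap;
      if (dvol < -volCap) dvol = -volCap;
      for (int k = b.z0; k <= b.z1; ++k) {
        const int kp = clampi(k + 1, 0, nz - 1), km = clampi(k - 1, 0, nz - 1);
        for (int j = b.y0; j <= b.y1; ++j) {
          const int jp = clampi(j + 1, 0, ny - 1), jm = clampi(j - 1, 0, ny - 1);
          const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          const R_xlen_t bjp = (R_xlen_t)nx * (jp + (R_xlen_t)ny * k);
          const R_xlen_t bjm = (R_xlen_t)nx * (jm + (R_xlen_t)ny * k);
          const R_xlen_t bkp = (R_xlen_t)nx * (j + (R_xlen_t)ny * kp);
          const R_xlen_t bkm = (R_xlen_t)nx * (j + (R_xlen_t)ny * km);
          for (int i = b.x0; i <= b.x1; ++i) {
            const int ip = clampi(i + 1, 0, nx - 1), im = clampi(i - 1, 0, nx - 1);
            const R_xlen_t v = base + i;
            const double gxv = gx[c][v], gyv = gy[c][v], gzv = gz[c][v];
            const double g2 = gxv * gxv + gyv * gyv + gzv * gzv;
            if (g2 <= maskThresh) {         // off the interface band: no advection
              fn[v] = f[v];
              continue;
            }
            const double lap = f[base + ip] + f[base + im] + f[bjp + i] +
                               f[bjm + i] + f[bkp + i] + f[bkm + i] - 6.0 * f[v];
            const double p = f[v];
            // scalar coefficients multiplying grad(phi_i), dotted with grad(phi_i)
            const double ten = -gamma * (lap - ccoef * wprime(p));
            const double rep = ge * p * egg2[v] + g * p * ((nc > 1 ? S2[v] : p * p) - p * p);
            double dot = (ten + rep) * g2 / (g2 + gradEps);
            dot += dvol * g2 / (std::sqrt(g2) + gradEps);
            double atr = 0.0;
            for (int c2 = 0; c2 < nc; ++c2) {
              if (c2 == c) continue;
              const double sg = sigma(c, c2);
              if (sg != 0.0)
                atr += sg * (gx[c2][v] * gxv + gy[c2][v] * gyv + gz[c2][v] * gzv);
            }
            dot += atr;
            fn[v] = p - (h / tau) * dot;
            if (!std::isfinite(fn[v]) && badStep == 0) badStep = s + 1;
          }
        }
      }
    }
    // reset S2 within the boxes for the next step
    if (nc > 1)
      for (int c = 0; c < nc; ++c) {
        const Box &b = box[c];
        for (int k = b.z0; k <= b.z1; ++k)
          for (int j = b.y0; j <= b.y1; ++j) {
            const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            std::fill(S2.begin() + base + b.x0, S2.begin() + base + b.x1 + 1, 0.0);
          }
      }
    for (int c = 0; c < nc; ++c) {
      // voxels outside the box are untouched: copy them over via swap+patch
      std::vector<double> &f = phi[c];
      std::vector<double> &fn = phinew[c];
      const Box &b = box[c];
      for (int k = b.z0; k <= b.z1; ++k)
        for (int j = b.y0; j <= b.y1; ++j) {
          const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          std::copy(fn.begin() + base + b.x0, fn.begin() + base + b.x1 + 1,
                    f.begin() + base + b.x0);
        }
    }
  }

  List outf(nc);
  NumericVector outv(nc);
  for (int c = 0; c < nc; ++c) {
    NumericVector f(phi[c].begin(), phi[c].end());
    f.attr("dim") = dims;
    outf[c] = f;
    double vsum = 0.0;
    for (R_xlen_t v = 0; v < n; ++v) vsum += phi[c][v];
    outv[c] = vsum;
  }
  return List::create(_["fields"] = outf, _["volumes"] = outv,
                      _["bad_step"] = badStep);
}

// Face counting between labels of a voxelized segmentation, for contact-area
// estimation.  `labels` are integers in 0..nlab-1 (0 = exterior).  Returns an
// nlab x nlab symmetric matrix of face counts between distinct labels.
// [[Rcpp::export]]
IntegerMatrix cpp_face_counts(IntegerVector labels, IntegerVector dims, int nlab) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerMatrix counts(nlab, nlab);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        const int a = labels[v];
        if (i + 1 < nx) {
          const int b = labels[v + 1];
          if (a != b) { counts(a, b)++; counts(b, a)++; }
        }
        if (j + 1 < ny) {
          const int b = labels[v + nx];
          if (a != b) { counts(a, b)++; counts(b, a)++; }
        }
        if (k + 1 < nz) {
          const int b = labels[v + (R_xlen_t)nx * ny];
          if (a != b) { counts(a, b)++; counts(b, a)++; }
        }
      }
  return counts;
}
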