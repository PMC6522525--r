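// Leap-frog FDTD acoustic solver on a staggered grid with locally
// reacting impedance walls, split-field PML, and surface/probe recording,
// plus a Kirchhoff-Helmholtz farfield summation kernel.
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int cidx(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
List fdtd_run_cpp(IntegerVector dims, LogicalVector solid_pad,
                  double h, double dt, int nsteps,
                  double c, double rho, double Z,
                  int npml, double sigma_max, int pml_m,
                  IntegerVector src_cell, NumericVector src_wave,
                  IntegerVector box, int stride,
                  IntegerMatrix probes, bool record_energy) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long ncell = (long)nx * ny * nz;
  std::vector<char> air(ncell);
  for (long q = 0; q < ncell; ++q) air[q] = solid_pad[q] ? 0 : 1;

  std::vector<double> p(ncell, 0.0), px(ncell, 0.0), py(ncell, 0.0),
      pz(ncell, 0.0);
  std::vector<double> vx((long)(nx + 1) * ny * nz, 0.0),
      vy((long)nx * (ny + 1) * nz, 0.0), vz((long)nx * ny * (nz + 1), 0.0);

  // 1D PML conductivity profiles (cell centers and faces) per axis
  auto sig_cell = [&](int i, int n) {
    double d = 0.0;
    if (i < npml) d = (npml - i - 0.5) / npml;
    else if (i >= n - npml) d = (i - (n - npml) + 0.5) / npml;
    return d > 0 ? sigma_max * std::pow(d, pml_m) : 0.0;
  };
  auto sig_face = [&](int i, int n) {  // face i sits between cells i-1, i
    double d = 0.0;
    if (i < npml) d = (double)(npml - i) / npml;
    else if (i > n - npml) d = (double)(i - (n - npml)) / npml;
    return d > 0 ? sigma_max * std::pow(d, pml_m) : 0.0;
  };
  std::vector<double> apx(nx), bpx(nx), apy(ny), bpy(ny), apz(nz), bpz(nz);
  const double pco = rho * c * c * dt / h;
  for (int i = 0; i < nx; ++i) {
    double s = sig_cell(i, nx) * dt / 2;
    apx[i] = (1 - s) / (1 + s); bpx[i] = pco / (1 + s);
  }
  for (int j = 0; j < ny; ++j) {
    double s = sig_cell(j, ny) * dt / 2;
    apy[j] = (1 - s) / (1 + s); bpy[j] = pco / (1 + s);
  }
  for (int k = 0; k < nz; ++k) {
    double s = sig_cell(k, nz) * dt / 2;
    apz[k] = (1 - s) / (1 + s); bpz[k] = pco / (1 + s);
  }
  std::vector<double> avx(nx + 1), bvx(nx + 1), avy(ny + 1), bvy(ny + 1),
      avz(nz + 1), bvz(nz + 1);
  const double vco = dt / (rho * h);
  for (int i = 0; i <= nx; ++i) {
    double s = sig_face(i, nx) * dt / 2;
    avx[i] = (1 - s) / (1 + s); bvx[i] = vco / (1 + s);
  }
  for (int j = 0; j <= ny; ++j) {
    double s = sig_face(j, ny) * dt / 2;
    avy[j] = (1 - s) / (1 + s); bvy[j] = vco / (1 + s);
  }
  for (int k = 0; k <= nz; ++k) {
    double s = sig_face(k, nz) * dt / 2;
    avz[k] = (1 - s) / (1 + s); bvz[k] = vco / (1 + s);
  }
  const double kap = Z * dt / (2 * rho * h);
  const double imp_a = (1 - kap) / (1 + kap), imp_b = vco / (1 + kap);

  // surface sample points on the boundary of the cell box [i0..i1] x ...
  const int i0 = box[0], i1 = box[1], j0 = box[2], j1 = box[3],
            k0 = box[4], k1 = box[5];
  std::vector<int> scell, sface;  // inner cell index; staggered face index
  std::vector<int> souter;        // outer neighbour cell index
  std::vector<int> sdir;          // 0=x,1=y,2=z
  std::vector<double> ssgn, spx, spy, spz;
  auto add_pt = [&](int ci, int cj, int ck, int dir, double sgn) {
    int cc = cidx(ci, cj, ck, nx, ny);
    int oi = ci + (dir == 0 ? (int)sgn : 0),
        oj = cj + (dir == 1 ? (int)sgn : 0),
        ok = ck + (dir == 2 ? (int)sgn : 0);
    int oc = cidx(oi, oj, ok, nx, ny);
    int f;
    if (dir == 0) f = (sgn > 0 ? ci + 1 : ci) + (nx + 1) * (cj + ny * ck);
    else if (dir == 1) f = ci + nx * ((sgn > 0 ? cj + 1 : cj) + (ny + 1) * ck);
    else f = ci + nx * (cj + ny * (sgn > 0 ? ck + 1 : ck));
    scell.push_back(cc); souter.push_back(oc); sface.push_back(f);
    sdir.push_back(dir); ssgn.push_back(sgn);
    spx.push_back(ci + (dir == 0 ? 0.5 * sgn : 0.0));
    spy.push_back(cj + (dir == 1 ? 0.5 * sgn : 0.0));
    spz.push_back(ck + (dir == 2 ? 0.5 * sgn : 0.0));
  };
  for (int k = k0; k <= k1; ++k)
    for (int j = j0; j <= j1; ++j) {
      add_pt(i0, j, k, 0, -1.0);
      add_pt(i1, j, k, 0, +1.0);
    }
  for (int k = k0; k <= k1; ++k)
    for (int i = i0; i <= i1; ++i) {
      add_pt(i, j0, k, 1, -1.0);
      add_pt(i, j1, k, 1, +1.0);
    }
  for (int j = j0; j <= j1; ++j)
    for (int i = i0; i <= i1; ++i) {
      add_pt(i, j, k0, 2, -1.0);
      add_pt(i, j, k1, 2, +1.0);
    }
  const int nsurf = (int)scell.size();
  const int nrec = nsteps / stride;
  NumericMatrix p_surf(nrec, nsurf), v_surf(nrec, nsurf);
  std::vector<double> vprev(nsurf, 0.0);

  const int nprob = probes.nrow();
  NumericMatrix probe_p(nsteps, std::max(nprob, 0));
  std::vector<int> pcell(nprob);
  for (int q = 0; q < nprob; ++q)
    pcell[q] = cidx(probes(q, 0), probes(q, 1), probes(q, 2), nx, ny);
  NumericVector energy(record_energy ? nsteps : 0);

  const int src = cidx(src_cell[0], src_cell[1], src_cell[2], nx, ny);
  if (!air[src]) stop("placement error: source cell is inside the solid");

  double maxp = 0.0;
  for (int n = 0; n < nsteps; ++n) {
    // record p^n (and probes) at time n*dt
    if (n % stride == 0) {
      int m = n / stride;
      for (int q = 0; q < nsurf; ++q)
        p_surf(m, q) = 0.5 * (p[scell[q]] + p[souter[q]]);
    }
    for (int q = 0; q < nprob; ++q) probe_p(n, q) = p[pcell[q]];

    // velocity update: v^{n-1/2} -> v^{n+1/2}
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        long row = (long)(nx + 1) * (j + (long)ny * k);
        long crow = (long)nx * (j + (long)ny * k);
        for (int i = 1; i < nx; ++i) {
          long f = row + i, c0 = crow + i - 1, c1 = crow + i;
          if (air[c0] && air[c1])
            vx[f] = avx[i] * vx[f] - bvx[i] * (p[c1] - p[c0]);
          else if (air[c0])
            vx[f] = imp_a * vx[f] + imp_b * p[c0];
          else if (air[c1])
            vx[f] = imp_a * vx[f] - imp_b * p[c1];
        }
      }
    for (int k = 0; k < nz; ++k)
      for (int j = 1; j < ny; ++j) {
        long frow = (long)nx * (j + (long)(ny + 1) * k);
        long c0r = (long)nx * ((j - 1) + (long)ny * k);
        long c1r = (long)nx * (j + (long)ny * k);
        for (int i = 0; i < nx; ++i) {
          long f = frow + i, c0 = c0r + i, c1 = c1r + i;
          if (air[c0] && air[c1])
            vy[f] = avy[j] * vy[f] - bvy[j] * (p[c1] - p[c0]);
          else if (air[c0])
            vy[f] = imp_a * vy[f] + imp_b * p[c0];
          else if (air[c1])
            vy[f] = imp_a * vy[f] - imp_b * p[c1];
        }
      }
    for (int k = 1; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        long frow = (long)nx * (j + (long)ny * k);
        long c0r = (long)nx * (j + (long)ny * (k - 1));
        long c1r = frow;
        for (int i = 0; i < nx; ++i) {
          long f = frow + i, c0 = c0r + i, c1 = c1r + i;
          if (air[c0] && air[c1])
            vz[f] = avz[k] * vz[f] - bvz[k] * (p[c1] - p[c0]);
          else if (air[c0])
            vz[f] = imp_a * vz[f] + imp_b * p[c0];
          else if (air[c1])
            vz[f] = imp_a * vz[f] - imp_b * p[c1];
        }
      }

    // record time-centered normal velocity at n*dt
    if (n % stride == 0) {
      int m = n / stride;
      for (int q = 0; q < nsurf; ++q) {
        double vn;
        if (sdir[q] == 0) vn = vx[sface[q]];
        else if (sdir[q] == 1) vn = vy[sface[q]];
        else vn = vz[sface[q]];
        vn *= ssgn[q];
        v_surf(m, q) = 0.5 * (vn + vprev[q]);
        vprev[q] = vn;
      }
    } else {
      for (int q = 0; q < nsurf; ++q) {
        double vn;
        if (sdir[q] == 0) vn = vx[sface[q]];
        else if (sdir[q] == 1) vn = vy[sface[q]];
        else vn = vz[sface[q]];
        vprev[q] = vn * ssgn[q];
      }
    }

    // pressure update (air cells only), then soft source
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        long crow = (long)nx * (j + (long)ny * k);
        long fxr = (long)(nx + 1) * (j + (long)ny * k);
        long fyr0 = (long)nx * (j + (long)(ny + 1) * k);
        long fyr1 = (long)nx * ((j + 1) + (long)(ny + 1) * k);
        long fzr0 = (long)nx * (j + (long)ny * k);
        long fzr1 = (long)nx * (j + (long)ny * (k + 1));
        for (int i = 0; i < nx; ++i) {
          long cc = crow + i;
          if (!air[cc]) continue;
          px[cc] = apx[i] * px[cc] - bpx[i] * (vx[fxr + i + 1] - vx[fxr + i]);
          py[cc] = apy[j] * py[cc] - bpy[j] * (vy[fyr1 + i] - vy[fyr0 + i]);
          pz[cc] = apz[k] * pz[cc] - bpz[k] * (vz[fzr1 + i] - vz[fzr0 + i]);
          p[cc] = px[cc] + py[cc] + pz[cc];
        }
      }
    px[src] += src_wave[n];
    p[src] = px[src] + py[src] + pz[src];
    if (std::abs(p[src]) > maxp) maxp = std::abs(p[src]);

    if (record_energy) {
      double e = 0.0;
      for (long q = 0; q < ncell; ++q)
        if (air[q]) e += p[q] * p[q] / (2 * rho * c * c);
      for (size_t q = 0; q < vx.size(); ++q) e += rho * vx[q] * vx[q] / 2;
      for (size_t q = 0; q < vy.size(); ++q) e += rho * vy[q] * vy[q] / 2;
      for (size_t q = 0; q < vz.size(); ++q) e += rho * vz[q] * vz[q] / 2;
      energy[n] = e * h * h * h;
    }
    if (n % 200 == 0) {
      double m2 = 0.0;
      for (long q = 0; q < ncell; q += 97) m2 = std::max(m2, std::abs(p[q]));
      if (!std::isfinite(m2) || m2 > 1e12 * (maxp + 1e-300))
        stop("stability error: field diverged (CFL or boundary instability)");
    }
  }

  NumericMatrix pos(nsurf, 3), nrm(nsurf, 3);
  for (int q = 0; q < nsurf; ++q) {
    pos(q, 0) = spx[q]; pos(q, 1) = spy[q]; pos(q, 2) = spz[q];
    nrm(q, 0) = sdir[q] == 0 ? ssgn[q] : 0.0;
    nrm(q, 1) = sdir[q] == 1 ? ssgn[q] : 0.0;
    nrm(q, 2) = sdir[q] == 2 ? ssgn[q] : 0.0;
  }
  return List::create(_["p_surf"] = p_surf, _["v_surf"] = v_surf,
                      _["pos_idx"] = pos, _["normal"] = nrm,
                      _["probe_p"] = probe_p, _["energy"] = energy,
                      _["nrec"] = nrec);
}

// Kirchhoff-Helmholtz farfield: exterior pressure from surface pressure
// and outward normal velocity spectra. Convention: spectra follow the
// e^{+i omega t} sign (R's fft of real time series), so the free-space
// Green's function is G = e^{-ikR} / (4 pi R) and dp/dn = -i omega rho vn.
// Frequencies must be uniformly spaced: k = k0 + b * dk.
// [[Rcpp::export]]
ComplexMatrix kh_farfield_cpp(ComplexMatrix Psurf, ComplexMatrix Vsurf,
                              NumericMatrix pos, NumericMatrix nrm,
                              double area, double k0, double dk,
                              double rho, double c,
                              NumericMatrix fieldpts) {
  const int nb = Psurf.nrow(), ncell = Psurf.ncol(), nd = fieldpts.nrow();
  ComplexMatrix out(nb, nd);
  std::vector<std::complex<double> > Pv((long)nb * ncell), Vv((long)nb * ncell);
  for (int q = 0; q < ncell; ++q)
    for (int b = 0; b < nb; ++b) {
      Rcomplex pc = Psurf(b, q), vc = Vsurf(b, q);
      Pv[(long)q * nb + b] = std::complex<double>(pc.r, pc.i);
      Vv[(long)q * nb + b] = std::complex<double>(vc.r, vc.i);
    }
  std::vector<std::complex<double> > acc(nb);
  for (int d = 0; d < nd; ++d) {
    const double fx = fieldpts(d, 0), fy = fieldpts(d, 1), fz = fieldpts(d, 2);
    std::fill(acc.begin(), acc.end(), std::complex<double>(0, 0));
    for (int q = 0; q < ncell; ++q) {
      const double dx = pos(q, 0) - fx, dy = pos(q, 1) - fy,
                   dz = pos(q, 2) - fz;
      const double R = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double dot = (dx * nrm(q, 0) + dy * nrm(q, 1) + dz * nrm(q, 2)) / R;
      const double g0 = area / (4 * M_PI * R);
      // phase recurrence over uniform k grid
      std::complex<double> ph = std::exp(std::complex<double>(0, -k0 * R));
      const std::complex<double> step =
          std::exp(std::complex<double>(0, -dk * R));
      const std::complex<double> *Pq = &Pv[(long)q * nb];
      const std::complex<double> *Vq = &Vv[(long)q * nb];
      for (int b = 0; b < nb; ++b) {
        const double k = k0 + b * dk;
        const std::complex<double> G = g0 * ph;
        const std::complex<double> dGdn =
            std::complex<double>(-1.0 / R, -k) * G * dot;
        const std::complex<double> iwr(0.0, (k * c) * rho);
        acc[b] += Pq[b] * dGdn + iwr * Vq[b] * G;
        ph *= step;
      }
    }
    for (int b = 0; b < nb; ++b) {
      out(b, d).r = acc[b].real();
      out(b, d).i = acc[b].imag();
    }
  }
  return out;
}
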