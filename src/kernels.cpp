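// Compiled kernels for the coupled intravascular/tissue oxygen solver.
//
// The network sweep advances intravascular PO2 segment by segment in
// decreasing-pressure (topological) order: junction mixing by bisection on
// the oxygen mass balance, then implicit-Euler integration of the axial
// advection equation with transvascular losses, accumulating the line-source
// weights for the tissue system on the fly. The tissue solver is a
// Jacobi-preconditioned conjugate gradient acting on the implicit 7-point
// Neumann Laplacian plus a diagonal (linearized consumption + exchange).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double hillS(double P, double n, double PS50) {
  if (P <= 0.0) return 0.0;
  double t = std::pow(P / PS50, n);
  return t / (1.0 + t);
}

// total blood O2 content per unit volume: alpha_p P + H c0 S(P)
static inline double bloodC(double P, double H, double n, double PS50,
                            double alpha_p, double c0) {
  return alpha_p * P + H * c0 * hillS(P, n, PS50);
}

// solve  qa*P + qh*c0*S(P) = iota  for P >= 0 (monotone; bisection)
static double junctionP(double iota, double qa, double qh, double n,
                        double PS50, double c0, double Pmax, double tol) {
  double lo = 0.0, hi = std::max(Pmax, 1e-6);
  // expand hi if necessary (iota may slightly exceed content at Pmax)
  for (int k = 0; k < 60; ++k) {
    double g = qa * hi + qh * c0 * hillS(hi, n, PS50) - iota;
    if (g >= 0.0) break;
    hi *= 2.0;
  }
  for (int k = 0; k < 200; ++k) {
    double mid = 0.5 * (lo + hi);
    double g = qa * mid + qh * c0 * hillS(mid, n, PS50) - iota;
    if (g > 0.0) hi = mid; else lo = mid;
    if (hi - lo < tol) break;
  }
  return 0.5 * (lo + hi);
}

struct Grid {
  int nx, ny, nz;
  double h;
  const double *Pt;
  long idx(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }
};

// trilinear interpolation of Pt at point (x,y,z); also used to scatter
// weights onto the 8 surrounding sites
static void corner_weights(const Grid &g, double x, double y, double z,
                           long cell[8], double w[8]) {
  double fx = x / g.h, fy = y / g.h, fz = z / g.h;
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
      k0 = (int)std::floor(fz);
  if (i0 < 0 || j0 < 0 || k0 < 0 || i0 > g.nx - 1 || j0 > g.ny - 1 ||
      k0 > g.nz - 1)
    stop("integration point outside tissue grid");
  if (i0 > g.nx - 2) i0 = g.nx - 2;
  if (j0 > g.ny - 2) j0 = g.ny - 2;
  if (k0 > g.nz - 2) k0 = g.nz - 2;
  double ax = fx - i0, ay = fy - j0, az = fz - k0;
  ax = std::min(std::max(ax, 0.0), 1.0);
  ay = std::min(std::max(ay, 0.0), 1.0);
  az = std::min(std::max(az, 0.0), 1.0);
  int c = 0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        cell[c] = g.idx(i0 + di, j0 + dj, k0 + dk);
        w[c] = (di ? ax : 1 - ax) * (dj ? ay : 1 - ay) * (dk ? az : 1 - az);
        ++c;
      }
}

static inline double interpPt(const Grid &g, double x, double y, double z) {
  long cell[8]; double w[8];
  corner_weights(g, x, y, z, cell, w);
  double v = 0.0;
  for (int c = 0; c < 8; ++c) v += w[c] * g.Pt[cell[c]];
  return v;
}

// implicit Euler step on the conservative form:
//   q c(P1) + A (P1 - Pt1) = q c(P0),  A = dx 2 pi r gamma
// monotone in P1; Newton with bisection safeguard
static double euler_step(double P0, double Pt1, double A, double q, double H,
                         double n, double PS50, double alpha_p, double c0) {
  double rhs = q * bloodC(P0, H, n, PS50, alpha_p, c0) + A * Pt1;
  double lo = std::min(P0, Pt1), hi = std::max(P0, Pt1);
  double P = P0;
  for (int it = 0; it < 100; ++it) {
    double S = hillS(P, n, PS50);
    double g = q * (alpha_p * P + H * c0 * S) + A * P - rhs;
    if (std::fabs(g) < 1e-12 * std::max(rhs, 1.0)) break;
    if (g > 0) hi = P; else lo = P;
    double dS = 0.0;
    if (P > 0) {
      double t = std::pow(P / PS50, n);
      dS = n * t / (P * (1.0 + t) * (1.0 + t));
    }
    double gp = q * (alpha_p + H * c0 * dS) + A;
    double Pn = P - g / gp;
    if (Pn <= lo || Pn >= hi) Pn = 0.5 * (lo + hi);
    if (std::fabs(Pn - P) < 1e-9) { P = Pn; break; }
    P = Pn;
  }
  return std::max(P, 0.0);
}

// [[Rcpp::export]]
List cpp_vessel_sweep(IntegerVector ia, IntegerVector ib,
                      NumericVector nodex, NumericVector nodey,
                      NumericVector nodez, NumericVector pressure,
                      IntegerVector role, NumericVector inletP,
                      NumericVector r, NumericVector l, NumericVector H,
                      NumericVector q, NumericVector gamma,
                      IntegerVector dims, double h, NumericVector Pt,
                      double n_hill, double PS50, double alpha_p, double c0,
                      double h_v, double qtol, double H_bc) {
  const int m = ia.size();
  const int nn = pressure.size();
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2]; g.h = h;
  g.Pt = REAL(Pt);
  long nsites = (long)g.nx * g.ny * g.nz;

  NumericVector QA(nsites), QB(nsites);
  NumericVector P_up(m, NA_REAL), P_down(m, NA_REAL), Sbar(m), Pbar(m),
      exch(m);

  // incidence lists
  std::vector<std::vector<int> > inc(nn);
  for (int s = 0; s < m; ++s) {
    inc[ia[s]].push_back(s);
    inc[ib[s]].push_back(s);
  }
  // node processing order: decreasing pressure
  std::vector<int> ord(nn);
  for (int i = 0; i < nn; ++i) ord[i] = i;
  const double *pr = REAL(pressure);
  std::sort(ord.begin(), ord.end(),
            [pr](int a, int b) { return pr[a] > pr[b]; });

  double influx = 0.0, outflux = 0.0;
  std::vector<char> done(m, 0);

  // handle unperfused segments: equilibrate with tissue, record exchange wts
  for (int s = 0; s < m; ++s) {
    if (std::fabs(q[s]) > qtol) continue;
    done[s] = 1;
    int np = (int)std::ceil(l[s] / h_v) + 1;
    if (np < 2) np = 2;
    double dx = l[s] / (np - 1);
    double ax = nodex[ia[s]], ay = nodey[ia[s]], az = nodez[ia[s]];
    double ux = (nodex[ib[s]] - ax) / l[s], uy = (nodey[ib[s]] - ay) / l[s],
           uz = (nodez[ib[s]] - az) / l[s];
    double ssum = 0.0, psum = 0.0, wsum = 0.0;
    for (int k = 0; k < np; ++k) {
      double wlen = (k == 0 || k == np - 1) ? dx / 2.0 : dx;
      double x = ax + ux * dx * k, y = ay + uy * dx * k, z = az + uz * dx * k;
      long cell[8]; double w[8];
      corner_weights(g, x, y, z, cell, w);
      double pt = 0.0;
      for (int c = 0; c < 8; ++c) pt += w[c] * g.Pt[cell[c]];
      double coef = wlen * 2.0 * M_PI * r[s] * gamma[s];
      for (int c = 0; c < 8; ++c) {
        QA[cell[c]] += coef * pt * w[c];
        QB[cell[c]] += coef * w[c];
      }
      ssum += wlen * hillS(pt, n_hill, PS50);
      psum += wlen * pt;
      wsum += wlen;
      if (k == 0) P_up[s] = pt;
      if (k == np - 1) P_down[s] = pt;
    }
    Sbar[s] = ssum / wsum;
    Pbar[s] = psum / wsum;
    exch[s] = 0.0;
  }

  for (int oi = 0; oi < nn; ++oi) {
    int u = ord[oi];
    const std::vector<int> &segs = inc[u];
    if (segs.empty()) continue;
    // classify
    double iota = 0.0, qout_a = 0.0, qout_h = 0.0, Pmax = 0.0;
    bool have_in = false, have_out = false;
    for (size_t t = 0; t < segs.size(); ++t) {
      int s = segs[t];
      if (done[s] && std::fabs(q[s]) <= qtol) continue;
      double qs = (ia[s] == u) ? q[s] : -q[s]; // positive: leaves u
      if (qs > qtol) {
        have_out = true;
        qout_a += qs;
        qout_h += qs * H[s];
      } else if (qs < -qtol) {
        have_in = true;
      }
    }
    if (!have_out) continue;
    double Pjunc;
    if (!have_in) {
      Pjunc = inletP[u];   // source node (root)
    } else {
      double qin_tot = 0.0, rbc_in = 0.0;
      for (size_t t = 0; t < segs.size(); ++t) {
        int s = segs[t];
        double qs = (ia[s] == u) ? q[s] : -q[s];
        if (qs < -qtol) {
          double Pd = P_down[s];
          if (ISNA(Pd)) stop("sweep order violated: inflow not yet integrated");
          iota += (-qs) * bloodC(Pd, H[s], n_hill, PS50, alpha_p, c0);
          qin_tot += -qs;
          rbc_in += (-qs) * H[s];
          if (Pd > Pmax) Pmax = Pd;
        }
      }
      // at root nodes blood also enters/leaves the domain; close the
      // balance with that external stream so the junction pressure stays
      // the mixture equilibrium
      if (role[u] != 0) {
        double drain = qin_tot - qout_a;
        if (drain > qtol) {
          qout_a += drain;
          qout_h += drain * (rbc_in / qin_tot);
        } else if (drain < -qtol) {
          iota += (-drain) * bloodC(inletP[u], H_bc, n_hill, PS50, alpha_p,
                                    c0);
          if (inletP[u] > Pmax) Pmax = inletP[u];
        }
      }
      Pjunc = junctionP(iota, qout_a * alpha_p, qout_h, n_hill, PS50, c0,
                        Pmax, 1e-8);
    }
    // integrate each outflow segment
    for (size_t t = 0; t < segs.size(); ++t) {
      int s = segs[t];
      double qs = (ia[s] == u) ? q[s] : -q[s];
      if (qs <= qtol) continue;
      done[s] = 1;
      P_up[s] = Pjunc;
      int np = (int)std::ceil(l[s] / h_v) + 1;
      if (np < 2) np = 2;
      double dx = l[s] / (np - 1);
      // direction: from u to the other end
      int vfrom = u, vto = (ia[s] == u) ? ib[s] : ia[s];
      double ax = nodex[vfrom], ay = nodey[vfrom], az = nodez[vfrom];
      double ux = (nodex[vto] - ax) / l[s], uy = (nodey[vto] - ay) / l[s],
             uz = (nodez[vto] - az) / l[s];
      double coef_full = 2.0 * M_PI * r[s] * gamma[s];
      double P = Pjunc;
      double ssum = 0.0, psum = 0.0, wsum = 0.0, ex = 0.0;
      for (int k = 0; k < np; ++k) {
        double x = ax + ux * dx * k, y = ay + uy * dx * k,
               z = az + uz * dx * k;
        long cell[8]; double w[8];
        corner_weights(g, x, y, z, cell, w);
        double pt = 0.0;
        for (int c = 0; c < 8; ++c) pt += w[c] * g.Pt[cell[c]];
        if (k > 0)
          P = euler_step(P, pt, dx * coef_full, qs, H[s], n_hill, PS50,
                         alpha_p, c0);
        double wlen = (k == 0 || k == np - 1) ? dx / 2.0 : dx;
        double coef = wlen * coef_full;
        for (int c = 0; c < 8; ++c) {
          QA[cell[c]] += coef * P * w[c];
          QB[cell[c]] += coef * w[c];
        }
        ex += coef * (P - pt);
        ssum += wlen * hillS(P, n_hill, PS50);
        psum += wlen * P;
        wsum += wlen;
      }
      P_down[s] = P;
      Sbar[s] = ssum / wsum;
      Pbar[s] = psum / wsum;
      exch[s] = ex;
      // root flux bookkeeping
      if (role[vfrom] != 0) influx += qs * bloodC(Pjunc, H[s], n_hill, PS50,
                                                  alpha_p, c0);
      if (role[vto] != 0) outflux += qs * bloodC(P, H[s], n_hill, PS50,
                                                 alpha_p, c0);
    }
  }

  return List::create(_["P_up"] = P_up, _["P_down"] = P_down,
                      _["Sbar"] = Sbar, _["Pbar"] = Pbar, _["QA"] = QA,
                      _["QB"] = QB, _["influx"] = influx,
                      _["outflux"] = outflux, _["exchange"] = exch);
}

// [[Rcpp::export]]
List cpp_tissue_cg(IntegerVector dims, double kappa, NumericVector diag,
                   NumericVector rhs, NumericVector x0, double tol,
                   int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  std::vector<double> x(REAL(x0), REAL(x0) + n), rr(n), p(n), z(n), Ap(n);
  const double *b = REAL(rhs);
  const double *dg = REAL(diag);

  auto matvec = [&](const std::vector<double> &v, std::vector<double> &out) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long id = (long)i + (long)nx * ((long)j + (long)ny * k);
          double c = dg[id] * v[id];
          double vi = v[id];
          if (i > 0) c += kappa * (vi - v[id - 1]);
          if (i < nx - 1) c += kappa * (vi - v[id + 1]);
          if (j > 0) c += kappa * (vi - v[id - nx]);
          if (j < ny - 1) c += kappa * (vi - v[id + nx]);
          if (k > 0) c += kappa * (vi - v[id - (long)nx * ny]);
          if (k < nz - 1) c += kappa * (vi - v[id + (long)nx * ny]);
          out[id] = c;
        }
  };

  std::vector<double> pc(n);
  for (long i = 0; i < n; ++i) {
    int ii = i % nx, jj = (i / nx) % ny, kk = i / ((long)nx * ny);
    int nb = (ii > 0) + (ii < nx - 1) + (jj > 0) + (jj < ny - 1) + (kk > 0) +
             (kk < nz - 1);
    double d = dg[i] + nb * kappa;
    pc[i] = (d > 0) ? 1.0 / d : 1.0;
  }

  matvec(x, Ap);
  double bnorm = 0.0;
  for (long i = 0; i < n; ++i) {
    rr[i] = b[i] - Ap[i];
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  double rz = 0.0;
  for (long i = 0; i < n; ++i) {
    z[i] = pc[i] * rr[i];
    p[i] = z[i];
    rz += rr[i] * z[i];
  }
  int it = 0;
  double relres = 0.0;
  for (it = 0; it < maxit; ++it) {
    double rn = 0.0;
    for (long i = 0; i < n; ++i) rn += rr[i] * rr[i];
    relres = std::sqrt(rn) / bnorm;
    if (relres < tol) break;
    matvec(p, Ap);
    double pAp = 0.0;
    for (long i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    for (long i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      rr[i] -= alpha * Ap[i];
    }
    double rznew = 0.0;
    for (long i = 0; i < n; ++i) {
      z[i] = pc[i] * rr[i];
      rznew += rr[i] * z[i];
    }
    double beta = rznew / rz;
    rz = rznew;
    for (long i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it, _["relres"] = relres);
}
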