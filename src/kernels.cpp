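#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// e^2 / (4 pi eps0) in kJ mol^-1 Angstrom e^-2; must match R/constants.R
static const double KE = 1389.35457644382;

// Mark grid nodes lying strictly inside any atom sphere (van der Waals
// dielectric boundary).  Column-major indexing: i + nx*(j + ny*k).
// [[Rcpp::export]]
LogicalVector grid_inside_mask_cpp(IntegerVector dims, NumericVector origin,
                                   double h, NumericMatrix coords,
                                   NumericVector radii) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector inside(static_cast<R_xlen_t>(nx) * ny * nz, false);
  const int na = coords.nrow();
  for (int a = 0; a < na; ++a) {
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    const double r = radii[a], r2 = r * r;
    int i0 = std::max(0, (int)std::ceil((cx - r - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::floor((cx + r - origin[0]) / h));
    int j0 = std::max(0, (int)std::ceil((cy - r - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::floor((cy + r - origin[1]) / h));
    int k0 = std::max(0, (int)std::ceil((cz - r - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::floor((cz + r - origin[2]) / h));
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * h - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * h - cy;
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * h - cx;
          if (dx * dx + dyz < r2)
            inside[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
        }
      }
    }
  }
  return inside;
}

// Analytic Coulomb potential of the source charges on the six box faces,
// screened by a uniform dielectric: Dirichlet boundary condition.
// phi is modified in place (interior untouched).
// [[Rcpp::export]]
void boundary_coulomb_cpp(NumericVector phi, IntegerVector dims,
                          NumericVector origin, double h,
                          NumericMatrix coords, NumericVector q,
                          double eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = coords.nrow();
  auto pot = [&](double x, double y, double z) {
    double s = 0.0;
    for (int a = 0; a < na; ++a) {
      if (q[a] == 0.0) continue;
      const double dx = x - coords(a, 0), dy = y - coords(a, 1),
                   dz = z - coords(a, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-6) r = 1e-6;
      s += KE * q[a] / (eps * r);
    }
    return s;
  };
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      phi[idx(0, j, k)] = pot(origin[0], origin[1] + j * h, origin[2] + k * h);
      phi[idx(nx - 1, j, k)] =
          pot(origin[0] + (nx - 1) * h, origin[1] + j * h, origin[2] + k * h);
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      phi[idx(i, 0, k)] = pot(origin[0] + i * h, origin[1], origin[2] + k * h);
      phi[idx(i, ny - 1, k)] =
          pot(origin[0] + i * h, origin[1] + (ny - 1) * h, origin[2] + k * h);
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      phi[idx(i, j, 0)] = pot(origin[0] + i * h, origin[1] + j * h, origin[2]);
      phi[idx(i, j, nz - 1)] =
          pot(origin[0] + i * h, origin[1] + j * h, origin[2] + (nz - 1) * h);
    }
}

// Analytic Coulomb potential of the sources on every grid node (uniform
// dielectric): used as the SOR initial guess.
// [[Rcpp::export]]
NumericVector coulomb_field_cpp(IntegerVector dims, NumericVector origin,
                                double h, NumericMatrix coords,
                                NumericVector q, double eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi((R_xlen_t)nx * ny * nz);
  const int na = coords.nrow();
  for (int k = 0; k < nz; ++k) {
    const double z = origin[2] + k * h;
    for (int j = 0; j < ny; ++j) {
      const double y = origin[1] + j * h;
      R_xlen_t t = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i, ++t) {
        const double x = origin[0] + i * h;
        double s = 0.0;
        for (int a = 0; a < na; ++a) {
          if (q[a] == 0.0) continue;
          const double dx = x - coords(a, 0), dy = y - coords(a, 1),
                       dz = z - coords(a, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < 0.5 * h) r = 0.5 * h;
          s += KE * q[a] / (eps * r);
        }
        phi[t] = s;
      }
    }
  }
  return phi;
}

// Successive over-relaxation for div(eps grad phi) = -4 pi ke rho on a
// uniform grid with Dirichlet boundaries already written into phi.
// eps_node holds the node dielectric; face values are harmonic means of the
// two adjacent nodes.  rho holds the charge (in e) assigned to each node.
// [[Rcpp::export]]
List sor_poisson_cpp(IntegerVector dims, NumericVector eps_node,
                     NumericVector rho, NumericVector phi_init, double h,
                     double omega, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector phi = clone(phi_init);
  const double fourpik = 4.0 * M_PI * KE;
  // source term b = 4 pi ke q / h (phi equation is divided by h^2)
  std::vector<double> b(n, 0.0);
  double bnorm2 = 0.0;
  for (R_xlen_t t = 0; t < n; ++t) {
    b[t] = fourpik * rho[t] / h;
    bnorm2 += b[t] * b[t];
  }
  const double bnorm = std::sqrt(bnorm2);
  const double denom = bnorm > 0.0 ? bnorm : 1.0;
  auto hmean = [](double a, double c) { return 2.0 * a * c / (a + c); };
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  double resid = R_PosInf;
  int it = 0;
  bool conv = false;
  for (it = 1; it <= maxit; ++it) {
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j) {
        R_xlen_t t0 = sy * j + sz * k;
        for (int i = 1; i < nx - 1; ++i) {
          const R_xlen_t t = t0 + i;
          const double e0 = eps_node[t];
          const double exm = hmean(e0, eps_node[t - sx]),
                       exp_ = hmean(e0, eps_node[t + sx]),
                       eym = hmean(e0, eps_node[t - sy]),
                       eyp = hmean(e0, eps_node[t + sy]),
                       ezm = hmean(e0, eps_node[t - sz]),
                       ezp = hmean(e0, eps_node[t + sz]);
          const double esum = exm + exp_ + eym + eyp + ezm + ezp;
          const double nbr = exm * phi[t - sx] + exp_ * phi[t + sx] +
                             eym * phi[t - sy] + eyp * phi[t + sy] +
                             ezm * phi[t - sz] + ezp * phi[t + sz];
          const double phinew = (nbr + b[t]) / esum;
          phi[t] += omega * (phinew - phi[t]);
        }
      }
    if (it % 10 == 0 || it == maxit) {
      double r2 = 0.0;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j) {
          R_xlen_t t0 = sy * j + sz * k;
          for (int i = 1; i < nx - 1; ++i) {
            const R_xlen_t t = t0 + i;
            const double e0 = eps_node[t];
            const double exm = hmean(e0, eps_node[t - sx]),
                         exp_ = hmean(e0, eps_node[t + sx]),
                         eym = hmean(e0, eps_node[t - sy]),
                         eyp = hmean(e0, eps_node[t + sy]),
                         ezm = hmean(e0, eps_node[t - sz]),
                         ezp = hmean(e0, eps_node[t + sz]);
            const double r = exm * phi[t - sx] + exp_ * phi[t + sx] +
                             eym * phi[t - sy] + eyp * phi[t + sy] +
                             ezm * phi[t - sz] + ezp * phi[t + sz] -
                             (exm + exp_ + eym + eyp + ezm + ezp) * phi[t] +
                             b[t];
            r2 += r * r;
          }
        }
      resid = std::sqrt(r2) / denom;
      if (resid < tol) {
        conv = true;
        break;
      }
    }
  }
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["residual"] = resid, _["converged"] = conv);
}

// Shrake-Rupley exposed area per atom: count quadrature points on the
// expanded sphere (r_i + probe) not covered by any neighbour's expanded
// sphere.  pts holds unit vectors (n_points x 3), identical for all atoms.
// [[Rcpp::export]]
NumericVector sasa_per_atom_cpp(NumericMatrix coords, NumericVector radii,
                                double probe, NumericMatrix pts) {
  const int na = coords.nrow(), np = pts.nrow();
  NumericVector area(na);
  std::vector<int> nbr;
  for (int a = 0; a < na; ++a) {
    const double ra = radii[a] + probe;
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    nbr.clear();
    for (int bj = 0; bj < na; ++bj) {
      if (bj == a) continue;
      const double cut = radii[a] + radii[bj] + 2.0 * probe;
      const double dx = coords(bj, 0) - cx, dy = coords(bj, 1) - cy,
                   dz = coords(bj, 2) - cz;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(bj);
    }
    int nexp = 0;
    for (int p = 0; p < np; ++p) {
      const double px = cx + ra * pts(p, 0), py = cy + ra * pts(p, 1),
                   pz = cz + ra * pts(p, 2);
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int bj = nbr[m];
        const double rb = radii[bj] + probe;
        const double dx = px - coords(bj, 0), dy = py - coords(bj, 1),
                     dz = pz - coords(bj, 2);
        if (dx * dx + dy * dy + dz * dz < rb * rb) {
          buried = true;
          break;
        }
      }
      if (!buried) ++nexp;
    }
    area[a] = 4.0 * M_PI * ra * ra * (double)nexp / (double)np;
  }
  return area;
}

// Minimum distance between two point sets (clash / contact detection).
// [[Rcpp::export]]
double min_cross_dist_cpp(NumericMatrix a, NumericMatrix b) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      const double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
                   dz = a(i, 2) - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
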