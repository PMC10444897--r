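#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Node flags (kept in sync with R/lattice.R)
static const int F_FLUID = 0, F_WALL = 1, F_INLET = 2, F_OUTLET = 3;

// Fused BGK collide + partial-bounce-back streaming + boundary kernel.
//
// Streaming rule (gray nodes): the population leaving node x in direction i
// is the blend (1-g) f*_i(x) + g f_opp(i)(x); populations aimed at flagged
// wall nodes are reflected at the source (half-way bounce-back).  Fixed
// density inlet/outlet planes are closed by the equilibrium distribution
// at the set density with the velocity taken from the adjacent bulk node.
//
// All index arguments are 0-based.  rho_in/rho_out of 0 disable the
// pressure boundaries (flags then contain no inlet/outlet nodes).
// The core is templated on the stencil size so that the inner loops
// unroll for the two lattices actually used (D2Q9, D3Q19); QT/DT of 0
// select the generic runtime-sized path.
template <int QT, int DT>
List lb_run_impl(NumericMatrix f_in, IntegerMatrix nbr, IntegerVector flags,
                 NumericVector gamma, IntegerMatrix cvel, NumericVector w,
                 IntegerVector opp, double cs2, double tau,
                 NumericVector gforce, double rho_in, double rho_out,
                 int max_steps, int check_every, double tol) {
  const int n = f_in.nrow();
  const int q = QT ? QT : f_in.ncol();
  const int dim = DT ? DT : cvel.ncol();
  std::vector<double> fa(f_in.begin(), f_in.end());
  std::vector<double> fb(fa), fs(fa);
  // flat copies of the index/stencil tables: the Rcpp matrix accessors
  // are too slow for the inner loops
  std::vector<int> nb_t(nbr.begin(), nbr.end());          // n x q, col-major
  std::vector<int> cv(static_cast<size_t>(q) * dim);      // q x dim, row-major
  for (int i = 0; i < q; ++i)
    for (int d = 0; d < dim; ++d) cv[i * dim + d] = cvel(i, d);
  std::vector<double> wv(w.begin(), w.end());
  std::vector<int> oppv(opp.begin(), opp.end());
  std::vector<int> flv(flags.begin(), flags.end());
  std::vector<double> gav(gamma.begin(), gamma.end());
  // column-major like R: population (x, i) at index x + n*i
  std::vector<double> Fi(q, 0.0);
  bool has_force = false;
  for (int i = 0; i < q; ++i) {
    double cg = 0.0;
    for (int d = 0; d < dim; ++d) cg += cv[i * dim + d] * gforce[d];
    Fi[i] = wv[i] * cg / cs2;
    if (Fi[i] != 0.0) has_force = true;
  }
  // direction indices along +x / -x for the boundary closure
  int dir_px = -1, dir_mx = -1;
  for (int i = 0; i < q; ++i) {
    bool px = cv[i * dim] == 1, mx = cv[i * dim] == -1;
    for (int d = 1; d < dim; ++d) { px = px && cv[i * dim + d] == 0; mx = mx && cv[i * dim + d] == 0; }
    if (px) dir_px = i;
    if (mx) dir_mx = i;
  }
  std::vector<double> uprev(static_cast<size_t>(n) * dim, 0.0),
      ucur(static_cast<size_t>(n) * dim, 0.0);
  double sflow_prev = NA_REAL;
  std::vector<double> feq(q), feq_nb(q);

  auto macro_u = [&](const std::vector<double> &fv, std::vector<double> &u) {
    for (int x = 0; x < n; ++x) {
      if (flv[x] == F_WALL) {
        for (int d = 0; d < dim; ++d) u[x + static_cast<size_t>(n) * d] = 0.0;
        continue;
      }
      double rho = 0.0;
      double mom[3] = {0.0, 0.0, 0.0};
      for (int i = 0; i < q; ++i) {
        const double fi = fv[x + static_cast<size_t>(n) * i];
        rho += fi;
        for (int d = 0; d < dim; ++d) mom[d] += cv[i * dim + d] * fi;
      }
      const double fac = (1.0 - gav[x]) / rho;
      for (int d = 0; d < dim; ++d) u[x + static_cast<size_t>(n) * d] = fac * mom[d];
    }
  };
  macro_u(fa, uprev);

  auto equil = [&](double rho, const double *u, std::vector<double> &out) {
    double usq = 0.0;
    for (int d = 0; d < dim; ++d) usq += u[d] * u[d];
    for (int i = 0; i < q; ++i) {
      double cu = 0.0;
      for (int d = 0; d < dim; ++d) cu += cv[i * dim + d] * u[d];
      out[i] = wv[i] * rho *
               (1.0 + cu / cs2 + cu * cu / (2.0 * cs2 * cs2) - usq / (2.0 * cs2));
    }
  };

  int steps_done = 0;
  bool converged = false, diverged = false;
  double max_u = 0.0;

  for (int step = 0; step < max_steps; ++step) {
    // --- collide ---
    for (int x = 0; x < n; ++x) {
      if (flv[x] == F_WALL) {
        for (int i = 0; i < q; ++i) fs[x + static_cast<size_t>(n) * i] = fa[x + static_cast<size_t>(n) * i];
        continue;
      }
      double rho = 0.0;
      double mom[3] = {0.0, 0.0, 0.0};
      for (int i = 0; i < q; ++i) {
        const double fi = fa[x + static_cast<size_t>(n) * i];
        rho += fi;
        for (int d = 0; d < dim; ++d) mom[d] += cv[i * dim + d] * fi;
      }
      double u[3] = {0.0, 0.0, 0.0};
      for (int d = 0; d < dim; ++d) u[d] = mom[d] / rho;
      equil(rho, u, feq);
      for (int i = 0; i < q; ++i) {
        const size_t k = x + static_cast<size_t>(n) * i;
        fs[k] = fa[k] - (fa[k] - feq[i]) / tau;
        if (has_force) fs[k] += Fi[i];
      }
    }
    // --- stream with PBB and wall bounce-back ---
    for (int x = 0; x < n; ++x)
      if (flv[x] == F_WALL)
        for (int i = 0; i < q; ++i)
          fb[x + static_cast<size_t>(n) * i] = fa[x + static_cast<size_t>(n) * i];
    for (int x = 0; x < n; ++x) {
      if (flv[x] == F_WALL) continue;
      const double g = gav[x];
      for (int i = 0; i < q; ++i) {
        const int dest = nb_t[x + static_cast<size_t>(n) * i];
        const double out = (1.0 - g) * fs[x + static_cast<size_t>(n) * i] +
                           g * fa[x + static_cast<size_t>(n) * oppv[i]];
        if (flv[dest] == F_WALL)
          fb[x + static_cast<size_t>(n) * oppv[i]] = fs[x + static_cast<size_t>(n) * i];
        else
          fb[dest + static_cast<size_t>(n) * i] = out;
      }
    }
    // --- fixed-density boundaries ---
    // Equilibrium closure at the imposed density with the velocity
    // extrapolated from the adjacent bulk node.  Deliberately diffusive:
    // it absorbs the acoustic modes that a non-equilibrium-extrapolation
    // closure reflects, which keeps gray (partial-bounce-back) domains
    // stable for relaxation times just above 1/2.
    if (rho_in > 0.0 || rho_out > 0.0) {
      for (int x = 0; x < n; ++x) {
        if (flv[x] != F_INLET && flv[x] != F_OUTLET) continue;
        const double rho_bc = (flv[x] == F_INLET) ? rho_in : rho_out;
        const int nb = nb_t[x + static_cast<size_t>(n) *
                            ((flv[x] == F_INLET) ? dir_px : dir_mx)];
        double rho_nb = 0.0;
        double mom[3] = {0.0, 0.0, 0.0};
        for (int i = 0; i < q; ++i) {
          const double fi = fb[nb + static_cast<size_t>(n) * i];
          rho_nb += fi;
          for (int d = 0; d < dim; ++d) mom[d] += cv[i * dim + d] * fi;
        }
        double u_nb[3] = {0.0, 0.0, 0.0};
        for (int d = 0; d < dim; ++d) u_nb[d] = mom[d] / rho_nb;
        equil(rho_bc, u_nb, feq);
        for (int i = 0; i < q; ++i)
          fb[x + static_cast<size_t>(n) * i] = feq[i];
      }
    }
    fa.swap(fb);
    ++steps_done;
    // --- stability / convergence checks ---
    if ((step + 1) % check_every == 0 || step + 1 == max_steps) {
      macro_u(fa, ucur);
      // Steadiness is judged on two scales: the L2 norm of the velocity
      // change (a pointwise max bottoms out at round-off on these
      // near-stagnant porous flows) and the net axial flow, which is the
      // quantity the quasi-steady coupling consumes.
      double d2 = 0.0, u2 = 0.0, umax = 0.0, sflow = 0.0;
      bool bad = false;
      for (size_t k = 0; k < ucur.size(); ++k) {
        if (!std::isfinite(ucur[k])) { bad = true; break; }
        const double a = std::fabs(ucur[k]);
        if (a > umax) umax = a;
        u2 += ucur[k] * ucur[k];
        const double d = ucur[k] - uprev[k];
        d2 += d * d;
      }
      for (int x = 0; x < n; ++x) sflow += ucur[x];  // axial component
      max_u = umax;
      if (bad || umax > 0.3) { diverged = true; break; }
      const bool l2_ok =
          std::sqrt(d2) / std::max(std::sqrt(u2), 1e-300) < tol;
      const bool flow_ok =
          std::isfinite(sflow_prev) &&
          std::fabs(sflow - sflow_prev) /
                  std::max(std::fabs(sflow), 1e-300) < tol;
      if (tol > 0.0 && (l2_ok || flow_ok)) {
        converged = true;
        break;
      }
      sflow_prev = sflow;
      uprev = ucur;
    }
  }
  if (tol == 0.0 && !diverged) converged = true;

  NumericMatrix f_out(n, q);
  std::copy(fa.begin(), fa.end(), f_out.begin());
  return List::create(_["f"] = f_out, _["steps"] = steps_done,
                      _["converged"] = converged, _["diverged"] = diverged,
                      _["max_u_lu"] = max_u);
}

// [[Rcpp::export]]
List cpp_lb_run(NumericMatrix f_in, IntegerMatrix nbr, IntegerVector flags,
                NumericVector gamma, IntegerMatrix cvel, NumericVector w,
                IntegerVector opp, double cs2, double tau,
                NumericVector gforce, double rho_in, double rho_out,
                int max_steps, int check_every, double tol) {
  const int q = f_in.ncol(), dim = cvel.ncol();
  if (q == 9 && dim == 2)
    return lb_run_impl<9, 2>(f_in, nbr, flags, gamma, cvel, w, opp, cs2,
                             tau, gforce, rho_in, rho_out, max_steps,
                             check_every, tol);
  if (q == 19 && dim == 3)
    return lb_run_impl<19, 3>(f_in, nbr, flags, gamma, cvel, w, opp, cs2,
                              tau, gforce, rho_in, rho_out, max_steps,
                              check_every, tol);
  return lb_run_impl<0, 0>(f_in, nbr, flags, gamma, cvel, w, opp, cs2,
                           tau, gforce, rho_in, rho_out, max_steps,
                           check_every, tol);
}

// Explicit conservative finite-volume step for the anti-fibrin agent on a
// 2D grid: first-order upwind advection plus central diffusion, with
// front-blocking (blocked cells receive incoming fluxes but emit none).
// Cells are indexed x + nx*y (0-based), x = flow axis.  Wall cells carry
// no concentration and exchange no flux.  Outlet cells lose mass through
// their +x face by upwind outflow; returns that mass (in concentration *
// cell-volume units) as `mass_out`.
// [[Rcpp::export]]
List cpp_transport_step(NumericVector Fbar_in, LogicalVector blocked,
                        NumericVector ux, NumericVector uy,
                        NumericVector udepx, NumericVector udepy,
                        IntegerVector flags, int nx, int ny,
                        double dx, double dt, double D, int nsub = 1,
                        Nullable<IntegerVector> inlet_cells = R_NilValue,
                        double Fbar0 = 0.0) {
  const int n = nx * ny;
  NumericVector Fbar(clone(Fbar_in));
  std::vector<double> dF(n, 0.0);
  double mass_out = 0.0;
  std::vector<int> inlet;
  if (inlet_cells.isNotNull()) {
    IntegerVector ic(inlet_cells);
    inlet.assign(ic.begin(), ic.end());   // 0-based
  }
  const double dts = dt / nsub;
  const double r = dts / dx;

  auto face_flux = [&](int a, int b, double ua_n, double ub_n,
                       double dep_a, double dep_b) {
    // flux density (concentration * velocity) from a to b (signed), with
    // ua_n/ub_n the two cells' velocity components normal to the face
    // and dep_a/dep_b their deposition intake velocities.  Deposition
    // onto a blocked (intact-fibrin) voxel uses that voxel's intake
    // velocity - its local Darcy velocity reconstructed from voxel
    // permeability and pressure gradient - because the porous slab
    // controls its intake and the sub-voxel wall boundary layer of the
    // lattice flow field would otherwise imprint spurious transverse
    // structure on the supply.
    const double uface = 0.5 * (ua_n + ub_n);
    double adv = 0.0;
    if (uface > 0.0) {
      if (!blocked[a])
        adv = (blocked[b] ? std::max(dep_b, 0.0) : uface) * Fbar[a];
    } else if (uface < 0.0) {
      if (!blocked[b])
        adv = (blocked[a] ? std::min(dep_a, 0.0) : uface) * Fbar[b];
    }
    double dif = -D * (Fbar[b] - Fbar[a]) / dx;
    // diffusive donor is the higher-concentration side
    if (dif > 0.0) { if (blocked[a]) dif = 0.0; }
    else if (dif < 0.0) { if (blocked[b]) dif = 0.0; }
    return adv + dif;
  };

  for (int sub = 0; sub < nsub; ++sub) {
    for (size_t k0 = 0; k0 < inlet.size(); ++k0) Fbar[inlet[k0]] = Fbar0;
    std::fill(dF.begin(), dF.end(), 0.0);
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int a = x + nx * y;
        if (flags[a] == F_WALL) continue;
        // +x face
        if (x + 1 < nx) {
          const int b = a + 1;
          if (flags[b] != F_WALL) {
            const double phi = face_flux(a, b, ux[a], ux[b], udepx[a], udepx[b]);
            dF[a] -= phi;
            dF[b] += phi;
          }
        } else {
          // outlet face: free advective outflow with the cell's own velocity
          if (ux[a] > 0.0 && !blocked[a]) {
            const double phi = ux[a] * Fbar[a];
            dF[a] -= phi;
            mass_out += phi * r * dx * dx;
          }
        }
        // +y face
        if (y + 1 < ny) {
          const int b = a + nx;
          if (flags[b] != F_WALL) {
            const double phi = face_flux(a, b, uy[a], uy[b], udepy[a], udepy[b]);
            dF[a] -= phi;
            dF[b] += phi;
          }
        }
      }
    }
    for (int k = 0; k < n; ++k) {
      if (flags[k] == F_WALL) continue;
      Fbar[k] = Fbar[k] + r * dF[k];
      if (Fbar[k] < 0.0) Fbar[k] = 0.0;
    }
    for (size_t k0 = 0; k0 < inlet.size(); ++k0) Fbar[inlet[k0]] = Fbar0;
  }
  return List::create(_["Fbar"] = Fbar, _["mass_out"] = mass_out);
}
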