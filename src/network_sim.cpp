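#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped, athermal dynamics of a cross-linked fiber network.
//
// Forces: harmonic stretching of each segment about its rest length,
// harmonic bending of each adjacent segment pair about its rest angle,
// and stiff harmonic couplings for cross-links. Cross-links rupture
// irreversibly when the transmitted coupling force exceeds f_break.
// Free nodes follow drag * dx/dt = F; clamped nodes are frozen; nodes on
// the moving face follow the prescribed axial velocity.
//
// Boundary realization: the confining walls are rigid and frictionless,
// so a wall constrains only its normal coordinate (frozen[i][d] = 1);
// nodes on the moving face follow the prescribed axial velocity in z and
// are free (or wall-constrained) laterally. Segment/bend/crosslink
// indices are 0-based.

static inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
List network_simulate_cpp(NumericMatrix nodes0,
                          IntegerMatrix seg_ij, NumericVector seg_l0,
                          NumericVector seg_ks,
                          IntegerMatrix bend_ijk, NumericVector bend_theta0,
                          double k_bend,
                          IntegerMatrix xl_ij, NumericVector xl_rest,
                          double xl_stiff, double f_break,
                          IntegerMatrix frozen,      // n x 3, 1 = frozen
                          LogicalVector moving,      // z follows vz_schedule
                          double drag, double dt, int n_steps,
                          NumericVector vz_schedule,   // moving-face z velocity per step
                          int record_every,
                          double face_area,
                          bool save_positions) {
  const int n = nodes0.nrow();
  const int ns = seg_ij.nrow();
  const int nb = bend_ijk.nrow();
  const int nx = xl_ij.nrow();

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = nodes0(i, d);
  std::vector<double> f(3 * n, 0.0);
  std::vector<int> intact(nx, 1);

  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_stress(n_rec), rec_us(n_rec), rec_ub(n_rec);
  IntegerVector rec_nxl(n_rec), rec_rupt(n_rec);
  NumericVector final_pos(3 * n);
  NumericVector rec_pos;
  if (save_positions) rec_pos = NumericVector(static_cast<R_xlen_t>(n_rec) * 3 * n);

  int ruptures_since_rec = 0;
  bool unstable = false;
  int irec = 0;
  double energy_scale = 0.0;  // for blow-up detection
  for (int s = 0; s < ns; ++s)
    energy_scale += 0.5 * seg_ks[s] * seg_l0[s] * seg_l0[s];

  for (int step = 0; step <= n_steps; ++step) {
    std::fill(f.begin(), f.end(), 0.0);
    double us = 0.0, ub = 0.0, fz_moving = 0.0;

    // stretching
    for (int s = 0; s < ns; ++s) {
      int i = seg_ij(s, 0), j = seg_ij(s, 1);
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      double l = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (l < 1e-30) continue;
      double ext = l - seg_l0[s];
      double fm = seg_ks[s] * ext / l;  // tension > 0 pulls ends together
      us += 0.5 * seg_ks[s] * ext * ext;
      f[3 * i] += fm * dx; f[3 * i + 1] += fm * dy; f[3 * i + 2] += fm * dz;
      f[3 * j] -= fm * dx; f[3 * j + 1] -= fm * dy; f[3 * j + 2] -= fm * dz;
    }

    // bending: harmonic in the angle between consecutive segment vectors,
    // implemented as interior angle phi at the middle node with rest pi -
    // theta0 (straight chain: theta0 = 0 -> phi0 = pi)
    for (int b = 0; b < nb; ++b) {
      int ia = bend_ijk(b, 0), ib = bend_ijk(b, 1), ic = bend_ijk(b, 2);
      double r1x = x[3 * ia] - x[3 * ib];
      double r1y = x[3 * ia + 1] - x[3 * ib + 1];
      double r1z = x[3 * ia + 2] - x[3 * ib + 2];
      double r2x = x[3 * ic] - x[3 * ib];
      double r2y = x[3 * ic + 1] - x[3 * ib + 1];
      double r2z = x[3 * ic + 2] - x[3 * ib + 2];
      double r1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      double r2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
      if (r1 < 1e-30 || r2 < 1e-30) continue;
      double c = (r1x * r2x + r1y * r2y + r1z * r2z) / (r1 * r2);
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      double phi = std::acos(c);
      double theta = M_PI - phi;  // bend angle (0 when straight)
      double dtheta = theta - bend_theta0[b];
      ub += 0.5 * k_bend * dtheta * dtheta;
      double s2 = 1.0 - c * c;
      double sphi = s2 > 1e-16 ? std::sqrt(s2) : 1e-8;
      // dU/dphi = -k_bend * dtheta (theta = pi - phi)
      double coef = -k_bend * dtheta;
      // grad_a phi = -(rhat2 - c*rhat1) / (r1*sin phi)
      double gax = -((r2x / r2) - c * (r1x / r1)) / (r1 * sphi);
      double gay = -((r2y / r2) - c * (r1y / r1)) / (r1 * sphi);
      double gaz = -((r2z / r2) - c * (r1z / r1)) / (r1 * sphi);
      double gcx = -((r1x / r1) - c * (r2x / r2)) / (r2 * sphi);
      double gcy = -((r1y / r1) - c * (r2y / r2)) / (r2 * sphi);
      double gcz = -((r1z / r1) - c * (r2z / r2)) / (r2 * sphi);
      double fax = -coef * gax, fay = -coef * gay, faz = -coef * gaz;
      double fcx = -coef * gcx, fcy = -coef * gcy, fcz = -coef * gcz;
      f[3 * ia] += fax; f[3 * ia + 1] += fay; f[3 * ia + 2] += faz;
      f[3 * ic] += fcx; f[3 * ic + 1] += fcy; f[3 * ic + 2] += fcz;
      f[3 * ib] -= fax + fcx;
      f[3 * ib + 1] -= fay + fcy;
      f[3 * ib + 2] -= faz + fcz;
    }

    // cross-links: stiff springs; rupture check on the transmitted force
    for (int q = 0; q < nx; ++q) {
      if (!intact[q]) continue;
      int i = xl_ij(q, 0), j = xl_ij(q, 1);
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      double l = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ext = l - xl_rest[q];
      double fmag = xl_stiff * std::fabs(ext);
      if (fmag > f_break) {       // bond ceases to exist, irreversibly
        intact[q] = 0;
        ++ruptures_since_rec;
        continue;
      }
      if (l < 1e-30) continue;
      double fm = xl_stiff * ext / l;
      f[3 * i] += fm * dx; f[3 * i + 1] += fm * dy; f[3 * i + 2] += fm * dz;
      f[3 * j] -= fm * dx; f[3 * j + 1] -= fm * dy; f[3 * j + 2] -= fm * dz;
    }

    // boundary stress: net axial elastic force transmitted to the moving
    // face divided by its area; compression gives positive stress
    for (int i = 0; i < n; ++i)
      if (moving[i]) fz_moving += f[3 * i + 2];
    double stress = face_area > 0 ? fz_moving / face_area : 0.0;

    if (step % record_every == 0) {
      rec_t[irec] = step * dt;
      rec_stress[irec] = stress;
      rec_us[irec] = us;
      rec_ub[irec] = ub;
      int cnt = 0;
      for (int q = 0; q < nx; ++q) cnt += intact[q];
      rec_nxl[irec] = cnt;
      rec_rupt[irec] = ruptures_since_rec;
      ruptures_since_rec = 0;
      if (save_positions) {
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            rec_pos[static_cast<R_xlen_t>(irec) * 3 * n + 3 * i + d] =
              x[3 * i + d];
      }
      ++irec;
      if (!std::isfinite(us) || !std::isfinite(ub) ||
          (energy_scale > 0 && us + ub > 1e3 * energy_scale)) {
        unstable = true;
        break;
      }
    }
    if (step == n_steps) break;

    // Euler update
    double vz = vz_schedule[step];
    for (int i = 0; i < n; ++i) {
      if (!frozen(i, 0)) x[3 * i] += dt * f[3 * i] / drag;
      if (!frozen(i, 1)) x[3 * i + 1] += dt * f[3 * i + 1] / drag;
      if (moving[i]) {
        x[3 * i + 2] += dt * vz;
      } else if (!frozen(i, 2)) {
        x[3 * i + 2] += dt * f[3 * i + 2] / drag;
      }
    }
  }

  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) final_pos[3 * i + d] = x[3 * i + d];

  LogicalVector intact_out(nx);
  for (int q = 0; q < nx; ++q) intact_out[q] = intact[q] == 1;

  List out = List::create(
    _["time"] = rec_t[Range(0, irec - 1)],
    _["stress"] = rec_stress[Range(0, irec - 1)],
    _["U_s"] = rec_us[Range(0, irec - 1)],
    _["U_b"] = rec_ub[Range(0, irec - 1)],
    _["n_xl"] = rec_nxl[Range(0, irec - 1)],
    _["ruptures"] = rec_rupt[Range(0, irec - 1)],
    _["final_positions"] = final_pos,
    _["intact"] = intact_out,
    _["unstable"] = unstable,
    _["n_recorded"] = irec
  );
  if (save_positions) {
    out["positions"] = rec_pos;
  }
  return out;
}

// Static force evaluation at given positions (used for force-balance audits
// and analytic toy checks from R).
// [[Rcpp::export]]
List network_forces_cpp(NumericMatrix nodes,
                        IntegerMatrix seg_ij, NumericVector seg_l0,
                        NumericVector seg_ks,
                        IntegerMatrix bend_ijk, NumericVector bend_theta0,
                        double k_bend,
                        IntegerMatrix xl_ij, NumericVector xl_rest,
                        double xl_stiff, LogicalVector intact) {
  const int n = nodes.nrow();
  NumericMatrix f(n, 3);
  double us = 0.0, ub = 0.0;
  NumericVector xlf(xl_ij.nrow());

  for (int s = 0; s < seg_ij.nrow(); ++s) {
    int i = seg_ij(s, 0), j = seg_ij(s, 1);
    double dx = nodes(j, 0) - nodes(i, 0);
    double dy = nodes(j, 1) - nodes(i, 1);
    double dz = nodes(j, 2) - nodes(i, 2);
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (l < 1e-30) continue;
    double ext = l - seg_l0[s];
    double fm = seg_ks[s] * ext / l;
    us += 0.5 * seg_ks[s] * ext * ext;
    f(i, 0) += fm * dx; f(i, 1) += fm * dy; f(i, 2) += fm * dz;
    f(j, 0) -= fm * dx; f(j, 1) -= fm * dy; f(j, 2) -= fm * dz;
  }
  for (int b = 0; b < bend_ijk.nrow(); ++b) {
    int ia = bend_ijk(b, 0), ib = bend_ijk(b, 1), ic = bend_ijk(b, 2);
    double r1x = nodes(ia, 0) - nodes(ib, 0);
    double r1y = nodes(ia, 1) - nodes(ib, 1);
    double r1z = nodes(ia, 2) - nodes(ib, 2);
    double r2x = nodes(ic, 0) - nodes(ib, 0);
    double r2y = nodes(ic, 1) - nodes(ib, 1);
    double r2z = nodes(ic, 2) - nodes(ib, 2);
    double r1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
    double r2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
    if (r1 < 1e-30 || r2 < 1e-30) continue;
    double c = (r1x * r2x + r1y * r2y + r1z * r2z) / (r1 * r2);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double phi = std::acos(c);
    double theta = M_PI - phi;
    double dtheta = theta - bend_theta0[b];
    ub += 0.5 * k_bend * dtheta * dtheta;
    double s2 = 1.0 - c * c;
    double sphi = s2 > 1e-16 ? std::sqrt(s2) : 1e-8;
    double coef = -k_bend * dtheta;
    double gax = -((r2x / r2) - c * (r1x / r1)) / (r1 * sphi);
    double gay = -((r2y / r2) - c * (r1y / r1)) / (r1 * sphi);
    double gaz = -((r2z / r2) - c * (r1z / r1)) / (r1 * sphi);
    double gcx = -((r1x / r1) - c * (r2x / r2)) / (r2 * sphi);
    double gcy = -((r1y / r1) - c * (r2y / r2)) / (r2 * sphi);
    double gcz = -((r1z / r1) - c * (r2z / r2)) / (r2 * sphi);
    f(ia, 0) -= coef * gax; f(ia, 1) -= coef * gay; f(ia, 2) -= coef * gaz;
    f(ic, 0) -= coef * gcx; f(ic, 1) -= coef * gcy; f(ic, 2) -= coef * gcz;
    f(ib, 0) += coef * (gax + gcx);
    f(ib, 1) += coef * (gay + gcy);
    f(ib, 2) += coef * (gaz + gcz);
  }
  for (int q = 0; q < xl_ij.nrow(); ++q) {
    if (!intact[q]) { xlf[q] = NA_REAL; continue; }
    int i = xl_ij(q, 0), j = xl_ij(q, 1);
    double dx = nodes(j, 0) - nodes(i, 0);
    double dy = nodes(j, 1) - nodes(i, 1);
    double dz = nodes(j, 2) - nodes(i, 2);
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ext = l - xl_rest[q];
    xlf[q] = xl_stiff * std::fabs(ext);
    if (l < 1e-30) continue;
    double fm = xl_stiff * ext / l;
    f(i, 0) += fm * dx; f(i, 1) += fm * dy; f(i, 2) += fm * dz;
    f(j, 0) -= fm * dx; f(j, 1) -= fm * dy; f(j, 2) -= fm * dz;
  }
  return List::create(_["forces"] = f, _["U_s"] = us, _["U_b"] = ub,
                      _["xl_force"] = xlf);
}

#include <unordered_map>
#include <set>

// Cross-link candidate detection: sample points along segments are binned
// into a uniform grid of cell size d_xl; any pair of sample points from
// different fibers closer than d_xl proposes a cross-link between the
// nearest discretization nodes of the two fibers. Returns a deduplicated
// node-pair list.
// [[Rcpp::export]]
IntegerMatrix crosslink_candidates_cpp(NumericMatrix pts,
                                       IntegerVector fiber_id,
                                       IntegerVector nearest_node,
                                       double d_xl) {
  const int m = pts.nrow();
  const double cell = d_xl;
  std::unordered_map<long long, std::vector<int> > grid;
  auto key = [cell](double x, double y, double z) {
    long long ix = (long long)std::floor(x / cell);
    long long iy = (long long)std::floor(y / cell);
    long long iz = (long long)std::floor(z / cell);
    return (ix * 73856093LL) ^ (iy * 19349663LL) ^ (iz * 83492791LL);
  };
  for (int i = 0; i < m; ++i)
    grid[key(pts(i, 0), pts(i, 1), pts(i, 2))].push_back(i);

  std::set<std::pair<int, int> > pairs;
  const double d2 = d_xl * d_xl;
  for (int i = 0; i < m; ++i) {
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          long long k = key(pts(i, 0) + ox * cell, pts(i, 1) + oy * cell,
                            pts(i, 2) + oz * cell);
          auto it = grid.find(k);
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            if (fiber_id[i] == fiber_id[j]) continue;
            double dx = pts(i, 0) - pts(j, 0);
            double dy = pts(i, 1) - pts(j, 1);
            double dz = pts(i, 2) - pts(j, 2);
            if (dx * dx + dy * dy + dz * dz >= d2) continue;
            int a = nearest_node[i], b = nearest_node[j];
            if (a == b) continue;
            pairs.insert(a < b ? std::make_pair(a, b)
                               : std::make_pair(b, a));
          }
        }
  }
  IntegerMatrix out(pairs.size(), 2);
  int r = 0;
  for (const auto& p : pairs) {
    out(r, 0) = p.first;
    out(r, 1) = p.second;
    ++r;
  }
  return out;
}
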