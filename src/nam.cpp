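#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Brownian-dynamics propagation for the Northrup-Allison-McCammon rate
// calculation. Substrates are launched uniformly on the b-sphere around the
// geometry centroid, propagated by free-draining BD (drift D*F*dt with F in
// kT/nm, Gaussian noise of variance 2*D*dt per coordinate), and terminated
// on reaction (within r_react of the active-site bead center) or escape
// (beyond the q-sphere). Far from the interaction envelope the time step is
// enlarged so that four standard deviations of the free displacement stay
// within the gap to the envelope; inside interaction range the fixed base
// step dt is used. Uses R's RNG, so results are reproducible via set.seed().
//
// [[Rcpp::export(name = ".nam_run")]]
List nam_run(NumericMatrix centers, int active_site, double bead_radius,
             double substrate_radius, double eps_lj,
             double b, double q, double r_react, double D, double dt,
             int n_traj, NumericMatrix core_centers, double core_radius) {
  const int nb = centers.nrow();
  std::vector<double> cx(nb), cy(nb), cz(nb);
  double rmax = 0.0;
  for (int i = 0; i < nb; ++i) {
    cx[i] = centers(i, 0); cy[i] = centers(i, 1); cz[i] = centers(i, 2);
    double r = std::sqrt(cx[i] * cx[i] + cy[i] * cy[i] + cz[i] * cz[i]);
    if (r > rmax) rmax = r;
  }
  const int ia = active_site - 1;
  const double ax = cx[ia], ay = cy[ia], az = cz[ia];
  const double sigma = bead_radius + substrate_radius;
  // repulsive (WCA) branch only: cut at the potential minimum 2^(1/6) sigma
  const double rc = std::pow(2.0, 1.0 / 6.0) * sigma;
  const double rc2 = rc * rc;
  const double r_react2 = r_react * r_react;
  const double q2 = q * q;
  // interaction envelope: beyond it no bead exerts force (rc = 0 when the
  // substrate does not interact at all)
  const double rc_eff = (eps_lj > 0.0) ? rc : 0.0;
  const double R_env = rmax + rc_eff;
  const double sd0 = std::sqrt(2.0 * D * dt);

  const int n_core = core_centers.nrow();
  long n_react = 0;
  double min_gap = std::numeric_limits<double>::infinity();                // min substrate-bead distance seen
  RNGScope scope;

  for (int t = 0; t < n_traj; ++t) {
    // uniform point on the b-sphere via a normalised Gaussian vector
    double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
    double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
    while (gn < 1e-12) {
      gx = norm_rand(); gy = norm_rand(); gz = norm_rand();
      gn = std::sqrt(gx * gx + gy * gy + gz * gz);
    }
    double x = b * gx / gn, y = b * gy / gn, z = b * gz / gn;

    for (;;) {
      const double r2 = x * x + y * y + z * z;
      if (r2 >= q2) break;                 // escape
      const double dxa = x - ax, dya = y - ay, dza = z - az;
      const double da2 = dxa * dxa + dya * dya + dza * dza;
      if (da2 <= r_react2) {               // capture
        ++n_react;
        break;
      }
      // gap: distance the substrate can safely cover without touching the
      // reaction surface or the near field of any bead. The fixed base
      // step is enforced only within 2 sigma of a bead, where the LJ force
      // is appreciable; between 2 and 3 sigma the force is still applied
      // but is far too weak to constrain the step.
      const double gap_react = std::sqrt(da2) - r_react;
      double gap = gap_react;
      double fx = 0.0, fy = 0.0, fz = 0.0;
      bool near_wall = false;
      const double r = std::sqrt(r2);
      if (r > R_env) {
        if (r - R_env < gap) gap = r - R_env;
      } else {
        double dnear2 = std::numeric_limits<double>::infinity();
        for (int i = 0; i < nb; ++i) {
          const double dx = x - cx[i], dy = y - cy[i], dz = z - cz[i];
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < dnear2) dnear2 = d2;
          if (d2 < rc2 && eps_lj > 0.0) {
            const double s2 = sigma * sigma / d2;
            const double s6 = s2 * s2 * s2;
            const double s12 = s6 * s6;
            const double coef = 4.0 * eps_lj * (12.0 * s12 - 6.0 * s6) / d2;
            fx += coef * dx; fy += coef * dy; fz += coef * dz;
          }
        }
        const double dnear = std::sqrt(dnear2);
        if (dnear < min_gap) min_gap = dnear;
        const double r_wall = (eps_lj > 0.0) ? rc : 0.0;
        near_wall = eps_lj > 0.0 && dnear < r_wall;
        if (dnear - r_wall < gap) gap = dnear - r_wall;
      }
      double step_dt = dt, sd = sd0;
      if (gap > 4.0 * sd0) {               // enlarge the step far away
        sd = gap / 4.0;
        step_dt = sd * sd / (2.0 * D);
      } else if (!near_wall) {
        // refine toward the absorbing reaction surface (keeps the
        // first-passage discretisation bias small); no refinement below
        // the base step when only the soft wall limits the move
        sd = gap / 4.0;
        const double floor_sd = (gap_react <= gap + 1e-12) ? sd0 / 8.0 : sd0;
        if (sd < floor_sd) sd = floor_sd;
        step_dt = sd * sd / (2.0 * D);
      }
      // cap the drift displacement: deep inside the 1/r^12 wall the force
      // would otherwise catapult the substrate across the bead shell in a
      // single step (a rare-noise instability, not physical dynamics)
      double ddx = D * fx * step_dt, ddy = D * fy * step_dt,
             ddz = D * fz * step_dt;
      const double dn2 = ddx * ddx + ddy * ddy + ddz * ddz;
      const double dmax = 2.0 * sd0;
      if (dn2 > dmax * dmax) {
        const double sc = dmax / std::sqrt(dn2);
        ddx *= sc; ddy *= sc; ddz *= sc;
      }
      x += ddx + sd * norm_rand();
      y += ddy + sd * norm_rand();
      z += ddz + sd * norm_rand();
      // the enzyme interior is impenetrable: reflect off the core
      // sphere(s) so the substrate cannot tunnel between beads into the
      // hollow of the shell (where it would be unphysically trapped)
      for (int m = 0; m < n_core; ++m) {
        const double ex = x - core_centers(m, 0);
        const double ey = y - core_centers(m, 1);
        const double ez = z - core_centers(m, 2);
        const double ed = std::sqrt(ex * ex + ey * ey + ez * ez);
        if (ed < core_radius && ed > 1e-12) {
          const double sc = (2.0 * core_radius - ed) / ed;
          x = core_centers(m, 0) + ex * sc;
          y = core_centers(m, 1) + ey * sc;
          z = core_centers(m, 2) + ez * sc;
        }
      }
    }
  }
  return List::create(_["n_react"] = (double)n_react,
                      _["n_traj"] = (double)n_traj,
                      _["min_bead_gap"] = min_gap);
}

// energy/force of the repulsive (WCA) branch of the 12-6 potential;
// mirrors the R reference implementation, used by the consistency tests
// [[Rcpp::export(name = ".lj_cpp")]]
List lj_cpp(NumericVector pos, NumericMatrix centers, double bead_radius,
            double substrate_radius, double eps_lj) {
  const double sigma = bead_radius + substrate_radius;
  const double rcut = std::pow(2.0, 1.0 / 6.0) * sigma;
  const double rc2 = rcut * rcut;
  const double shift = -eps_lj;
  double U = 0.0, fx = 0.0, fy = 0.0, fz = 0.0;
  for (int i = 0; i < centers.nrow(); ++i) {
    const double dx = pos[0] - centers(i, 0);
    const double dy = pos[1] - centers(i, 1);
    const double dz = pos[2] - centers(i, 2);
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 == 0.0) stop("substrate overlaps a bead center exactly");
    if (d2 < rc2) {
      const double s2 = sigma * sigma / d2;
      const double s6 = s2 * s2 * s2;
      const double s12 = s6 * s6;
      U += 4.0 * eps_lj * (s12 - s6) - shift;
      const double coef = 4.0 * eps_lj * (12.0 * s12 - 6.0 * s6) / d2;
      fx += coef * dx; fy += coef * dy; fz += coef * dz;
    }
  }
  return List::create(_["U"] = U,
                      _["F"] = NumericVector::create(fx, fy, fz));
}
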