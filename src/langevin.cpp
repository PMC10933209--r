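#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Overdamped Langevin dynamics of N rigid molecules (1 or 3 beads each) in a
// periodic box, reduced units: sigma = 1, kT = 1. Pair potential between beads
// of different molecules is a WCA decomposition of Lennard-Jones:
//   core:       WCA repulsion of fixed strength eps_core (default 1 kT),
//               cut at r_min = 2^(1/6)
//   attraction: LJ tail of well depth eps for r_min <= r < 2.5, truncated and
//               shifted to vanish at the 2.5 cutoff; constant (-eps) inside
//               r_min, hence force-free there
// so eps = 0 leaves a purely repulsive core and eps is the exact well depth.
//
// Update per step: x += (F/g) dt + N(0, sqrt(2 dt / g)) with g the molecular
// translational friction; trimers additionally rotate about their centre from
// the pair torque plus rotational noise. Uses R's RNG, so runs are exactly
// reproducible from set.seed().

static const double RMIN = 1.122462048309373;  // 2^(1/6)
static const double RCUT = 2.5;
static const double RCAP = 0.9;  // force-cap radius: U(0.9) ~ 18 kT per kT of core

// force magnitude dU/dr * (-1) decomposed as described; returns dF such that
// force on i is dF * (xi - xj) (i.e. dF = -(dU/dr)/r). Below RCAP the core
// force is held at its RCAP value (standard Brownian-dynamics force capping:
// the region is thermally unreachable, but capping keeps the explicit Euler
// update stable should a fluctuation land there).
static double core_force_mag(double r, double eps_core) {
  double sr6 = 1.0 / (r * r * r * r * r * r);
  double sr12 = sr6 * sr6;
  return 24.0 * eps_core * (2.0 * sr12 - sr6) / r;
}

static double pair_fcoef(double r2, double eps, double eps_core) {
  double inv2 = 1.0 / r2;
  double sr6 = inv2 * inv2 * inv2;
  double sr12 = sr6 * sr6;
  double f = 0.0;
  if (r2 < RCAP * RCAP) {
    double r = std::sqrt(r2);
    f += core_force_mag(RCAP, eps_core) / r;            // capped core
  } else if (r2 < RMIN * RMIN) {
    f += 24.0 * eps_core * (2.0 * sr12 - sr6) * inv2;   // WCA core
  } else if (eps > 0.0 && r2 < RCUT * RCUT) {
    f += 24.0 * eps * (2.0 * sr12 - sr6) * inv2;        // attractive tail
  }
  return f;
}

// [[Rcpp::export]]
List simulate_langevin_cpp(NumericMatrix centers0, NumericMatrix orient0,
                           int beads_per_mol, NumericVector box_lengths,
                           double eps, double eps_core, double dt,
                           int n_steps, int save_every, double gamma_bead) {
  int nmol = centers0.nrow();
  if (beads_per_mol != 1 && beads_per_mol != 3)
    stop("beads_per_mol must be 1 or 3");
  double L[3] = { box_lengths[0], box_lengths[1], box_lengths[2] };
  double g_t = gamma_bead * beads_per_mol;     // translational friction
  double g_r = 2.0 * gamma_bead;               // rotational friction (trimer)
  double sd_t = std::sqrt(2.0 * dt / g_t);
  double sd_r = std::sqrt(2.0 * dt / g_r);

  std::vector<double> x(nmol * 3), u(nmol * 3);
  for (int i = 0; i < nmol; ++i)
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = centers0(i, k);
      u[3 * i + k] = orient0(i, k);
    }

  int n_frames = n_steps / save_every + 1;
  int nbead = nmol * beads_per_mol;
  NumericVector traj(Dimension(nbead, 3, n_frames));
  IntegerVector steps_saved(n_frames);

  std::vector<double> bx(nbead * 3), F(nbead * 3);
  double max_disp = 0.0;
  bool unstable = false;
  int frame = 0;

  for (int step = 0; step <= n_steps; ++step) {
    // bead positions from centres + orientation
    for (int i = 0; i < nmol; ++i) {
      for (int b = 0; b < beads_per_mol; ++b) {
        double off = (beads_per_mol == 1) ? 0.0 : (double)(b - 1);
        for (int k = 0; k < 3; ++k)
          bx[3 * (i * beads_per_mol + b) + k] =
            x[3 * i + k] + off * u[3 * i + k];
      }
    }
    // save frame (wrapped into the primary cell)
    if (step % save_every == 0) {
      for (int a = 0; a < nbead; ++a)
        for (int k = 0; k < 3; ++k) {
          double v = bx[3 * a + k];
          v -= L[k] * std::floor(v / L[k]);
          traj[frame * nbead * 3 + k * nbead + a] = v;
        }
      steps_saved[frame] = step;
      ++frame;
    }
    if (step == n_steps) break;

    // pair forces between beads of different molecules (minimum image)
    std::fill(F.begin(), F.end(), 0.0);
    for (int a = 0; a < nbead; ++a) {
      int ma = a / beads_per_mol;
      for (int b = a + 1; b < nbead; ++b) {
        if (b / beads_per_mol == ma) continue;
        double d[3];
        double r2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double dk = bx[3 * a + k] - bx[3 * b + k];
          dk -= L[k] * std::nearbyint(dk / L[k]);
          d[k] = dk;
          r2 += dk * dk;
        }
        if (r2 >= RCUT * RCUT || r2 < 1e-12) continue;
        double fc = pair_fcoef(r2, eps, eps_core);
        for (int k = 0; k < 3; ++k) {
          F[3 * a + k] += fc * d[k];
          F[3 * b + k] -= fc * d[k];
        }
      }
    }

    // propagate centres (+ orientations for trimers)
    for (int i = 0; i < nmol; ++i) {
      double Fc[3] = { 0.0, 0.0, 0.0 }, tq[3] = { 0.0, 0.0, 0.0 };
      for (int b = 0; b < beads_per_mol; ++b) {
        int a = i * beads_per_mol + b;
        double off = (beads_per_mol == 1) ? 0.0 : (double)(b - 1);
        for (int k = 0; k < 3; ++k) Fc[k] += F[3 * a + k];
        if (beads_per_mol == 3) {
          double r[3] = { off * u[3 * i + 0], off * u[3 * i + 1],
                          off * u[3 * i + 2] };
          tq[0] += r[1] * F[3 * a + 2] - r[2] * F[3 * a + 1];
          tq[1] += r[2] * F[3 * a + 0] - r[0] * F[3 * a + 2];
          tq[2] += r[0] * F[3 * a + 1] - r[1] * F[3 * a + 0];
        }
      }
      double dx[3];
      for (int k = 0; k < 3; ++k) {
        dx[k] = (Fc[k] / g_t) * dt + sd_t * norm_rand();
        x[3 * i + k] += dx[k];
        // keep centres in the primary cell; forces use minimum image anyway
        x[3 * i + k] -= L[k] * std::floor(x[3 * i + k] / L[k]);
      }
      double disp = std::sqrt(dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
      if (disp > max_disp) max_disp = disp;
      if (disp > 0.5) { unstable = true; break; }

      if (beads_per_mol == 3) {
        double w[3];
        for (int k = 0; k < 3; ++k)
          w[k] = (tq[k] / g_r) * dt + sd_r * norm_rand();
        double du[3] = {
          w[1] * u[3 * i + 2] - w[2] * u[3 * i + 1],
          w[2] * u[3 * i + 0] - w[0] * u[3 * i + 2],
          w[0] * u[3 * i + 1] - w[1] * u[3 * i + 0]
        };
        double nrm = 0.0;
        for (int k = 0; k < 3; ++k) {
          u[3 * i + k] += du[k];
          nrm += u[3 * i + k] * u[3 * i + k];
        }
        nrm = std::sqrt(nrm);
        for (int k = 0; k < 3; ++k) u[3 * i + k] /= nrm;
      }
    }
    if (unstable) break;
  }

  return List::create(_["coords"] = traj,
                      _["steps_saved"] = steps_saved,
                      _["n_frames_saved"] = frame,
                      _["max_step_displacement"] = max_disp,
                      _["unstable"] = unstable);
}
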