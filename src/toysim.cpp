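#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped (Brownian) steered dynamics of a bead-spring complex.
// Units: positions A, forces pN, time ps, friction pN ps / A,
// kB = 0.0138065 pN A / K. Euler-Maruyama update per free bead:
//   dr = (F / gamma) dt + sqrt(2 kB T dt / gamma) xi,  xi ~ N(0,1)
// Breakable bonds are removed permanently the first step their length
// exceeds r_break. Noise is drawn from R's RNG so set.seed() governs runs.

// [[Rcpp::export]]
List cpp_run_toy_smd(NumericMatrix pos0, NumericVector mass, NumericVector gamma_,
                     IntegerVector bond_i, IntegerVector bond_j,
                     NumericVector bond_k, NumericVector bond_r0,
                     LogicalVector bond_breakable, NumericVector bond_rbreak,
                     double temperature, LogicalVector is_fixed,
                     IntegerVector pulled_idx, NumericVector dir,
                     double k_spring, double v_pull, double dt,
                     int n_steps, int log_stride, double kB) {
  const int n = pos0.nrow();
  const int nb = bond_i.size();
  const int np = pulled_idx.size();

  std::vector<double> x(n), y(n), z(n);
  for (int a = 0; a < n; ++a) { x[a] = pos0(a,0); y[a] = pos0(a,1); z[a] = pos0(a,2); }

  // mass weights of the pulled group
  double msum = 0.0;
  std::vector<double> w(np);
  for (int p = 0; p < np; ++p) msum += mass[pulled_idx[p] - 1];
  for (int p = 0; p < np; ++p) w[p] = mass[pulled_idx[p] - 1] / msum;

  auto pulled_com = [&](double com[3]) {
    com[0] = com[1] = com[2] = 0.0;
    for (int p = 0; p < np; ++p) {
      int a = pulled_idx[p] - 1;
      com[0] += w[p] * x[a]; com[1] += w[p] * y[a]; com[2] += w[p] * z[a];
    }
  };

  double com0[3];
  pulled_com(com0);

  std::vector<bool> broken(nb, false);
  std::vector<double> fx(n), fy(n), fz(n);

  const int n_logs = n_steps / log_stride;
  NumericMatrix log_mat(n_logs, 7);               // step, com xyz, F xyz (pN)
  NumericVector frames(Dimension(n, 3, n_logs));  // coordinates at log steps
  std::vector<double> break_step, break_bond;
  int log_row = 0;

  for (int step = 1; step <= n_steps; ++step) {
    const double t = step * dt;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // harmonic bonds, with irreversible breakage
    for (int b = 0; b < nb; ++b) {
      if (broken[b]) continue;
      int i = bond_i[b] - 1, j = bond_j[b] - 1;
      double dxx = x[i] - x[j], dyy = y[i] - y[j], dzz = z[i] - z[j];
      double r = std::sqrt(dxx*dxx + dyy*dyy + dzz*dzz);
      if (bond_breakable[b] && r > bond_rbreak[b]) {
        broken[b] = true;
        break_step.push_back(step);
        break_bond.push_back(b + 1);
        continue;
      }
      if (r < 1e-12) continue;
      double f = -bond_k[b] * (r - bond_r0[b]) / r;  // force magnitude / r
      fx[i] += f * dxx; fy[i] += f * dyy; fz[i] += f * dzz;
      fx[j] -= f * dxx; fy[j] -= f * dyy; fz[j] -= f * dzz;
    }

    // constant-velocity SMD spring on the pulled COM, distributed by mass
    double com[3];
    pulled_com(com);
    double proj = (com[0] - com0[0]) * dir[0] + (com[1] - com0[1]) * dir[1]
                + (com[2] - com0[2]) * dir[2];
    double fscal = k_spring * (v_pull * t - proj);
    double Fx = fscal * dir[0], Fy = fscal * dir[1], Fz = fscal * dir[2];
    for (int p = 0; p < np; ++p) {
      int a = pulled_idx[p] - 1;
      fx[a] += Fx * w[p]; fy[a] += Fy * w[p]; fz[a] += Fz * w[p];
    }

    // Euler-Maruyama update of free beads
    for (int a = 0; a < n; ++a) {
      if (is_fixed[a]) continue;
      double mob = dt / gamma_[a];
      double amp = std::sqrt(2.0 * kB * temperature * dt / gamma_[a]);
      x[a] += fx[a] * mob + (temperature > 0 ? amp * norm_rand() : 0.0);
      y[a] += fy[a] * mob + (temperature > 0 ? amp * norm_rand() : 0.0);
      z[a] += fz[a] * mob + (temperature > 0 ? amp * norm_rand() : 0.0);
      if (!std::isfinite(x[a]) || !std::isfinite(y[a]) || !std::isfinite(z[a]))
        stop("toy simulation diverged at step %d (non-finite coordinate); reduce dt", step);
    }

    if (step % log_stride == 0) {
      log_mat(log_row, 0) = step;
      log_mat(log_row, 1) = com[0]; log_mat(log_row, 2) = com[1]; log_mat(log_row, 3) = com[2];
      log_mat(log_row, 4) = Fx; log_mat(log_row, 5) = Fy; log_mat(log_row, 6) = Fz;
      for (int a = 0; a < n; ++a) {
        frames[a + n * (0 + 3 * log_row)] = x[a];
        frames[a + n * (1 + 3 * log_row)] = y[a];
        frames[a + n * (2 + 3 * log_row)] = z[a];
      }
      ++log_row;
    }
  }

  return List::create(_["log"] = log_mat, _["frames"] = frames,
                      _["breaks"] = DataFrame::create(_["step"] = break_step,
                                                      _["bond"] = break_bond));
}
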