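// Overdamped Langevin dynamics on an analytic 2D potential with
// well-tempered metadynamics biasing (multiple walkers, shared bias).
//
// The shared bias is accumulated on a regular grid: each deposited
// Gaussian hill is added analytically to the grid of bias values and
// bias forces, and per-step forces are read back by bilinear
// interpolation. Hills themselves are recorded exactly, so any
// downstream free-energy reconstruction can use exact Gaussian
// summation over the returned log.
//
// All randomness comes from R's RNG (norm_rand), so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Potential {
  int form; // 1 = tilted double well, 2 = harmonic
  double p0, p1, p2, p3;

  inline void grad(double x, double y, double &gx, double &gy) const {
    if (form == 1) {
      // p0 = barrier, p1 = delta, p2 = ky
      gx = 4.0 * p0 * x * (x * x - 1.0) +
           0.75 * p1 * (x * x - 1.0);
      gy = p2 * y;
    } else {
      // p0 = kx, p1 = ky, p2 = x0, p3 = y0
      gx = p0 * (x - p2);
      gy = p1 * (y - p3);
    }
  }
};

struct BiasGrid {
  int nx, ny;
  double xmin, ymin, dx, dy;
  std::vector<double> V, Fx, Fy;

  BiasGrid(int nx_, int ny_, double xmin_, double xmax_, double ymin_,
           double ymax_)
      : nx(nx_), ny(ny_), xmin(xmin_), ymin(ymin_),
        dx((xmax_ - xmin_) / (nx_ - 1)), dy((ymax_ - ymin_) / (ny_ - 1)),
        V(nx_ * ny_, 0.0), Fx(nx_ * ny_, 0.0), Fy(nx_ * ny_, 0.0) {}

  inline int idx(int i, int j) const { return i + nx * j; }

  void add_hill(double cx, double cy, double sx, double sy, double h) {
    int i0 = std::max(0, (int)std::floor((cx - 6.0 * sx - xmin) / dx));
    int i1 = std::min(nx - 1,
                      (int)std::ceil((cx + 6.0 * sx - xmin) / dx));
    int j0 = std::max(0, (int)std::floor((cy - 6.0 * sy - ymin) / dy));
    int j1 = std::min(ny - 1,
                      (int)std::ceil((cy + 6.0 * sy - ymin) / dy));
    double isx2 = 1.0 / (sx * sx), isy2 = 1.0 / (sy * sy);
    for (int j = j0; j <= j1; ++j) {
      double ddy = ymin + j * dy - cy;
      double ey = std::exp(-0.5 * ddy * ddy * isy2);
      for (int i = i0; i <= i1; ++i) {
        double ddx = xmin + i * dx - cx;
        double e = h * std::exp(-0.5 * ddx * ddx * isx2) * ey;
        int k = idx(i, j);
        V[k] += e;
        Fx[k] += e * ddx * isx2; // -dV/dx
        Fy[k] += e * ddy * isy2;
      }
    }
  }

  // bilinear interpolation of (V, Fx, Fy) at (x, y)
  inline void interp(double x, double y, double &v, double &fx,
                     double &fy) const {
    double u = (x - xmin) / dx, w = (y - ymin) / dy;
    int i = std::min(std::max((int)std::floor(u), 0), nx - 2);
    int j = std::min(std::max((int)std::floor(w), 0), ny - 2);
    double a = u - i, b = w - j;
    a = std::min(std::max(a, 0.0), 1.0);
    b = std::min(std::max(b, 0.0), 1.0);
    double w00 = (1 - a) * (1 - b), w10 = a * (1 - b);
    double w01 = (1 - a) * b, w11 = a * b;
    int k00 = idx(i, j), k10 = idx(i + 1, j), k01 = idx(i, j + 1),
        k11 = idx(i + 1, j + 1);
    v = w00 * V[k00] + w10 * V[k10] + w01 * V[k01] + w11 * V[k11];
    fx = w00 * Fx[k00] + w10 * Fx[k10] + w01 * Fx[k01] + w11 * Fx[k11];
    fy = w00 * Fy[k00] + w10 * Fy[k10] + w01 * Fy[k01] + w11 * Fy[k11];
  }
};

} // namespace

// [[Rcpp::export]]
List metad_driver_cpp(int pot_form, NumericVector pot_params, double dt,
                      double friction, double temperature, double kB,
                      double gamma, double h0, int dep_stride,
                      int window_steps, double sigma_min,
                      double sigma_max, NumericVector sigma0,
                      NumericMatrix x0, int n_steps, int sample_stride,
                      NumericVector domain, IntegerVector grid_dims) {
  Potential pot;
  pot.form = pot_form;
  pot.p0 = pot_params.size() > 0 ? pot_params[0] : 0.0;
  pot.p1 = pot_params.size() > 1 ? pot_params[1] : 0.0;
  pot.p2 = pot_params.size() > 2 ? pot_params[2] : 0.0;
  pot.p3 = pot_params.size() > 3 ? pot_params[3] : 0.0;

  const int nw = x0.nrow();
  const double xmin = domain[0], xmax = domain[1], ymin = domain[2],
               ymax = domain[3];
  const double guard = 1.0; // hard stop this far outside the domain
  BiasGrid grid(grid_dims[0], grid_dims[1], xmin, xmax, ymin, ymax);

  const double kBT = kB * temperature;
  const double dT = (gamma - 1.0) * temperature;
  const double mob = dt / friction;
  const double noise_amp = std::sqrt(2.0 * kBT * dt / friction);
  const bool deposit = h0 > 0.0 && dep_stride > 0;

  // subsampled CV history per walker for the adaptive widths
  const int hist_len = 32;
  int hist_stride = std::max(1, window_steps / hist_len);
  std::vector<std::vector<double>> hx(nw), hy(nw);
  std::vector<std::vector<int>> ht(nw);

  std::vector<double> x(nw), y(nw);
  for (int w = 0; w < nw; ++w) {
    x[w] = x0(w, 0);
    y[w] = x0(w, 1);
  }

  std::vector<double> hill_rows; // 8 cols per hill
  std::vector<double> samp_rows; // 4 cols per sample

  RNGScope scope;

  for (int step = 1; step <= n_steps; ++step) {
    for (int w = 0; w < nw; ++w) {
      double gx, gy, bv, bfx, bfy;
      pot.grad(x[w], y[w], gx, gy);
      grid.interp(x[w], y[w], bv, bfx, bfy);
      double fx = -gx + bfx, fy = -gy + bfy;
      x[w] += mob * fx + noise_amp * norm_rand();
      y[w] += mob * fy + noise_amp * norm_rand();
      if (!std::isfinite(x[w]) || !std::isfinite(y[w]) ||
          x[w] < xmin - guard || x[w] > xmax + guard ||
          y[w] < ymin - guard || y[w] > ymax + guard)
        stop("trajectory diverged at step %d (walker %d)", step, w + 1);
      // reflective domain walls
      if (x[w] < xmin) x[w] = 2.0 * xmin - x[w];
      if (x[w] > xmax) x[w] = 2.0 * xmax - x[w];
      if (y[w] < ymin) y[w] = 2.0 * ymin - y[w];
      if (y[w] > ymax) y[w] = 2.0 * ymax - y[w];

      if (step % hist_stride == 0) {
        hx[w].push_back(x[w]);
        hy[w].push_back(y[w]);
        ht[w].push_back(step);
        if ((int)hx[w].size() > 2 * hist_len) {
          hx[w].erase(hx[w].begin());
          hy[w].erase(hy[w].begin());
          ht[w].erase(ht[w].begin());
        }
      }
      if (sample_stride > 0 && step % sample_stride == 0) {
        samp_rows.push_back(step * dt);
        samp_rows.push_back(w + 1.0);
        samp_rows.push_back(x[w]);
        samp_rows.push_back(y[w]);
      }
    }

    if (deposit && step % dep_stride == 0) {
      double t = step * dt;
      for (int w = 0; w < nw; ++w) {
        double bv, bfx, bfy;
        grid.interp(x[w], y[w], bv, bfx, bfy);
        double h = h0 * std::exp(-bv / (kB * dT));
        // adaptive sigma: rms displacement of the trailing window
        // relative to the current position
        double sx = sigma0[0], sy = sigma0[1];
        int n_in = 0, oldest = step;
        double sum2x = 0.0, sum2y = 0.0;
        for (size_t q = 0; q < hx[w].size(); ++q) {
          if (ht[w][q] >= step - window_steps) {
            double ddx = x[w] - hx[w][q], ddy = y[w] - hy[w][q];
            sum2x += ddx * ddx;
            sum2y += ddy * ddy;
            if (ht[w][q] < oldest) oldest = ht[w][q];
            ++n_in;
          }
        }
        if (n_in >= 2 && (step - oldest) >= window_steps / 2) {
          sx = std::sqrt(sum2x / n_in);
          sy = std::sqrt(sum2y / n_in);
          sx = std::min(std::max(sx, sigma_min), sigma_max);
          sy = std::min(std::max(sy, sigma_min), sigma_max);
        }
        grid.add_hill(x[w], y[w], sx, sy, h);
        double row[8] = {t, x[w], y[w], sx, sy, h, gamma, w + 1.0};
        hill_rows.insert(hill_rows.end(), row, row + 8);
      }
    }
  }

  int n_hills = hill_rows.size() / 8;
  NumericMatrix hills(n_hills, 8);
  for (int r = 0; r < n_hills; ++r)
    for (int c = 0; c < 8; ++c) hills(r, c) = hill_rows[8 * r + c];
  colnames(hills) = CharacterVector::create(
      "time", "s1", "s2", "sigma1", "sigma2", "height", "biasf",
      "walker");

  int n_samp = samp_rows.size() / 4;
  NumericMatrix samples(n_samp, 4);
  for (int r = 0; r < n_samp; ++r)
    for (int c = 0; c < 4; ++c) samples(r, c) = samp_rows[4 * r + c];
  colnames(samples) =
      CharacterVector::create("time", "walker", "s1", "s2");

  NumericMatrix xfinal(nw, 2);
  for (int w = 0; w < nw; ++w) {
    xfinal(w, 0) = x[w];
    xfinal(w, 1) = y[w];
  }

  return List::create(_["hills"] = hills, _["samples"] = samples,
                      _["final_state"] = xfinal);
}
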