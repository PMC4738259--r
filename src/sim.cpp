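#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean-filter diffusion with absorbing boundary: each cell becomes
// damping * (sum of k x k neighbourhood) / k^2, where out-of-bounds cells
// contribute 0 but still count in the divisor. Implemented as two separable
// box-sum passes (vertical then horizontal) with zero padding.
// Matrix layout: field(row, col) = cell (x = col, y = row), 0-based cells.
// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix field, int kernel, double damping) {
  int h = field.nrow(), w = field.ncol(), r = kernel / 2;
  NumericMatrix tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j) {            // vertical box sums per column
    double s = 0.0;
    for (int i = 0; i < r && i < h; ++i) s += field(i, j);
    for (int i = 0; i < h; ++i) {
      if (i + r < h) s += field(i + r, j);
      tmp(i, j) = s;
      if (i - r >= 0) s -= field(i - r, j);
    }
  }
  double norm = damping / (double)(kernel * kernel);
  for (int i = 0; i < h; ++i) {            // horizontal box sums per row
    double s = 0.0;
    for (int j = 0; j < r && j < w; ++j) s += tmp(i, j);
    for (int j = 0; j < w; ++j) {
      if (j + r < w) s += tmp(i, j + r);
      out(i, j) = s * norm;
      if (j - r >= 0) s -= tmp(i, j - r);
    }
  }
  return out;
}

static inline double sample_field(const NumericMatrix &field, double px, double py,
                                  int w, int h) {
  int xi = (int)std::floor(px), yi = (int)std::floor(py);
  if (xi < 0 || yi < 0 || xi >= w || yi >= h) return 0.0;
  return field(yi, xi);
}

static inline double wrap360(double a) {
  a -= 360.0 * std::floor(a / 360.0);
  if (a >= 360.0) a -= 360.0;   // guard against rounding at the seam
  return a;
}

// Full scheduler loop. One step = project active stimuli, update every
// particle once in a fresh random order (sense -> orient -> attempt move),
// then diffuse. All randomness comes from R's RNG, so set.seed() upstream
// makes runs bit-reproducible.
//
// sources: columns (x, y, weight, from, to); active when from <= t < to.
// win:     one row per measurement window, columns (xmin, xmax, ymin, ymax),
//          0-based inclusive cell bounds.
// Occupancy counts are recorded after completing step t whenever
// t + 1 >= sample_start and (t + 1 - sample_start) %% sample_interval == 0;
// the recorded time label is t + 1 - sample_start (post-warm-up clock).
// [[Rcpp::export]]
List cpp_run(NumericVector x0, NumericVector y0, NumericVector heading0,
             NumericMatrix field0, IntegerMatrix occ0,
             NumericMatrix sources,
             int t_start, int n_steps,
             double sa_deg, double ra_deg, double so, double deposition,
             double step_len, int kernel, double damping,
             IntegerMatrix win, int sample_start, int sample_interval) {
  NumericVector x = clone(x0), y = clone(y0), heading = clone(heading0);
  NumericMatrix field = clone(field0);
  IntegerMatrix occ = clone(occ0);
  int n = x.size(), w = field.ncol(), h = field.nrow();
  int n_src = sources.nrow(), n_win = win.nrow();
  double sa = sa_deg * M_PI / 180.0;
  const double deg2rad = M_PI / 180.0;

  std::vector<int> perm(n);
  std::vector<int> times;
  std::vector<std::vector<int> > counts; // one vector of n_win counts per sample

  RNGScope scope;

  for (int step = 0; step < n_steps; ++step) {
    int t = t_start + step;

    for (int s = 0; s < n_src; ++s) {
      if (sources(s, 3) <= t && t < sources(s, 4)) {
        int sx = (int)sources(s, 0), sy = (int)sources(s, 1);
        field(sy, sx) += sources(s, 2);
      }
    }

    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {      // Fisher-Yates off R's RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }

    for (int k = 0; k < n; ++k) {
      int p = perm[k];
      double th = heading[p] * deg2rad;
      double F  = sample_field(field, x[p] + so * std::cos(th),      y[p] + so * std::sin(th),      w, h);
      double FL = sample_field(field, x[p] + so * std::cos(th + sa), y[p] + so * std::sin(th + sa), w, h);
      double FR = sample_field(field, x[p] + so * std::cos(th - sa), y[p] + so * std::sin(th - sa), w, h);

      if (F > FL && F > FR) {
        // keep heading
      } else if (F < FL && F < FR) {
        heading[p] = wrap360(heading[p] + (unif_rand() < 0.5 ? ra_deg : -ra_deg));
      } else if (FL > FR) {
        heading[p] = wrap360(heading[p] + ra_deg);
      } else if (FR > FL) {
        heading[p] = wrap360(heading[p] - ra_deg);
      } // exact tie: keep heading

      th = heading[p] * deg2rad;
      double nx = x[p] + step_len * std::cos(th);
      double ny = y[p] + step_len * std::sin(th);
      int cxi = (int)std::floor(nx), cyi = (int)std::floor(ny);
      int oxi = (int)std::floor(x[p]), oyi = (int)std::floor(y[p]);
      bool inb = cxi >= 0 && cyi >= 0 && cxi < w && cyi < h;
      if (inb && (occ(cyi, cxi) == 0 || (cxi == oxi && cyi == oyi))) {
        occ(oyi, oxi) = 0;
        occ(cyi, cxi) = 1;
        x[p] = nx; y[p] = ny;
        field(cyi, cxi) += deposition;
      } else {
        heading[p] = unif_rand() * 360.0;
      }
    }

    field = cpp_diffuse(field, kernel, damping);

    if (sample_interval > 0 && t + 1 >= sample_start &&
        (t + 1 - sample_start) % sample_interval == 0) {
      std::vector<int> row(n_win, 0);
      for (int v = 0; v < n_win; ++v) {
        int c = 0;
        for (int yy = win(v, 2); yy <= win(v, 3); ++yy)
          for (int xx = win(v, 0); xx <= win(v, 1); ++xx)
            c += occ(yy, xx);
        row[v] = c;
      }
      times.push_back(t + 1 - sample_start);
      counts.push_back(row);
    }
  }

  int n_samp = times.size();
  IntegerMatrix cm(n_win, n_samp);
  IntegerVector tv(n_samp);
  for (int s = 0; s < n_samp; ++s) {
    tv[s] = times[s];
    for (int v = 0; v < n_win; ++v) cm(v, s) = counts[s][v];
  }

  return List::create(_["x"] = x, _["y"] = y, _["heading"] = heading,
                      _["field"] = field, _["occupancy"] = occ,
                      _["times"] = tv, _["counts"] = cm);
}
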