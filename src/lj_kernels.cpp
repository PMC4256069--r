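#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 12-6 LJ energy of one probe site against all matrix sites.
// epsc/sigc are the pre-combined (probe-site x matrix-site) parameters.
// Overlaps are clamped so the energy stays finite (large positive).
static inline double site_energy(double px, double py, double pz,
                                 const double* cx, const double* cy,
                                 const double* cz, const double* eps,
                                 const double* sig, int m, double cut2,
                                 const double* box, bool periodic) {
  double e = 0.0;
  for (int j = 0; j < m; j++) {
    if (eps[j] == 0.0) continue;
    double dx = px - cx[j], dy = py - cy[j], dz = pz - cz[j];
    if (periodic) {
      dx -= box[0] * std::round(dx / box[0]);
      dy -= box[1] * std::round(dy / box[1]);
      dz -= box[2] * std::round(dz / box[2]);
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cut2) continue;
    if (r2 < 1e-6) r2 = 1e-6;
    double s2 = sig[j] * sig[j] / r2;
    double s6 = s2 * s2 * s2;
    e += 4.0 * eps[j] * s6 * (s6 - 1.0);
  }
  return e;
}

// Energies of a batch of rigid diatomic placements against one frame.
// centers, axes: n x 3 (axes unit vectors); coords: m x 3 matrix sites;
// epsc, sigc: m x 2 combined LJ parameters (columns = probe sites).
// [[Rcpp::export(name = ".lj_batch_energies")]]
NumericVector lj_batch_energies(NumericMatrix centers, NumericMatrix axes,
                                double half_bond, NumericMatrix coords,
                                NumericMatrix epsc, NumericMatrix sigc,
                                double cutoff, NumericVector box,
                                bool periodic) {
  int n = centers.nrow(), m = coords.nrow();
  double cut2 = cutoff * cutoff;
  std::vector<double> cx(m), cy(m), cz(m), e1(m), s1(m), e2(m), s2(m);
  for (int j = 0; j < m; j++) {
    cx[j] = coords(j, 0); cy[j] = coords(j, 1); cz[j] = coords(j, 2);
    e1[j] = epsc(j, 0); s1[j] = sigc(j, 0);
    e2[j] = epsc(j, 1); s2[j] = sigc(j, 1);
  }
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double ax = axes(i, 0), ay = axes(i, 1), az = axes(i, 2);
    double px = centers(i, 0), py = centers(i, 1), pz = centers(i, 2);
    double e = site_energy(px + half_bond * ax, py + half_bond * ay,
                           pz + half_bond * az, cx.data(), cy.data(),
                           cz.data(), e1.data(), s1.data(), m, cut2,
                           box.begin(), periodic);
    e += site_energy(px - half_bond * ax, py - half_bond * ay,
                     pz - half_bond * az, cx.data(), cy.data(), cz.data(),
                     e2.data(), s2.data(), m, cut2, box.begin(), periodic);
    out[i] = e;
  }
  return out;
}

static inline double wrap(double x, double L) {
  return x - L * std::floor(x / L);
}

// Rodrigues rotation of v about unit axis u by angle th (in place).
static inline void rotate(double* v, const double* u, double th) {
  double c = std::cos(th), s = std::sin(th);
  double dot = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  double cr0 = u[1] * v[2] - u[2] * v[1];
  double cr1 = u[2] * v[0] - u[0] * v[2];
  double cr2 = u[0] * v[1] - u[1] * v[0];
  double w0 = v[0] * c + cr0 * s + u[0] * dot * (1 - c);
  double w1 = v[1] * c + cr1 * s + u[1] * dot * (1 - c);
  double w2 = v[2] * c + cr2 * s + u[2] * dot * (1 - c);
  v[0] = w0; v[1] = w1; v[2] = w2;
}

static void random_unit(double* u) {
  double n2 = 0.0;
  do {
    u[0] = norm_rand(); u[1] = norm_rand(); u[2] = norm_rand();
    n2 = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
  } while (n2 < 1e-12);
  double n = std::sqrt(n2);
  u[0] /= n; u[1] /= n; u[2] /= n;
}

// Metropolis random walk of a rigid diatomic probe in the field of a
// randomly re-drawn ensemble frame. Uses R's RNG (seed via set.seed()).
// coords_all: (m * nf) x 3, frames stacked; epsc/sigc: m x 2 combined LJ.
// Returns recorded centers, per-window acceptance counts, acceptance rate.
// [[Rcpp::export(name = ".metropolis_diatomic")]]
List metropolis_diatomic(NumericMatrix coords_all, int n_sites, int n_frames,
                         NumericMatrix epsc, NumericMatrix sigc,
                         double half_bond, double cutoff, NumericVector box,
                         bool periodic, int n_steps, double beta,
                         double trans_step, double rot_step, int frame_stride,
                         int record_stride, int window) {
  int m = n_sites;
  double cut2 = cutoff * cutoff;
  std::vector<double> cx(m), cy(m), cz(m), e1(m), s1(m), e2(m), s2(m);
  for (int j = 0; j < m; j++) {
    e1[j] = epsc(j, 0); s1[j] = sigc(j, 0);
    e2[j] = epsc(j, 1); s2[j] = sigc(j, 1);
  }
  auto load_frame = [&](int f) {
    for (int j = 0; j < m; j++) {
      cx[j] = coords_all(f * m + j, 0);
      cy[j] = coords_all(f * m + j, 1);
      cz[j] = coords_all(f * m + j, 2);
    }
  };
  auto energy = [&](const double* p, const double* a) {
    double e = site_energy(p[0] + half_bond * a[0], p[1] + half_bond * a[1],
                           p[2] + half_bond * a[2], cx.data(), cy.data(),
                           cz.data(), e1.data(), s1.data(), m, cut2,
                           box.begin(), periodic);
    e += site_energy(p[0] - half_bond * a[0], p[1] - half_bond * a[1],
                     p[2] - half_bond * a[2], cx.data(), cy.data(), cz.data(),
                     e2.data(), s2.data(), m, cut2, box.begin(), periodic);
    return e;
  };

  int fi = (int)std::floor(unif_rand() * n_frames);
  if (fi >= n_frames) fi = n_frames - 1;
  load_frame(fi);
  double pos[3], axis[3];
  for (int k = 0; k < 3; k++) pos[k] = unif_rand() * box[k];
  random_unit(axis);
  double ecur = energy(pos, axis);

  int n_rec = n_steps / record_stride;
  NumericMatrix rec(n_rec, 3);
  int n_win = (n_steps + window - 1) / window;
  IntegerVector win_acc(n_win);
  long accepted = 0;
  int irec = 0;

  for (int step = 0; step < n_steps; step++) {
    if (frame_stride > 0 && step % frame_stride == 0 && n_frames > 1) {
      fi = (int)std::floor(unif_rand() * n_frames);
      if (fi >= n_frames) fi = n_frames - 1;
      load_frame(fi);
      ecur = energy(pos, axis);  // energy depends on the active frame
    }
    double np[3], na[3], u[3];
    for (int k = 0; k < 3; k++)
      np[k] = wrap(pos[k] + (unif_rand() - 0.5) * 2.0 * trans_step, box[k]);
    na[0] = axis[0]; na[1] = axis[1]; na[2] = axis[2];
    random_unit(u);
    rotate(na, u, rot_step * norm_rand());
    double enew = energy(np, na);
    double dE = enew - ecur;
    if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
      pos[0] = np[0]; pos[1] = np[1]; pos[2] = np[2];
      axis[0] = na[0]; axis[1] = na[1]; axis[2] = na[2];
      ecur = enew;
      accepted++;
      win_acc[step / window]++;
    }
    if ((step + 1) % record_stride == 0 && irec < n_rec) {
      rec(irec, 0) = pos[0]; rec(irec, 1) = pos[1]; rec(irec, 2) = pos[2];
      irec++;
    }
  }
  return List::create(_["positions"] = rec,
                      _["window_accepts"] = win_acc,
                      _["acceptance_rate"] = (double)accepted / n_steps);
}
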