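// Pairwise toy-Hamiltonian energy/force kernels and the overdamped Langevin
// (Brownian dynamics) integrator. Units: kcal/mol, Angstrom, ps, elementary
// charge. Periodic minimum image in x and y only; z is confined by soft
// walls. Randomness comes from R's RNG so set.seed() governs everything.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Params {
  int n;
  // pair matrices, row-major n*n: sigma_ij, eps_ij, kq_ij = 332.06 qi qj / eps_r
  std::vector<double> sig, eps, kq;
  double Lx, Ly, rc2;
  // flat-bottom radial tethers (r0 = 0 gives plain harmonic)
  std::vector<int> teth_atom;
  std::vector<double> tax, tay, taz, tk, tr0;
  // harmonic bonds
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  // soft z walls applied to flagged atoms
  double wall_k, wall_z;
  std::vector<int> wall_atom;
  // flat-bottom sphere restraints
  std::vector<int> ra;
  std::vector<double> rx, ry, rz, rr, rk;
  // optional 1-D double-well external field on z (integrator validation field)
  bool has_dw;
  double dw_k, dw_z1, dw_z2, dw_dU;
  std::vector<int> dw_atom;
};

static Params unpack(const List& par) {
  Params P;
  P.n = as<int>(par["n"]);
  P.sig = as<std::vector<double>>(par["sig"]);
  P.eps = as<std::vector<double>>(par["eps"]);
  P.kq  = as<std::vector<double>>(par["kq"]);
  NumericVector box = par["box"];
  P.Lx = box[0]; P.Ly = box[1];
  double rc = as<double>(par["cutoff"]);
  P.rc2 = rc * rc;
  P.teth_atom = as<std::vector<int>>(par["teth_atom"]);
  P.tax = as<std::vector<double>>(par["teth_x"]);
  P.tay = as<std::vector<double>>(par["teth_y"]);
  P.taz = as<std::vector<double>>(par["teth_z"]);
  P.tk  = as<std::vector<double>>(par["teth_k"]);
  P.tr0 = as<std::vector<double>>(par["teth_r0"]);
  P.bi = as<std::vector<int>>(par["bond_i"]);
  P.bj = as<std::vector<int>>(par["bond_j"]);
  P.bk = as<std::vector<double>>(par["bond_k"]);
  P.br0 = as<std::vector<double>>(par["bond_r0"]);
  P.wall_k = as<double>(par["wall_k"]);
  P.wall_z = as<double>(par["wall_z"]);
  P.wall_atom = as<std::vector<int>>(par["wall_atom"]);
  P.ra = as<std::vector<int>>(par["restr_atom"]);
  P.rx = as<std::vector<double>>(par["restr_x"]);
  P.ry = as<std::vector<double>>(par["restr_y"]);
  P.rz = as<std::vector<double>>(par["restr_z"]);
  P.rr = as<std::vector<double>>(par["restr_r"]);
  P.rk = as<std::vector<double>>(par["restr_k"]);
  List dw = par["double_well"];
  P.has_dw = dw.size() > 0;
  if (P.has_dw) {
    P.dw_k = as<double>(dw["k"]);
    P.dw_z1 = as<double>(dw["z1"]);
    P.dw_z2 = as<double>(dw["z2"]);
    P.dw_dU = as<double>(dw["dU"]);
    P.dw_atom = as<std::vector<int>>(dw["atoms"]);
  }
  return P;
}

static inline double mimg(double d, double L) {
  if (L > 0.0) d -= L * std::nearbyint(d / L);
  return d;
}

// comps (if non-null, length 6): coulomb, lj, tether, bond, wall, restraint(+dw)
static double energy_core(const Params& P, const double* X, double* comps) {
  const int n = P.n;
  double e_c = 0.0, e_lj = 0.0, e_t = 0.0, e_b = 0.0, e_w = 0.0, e_r = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = X[i], yi = X[i + n], zi = X[i + 2 * n];
    for (int j = i + 1; j < n; ++j) {
      double dx = mimg(xi - X[j], P.Lx);
      double dy = mimg(yi - X[j + n], P.Ly);
      double dz = zi - X[j + 2 * n];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= P.rc2) continue;
      const double kq = P.kq[i * n + j];
      const double ep = P.eps[i * n + j];
      if (kq != 0.0) e_c += kq / std::sqrt(r2);
      if (ep != 0.0) {
        double s2 = P.sig[i * n + j];
        s2 = s2 * s2 / r2;
        double s6 = s2 * s2 * s2;
        e_lj += 4.0 * ep * (s6 * s6 - s6);
      }
    }
  }
  for (size_t t = 0; t < P.teth_atom.size(); ++t) {
    int i = P.teth_atom[t];
    double dx = X[i] - P.tax[t], dy = X[i + n] - P.tay[t], dz = X[i + 2 * n] - P.taz[t];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ex = d - P.tr0[t];
    if (ex > 0.0) e_t += 0.5 * P.tk[t] * ex * ex;
  }
  for (size_t b = 0; b < P.bi.size(); ++b) {
    int i = P.bi[b], j = P.bj[b];
    double dx = X[i] - X[j], dy = X[i + n] - X[j + n], dz = X[i + 2 * n] - X[j + 2 * n];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ex = d - P.br0[b];
    e_b += 0.5 * P.bk[b] * ex * ex;
  }
  for (size_t w = 0; w < P.wall_atom.size(); ++w) {
    double z = X[P.wall_atom[w] + 2 * n];
    double ex = std::fabs(z) - P.wall_z;
    if (ex > 0.0) e_w += 0.5 * P.wall_k * ex * ex;
  }
  for (size_t r = 0; r < P.ra.size(); ++r) {
    int i = P.ra[r];
    double dx = X[i] - P.rx[r], dy = X[i + n] - P.ry[r], dz = X[i + 2 * n] - P.rz[r];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ex = d - P.rr[r];
    if (ex > 0.0) e_r += 0.5 * P.rk[r] * ex * ex;
  }
  if (P.has_dw) {
    for (size_t a = 0; a < P.dw_atom.size(); ++a) {
      double z = X[P.dw_atom[a] + 2 * n];
      double u1 = 0.5 * P.dw_k * (z - P.dw_z1) * (z - P.dw_z1);
      double u2 = P.dw_dU + 0.5 * P.dw_k * (z - P.dw_z2) * (z - P.dw_z2);
      e_r += (u1 < u2) ? u1 : u2;
    }
  }
  if (comps) {
    comps[0] = e_c; comps[1] = e_lj; comps[2] = e_t;
    comps[3] = e_b; comps[4] = e_w; comps[5] = e_r;
  }
  return e_c + e_lj + e_t + e_b + e_w + e_r;
}

static void forces_core(const Params& P, const double* X, double* F) {
  const int n = P.n;
  std::fill(F, F + 3 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = X[i], yi = X[i + n], zi = X[i + 2 * n];
    for (int j = i + 1; j < n; ++j) {
      double dx = mimg(xi - X[j], P.Lx);
      double dy = mimg(yi - X[j + n], P.Ly);
      double dz = zi - X[j + 2 * n];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= P.rc2) continue;
      const double kq = P.kq[i * n + j];
      const double ep = P.eps[i * n + j];
      double scal = 0.0;
      if (kq != 0.0) scal += kq / (r2 * std::sqrt(r2));
      if (ep != 0.0) {
        double s2 = P.sig[i * n + j];
        s2 = s2 * s2 / r2;
        double s6 = s2 * s2 * s2;
        scal += 24.0 * ep * (2.0 * s6 * s6 - s6) / r2;
      }
      if (scal != 0.0) {
        F[i] += dx * scal;         F[j] -= dx * scal;
        F[i + n] += dy * scal;     F[j + n] -= dy * scal;
        F[i + 2 * n] += dz * scal; F[j + 2 * n] -= dz * scal;
      }
    }
  }
  for (size_t t = 0; t < P.teth_atom.size(); ++t) {
    int i = P.teth_atom[t];
    double dx = X[i] - P.tax[t], dy = X[i + n] - P.tay[t], dz = X[i + 2 * n] - P.taz[t];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ex = d - P.tr0[t];
    if (ex > 0.0 && d > 1e-12) {
      double c = -P.tk[t] * ex / d;
      F[i] += c * dx; F[i + n] += c * dy; F[i + 2 * n] += c * dz;
    }
  }
  for (size_t b = 0; b < P.bi.size(); ++b) {
    int i = P.bi[b], j = P.bj[b];
    double dx = X[i] - X[j], dy = X[i + n] - X[j + n], dz = X[i + 2 * n] - X[j + 2 * n];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-12) continue;
    double c = -P.bk[b] * (d - P.br0[b]) / d;
    F[i] += c * dx;         F[j] -= c * dx;
    F[i + n] += c * dy;     F[j + n] -= c * dy;
    F[i + 2 * n] += c * dz; F[j + 2 * n] -= c * dz;
  }
  for (size_t w = 0; w < P.wall_atom.size(); ++w) {
    int i = P.wall_atom[w];
    double z = X[i + 2 * n];
    double ex = std::fabs(z) - P.wall_z;
    if (ex > 0.0) F[i + 2 * n] -= P.wall_k * ex * ((z > 0) ? 1.0 : -1.0);
  }
  for (size_t r = 0; r < P.ra.size(); ++r) {
    int i = P.ra[r];
    double dx = X[i] - P.rx[r], dy = X[i + n] - P.ry[r], dz = X[i + 2 * n] - P.rz[r];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ex = d - P.rr[r];
    if (ex > 0.0 && d > 1e-12) {
      double c = -P.rk[r] * ex / d;
      F[i] += c * dx; F[i + n] += c * dy; F[i + 2 * n] += c * dz;
    }
  }
  if (P.has_dw) {
    for (size_t a = 0; a < P.dw_atom.size(); ++a) {
      int i = P.dw_atom[a];
      double z = X[i + 2 * n];
      double u1 = 0.5 * P.dw_k * (z - P.dw_z1) * (z - P.dw_z1);
      double u2 = P.dw_dU + 0.5 * P.dw_k * (z - P.dw_z2) * (z - P.dw_z2);
      F[i + 2 * n] -= P.dw_k * (z - ((u1 < u2) ? P.dw_z1 : P.dw_z2));
    }
  }
}

// [[Rcpp::export]]
NumericVector energy_components_cpp(NumericMatrix coords, List par) {
  Params P = unpack(par);
  if (coords.nrow() != P.n) stop("coordinate/parameter atom-count mismatch");
  double comps[6];
  double tot = energy_core(P, coords.begin(), comps);
  NumericVector out = NumericVector::create(
    _["total"] = tot, _["coulomb"] = comps[0], _["lj"] = comps[1],
    _["tether"] = comps[2], _["bond"] = comps[3], _["wall"] = comps[4],
    _["restraint"] = comps[5]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix forces_cpp(NumericMatrix coords, List par) {
  Params P = unpack(par);
  if (coords.nrow() != P.n) stop("coordinate/parameter atom-count mismatch");
  NumericMatrix F(P.n, 3);
  forces_core(P, coords.begin(), F.begin());
  return F;
}

// Evaluate the total energy on every frame of an n x 3 x m array.
// [[Rcpp::export]]
NumericVector energy_frames_cpp(NumericVector frames, List par) {
  Params P = unpack(par);
  IntegerVector dim = frames.attr("dim");
  if (dim.size() != 3 || dim[0] != P.n || dim[1] != 3)
    stop("frames must be an n_atoms x 3 x n_frames array matching the parameters");
  int m = dim[2];
  NumericVector out(m);
  const double* base = frames.begin();
  for (int f = 0; f < m; ++f)
    out[f] = energy_core(P, base + (size_t)f * 3 * P.n, nullptr);
  return out;
}

// Overdamped Langevin (Euler-Maruyama):
//   dx = F/gamma * dt + sqrt(2 kT dt / gamma) * N(0,1)
// mobile: per-atom flag; dims: which Cartesian axes are integrated.
// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix coords0, List par, int nsteps, double dt,
                double kT, double gamma, int save_every,
                LogicalVector mobile, LogicalVector dims, double t0) {
  Params P = unpack(par);
  const int n = P.n;
  if (coords0.nrow() != n) stop("coordinate/parameter atom-count mismatch");
  if (nsteps < 1) stop("nsteps must be >= 1");
  std::vector<double> X(coords0.begin(), coords0.end());
  std::vector<double> F(3 * n);
  const double mob = dt / gamma;
  const double amp = std::sqrt(2.0 * kT * dt / gamma);
  const int nsave = nsteps / save_every;
  NumericVector frames((size_t)n * 3 * std::max(nsave, 1));
  NumericVector times(std::max(nsave, 1));
  const double esc_x = 2.0 * std::max(P.Lx, 1.0), esc_z = 2.0 * std::max(4.0 * P.wall_z, P.Lx);
  int isave = 0;
  for (int step = 1; step <= nsteps; ++step) {
    forces_core(P, X.data(), F.data());
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int d = 0; d < 3; ++d) {
        if (!dims[d]) continue;
        // deterministic drift clamped at 0.3 A/step: tames the steep LJ
        // core on rare deep collisions without touching thermal statistics
        double drift = F[i + d * n] * mob;
        if (drift > 0.3) drift = 0.3; else if (drift < -0.3) drift = -0.3;
        double dx = drift;
        if (amp > 0.0) dx += amp * norm_rand();
        X[i + d * n] += dx;
      }
      // wrap x, y into the primary image
      if (P.Lx > 0.0) X[i] = mimg(X[i], P.Lx);
      if (P.Ly > 0.0) X[i + n] = mimg(X[i + n], P.Ly);
    }
    if (step % 128 == 0) {
      for (int i = 0; i < n; ++i) {
        if (std::fabs(X[i]) > esc_x || std::fabs(X[i + 2 * n]) > esc_z ||
            !std::isfinite(X[i]) || !std::isfinite(X[i + 2 * n]))
          stop("simulation unstable at step %d (atom %d escaped the box); use a smaller timestep",
               step, i + 1);
      }
    }
    if (step % save_every == 0 && isave < std::max(nsave, 1)) {
      std::copy(X.begin(), X.end(), frames.begin() + (size_t)isave * 3 * n);
      times[isave] = t0 + step * dt;
      ++isave;
    }
  }
  if (isave == 0) { // nsteps < save_every: keep the final configuration
    std::copy(X.begin(), X.end(), frames.begin());
    times[0] = t0 + nsteps * dt;
    isave = 1;
  }
  frames.attr("dim") = IntegerVector::create(n, 3, std::max(nsave, 1));
  NumericMatrix Xf(n, 3);
  std::copy(X.begin(), X.end(), Xf.begin());
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["final"] = Xf, _["n_saved"] = isave);
}
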