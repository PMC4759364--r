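// Coarse-grained hairpin model: internal-coordinate chain building (NeRF),
// the census-derived well energy, and the Metropolis torsion-space sweep.
// Coordinates in nm, angles in degrees at the interface, reduced energy
// units (kB = 1). All randomness comes from R's RNG so set.seed() governs.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// backbone geometry (nm / degrees)
static const double B_N_CA = 0.1458, B_CA_C = 0.1525, B_C_N = 0.1329;
static const double B_C_O = 0.1231, B_N_H = 0.101, B_CA_CB = 0.153;
static const double A_N_CA_C = 111.0, A_CA_C_N = 116.2, A_C_N_CA = 121.7;
static const double A_CA_C_O = 120.8;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double norm3(const double* a) {
  return std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
}

static inline void unit3(double* a) {
  double n = norm3(a);
  for (int k = 0; k < 3; ++k) a[k] /= n;
}

// Place D bonded to C with |CD| = r, angle B-C-D = theta and dihedral
// A-B-C-D = chi (natural extension of reference frame, NeRF).
static void nerf(const double* A, const double* B, const double* C,
                 double r, double theta_deg, double chi_deg, double* D) {
  double th = theta_deg * DEG, chi = chi_deg * DEG;
  double ab[3], bc[3], n[3], m[3];
  for (int k = 0; k < 3; ++k) { ab[k] = B[k] - A[k]; bc[k] = C[k] - B[k]; }
  unit3(bc);
  cross3(ab, bc, n); unit3(n);
  cross3(n, bc, m);
  double d0 = -r * std::cos(th);
  double d1 = r * std::sin(th) * std::cos(chi);
  double d2 = -r * std::sin(th) * std::sin(chi);
  for (int k = 0; k < 3; ++k) D[k] = C[k] + d0 * bc[k] + d1 * m[k] + d2 * n[k];
}

// Build the full chain. Index vectors are 1-based positions into the atom
// table (0 = atom absent for this residue).
static void build_core(int L, const double* phi, const double* psi,
                       const int* iN, const int* iH, const int* iCA,
                       const int* iC, const int* iO, const int* iCB,
                       double* X /* natoms x 3, column-major */,
                       int natoms) {
  double (*row)[1] = nullptr; (void)row;
  #define XP(idx, k) X[(idx) - 1 + natoms * (k)]
  double N[3], CA[3], C[3], prevN[3], prevCA[3], prevC[3];
  // residue 1
  N[0] = 0; N[1] = 0; N[2] = 0;
  CA[0] = B_N_CA; CA[1] = 0; CA[2] = 0;
  double a = A_N_CA_C * DEG;
  C[0] = CA[0] - B_CA_C * std::cos(a);
  C[1] = B_CA_C * std::sin(a);
  C[2] = 0;
  for (int i = 0; i < L; ++i) {
    if (i > 0) {
      for (int k = 0; k < 3; ++k) {
        prevN[k] = N[k]; prevCA[k] = CA[k]; prevC[k] = C[k];
      }
      nerf(prevN, prevCA, prevC, B_C_N, A_CA_C_N, psi[i - 1], N);
      nerf(prevCA, prevC, N, B_N_CA, A_C_N_CA, 180.0, CA);
      nerf(prevC, N, CA, B_CA_C, A_N_CA_C, phi[i], C);
    }
    for (int k = 0; k < 3; ++k) {
      XP(iN[i], k) = N[k]; XP(iCA[i], k) = CA[k]; XP(iC[i], k) = C[k];
    }
    // carbonyl O: anti to the next amide nitrogen
    double O[3];
    nerf(N, CA, C, B_C_O, A_CA_C_O, psi[i] + 180.0, O);
    for (int k = 0; k < 3; ++k) XP(iO[i], k) = O[k];
    // amide H: along the bisector opposing C(prev) and CA
    if (iH[i] > 0 && i > 0) {
      double u1[3], u2[3], dir[3];
      for (int k = 0; k < 3; ++k) {
        u1[k] = N[k] - prevC[k];
        u2[k] = N[k] - CA[k];
      }
      unit3(u1); unit3(u2);
      for (int k = 0; k < 3; ++k) dir[k] = u1[k] + u2[k];
      unit3(dir);
      for (int k = 0; k < 3; ++k) XP(iH[i], k) = N[k] + B_N_H * dir[k];
    }
    // CB pseudo-atom: tetrahedral, out of the N-CA-C plane
    if (iCB[i] > 0) {
      double u[3], v[3], w[3], x[3];
      for (int k = 0; k < 3; ++k) {
        u[k] = N[k] - CA[k];
        v[k] = C[k] - CA[k];
      }
      unit3(u); unit3(v);
      for (int k = 0; k < 3; ++k) w[k] = u[k] + v[k];
      unit3(w);
      cross3(u, v, x); unit3(x);
      const double c1 = std::sqrt(1.0 / 3.0), c2 = std::sqrt(2.0 / 3.0);
      for (int k = 0; k < 3; ++k) {
        XP(iCB[i], k) = CA[k] + B_CA_CB * (-c1 * w[k] - c2 * x[k]);
      }
    }
  }
  #undef XP
}

// [[Rcpp::export]]
NumericMatrix cpp_build_chain(NumericVector phi, NumericVector psi,
                              IntegerVector iN, IntegerVector iH,
                              IntegerVector iCA, IntegerVector iC,
                              IntegerVector iO, IntegerVector iCB,
                              int natoms) {
  int L = phi.size();
  NumericMatrix X(natoms, 3);
  build_core(L, phi.begin(), psi.begin(), iN.begin(), iH.begin(),
             iCA.begin(), iC.begin(), iO.begin(), iCB.begin(),
             X.begin(), natoms);
  return X;
}

// Toy energy: bounded Gaussian attraction wells + soft-sphere repulsion on
// a reduced atom set + cosine torsion bias toward reference angles.
static double toy_energy_core(
    const double* X, int natoms,
    const double* wells, int nwells,      // columns: i, j, w, r0, sigma
    const int* rep_idx, const int* rep_res, int nrep,
    double r_ev, double k_rep,
    const double* phi, const double* psi,
    const double* phi0, const double* psi0,
    const double* w_tor, int L) {
  double E = 0.0;
  for (int q = 0; q < nwells; ++q) {
    int i = (int)wells[q] - 1;
    int j = (int)wells[q + nwells] - 1;
    double w = wells[q + 2 * nwells];
    double r0 = wells[q + 3 * nwells];
    double sg = wells[q + 4 * nwells];
    double dx = X[i] - X[j];
    double dy = X[i + natoms] - X[j + natoms];
    double dz = X[i + 2 * natoms] - X[j + 2 * natoms];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double z = (d - r0) / sg;
    if (z * z < 36.0) E -= w * std::exp(-z * z);
  }
  for (int a = 0; a < nrep; ++a) {
    for (int b = a + 1; b < nrep; ++b) {
      if (std::abs(rep_res[a] - rep_res[b]) <= 2) continue;
      int i = rep_idx[a] - 1, j = rep_idx[b] - 1;
      double dx = X[i] - X[j];
      double dy = X[i + natoms] - X[j + natoms];
      double dz = X[i + 2 * natoms] - X[j + 2 * natoms];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < r_ev * r_ev) {
        double d = std::sqrt(d2);
        double t = 1.0 - d / r_ev;
        E += k_rep * t * t;
      }
    }
  }
  for (int i = 0; i < L; ++i) {
    E += w_tor[i] * ((1.0 - std::cos((phi[i] - phi0[i]) * DEG)) +
                     (1.0 - std::cos((psi[i] - psi0[i]) * DEG)));
  }
  return E;
}

// [[Rcpp::export]]
double cpp_toy_energy(NumericMatrix X, NumericMatrix wells,
                      IntegerVector rep_idx, IntegerVector rep_res,
                      double r_ev, double k_rep,
                      NumericVector phi, NumericVector psi,
                      NumericVector phi0, NumericVector psi0,
                      NumericVector w_tor) {
  return toy_energy_core(X.begin(), X.nrow(), wells.begin(), wells.nrow(),
                         rep_idx.begin(), rep_res.begin(), rep_idx.size(),
                         r_ev, k_rep, phi.begin(), psi.begin(),
                         phi0.begin(), psi0.begin(), w_tor.begin(),
                         phi.size());
}

static inline double wrap_deg(double x) {
  while (x > 180.0) x -= 360.0;
  while (x <= -180.0) x += 360.0;
  return x;
}

// One Metropolis segment: n_sweeps sweeps of L proposed torsion moves
// (single-angle perturbation or crankshaft phi_u += d, psi_u -= d),
// full-chain rebuild per proposal, acceptance min(1, exp(-dE/T)).
// Snapshots (coordinates + energy) every save_stride sweeps.
// [[Rcpp::export]]
List cpp_mc_segment(NumericVector phi_in, NumericVector psi_in,
                    IntegerVector iN, IntegerVector iH, IntegerVector iCA,
                    IntegerVector iC, IntegerVector iO, IntegerVector iCB,
                    int natoms, NumericMatrix wells,
                    IntegerVector rep_idx, IntegerVector rep_res,
                    double r_ev, double k_rep,
                    NumericVector phi0, NumericVector psi0,
                    NumericVector w_tor,
                    double temperature, int n_sweeps, int save_stride,
                    double max_step_deg, double p_crank) {
  int L = phi_in.size();
  std::vector<double> phi(phi_in.begin(), phi_in.end());
  std::vector<double> psi(psi_in.begin(), psi_in.end());
  std::vector<double> X(natoms * 3), Xnew(natoms * 3);
  build_core(L, phi.data(), psi.data(), iN.begin(), iH.begin(), iCA.begin(),
             iC.begin(), iO.begin(), iCB.begin(), X.data(), natoms);
  double E = toy_energy_core(X.data(), natoms, wells.begin(), wells.nrow(),
                             rep_idx.begin(), rep_res.begin(),
                             rep_idx.size(), r_ev, k_rep, phi.data(),
                             psi.data(), phi0.begin(), psi0.begin(),
                             w_tor.begin(), L);
  int n_save = (save_stride > 0) ? n_sweeps / save_stride : 0;
  NumericVector frames(n_save > 0 ? (R_xlen_t)natoms * 3 * n_save : 0);
  NumericVector saved_E(n_save);
  long n_acc = 0, n_moves = 0;
  int isave = 0;
  for (int sw = 1; sw <= n_sweeps; ++sw) {
    for (int mv = 0; mv < L; ++mv) {
      int u = (int)(unif_rand() * L);
      if (u >= L) u = L - 1;
      bool crank = unif_rand() < p_crank;
      double delta = (2.0 * unif_rand() - 1.0) * max_step_deg;
      double old_phi = phi[u], old_psi = psi[u];
      if (crank) {
        phi[u] = wrap_deg(phi[u] + delta);
        psi[u] = wrap_deg(psi[u] - delta);
      } else if (unif_rand() < 0.5) {
        phi[u] = wrap_deg(phi[u] + delta);
      } else {
        psi[u] = wrap_deg(psi[u] + delta);
      }
      build_core(L, phi.data(), psi.data(), iN.begin(), iH.begin(),
                 iCA.begin(), iC.begin(), iO.begin(), iCB.begin(),
                 Xnew.data(), natoms);
      double Enew = toy_energy_core(Xnew.data(), natoms, wells.begin(),
                                    wells.nrow(), rep_idx.begin(),
                                    rep_res.begin(), rep_idx.size(), r_ev,
                                    k_rep, phi.data(), psi.data(),
                                    phi0.begin(), psi0.begin(),
                                    w_tor.begin(), L);
      ++n_moves;
      bool accept = (Enew <= E) ||
        (unif_rand() < std::exp(-(Enew - E) / temperature));
      if (accept) {
        E = Enew;
        std::swap(X, Xnew);
        ++n_acc;
      } else {
        phi[u] = old_phi; psi[u] = old_psi;
      }
    }
    if (save_stride > 0 && sw % save_stride == 0 && isave < n_save) {
      std::copy(X.begin(), X.end(),
                frames.begin() + (R_xlen_t)isave * natoms * 3);
      saved_E[isave] = E;
      ++isave;
    }
  }
  if (n_save > 0) frames.attr("dim") = IntegerVector::create(natoms, 3, n_save);
  return List::create(
    _["phi"] = NumericVector(phi.begin(), phi.end()),
    _["psi"] = NumericVector(psi.begin(), psi.end()),
    _["energy"] = E,
    _["n_accept"] = (double)n_acc,
    _["n_moves"] = (double)n_moves,
    _["frames"] = frames,
    _["frame_energies"] = saved_E);
}
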