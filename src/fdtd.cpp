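// 2D TMz FDTD with single-pole Debye dispersion (auxiliary differential
// equation) plus static conductivity, terminated by convolutional PML.
// Grids arrive padded: the caller replicates the phantom edges npml cells
// outward so the PML is filled with the adjacent medium.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double EPS0 = 8.8541878128e-12;
static const double MU0  = 1.25663706212e-6;

// Polarization update:  P^{n+1} = a P^n + b (E^{n+1} + E^n)
//   a = (2 tau - dt) / (2 tau + dt),  b = eps0 deps dt / (2 tau + dt)
// Ampere (semi-implicit conduction):
//   E^{n+1} = cE * E^n + cP * P^n + cC * curlH
// with A = eps0 epsinf / dt, B = b/dt + sigma/2,
//   cE = (A - B)/(A + B), cP = (1 - a)/(dt (A + B)), cC = 1/(A + B).

// [[Rcpp::export]]
NumericVector fdtd_run_cpp(NumericMatrix eps_inf, NumericMatrix delta_eps,
                           NumericMatrix sigma_s, NumericMatrix tau,
                           double dx, double dt, int nsteps, int npml,
                           int src_i, int src_j, NumericVector pulse,
                           int rec_i = -1, int rec_j = -1,
                           double abort_threshold = 1e30) {
  const int nd = eps_inf.nrow();   // depth cells (i)
  const int nl = eps_inf.ncol();   // lateral cells (j)
  const int N  = nd * nl;
  std::vector<double> Ez(N, 0.0), P(N, 0.0);
  std::vector<double> Hx(N, 0.0), Hy(N, 0.0);          // Hx at (i+1/2, j), Hy at (i, j+1/2)
  std::vector<double> cE(N), cP(N), cC(N), pa(N), pb(N);

  for (int j = 0; j < nl; ++j)
    for (int i = 0; i < nd; ++i) {
      const int k = i + nd * j;
      const double t  = tau(i, j);
      const double a  = (2.0 * t - dt) / (2.0 * t + dt);
      const double b  = EPS0 * delta_eps(i, j) * dt / (2.0 * t + dt);
      const double A  = EPS0 * eps_inf(i, j) / dt;
      const double B  = b / dt + 0.5 * sigma_s(i, j);
      pa[k] = a;
      pb[k] = b;
      cE[k] = (A - B) / (A + B);
      cP[k] = (1.0 - a) / (dt * (A + B));
      cC[k] = 1.0 / (A + B);
    }

  // CPML profiles (Roden & Gedney), polynomial grading m = 3.
  const int m = 3;
  const double sig_max = 0.8 * (m + 1) / (std::sqrt(MU0 / EPS0) * dx);
  const double kap_max = 5.0, alp_max = 0.05;
  // Profiles indexed by distance into the PML measured in cells; E nodes at
  // integer positions, H nodes offset by one half cell.
  auto prof = [&](double d, double L, double& bcoef, double& ccoef) {
    if (d < 0) { bcoef = 1.0; ccoef = 0.0; return; }
    const double x = d / L;
    const double sg = sig_max * std::pow(x, m);
    const double kp = 1.0 + (kap_max - 1.0) * std::pow(x, m);
    const double al = alp_max * (1.0 - x);
    bcoef = std::exp(-(sg / kp + al) * dt / EPS0);
    ccoef = (sg == 0.0 && al == 0.0) ? 0.0
          : sg * (bcoef - 1.0) / ((sg + kp * al) * kp);
  };
  // kappa stored separately for the stretched-coordinate division
  auto kappa_of = [&](double d, double L) {
    if (d < 0) return 1.0;
    return 1.0 + (kap_max - 1.0) * std::pow(d / L, m);
  };
  const double L = (double)npml;

  std::vector<double> bEi(nd), cEi(nd), kEi(nd);  // depth profile at E nodes
  std::vector<double> bHi(nd), cHi(nd), kHi(nd);  // depth profile at H (i+1/2)
  std::vector<double> bEj(nl), cEj(nl), kEj(nl);
  std::vector<double> bHj(nl), cHj(nl), kHj(nl);
  for (int i = 0; i < nd; ++i) {
    double dE = std::max((double)(npml - i), (double)(i - (nd - 1 - npml)));
    double dH = std::max((double)(npml - i) - 0.5, (double)(i + 0.5 - (nd - 1 - npml)));
    prof(dE, L, bEi[i], cEi[i]); kEi[i] = kappa_of(dE, L);
    prof(dH, L, bHi[i], cHi[i]); kHi[i] = kappa_of(dH, L);
  }
  for (int j = 0; j < nl; ++j) {
    double dE = std::max((double)(npml - j), (double)(j - (nl - 1 - npml)));
    double dH = std::max((double)(npml - j) - 0.5, (double)(j + 0.5 - (nl - 1 - npml)));
    prof(dE, L, bEj[j], cEj[j]); kEj[j] = kappa_of(dE, L);
    prof(dH, L, bHj[j], cHj[j]); kHj[j] = kappa_of(dH, L);
  }

  // CPML memory fields (allocated over the full grid for simplicity; the
  // recursion is a no-op where c = 0)
  std::vector<double> psiHxy(N, 0.0), psiHyx(N, 0.0), psiEzx(N, 0.0), psiEzy(N, 0.0);

  NumericVector rec(nsteps);
  const double dtm = dt / MU0;
  const int ksrc = src_i + nd * src_j;
  const int krec = (rec_i < 0 || rec_j < 0) ? ksrc : (rec_i + nd * rec_j);

  for (int n = 0; n < nsteps; ++n) {
    // H updates
    for (int j = 0; j < nl; ++j) {
      const int off = nd * j;
      for (int i = 0; i < nd - 1; ++i) {
        const int k = i + off;
        const double dEzy = (Ez[k + 1] - Ez[k]) / dx;
        psiHxy[k] = bHi[i] * psiHxy[k] + cHi[i] * dEzy;
        Hx[k] -= dtm * (dEzy / kHi[i] + psiHxy[k]);
      }
    }
    for (int j = 0; j < nl - 1; ++j) {
      const int off = nd * j;
      for (int i = 0; i < nd; ++i) {
        const int k = i + off;
        const double dEzx = (Ez[k + nd] - Ez[k]) / dx;
        psiHyx[k] = bHj[j] * psiHyx[k] + cHj[j] * dEzx;
        Hy[k] += dtm * (dEzx / kHj[j] + psiHyx[k]);
      }
    }
    // E update (interior nodes; outermost ring stays PEC-backed at zero)
    for (int j = 1; j < nl - 1; ++j) {
      const int off = nd * j;
      for (int i = 1; i < nd - 1; ++i) {
        const int k = i + off;
        const double dHyx = (Hy[k] - Hy[k - nd]) / dx;
        const double dHxy = (Hx[k] - Hx[k - 1]) / dx;
        psiEzx[k] = bEj[j] * psiEzx[k] + cEj[j] * dHyx;
        psiEzy[k] = bEi[i] * psiEzy[k] + cEi[i] * dHxy;
        const double curl = dHyx / kEj[j] + psiEzx[k] - dHxy / kEi[i] - psiEzy[k];
        const double Eold = Ez[k];
        const double Enew = cE[k] * Eold + cP[k] * P[k] + cC[k] * curl;
        P[k] = pa[k] * P[k] + pb[k] * (Enew + Eold);
        Ez[k] = Enew;
      }
    }
    // soft source
    Ez[ksrc] += pulse[n];
    rec[n] = Ez[krec];
    if (!(std::abs(rec[n]) < abort_threshold))
      stop("FDTD instability detected at step %d (|Ez| = %g)", n, rec[n]);
  }
  return rec;
}
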