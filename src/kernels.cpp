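// Numerical kernels: Abeles matrix reflectivity, Gaussian dq/q resolution
// smearing, erf-smeared step profiles, the multi-contrast score and the
// simulated-annealing loop. The annealing evaluates the full score
// O(1e5-1e6) times per run, hence compiled code.

#include <Rcpp.h>
#include <complex>
#include <cmath>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

// FWHM of a Gaussian = 2 sqrt(2 ln 2) * sd
static const double FWHM_TO_SD = 2.3548200450309493;

// principal square root with non-negative imaginary part so evanescent
// waves decay into the medium
static inline cplx branch_sqrt(double x) {
  if (x >= 0.0) return cplx(std::sqrt(x), 0.0);
  return cplx(0.0, std::sqrt(-x));
}

// ---------------------------------------------------------------------------
// Abeles recursion. th: interior layer thicknesses (length L, may be 0);
// sld: L+2 values fronting..backing; rough: L+1 interfacial widths (>= 0).
// k_n = sqrt(q^2/4 - 4 pi (sld_n - sld_fronting)).
// Interface matrix (phase of layer n folded in):
//   [[ e^{i b_n},  r e^{i b_n} ], [ r e^{-i b_n}, e^{-i b_n} ]],  b_0 = 0,
// R = |M21 / M11|^2.
// ---------------------------------------------------------------------------
static double abeles_one(double q,
                         const std::vector<double>& th,
                         const std::vector<double>& sld,
                         const std::vector<double>& rough,
                         std::vector<cplx>& k /* scratch, size L+2 */) {
  const size_t nmed = sld.size();
  const double q24 = 0.25 * q * q;
  for (size_t n = 0; n < nmed; ++n)
    k[n] = branch_sqrt(q24 - 4.0 * M_PI * (sld[n] - sld[0]));

  cplx M11(1.0, 0.0), M12(0.0, 0.0), M21(0.0, 0.0), M22(1.0, 0.0);
  for (size_t n = 0; n + 1 < nmed; ++n) {
    cplx ksum = k[n] + k[n + 1];
    cplx r = (std::abs(ksum) == 0.0) ? cplx(0.0, 0.0)
                                     : (k[n] - k[n + 1]) / ksum;
    if (rough[n] > 0.0)
      r *= std::exp(-2.0 * k[n] * k[n + 1] * rough[n] * rough[n]);
    cplx eb(1.0, 0.0), ebi(1.0, 0.0);
    if (n > 0) {
      cplx ib = cplx(0.0, 1.0) * k[n] * th[n - 1];
      eb = std::exp(ib);
      ebi = 1.0 / eb;
    }
    const cplx A11 = eb, A12 = r * eb, A21 = r * ebi, A22 = ebi;
    const cplx N11 = M11 * A11 + M12 * A21;
    const cplx N12 = M11 * A12 + M12 * A22;
    const cplx N21 = M21 * A11 + M22 * A21;
    const cplx N22 = M21 * A12 + M22 * A22;
    M11 = N11; M12 = N12; M21 = N21; M22 = N22;
  }
  return std::norm(M21 / M11);
}

// [[Rcpp::export]]
NumericVector abeles_cpp(NumericVector q, NumericVector thickness,
                         NumericVector sld, NumericVector roughness,
                         bool clamp_unit = true) {
  const int L = thickness.size();
  if (sld.size() != L + 2) stop("sld must have length(thickness) + 2 values");
  if (roughness.size() != L + 1) stop("roughness must have length(thickness) + 1 values");
  std::vector<double> th(thickness.begin(), thickness.end());
  std::vector<double> sl(sld.begin(), sld.end());
  std::vector<double> ro(roughness.begin(), roughness.end());
  std::vector<cplx> k(L + 2);
  NumericVector out(q.size());
  for (int i = 0; i < q.size(); ++i) {
    double R = abeles_one(q[i], th, sl, ro, k);
    if (clamp_unit) {
      if (R > 1.0) R = 1.0;
      if (R < 0.0) R = 0.0;
    }
    out[i] = R;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Gaussian resolution smearing: p-point average spanning +/- 2.5 sd of a
// Gaussian with FWHM = dq/q * q, values taken from the tabulated curve by
// linear interpolation (clamped at the ends). dqq may be scalar or per-point.
// ---------------------------------------------------------------------------
static double interp_clamped(const std::vector<double>& x,
                             const std::vector<double>& y, double xq) {
  const int n = (int)x.size();
  if (xq <= x[0]) return y[0];
  if (xq >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= xq) lo = mid; else hi = mid;
  }
  const double t = (xq - x[lo]) / (x[hi] - x[lo]);
  return y[lo] * (1.0 - t) + y[hi] * t;
}

static void smear_core(const std::vector<double>& q,
                       const std::vector<double>& R,
                       const std::vector<double>& dqq, int p,
                       std::vector<double>& out) {
  const int n = (int)q.size();
  const double span = 2.5;
  // offsets and weights in units of sd are the same for every point
  std::vector<double> xs(p), w(p);
  double wsum = 0.0;
  for (int a = 0; a < p; ++a) {
    xs[a] = -span + 2.0 * span * a / (p - 1.0);
    w[a] = std::exp(-0.5 * xs[a] * xs[a]);
    wsum += w[a];
  }
  for (int a = 0; a < p; ++a) w[a] /= wsum;
  for (int j = 0; j < n; ++j) {
    const double f = dqq.size() == 1 ? dqq[0] : dqq[j];
    if (f <= 0.0) { out[j] = R[j]; continue; }
    const double sd = f * q[j] / FWHM_TO_SD;
    double acc = 0.0;
    for (int a = 0; a < p; ++a)
      acc += w[a] * interp_clamped(q, R, q[j] + xs[a] * sd);
    out[j] = acc;
  }
}

// [[Rcpp::export]]
NumericVector smear_cpp(NumericVector q, NumericVector R, NumericVector dq_over_q,
                        int p) {
  if (p < 3 || p % 2 == 0) stop("p must be an odd integer >= 3");
  std::vector<double> qv(q.begin(), q.end()), Rv(R.begin(), R.end());
  std::vector<double> fv(dq_over_q.begin(), dq_over_q.end());
  std::vector<double> out(qv.size());
  smear_core(qv, Rv, fv, p, out);
  return NumericVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// erf-smeared step profile: plateau v[0] before the first boundary, value
// v[j+1] after boundary zb[j]; every boundary blended with the same width
// sigma. Terms with |z - zb| > 7.5 sigma are treated as full steps.
// ---------------------------------------------------------------------------
static inline double erf_blend(double x) { return 0.5 * (1.0 + std::erf(x)); }

// [[Rcpp::export]]
NumericVector erf_profile_cpp(NumericVector z, NumericVector zb,
                              NumericVector v, NumericVector sigma) {
  const int nz = z.size(), nb = zb.size();
  if (v.size() != nb + 1) stop("v must have length(zb) + 1 values");
  if (sigma.size() != 1 && sigma.size() != nb)
    stop("sigma must be scalar or one value per boundary");
  NumericVector out(nz);
  for (int i = 0; i < nz; ++i) {
    double val = v[0];
    for (int j = 0; j < nb; ++j) {
      const double dv = v[j + 1] - v[j];
      if (dv == 0.0) continue;
      const double s = sigma.size() == 1 ? sigma[0] : sigma[j];
      const double dz = z[i] - zb[j];
      if (s <= 1e-12) {
        if (dz >= 0.0) val += dv;
      } else if (dz > 7.5 * s) {
        val += dv;
      } else if (dz >= -7.5 * s) {
        val += dv * erf_blend(dz / (s * M_SQRT2));
      }
    }
    out[i] = val;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Multi-contrast score (the annealing objective):
//   f = (1/M_c) sum_c [ mean_j ((y_e - y_t)/<y_e>)^2 + mean_j (ln R_e - ln R_t)^2 ]
// with y = q^4 R and <.> the per-curve mean of the experimental q^4 R.
// ---------------------------------------------------------------------------
struct ContrastData {
  std::vector<double> q, Rexp, logRexp, yexp, q4;
  double norm, rho0, rhos, dqq;
  int p;
  std::vector<double> Rth, Rsm, dqqv;
  // precomputed smearing stencil: p (index, two weights) triplets per point
  std::vector<int> sm_idx;
  std::vector<double> sm_wlo, sm_whi;
};

struct ScoreWork {
  int N, npad, nslab;
  double D, d;
  std::vector<ContrastData> cs;
  // scratch
  std::vector<double> zc, comp, th, slds, rough;
  std::vector<cplx> k;

  void init(List contrasts, double D_, int N_, int npad_) {
    D = D_; N = N_; npad = npad_;
    d = D / N;
    nslab = N + 2 * npad;
    zc.resize(nslab);
    for (int i = 0; i < nslab; ++i) zc[i] = -npad * d + d / 2.0 + i * d;
    comp.resize(nslab);
    th.assign(nslab, d);
    slds.resize(nslab + 2);
    rough.assign(nslab + 1, 0.0);
    k.resize(nslab + 2);
    const int M = contrasts.size();
    cs.resize(M);
    for (int c = 0; c < M; ++c) {
      List ci = contrasts[c];
      NumericVector q = ci["q"], R = ci["R"];
      cs[c].q.assign(q.begin(), q.end());
      cs[c].Rexp.assign(R.begin(), R.end());
      cs[c].rho0 = as<double>(ci["rho_fronting"]);
      cs[c].rhos = as<double>(ci["rho_solvent"]);
      cs[c].dqq = as<double>(ci["dq_over_q"]);
      cs[c].p = ci.containsElementNamed("p") ? as<int>(ci["p"]) : 17;
      const int n = (int)cs[c].q.size();
      cs[c].logRexp.resize(n);
      cs[c].yexp.resize(n);
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        const double q4 = std::pow(cs[c].q[j], 4);
        cs[c].yexp[j] = q4 * cs[c].Rexp[j];
        cs[c].logRexp[j] = std::log(cs[c].Rexp[j]);
        s += cs[c].yexp[j];
      }
      cs[c].norm = s / n;
      cs[c].Rth.resize(n);
      cs[c].Rsm.resize(n);
      cs[c].dqqv.assign(1, cs[c].dqq);
      cs[c].q4.resize(n);
      for (int j = 0; j < n; ++j) cs[c].q4[j] = std::pow(cs[c].q[j], 4);
      // smearing stencil (the q grid never changes during a run)
      const int p = cs[c].p;
      cs[c].sm_idx.resize((size_t)n * p);
      cs[c].sm_wlo.resize((size_t)n * p);
      cs[c].sm_whi.resize((size_t)n * p);
      const double span = 2.5;
      std::vector<double> xs(p), w(p);
      double wsum = 0.0;
      for (int a = 0; a < p; ++a) {
        xs[a] = -span + 2.0 * span * a / (p - 1.0);
        w[a] = std::exp(-0.5 * xs[a] * xs[a]);
        wsum += w[a];
      }
      for (int a = 0; a < p; ++a) w[a] /= wsum;
      for (int j = 0; j < n; ++j) {
        const double sd = cs[c].dqq * cs[c].q[j] / FWHM_TO_SD;
        for (int a = 0; a < p; ++a) {
          const size_t o = (size_t)j * p + a;
          const double qx = cs[c].q[j] + xs[a] * sd;
          if (cs[c].dqq <= 0.0) {  // identity: keep the point itself
            if (j < n - 1) {
              cs[c].sm_idx[o] = j; cs[c].sm_wlo[o] = w[a]; cs[c].sm_whi[o] = 0.0;
            } else {
              cs[c].sm_idx[o] = j - 1; cs[c].sm_wlo[o] = 0.0; cs[c].sm_whi[o] = w[a];
            }
          } else if (qx <= cs[c].q[0]) {
            cs[c].sm_idx[o] = 0; cs[c].sm_wlo[o] = w[a]; cs[c].sm_whi[o] = 0.0;
          } else if (qx >= cs[c].q[n - 1]) {
            cs[c].sm_idx[o] = n - 2; cs[c].sm_wlo[o] = 0.0; cs[c].sm_whi[o] = w[a];
          } else {
            int lo = 0, hi = n - 1;
            while (hi - lo > 1) {
              int mid = (lo + hi) / 2;
              if (cs[c].q[mid] <= qx) lo = mid; else hi = mid;
            }
            const double t = (qx - cs[c].q[lo]) / (cs[c].q[hi] - cs[c].q[lo]);
            cs[c].sm_idx[o] = lo;
            cs[c].sm_wlo[o] = w[a] * (1.0 - t);
            cs[c].sm_whi[o] = w[a] * t;
          }
        }
      }
    }
  }

  // composite SLD on the slab grid for contrast c, given profile parameters
  void composite(const std::vector<double>& rho, const std::vector<double>& h,
                 double sigma, const ContrastData& c) {
    // steps at z = 0, d, ..., N d; hydration plateaus 0 -> 1,
    // non-solvent SLD plateaus rho0 -> rho_solvent
    const double w = 7.5 * sigma;
    for (int i = 0; i < nslab; ++i) {
      const double z = zc[i];
      // boundaries j = 0..N at z_j = j d; value after boundary j is layer j+1
      int jlo = (int)std::ceil((z - w) / d);
      int jhi = (int)std::floor((z + w) / d);
      if (jlo < 0) jlo = 0;
      if (jhi > N) jhi = N;
      double vr, vh;
      if (jlo > N) { vr = c.rhos; vh = 1.0; }       // past every boundary
      else {
        // plateau below boundary jlo: layer index jlo (0 = fronting)
        vr = (jlo == 0) ? c.rho0 : rho[jlo - 1];
        vh = (jlo == 0) ? 0.0 : h[jlo - 1];
        if (jhi >= jlo) {
          for (int j = jlo; j <= jhi; ++j) {
            const double rlo = (j == 0) ? c.rho0 : rho[j - 1];
            const double rhi = (j == N) ? c.rhos : rho[j];
            const double hlo = (j == 0) ? 0.0 : h[j - 1];
            const double hhi = (j == N) ? 1.0 : h[j];
            // profile convention: erf((z - nd)/sigma); sigma is sqrt(2)
            // times the equivalent Gaussian interface width
            const double g = erf_blend((z - j * d) / sigma);
            vr += (rhi - rlo) * g;
            vh += (hhi - hlo) * g;
          }
        }
      }
      comp[i] = vr * (1.0 - vh) + vh * c.rhos;
    }
  }

  // sharp-stack reflectivity on the equal-thickness slab grid via the
  // Parratt recursion (algebraically identical to the matrix product for
  // sharp interfaces, ~40% cheaper); exp/sincos skipped where the
  // wavevector is purely real or purely imaginary
  double abeles_fast(double q) {
    const double q24 = 0.25 * q * q;
    const int nmed = nslab + 2;
    for (int n = 0; n < nmed; ++n)
      k[n] = branch_sqrt(q24 - 4.0 * M_PI * (slds[n] - slds[0]));
    // hand-rolled complex arithmetic (no IEC-559 edge handling needed:
    // all quantities stay finite and the denominators are >= 1 - |f||rp|)
    double rr = 0.0, ri = 0.0;
    for (int n = nmed - 2; n >= 0; --n) {
      const double sr = k[n].real() + k[n + 1].real();
      const double si = k[n].imag() + k[n + 1].imag();
      const double dr = k[n].real() - k[n + 1].real();
      const double di = k[n].imag() - k[n + 1].imag();
      const double sn = sr * sr + si * si;
      double fr = 0.0, fi = 0.0;
      if (sn > 0.0) {  // f = (k_n - k_{n+1}) / (k_n + k_{n+1})
        fr = (dr * sr + di * si) / sn;
        fi = (di * sr - dr * si) / sn;
      }
      if (n < nmed - 2) {
        // phase of layer n+1: exp(2 i k d)
        const double a = 2.0 * k[n + 1].real() * d;
        const double b = 2.0 * k[n + 1].imag() * d;
        double pr, pi;
        if (b == 0.0) { pr = std::cos(a); pi = std::sin(a); }
        else if (a == 0.0) { pr = std::exp(-b); pi = 0.0; }
        else {
          const double em = std::exp(-b);
          pr = em * std::cos(a); pi = em * std::sin(a);
        }
        const double rpr = rr * pr - ri * pi;
        const double rpi = rr * pi + ri * pr;
        const double nr = fr + rpr, ni = fi + rpi;          // numerator
        const double er = 1.0 + fr * rpr - fi * rpi;        // denominator
        const double ei = fr * rpi + fi * rpr;
        const double en = er * er + ei * ei;
        rr = (nr * er + ni * ei) / en;
        ri = (ni * er - nr * ei) / en;
      } else {
        rr = fr; ri = fi;
      }
    }
    const double R = rr * rr + ri * ri;
    return R > 1.0 ? 1.0 : R;
  }

  double score(const std::vector<double>& rho, const std::vector<double>& h,
               double sigma) {
    double f = 0.0;
    for (size_t ic = 0; ic < cs.size(); ++ic) {
      ContrastData& c = cs[ic];
      composite(rho, h, sigma, c);
      slds[0] = c.rho0;
      for (int i = 0; i < nslab; ++i) slds[i + 1] = comp[i];
      slds[nslab + 1] = c.rhos;
      const int n = (int)c.q.size();
      for (int j = 0; j < n; ++j) c.Rth[j] = abeles_fast(c.q[j]);
      const int p = c.p;
      double t1 = 0.0, t2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        const size_t o0 = (size_t)j * p;
        for (int a = 0; a < p; ++a) {
          const size_t o = o0 + a;
          const int lo = c.sm_idx[o];
          acc += c.sm_wlo[o] * c.Rth[lo] + c.sm_whi[o] * c.Rth[lo + 1];
        }
        const double Rt = acc > 1e-300 ? acc : 1e-300;
        const double dy = (c.yexp[j] - c.q4[j] * Rt) / c.norm;
        const double dl = c.logRexp[j] - std::log(Rt);
        t1 += dy * dy;
        t2 += dl * dl;
      }
      f += (t1 + t2) / n;
    }
    return f / cs.size();
  }
};

// [[Rcpp::export]]
double score_cpp(NumericVector rho, NumericVector h, double sigma, double D,
                 int npad, List contrasts) {
  ScoreWork wk;
  wk.init(contrasts, D, rho.size(), npad);
  std::vector<double> r(rho.begin(), rho.end()), hh(h.begin(), h.end());
  return wk.score(r, hh, sigma);
}

// ---------------------------------------------------------------------------
// Simulated annealing. Uses R's RNG so set.seed() makes runs reproducible.
// Move: pick uniformly among the free parameters (N_rho_free + N_h_free + 1
// for sigma) and redraw it uniformly within its admissible interval.
// Metropolis: accept if df <= 0, else with probability exp(-df/T).
// Stops after `stop_rejections` consecutive rejections (global counter) or
// `max_temps` temperature decrements.
// ---------------------------------------------------------------------------
// random change of a parameter within [lo, hi]: a fresh uniform draw with
// probability fresh_prob, otherwise a local uniform step of half-width
// step_frac * (hi - lo), reflected at the bounds
static inline double draw_move(double old, double lo, double hi,
                               double fresh_prob, double step_frac) {
  if (unif_rand() < fresh_prob) return lo + unif_rand() * (hi - lo);
  const double w = step_frac * (hi - lo);
  double v = old + (2.0 * unif_rand() - 1.0) * w;
  if (v < lo) v = lo + (lo - v);
  if (v > hi) v = hi - (v - hi);
  if (v < lo) v = lo;
  if (v > hi) v = hi;
  return v;
}

// [[Rcpp::export]]
List anneal_cpp(List contrasts, double D, int N, int npad,
                NumericVector rho_init, NumericVector h_init, double sigma_init,
                double rho_min, double rho_max,
                double sigma_min, double sigma_max,
                LogicalVector rho_free, LogicalVector h_free,
                double T0, int trials_per_T, double cooling,
                int stop_rejections, int max_temps,
                double fresh_prob = 0.2, double step_min_frac = 0.02) {
  ScoreWork wk;
  wk.init(contrasts, D, N, npad);

  std::vector<double> rho(rho_init.begin(), rho_init.end());
  std::vector<double> h(h_init.begin(), h_init.end());
  double sigma = sigma_init;

  std::vector<int> irho, ih;
  for (int i = 0; i < N; ++i) {
    if (rho_free[i]) irho.push_back(i);
    if (h_free[i]) ih.push_back(i);
  }
  const int nr = (int)irho.size(), nh = (int)ih.size();
  const int nmove = nr + nh + 1;

  double f_cur = wk.score(rho, h, sigma);
  if (!std::isfinite(f_cur)) stop("non-finite score at initialization");
  std::vector<double> best_rho = rho, best_h = h;
  double best_sigma = sigma, f_best = f_cur;

  std::vector<double> trace_T, trace_f, trace_fbest, trace_acc;
  long n_trials = 0, n_accepted = 0;
  int consec_rej = 0;
  double T = T0;
  std::string stopped_by = "max_temps";
  bool aborted = false;

  for (int it = 0; it < max_temps && !aborted; ++it) {
    int acc_T = 0;
    const double step_frac =
      std::max(step_min_frac, std::min(1.0, std::sqrt(T / T0)));
    for (int tr = 0; tr < trials_per_T; ++tr) {
      const int m = (int)std::floor(unif_rand() * nmove);
      int idx = -1;
      double old = 0.0;
      int kind; // 0 rho, 1 h, 2 sigma
      if (m < nr) {
        kind = 0; idx = irho[m]; old = rho[idx];
        rho[idx] = draw_move(old, rho_min, rho_max, fresh_prob, step_frac);
      } else if (m < nr + nh) {
        kind = 1; idx = ih[m - nr]; old = h[idx];
        h[idx] = draw_move(old, 0.0, 1.0, fresh_prob, step_frac);
      } else {
        kind = 2; old = sigma;
        sigma = draw_move(old, sigma_min, sigma_max, fresh_prob, step_frac);
      }
      const double f_new = wk.score(rho, h, sigma);
      ++n_trials;
      if (!std::isfinite(f_new)) { aborted = true; stopped_by = "non_finite"; }
      const double df = f_new - f_cur;
      bool accept = !aborted &&
        (df <= 0.0 || unif_rand() < std::exp(-df / T));
      if (accept) {
        f_cur = f_new;
        consec_rej = 0;
        ++acc_T; ++n_accepted;
        if (f_cur < f_best) {
          f_best = f_cur; best_rho = rho; best_h = h; best_sigma = sigma;
        }
      } else {
        if (kind == 0) rho[idx] = old;
        else if (kind == 1) h[idx] = old;
        else sigma = old;
        if (++consec_rej >= stop_rejections) {
          stopped_by = aborted ? stopped_by : "rejections";
          aborted = true;
        }
      }
      if (aborted) break;
    }
    trace_T.push_back(T);
    trace_f.push_back(f_cur);
    trace_fbest.push_back(f_best);
    trace_acc.push_back((double)acc_T / trials_per_T);
    T *= cooling;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["rho"] = NumericVector(best_rho.begin(), best_rho.end()),
    _["h"] = NumericVector(best_h.begin(), best_h.end()),
    _["sigma"] = best_sigma,
    _["f"] = f_best,
    _["final_rho"] = NumericVector(rho.begin(), rho.end()),
    _["final_h"] = NumericVector(h.begin(), h.end()),
    _["final_sigma"] = sigma,
    _["final_f"] = f_cur,
    _["trace"] = DataFrame::create(_["T"] = trace_T, _["f"] = trace_f,
                                   _["f_best"] = trace_fbest,
                                   _["acceptance"] = trace_acc),
    _["n_trials"] = (double)n_trials,
    _["n_accepted"] = (double)n_accepted,
    _["stopped_by"] = stopped_by);
}
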