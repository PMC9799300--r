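#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Stochastic simulators for the negative-feedback gene regulation motif.
// All randomness comes from R's RNG (unif_rand / norm_rand / exp_rand),
// so set.seed() on the R side gives bitwise-deterministic replay.

static inline void check_cap(double total, double cap) {
  if (total > cap)
    stop("copy-number cap exceeded (runaway parameters); raise count_cap only if intended");
}

// Exact SSA (Gillespie direct method) for the well-mixed model.
// Species: gene (free/bound), mRNA (m), protein (p).
// kb: per-pair binding propensity constant (min^-1).
// [[Rcpp::export]]
IntegerMatrix cpp_ssa_wmm(double kb, double kd, double mu, double kappa,
                          double gamma, double t_burn, int n_samples,
                          double dt_sample, double count_cap) {
  IntegerMatrix out(n_samples, 2);
  int gene_free = 1;
  double m = 0.0, p = 0.0;
  double t = 0.0;
  int isamp = 0;
  double t_next = t_burn;
  double a[6];
  while (isamp < n_samples) {
    a[0] = kb * gene_free * p;   // bind
    a[1] = kd * (1 - gene_free); // unbind
    a[2] = mu * gene_free;       // transcribe
    a[3] = kappa * m;            // translate
    a[4] = gamma * m;            // degrade mRNA
    a[5] = gamma * p;            // degrade P
    double a0 = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
    double tau = (a0 > 0.0) ? exp_rand() / a0 : R_PosInf;
    while (isamp < n_samples && t + tau >= t_next) {
      out(isamp, 0) = (int)m;
      out(isamp, 1) = (int)p;
      ++isamp;
      t_next = t_burn + (double)isamp * dt_sample;
    }
    if (isamp >= n_samples) break;
    t += tau;
    double u = unif_rand() * a0;
    if ((u -= a[0]) < 0)      { gene_free = 0; p -= 1.0; }
    else if ((u -= a[1]) < 0) { gene_free = 1; p += 1.0; }
    else if ((u -= a[2]) < 0) { m += 1.0; }
    else if ((u -= a[3]) < 0) { p += 1.0; }
    else if ((u -= a[4]) < 0) { m -= 1.0; }
    else                      { p -= 1.0; }
    check_cap(m + p, count_cap);
  }
  return out;
}

// Exact SSA for the two-compartment model. Nuclear species bind the gene;
// translation only from cytoplasmic mRNA; two-way diffusive hops.
// kb: per-pair binding propensity in the nucleus volume (min^-1).
// [[Rcpp::export]]
IntegerMatrix cpp_ssa_cbm(double kb, double kd, double mu, double kappa,
                          double gamma, double k_exit, double k_entry,
                          double t_burn, int n_samples, double dt_sample,
                          double count_cap) {
  IntegerMatrix out(n_samples, 2);
  int gene_free = 1;
  double mn = 0.0, mc = 0.0, pn = 0.0, pc = 0.0;
  double t = 0.0;
  int isamp = 0;
  double t_next = t_burn;
  double a[12];
  while (isamp < n_samples) {
    a[0] = kb * gene_free * pn;   // bind (nucleus)
    a[1] = kd * (1 - gene_free);  // unbind -> P_nuc
    a[2] = mu * gene_free;        // transcribe -> mRNA_nuc
    a[3] = kappa * mc;            // translate -> P_cyt
    a[4] = gamma * mn;            // degrade
    a[5] = gamma * mc;
    a[6] = gamma * pn;
    a[7] = gamma * pc;
    a[8] = k_exit * mn;           // hops
    a[9] = k_entry * mc;
    a[10] = k_exit * pn;
    a[11] = k_entry * pc;
    double a0 = 0.0;
    for (int i = 0; i < 12; ++i) a0 += a[i];
    double tau = (a0 > 0.0) ? exp_rand() / a0 : R_PosInf;
    while (isamp < n_samples && t + tau >= t_next) {
      out(isamp, 0) = (int)(mn + mc);
      out(isamp, 1) = (int)(pn + pc);
      ++isamp;
      t_next = t_burn + (double)isamp * dt_sample;
    }
    if (isamp >= n_samples) break;
    t += tau;
    double u = unif_rand() * a0;
    int r = 0;
    while (r < 11 && (u -= a[r]) >= 0) ++r;
    switch (r) {
      case 0: gene_free = 0; pn -= 1.0; break;
      case 1: gene_free = 1; pn += 1.0; break;
      case 2: mn += 1.0; break;
      case 3: pc += 1.0; break;
      case 4: mn -= 1.0; break;
      case 5: mc -= 1.0; break;
      case 6: pn -= 1.0; break;
      case 7: pc -= 1.0; break;
      case 8: mn -= 1.0; mc += 1.0; break;
      case 9: mc -= 1.0; mn += 1.0; break;
      case 10: pn -= 1.0; pc += 1.0; break;
      default: pc -= 1.0; pn += 1.0; break;
    }
    check_cap(mn + mc + pn + pc, count_cap);
  }
  return out;
}

struct Particles {
  std::vector<double> x, y, z;
  size_t size() const { return x.size(); }
  void add(double xi, double yi, double zi) {
    x.push_back(xi); y.push_back(yi); z.push_back(zi);
  }
  void remove(size_t i) {
    x[i] = x.back(); y[i] = y.back(); z[i] = z.back();
    x.pop_back(); y.pop_back(); z.pop_back();
  }
};

static inline double norm2(double x, double y, double z) {
  return std::sqrt(x * x + y * y + z * z);
}

// Gaussian step + reflection at |x| = R
static inline void diffuse_all(Particles &ps, double s, double R) {
  for (size_t i = 0; i < ps.size(); ++i) {
    ps.x[i] += s * norm_rand();
    ps.y[i] += s * norm_rand();
    ps.z[i] += s * norm_rand();
    double nr = norm2(ps.x[i], ps.y[i], ps.z[i]);
    if (nr > R) {
      double f = (2.0 * R - nr) / nr;
      if (f < 0.0) f = R / nr; // pathological overshoot: clamp to wall
      ps.x[i] *= f; ps.y[i] *= f; ps.z[i] *= f;
    }
  }
}

static inline void thin(Particles &ps, double pdeg) {
  for (size_t i = 0; i < ps.size();) {
    if (unif_rand() < pdeg) ps.remove(i); else ++i;
  }
}

// Fixed-time-step Brownian dynamics of the full motif.
// [[Rcpp::export]]
IntegerMatrix cpp_bd_sim(double D, double R, double r, double sigma_b,
                         double release_radius, double kd, double mu,
                         double kappa, double gamma, double dt,
                         double t_burn, int n_samples, double dt_sample,
                         double count_cap) {
  IntegerMatrix out(n_samples, 2);
  Particles M, P;
  bool gene_bound = false;
  double s = std::sqrt(2.0 * D * dt);
  double p_deg = 1.0 - std::exp(-gamma * dt);
  double p_tx  = 1.0 - std::exp(-mu * dt);
  double p_tl  = 1.0 - std::exp(-kappa * dt);
  double p_off = 1.0 - std::exp(-kd * dt);
  long n_steps = (long)std::ceil((t_burn + (n_samples - 1) * dt_sample) / dt);
  int isamp = 0;
  long samp_step = (long)std::floor(t_burn / dt + 0.5);
  long samp_stride = (long)std::floor(dt_sample / dt + 0.5);

  for (long step = 0; step <= n_steps; ++step) {
    if (isamp < n_samples && step == samp_step + (long)isamp * samp_stride) {
      out(isamp, 0) = (int)M.size();
      out(isamp, 1) = (int)P.size();
      ++isamp;
      if (isamp == n_samples) break;
    }
    // 1. diffusion with reflecting cell wall
    diffuse_all(M, s, R);
    diffuse_all(P, s, R);
    // 2. degradation
    thin(M, p_deg);
    thin(P, p_deg);
    // 3. transcription at the gene (origin)
    if (!gene_bound && unif_rand() < p_tx) M.add(0.0, 0.0, 0.0);
    // 4. translation from cytoplasmic mRNA (new P at the mRNA's position)
    size_t nm = M.size();
    for (size_t i = 0; i < nm; ++i) {
      if (norm2(M.x[i], M.y[i], M.z[i]) > r && unif_rand() < p_tl)
        P.add(M.x[i], M.y[i], M.z[i]);
    }
    // 5. binding: free gene absorbs the closest protein inside sigma_b
    if (!gene_bound && sigma_b > 0.0) {
      double best = sigma_b;
      long best_i = -1;
      for (size_t i = 0; i < P.size(); ++i) {
        double nr = norm2(P.x[i], P.y[i], P.z[i]);
        if (nr <= best) { best = nr; best_i = (long)i; }
      }
      if (best_i >= 0) { P.remove((size_t)best_i); gene_bound = true; }
    }
    // 6. unbinding: release just outside the binding radius
    else if (gene_bound && unif_rand() < p_off) {
      double ux, uy, uz, nr;
      do {
        ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
        nr = norm2(ux, uy, uz);
      } while (nr == 0.0);
      P.add(release_radius * ux / nr, release_radius * uy / nr,
            release_radius * uz / nr);
      gene_bound = false;
    }
    check_cap((double)(M.size() + P.size()), count_cap);
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Mean lifetime of an irreversibly absorbed Brownian pair: particle starts
// uniformly in the shell (sigma, L], reflects at |x| = L, is absorbed when
// its end-of-step distance to the origin is <= sigma. Used to calibrate
// the binding radius for a given time step.
// [[Rcpp::export]]
double cpp_pair_lifetime(double sigma, double D, double dt, double L,
                         int n_pairs) {
  double s = std::sqrt(2.0 * D * dt);
  double total = 0.0;
  long max_steps = 100000000L / (n_pairs > 0 ? n_pairs : 1);
  for (int k = 0; k < n_pairs; ++k) {
    // uniform radius in the shell: density 3 rho^2 / (L^3 - sigma^3)
    double u = unif_rand();
    double rho = std::cbrt(sigma * sigma * sigma +
                           u * (L * L * L - sigma * sigma * sigma));
    double ux, uy, uz, nr;
    do {
      ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
      nr = norm2(ux, uy, uz);
    } while (nr == 0.0);
    double x = rho * ux / nr, y = rho * uy / nr, z = rho * uz / nr;
    long steps = 0;
    for (;;) {
      ++steps;
      x += s * norm_rand(); y += s * norm_rand(); z += s * norm_rand();
      nr = norm2(x, y, z);
      if (nr > L) {
        double f = (2.0 * L - nr) / nr;
        if (f < 0.0) f = L / nr;
        x *= f; y *= f; z *= f;
        nr = norm2(x, y, z);
      }
      if (nr <= sigma || steps >= max_steps) break;
    }
    total += (double)steps * dt;
  }
  return total / n_pairs;
}

// Diagnostic: n independent Brownian particles started at the origin,
// stepped n_steps times through the same diffusion/reflection code as the
// simulator. Returns final x, y, z and the maximum radius visited.
// R_wall <= 0 disables the wall.
// [[Rcpp::export]]
NumericMatrix cpp_brownian_paths(double D, double dt, int n_steps, int n,
                                 double R_wall) {
  double wall = (R_wall > 0.0) ? R_wall : 1e12;
  Particles ps;
  std::vector<double> maxnorm(n, 0.0);
  for (int i = 0; i < n; ++i) ps.add(0.0, 0.0, 0.0);
  double s = std::sqrt(2.0 * D * dt);
  for (int step = 0; step < n_steps; ++step) {
    diffuse_all(ps, s, wall);
    for (int i = 0; i < n; ++i) {
      double nr = norm2(ps.x[i], ps.y[i], ps.z[i]);
      if (nr > maxnorm[i]) maxnorm[i] = nr;
    }
  }
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = ps.x[i]; out(i, 1) = ps.y[i]; out(i, 2) = ps.z[i];
    out(i, 3) = maxnorm[i];
  }
  return out;
}
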