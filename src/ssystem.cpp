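#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// S-system right-hand side at one state.
//   dx_i = alpha_i * prod_j x_j^g_ij - beta_i * prod_j x_j^h_ij
// The state is clamped to eps before exponentiation only (the integration
// state itself is never clamped), so powers of nonpositive values cannot
// occur. Power products are evaluated as exp(g_i . log(x)) which is both
// faster and numerically identical for positive bases.
static inline void ss_deriv(int N, const double* alpha, const double* beta,
                            const double* g, const double* h, // N x N, column-major
                            const double* x, double eps,
                            double* lx, double* sg, double* sh, double* dx) {
  for (int j = 0; j < N; ++j) {
    double xj = x[j];
    if (!(xj > eps)) xj = eps;
    lx[j] = std::log(xj);
  }
  for (int i = 0; i < N; ++i) { sg[i] = 0.0; sh[i] = 0.0; }
  for (int j = 0; j < N; ++j) {
    const double lxj = lx[j];
    const double* gcol = g + (size_t)N * j;
    const double* hcol = h + (size_t)N * j;
    for (int i = 0; i < N; ++i) {
      sg[i] += gcol[i] * lxj;
      sh[i] += hcol[i] * lxj;
    }
  }
  for (int i = 0; i < N; ++i)
    dx[i] = alpha[i] * std::exp(sg[i]) - beta[i] * std::exp(sh[i]);
}

struct Workspace {
  std::vector<double> x, k1, k2, k3, k4, xt, lx, sg, sh;
  explicit Workspace(int N)
      : x(N), k1(N), k2(N), k3(N), k4(N), xt(N), lx(N), sg(N), sh(N) {}
};

// Fixed-step classical RK4 over the requested grid, `substeps` internal steps
// per grid interval. Writes the trajectory (N x T, column-major) into `out`.
// Returns the number of grid points completed; < T means the trajectory
// diverged (some |x| exceeded `guard` or became non-finite) and the remaining
// columns are left untouched by the caller's convention.
static int rk4_integrate(int N, const double* alpha, const double* beta,
                         const double* g, const double* h,
                         const double* x0, const double* times, int T,
                         int substeps, double eps, double guard,
                         double* out, Workspace& w) {
  double* x = w.x.data();
  for (int i = 0; i < N; ++i) x[i] = x0[i];
  for (int i = 0; i < N; ++i) out[i] = x[i];
  int done = 1;
  for (int t = 1; t < T; ++t) {
    const double dt = (times[t] - times[t - 1]) / substeps;
    for (int s = 0; s < substeps; ++s) {
      ss_deriv(N, alpha, beta, g, h, x, eps, w.lx.data(), w.sg.data(), w.sh.data(), w.k1.data());
      for (int i = 0; i < N; ++i) w.xt[i] = x[i] + 0.5 * dt * w.k1[i];
      ss_deriv(N, alpha, beta, g, h, w.xt.data(), eps, w.lx.data(), w.sg.data(), w.sh.data(), w.k2.data());
      for (int i = 0; i < N; ++i) w.xt[i] = x[i] + 0.5 * dt * w.k2[i];
      ss_deriv(N, alpha, beta, g, h, w.xt.data(), eps, w.lx.data(), w.sg.data(), w.sh.data(), w.k3.data());
      for (int i = 0; i < N; ++i) w.xt[i] = x[i] + dt * w.k3[i];
      ss_deriv(N, alpha, beta, g, h, w.xt.data(), eps, w.lx.data(), w.sg.data(), w.sh.data(), w.k4.data());
      bool bad = false;
      for (int i = 0; i < N; ++i) {
        x[i] += dt / 6.0 * (w.k1[i] + 2.0 * w.k2[i] + 2.0 * w.k3[i] + w.k4[i]);
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > guard) bad = true;
      }
      if (bad) return done;
    }
    double* col = out + (size_t)N * t;
    for (int i = 0; i < N; ++i) col[i] = x[i];
    ++done;
  }
  return done;
}

// Decode one flat parameter vector (per-gene blocks
// [alpha_i, g_{i,1..N}, beta_i, h_{i,1..N}], ascending i) into the four
// coefficient arrays. Must agree with ss_encode()/ss_decode() on the R side.
static void decode_flat(int N, const double* p, double* alpha, double* beta,
                        double* g, double* h) {
  const int blk = 2 * (N + 1);
  for (int i = 0; i < N; ++i) {
    const double* b = p + (size_t)i * blk;
    alpha[i] = b[0];
    beta[i] = b[N + 1];
    for (int j = 0; j < N; ++j) {
      g[i + (size_t)N * j] = b[1 + j];
      h[i + (size_t)N * j] = b[N + 2 + j];
    }
  }
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector alpha, NumericVector beta,
                  NumericMatrix g, NumericMatrix h,
                  NumericVector x0, NumericVector times,
                  int substeps, double eps, double guard) {
  const int N = alpha.size(), T = times.size();
  NumericMatrix out(N, T);
  std::fill(out.begin(), out.end(), NA_REAL);
  Workspace w(N);
  int done = rk4_integrate(N, alpha.begin(), beta.begin(), g.begin(), h.begin(),
                           x0.begin(), times.begin(), T, substeps, eps, guard,
                           out.begin(), w);
  return List::create(_["values"] = out, _["diverged"] = (done < T),
                      _["completed"] = done);
}

// Batch fitness for a population of flat parameter vectors (one per row of
// `pop`). Each candidate is simulated from x0 on the target grid; the fitness
// is the relative squared error sum_i sum_t ((xa - xd)/denom)^2 where `denom`
// is the guard-adjusted target matrix prepared by the caller. Divergent
// trajectories receive `penalty`.
// [[Rcpp::export]]
NumericVector cpp_fitness_batch(NumericMatrix pop, int n_genes,
                                NumericMatrix target, NumericMatrix denom,
                                NumericVector x0, NumericVector times,
                                int substeps, double eps, double guard,
                                double penalty, bool mean_form) {
  const int N = n_genes, T = times.size(), M = pop.nrow(), mu = pop.ncol();
  if (mu != 2 * N * (N + 1)) stop("parameter vector length does not match 2N(N+1)");
  if (target.nrow() != N || target.ncol() != T) stop("target dimensions do not match");
  NumericVector res(M);
  std::vector<double> p(mu), alpha(N), beta(N), g((size_t)N * N), h((size_t)N * N),
      traj((size_t)N * T);
  Workspace w(N);
  for (int m = 0; m < M; ++m) {
    for (int k = 0; k < mu; ++k) p[k] = pop(m, k);
    decode_flat(N, p.data(), alpha.data(), beta.data(), g.data(), h.data());
    int done = rk4_integrate(N, alpha.data(), beta.data(), g.data(), h.data(),
                             x0.begin(), times.begin(), T, substeps, eps, guard,
                             traj.data(), w);
    if (done < T) {
      res[m] = penalty;
      continue;
    }
    double acc = 0.0;
    for (int t = 0; t < T; ++t) {
      const double* xa = traj.data() + (size_t)N * t;
      for (int i = 0; i < N; ++i) {
        const double e = (xa[i] - target(i, t)) / denom(i, t);
        acc += e * e;
      }
    }
    if (!std::isfinite(acc)) acc = penalty;
    if (mean_form) acc /= (double)N * T;
    res[m] = acc;
  }
  return res;
}
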