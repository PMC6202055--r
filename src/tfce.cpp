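#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Threshold-free cluster enhancement on an arbitrary undirected graph given
// in CSR form (0-based).  For each node, sums e(h)^E * h^H * dh over
// thresholds h = dh, 2dh, ..., where e(h) is the size of the connected
// component of supra-threshold (stat >= h) nodes containing it.  Negative
// values are enhanced on the negated map and re-negated.
static void tfce_one_sign(const std::vector<double>& stat,
                          const int* ptr, const int* idx, int n,
                          double H, double E, int nsteps, double dh_opt,
                          std::vector<double>& out) {
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) if (stat[i] > hmax) hmax = stat[i];
  if (hmax <= 0.0) return;
  double dh = dh_opt > 0.0 ? dh_opt : hmax / nsteps;

  std::vector<int> comp(n), stack, members;
  stack.reserve(n); members.reserve(n);
  for (int step = 1; ; ++step) {
    double h = step * dh;   // no floating accumulation drift
    if (h > hmax * (1 + 1e-12)) break;
    std::fill(comp.begin(), comp.end(), -1);
    int cid = 0;
    for (int s = 0; s < n; ++s) {
      if (stat[s] < h || comp[s] != -1) continue;
      members.clear();
      stack.clear();
      stack.push_back(s);
      comp[s] = cid;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        members.push_back(u);
        for (int e = ptr[u]; e < ptr[u + 1]; ++e) {
          int v = idx[e];
          if (stat[v] >= h && comp[v] == -1) {
            comp[v] = cid;
            stack.push_back(v);
          }
        }
      }
      double add = std::pow((double)members.size(), E) * std::pow(h, H) * dh;
      for (int u : members) out[u] += add;
      ++cid;
    }
  }
}

static std::vector<double> tfce_signed(const std::vector<double>& stat,
                                       const int* ptr, const int* idx, int n,
                                       double H, double E, int nsteps,
                                       double dh_opt) {
  std::vector<double> out(n, 0.0), neg(n), outneg(n, 0.0);
  tfce_one_sign(stat, ptr, idx, n, H, E, nsteps, dh_opt, out);
  for (int i = 0; i < n; ++i) neg[i] = -stat[i];
  tfce_one_sign(neg, ptr, idx, n, H, E, nsteps, dh_opt, outneg);
  for (int i = 0; i < n; ++i) out[i] -= outneg[i];
  return out;
}

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector adj_ptr,
                       IntegerVector adj_idx, double H, double E,
                       int nsteps, double dh) {
  int n = stat.size();
  std::vector<double> s(stat.begin(), stat.end());
  std::vector<double> out = tfce_signed(s, adj_ptr.begin(), adj_idx.begin(),
                                        n, H, E, nsteps, dh);
  return NumericVector(out.begin(), out.end());
}

// t -> z conversion that stays finite in the far tails
static double t_to_z(double t, double df) {
  double lp = R::pt(std::fabs(t), df, 0, 1);  // log upper-tail prob
  double z = R::qnorm(lp, 0.0, 1.0, 0, 1);    // upper-tail quantile
  return t < 0 ? -z : z;
}

// Paired (one-sample on differences) contrast with sign-flip permutation
// null, TFCE enhancement and max-|TFCE| FWE correction.  D is the n x G
// matrix of within-subject difference maps.
// [[Rcpp::export]]
List paired_contrast_cpp(NumericMatrix D, IntegerVector adj_ptr,
                         IntegerVector adj_idx, int nperm, double H,
                         double E, int nsteps, int seed) {
  int n = D.nrow(), G = D.ncol();
  double df = n - 1.0;
  std::vector<double> t_obs(G), z_obs(G), abs_t(G);

  auto tstat = [&](const std::vector<double>& sgn, std::vector<double>& t) {
    for (int g = 0; g < G; ++g) {
      double m = 0.0, ss = 0.0;
      for (int i = 0; i < n; ++i) m += sgn[i] * D(i, g);
      m /= n;
      for (int i = 0; i < n; ++i) {
        double d = sgn[i] * D(i, g) - m;
        ss += d * d;
      }
      double se = std::sqrt(ss / (df * n));
      t[g] = se > 0 ? m / se : 0.0;
    }
  };

  std::vector<double> ones(n, 1.0);
  tstat(ones, t_obs);
  for (int g = 0; g < G; ++g) {
    z_obs[g] = t_to_z(t_obs[g], df);
    abs_t[g] = std::fabs(t_obs[g]);
  }
  std::vector<double> tfce_obs = tfce_signed(z_obs, adj_ptr.begin(),
                                             adj_idx.begin(), G, H, E,
                                             nsteps, -1.0);

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  NumericVector max_null(nperm);
  std::vector<int> exceed_t(G, 0);
  std::vector<double> sgn(n), t_p(G), z_p(G);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < n; ++i) sgn[i] = unif(rng) < 0.5 ? -1.0 : 1.0;
    tstat(sgn, t_p);
    for (int g = 0; g < G; ++g) {
      z_p[g] = t_to_z(t_p[g], df);
      if (std::fabs(t_p[g]) >= abs_t[g]) ++exceed_t[g];
    }
    std::vector<double> tf = tfce_signed(z_p, adj_ptr.begin(),
                                         adj_idx.begin(), G, H, E,
                                         nsteps, -1.0);
    double mx = 0.0;
    for (int g = 0; g < G; ++g) {
      double a = std::fabs(tf[g]);
      if (a > mx) mx = a;
    }
    max_null[p] = mx;
  }

  NumericVector fwe_p(G), unc_p(G), z_out(G), tfce_out(G);
  for (int g = 0; g < G; ++g) {
    int cnt = 0;
    double a = std::fabs(tfce_obs[g]);
    for (int p = 0; p < nperm; ++p) if (max_null[p] >= a) ++cnt;
    fwe_p[g] = (1.0 + cnt) / (nperm + 1.0);
    unc_p[g] = (1.0 + exceed_t[g]) / (nperm + 1.0);
    z_out[g] = z_obs[g];
    tfce_out[g] = tfce_obs[g];
  }
  return List::create(_["z"] = z_out, _["tfce"] = tfce_out,
                      _["fwe_p"] = fwe_p, _["unc_p"] = unc_p,
                      _["max_null"] = max_null);
}

// Repeated-measures one-way F across 3 conditions with within-subject
// label-permutation null.  Y1..Y3 are n x G condition maps.
// [[Rcpp::export]]
List rm_anova_cpp(NumericMatrix Y1, NumericMatrix Y2, NumericMatrix Y3,
                  IntegerVector adj_ptr, IntegerVector adj_idx, int nperm,
                  double H, double E, int nsteps, int seed) {
  int n = Y1.nrow(), G = Y1.ncol();
  const int k = 3;
  double df1 = k - 1.0, df2 = (double)(k - 1) * (n - 1);

  // per-subject condition orderings: all 6 permutations of 3 labels
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},
                                  {2,0,1},{2,1,0}};

  auto fstat = [&](const std::vector<int>& pidx, std::vector<double>& F) {
    for (int g = 0; g < G; ++g) {
      double y[3];
      double cm[3] = {0, 0, 0}, grand = 0.0;
      double ss_tot = 0.0, ss_subj = 0.0;
      // first pass: means
      for (int i = 0; i < n; ++i) {
        const int* pr = perms[pidx[i]];
        double raw[3] = {Y1(i, g), Y2(i, g), Y3(i, g)};
        for (int c = 0; c < k; ++c) {
          y[c] = raw[pr[c]];
          cm[c] += y[c];
        }
      }
      for (int c = 0; c < k; ++c) { cm[c] /= n; grand += cm[c]; }
      grand /= k;
      double ss_cond = 0.0;
      for (int c = 0; c < k; ++c)
        ss_cond += (cm[c] - grand) * (cm[c] - grand);
      ss_cond *= n;
      for (int i = 0; i < n; ++i) {
        const int* pr = perms[pidx[i]];
        double raw[3] = {Y1(i, g), Y2(i, g), Y3(i, g)};
        double sm = 0.0;
        for (int c = 0; c < k; ++c) sm += raw[pr[c]];
        sm /= k;
        ss_subj += k * (sm - grand) * (sm - grand);
        for (int c = 0; c < k; ++c) {
          double d = raw[pr[c]] - grand;
          ss_tot += d * d;
        }
      }
      double ss_err = ss_tot - ss_subj - ss_cond;
      if (ss_err < 0) ss_err = 0;
      double ms_err = ss_err / df2;
      F[g] = ms_err > 0 ? (ss_cond / df1) / ms_err : 0.0;
    }
  };

  std::vector<int> ident(n, 0), pidx(n);
  std::vector<double> F_obs(G), F_p(G);
  fstat(ident, F_obs);
  std::vector<double> tfce_obs(G, 0.0);
  tfce_one_sign(F_obs, adj_ptr.begin(), adj_idx.begin(), G, H, E, nsteps,
                -1.0, tfce_obs);
  // recompute dh from the observed max inside tfce_one_sign (dh_opt=-1)

  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, 5);
  NumericVector max_null(nperm);
  std::vector<int> exceed(G, 0);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < n; ++i) pidx[i] = pick(rng);
    fstat(pidx, F_p);
    for (int g = 0; g < G; ++g) if (F_p[g] >= F_obs[g]) ++exceed[g];
    std::vector<double> tf(G, 0.0);
    tfce_one_sign(F_p, adj_ptr.begin(), adj_idx.begin(), G, H, E, nsteps,
                  -1.0, tf);
    double mx = 0.0;
    for (int g = 0; g < G; ++g) if (tf[g] > mx) mx = tf[g];
    max_null[p] = mx;
  }

  NumericVector Fv(G), tfce_out(G), fwe_p(G), unc_p(G);
  for (int g = 0; g < G; ++g) {
    int cnt = 0;
    for (int p = 0; p < nperm; ++p) if (max_null[p] >= tfce_obs[g]) ++cnt;
    Fv[g] = F_obs[g];
    tfce_out[g] = tfce_obs[g];
    fwe_p[g] = (1.0 + cnt) / (nperm + 1.0);
    unc_p[g] = (1.0 + exceed[g]) / (nperm + 1.0);
  }
  return List::create(_["F"] = Fv, _["tfce"] = tfce_out,
                      _["fwe_p"] = fwe_p, _["unc_p"] = unc_p,
                      _["max_null"] = max_null);
}
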