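// Metropolis-within-Gibbs samplers for the hypergraph and categorical-edges
// posteriors. Structure moves are single-hyperedge flips with symmetric
// proposals, so the acceptance ratio reduces to a posterior ratio evaluated
// only over the pairs whose label changes. All randomness flows through R's
// RNG (RNGScope), which makes chains reproducible from a single set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct PairTable {
  // enumeration of all pairs i<j (0-based) for uniform proposals
  std::vector<int> pi, pj;
  void build(int n) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) { pi.push_back(i); pj.push_back(j); }
  }
};

struct TripleTable {
  std::vector<int> ti, tj, tk;
  void build(int n) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        for (int k = j + 1; k < n; ++k) {
          ti.push_back(i); tj.push_back(j); tk.push_back(k);
        }
  }
};

inline double poisson_delta(int x, double mu_old, double mu_new,
                            double lmu_old, double lmu_new) {
  return x * (lmu_new - lmu_old) - (mu_new - mu_old);
}

inline int runif_int(int m) {  // uniform on 0..m-1
  int r = (int)(unif_rand() * m);
  return r >= m ? m - 1 : r;
}

// ---------------------------------------------------------------------------
// Hypergraph state: 2-edge adjacency, per-pair 3-edge cover counts, triple
// membership, and O(1)-update hyperedge lists for sample export.
struct HyperState {
  int n;
  std::vector<char> adj;       // n*n
  std::vector<int> cov;        // n*n, number of covering 3-edges
  std::vector<char> tri;       // n*n*n membership (i<j<k at i*n*n+j*n+k)
  std::vector<long> elist, tlist;
  std::vector<long> epos, tpos;  // code -> position in list (or -1)
  long h1 = 0, h2 = 0;

  void init(int n_, const IntegerMatrix &E, const IntegerMatrix &T) {
    n = n_;
    adj.assign((size_t)n * n, 0);
    cov.assign((size_t)n * n, 0);
    tri.assign((size_t)n * n * n, 0);
    epos.assign((size_t)n * n, -1);
    tpos.assign((size_t)n * n * n, -1);
    for (int r = 0; r < E.nrow(); ++r)
      flip_pair_raw(E(r, 0) - 1, E(r, 1) - 1);
    for (int r = 0; r < T.nrow(); ++r)
      flip_triple_raw(T(r, 0) - 1, T(r, 1) - 1, T(r, 2) - 1);
  }

  inline long pcode(int i, int j) const { return (long)i * n + j; }
  inline long tcode(int i, int j, int k) const {
    return ((long)i * n + j) * n + k;
  }
  inline int label(int i, int j) const {
    long c = pcode(i, j);
    return cov[c] > 0 ? 2 : (adj[c] ? 1 : 0);
  }

  void flip_pair_raw(int i, int j) {  // toggle 2-edge (i<j)
    long c = pcode(i, j);
    if (adj[c]) {
      adj[c] = 0;
      long pos = epos[c], last = elist.back();
      elist[pos] = last; epos[last] = pos;
      elist.pop_back(); epos[c] = -1;
      --h1;
    } else {
      adj[c] = 1;
      epos[c] = (long)elist.size();
      elist.push_back(c);
      ++h1;
    }
  }

  void flip_triple_raw(int i, int j, int k) {  // toggle 3-edge (i<j<k)
    long c = tcode(i, j, k);
    int d;
    if (tri[c]) {
      tri[c] = 0; d = -1;
      long pos = tpos[c], last = tlist.back();
      tlist[pos] = last; tpos[last] = pos;
      tlist.pop_back(); tpos[c] = -1;
      --h2;
    } else {
      tri[c] = 1; d = 1;
      tpos[c] = (long)tlist.size();
      tlist.push_back(c);
      ++h2;
    }
    cov[pcode(i, j)] += d;
    cov[pcode(i, k)] += d;
    cov[pcode(j, k)] += d;
  }

  IntegerMatrix edge_matrix() const {  // 1-based
    IntegerMatrix E((int)elist.size(), 2);
    for (size_t r = 0; r < elist.size(); ++r) {
      E(r, 0) = (int)(elist[r] / n) + 1;
      E(r, 1) = (int)(elist[r] % n) + 1;
    }
    return E;
  }
  IntegerMatrix triple_matrix() const {
    IntegerMatrix T((int)tlist.size(), 3);
    for (size_t r = 0; r < tlist.size(); ++r) {
      long c = tlist[r];
      T(r, 2) = (int)(c % n) + 1; c /= n;
      T(r, 1) = (int)(c % n) + 1; c /= n;
      T(r, 0) = (int)c + 1;
    }
    return T;
  }
};

// One block of single-hyperedge flip proposals at fixed (mu, phi).
void hyper_mh_block(HyperState &st, const IntegerMatrix &X,
                    const double *mu, const double *lmu,
                    double q, double p, int n_props,
                    const PairTable &PT, const TripleTable &TT) {
  const double lq = std::log(q / (1.0 - q));
  const double lp = std::log(p / (1.0 - p));
  const bool have_triples = !TT.ti.empty();
  const int npairs = (int)PT.pi.size();
  const int ntrip = (int)TT.ti.size();
  for (int s = 0; s < n_props; ++s) {
    bool pair_move = !have_triples || unif_rand() < 0.5;
    if (pair_move) {
      int r = runif_int(npairs);
      int i = PT.pi[r], j = PT.pj[r];
      long c = st.pcode(i, j);
      bool present = st.adj[c];
      double dlp = present ? -lq : lq;
      if (st.cov[c] == 0) {  // label changes 0<->1 only when uncovered
        int a = present ? 1 : 0, b = 1 - a;
        dlp += poisson_delta(X(i, j), mu[a], mu[b], lmu[a], lmu[b]);
      }
      if (dlp >= 0 || std::log(unif_rand()) < dlp) st.flip_pair_raw(i, j);
    } else {
      int r = runif_int(ntrip);
      int i = TT.ti[r], j = TT.tj[r], k = TT.tk[r];
      bool present = st.tri[st.tcode(i, j, k)];
      int d = present ? -1 : 1;
      double dlp = present ? -lp : lp;
      const int pr[3][2] = {{i, j}, {i, k}, {j, k}};
      for (int t = 0; t < 3; ++t) {
        long c = st.pcode(pr[t][0], pr[t][1]);
        int a = st.cov[c] > 0 ? 2 : (st.adj[c] ? 1 : 0);
        int b = st.cov[c] + d > 0 ? 2 : (st.adj[c] ? 1 : 0);
        if (a != b)
          dlp += poisson_delta(X(pr[t][0], pr[t][1]), mu[a], mu[b],
                               lmu[a], lmu[b]);
      }
      if (dlp >= 0 || std::log(unif_rand()) < dlp) st.flip_triple_raw(i, j, k);
    }
  }
}

// ---------------------------------------------------------------------------
// Categorical-edges state: per-pair label in {0,1,2}.
struct GraphState {
  int n;
  std::vector<char> lab;  // n*n upper triangle used
  long m1 = 0, m2 = 0;
  void init(int n_, const IntegerMatrix &E1, const IntegerMatrix &E2) {
    n = n_;
    lab.assign((size_t)n * n, 0);
    for (int r = 0; r < E1.nrow(); ++r) {
      lab[(long)(E1(r, 0) - 1) * n + (E1(r, 1) - 1)] = 1; ++m1;
    }
    for (int r = 0; r < E2.nrow(); ++r) {
      lab[(long)(E2(r, 0) - 1) * n + (E2(r, 1) - 1)] = 2; ++m2;
    }
  }
  IntegerMatrix edge_matrix(char type) const {
    std::vector<int> a, b;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (lab[(long)i * n + j] == type) { a.push_back(i + 1); b.push_back(j + 1); }
    IntegerMatrix E((int)a.size(), 2);
    for (size_t r = 0; r < a.size(); ++r) { E(r, 0) = a[r]; E(r, 1) = b[r]; }
    return E;
  }
};

// Eq.-style two-step prior log-probability as a function of (m1, m2).
inline double graph_prior_terms(long m1, long m2, long npairs,
                                double lq1, double l1q1,
                                double lq2, double l1q2) {
  return m1 * lq1 + (npairs - m1 - m2) * l1q1 + m2 * lq2 + (npairs - m2) * l1q2;
}

void graph_mh_block(GraphState &st, const IntegerMatrix &X,
                    const double *mu, const double *lmu,
                    double q1, double q2, int n_props, const PairTable &PT) {
  const long npairs = (long)PT.pi.size();
  const double lq1 = std::log(q1), l1q1 = std::log1p(-q1);
  const double lq2 = std::log(q2), l1q2 = std::log1p(-q2);
  static const long dm1[3] = {0, 1, 0}, dm2[3] = {0, 0, 1};
  for (int s = 0; s < n_props; ++s) {
    int r = runif_int((int)npairs);
    int i = PT.pi[r], j = PT.pj[r];
    long c = (long)i * st.n + j;
    int a = st.lab[c];
    int b = (a + 1 + (unif_rand() < 0.5 ? 0 : 1)) % 3;  // uniform other label
    long m1n = st.m1 - dm1[a] + dm1[b], m2n = st.m2 - dm2[a] + dm2[b];
    double dlp =
        graph_prior_terms(m1n, m2n, npairs, lq1, l1q1, lq2, l1q2) -
        graph_prior_terms(st.m1, st.m2, npairs, lq1, l1q1, lq2, l1q2) +
        poisson_delta(X(i, j), mu[a], mu[b], lmu[a], lmu[b]);
    if (dlp >= 0 || std::log(unif_rand()) < dlp) {
      st.lab[c] = (char)b; st.m1 = m1n; st.m2 = m2n;
    }
  }
}

// ---------------------------------------------------------------------------
// Conjugate updates.

// Inverse-CDF draw from gamma(shape, rate) truncated to (lo, hi).
double rtrunc_gamma(double shape, double rate, double lo, double hi) {
  double scale = 1.0 / rate;
  double Flo = lo <= 0 ? 0.0 : R::pgamma(lo, shape, scale, 1, 0);
  double Fhi = R_FINITE(hi) ? R::pgamma(hi, shape, scale, 1, 0) : 1.0;
  if (Fhi - Flo < 1e-12) {
    // numerically degenerate window: clamp the posterior mean inside
    double x = shape * scale;
    double lo2 = lo <= 0 ? 0.0 : lo;
    if (x <= lo2) x = lo2 + (R_FINITE(hi) ? (hi - lo2) * 1e-6 : lo2 * 1e-6 + 1e-12);
    if (R_FINITE(hi) && x >= hi) x = lo2 + (hi - lo2) * (1 - 1e-6);
    return x;
  }
  double u = Flo + unif_rand() * (Fhi - Flo);
  if (u <= 0) u = 1e-300;
  if (u >= 1) u = 1 - 1e-16;
  return R::qgamma(u, shape, scale, 1, 0);
}

// Draw (mu0, mu1, mu2) from the conjugate gamma full conditionals under the
// ordering constraint. constraint: 0 none, 1 hypergraph (mu0<mu1, mu0<mu2),
// 2 graph (mu0<mu1<mu2). When use_cur, truncation bounds come from the
// current values `mu` (proper Gibbs scan); otherwise bounds are built
// sequentially from the values drawn so far.
void gibbs_mu_draw(const double *sumx, const double *cnt,
                   const double *shape0, const double *rate0,
                   int constraint, const double *mu_cur, bool use_cur,
                   double *out) {
  double sh[3], ra[3];
  for (int k = 0; k < 3; ++k) {
    sh[k] = shape0[k] + sumx[k];
    ra[k] = rate0[k] + cnt[k];
  }
  const double inf = R_PosInf;
  if (constraint == 0) {
    for (int k = 0; k < 3; ++k) out[k] = rtrunc_gamma(sh[k], ra[k], 0, inf);
  } else if (constraint == 1) {
    double hi0 = use_cur ? std::min(mu_cur[1], mu_cur[2]) : inf;
    out[0] = rtrunc_gamma(sh[0], ra[0], 0, hi0);
    out[1] = rtrunc_gamma(sh[1], ra[1], out[0], inf);
    out[2] = rtrunc_gamma(sh[2], ra[2], out[0], inf);
  } else {
    double hi0 = use_cur ? mu_cur[1] : inf;
    out[0] = rtrunc_gamma(sh[0], ra[0], 0, hi0);
    double hi1 = use_cur ? mu_cur[2] : inf;
    out[1] = rtrunc_gamma(sh[1], ra[1], out[0], hi1);
    out[2] = rtrunc_gamma(sh[2], ra[2], out[1], inf);
  }
}

double log_lik_full(const IntegerMatrix &X, const std::vector<int> &labv,
                    const double *mu) {
  int n = X.nrow();
  double ll = 0;
  int t = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j, ++t)
      ll += R::dpois(X(i, j), mu[labv[t]], 1);
  return ll;
}

double log_hyperprior_cpp(const double *mu, const double *phi,
                          const NumericVector &mu_shape,
                          const NumericVector &mu_rate,
                          const NumericVector &beta_a,
                          const NumericVector &beta_b) {
  double lp = 0;
  for (int k = 0; k < 3; ++k)
    lp += R::dgamma(mu[k], mu_shape[k], 1.0 / mu_rate[k], 1);
  for (int k = 0; k < 2; ++k)
    lp += R::dbeta(phi[k], beta_a[k], beta_b[k], 1);
  return lp;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported pieces.

// [[Rcpp::export]]
List mh_structure_hyper_cpp(IntegerMatrix X, IntegerMatrix E, IntegerMatrix T,
                            NumericVector mu, double q, double p,
                            int n_proposals) {
  int n = X.nrow();
  HyperState st;
  st.init(n, E, T);
  PairTable PT; PT.build(n);
  TripleTable TT; if (n >= 3) TT.build(n);
  double muv[3] = {mu[0], mu[1], mu[2]};
  double lmu[3] = {std::log(mu[0]), std::log(mu[1]), std::log(mu[2])};
  hyper_mh_block(st, X, muv, lmu, q, p, n_proposals, PT, TT);
  return List::create(_["edges"] = st.edge_matrix(),
                      _["triples"] = st.triple_matrix());
}

// [[Rcpp::export]]
List mh_structure_graph_cpp(IntegerMatrix X, IntegerMatrix E1,
                            IntegerMatrix E2, NumericVector mu, double q1,
                            double q2, int n_proposals) {
  int n = X.nrow();
  GraphState st;
  st.init(n, E1, E2);
  PairTable PT; PT.build(n);
  double muv[3] = {mu[0], mu[1], mu[2]};
  double lmu[3] = {std::log(mu[0]), std::log(mu[1]), std::log(mu[2])};
  graph_mh_block(st, X, muv, lmu, q1, q2, n_proposals, PT);
  return List::create(_["weak"] = st.edge_matrix(1),
                      _["strong"] = st.edge_matrix(2));
}

// [[Rcpp::export]]
NumericVector gibbs_mu_cpp(NumericVector sumx, NumericVector cnt,
                           NumericVector shape, NumericVector rate,
                           int constraint, NumericVector mu_cur,
                           bool use_cur) {
  double out[3];
  double mc[3] = {0, 0, 0};
  if (use_cur) { mc[0] = mu_cur[0]; mc[1] = mu_cur[1]; mc[2] = mu_cur[2]; }
  gibbs_mu_draw(&sumx[0], &cnt[0], &shape[0], &rate[0], constraint, mc,
                use_cur, out);
  return NumericVector::create(out[0], out[1], out[2]);
}

// [[Rcpp::export]]
List run_chain_hyper_cpp(IntegerMatrix X, IntegerMatrix E0, IntegerMatrix T0,
                         NumericVector mu0, NumericVector phi0, List spec,
                         int n_samples, int burn_in, int thin, int props,
                         bool update_mu, bool update_phi) {
  int n = X.nrow();
  if (n > 512) stop("hypergraph sampler supports at most 512 vertices");
  HyperState st;
  st.init(n, E0, T0);
  PairTable PT; PT.build(n);
  TripleTable TT; if (n >= 3) TT.build(n);
  const long npairs = (long)PT.pi.size();
  const long ntrip = (long)TT.ti.size();
  NumericVector mu_shape = spec["mu_shape"], mu_rate = spec["mu_rate"];
  NumericVector beta_a = spec["beta_a"], beta_b = spec["beta_b"];
  double mu[3] = {mu0[0], mu0[1], mu0[2]};
  double lmu[3];
  double q = phi0[0], p = phi0[1];
  std::vector<int> labv(npairs);
  List samples(n_samples);
  int kept = 0;
  long total_sweeps = (long)burn_in + (long)n_samples * thin;
  for (long sweep = 1; sweep <= total_sweeps; ++sweep) {
    for (int k = 0; k < 3; ++k) lmu[k] = std::log(mu[k]);
    hyper_mh_block(st, X, mu, lmu, q, p, props, PT, TT);
    {  // refresh label vector (upper triangle, row-major)
      int t = 0;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j, ++t) labv[t] = st.label(i, j);
    }
    if (update_mu) {
      double sumx[3] = {0, 0, 0}, cnt[3] = {0, 0, 0};
      int t = 0;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j, ++t) {
          sumx[labv[t]] += X(i, j);
          cnt[labv[t]] += 1;
        }
      double out[3];
      gibbs_mu_draw(sumx, cnt, &mu_shape[0], &mu_rate[0], 1, mu, true, out);
      for (int k = 0; k < 3; ++k) mu[k] = out[k];
    }
    if (update_phi) {
      q = R::rbeta(beta_a[0] + st.h1, beta_b[0] + npairs - st.h1);
      p = R::rbeta(beta_a[1] + st.h2, beta_b[1] + ntrip - st.h2);
    }
    if (sweep > burn_in && (sweep - burn_in) % thin == 0) {
      double phi[2] = {q, p};
      double lpost =
          log_lik_full(X, labv, mu) +
          st.h1 * std::log(q) + (npairs - st.h1) * std::log1p(-q) +
          st.h2 * std::log(p) + (ntrip - st.h2) * std::log1p(-p) +
          log_hyperprior_cpp(mu, phi, mu_shape, mu_rate, beta_a, beta_b);
      samples[kept++] = List::create(
          _["edges"] = st.edge_matrix(), _["triples"] = st.triple_matrix(),
          _["mu"] = NumericVector::create(mu[0], mu[1], mu[2]),
          _["phi"] = NumericVector::create(_["q"] = q, _["p"] = p),
          _["log_posterior"] = lpost, _["sweep"] = (double)sweep);
    }
  }
  return samples;
}

// [[Rcpp::export]]
List run_chain_graph_cpp(IntegerMatrix X, IntegerMatrix E1_0,
                         IntegerMatrix E2_0, NumericVector mu0,
                         NumericVector phi0, List spec, int n_samples,
                         int burn_in, int thin, int props, bool update_mu,
                         bool update_phi) {
  int n = X.nrow();
  GraphState st;
  st.init(n, E1_0, E2_0);
  PairTable PT; PT.build(n);
  const long npairs = (long)PT.pi.size();
  NumericVector mu_shape = spec["mu_shape"], mu_rate = spec["mu_rate"];
  NumericVector beta_a = spec["beta_a"], beta_b = spec["beta_b"];
  double mu[3] = {mu0[0], mu0[1], mu0[2]};
  double lmu[3];
  double q1 = phi0[0], q2 = phi0[1];
  std::vector<int> labv(npairs);
  List samples(n_samples);
  int kept = 0;
  long total_sweeps = (long)burn_in + (long)n_samples * thin;
  for (long sweep = 1; sweep <= total_sweeps; ++sweep) {
    for (int k = 0; k < 3; ++k) lmu[k] = std::log(mu[k]);
    graph_mh_block(st, X, mu, lmu, q1, q2, props, PT);
    {
      int t = 0;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j, ++t) labv[t] = st.lab[(long)i * n + j];
    }
    if (update_mu) {
      double sumx[3] = {0, 0, 0}, cnt[3] = {0, 0, 0};
      int t = 0;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j, ++t) {
          sumx[labv[t]] += X(i, j);
          cnt[labv[t]] += 1;
        }
      double out[3];
      gibbs_mu_draw(sumx, cnt, &mu_shape[0], &mu_rate[0], 2, mu, true, out);
      for (int k = 0; k < 3; ++k) mu[k] = out[k];
    }
    if (update_phi) {
      q1 = R::rbeta(beta_a[0] + st.m1, beta_b[0] + npairs - st.m1 - st.m2);
      q2 = R::rbeta(beta_a[1] + st.m2, beta_b[1] + npairs - st.m2);
    }
    if (sweep > burn_in && (sweep - burn_in) % thin == 0) {
      double phi[2] = {q1, q2};
      double lpost =
          log_lik_full(X, labv, mu) +
          graph_prior_terms(st.m1, st.m2, npairs, std::log(q1),
                            std::log1p(-q1), std::log(q2), std::log1p(-q2)) +
          log_hyperprior_cpp(mu, phi, mu_shape, mu_rate, beta_a, beta_b);
      samples[kept++] = List::create(
          _["weak"] = st.edge_matrix(1), _["strong"] = st.edge_matrix(2),
          _["mu"] = NumericVector::create(mu[0], mu[1], mu[2]),
          _["phi"] = NumericVector::create(_["q1"] = q1, _["q2"] = q2),
          _["log_posterior"] = lpost, _["sweep"] = (double)sweep);
    }
  }
  return samples;
}
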