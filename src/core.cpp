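// Numerical core: scaled forward-backward recursions, Viterbi, and the
// clustered LIF network integrator. Everything here is called from thin R
// wrappers that own validation and bookkeeping.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Scaled forward-backward pass for one trial.
//
// logB: m x T matrix of per-bin log emission probabilities.
// Gamma: m x m row-stochastic transition matrix.
// pi: length-m initial state distribution.
// want_xi: return the full m x m x (T-1) pairwise-posterior array.
//
// Per-bin scaling: emissions are exponentiated after subtracting the bin
// maximum, and the forward variables are renormalized each bin; the log
// scale factors accumulate into the exact log-likelihood.
// [[Rcpp::export]]
List fb_cpp(const arma::mat& logB, const arma::mat& Gamma,
            const arma::vec& pi, bool want_xi) {
  const arma::uword m = logB.n_rows, T = logB.n_cols;
  arma::mat btil(m, T);       // emissions scaled by per-bin max
  arma::vec mx(T);
  for (arma::uword t = 0; t < T; ++t) {
    mx(t) = logB.col(t).max();
    btil.col(t) = arma::exp(logB.col(t) - mx(t));
  }
  arma::mat alpha(m, T), beta(m, T);
  arma::vec c(T);
  alpha.col(0) = pi % btil.col(0);
  c(0) = arma::accu(alpha.col(0));
  if (!(c(0) > 0.0))
    stop("forward pass degenerate: zero total probability at bin 1");
  alpha.col(0) /= c(0);
  for (arma::uword t = 1; t < T; ++t) {
    alpha.col(t) = (Gamma.t() * alpha.col(t - 1)) % btil.col(t);
    c(t) = arma::accu(alpha.col(t));
    if (!(c(t) > 0.0))
      stop("forward pass degenerate: zero total probability at bin %d",
           (int)(t + 1));
    alpha.col(t) /= c(t);
  }
  double loglik = arma::accu(arma::log(c)) + arma::accu(mx);

  beta.col(T - 1).ones();
  for (arma::uword t = T - 1; t >= 1; --t) {
    beta.col(t - 1) =
      Gamma * (btil.col(t) % beta.col(t)) / c(t);
  }
  arma::mat q = alpha % beta;  // already normalized per bin
  // renormalize defensively against accumulated round-off
  for (arma::uword t = 0; t < T; ++t) q.col(t) /= arma::accu(q.col(t));

  arma::mat xi_sum(m, m, arma::fill::zeros);
  arma::cube xi;
  if (want_xi && T > 1) xi.set_size(m, m, T - 1);
  for (arma::uword t = 0; t + 1 < T; ++t) {
    arma::mat x = (alpha.col(t) * (btil.col(t + 1) % beta.col(t + 1)).t())
      % Gamma / c(t + 1);
    xi_sum += x;
    if (want_xi) xi.slice(t) = x;
  }
  List out = List::create(
    _["q"] = q, _["xi_sum"] = xi_sum, _["loglik"] = loglik);
  if (want_xi && T > 1) out["xi"] = xi;
  return out;
}

// Log-space Viterbi path for one trial. Returns the 1-based max-probability
// state path and its joint log-probability. Ties broken by lowest index
// (index_max returns the first maximum).
// [[Rcpp::export]]
List viterbi_cpp(const arma::mat& logB, const arma::mat& Gamma,
                 const arma::vec& pi) {
  const arma::uword m = logB.n_rows, T = logB.n_cols;
  arma::mat lG = arma::log(Gamma);
  arma::mat delta(m, T);
  arma::umat psi(m, T, arma::fill::zeros);
  delta.col(0) = arma::log(pi) + logB.col(0);
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword j = 0; j < m; ++j) {
      arma::vec cand = delta.col(t - 1) + lG.col(j);
      arma::uword best = cand.index_max();
      psi(j, t) = best;
      delta(j, t) = cand(best) + logB(j, t);
    }
  }
  arma::uword last = delta.col(T - 1).index_max();
  double logp = delta(last, T - 1);
  IntegerVector path(T);
  path[T - 1] = (int)last + 1;
  for (arma::uword t = T - 1; t >= 1; --t) {
    last = psi(path[t] - 1, t);
    path[t - 1] = (int)last + 1;
  }
  return List::create(_["path"] = path, _["logp"] = logp);
}

// Clustered LIF network, forward Euler.
//
// Units: membrane potential in mV, time in ms, currents in nA, capacitance
// in nF (so I/C is directly mV/ms). Each presynaptic spike adds w/tau_syn
// to the postsynaptic current, which then decays exponentially: the
// delta-function drive integrated across a spike gives a total injected
// charge w (nA*ms) per spike.
//
// record: 0-based indices of neurons whose spikes are returned.
// Returns spike (time_ms, neuron) pairs for recorded neurons only.
// [[Rcpp::export]]
List snn_cpp(int n_e, int n_i, int q_clusters, double f_clustered,
             double p_ee, double p_ei, double p_ie, double p_ii,
             double w_ee, double w_ie, double w_ei, double w_ii,
             double sd_ee_ei, double sd_ie_ii,
             double j_plus, double j_minus,
             double v_th_e, double v_th_i, double v_r, double v_l,
             double tau_e, double tau_i, double tau_syn_e, double tau_syn_i,
             double cap, double i_ext_e, double i_ext_i,
             double refractory, double euler_dt, double duration,
             const arma::ivec& record) {
  const int n = n_e + n_i;
  // cluster label per excitatory neuron: 1..Q for the clustered fraction,
  // 0 for background E and for I neurons
  const int n_clustered = (int)std::round(f_clustered * n_e);
  const int csize = n_clustered / q_clusters;
  std::vector<int> cluster(n, 0);
  for (int i = 0; i < n_clustered; ++i) cluster[i] = i / csize + 1;

  // adjacency in CSR-by-presynaptic-neuron layout
  std::vector<std::vector<int>> post(n);
  std::vector<std::vector<double>> wt(n);
  for (int pre = 0; pre < n; ++pre) {
    bool pre_e = pre < n_e;
    for (int po = 0; po < n; ++po) {
      if (po == pre) continue;
      bool po_e = po < n_e;
      double p, mu, sd;
      if (pre_e && po_e)       { p = p_ee; mu = w_ee; sd = sd_ee_ei; }
      else if (pre_e && !po_e) { p = p_ie; mu = w_ie; sd = sd_ie_ii; }
      else if (!pre_e && po_e) { p = p_ei; mu = w_ei; sd = sd_ee_ei; }
      else                     { p = p_ii; mu = w_ii; sd = sd_ie_ii; }
      if (R::unif_rand() < p) {
        double scale = 1.0;
        if (pre_e && po_e && cluster[pre] > 0 && cluster[po] > 0)
          scale = (cluster[pre] == cluster[po]) ? j_plus : j_minus;
        post[pre].push_back(po);
        wt[pre].push_back((mu + sd * R::norm_rand()) * scale);
      }
    }
  }

  arma::vec V(n), Ie(n, arma::fill::zeros), Ii(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) V(i) = v_l + R::unif_rand() * 5.0;
  arma::vec refr_until(n);
  refr_until.fill(-1.0);
  std::vector<bool> rec_mask(n, false);
  for (arma::uword k = 0; k < record.n_elem; ++k) rec_mask[record(k)] = true;

  std::vector<double> sp_t;
  std::vector<int> sp_n;
  const long nsteps = (long)std::round(duration / euler_dt);
  const double de = euler_dt / tau_syn_e, di = euler_dt / tau_syn_i;
  std::vector<int> fired;
  fired.reserve(256);
  for (long s = 0; s < nsteps; ++s) {
    double t = s * euler_dt;
    fired.clear();
    for (int i = 0; i < n; ++i) {
      if (t < refr_until(i)) { V(i) = v_r; continue; }
      double tau = (i < n_e) ? tau_e : tau_i;
      double iext = (i < n_e) ? i_ext_e : i_ext_i;
      V(i) += euler_dt *
        (-(V(i) - v_l) / tau + (Ie(i) + Ii(i) + iext) / cap);
      double vth = (i < n_e) ? v_th_e : v_th_i;
      if (V(i) >= vth) {
        V(i) = v_r;
        refr_until(i) = t + refractory;
        fired.push_back(i);
        if (rec_mask[i]) { sp_t.push_back(t); sp_n.push_back(i); }
      }
      if (!std::isfinite(V(i)))
        stop("LIF integration diverged (non-finite membrane potential)");
    }
    Ie -= Ie * de;
    Ii -= Ii * di;
    for (int pre : fired) {
      bool pre_e = pre < n_e;
      const std::vector<int>& ps = post[pre];
      const std::vector<double>& ws = wt[pre];
      if (pre_e)
        for (size_t k = 0; k < ps.size(); ++k) Ie(ps[k]) += ws[k] / tau_syn_e;
      else
        for (size_t k = 0; k < ps.size(); ++k) Ii(ps[k]) += ws[k] / tau_syn_i;
    }
  }
  return List::create(_["time_ms"] = wrap(sp_t), _["neuron"] = wrap(sp_n),
                      _["cluster_of"] = wrap(cluster));
}
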