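#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// One simulated stimulus presentation (trial) of the two-layer k-WTA network.
//
// Per timestep: (1) synaptic traces are advanced from the spikes of the
// previous timestep (double-exponential kernel, recursive form); (2) afferent
// Bernoulli spikes are drawn; (3) excitatory membrane potentials are computed
// from traces of spikes strictly before t, and spikes are sampled through the
// logistic of the potential with absolute refractoriness; (4) inhibitory
// rectified rates generate Poisson-discretized spikes; (5) optionally the
// response vector is identified against the clustering sets (energy
// distances, leave-one-out thresholds, bootstrap membership, softmax action)
// and (6) optionally eligibility traces accumulate and a reward converts them
// into clipped weight updates plus a FIFO cluster append.
//
// All random draws come from R's RNG (unif_rand) in a documented order, and
// every floating-point reduction reproduces the exact grouping of the
// reference R implementation (run_trial_r): the feedforward drive W.x~ uses
// the same BLAS dgemm R's %*% calls, and the remaining reductions use long
// double accumulators matching R's sum(). Trials are therefore reproducible
// bit-for-bit from an R seed through either route.

// matches weight_penalty() in R bit-for-bit (expm1 avoids cancellation near
// the clip floor)
static inline double penalty(double w) {
  return (1.0 - 1.0 / w) + 1.0 / std::expm1(w);
}

struct Cluster {
  // members stored as column vectors (length K), FIFO order (oldest first)
  std::vector<std::vector<double>> cols;
  // caches, valid while the member list is unchanged
  bool valid = false;
  std::vector<double> D;    // m x m pairwise distances, column-major
  std::vector<double> loo;  // leave-one-out energy distances
};

static void refresh_cache(Cluster& c) {
  if (c.valid) return;
  const int m = (int)c.cols.size();
  const int K = (int)c.cols[0].size();
  c.D.assign((size_t)m * m, 0.0);
  for (int i = 0; i < m - 1; ++i) {
    const double* xi = c.cols[(size_t)i].data();
    for (int j = i + 1; j < m; ++j) {
      const double* xj = c.cols[(size_t)j].data();
      long double acc = 0.0L;
      for (int k = 0; k < K; ++k) {
        const double d = xi[k] - xj[k];
        acc += d * d;
      }
      const double dist = std::sqrt((double)acc);
      c.D[(size_t)j * m + i] = dist;
      c.D[(size_t)i * m + j] = dist;
    }
  }
  // leave-one-out energy distance of each member to the rest, O(m) from
  // cached row sums: e_i = 2/(m-1) rs_i - (tot - 2 rs_i) / (m-1)^2
  std::vector<double> rs((size_t)m);
  for (int i = 0; i < m; ++i) {
    long double acc = 0.0L;
    for (int j = 0; j < m; ++j) acc += c.D[(size_t)j * m + i];
    rs[(size_t)i] = (double)acc;
  }
  long double tot_acc = 0.0L;
  for (int i = 0; i < m; ++i) tot_acc += rs[(size_t)i];
  const double tot = (double)tot_acc;
  const double mm1 = (double)(m - 1);
  c.loo.assign((size_t)m, 0.0);
  for (int i = 0; i < m; ++i)
    c.loo[(size_t)i] = (2.0 / mm1) * rs[(size_t)i] - (tot - 2.0 * rs[(size_t)i]) / (mm1 * mm1);
  c.valid = true;
}

static void dist_to_members(const Cluster& c, const std::vector<double>& z,
                            std::vector<double>& dz) {
  const int m = (int)c.cols.size();
  const int K = (int)z.size();
  dz.assign((size_t)m, 0.0);
  for (int i = 0; i < m; ++i) {
    const double* xi = c.cols[(size_t)i].data();
    long double acc = 0.0L;
    for (int k = 0; k < K; ++k) {
      const double d = xi[k] - z[k];
      acc += d * d;
    }
    dz[(size_t)i] = std::sqrt((double)acc);
  }
}

// [[Rcpp::export(name = ".run_trial_engine")]]
List run_trial_engine(NumericMatrix W0, NumericMatrix V0,
                      IntegerMatrix M_IE, IntegerMatrix M_EI, IntegerMatrix M_II,
                      NumericVector b, NumericVector rates,
                      List clusters0, int label, int T, List opts) {
  const int K = W0.nrow(), N = W0.ncol(), J = M_EI.nrow();
  const double v_EI = as<double>(opts["v_EI"]);
  const double v_IE = as<double>(opts["v_IE"]);
  const double v_II = as<double>(opts["v_II"]);
  const double tau_r = as<double>(opts["tau_r"]);
  const double tau_f = as<double>(opts["tau_f"]);
  const int refrac_E = as<int>(opts["refrac_E"]);
  const int refrac_I = as<int>(opts["refrac_I"]);
  const double gamma = as<double>(opts["gamma"]);
  const double eta = as<double>(opts["eta"]);
  const double clip_eps = as<double>(opts["clip_eps"]);
  const double alpha_sig = as<double>(opts["alpha_sig"]);
  const int R = as<int>(opts["R"]);
  const int n_cluster = as<int>(opts["n_cluster"]);
  const bool do_ident = as<bool>(opts["do_ident"]);
  const bool do_learn = as<bool>(opts["do_learn"]);
  const bool collect_x = as<bool>(opts["collect_x"]);
  const int reward_override = as<int>(opts["reward_override"]);

  NumericMatrix W = clone(W0), V = clone(V0);
  const int S = clusters0.size();
  std::vector<Cluster> clusters((size_t)S);
  for (int s = 0; s < S; ++s) {
    NumericMatrix ms = clusters0[s];
    if (ms.nrow() != K) stop("cluster member length does not match K");
    Cluster& c = clusters[(size_t)s];
    for (int i = 0; i < ms.ncol(); ++i) {
      std::vector<double> col((size_t)K);
      for (int k = 0; k < K; ++k) col[(size_t)k] = ms(k, i);
      c.cols.push_back(col);
    }
    if (do_ident && (int)c.cols.size() < 2)
      stop("all clustering sets must have >= 2 members before identification");
  }

  const double df = std::exp(-1.0 / tau_f), dr = std::exp(-1.0 / tau_r);
  std::vector<double> xf(N, 0), xr(N, 0), zf(K, 0), zr(K, 0), yf(J, 0), yr(J, 0);
  std::vector<double> xt(N), zt(K), yt(J);
  std::vector<int> x_prev(N, 0), z_prev(K, 0), y_prev(J, 0);
  std::vector<int> rc_e(K, 0), rc_i(J, 0);
  std::vector<double> u(K), ff(K), rho(J);

  std::vector<double> EW, EV;
  if (do_learn) { EW.assign((size_t)K * N, 0.0); EV.assign((size_t)K * K, 0.0); }

  IntegerMatrix zras(K, T), yras(J, T);
  IntegerMatrix xras = collect_x ? IntegerMatrix(N, T) : IntegerMatrix(0, 0);
  NumericVector x_count(N);
  IntegerVector rewards(T), actions(T);
  NumericMatrix pmat = do_ident ? NumericMatrix(S, T) : NumericMatrix(0, 0);

  std::vector<double> dz, samp((size_t)std::max(R, 1)), thr((size_t)std::max(S, 1)),
      pvec((size_t)std::max(S, 1)), cum((size_t)std::max(S, 1));
  std::vector<int> xspk(N), zspk(K), yspk(J), idxv;
  std::vector<double> zvec((size_t)K);
  const char* noTrans = "N";
  const double d_one = 1.0, d_zero = 0.0;
  const int i_one = 1;

  for (int t = 0; t < T; ++t) {
    // (1) traces from spikes up to t-1
    for (int n = 0; n < N; ++n) {
      xf[n] = (xf[n] + x_prev[n]) * df;
      xr[n] = (xr[n] + x_prev[n]) * dr;
      xt[n] = xf[n] - xr[n];
    }
    for (int k = 0; k < K; ++k) {
      zf[k] = (zf[k] + z_prev[k]) * df;
      zr[k] = (zr[k] + z_prev[k]) * dr;
      zt[k] = zf[k] - zr[k];
    }
    for (int j = 0; j < J; ++j) {
      yf[j] = (yf[j] + y_prev[j]) * df;
      yr[j] = (yr[j] + y_prev[j]) * dr;
      yt[j] = yf[j] - yr[j];
    }

    // (2) afferent Bernoulli spikes
    for (int n = 0; n < N; ++n) xspk[n] = (unif_rand() < rates[n]) ? 1 : 0;

    // (3) excitatory potentials (feedforward term via the same dgemm that
    // backs R's %*%) and stochastic spiking
    F77_CALL(dgemm)(noTrans, noTrans, &K, &i_one, &N, &d_one,
                    W.begin(), &K, xt.data(), &N, &d_zero, ff.data(), &K
                    FCONE FCONE);
    for (int k = 0; k < K; ++k) {
      long double a2 = 0.0L, a3 = 0.0L;
      for (int k2 = 0; k2 < K; ++k2) a2 += V(k, k2) * zt[k2];
      for (int j = 0; j < J; ++j) a3 += (double)M_IE(k, j) * yt[j];
      u[k] = (ff[k] + (double)a2) - v_EI * (double)a3 + b[k];
    }
    for (int k = 0; k < K; ++k) {
      if (rc_e[k] > 0) { zspk[k] = 0; rc_e[k]--; }
      else {
        const double p = 1.0 / (1.0 + std::exp(-u[k]));
        if (unif_rand() < p) { zspk[k] = 1; rc_e[k] = refrac_E; }
        else zspk[k] = 0;
      }
    }

    // (4) inhibitory rectified rates and Poisson-discretized spiking
    for (int j = 0; j < J; ++j) {
      long double a1 = 0.0L, a2 = 0.0L;
      for (int k = 0; k < K; ++k) a1 += (double)M_EI(j, k) * zt[k];
      for (int j2 = 0; j2 < J; ++j2) a2 += (double)M_II(j, j2) * yt[j2];
      double r = v_IE * (double)a1 - v_II * (double)a2;
      rho[j] = r > 0 ? r : 0.0;
    }
    for (int j = 0; j < J; ++j) {
      if (rc_i[j] > 0) { yspk[j] = 0; rc_i[j]--; }
      else {
        const double p = 1.0 - std::exp(-rho[j]);
        if (unif_rand() < p) { yspk[j] = 1; rc_i[j] = refrac_I; }
        else yspk[j] = 0;
      }
    }

    // (5) identification
    int r_t = -1, a_t = 0;
    if (do_ident) {
      for (int k = 0; k < K; ++k) zvec[(size_t)k] = (double)zspk[k];
      // per-cluster acceptance thresholds from R leave-one-out resamples
      for (int s = 0; s < S; ++s) {
        Cluster& c = clusters[(size_t)s];
        const int m = (int)c.cols.size();
        refresh_cache(c);
        for (int r = 0; r < R; ++r) {
          int i = (int)(unif_rand() * m);
          samp[(size_t)r] = c.loo[(size_t)(i < m ? i : m - 1)];
        }
        std::sort(samp.begin(), samp.begin() + R);
        int idx = (int)std::ceil((1.0 - alpha_sig) * R);
        if (idx < 1) idx = 1; if (idx > R) idx = R;
        thr[(size_t)s] = samp[(size_t)(idx - 1)];
      }
      double e_acc = thr[0];
      for (int s = 1; s < S; ++s) if (thr[(size_t)s] < e_acc) e_acc = thr[(size_t)s];
      // bootstrap membership probabilities against the common threshold
      for (int s = 0; s < S; ++s) {
        Cluster& c = clusters[(size_t)s];
        const int m = (int)c.cols.size();
        dist_to_members(c, zvec, dz);
        const double* D = c.D.data();
        idxv.assign((size_t)m, 0);
        int hit = 0;
        for (int r = 0; r < R; ++r) {
          for (int a = 0; a < m; ++a) {
            int i = (int)(unif_rand() * m);
            idxv[(size_t)a] = i < m ? i : m - 1;
          }
          long double s1 = 0.0L;
          for (int a = 0; a < m; ++a) s1 += dz[(size_t)idxv[(size_t)a]];
          long double s2 = 0.0L;
          for (int bb = 0; bb < m; ++bb) {     // column-major like R's sum(D[idx, idx])
            const double* col = D + (size_t)idxv[(size_t)bb] * m;
            for (int a = 0; a < m; ++a) s2 += col[idxv[(size_t)a]];
          }
          const double e = (2.0 / m) * (double)s1 - (double)s2 / ((double)m * m);
          if (e <= e_acc) ++hit;
        }
        pvec[(size_t)s] = (double)hit / R;
        pmat(s, t) = pvec[(size_t)s];
      }
      // softmax action
      long double acc = 0.0L;
      for (int s = 0; s < S; ++s) { acc += std::exp(pvec[(size_t)s]); cum[(size_t)s] = (double)acc; }
      const double uu = unif_rand() * cum[(size_t)(S - 1)];
      a_t = S;
      for (int s = 0; s < S; ++s) if (cum[(size_t)s] >= uu) { a_t = s + 1; break; }
      r_t = (a_t == label) ? 1 : 0;
      if (reward_override >= 0) r_t = reward_override;
    }

    // (6) eligibility and reward-gated updates (learning only)
    if (do_learn) {
      for (size_t i = 0; i < EW.size(); ++i) EW[i] *= gamma;
      for (size_t i = 0; i < EV.size(); ++i) EV[i] *= gamma;
      for (int k = 0; k < K; ++k) {
        if (!zspk[k]) continue;
        for (int n = 0; n < N; ++n)
          EW[(size_t)n * K + k] += xt[n] - penalty(W(k, n));
        for (int k2 = 0; k2 < K; ++k2) {
          if (k2 == k) continue;
          EV[(size_t)k2 * K + k] += zt[k2] - penalty(V(k, k2));
        }
      }
      if (r_t == 1) {
        const double hi = 1.0 - clip_eps;
        for (int n = 0; n < N; ++n)
          for (int k = 0; k < K; ++k) {
            double w = W(k, n) + eta * EW[(size_t)n * K + k];
            W(k, n) = std::min(std::max(w, clip_eps), hi);
          }
        for (int k2 = 0; k2 < K; ++k2)
          for (int k = 0; k < K; ++k) {
            if (k == k2) { V(k, k2) = 0.0; continue; }
            double w = V(k, k2) + eta * EV[(size_t)k2 * K + k];
            V(k, k2) = std::min(std::max(w, clip_eps), hi);
          }
        // FIFO append to the presented stimulus's clustering set; an empty
        // response vector identifies nothing and is not collected
        int nspk = 0;
        for (int k = 0; k < K; ++k) nspk += zspk[k];
        if (nspk > 0) {
          Cluster& c = clusters[(size_t)(label - 1)];
          std::vector<double> col((size_t)K);
          for (int k = 0; k < K; ++k) col[(size_t)k] = (double)zspk[k];
          c.cols.push_back(col);
          while ((int)c.cols.size() > n_cluster) c.cols.erase(c.cols.begin());
          c.valid = false;
        }
      }
    }

    // bookkeeping
    for (int k = 0; k < K; ++k) zras(k, t) = zspk[k];
    for (int j = 0; j < J; ++j) yras(j, t) = yspk[j];
    for (int n = 0; n < N; ++n) {
      x_count[n] += xspk[n];
      if (collect_x) xras(n, t) = xspk[n];
    }
    rewards[t] = r_t;
    actions[t] = a_t;
    x_prev = xspk; z_prev = zspk; y_prev = yspk;
  }

  List outClusters(S);
  for (int s = 0; s < S; ++s) {
    const Cluster& c = clusters[(size_t)s];
    NumericMatrix ms(K, (int)c.cols.size());
    for (int i = 0; i < (int)c.cols.size(); ++i)
      for (int k = 0; k < K; ++k) ms(k, i) = c.cols[(size_t)i][(size_t)k];
    outClusters[s] = ms;
  }

  List out = List::create(
    _["W"] = W, _["V"] = V, _["clusters"] = outClusters,
    _["z"] = zras, _["y"] = yras, _["x_count"] = x_count,
    _["rewards"] = rewards, _["actions"] = actions, _["p"] = pmat);
  if (collect_x) out["x"] = xras;
  return out;
}
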