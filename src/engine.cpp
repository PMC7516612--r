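// Nested-sampling engine: likelihood evaluation, lawn-mower walk, fallback
// search strategies, blurring mean-shift clustering, and the main sampling
// loop. Exposed to R through thin wrappers; all randomness uses R's RNG so
// set.seed() gives bit-reproducible runs.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logaddexp(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a > b) return a + std::log1p(std::exp(b - a));
  return b + std::log1p(std::exp(a - b));
}

// ---------------------------------------------------------------------------
// Likelihood specification
//
// kind: 0 = built-in model + counting statistic
//       1 = direct R log-likelihood callback fn(a) -> scalar lnL
//       2 = R predict callback fn(a) -> expected values, + counting statistic
// stat: 0 = poisson, 1 = gaussian
// model: 0 = gauss_peaks (a = bg, w, x0_1..P, A_1..P)
//        1 = mod_decay   (a = C, tau, amod, omega, phi, bg)
// ---------------------------------------------------------------------------
struct Lik {
  int kind, stat, model, npeaks;
  std::vector<double> x, cnt, y, s;
  double lgamma_sum;   // sum lgamma(n_i + 1), poisson
  double gauss_norm;   // sum log(s_i * sqrt(2*pi)), gaussian
  RObject fnobj;
  std::vector<double> lam;   // scratch for predictions
  long n_eval;

  explicit Lik(List spec) : n_eval(0) {
    kind = as<int>(spec["kind"]);
    stat = spec.containsElementNamed("stat") ? as<int>(spec["stat"]) : 0;
    model = spec.containsElementNamed("model_id") ? as<int>(spec["model_id"]) : -1;
    npeaks = spec.containsElementNamed("npeaks") ? as<int>(spec["npeaks"]) : 0;
    lgamma_sum = 0.0; gauss_norm = 0.0;
    if (kind != 1) {
      NumericVector xs = spec["x"];
      x.assign(xs.begin(), xs.end());
      if (stat == 0) {
        NumericVector n = spec["counts"];
        cnt.assign(n.begin(), n.end());
        lgamma_sum = as<double>(spec["lgamma_sum"]);
      } else {
        NumericVector yy = spec["y"], ss = spec["sigma"];
        y.assign(yy.begin(), yy.end());
        s.assign(ss.begin(), ss.end());
        gauss_norm = as<double>(spec["gauss_norm"]);
      }
      lam.resize(x.size());
    }
    if (kind == 1 || kind == 2) fnobj = spec["fn"];
  }

  void predict_builtin(const double* a, int J) {
    size_t M = x.size();
    if (model == 0) {                      // gauss_peaks
      double bg = a[0], w = a[1];
      if (w <= 0.0) stop("invalid model: peak width must be > 0");
      double inv2w2 = 1.0 / (2.0 * w * w);
      double norm = 1.0 / (w * std::sqrt(2.0 * M_PI));
      for (size_t i = 0; i < M; ++i) lam[i] = bg;
      for (int p = 0; p < npeaks; ++p) {
        double x0 = a[2 + p], A = a[2 + npeaks + p];
        double amp = A * norm;
        for (size_t i = 0; i < M; ++i) {
          double dx = x[i] - x0;
          lam[i] += amp * std::exp(-dx * dx * inv2w2);
        }
      }
    } else if (model == 1) {               // mod_decay
      double C = a[0], tau = a[1], amod = a[2], om = a[3], phi = a[4], bg = a[5];
      if (tau <= 0.0) stop("invalid model: lifetime must be > 0");
      for (size_t i = 0; i < M; ++i)
        lam[i] = C * std::exp(-x[i] / tau) * (1.0 + amod * std::cos(om * x[i] + phi)) + bg;
    } else {
      stop("unknown built-in model id");
    }
    (void)J;
  }

  double stat_loglik() {
    size_t M = x.size();
    double ll = 0.0;
    if (stat == 0) {
      for (size_t i = 0; i < M; ++i) {
        double l = lam[i];
        if (l < 0.0) stop("invalid model: negative Poisson rate");
        if (l == 0.0) {
          if (cnt[i] > 0.0) return NEG_INF;   // 0 rate, observed counts
          // n = 0: 0*log(0) := 0, contributes nothing
        } else {
          ll += cnt[i] * std::log(l) - l;
        }
      }
      ll -= lgamma_sum;
    } else {
      for (size_t i = 0; i < M; ++i) {
        double r = (y[i] - lam[i]) / s[i];
        ll -= 0.5 * r * r;
      }
      ll -= gauss_norm;
    }
    return ll;
  }

  double eval(const double* a, int J) {
    ++n_eval;
    if (kind == 0) {
      predict_builtin(a, J);
      return stat_loglik();
    }
    NumericVector av(a, a + J);
    Function fn(fnobj);
    if (kind == 1) {
      double v = as<double>(fn(av));
      if (ISNAN(v)) return NEG_INF;
      return v;
    }
    NumericVector pr = fn(av);
    if ((size_t)pr.size() != x.size()) stop("model prediction length mismatch");
    std::copy(pr.begin(), pr.end(), lam.begin());
    return stat_loglik();
  }
};

// [[Rcpp::export]]
double eval_loglik_cpp(List spec, NumericVector a) {
  Lik lik(spec);
  return lik.eval(a.begin(), a.size());
}

// [[Rcpp::export]]
NumericVector eval_loglik_batch_cpp(List spec, NumericMatrix A) {
  Lik lik(spec);
  int K = A.nrow(), J = A.ncol();
  NumericVector out(K);
  std::vector<double> a(J);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < J; ++j) a[j] = A(k, j);
    out[k] = lik.eval(a.data(), J);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector predict_builtin_cpp(int model_id, int npeaks, NumericVector x,
                                  NumericVector a) {
  List spec = List::create(_["kind"] = 0, _["stat"] = 0, _["model_id"] = model_id,
                           _["npeaks"] = npeaks, _["x"] = x,
                           _["counts"] = NumericVector(x.size()),
                           _["lgamma_sum"] = 0.0);
  Lik lik(spec);
  lik.predict_builtin(a.begin(), a.size());
  return NumericVector(lik.lam.begin(), lik.lam.end());
}

// ---------------------------------------------------------------------------
// Blurring mean shift (the ensemble itself is replaced by the shifted means
// each iteration), truncated flat or Gaussian kernel, single-linkage merge of
// the converged modes.
// ---------------------------------------------------------------------------
struct MSResult {
  std::vector<int> labels;           // 1..C
  int C;
  std::vector<double> modes;         // C x J, row-major
  int iterations;
  bool converged;
};

static MSResult mean_shift_core(const std::vector<double>& X0, int K, int J,
                                const std::vector<char>& use_dim,
                                int kernel, double D, double ell,
                                double tol, int max_iter, double merge_dist,
                                bool blurring) {
  // standard mode: the data stay fixed at X0 and only the query points M
  // iterate (each can be frozen once converged); blurring mode: the shifted
  // ensemble replaces the data each iteration.
  std::vector<double> M(X0), Mnew(K * J);
  std::vector<char> active(K, 1);
  int it = 0;
  bool conv = false;
  double D2 = D * D;
  for (it = 1; it <= max_iter; ++it) {
    double maxdisp = 0.0;
    const std::vector<double>& data = blurring ? M : X0;
    for (int i = 0; i < K; ++i) {
      const double* mi = &M[(size_t)i * J];
      double* out = &Mnew[(size_t)i * J];
      if (!blurring && !active[i]) {
        for (int j = 0; j < J; ++j) out[j] = mi[j];
        continue;
      }
      double wsum = 0.0;
      std::vector<double> acc(J, 0.0);
      for (int jpt = 0; jpt < K; ++jpt) {
        const double* mj = &data[(size_t)jpt * J];
        double d2 = 0.0;
        for (int j = 0; j < J; ++j) {
          if (!use_dim[j]) continue;
          double dd = mi[j] - mj[j];
          d2 += dd * dd;
        }
        if (d2 >= D2) continue;
        double w = 1.0;
        if (kernel == 1) w = std::exp(-std::sqrt(d2) / ell);
        wsum += w;
        for (int j = 0; j < J; ++j) acc[j] += w * mj[j];
      }
      if (wsum > 0.0) {
        double disp2 = 0.0;
        for (int j = 0; j < J; ++j) {
          out[j] = acc[j] / wsum;
          double dd = out[j] - mi[j];
          if (use_dim[j]) disp2 += dd * dd;
        }
        double disp = std::sqrt(disp2);
        if (disp > maxdisp) maxdisp = disp;
        if (!blurring && disp < tol) active[i] = 0;
      } else {
        for (int j = 0; j < J; ++j) out[j] = mi[j];
        if (!blurring) active[i] = 0;
      }
    }
    M.swap(Mnew);
    if (maxdisp < tol) { conv = true; break; }
  }
  if (it > max_iter) it = max_iter;

  // single-linkage merge of converged points within merge_dist (union-find)
  std::vector<int> parent(K);
  for (int i = 0; i < K; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  double md2 = merge_dist * merge_dist;
  for (int i = 0; i < K; ++i)
    for (int jpt = i + 1; jpt < K; ++jpt) {
      double d2 = 0.0;
      for (int j = 0; j < J; ++j) {
        if (!use_dim[j]) continue;
        double dd = M[(size_t)i * J + j] - M[(size_t)jpt * J + j];
        d2 += dd * dd;
      }
      if (d2 < md2) {
        int a = find(i), b = find(jpt);
        if (a != b) parent[b] = a;
      }
    }
  MSResult res;
  res.labels.assign(K, 0);
  std::vector<int> rootlab(K, 0);
  int C = 0;
  for (int i = 0; i < K; ++i) {
    int r = find(i);
    if (rootlab[r] == 0) rootlab[r] = ++C;
    res.labels[i] = rootlab[r];
  }
  res.C = C;
  res.modes.assign((size_t)C * J, 0.0);
  std::vector<int> csize(C, 0);
  for (int i = 0; i < K; ++i) {
    int c = res.labels[i] - 1;
    ++csize[c];
    for (int j = 0; j < J; ++j) res.modes[(size_t)c * J + j] += M[(size_t)i * J + j];
  }
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < J; ++j) res.modes[(size_t)c * J + j] /= csize[c];
  res.iterations = it;
  res.converged = conv;
  return res;
}

// [[Rcpp::export]]
List mean_shift_cpp(NumericMatrix X, LogicalVector use_dim, int kernel,
                    double D, double ell, double tol, int max_iter,
                    double merge_dist, bool blurring) {
  int K = X.nrow(), J = X.ncol();
  std::vector<double> x0((size_t)K * J);
  std::vector<char> ud(J);
  for (int j = 0; j < J; ++j) ud[j] = use_dim[j] ? 1 : 0;
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < J; ++j) x0[(size_t)i * J + j] = X(i, j);
  MSResult r = mean_shift_core(x0, K, J, ud, kernel, D, ell, tol, max_iter,
                               merge_dist, blurring);
  IntegerVector labels(r.labels.begin(), r.labels.end());
  NumericMatrix modes(r.C, J);
  for (int c = 0; c < r.C; ++c)
    for (int j = 0; j < J; ++j) modes(c, j) = r.modes[(size_t)c * J + j];
  return List::create(_["labels"] = labels, _["n_clusters"] = r.C,
                      _["modes"] = modes, _["iterations"] = r.iterations,
                      _["converged"] = r.converged);
}

// ---------------------------------------------------------------------------
// Search: lawn-mower walk + fallbacks + escalation, shared by the standalone
// wrappers and the main engine.
// ---------------------------------------------------------------------------
struct SearchCfg {
  double f;
  int N, Nt, NNt;
  int walk_unit;             // 0 = count accepted jumps, 1 = count proposals
  int proposal;              // 0 = standard normal components, 1 = uniform(-1,1)
  bool cluster_enabled;
  int max_cluster_analyses;
  int kernel; double D, ell, ms_tol; int ms_max_iter; double merge_dist;
  bool ms_blurring;
  double sigma_floor_rel;
  long max_fail_per_search;  // hard safety cap
};

struct Counters {
  long nt;                    // failed tries since last reset
  long fails_since_cluster;   // failed walk proposals since last cluster analysis
  long total_proposals, total_fails;
  long n_fallback_bary, n_fallback_mix;
  int n_cluster_analyses;
  Counters() : nt(0), fails_since_cluster(0), total_proposals(0), total_fails(0),
               n_fallback_bary(0), n_fallback_mix(0), n_cluster_analyses(0) {}
};

// event codes for the structured trace
enum { EV_ESCALATE = 1, EV_FB_BARY_OK = 2, EV_FB_BARY_FAIL = 3,
       EV_FB_MIX_OK = 4, EV_FB_MIX_FAIL = 5, EV_CLUSTER = 6, EV_RESTART = 7 };

struct Engine {
  int K, J;
  std::vector<double> live;    // K x J row-major
  std::vector<double> lnL;
  std::vector<int> labels;     // 0 = unlabelled
  bool labels_active;
  NumericVector lo, hi;
  Lik& lik;
  SearchCfg cfg;
  Counters ctr;
  // running moments for global sigma / barycenter
  std::vector<double> sum, sumsq;
  long n_since_refresh;
  // per-cluster moments
  int C;
  std::vector<double> csum, csumsq;
  std::vector<int> csize;
  // cluster-analysis history (+ live-set snapshots when recording)
  std::vector<long> hist_step;
  std::vector<int> hist_C;
  std::vector<std::vector<double>> snapshots;
  std::vector<std::vector<int>> snapshot_labels;
  // optional event trace
  bool record_events;
  std::vector<int> ev_code;
  std::vector<long> ev_step;
  long cur_step;

  Engine(Lik& lik_, NumericVector lo_, NumericVector hi_, SearchCfg cfg_,
         NumericMatrix live0, NumericVector lnL0, IntegerVector labels0,
         bool record_ev)
      : lik(lik_), cfg(cfg_), record_events(record_ev), cur_step(0) {
    K = live0.nrow(); J = live0.ncol();
    lo = lo_; hi = hi_;
    live.resize((size_t)K * J);
    lnL.assign(lnL0.begin(), lnL0.end());
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) live[(size_t)k * J + j] = live0(k, j);
    labels.assign(K, 0);
    labels_active = false;
    C = 0;
    if (labels0.size() == K) {
      bool any = false;
      for (int k = 0; k < K; ++k) {
        labels[k] = labels0[k];
        if (labels0[k] > 0) any = true;
      }
      if (any) {
        labels_active = true;
        C = *std::max_element(labels.begin(), labels.end());
        rebuild_cluster_moments();
      }
    }
    refresh_moments();
  }

  void note(int code) {
    if (record_events) { ev_code.push_back(code); ev_step.push_back(cur_step); }
  }

  void refresh_moments() {
    sum.assign(J, 0.0); sumsq.assign(J, 0.0);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) {
        double v = live[(size_t)k * J + j];
        sum[j] += v; sumsq[j] += v * v;
      }
    n_since_refresh = 0;
  }

  void rebuild_cluster_moments() {
    csum.assign((size_t)C * J, 0.0);
    csumsq.assign((size_t)C * J, 0.0);
    csize.assign(C, 0);
    for (int k = 0; k < K; ++k) {
      int c = labels[k];
      if (c < 1 || c > C) continue;
      ++csize[c - 1];
      for (int j = 0; j < J; ++j) {
        double v = live[(size_t)k * J + j];
        csum[(size_t)(c - 1) * J + j] += v;
        csumsq[(size_t)(c - 1) * J + j] += v * v;
      }
    }
  }

  double sigma_floor(int j) const { return cfg.sigma_floor_rel * (hi[j] - lo[j]); }

  void global_sigma(std::vector<double>& sg) const {
    sg.resize(J);
    for (int j = 0; j < J; ++j) {
      double m = sum[j] / K;
      double v = sumsq[j] / K - m * m;
      if (v < 0) v = 0;
      double s = std::sqrt(v);
      double fl = sigma_floor(j);
      sg[j] = (s < fl) ? fl : s;
    }
  }

  // population sd of cluster c (1-based); singleton or empty clusters fall
  // back to the global scale (a floored near-zero scale would freeze the
  // walk into duplicating its start)
  void cluster_sigma(int c, std::vector<double>& sg) const {
    if (c < 1 || c > C || csize[c - 1] < 2) { global_sigma(sg); return; }
    int n = csize[c - 1];
    sg.resize(J);
    for (int j = 0; j < J; ++j) {
      double m = csum[(size_t)(c - 1) * J + j] / n;
      double v = csumsq[(size_t)(c - 1) * J + j] / n - m * m;
      if (v < 0) v = 0;
      double s = std::sqrt(v);
      double fl = sigma_floor(j);
      sg[j] = (s < fl) ? fl : s;
    }
  }

  void barycenter(std::vector<double>& b) const {
    b.resize(J);
    for (int j = 0; j < J; ++j) b[j] = sum[j] / K;
  }

  void replace(int idx, const std::vector<double>& a, double l, int lab) {
    for (int j = 0; j < J; ++j) {
      double old = live[(size_t)idx * J + j];
      sum[j] += a[j] - old;
      sumsq[j] += a[j] * a[j] - old * old;
    }
    int oldlab = labels[idx];
    if (labels_active) {
      if (oldlab >= 1 && oldlab <= C) {
        --csize[oldlab - 1];
        for (int j = 0; j < J; ++j) {
          double old = live[(size_t)idx * J + j];
          csum[(size_t)(oldlab - 1) * J + j] -= old;
          csumsq[(size_t)(oldlab - 1) * J + j] -= old * old;
        }
      }
      if (lab >= 1 && lab <= C) {
        ++csize[lab - 1];
        for (int j = 0; j < J; ++j) {
          csum[(size_t)(lab - 1) * J + j] += a[j];
          csumsq[(size_t)(lab - 1) * J + j] += a[j] * a[j];
        }
      }
    }
    for (int j = 0; j < J; ++j) live[(size_t)idx * J + j] = a[j];
    lnL[idx] = l;
    labels[idx] = lab;
    if (++n_since_refresh >= 8192) { refresh_moments(); if (labels_active) rebuild_cluster_moments(); }
  }

  bool in_bounds(const std::vector<double>& a) const {
    for (int j = 0; j < J; ++j)
      if (a[j] < lo[j] || a[j] > hi[j]) return false;
    return true;
  }

  // lawn-mower walk; returns true on success (step budget N met: accepted
  // jumps by default, proposals when walk_unit == 1), false on escalation
  // (nt reached Nt). a/l are the current chain point, a_fail/l_fail the
  // last rejected proposal (valid when escalated).
  bool walk(std::vector<double>& a, double& l, const std::vector<double>& sigma,
            double thr, int& n_done, std::vector<double>& a_fail,
            double& l_fail) {
    std::vector<double> prop(J);
    while (n_done < cfg.N) {
      for (int j = 0; j < J; ++j) {
        double r = (cfg.proposal == 0) ? norm_rand() : (2.0 * unif_rand() - 1.0);
        prop[j] = a[j] + cfg.f * r * sigma[j];
      }
      ++ctr.total_proposals;
      bool ok = in_bounds(prop);
      double lp = NEG_INF;
      if (ok) {
        lp = lik.eval(prop.data(), J);
        ok = (lp >= thr);   // >= : plateaus (ties) remain reachable
      }
      if (ok) {
        a = prop; l = lp;
        ++n_done;
        ctr.nt = 0;   // nt counts *consecutive* failures: any progress resets
      } else {
        a_fail = prop; l_fail = lp;
        if (cfg.walk_unit == 1) ++n_done;   // a rejection is a (held) step
        ++ctr.nt; ++ctr.total_fails; ++ctr.fails_since_cluster;
        // escalate every Nt-th consecutive failure (nt keeps growing across
        // failed fallbacks/restarts until the Nt*NNt cluster trigger)
        if (ctr.nt % cfg.Nt == 0) return false;
      }
    }
    return true;
  }

  // one cluster analysis on the current live set (min-max normalized,
  // degenerate dimensions excluded from distances)
  void cluster_analysis() {
    std::vector<double> mn(J, R_PosInf), mx(J, R_NegInf);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) {
        double v = live[(size_t)k * J + j];
        if (v < mn[j]) mn[j] = v;
        if (v > mx[j]) mx[j] = v;
      }
    std::vector<char> ud(J);
    std::vector<double> Xn((size_t)K * J);
    for (int j = 0; j < J; ++j) ud[j] = (mx[j] > mn[j]) ? 1 : 0;
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j)
        Xn[(size_t)k * J + j] = ud[j]
          ? (live[(size_t)k * J + j] - mn[j]) / (mx[j] - mn[j]) : 0.5;
    MSResult r = mean_shift_core(Xn, K, J, ud, cfg.kernel, cfg.D, cfg.ell,
                                 cfg.ms_tol, cfg.ms_max_iter, cfg.merge_dist,
                                 cfg.ms_blurring);
    labels = r.labels;
    labels_active = true;
    C = r.C;
    rebuild_cluster_moments();
    ++ctr.n_cluster_analyses;
    hist_step.push_back(cur_step);
    hist_C.push_back(r.C);
    if (record_events) {
      snapshots.push_back(live);
      snapshot_labels.push_back(labels);
    }
    note(EV_CLUSTER);
  }

  // find a point with lnL >= thr; returns index-free result.
  // exclude: live index not eligible as a walk start (the point being
  // replaced), or -1. On failure sets *err.
  bool find_new(double thr, int exclude, std::vector<double>& out, double& out_l,
                int& out_lab, std::vector<double>& out_sigma, int& out_start,
                int* err) {
    long fails_at_entry = ctr.total_fails;
    std::vector<double> a(J), a_fail(J), sigma, bary, cand(J);
    double l, l_fail;
    for (;;) {
      // fresh random start
      int start;
      do {
        start = (int)std::floor(unif_rand() * K);
        if (start >= K) start = K - 1;
      } while (start == exclude && K > 1);
      int lab = labels_active ? labels[start] : 0;
      if (lab > 0) cluster_sigma(lab, sigma); else global_sigma(sigma);
      for (int j = 0; j < J; ++j) a[j] = live[(size_t)start * J + j];
      l = lnL[start];
      int n_acc = 0;
      for (;;) {
        if (walk(a, l, sigma, thr, n_acc, a_fail, l_fail)) {
          out = a; out_l = l; out_lab = lab; out_sigma = sigma; out_start = start;
          return true;
        }
        // escalation: another Nt consecutive failures
        note(EV_ESCALATE);
        if (ctr.total_fails - fails_at_entry > cfg.max_fail_per_search) {
          *err = 3; return false;
        }
        if (cfg.cluster_enabled && ctr.nt >= (long)cfg.Nt * cfg.NNt) {
          if (ctr.n_cluster_analyses >= cfg.max_cluster_analyses) {
            *err = 2; return false;
          }
          cluster_analysis();
          ctr.nt = 0;
          ctr.fails_since_cluster = 0;
          break;   // restart from a random live point with its cluster sigma
        }
        // pick a fallback strategy with a fair coin
        bool use_bary = (unif_rand() < 0.5);
        bool ok = false;
        if (use_bary) {
          ++ctr.n_fallback_bary;
          barycenter(bary);
          double u = unif_rand();
          for (int j = 0; j < J; ++j) cand[j] = bary[j] + u * (a_fail[j] - bary[j]);
          double lc = NEG_INF;
          if (in_bounds(cand)) lc = lik.eval(cand.data(), J);
          ok = (lc >= thr);
          note(ok ? EV_FB_BARY_OK : EV_FB_BARY_FAIL);
          if (ok) { a = cand; l = lc; }
        } else {
          ++ctr.n_fallback_mix;
          for (int j = 0; j < J; ++j) {
            int k = (int)std::floor(unif_rand() * K);
            if (k >= K) k = K - 1;
            cand[j] = live[(size_t)k * J + j];
          }
          double lc = lik.eval(cand.data(), J);
          ok = (lc >= thr);
          note(ok ? EV_FB_MIX_OK : EV_FB_MIX_FAIL);
          if (ok) { a = cand; l = lc; }
        }
        if (ok) {
          ctr.nt = 0;          // fallback progress also clears the counter
          continue;            // resume walk from candidate, remaining budget
        }
        note(EV_RESTART);
        break;                 // restart from a fresh random live point;
                               // nt keeps accumulating toward the trigger
      }
    }
  }
};

static SearchCfg parse_cfg(List cfg) {
  SearchCfg c;
  c.f = as<double>(cfg["f"]);
  c.N = as<int>(cfg["N"]);
  c.Nt = as<int>(cfg["Nt"]);
  c.NNt = as<int>(cfg["NNt"]);
  c.walk_unit = cfg.containsElementNamed("walk_unit_id")
      ? as<int>(cfg["walk_unit_id"]) : 0;
  c.proposal = as<int>(cfg["proposal_id"]);
  c.cluster_enabled = as<bool>(cfg["cluster"]);
  c.max_cluster_analyses = as<int>(cfg["max_cluster_analyses"]);
  c.kernel = as<int>(cfg["kernel_id"]);
  c.D = as<double>(cfg["D"]);
  c.ell = as<double>(cfg["ell"]);
  c.ms_tol = as<double>(cfg["ms_tol"]);
  c.ms_max_iter = as<int>(cfg["ms_max_iter"]);
  c.merge_dist = as<double>(cfg["merge_dist"]);
  c.ms_blurring = cfg.containsElementNamed("ms_blurring")
      ? as<bool>(cfg["ms_blurring"]) : false;
  c.sigma_floor_rel = as<double>(cfg["sigma_floor_rel"]);
  c.max_fail_per_search = cfg.containsElementNamed("max_fail_per_search")
      ? (long)as<double>(cfg["max_fail_per_search"]) : 100000000L;
  return c;
}

static List counters_list(const Counters& ctr) {
  return List::create(
      _["nt"] = (double)ctr.nt,
      _["fails_since_cluster"] = (double)ctr.fails_since_cluster,
      _["total_proposals"] = (double)ctr.total_proposals,
      _["total_fails"] = (double)ctr.total_fails,
      _["n_fallback_bary"] = (double)ctr.n_fallback_bary,
      _["n_fallback_mix"] = (double)ctr.n_fallback_mix,
      _["n_cluster_analyses"] = ctr.n_cluster_analyses);
}

// ---------------------------------------------------------------------------
// Standalone wrappers (unit-testable pieces sharing the engine internals)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List lawn_mower_walk_cpp(NumericVector a0, double lnL0, NumericVector sigma,
                         double lnL_threshold, double f, int N,
                         NumericVector lower, NumericVector upper, List spec,
                         int nt, int Nt, int proposal_id, int walk_unit_id) {
  Lik lik(spec);
  List cfg = List::create(_["f"] = f, _["N"] = N, _["Nt"] = Nt, _["NNt"] = 1,
                          _["walk_unit_id"] = walk_unit_id,
                          _["proposal_id"] = proposal_id, _["cluster"] = false,
                          _["max_cluster_analyses"] = 0, _["kernel_id"] = 1,
                          _["D"] = 0.6, _["ell"] = 0.2, _["ms_tol"] = 1e-4,
                          _["ms_max_iter"] = 100, _["merge_dist"] = 0.05,
                          _["sigma_floor_rel"] = 1e-12);
  SearchCfg sc = parse_cfg(cfg);
  NumericMatrix live0(1, a0.size());
  for (int j = 0; j < a0.size(); ++j) live0(0, j) = a0[j];
  NumericVector l0(1); l0[0] = lnL0;
  Engine eng(lik, lower, upper, sc, live0, l0, IntegerVector(0), false);
  eng.ctr.nt = nt;
  std::vector<double> a(a0.begin(), a0.end()), sg(sigma.begin(), sigma.end());
  std::vector<double> a_fail(a0.size());
  double l = lnL0, l_fail = NEG_INF;
  int n_done = 0;
  bool ok = eng.walk(a, l, sg, lnL_threshold, n_done, a_fail, l_fail);
  long n_acc = eng.ctr.total_proposals - eng.ctr.total_fails;
  return List::create(_["a"] = NumericVector(a.begin(), a.end()),
                      _["lnL"] = l, _["n_steps"] = n_done,
                      _["n_accepted"] = (double)n_acc,
                      _["nt"] = (double)eng.ctr.nt,
                      _["escalated"] = !ok,
                      _["a_fail"] = NumericVector(a_fail.begin(), a_fail.end()),
                      _["n_proposals"] = (double)eng.ctr.total_proposals);
}

// [[Rcpp::export]]
List barycenter_fallback_cpp(NumericVector a_fail, NumericVector barycenter,
                             double lnL_threshold, NumericVector lower,
                             NumericVector upper, List spec) {
  Lik lik(spec);
  int J = a_fail.size();
  double u = unif_rand();
  std::vector<double> cand(J);
  for (int j = 0; j < J; ++j)
    cand[j] = barycenter[j] + u * (a_fail[j] - barycenter[j]);
  bool inb = true;
  for (int j = 0; j < J; ++j)
    if (cand[j] < lower[j] || cand[j] > upper[j]) inb = false;
  double l = inb ? lik.eval(cand.data(), J) : NEG_INF;
  return List::create(_["a"] = NumericVector(cand.begin(), cand.end()),
                      _["lnL"] = l, _["u"] = u,
                      _["success"] = (l >= lnL_threshold));
}

// [[Rcpp::export]]
List coordinate_mix_fallback_cpp(NumericMatrix live, double lnL_threshold,
                                 List spec) {
  Lik lik(spec);
  int K = live.nrow(), J = live.ncol();
  std::vector<double> cand(J);
  for (int j = 0; j < J; ++j) {
    int k = (int)std::floor(unif_rand() * K);
    if (k >= K) k = K - 1;
    cand[j] = live(k, j);
  }
  double l = lik.eval(cand.data(), J);
  return List::create(_["a"] = NumericVector(cand.begin(), cand.end()),
                      _["lnL"] = l, _["success"] = (l >= lnL_threshold));
}

// [[Rcpp::export]]
List find_new_live_point_cpp(NumericMatrix live, NumericVector lnL,
                             IntegerVector labels, double lnL_threshold,
                             NumericVector lower, NumericVector upper,
                             List spec, List cfg, List state, int exclude) {
  Lik lik(spec);
  SearchCfg sc = parse_cfg(cfg);
  Engine eng(lik, lower, upper, sc, live, lnL, labels, true);
  eng.ctr.nt = (long)as<double>(state["nt"]);
  eng.ctr.fails_since_cluster = (long)as<double>(state["fails_since_cluster"]);
  eng.ctr.n_cluster_analyses = as<int>(state["n_cluster_analyses"]);
  std::vector<double> out, out_sigma;
  double out_l; int out_lab, out_start, err = 0;
  bool ok = eng.find_new(lnL_threshold, exclude, out, out_l, out_lab, out_sigma,
                         out_start, &err);
  List res = List::create(
      _["success"] = ok,
      _["a"] = ok ? NumericVector(out.begin(), out.end()) : NumericVector(0),
      _["lnL"] = ok ? out_l : NA_REAL,
      _["cluster_label"] = ok ? out_lab : NA_INTEGER,
      _["sigma_used"] = ok ? NumericVector(out_sigma.begin(), out_sigma.end())
                           : NumericVector(0),
      _["start_index"] = ok ? out_start + 1 : NA_INTEGER,
      _["state"] = counters_list(eng.ctr),
      _["events"] = IntegerVector(eng.ev_code.begin(), eng.ev_code.end()),
      _["labels"] = IntegerVector(eng.labels.begin(), eng.labels.end()),
      _["labels_active"] = eng.labels_active,
      _["error"] = err);
  return res;
}

// ---------------------------------------------------------------------------
// Main nested-sampling loop (single run)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List ns_run_cpp(List spec, NumericVector lower, NumericVector upper, List cfg,
                NumericMatrix live0, NumericVector lnL0) {
  Lik lik(spec);
  SearchCfg sc = parse_cfg(cfg);
  int K = live0.nrow(), J = live0.ncol();
  double stop_tol = as<double>(cfg["stop_tol"]);
  long max_steps = (long)as<double>(cfg["max_steps"]);
  bool record_ev = as<bool>(cfg["record_events"]);
  Engine eng(lik, lower, upper, sc, live0, lnL0, IntegerVector(0), record_ev);

  std::vector<double> dead_a;  dead_a.reserve(40960ul * J);
  std::vector<double> dead_lnL, dead_lnw;
  double lnE = NEG_INF;
  double ln_stop = std::log(stop_tol);
  double lnLmax = *std::max_element(eng.lnL.begin(), eng.lnL.end());
  double lnsinh = std::log(std::sinh(1.0 / K));
  long m = 0;
  int status = 0;   // 0 converged, 1 max_steps, 2 cluster cap, 3 search cap

  for (;;) {
    if ((m & 255) == 0) Rcpp::checkUserInterrupt();
    // termination check with m points discarded so far
    if (m >= 2 && lnLmax - (double)m / K < ln_stop + lnE) break;
    if (m >= max_steps) { status = 1; break; }
    ++m;
    eng.cur_step = m;
    // discard the worst live point
    int worst = 0;
    for (int k = 1; k < K; ++k) if (eng.lnL[k] < eng.lnL[worst]) worst = k;
    double lw = eng.lnL[worst];
    double lnDX;
    if (m == 1)
      lnDX = std::log(1.0 - 0.5 * (std::exp(-1.0 / K) + std::exp(-2.0 / K)));
    else
      lnDX = lnsinh - (double)m / K;
    double lnw = lw + lnDX;
    for (int j = 0; j < J; ++j) dead_a.push_back(eng.live[(size_t)worst * J + j]);
    dead_lnL.push_back(lw);
    dead_lnw.push_back(lnw);
    lnE = logaddexp(lnE, lnw);
    // replace it
    std::vector<double> a, sg;
    double l; int lab, start, err = 0;
    if (!eng.find_new(lw, worst, a, l, lab, sg, start, &err)) {
      status = err;
      // keep the dead record; partial state is returned with the error status
      break;
    }
    eng.replace(worst, a, l, lab);
    if (l > lnLmax) lnLmax = l;
    // a found point closes the search episode: the cluster-analysis trigger
    // watches *consecutive* failed effort, so both failure counters reset
    eng.ctr.nt = 0;
    eng.ctr.fails_since_cluster = 0;
  }

  long M = (long)dead_lnL.size();
  NumericMatrix dead((int)M, J);
  for (long i = 0; i < M; ++i)
    for (int j = 0; j < J; ++j) dead(i, j) = dead_a[(size_t)i * J + j];
  NumericMatrix live_out(K, J);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < J; ++j) live_out(k, j) = eng.live[(size_t)k * J + j];

  return List::create(
      _["steps"] = (double)M,
      _["dead"] = dead,
      _["dead_lnL"] = NumericVector(dead_lnL.begin(), dead_lnL.end()),
      _["dead_lnw"] = NumericVector(dead_lnw.begin(), dead_lnw.end()),
      _["lnE_dead"] = lnE,
      _["live"] = live_out,
      _["live_lnL"] = NumericVector(eng.lnL.begin(), eng.lnL.end()),
      _["live_labels"] = IntegerVector(eng.labels.begin(), eng.labels.end()),
      _["status"] = status,
      _["counters"] = counters_list(eng.ctr),
      _["cluster_history"] = DataFrame::create(
          _["step"] = NumericVector(eng.hist_step.begin(), eng.hist_step.end()),
          _["n_clusters"] = IntegerVector(eng.hist_C.begin(), eng.hist_C.end())),
      _["cluster_snapshots"] = [&]() -> SEXP {
          if (!record_ev) return R_NilValue;
          List out(eng.snapshots.size());
          for (size_t s = 0; s < eng.snapshots.size(); ++s) {
            NumericMatrix m(K, J);
            for (int k = 0; k < K; ++k)
              for (int j = 0; j < J; ++j)
                m(k, j) = eng.snapshots[s][(size_t)k * J + j];
            m.attr("labels") = IntegerVector(eng.snapshot_labels[s].begin(),
                                             eng.snapshot_labels[s].end());
            out[s] = m;
          }
          return out;
        }(),
      _["n_likelihood_evals"] = (double)lik.n_eval,
      _["events"] = record_ev
          ? (SEXP)DataFrame::create(
                _["step"] = NumericVector(eng.ev_step.begin(), eng.ev_step.end()),
                _["code"] = IntegerVector(eng.ev_code.begin(), eng.ev_code.end()))
          : R_NilValue);
}
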