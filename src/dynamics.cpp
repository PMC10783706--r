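#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Uniform integer in [0, n): uses R's RNG so set.seed() governs everything.
static inline int runif_int(int n) {
  int i = (int)(unif_rand() * n);
  return (i >= n) ? n - 1 : i;
}

static inline void shuffle_vec(std::vector<int>& v) {
  for (int k = (int)v.size() - 1; k > 0; --k) {
    int j = runif_int(k + 1);
    std::swap(v[k], v[j]);
  }
}

// ---------------------------------------------------------------------------
// Molloy-Reed stub matching with rejection re-pairing.
//
// Each node contributes deg(i) stubs; stubs are paired uniformly at random.
// Pairs that would create a self-loop or a parallel edge are rejected and
// their stubs re-paired among themselves.  If the leftover pool stops
// shrinking (a parity deadlock, e.g. two stubs of one node remaining), a
// random accepted edge is broken back into the pool so the chain can escape
// while the degree sequence stays exact.  A bounded number of full restarts
// guards against pathological sequences.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List build_graph_cpp(IntegerVector degrees, int max_retries) {
  const int n = degrees.size();
  long long total = 0;
  for (int i = 0; i < n; ++i) {
    if (degrees[i] < 1 || degrees[i] > n - 1)
      stop("degree out of range for a simple graph");
    total += degrees[i];
  }
  if (total % 2 != 0) stop("degree sequence has odd sum");

  std::vector<int> stubs;
  stubs.reserve((size_t)total);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < degrees[i]; ++d) stubs.push_back(i);

  const long long nn = n;
  auto key_of = [nn](int a, int b) {
    int lo = a < b ? a : b, hi = a < b ? b : a;
    return (long long)lo * nn + hi;
  };

  for (int attempt = 0; attempt < max_retries; ++attempt) {
    std::vector<int> s(stubs);
    shuffle_vec(s);

    std::unordered_set<long long> eset;
    std::vector<long long> elist;
    eset.reserve(s.size());
    elist.reserve(s.size() / 2);
    std::vector<int> pool;

    for (size_t k = 0; k + 1 < s.size(); k += 2) {
      int a = s[k], b = s[k + 1];
      long long key = key_of(a, b);
      if (a == b || eset.count(key)) {
        pool.push_back(a);
        pool.push_back(b);
      } else {
        eset.insert(key);
        elist.push_back(key);
      }
    }

    bool ok = true;
    int rounds = 0, stall = 0;
    size_t last = pool.size();
    while (!pool.empty()) {
      if (++rounds > 5000) { ok = false; break; }
      shuffle_vec(pool);
      std::vector<int> next;
      for (size_t k = 0; k + 1 < pool.size(); k += 2) {
        int a = pool[k], b = pool[k + 1];
        long long key = key_of(a, b);
        if (a == b || eset.count(key)) {
          next.push_back(a);
          next.push_back(b);
        } else {
          eset.insert(key);
          elist.push_back(key);
        }
      }
      pool.swap(next);
      if (pool.size() >= last) {
        if (++stall >= 25 && !elist.empty()) {
          // deadlocked: dissolve a random accepted edge into the pool
          size_t idx = (size_t)runif_int((int)elist.size());
          long long key = elist[idx];
          eset.erase(key);
          elist[idx] = elist.back();
          elist.pop_back();
          pool.push_back((int)(key / nn));
          pool.push_back((int)(key % nn));
          stall = 0;
        }
      } else {
        stall = 0;
      }
      last = pool.size();
    }
    if (!ok) continue;

    // CSR adjacency, neighbours sorted for deterministic layout
    std::vector<std::vector<int>> adj(n);
    for (int i = 0; i < n; ++i) adj[i].reserve(degrees[i]);
    for (long long key : elist) {
      int a = (int)(key / nn), b = (int)(key % nn);
      adj[a].push_back(b);
      adj[b].push_back(a);
    }
    IntegerVector ptr(n + 1), nbr((int)total);
    int pos = 0;
    ptr[0] = 0;
    for (int i = 0; i < n; ++i) {
      std::sort(adj[i].begin(), adj[i].end());
      for (int x : adj[i]) nbr[pos++] = x + 1;  // 1-based for R
      ptr[i + 1] = pos;
    }
    return List::create(_["ptr"] = ptr, _["nbr"] = nbr,
                        _["attempts"] = attempt + 1);
  }
  return List::create(_["ptr"] = R_NilValue, _["nbr"] = R_NilValue,
                      _["attempts"] = max_retries);
}

// ---------------------------------------------------------------------------
// Elementary steps.  model: 0 = exogenous (majority-conformity),
// 1 = endogenous (goal function).  parse: 0 = social-normalized,
// 1 = fully-normalized anchor in the goal function.
// ---------------------------------------------------------------------------

struct State {
  std::vector<int> omega;
  std::vector<int> expressed;
};

static inline void step_once(int i, const int* ptr, const int* nbr,
                             const int* b, const double* sigma,
                             const int* is_hc, int model, int parse,
                             State& st) {
  const int lo = ptr[i], hi = ptr[i + 1];
  const int deg_i = hi - lo;
  if (model == 0) {
    if (unif_rand() < sigma[i]) {
      st.omega[i] = b[i];
      st.expressed[i] = 1;
    } else {
      int s = 0, anyexp = 0;
      for (int k = lo; k < hi; ++k) {
        int j = nbr[k] - 1;
        s += st.omega[j];
        anyexp |= st.expressed[j];
      }
      if (s > 0) st.omega[i] = 1;
      else if (s < 0) st.omega[i] = -1;
      else if (anyexp) st.omega[i] = (unif_rand() < 0.5) ? 1 : -1;
      else st.omega[i] = 0;  // nobody nearby has ever spoken: stay null
      if (st.omega[i] != 0) st.expressed[i] = 1;
    }
  } else {
    if (is_hc[i]) {
      st.omega[i] = -1;
      st.expressed[i] = 1;
      return;
    }
    double social = 0.0;
    int m = 0;
    for (int k = lo; k < hi; ++k) {
      int j = nbr[k] - 1;
      int w = st.omega[j];
      if (w != 0) {
        int deg_j = ptr[j + 1] - ptr[j];
        social += (double)deg_j / (double)deg_i * (double)w;
        ++m;
      }
    }
    double v = (parse == 0)
                   ? sigma[i] * b[i] + social / (double)(m + 1)
                   : (sigma[i] * b[i] + social) / (double)(m + 1);
    const double eps = 1e-12;
    int w;
    if (std::fabs(v - 0.5) < eps) w = (unif_rand() < 0.5) ? 1 : 0;
    else if (std::fabs(v + 0.5) < eps) w = (unif_rand() < 0.5) ? -1 : 0;
    else if (v > 0.5) w = 1;
    else if (v < -0.5) w = -1;
    else w = 0;
    st.omega[i] = w;
    if (w != 0) st.expressed[i] = 1;
  }
}

static State make_state(IntegerVector omega, IntegerVector expressed) {
  State st;
  st.omega.assign(omega.begin(), omega.end());
  st.expressed.assign(expressed.begin(), expressed.end());
  return st;
}

// Run a fixed number of elementary steps (agents chosen uniformly at random).
// [[Rcpp::export]]
List steps_cpp(IntegerVector ptr, IntegerVector nbr, IntegerVector b,
               NumericVector sigma, IntegerVector omega,
               IntegerVector expressed, IntegerVector is_hc, int model,
               int parse, int nsteps) {
  const int n = ptr.size() - 1;
  State st = make_state(omega, expressed);
  for (int s = 0; s < nsteps; ++s) {
    int i = runif_int(n);
    step_once(i, ptr.begin(), nbr.begin(), b.begin(), sigma.begin(),
              is_hc.begin(), model, parse, st);
  }
  return List::create(_["omega"] = IntegerVector(st.omega.begin(), st.omega.end()),
                      _["expressed"] = IntegerVector(st.expressed.begin(), st.expressed.end()));
}

// Many independent one-step trials from the same initial state; returns the
// resulting omega / expressed configurations row-wise (oracle comparisons).
// [[Rcpp::export]]
List one_step_trials_cpp(IntegerVector ptr, IntegerVector nbr, IntegerVector b,
                         NumericVector sigma, IntegerVector omega,
                         IntegerVector expressed, IntegerVector is_hc,
                         int model, int parse, int ntrials) {
  const int n = ptr.size() - 1;
  IntegerMatrix om(ntrials, n), ex(ntrials, n);
  for (int t = 0; t < ntrials; ++t) {
    State st = make_state(omega, expressed);
    int i = runif_int(n);
    step_once(i, ptr.begin(), nbr.begin(), b.begin(), sigma.begin(),
              is_hc.begin(), model, parse, st);
    for (int k = 0; k < n; ++k) {
      om(t, k) = st.omega[k];
      ex(t, k) = st.expressed[k];
    }
  }
  return List::create(_["omega"] = om, _["expressed"] = ex);
}

// Full trajectory: one time unit = n elementary steps; a per-unit snapshot
// of <omega>, r and the expression fractions is recorded (t = 0 included).
// Stops early once |<omega>(t) - <omega>(t - window)| < tol.
// [[Rcpp::export]]
List run_dynamics_cpp(IntegerVector ptr, IntegerVector nbr, IntegerVector b,
                      NumericVector sigma, IntegerVector omega,
                      IntegerVector expressed, IntegerVector is_hc, int model,
                      int parse, int horizon, int window, double tol) {
  const int n = ptr.size() - 1;
  State st = make_state(omega, expressed);

  std::vector<double> c_mo, c_r, c_fp, c_fm, c_fs;
  c_mo.reserve(horizon + 1);

  auto record = [&]() {
    double so = 0.0, sr = 0.0;
    int np = 0, nm = 0;
    for (int i = 0; i < n; ++i) {
      so += st.omega[i];
      if (st.omega[i] == 1) ++np;
      else if (st.omega[i] == -1) ++nm;
      double loc = 0.0;
      int lo = ptr[i], hi = ptr[i + 1];
      for (int k = lo; k < hi; ++k) loc += st.omega[nbr[k] - 1];
      sr += loc / (double)(hi - lo);
    }
    c_mo.push_back(so / n);
    c_r.push_back(sr / n);
    c_fp.push_back((double)np / n);
    c_fm.push_back((double)nm / n);
    c_fs.push_back((double)(n - np - nm) / n);
  };

  record();  // t = 0
  bool converged = false;
  int t_stop = 0;
  for (int t = 1; t <= horizon; ++t) {
    for (int s = 0; s < n; ++s) {
      int i = runif_int(n);
      step_once(i, ptr.begin(), nbr.begin(), b.begin(), sigma.begin(),
                is_hc.begin(), model, parse, st);
    }
    record();
    t_stop = t;
    if (t >= window && std::fabs(c_mo[t] - c_mo[t - window]) < tol) {
      converged = true;
      break;
    }
  }

  int T = (int)c_mo.size();
  NumericMatrix traj(T, 6);
  for (int t = 0; t < T; ++t) {
    traj(t, 0) = t;
    traj(t, 1) = c_mo[t];
    traj(t, 2) = c_r[t];
    traj(t, 3) = c_fp[t];
    traj(t, 4) = c_fm[t];
    traj(t, 5) = c_fs[t];
  }
  return List::create(
      _["traj"] = traj,
      _["omega"] = IntegerVector(st.omega.begin(), st.omega.end()),
      _["expressed"] = IntegerVector(st.expressed.begin(), st.expressed.end()),
      _["t_stop"] = t_stop, _["converged"] = converged);
}
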