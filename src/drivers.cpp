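#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include "rng.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Site key packing. Coordinates are kept as 64-bit integers; a single 64-bit
// hash key encodes the whole site. Bit budgets per dimension:
//   d = 1 : full 63-bit range (Levy flights can travel far)
//   d = 2 : 31 bits per coordinate (|x| < 2^30)
//   d = 3 : 21 bits per coordinate (|x| < 2^20)
//   d = 4..6 : 10 bits per coordinate (|x| < 512; nearest-neighbour walks
//              at the horizons used here stay well inside)
// ---------------------------------------------------------------------------
static inline uint64_t pack_site(const long long *pos, int d) {
  if (d == 1) {
    return (uint64_t)(pos[0] + (1LL << 62));
  } else if (d == 2) {
    if (std::llabs(pos[0]) >= (1LL << 30) || std::llabs(pos[1]) >= (1LL << 30))
      stop("walker left the addressable 2d region");
    return (uint64_t)(pos[0] + (1LL << 30)) |
           ((uint64_t)(pos[1] + (1LL << 30)) << 31);
  } else if (d == 3) {
    uint64_t k = 0;
    for (int i = 0; i < 3; i++) {
      if (std::llabs(pos[i]) >= (1LL << 20))
        stop("walker left the addressable 3d region");
      k |= (uint64_t)(pos[i] + (1LL << 20)) << (21 * i);
    }
    return k;
  } else {
    uint64_t k = 0;
    for (int i = 0; i < d; i++) {
      if (std::llabs(pos[i]) >= 512)
        stop("walker left the addressable region (|coordinate| must stay < 512 for d > 3)");
      k |= (uint64_t)(pos[i] + 512) << (10 * i);
    }
    return k;
  }
}

// ---------------------------------------------------------------------------
// Discrete symmetric Levy jump sampler: p(s) = 1 / (2 zeta(1+alpha) |s|^(1+alpha)),
// s in Z \ {0}. Inverse transform on a tabulated CDF up to M, with a Pareto
// tail continuation beyond (conditional tail mass ~ 1e-5 at alpha = 1).
// ---------------------------------------------------------------------------
static double zeta_em(double z) {
  // Riemann zeta via direct sum + Euler-Maclaurin tail correction
  const int K = 2000;
  double s = 0.0;
  for (int n = 1; n <= K; n++) s += std::pow((double)n, -z);
  double Kd = (double)K;
  s += std::pow(Kd, 1.0 - z) / (z - 1.0) - 0.5 * std::pow(Kd, -z) +
       (z / 12.0) * std::pow(Kd, -z - 1.0);
  return s;
}

struct LevySampler {
  double alpha;
  int M;
  std::vector<double> cdf; // cdf[m-1] = P(|s| <= m)
  double cdfM;
  void init(double a) {
    alpha = a;
    M = 65536;
    double z = zeta_em(1.0 + a);
    cdf.resize(M);
    double c = 0.0;
    for (int m = 1; m <= M; m++) {
      c += std::pow((double)m, -(1.0 + a)) / z;
      cdf[m - 1] = c;
    }
    cdfM = c;
  }
  long long magnitude(RWRng &rng) {
    double u = rng.unif();
    if (u < cdfM) {
      int lo = 0, hi = M - 1;
      while (lo < hi) {
        int mid = (lo + hi) >> 1;
        if (cdf[mid] < u) lo = mid + 1; else hi = mid;
      }
      return (long long)(lo + 1);
    }
    double v = rng.unif();
    if (v < 1e-300) v = 1e-300;
    double x = (double)M * std::pow(v, -1.0 / alpha);
    long long m = (long long)std::floor(x);
    if (m <= M) m = M + 1;
    if (m > (1LL << 40)) m = (1LL << 40);
    return m;
  }
  long long sample(RWRng &rng) {
    long long m = magnitude(rng);
    return rng.unif() < 0.5 ? -m : m;
  }
};

// cache: rebuilding the 64k-entry CDF per realization would dominate the
// runtime of Levy ensembles
static LevySampler &levy_sampler_for(double alpha) {
  static LevySampler s;
  static double cur = -1.0;
  if (cur != alpha) {
    s.init(alpha);
    cur = alpha;
  }
  return s;
}

// [[Rcpp::export]]
double cpp_zeta(double z) { return zeta_em(z); }

// [[Rcpp::export]]
NumericVector cpp_levy_samples(double alpha, int n, double seed, double stream) {
  if (alpha < 1.0) stop("alpha must be >= 1");
  LevySampler ls;
  ls.init(alpha);
  RWRng rng((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = (double)ls.sample(rng);
  return out;
}

// ---------------------------------------------------------------------------
// Lattice walker: model codes
//   0 simple, 1 persistent(p), 2 levy1d(alpha), 3 levy2d(alpha), 4 tsaw1d
// ---------------------------------------------------------------------------
struct LatticeWalker {
  int model, d;
  double p;
  long long pos[6];
  int prevdir; // -1 before the first step (persistent model)
  LevySampler *levy;
  std::unordered_map<uint64_t, int> counts; // TSAW visit counts

  void init(int model_, int d_, double par) {
    model = model_;
    d = d_;
    p = par;
    for (int i = 0; i < 6; i++) pos[i] = 0;
    prevdir = -1;
    levy = nullptr;
    if (model == 2 || model == 3) {
      if (par < 1.0) stop("alpha must be >= 1");
      levy = &levy_sampler_for(par);
    }
    if (model == 1 && (par <= 0.0 || par >= 1.0)) stop("p must be in (0, 1)");
    if (model == 4) {
      counts.clear();
      counts[pack_site(pos, 1)] = 1; // arrival at the start site counts
    }
  }
  inline void move_dir(int dir) {
    pos[dir >> 1] += (dir & 1) ? 1 : -1;
  }
  void step(RWRng &rng) {
    switch (model) {
    case 0: {
      move_dir(rng.below(2 * d));
      break;
    }
    case 1: {
      int dir;
      if (prevdir < 0) {
        dir = rng.below(2 * d);
      } else if (rng.unif() < p) {
        dir = prevdir;
      } else {
        int r = rng.below(2 * d - 1);
        dir = (r >= prevdir) ? r + 1 : r;
      }
      prevdir = dir;
      move_dir(dir);
      break;
    }
    case 2: {
      pos[0] += levy->sample(rng);
      break;
    }
    case 3: {
      long long m = levy->magnitude(rng);
      int dir = rng.below(4);
      pos[dir >> 1] += ((dir & 1) ? 1 : -1) * m;
      break;
    }
    case 4: {
      long long right = pos[0] + 1, left = pos[0] - 1;
      uint64_t kr = pack_site(&right, 1), kl = pack_site(&left, 1);
      auto itr = counts.find(kr);
      auto itl = counts.find(kl);
      double cr = (itr == counts.end()) ? 0.0 : (double)itr->second;
      double cl = (itl == counts.end()) ? 0.0 : (double)itl->second;
      double er = std::exp(-cr), el = std::exp(-cl);
      pos[0] = (rng.unif() < er / (er + el)) ? right : left;
      counts[pack_site(pos, 1)]++;
      break;
    }
    default:
      stop("unknown model code");
    }
  }
};

static void check_model_d(int model, int d) {
  if (d < 1 || d > 6) stop("d must be between 1 and 6");
  if ((model == 2 || model == 4) && d != 1) stop("this model is 1d only");
  if (model == 3 && d != 2) stop("2d Levy flights require d = 2");
}

// [[Rcpp::export]]
NumericMatrix cpp_walk_lattice(int model, int d, double par, double steps,
                               double seed, double stream) {
  check_model_d(model, d);
  LatticeWalker w;
  w.init(model, d, par);
  RWRng rng((uint64_t)seed, (uint64_t)stream);
  long long T = (long long)steps;
  NumericMatrix out(T + 1, d);
  for (int j = 0; j < d; j++) out(0, j) = 0.0;
  for (long long t = 1; t <= T; t++) {
    w.step(rng);
    for (int j = 0; j < d; j++) out(t, j) = (double)w.pos[j];
  }
  return out;
}

// Run one realization, recording the tau series and the visited sites in
// discovery order, until n_max distinct sites or the step horizon.
// [[Rcpp::export]]
List cpp_tau_single(int model, int d, double par, int n_max, double horizon,
                    double seed, double stream) {
  check_model_d(model, d);
  LatticeWalker w;
  w.init(model, d, par);
  RWRng rng((uint64_t)seed, (uint64_t)stream);
  std::unordered_set<uint64_t> visited;
  visited.reserve(2 * (size_t)n_max);
  std::vector<long long> sites;
  sites.reserve((size_t)n_max * d);
  visited.insert(pack_site(w.pos, d));
  for (int j = 0; j < d; j++) sites.push_back(w.pos[j]);
  std::vector<double> taus;
  taus.reserve(n_max);
  long long t = 0, last_new = 0;
  long long H = (long long)horizon;
  int n = 1;
  while (n < n_max && t < H) {
    w.step(rng);
    t++;
    if (visited.insert(pack_site(w.pos, d)).second) {
      taus.push_back((double)(t - last_new));
      last_new = t;
      n++;
      for (int j = 0; j < d; j++) sites.push_back(w.pos[j]);
    }
  }
  NumericMatrix sm(n, d);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < d; j++) sm(i, j) = (double)sites[(size_t)i * d + j];
  return List::create(_["taus"] = NumericVector(taus.begin(), taus.end()),
                      _["sites"] = sm, _["steps"] = (double)t,
                      _["reached"] = (n == n_max));
}

// Ensemble of realizations; records tau_n for the requested n values only.
// [[Rcpp::export]]
NumericMatrix cpp_tau_ensemble(int model, int d, double par,
                               IntegerVector n_record, int reps,
                               double horizon, double seed) {
  check_model_d(model, d);
  int K = n_record.size();
  int n_max = n_record[K - 1];
  NumericMatrix out(reps, K);
  std::fill(out.begin(), out.end(), NA_REAL);
  long long H = (long long)horizon;
  for (int rep = 0; rep < reps; rep++) {
    LatticeWalker w;
    w.init(model, d, par);
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    std::unordered_set<uint64_t> visited;
    visited.reserve(2 * (size_t)n_max);
    visited.insert(pack_site(w.pos, d));
    long long t = 0, last_new = 0;
    int n = 1, k = 0;
    while (k < K && t < H) {
      w.step(rng);
      t++;
      if (visited.insert(pack_site(w.pos, d)).second) {
        while (k < K && n_record[k] < n) k++;
        if (k < K && n_record[k] == n) {
          out(rep, k) = (double)(t - last_new);
          k++;
        }
        last_new = t;
        n++;
      }
    }
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// N(t) (number of distinct sites visited) at the requested times.
// [[Rcpp::export]]
NumericMatrix cpp_N_ensemble(int model, int d, double par,
                             NumericVector t_record, int reps, double seed) {
  check_model_d(model, d);
  int K = t_record.size();
  long long H = (long long)t_record[K - 1];
  NumericMatrix out(reps, K);
  for (int rep = 0; rep < reps; rep++) {
    LatticeWalker w;
    w.init(model, d, par);
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    std::unordered_set<uint64_t> visited;
    visited.insert(pack_site(w.pos, d));
    long long n = 1;
    int k = 0;
    while (k < K && (long long)t_record[k] <= 0) out(rep, k++) = 1.0;
    for (long long t = 1; t <= H; t++) {
      w.step(rng);
      if (visited.insert(pack_site(w.pos, d)).second) n++;
      while (k < K && (long long)t_record[k] == t) out(rep, k++) = (double)n;
    }
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Squared Euclidean displacement at the requested times.
// [[Rcpp::export]]
NumericMatrix cpp_msd_ensemble(int model, int d, double par,
                               NumericVector t_record, int reps, double seed) {
  check_model_d(model, d);
  int K = t_record.size();
  long long H = (long long)t_record[K - 1];
  NumericMatrix out(reps, K);
  for (int rep = 0; rep < reps; rep++) {
    LatticeWalker w;
    w.init(model, d, par);
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    int k = 0;
    while (k < K && (long long)t_record[k] <= 0) out(rep, k++) = 0.0;
    for (long long t = 1; t <= H; t++) {
      w.step(rng);
      if (k < K && (long long)t_record[k] == t) {
        double r2 = 0.0;
        for (int j = 0; j < d; j++) r2 += (double)w.pos[j] * (double)w.pos[j];
        out(rep, k++) = r2;
      }
      if (k >= K) break;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Graph substrate walkers (CSR adjacency, 0-based node ids)
// ---------------------------------------------------------------------------
static inline int graph_step(const int *indptr, const int *indices, int v,
                             RWRng &rng) {
  int deg = indptr[v + 1] - indptr[v];
  return indices[indptr[v] + rng.below(deg)];
}

// [[Rcpp::export]]
List cpp_tau_single_graph(IntegerVector indptr, IntegerVector indices,
                          int start, int n_max, double horizon, double seed,
                          double stream) {
  int nv = indptr.size() - 1;
  if (start < 0 || start >= nv) stop("start node out of range");
  RWRng rng((uint64_t)seed, (uint64_t)stream);
  std::vector<uint8_t> visited(nv, 0);
  std::vector<int> sites;
  std::vector<double> taus;
  int v = start;
  visited[v] = 1;
  sites.push_back(v);
  long long t = 0, last_new = 0, H = (long long)horizon;
  int n = 1;
  const int *ip = indptr.begin(), *ix = indices.begin();
  while (n < n_max && t < H) {
    v = graph_step(ip, ix, v, rng);
    t++;
    if (!visited[v]) {
      visited[v] = 1;
      taus.push_back((double)(t - last_new));
      last_new = t;
      n++;
      sites.push_back(v);
    }
  }
  return List::create(_["taus"] = NumericVector(taus.begin(), taus.end()),
                      _["sites"] = IntegerVector(sites.begin(), sites.end()),
                      _["steps"] = (double)t, _["reached"] = (n == n_max));
}

// [[Rcpp::export]]
NumericMatrix cpp_tau_ensemble_graph(IntegerVector indptr, IntegerVector indices,
                                     IntegerVector starts, IntegerVector n_record,
                                     int reps, double horizon, double seed) {
  int nv = indptr.size() - 1;
  int K = n_record.size();
  NumericMatrix out(reps, K);
  std::fill(out.begin(), out.end(), NA_REAL);
  long long H = (long long)horizon;
  const int *ip = indptr.begin(), *ix = indices.begin();
  for (int rep = 0; rep < reps; rep++) {
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    int v = starts.size() == 1 ? starts[0]
            : starts.size() == reps ? starts[rep]
                                    : starts[rng.below(starts.size())];
    if (v < 0 || v >= nv) stop("start node out of range");
    std::vector<uint8_t> visited(nv, 0);
    visited[v] = 1;
    long long t = 0, last_new = 0;
    int n = 1, k = 0;
    while (k < K && t < H) {
      v = graph_step(ip, ix, v, rng);
      t++;
      if (!visited[v]) {
        visited[v] = 1;
        while (k < K && n_record[k] < n) k++;
        if (k < K && n_record[k] == n) {
          out(rep, k) = (double)(t - last_new);
          k++;
        }
        last_new = t;
        n++;
      }
    }
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_N_ensemble_graph(IntegerVector indptr, IntegerVector indices,
                                   IntegerVector starts, NumericVector t_record,
                                   int reps, double seed) {
  int nv = indptr.size() - 1;
  int K = t_record.size();
  long long H = (long long)t_record[K - 1];
  NumericMatrix out(reps, K);
  const int *ip = indptr.begin(), *ix = indices.begin();
  for (int rep = 0; rep < reps; rep++) {
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    int v = starts.size() == 1 ? starts[0]
            : starts.size() == reps ? starts[rep]
                                    : starts[rng.below(starts.size())];
    if (v < 0 || v >= nv) stop("start node out of range");
    std::vector<uint8_t> visited(nv, 0);
    visited[v] = 1;
    long long n = 1;
    int k = 0;
    while (k < K && (long long)t_record[k] <= 0) out(rep, k++) = 1.0;
    for (long long t = 1; t <= H; t++) {
      v = graph_step(ip, ix, v, rng);
      if (!visited[v]) { visited[v] = 1; n++; }
      while (k < K && (long long)t_record[k] == t) out(rep, k++) = (double)n;
    }
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Squared Euclidean displacement on a graph substrate with embedded coords.
// Also reports (via attribute) how many walks touched guard nodes.
// [[Rcpp::export]]
NumericMatrix cpp_msd_ensemble_graph(IntegerVector indptr, IntegerVector indices,
                                     NumericMatrix coords, IntegerVector starts,
                                     IntegerVector guard, NumericVector t_record,
                                     int reps, double seed) {
  int nv = indptr.size() - 1;
  int K = t_record.size();
  long long H = (long long)t_record[K - 1];
  NumericMatrix out(reps, K);
  std::vector<uint8_t> is_guard(nv, 0);
  for (int i = 0; i < guard.size(); i++) is_guard[guard[i]] = 1;
  int guard_hits = 0;
  const int *ip = indptr.begin(), *ix = indices.begin();
  int nc = coords.ncol();
  for (int rep = 0; rep < reps; rep++) {
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    int v0 = starts.size() == 1 ? starts[0]
             : starts.size() == reps ? starts[rep]
                                     : starts[rng.below(starts.size())];
    int v = v0;
    bool hit = false;
    int k = 0;
    while (k < K && (long long)t_record[k] <= 0) out(rep, k++) = 0.0;
    for (long long t = 1; t <= H; t++) {
      v = graph_step(ip, ix, v, rng);
      if (is_guard[v]) hit = true;
      if (k < K && (long long)t_record[k] == t) {
        double r2 = 0.0;
        for (int j = 0; j < nc; j++) {
          double dx = coords(v, j) - coords(v0, j);
          r2 += dx * dx;
        }
        out(rep, k++) = r2;
      }
      if (k >= K) break;
    }
    if (hit) guard_hits++;
  }
  out.attr("guard_hits") = guard_hits;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_walk_graph(IntegerVector indptr, IntegerVector indices,
                             int start, double steps, double seed,
                             double stream) {
  int nv = indptr.size() - 1;
  if (start < 0 || start >= nv) stop("start node out of range");
  RWRng rng((uint64_t)seed, (uint64_t)stream);
  long long T = (long long)steps;
  IntegerVector out(T + 1);
  const int *ip = indptr.begin(), *ix = indices.begin();
  int v = start;
  out[0] = v;
  for (long long t = 1; t <= T; t++) {
    v = graph_step(ip, ix, v, rng);
    out[t] = v;
  }
  return out;
}

// Time of the first visit to the n-th distinct site (n in n_record), i.e.
// the partial sums of the tau series.
// [[Rcpp::export]]
NumericMatrix cpp_visit_time_ensemble(int model, int d, double par,
                                      IntegerVector n_record, int reps,
                                      double horizon, double seed) {
  check_model_d(model, d);
  int K = n_record.size();
  int n_max = n_record[K - 1];
  NumericMatrix out(reps, K);
  std::fill(out.begin(), out.end(), NA_REAL);
  long long H = (long long)horizon;
  for (int rep = 0; rep < reps; rep++) {
    LatticeWalker w;
    w.init(model, d, par);
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    std::unordered_set<uint64_t> visited;
    visited.reserve(2 * (size_t)n_max);
    visited.insert(pack_site(w.pos, d));
    long long t = 0;
    int n = 1, k = 0;
    while (k < K && n_record[k] <= 1) out(rep, k++) = 0.0;
    while (k < K && t < H) {
      w.step(rng);
      t++;
      if (visited.insert(pack_site(w.pos, d)).second) {
        n++;
        while (k < K && n_record[k] == n) out(rep, k++) = (double)t;
      }
    }
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Boundary observables on the 2d square lattice (simple walk)
// ---------------------------------------------------------------------------

// First-attainment times of each even perimeter level 6, 8, ..., p_max.
// Perimeter = number of visited<->unvisited nearest-neighbour bonds; the
// initial single-site domain has P = 4 at t = 0.
// [[Rcpp::export]]
NumericMatrix cpp_perimeter_levels(int p_max, double horizon, int reps,
                                   double seed) {
  int K = (p_max - 4) / 2;
  NumericMatrix out(reps, K);
  std::fill(out.begin(), out.end(), NA_REAL);
  long long H = (long long)horizon;
  for (int rep = 0; rep < reps; rep++) {
    LatticeWalker w;
    w.init(0, 2, 0.0);
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    std::unordered_set<uint64_t> visited;
    visited.insert(pack_site(w.pos, 2));
    long long P = 4;
    int k = 0;
    for (long long t = 1; t <= H && k < K; t++) {
      w.step(rng);
      if (visited.insert(pack_site(w.pos, 2)).second) {
        int nvis = 0;
        long long nb[2];
        for (int dir = 0; dir < 4; dir++) {
          nb[0] = w.pos[0]; nb[1] = w.pos[1];
          nb[dir >> 1] += (dir & 1) ? 1 : -1;
          if (visited.count(pack_site(nb, 2))) nvis++;
        }
        P += 4 - 2 * nvis;
        while (k < K && P >= (long long)(6 + 2 * k)) {
          out(rep, k) = (double)t;
          k++;
        }
      }
    }
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// First-attainment times of island counts 1..i_max for 1d Levy flights.
// Islands are maximal runs of unvisited sites strictly inside [min, max]
// of the visited set.
// [[Rcpp::export]]
NumericMatrix cpp_island_levels(double alpha, int i_max, double horizon,
                                int reps, double seed) {
  NumericMatrix out(reps, i_max);
  std::fill(out.begin(), out.end(), NA_REAL);
  long long H = (long long)horizon;
  for (int rep = 0; rep < reps; rep++) {
    LatticeWalker w;
    w.init(2, 1, alpha);
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    std::unordered_set<uint64_t> visited;
    long long key0 = 0;
    visited.insert(pack_site(&key0, 1));
    long long lo = 0, hi = 0, I = 0;
    int k = 0;
    for (long long t = 1; t <= H && k < i_max; t++) {
      w.step(rng);
      long long x = w.pos[0];
      if (!visited.insert(pack_site(&x, 1)).second) continue;
      if (x > hi) {
        if (x > hi + 1) I++; // new gap (hi+1 .. x-1)
        hi = x;
      } else if (x < lo) {
        if (x < lo - 1) I++;
        lo = x;
      } else {
        long long xl = x - 1, xr = x + 1;
        bool vl = visited.count(pack_site(&xl, 1)) > 0;
        bool vr = visited.count(pack_site(&xr, 1)) > 0;
        if (vl && vr) I--;        // gap of size one filled
        else if (!vl && !vr) I++; // gap split in two
      }
      while (k < i_max && I >= (long long)(k + 1)) {
        out(rep, k) = (double)t;
        k++;
      }
    }
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// New-site discovery times and dimer-increment times for one 1d Levy
// realization (dimer = pair of adjacent visited sites; a bulk observable).
// [[Rcpp::export]]
List cpp_levy1d_bulk_events(double alpha, int n_events, double horizon,
                            double seed, double stream) {
  LatticeWalker w;
  w.init(2, 1, alpha);
  RWRng rng((uint64_t)seed, (uint64_t)stream);
  std::unordered_set<uint64_t> visited;
  long long z = 0;
  visited.insert(pack_site(&z, 1));
  std::vector<double> site_times, dimer_times;
  long long H = (long long)horizon;
  for (long long t = 1; t <= H && (int)site_times.size() < n_events; t++) {
    w.step(rng);
    long long x = w.pos[0];
    if (!visited.insert(pack_site(&x, 1)).second) continue;
    site_times.push_back((double)t);
    long long xl = x - 1, xr = x + 1;
    int k = (visited.count(pack_site(&xl, 1)) > 0) +
            (visited.count(pack_site(&xr, 1)) > 0);
    if (k > 0) dimer_times.push_back((double)t);
  }
  return List::create(
      _["site_times"] = NumericVector(site_times.begin(), site_times.end()),
      _["dimer_times"] = NumericVector(dimer_times.begin(), dimer_times.end()));
}

// ---------------------------------------------------------------------------
// Starving forager: dies when S consecutive steps pass without finding a
// previously unvisited (food-bearing) site.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_starving(int d, int S, int reps, double seed) {
  if (d != 1 && d != 2) stop("starving walks are implemented in 1d and 2d");
  NumericMatrix out(reps, 2);
  for (int rep = 0; rep < reps; rep++) {
    LatticeWalker w;
    w.init(0, d, 0.0);
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    std::unordered_set<uint64_t> visited;
    visited.insert(pack_site(w.pos, d));
    long long t = 0, hungry = 0, n = 1;
    while (hungry < S) {
      w.step(rng);
      t++;
      if (visited.insert(pack_site(w.pos, d)).second) {
        n++;
        hungry = 0;
      } else {
        hungry++;
      }
    }
    out(rep, 0) = (double)t;
    out(rep, 1) = (double)n;
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Monte-Carlo first-exit times from a frozen visited domain (oracle for the
// exact enumeration). Models: 0 simple, 1 persistent, 2 levy1d.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_mc_exit(int model, int d, double par, NumericMatrix sites,
                          int start_row, int reps, double seed) {
  check_model_d(model, d);
  std::unordered_set<uint64_t> dom;
  int n = sites.nrow();
  for (int i = 0; i < n; i++) {
    long long pos[6] = {0, 0, 0, 0, 0, 0};
    for (int j = 0; j < d; j++) pos[j] = (long long)sites(i, j);
    dom.insert(pack_site(pos, d));
  }
  NumericVector out(reps);
  for (int rep = 0; rep < reps; rep++) {
    LatticeWalker w;
    w.init(model, d, par);
    for (int j = 0; j < d; j++) w.pos[j] = (long long)sites(start_row - 1, j);
    RWRng rng((uint64_t)seed, (uint64_t)rep);
    long long t = 0;
    while (true) {
      w.step(rng);
      t++;
      if (!dom.count(pack_site(w.pos, d))) break;
      if (t > 100000000LL) stop("MC exit walk did not terminate");
    }
    out[rep] = (double)t;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact enumeration: propagate the occupation vector through the
// sub-stochastic matrix restricted to the visited domain.  M is the
// transpose of the restricted transition matrix in CSC form (so each
// iteration is v <- M %*% v); e[j] is the one-step exit probability from
// state j.  Stops when residual survival < tol or tau_max reached.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_exit_propagate(IntegerVector indptr, IntegerVector indices,
                        NumericVector xvals, NumericVector e, NumericVector v0,
                        double tau_max, double tol) {
  int n = v0.size();
  std::vector<double> v(v0.begin(), v0.end()), vn(n);
  std::vector<double> mass, ss;
  long long T = (long long)tau_max;
  mass.reserve((size_t)std::min(T, (long long)1e7));
  ss.reserve((size_t)std::min(T, (long long)1e7));
  double surv = 0.0;
  for (int i = 0; i < n; i++) surv += v[i];
  const int *ip = indptr.begin(), *ix = indices.begin();
  const double *xv = xvals.begin();
  for (long long t = 1; t <= T; t++) {
    double m = 0.0;
    for (int j = 0; j < n; j++) m += v[j] * e[j];
    mass.push_back(m);
    std::fill(vn.begin(), vn.end(), 0.0);
    for (int j = 0; j < n; j++) {
      double vj = v[j];
      if (vj == 0.0) continue;
      for (int q = ip[j]; q < ip[j + 1]; q++) vn[ix[q]] += xv[q] * vj;
    }
    std::swap(v, vn);
    surv = 0.0;
    for (int i = 0; i < n; i++) surv += v[i];
    ss.push_back(surv); // computed from v directly: no 1-cumsum cancellation
    if (surv < tol) break;
    if (t % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["mass"] = NumericVector(mass.begin(), mass.end()),
                      _["survival"] = surv,
                      _["survival_series"] = NumericVector(ss.begin(), ss.end()));
}

// ---------------------------------------------------------------------------
// Suffix regrowth for Wang-Landau domain sampling: rebuild the visited set
// from a trajectory prefix and continue the walk until n_target distinct
// sites. Models: 0 simple, 1 persistent.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_prefix_extend(int model, int d, double par,
                                NumericMatrix prefix, int n_target,
                                double horizon, double seed, double stream) {
  check_model_d(model, d);
  if (model != 0 && model != 1) stop("suffix regrowth supports simple and persistent walks");
  int T0 = prefix.nrow();
  LatticeWalker w;
  w.init(model, d, par);
  std::unordered_set<uint64_t> visited;
  std::vector<long long> traj;
  traj.reserve((size_t)(T0 + 16) * d);
  int n = 0;
  for (int i = 0; i < T0; i++) {
    long long pos[6] = {0, 0, 0, 0, 0, 0};
    for (int j = 0; j < d; j++) {
      pos[j] = (long long)prefix(i, j);
      traj.push_back(pos[j]);
    }
    if (visited.insert(pack_site(pos, d)).second) n++;
    for (int j = 0; j < d; j++) w.pos[j] = pos[j];
  }
  if (model == 1 && T0 >= 2) {
    for (int j = 0; j < d; j++) {
      long long delta = (long long)prefix(T0 - 1, j) - (long long)prefix(T0 - 2, j);
      if (delta == 1) w.prevdir = 2 * j + 1;
      else if (delta == -1) w.prevdir = 2 * j;
    }
  }
  RWRng rng((uint64_t)seed, (uint64_t)stream);
  long long H = (long long)horizon, t = 0;
  while (n < n_target && t < H) {
    w.step(rng);
    t++;
    for (int j = 0; j < d; j++) traj.push_back(w.pos[j]);
    if (visited.insert(pack_site(w.pos, d)).second) n++;
  }
  int TT = (int)(traj.size() / d);
  NumericMatrix out(TT, d);
  for (int i = 0; i < TT; i++)
    for (int j = 0; j < d; j++) out(i, j) = (double)traj[(size_t)i * d + j];
  return out;
}

// max over rows of a of the min squared Euclidean distance to rows of b
// [[Rcpp::export]]
double cpp_max_min_dist2(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow(), d = a.ncol();
  double best = 0.0;
  for (int i = 0; i < n; i++) {
    double mn = R_PosInf;
    for (int j = 0; j < m; j++) {
      double s = 0.0;
      for (int k = 0; k < d; k++) {
        double dx = a(i, k) - b(j, k);
        s += dx * dx;
      }
      if (s < mn) {
        mn = s;
        if (mn <= best) break; // cannot raise the max
      }
    }
    if (mn > best && mn < R_PosInf) best = mn;
  }
  return best;
}

// Count of visited<->unvisited nearest-neighbour bonds (the boundary
// "surface" of a lattice domain).
// [[Rcpp::export]]
double cpp_boundary_bonds(NumericMatrix sites, int d) {
  std::unordered_set<uint64_t> dom;
  int n = sites.nrow();
  for (int i = 0; i < n; i++) {
    long long pos[6] = {0, 0, 0, 0, 0, 0};
    for (int j = 0; j < d; j++) pos[j] = (long long)sites(i, j);
    dom.insert(pack_site(pos, d));
  }
  long long count = 0;
  for (int i = 0; i < n; i++) {
    long long pos[6] = {0, 0, 0, 0, 0, 0};
    for (int j = 0; j < d; j++) pos[j] = (long long)sites(i, j);
    for (int dir = 0; dir < 2 * d; dir++) {
      long long nb[6];
      for (int j = 0; j < d; j++) nb[j] = pos[j];
      nb[dir >> 1] += (dir & 1) ? 1 : -1;
      if (!dom.count(pack_site(nb, d))) count++;
    }
  }
  return (double)count;
}
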