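// Structured-coalescent engines for a two-deme history with piecewise-constant
// deme sizes, a divergence event (demes merge backwards in time into an
// ancestral deme) and timed migration windows.
//
// Two entry points:
//   sfs_branch_cpp()  - accumulates branch lengths by joint descendant-count
//                       class (i samples in deme 1, j in deme 2); the expected
//                       SFS is proportional to these lengths. No recombination
//                       (the expected SFS is recombination-invariant). O(events)
//                       per replicate: a lineage's class is fixed at creation,
//                       so it contributes (death - birth) once.
//   panel_cpp()       - simulates a haplotype panel with infinite-sites
//                       mutation; optional Hudson ancestral recombination
//                       graph so LD decays with physical distance.
//
// Conventions: sizes are diploid Ne and pairwise coalescence rate in a deme of
// size N is 1/(2N) (selfing strains sampled as single haplotypes). Migration
// rates are backwards-in-time per-lineage deme-switch rates per generation.
// All times are generations before present. R's RNG is used throughout so
// set.seed() in the caller governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Demography {
  double t_div;
  std::vector<double> d1_t, d1_N;    // change times (ascending, first = 0), sizes
  std::vector<double> d2_t, d2_N;
  std::vector<double> anc_t, anc_N;  // first change time = t_div
  std::vector<double> mig_t0, mig_t1, m12, m21;

  static double piece(const std::vector<double>& tt,
                      const std::vector<double>& NN, double t) {
    size_t k = 0;
    while (k + 1 < tt.size() && t >= tt[k + 1]) ++k;
    return NN[k];
  }
  double size1(double t) const {
    if (t >= t_div) return piece(anc_t, anc_N, t);
    return piece(d1_t, d1_N, t);
  }
  double size2(double t) const {
    if (t >= t_div) return piece(anc_t, anc_N, t);
    return piece(d2_t, d2_N, t);
  }
  // current backward migration rates (summed over any overlapping windows)
  void mig(double t, double& r12, double& r21) const {
    r12 = 0.0; r21 = 0.0;
    if (t >= t_div) return;
    for (size_t w = 0; w < mig_t0.size(); ++w)
      if (t >= mig_t0[w] && t < mig_t1[w]) { r12 += m12[w]; r21 += m21[w]; }
  }
  // next time > t at which any rate can change
  double next_boundary(double t) const {
    double b = R_PosInf;
    if (t < t_div) b = t_div;
    auto scan = [&](const std::vector<double>& tt) {
      for (double x : tt) if (x > t && x < b) b = x;
    };
    scan(d1_t); scan(d2_t); scan(anc_t);
    for (size_t w = 0; w < mig_t0.size(); ++w) {
      if (mig_t0[w] > t && mig_t0[w] < b) b = mig_t0[w];
      if (mig_t1[w] > t && mig_t1[w] < b) b = mig_t1[w];
    }
    return b;
  }
};

Demography parse_demography(double t_div,
                            NumericVector d1_t, NumericVector d1_N,
                            NumericVector d2_t, NumericVector d2_N,
                            NumericVector anc_t, NumericVector anc_N,
                            NumericVector mig_t0, NumericVector mig_t1,
                            NumericVector m12, NumericVector m21) {
  Demography dem;
  dem.t_div = t_div;
  dem.d1_t = as<std::vector<double>>(d1_t);
  dem.d1_N = as<std::vector<double>>(d1_N);
  dem.d2_t = as<std::vector<double>>(d2_t);
  dem.d2_N = as<std::vector<double>>(d2_N);
  dem.anc_t = as<std::vector<double>>(anc_t);
  dem.anc_N = as<std::vector<double>>(anc_N);
  dem.mig_t0 = as<std::vector<double>>(mig_t0);
  dem.mig_t1 = as<std::vector<double>>(mig_t1);
  dem.m12 = as<std::vector<double>>(m12);
  dem.m21 = as<std::vector<double>>(m21);
  return dem;
}

inline int runif_int(int n) {  // uniform on 0..n-1
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Fast local PRNG (xoshiro256+) seeded once per call from R's RNG, so
// set.seed() in R fully determines the stream while the hot loop avoids
// per-draw calls into R's generator.
struct FastRng {
  uint64_t s[4];
  explicit FastRng(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double expo() { return -std::log(unif()); }
  inline int below(int n) {  // uniform 0..n-1
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

}  // namespace

// ---------------------------------------------------------------------------
// Branch-length joint SFS accumulator (no recombination).
// Returns (n1+1) x (n2+1) matrix: total branch length (generations, summed
// over n_sims genealogies) subtending i deme-1 samples and j deme-2 samples.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".sfs_branch_cpp")]]
NumericMatrix sfs_branch_cpp(int n1, int n2, int n_sims, double t_div,
                             NumericVector d1_t, NumericVector d1_N,
                             NumericVector d2_t, NumericVector d2_N,
                             NumericVector anc_t, NumericVector anc_N,
                             NumericVector mig_t0, NumericVector mig_t1,
                             NumericVector m12, NumericVector m21) {
  Demography dem = parse_demography(t_div, d1_t, d1_N, d2_t, d2_N,
                                    anc_t, anc_N, mig_t0, mig_t1, m12, m21);
  const int n = n1 + n2;
  NumericMatrix out(n1 + 1, n2 + 1);
  if (n < 2) return out;
  FastRng rng((uint64_t)(unif_rand() * 9007199254740992.0));

  // precompute the sorted boundary times at which any rate can change
  std::vector<double> bounds;
  auto add_b = [&](double x) { if (x > 0.0 && R_FINITE(x)) bounds.push_back(x); };
  for (double x : dem.d1_t) add_b(x);
  for (double x : dem.d2_t) add_b(x);
  for (double x : dem.anc_t) add_b(x);
  for (double x : dem.mig_t0) add_b(x);
  for (double x : dem.mig_t1) add_b(x);
  add_b(dem.t_div);
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());

  const int cap = 2 * n;
  std::vector<int> k1(cap), k2(cap);
  std::vector<double> birth(cap);
  std::vector<int> dl[2];  // per-deme lineage id lists
  dl[0].reserve(cap); dl[1].reserve(cap);

  for (int s = 0; s < n_sims; ++s) {
    dl[0].clear(); dl[1].clear();
    for (int i = 0; i < n; ++i) {
      k1[i] = (i < n1) ? 1 : 0;
      k2[i] = (i < n1) ? 0 : 1;
      birth[i] = 0.0;
      dl[i < n1 ? 0 : 1].push_back(i);
    }
    int next_id = n;
    double t = 0.0;
    size_t bi = 0;
    bool merged = !(dem.t_div > 0.0 && R_FINITE(dem.t_div)) && n2 == 0;
    bool fresh = true;          // rates must be recomputed
    double N1 = 1, N2 = 1, r12 = 0, r21 = 0, bnd = R_PosInf;

    while ((int)(dl[0].size() + dl[1].size()) > 1) {
      if (fresh) {
        if (!merged && t >= dem.t_div) {
          // merge demes: move all deme-2 lineages into deme 1
          for (int id : dl[1]) dl[0].push_back(id);
          dl[1].clear();
          merged = true;
        }
        N1 = dem.size1(t);
        N2 = dem.size2(t);
        dem.mig(t, r12, r21);
        if (merged) { r12 = r21 = 0.0; }
        while (bi < bounds.size() && bounds[bi] <= t) ++bi;
        bnd = bi < bounds.size() ? bounds[bi] : R_PosInf;
        fresh = false;
      }
      int c1 = (int)dl[0].size(), c2 = (int)dl[1].size();
      double rc1 = c1 >= 2 ? (double)c1 * (c1 - 1) / 2.0 / (2.0 * N1) : 0.0;
      double rc2 = c2 >= 2 ? (double)c2 * (c2 - 1) / 2.0 / (2.0 * N2) : 0.0;
      double rm = c1 * r12 + c2 * r21;
      double lambda = rc1 + rc2 + rm;
      if (lambda <= 0.0) {
        if (!R_FINITE(bnd))
          stop("coalescent cannot complete: isolated lineages with no migration and no divergence");
        t = bnd;
        fresh = true;
        continue;
      }
      double dt = rng.expo() / lambda;
      if (t + dt >= bnd) { t = bnd; fresh = true; continue; }
      t += dt;
      double u = rng.unif() * lambda;
      if (u < rc1 + rc2) {
        int d = (u < rc1) ? 0 : 1;
        std::vector<int>& v = dl[d];
        int cnt = (int)v.size();
        int a = rng.below(cnt), b = rng.below(cnt - 1);
        if (b >= a) ++b;
        int la = v[a], lb = v[b];
        out(k1[la], k2[la]) += t - birth[la];
        out(k1[lb], k2[lb]) += t - birth[lb];
        int id = next_id++;
        k1[id] = k1[la] + k1[lb];
        k2[id] = k2[la] + k2[lb];
        birth[id] = t;
        if (a < b) std::swap(a, b);
        v[a] = v.back(); v.pop_back();
        v[b] = v.back(); v.pop_back();
        v.push_back(id);
      } else {
        double v = u - rc1 - rc2;
        int d = (v < c1 * r12) ? 0 : 1;
        std::vector<int>& src = dl[d];
        std::vector<int>& dst = dl[1 - d];
        int a = rng.below((int)src.size());
        dst.push_back(src[a]);
        src[a] = src.back();
        src.pop_back();
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Haplotype panel simulator (infinite sites; optional Hudson ARG).
// Returns a list: positions (continuous, in [0, L)), and a list of carrier
// bitmasks (raw 64-bit words packed as doubles would lose precision, so we
// return an IntegerMatrix of 0/1 columns directly).
// ---------------------------------------------------------------------------

namespace {

struct Seg {
  double a, b;                  // [a, b) in bp coordinates
  std::vector<uint64_t> bits;   // descendant sample set
  int cnt;                      // popcount
};

struct Lin {
  int deme;
  double birth;
  std::vector<Seg> segs;        // sorted, non-overlapping
  double lo, hi;                // span of ancestral material
  void span() {
    lo = segs.front().a;
    hi = segs.back().b;
  }
};

struct Mut {
  double pos;
  std::vector<uint64_t> bits;
};

inline int popcount_words(const std::vector<uint64_t>& w) {
  int c = 0;
  for (uint64_t x : w) {
#if defined(__GNUC__) || defined(__clang__)
    c += __builtin_popcountll(x);
#else
    while (x) { c += (int)(x & 1); x >>= 1; }
#endif
  }
  return c;
}

// Poisson mutations over a lineage's lifetime; carriers = segment bits.
void drop_mutations(const Lin& L, double t_now, double mu,
                    std::vector<Mut>& muts) {
  double dt = t_now - L.birth;
  if (dt <= 0.0 || mu <= 0.0) return;
  for (const Seg& s : L.segs) {
    double lam = mu * (s.b - s.a) * dt;
    if (lam <= 0.0) continue;
    int k = (int)R::rpois(lam);
    for (int i = 0; i < k; ++i) {
      Mut m;
      m.pos = s.a + unif_rand() * (s.b - s.a);
      m.bits = s.bits;
      muts.push_back(std::move(m));
    }
  }
}

// Merge two segment lists at a coalescence; intervals whose union covers the
// whole sample have found their MRCA and are dropped.
std::vector<Seg> merge_segs(const std::vector<Seg>& A, const std::vector<Seg>& B,
                            int n, int W) {
  std::vector<double> cuts;
  for (const Seg& s : A) { cuts.push_back(s.a); cuts.push_back(s.b); }
  for (const Seg& s : B) { cuts.push_back(s.a); cuts.push_back(s.b); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  for (size_t c = 0; c + 1 < cuts.size(); ++c) {
    double a = cuts[c], b = cuts[c + 1];
    while (ia < A.size() && A[ia].b <= a) ++ia;
    while (ib < B.size() && B[ib].b <= a) ++ib;
    const Seg* sa = (ia < A.size() && A[ia].a <= a && A[ia].b >= b) ? &A[ia] : nullptr;
    const Seg* sb = (ib < B.size() && B[ib].a <= a && B[ib].b >= b) ? &B[ib] : nullptr;
    if (!sa && !sb) continue;
    Seg s;
    s.a = a; s.b = b;
    if (sa && sb) {
      s.bits.resize(W);
      for (int w = 0; w < W; ++w) s.bits[w] = sa->bits[w] | sb->bits[w];
    } else {
      s.bits = sa ? sa->bits : sb->bits;
    }
    s.cnt = popcount_words(s.bits);
    if (s.cnt >= n) continue;  // MRCA reached for this interval
    // coalesce adjacent identical-carrier intervals to keep lists short
    if (!out.empty() && out.back().b == s.a && out.back().bits == s.bits) {
      out.back().b = s.b;
    } else {
      out.push_back(std::move(s));
    }
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".panel_cpp")]]
List panel_cpp(int n1, int n2, double seq_len, double mu, double rec,
               double t_div,
               NumericVector d1_t, NumericVector d1_N,
               NumericVector d2_t, NumericVector d2_N,
               NumericVector anc_t, NumericVector anc_N,
               NumericVector mig_t0, NumericVector mig_t1,
               NumericVector m12, NumericVector m21) {
  Demography dem = parse_demography(t_div, d1_t, d1_N, d2_t, d2_N,
                                    anc_t, anc_N, mig_t0, mig_t1, m12, m21);
  const int n = n1 + n2;
  if (n < 2) stop("need at least two haplotypes");
  const int W = (n + 63) / 64;

  std::vector<Lin> lin;
  lin.reserve(4 * n);
  for (int i = 0; i < n; ++i) {
    Lin L;
    L.deme = (i < n1) ? 1 : 2;
    L.birth = 0.0;
    Seg s;
    s.a = 0.0; s.b = seq_len;
    s.bits.assign(W, 0);
    s.bits[i / 64] |= (uint64_t)1 << (i % 64);
    s.cnt = 1;
    L.segs.push_back(std::move(s));
    L.span();
    lin.push_back(std::move(L));
  }

  std::vector<Mut> muts;
  double t = 0.0;
  bool merged = false;
  long long guard = 0;

  while (lin.size() > 1) {
    if (++guard > 200000000LL) stop("ARG simulation failed to terminate");
    if (!merged && t >= dem.t_div) {
      for (Lin& L : lin) L.deme = 1;
      merged = true;
    }
    int c1 = 0, c2 = 0;
    double span1 = 0.0, span_all = 0.0;
    for (const Lin& L : lin) {
      (L.deme == 1 ? c1 : c2)++;
      span_all += (L.hi - L.lo);
    }
    (void)span1;
    double N1 = dem.size1(t), N2 = dem.size2(t);
    double r12, r21;
    dem.mig(t, r12, r21);
    if (merged) { r12 = r21 = 0.0; }
    double rc1 = c1 >= 2 ? (double)c1 * (c1 - 1) / 2.0 / (2.0 * N1) : 0.0;
    double rc2 = c2 >= 2 ? (double)c2 * (c2 - 1) / 2.0 / (2.0 * N2) : 0.0;
    double rr = rec > 0.0 ? rec * span_all : 0.0;
    double rm = c1 * r12 + c2 * r21;
    double lambda = rc1 + rc2 + rr + rm;
    double bnd = dem.next_boundary(t);
    if (lambda <= 0.0) {
      if (!R_FINITE(bnd))
        stop("coalescent cannot complete: isolated lineages with no migration and no divergence");
      t = bnd;
      continue;
    }
    double dt = exp_rand() / lambda;
    if (t + dt >= bnd) { t = bnd; continue; }
    t += dt;
    double u = unif_rand() * lambda;
    if (u < rc1 + rc2) {
      int d = (u < rc1) ? 1 : 2;
      int cnt = (d == 1) ? c1 : c2;
      int a = runif_int(cnt), b = runif_int(cnt - 1);
      if (b >= a) ++b;
      int ia = -1, ib = -1, seen = 0;
      for (size_t k = 0; k < lin.size(); ++k) {
        if (lin[k].deme == d) {
          if (seen == a) ia = (int)k;
          if (seen == b) ib = (int)k;
          ++seen;
        }
      }
      drop_mutations(lin[ia], t, mu, muts);
      drop_mutations(lin[ib], t, mu, muts);
      Lin merged_lin;
      merged_lin.deme = d;
      merged_lin.birth = t;
      merged_lin.segs = merge_segs(lin[ia].segs, lin[ib].segs, n, W);
      if (ia < ib) std::swap(ia, ib);
      lin[ia] = std::move(lin.back()); lin.pop_back();
      lin[ib] = std::move(lin.back()); lin.pop_back();
      if (!merged_lin.segs.empty()) {
        merged_lin.span();
        lin.push_back(std::move(merged_lin));
      }
    } else if (u < rc1 + rc2 + rr) {
      // recombination: pick lineage weighted by span, split at uniform point
      double v = (u - rc1 - rc2) / rec;
      size_t i = 0;
      double acc = 0.0;
      for (; i < lin.size(); ++i) {
        acc += lin[i].hi - lin[i].lo;
        if (v < acc) break;
      }
      if (i >= lin.size()) i = lin.size() - 1;
      Lin& L = lin[i];
      double x = L.lo + unif_rand() * (L.hi - L.lo);
      if (x <= L.lo || x >= L.hi) continue;  // degenerate draw; no-op
      drop_mutations(L, t, mu, muts);
      Lin left, right;
      left.deme = right.deme = L.deme;
      left.birth = right.birth = t;
      for (const Seg& s : L.segs) {
        if (s.b <= x) left.segs.push_back(s);
        else if (s.a >= x) right.segs.push_back(s);
        else {
          Seg sl = s, sr = s;
          sl.b = x; sr.a = x;
          left.segs.push_back(std::move(sl));
          right.segs.push_back(std::move(sr));
        }
      }
      if (left.segs.empty() || right.segs.empty()) {
        // breakpoint fell in a terminal gap: restore lifetime bookkeeping
        L.birth = t;
        continue;
      }
      left.span(); right.span();
      lin[i] = std::move(left);
      lin.push_back(std::move(right));
    } else {
      double v = u - rc1 - rc2 - rr;
      int d = (v < c1 * r12) ? 1 : 2;
      int cnt = (d == 1) ? c1 : c2;
      int a = runif_int(cnt), seen = 0;
      for (Lin& L : lin) {
        if (L.deme == d) {
          if (seen == a) { L.deme = (d == 1) ? 2 : 1; break; }
          ++seen;
        }
      }
    }
  }
  // a single surviving lineage holds intervals that never reach a full-sample
  // MRCA only if material was dropped; its mutations would be shared by a
  // proper subset, but with one lineage left no further coalescence can occur
  // and any remaining material is ancestral to all retained carriers only --
  // mutations above it are still polymorphic in the sample only if cnt < n,
  // which cannot happen here because singleton survival implies cnt == n or
  // untraceable material; we therefore stop without adding mutations.

  // pack mutations: sort by position, integerize with collision re-draw
  std::sort(muts.begin(), muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  int S = (int)muts.size();
  IntegerVector pos(S);
  IntegerMatrix geno(n, S);
  std::set<int> used;
  int L_int = (int)seq_len;
  for (int j = 0; j < S; ++j) {
    int p = 1 + (int)std::floor(muts[j].pos);
    if (p > L_int) p = L_int;
    int tries = 0;
    while (used.count(p)) {
      p = 1 + runif_int(L_int);
      if (++tries > 10000) stop("cannot place mutation without collision");
    }
    used.insert(p);
    pos[j] = p;
    for (int i = 0; i < n; ++i)
      geno(i, j) = (muts[j].bits[i / 64] >> (i % 64)) & 1 ? 1 : 0;
  }
  return List::create(_["positions"] = pos, _["geno"] = geno);
}
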