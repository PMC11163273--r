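// Core numerical engine: neighbor lists, Mpipi-style pair interactions
// (Wang-Frenkel + Debye-Hueckel + harmonic bonds), BAOAB Langevin /
// velocity-Verlet integration, and steepest-descent relaxation.
//
// Units: nm, ps, kJ/mol, g/mol, elementary charge, kelvin.
// With these units 1/2 m v^2 [g/mol (nm/ps)^2] is directly kJ/mol.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic RNG (splitmix64 + Box-Muller), independent of R's RNG so that
// seeded trajectories are bitwise reproducible
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s;
  bool has_spare;
  double spare;
  explicit Rng(uint64_t seed) : s(seed), has_spare(false), spare(0.0) {}
  uint64_t next_u64() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// helpers
// ---------------------------------------------------------------------------
// assumes |d| < 1.5 L, which holds because positions are kept wrapped
// (at entry and at every neighbor-list rebuild)
static inline double min_image(double d, double L) {
  if (d > 0.5 * L) return d - L;
  if (d < -0.5 * L) return d + L;
  return d;
}

static inline double wrap_coord(double x, double L) {
  return x - L * std::floor(x / L);
}

// exp(x) via range reduction + degree-10 Taylor; relative error ~2e-13
// over the screened-Coulomb argument range, ~4x faster than libm
static inline double fast_exp(double x) {
  const double LOG2E = 1.4426950408889634;
  const double LN2HI = 6.93147180369123816490e-01;
  const double LN2LO = 1.90821492927058770002e-10;
  double k = std::floor(x * LOG2E + 0.5);
  double f = (x - k * LN2HI) - k * LN2LO;
  double p = 1.0 + f * (1.0 + f * (0.5 + f * (1.0 / 6 + f * (1.0 / 24 +
             f * (1.0 / 120 + f * (1.0 / 720 + f * (1.0 / 5040 +
             f * (1.0 / 40320 + f * (1.0 / 362880 +
             f * (1.0 / 3628800))))))))));
  union { uint64_t u; double d; } s;
  s.u = (uint64_t)((int64_t)k + 1023) << 52;
  return p * s.d;
}

#if defined(__SSE2__) && !defined(CONDEVOL_NO_SIMD)
#include <emmintrin.h>
// two-lane mirror of fast_exp (identical operation order, so results are
// bitwise equal to the scalar path); valid for the screened-Coulomb
// argument range
static inline __m128d v_fast_exp(__m128d x) {
  const __m128d LOG2E = _mm_set1_pd(1.4426950408889634);
  const __m128d LN2HI = _mm_set1_pd(6.93147180369123816490e-01);
  const __m128d LN2LO = _mm_set1_pd(1.90821492927058770002e-10);
  __m128d t = _mm_add_pd(_mm_mul_pd(x, LOG2E), _mm_set1_pd(0.5));
  __m128i ti = _mm_cvttpd_epi32(t);
  __m128d k = _mm_cvtepi32_pd(ti);
  __m128d adj = _mm_and_pd(_mm_cmpgt_pd(k, t), _mm_set1_pd(1.0));
  k = _mm_sub_pd(k, adj);  // floor(t)
  __m128d f = _mm_sub_pd(_mm_sub_pd(x, _mm_mul_pd(k, LN2HI)),
                         _mm_mul_pd(k, LN2LO));
  __m128d p = _mm_set1_pd(1.0 / 3628800);
  p = _mm_add_pd(_mm_set1_pd(1.0 / 362880), _mm_mul_pd(f, p));
  p = _mm_add_pd(_mm_set1_pd(1.0 / 40320), _mm_mul_pd(f, p));
  p = _mm_add_pd(_mm_set1_pd(1.0 / 5040), _mm_mul_pd(f, p));
  p = _mm_add_pd(_mm_set1_pd(1.0 / 720), _mm_mul_pd(f, p));
  p = _mm_add_pd(_mm_set1_pd(1.0 / 120), _mm_mul_pd(f, p));
  p = _mm_add_pd(_mm_set1_pd(1.0 / 24), _mm_mul_pd(f, p));
  p = _mm_add_pd(_mm_set1_pd(1.0 / 6), _mm_mul_pd(f, p));
  p = _mm_add_pd(_mm_set1_pd(0.5), _mm_mul_pd(f, p));
  p = _mm_add_pd(_mm_set1_pd(1.0), _mm_mul_pd(f, p));
  p = _mm_add_pd(_mm_set1_pd(1.0), _mm_mul_pd(f, p));
  // scale by 2^k
  __m128i ki = _mm_cvttpd_epi32(k);  // k is integral and small
  __m128i sign = _mm_srai_epi32(ki, 31);
  __m128i k64 = _mm_unpacklo_epi32(ki, sign);
  k64 = _mm_add_epi64(k64, _mm_set1_epi64x(1023));
  k64 = _mm_slli_epi64(k64, 52);
  return _mm_mul_pd(p, _mm_castsi128_pd(k64));
}
#endif

// x^n for small integer n >= 0
static inline double powint(double x, int n) {
  double r = 1.0;
  while (n > 0) {
    if (n & 1) r *= x;
    x *= x;
    n >>= 1;
  }
  return r;
}

// Interaction tables flattened over bead types.
struct PairTables {
  int nt;
  std::vector<double> eps_alpha;  // eps_ij * alpha_ij
  std::vector<double> sigma2;     // sigma_ij^2
  std::vector<double> R2;         // R_ij^2
  std::vector<double> mu;         // mu_ij
  std::vector<int> mu_int;        // mu as int if integral, else -1
  std::vector<int> two_nu;        // 2*nu_ij (assumed integral)
  double kq;                      // 138.935458 / eps_r  [kJ/mol nm e^-2]
  double kappa;                   // 1 / debye_length [1/nm]
  double rcoul2;                  // coulomb cutoff^2
};

static PairTables make_tables(const NumericMatrix& eps_alpha,
                              const NumericMatrix& sigma,
                              const NumericMatrix& mu,
                              const NumericMatrix& nu,
                              const NumericMatrix& Rcut,
                              double kq, double kappa, double rcoul) {
  PairTables t;
  t.nt = eps_alpha.nrow();
  int n2 = t.nt * t.nt;
  t.eps_alpha.resize(n2);
  t.sigma2.resize(n2);
  t.R2.resize(n2);
  t.mu.resize(n2);
  t.mu_int.resize(n2);
  t.two_nu.resize(n2);
  for (int i = 0; i < t.nt; ++i) {
    for (int j = 0; j < t.nt; ++j) {
      int k = i * t.nt + j;
      t.eps_alpha[k] = eps_alpha(i, j);
      t.sigma2[k] = sigma(i, j) * sigma(i, j);
      t.R2[k] = Rcut(i, j) * Rcut(i, j);
      double m = mu(i, j);
      t.mu[k] = m;
      t.mu_int[k] = (m == std::floor(m) && m > 0 && m < 16) ? (int)m : -1;
      t.two_nu[k] = (int)std::lround(2.0 * nu(i, j));
    }
  }
  t.kq = kq;
  t.kappa = kappa;
  t.rcoul2 = rcoul * rcoul;
  return t;
}

// Wang-Frenkel + Debye-Hueckel for one pair at squared distance r2.
// Adds energy to ewf/eel and returns fscal such that F_i += fscal * dvec_ij.
static inline double pair_ef(const PairTables& t, int ti, int tj, double qq,
                             double r2, double& ewf, double& eel) {
  int k = ti * t.nt + tj;
  double fscal = 0.0;
  if (r2 < t.R2[k] && t.eps_alpha[k] != 0.0) {
    double inv2 = 1.0 / r2;
    double u = t.sigma2[k] * inv2;  // (sigma/r)^2
    double w = t.R2[k] * inv2;      // (R/r)^2
    double um, wm;
    if (t.mu_int[k] > 0) {
      um = powint(u, t.mu_int[k]);
      wm = powint(w, t.mu_int[k]);
    } else {
      um = std::pow(u, t.mu[k]);
      wm = std::pow(w, t.mu[k]);
    }
    double A = um - 1.0;
    double B = wm - 1.0;
    int tn = t.two_nu[k];
    double Bn1 = powint(B, tn - 1);
    double Bn = Bn1 * B;
    ewf += t.eps_alpha[k] * A * Bn;
    // dphi/dr = eps*alpha * (-2 mu / r) * (um*Bn + A*2nu*Bn1*wm)
    // fscal = -(dphi/dr)/r
    fscal += t.eps_alpha[k] * (2.0 * t.mu[k] * inv2) *
             (um * Bn + A * tn * Bn1 * wm);
  }
  if (qq != 0.0 && r2 < t.rcoul2) {
    double r = std::sqrt(r2);
    double inv_r = 1.0 / r;
    double e = t.kq * qq * fast_exp(-t.kappa * r) * inv_r;
    eel += e;
    fscal += e * (t.kappa + inv_r) * inv_r;
  }
  return fscal;
}

// ---------------------------------------------------------------------------
// neighbor list (cell list with all-pairs fallback for small boxes)
// ---------------------------------------------------------------------------
struct NList {
  std::vector<int> pi, pj;
};

static void build_pairs(const std::vector<double>& x,
                        const std::vector<double>& y,
                        const std::vector<double>& z,
                        const double box[3], double rlist,
                        NList& nl) {
  int n = (int)x.size();
  nl.pi.clear();
  nl.pj.clear();
  double rl2 = rlist * rlist;
  int nc[3];
  for (int d = 0; d < 3; ++d) nc[d] = (int)std::floor(box[d] / rlist);
  bool cells = nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3;
  if (!cells) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(x[i] - x[j], box[0]);
        double dy = min_image(y[i] - y[j], box[1]);
        double dz = min_image(z[i] - z[j], box[2]);
        if (dx * dx + dy * dy + dz * dz < rl2) {
          nl.pi.push_back(i);
          nl.pj.push_back(j);
        }
      }
    }
    return;
  }
  int ncc = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncc, -1), next(n, -1);
  auto cellof = [&](double xx, double L, int m) {
    double f = xx / L - std::floor(xx / L);  // [0,1)
    int c = (int)(f * m);
    if (c >= m) c = m - 1;
    return c;
  };
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    ci[i] = cellof(x[i], box[0], nc[0]);
    cj[i] = cellof(y[i], box[1], nc[1]);
    ck[i] = cellof(z[i], box[2], nc[2]);
    int c = (ck[i] * nc[1] + cj[i]) * nc[0] + ci[i];
    next[i] = head[c];
    head[c] = i;
  }
  for (int i = 0; i < n; ++i) {
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = (ck[i] + dk + nc[2]) % nc[2];
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = (cj[i] + dj + nc[1]) % nc[1];
        for (int di = -1; di <= 1; ++di) {
          int ii = (ci[i] + di + nc[0]) % nc[0];
          int c = (kk * nc[1] + jj) * nc[0] + ii;
          for (int j = head[c]; j != -1; j = next[j]) {
            if (j <= i) continue;
            double dx = min_image(x[i] - x[j], box[0]);
            double dy = min_image(y[i] - y[j], box[1]);
            double dz = min_image(z[i] - z[j], box[2]);
            if (dx * dx + dy * dy + dz * dz < rl2) {
              nl.pi.push_back(i);
              nl.pj.push_back(j);
            }
          }
        }
      }
    }
  }
}

// per-bead exclusion sets (directly bonded pairs only: the 1-2 rule);
// the common linear-chain case (all bonds between consecutive indices)
// gets an O(1) flag-array check
struct Excl {
  bool consec_only;
  std::vector<char> link;               // bond between i and i+1
  std::vector<std::vector<int>> ex;     // general fallback
};

static Excl build_excl(const IntegerMatrix& bonds, int n) {
  Excl e;
  e.consec_only = true;
  e.link.assign(n, 0);
  e.ex.resize(n);
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    if (i < 0 || j < 0 || i >= n || j >= n)
      stop("bond index out of range");
    if (j == i + 1) e.link[i] = 1;
    else if (i == j + 1) e.link[j] = 1;
    else e.consec_only = false;
    e.ex[i].push_back(j);
    e.ex[j].push_back(i);
  }
  return e;
}

// i < j assumed
static inline bool excluded(const Excl& e, int i, int j) {
  if (e.consec_only) return j == i + 1 && e.link[i];
  for (int k : e.ex[i])
    if (k == j) return true;
  return false;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector box,
                                 double cutoff) {
  int n = pos.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = wrap_coord(pos(i, 0), bx[0]);
    y[i] = wrap_coord(pos(i, 1), bx[1]);
    z[i] = wrap_coord(pos(i, 2), bx[2]);
  }
  NList nl;
  build_pairs(x, y, z, bx, cutoff, nl);
  int m = (int)nl.pi.size();
  IntegerMatrix out(m, 2);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = nl.pi[k] + 1;
    out(k, 1) = nl.pj[k] + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// energy + forces (+ optional species-group decomposition of the nonbonded
// energy, counting each unordered pair once)
// ---------------------------------------------------------------------------
struct EnergyOut {
  double e_bond, e_wf, e_el;
};

static EnergyOut compute_forces(
    const std::vector<double>& x, const std::vector<double>& y,
    const std::vector<double>& z, const double box[3],
    const std::vector<int>& type, const std::vector<double>& charge,
    const IntegerMatrix& bonds, const NumericVector& bond_ref, double bond_k,
    const PairTables& t, const Excl& ex,
    const NList& nl, std::vector<double>& fx, std::vector<double>& fy,
    std::vector<double>& fz, double* gmat, const std::vector<int>* group,
    int ngroup) {
  int n = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  EnergyOut E = {0.0, 0.0, 0.0};
  int np = (int)nl.pi.size();
  // Pairs are processed in blocks with the Debye-Hueckel sqrt/div/exp
  // chains batched into their own tight loops, so the long-latency
  // operations of independent pairs overlap instead of serializing.
  const int BLK = 32;
  double bdx[BLK], bdy[BLK], bdz[BLK], br2[BLK], bqq[BLK], bfs[BLK];
  double bew[BLK], bee[BLK];
  int bi[BLK], bj[BLK];
  int ei[BLK];  // DH-active slots
  for (int base = 0; base < np; base += BLK) {
    int m = np - base < BLK ? np - base : BLK;
    for (int k = 0; k < m; ++k) {
      int i = nl.pi[base + k], j = nl.pj[base + k];
      bi[k] = i;
      bj[k] = j;
      double dx = min_image(x[i] - x[j], box[0]);
      double dy = min_image(y[i] - y[j], box[1]);
      double dz = min_image(z[i] - z[j], box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      bdx[k] = dx;
      bdy[k] = dy;
      bdz[k] = dz;
      bqq[k] = charge[i] * charge[j];
      if (excluded(ex, i, j)) {
        r2 = 1e30;  // sentinel: skip every interaction branch
      } else if (r2 < 1e-12) {
        stop("overlapping beads %d and %d (r < 1e-6 nm)", i + 1, j + 1);
      }
      br2[k] = r2;
      bfs[k] = 0.0;
      bew[k] = 0.0;
      bee[k] = 0.0;
    }
    // short-range Wang-Frenkel (a small fraction of the list)
    for (int k = 0; k < m; ++k) {
      int kk = type[bi[k]] * t.nt + type[bj[k]];
      double r2 = br2[k];
      if (r2 < t.R2[kk] && t.eps_alpha[kk] != 0.0) {
        double inv2 = 1.0 / r2;
        double u = t.sigma2[kk] * inv2;
        double w = t.R2[kk] * inv2;
        double um, wm;
        if (t.mu_int[kk] > 0) {
          um = powint(u, t.mu_int[kk]);
          wm = powint(w, t.mu_int[kk]);
        } else {
          um = std::pow(u, t.mu[kk]);
          wm = std::pow(w, t.mu[kk]);
        }
        double A = um - 1.0;
        double Bv = wm - 1.0;
        int tn = t.two_nu[kk];
        double Bn1 = powint(Bv, tn - 1);
        double Bn = Bn1 * Bv;
        bew[k] = t.eps_alpha[kk] * A * Bn;
        bfs[k] = t.eps_alpha[kk] * (2.0 * t.mu[kk] * inv2) *
                 (um * Bn + A * tn * Bn1 * wm);
      }
    }
    // electrostatics: compact, then batch sqrt / div / exp
    int ne = 0;
    for (int k = 0; k < m; ++k) {
      if (bqq[k] != 0.0 && br2[k] < t.rcoul2) ei[ne++] = k;
    }
    int k0 = 0;
#if defined(__SSE2__) && !defined(CONDEVOL_NO_SIMD)
    {
      const __m128d negk = _mm_set1_pd(-t.kappa);
      const __m128d kap = _mm_set1_pd(t.kappa);
      const __m128d kqv = _mm_set1_pd(t.kq);
      const __m128d one = _mm_set1_pd(1.0);
      for (; k0 + 2 <= ne; k0 += 2) {
        int a = ei[k0], b = ei[k0 + 1];
        __m128d r2v = _mm_set_pd(br2[b], br2[a]);
        __m128d rv = _mm_sqrt_pd(r2v);
        __m128d iv = _mm_div_pd(one, rv);
        __m128d ex = v_fast_exp(_mm_mul_pd(negk, rv));
        __m128d qq = _mm_set_pd(bqq[b], bqq[a]);
        __m128d e = _mm_mul_pd(_mm_mul_pd(_mm_mul_pd(kqv, qq), ex), iv);
        __m128d fs = _mm_mul_pd(_mm_mul_pd(e, _mm_add_pd(kap, iv)), iv);
        double ee2[2], fs2[2];
        _mm_storeu_pd(ee2, e);
        _mm_storeu_pd(fs2, fs);
        bee[a] = ee2[0];
        bee[b] = ee2[1];
        bfs[a] += fs2[0];
        bfs[b] += fs2[1];
      }
    }
#endif
    for (int k = k0; k < ne; ++k) {
      int kk = ei[k];
      double r = std::sqrt(br2[kk]);
      double iv = 1.0 / r;
      double e = t.kq * bqq[kk] * fast_exp(-t.kappa * r) * iv;
      bee[kk] = e;
      bfs[kk] += e * (t.kappa + iv) * iv;
    }
    // accumulate
    for (int k = 0; k < m; ++k) {
      E.e_wf += bew[k];
      E.e_el += bee[k];
      double fs = bfs[k];
      if (fs != 0.0) {
        int i = bi[k], j = bj[k];
        fx[i] += fs * bdx[k];
        fy[i] += fs * bdy[k];
        fz[i] += fs * bdz[k];
        fx[j] -= fs * bdx[k];
        fy[j] -= fs * bdy[k];
        fz[j] -= fs * bdz[k];
      }
      if (gmat && (bew[k] != 0.0 || bee[k] != 0.0)) {
        int gi = (*group)[bi[k]], gj = (*group)[bj[k]];
        int a = gi <= gj ? gi : gj, b = gi <= gj ? gj : gi;
        gmat[a * ngroup + b] += bew[k] + bee[k];
      }
    }
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = min_image(x[i] - x[j], box[0]);
    double dy = min_image(y[i] - y[j], box[1]);
    double dz = min_image(z[i] - z[j], box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - bond_ref[b];
    E.e_bond += 0.5 * bond_k * d * d;
    if (r > 0) {
      double fs = -bond_k * d / r;
      fx[i] += fs * dx;
      fy[i] += fs * dy;
      fz[i] += fs * dz;
      fx[j] -= fs * dx;
      fy[j] -= fs * dy;
      fz[j] -= fs * dz;
    }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector box, IntegerVector type,
                       NumericVector charge, IntegerMatrix bonds,
                       NumericVector bond_ref, double bond_k,
                       NumericMatrix eps_alpha, NumericMatrix sigma,
                       NumericMatrix mu, NumericMatrix nu, NumericMatrix Rcut,
                       double kq, double kappa, double rcoul, double rlist,
                       IntegerVector group, int ngroup) {
  int n = pos.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> x(n), y(n), z(n);
  std::vector<int> ty(n);
  std::vector<double> q(n);
  for (int i = 0; i < n; ++i) {
    x[i] = wrap_coord(pos(i, 0), bx[0]);
    y[i] = wrap_coord(pos(i, 1), bx[1]);
    z[i] = wrap_coord(pos(i, 2), bx[2]);
    ty[i] = type[i];
    q[i] = charge[i];
  }
  PairTables t = make_tables(eps_alpha, sigma, mu, nu, Rcut, kq, kappa, rcoul);
  auto ex = build_excl(bonds, n);
  NList nl;
  build_pairs(x, y, z, bx, rlist, nl);
  std::vector<double> fxv(n), fyv(n), fzv(n);
  std::vector<double> gm;
  std::vector<int> grp(n);
  double* gptr = nullptr;
  bool do_groups = ngroup > 0;
  if (do_groups) {
    gm.assign((size_t)ngroup * ngroup, 0.0);
    for (int i = 0; i < n; ++i) grp[i] = group[i];
    gptr = gm.data();
  }
  EnergyOut E = compute_forces(x, y, z, bx, ty, q, bonds, bond_ref, bond_k, t,
                               ex, nl, fxv, fyv, fzv, gptr,
                               do_groups ? &grp : nullptr, ngroup);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = fxv[i];
    F(i, 1) = fyv[i];
    F(i, 2) = fzv[i];
  }
  List out = List::create(
      _["e_bond"] = E.e_bond, _["e_wf"] = E.e_wf, _["e_elec"] = E.e_el,
      _["total"] = E.e_bond + E.e_wf + E.e_el, _["forces"] = F);
  if (do_groups) {
    NumericMatrix G(ngroup, ngroup);
    for (int a = 0; a < ngroup; ++a)
      for (int b = 0; b < ngroup; ++b) {
        // stored upper-triangular; mirror for convenience
        double v = a <= b ? gm[a * ngroup + b] : gm[b * ngroup + a];
        G(a, b) = v;
      }
    out["group_energy"] = G;
  }
  return out;
}

// ---------------------------------------------------------------------------
// BAOAB Langevin / velocity-Verlet dynamics
// gamma = 1/friction_time; gamma = 0 gives NVE velocity Verlet
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, NumericVector box,
                IntegerVector type, NumericVector charge, NumericVector mass,
                IntegerMatrix bonds, NumericVector bond_ref, double bond_k,
                NumericMatrix eps_alpha, NumericMatrix sigma, NumericMatrix mu,
                NumericMatrix nu, NumericMatrix Rcut, double kq, double kappa,
                double rcoul, double rlist_cut, double skin, double dt,
                int nsteps, double gamma, double kT, double seed,
                int save_every, bool remove_com, bool save_vel) {
  int n = pos.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), m(n), q(n);
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) {
    x[i] = wrap_coord(pos(i, 0), bx[0]);
    y[i] = wrap_coord(pos(i, 1), bx[1]);
    z[i] = wrap_coord(pos(i, 2), bx[2]);
    vx[i] = vel(i, 0);
    vy[i] = vel(i, 1);
    vz[i] = vel(i, 2);
    m[i] = mass[i];
    q[i] = charge[i];
    ty[i] = type[i];
  }
  PairTables t = make_tables(eps_alpha, sigma, mu, nu, Rcut, kq, kappa, rcoul);
  auto ex = build_excl(bonds, n);
  double rlist = rlist_cut + skin;
  double half_skin2 = 0.25 * skin * skin;

  NList nl;
  std::vector<double> x0(n), y0(n), z0(n);  // positions at last list build
  auto rebuild = [&]() {
    for (int i = 0; i < n; ++i) {
      x[i] = wrap_coord(x[i], bx[0]);
      y[i] = wrap_coord(y[i], bx[1]);
      z[i] = wrap_coord(z[i], bx[2]);
    }
    build_pairs(x, y, z, bx, rlist, nl);
    x0 = x;
    y0 = y;
    z0 = z;
  };
  rebuild();
  int nrebuild = 1;

  std::vector<double> fxv(n), fyv(n), fzv(n);
  EnergyOut E = compute_forces(x, y, z, bx, ty, q, bonds, bond_ref, bond_k, t,
                               ex, nl, fxv, fyv, fzv, nullptr, nullptr, 0);

  Rng rng((uint64_t)seed * 2654435761ULL + 12345ULL);
  double c1 = gamma > 0 ? std::exp(-gamma * dt) : 1.0;
  double c2 = gamma > 0 ? std::sqrt(1.0 - c1 * c1) : 0.0;
  std::vector<double> sd(n);
  for (int i = 0; i < n; ++i) sd[i] = std::sqrt(kT / m[i]);
  double hdt = 0.5 * dt;

  int nsave = save_every > 0 ? nsteps / save_every : 0;
  List frames(nsave), vframes(save_vel ? nsave : 0);
  NumericVector times(nsave), pe(nsave);
  NumericVector ke_trace(nsteps);
  double msum = 0.0;
  for (int i = 0; i < n; ++i) msum += m[i];
  int isave = 0;

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) {  // B
      double im = hdt / m[i];
      vx[i] += fxv[i] * im;
      vy[i] += fyv[i] * im;
      vz[i] += fzv[i] * im;
    }
    for (int i = 0; i < n; ++i) {  // A
      x[i] += vx[i] * hdt;
      y[i] += vy[i] * hdt;
      z[i] += vz[i] * hdt;
    }
    if (gamma > 0) {  // O
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * sd[i] * rng.norm();
        vy[i] = c1 * vy[i] + c2 * sd[i] * rng.norm();
        vz[i] = c1 * vz[i] + c2 * sd[i] * rng.norm();
      }
    }
    for (int i = 0; i < n; ++i) {  // A
      x[i] += vx[i] * hdt;
      y[i] += vy[i] * hdt;
      z[i] += vz[i] * hdt;
    }
    // half-skin displacement rebuild trigger
    double maxd2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (maxd2 > half_skin2) {
      rebuild();
      ++nrebuild;
    }
    E = compute_forces(x, y, z, bx, ty, q, bonds, bond_ref, bond_k, t, ex, nl,
                       fxv, fyv, fzv, nullptr, nullptr, 0);
    for (int i = 0; i < n; ++i) {  // B
      double im = hdt / m[i];
      vx[i] += fxv[i] * im;
      vy[i] += fyv[i] * im;
      vz[i] += fzv[i] * im;
    }
    if (remove_com) {
      double px = 0, py = 0, pz = 0;
      for (int i = 0; i < n; ++i) {
        px += m[i] * vx[i];
        py += m[i] * vy[i];
        pz += m[i] * vz[i];
      }
      px /= msum;
      py /= msum;
      pz /= msum;
      for (int i = 0; i < n; ++i) {
        vx[i] -= px;
        vy[i] -= py;
        vz[i] -= pz;
      }
    }
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * m[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    ke_trace[step - 1] = ke;

    if (save_every > 0 && step % save_every == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) {  // wrap saved frames into the box
        fr(i, 0) = x[i] - bx[0] * std::floor(x[i] / bx[0]);
        fr(i, 1) = y[i] - bx[1] * std::floor(y[i] / bx[1]);
        fr(i, 2) = z[i] - bx[2] * std::floor(z[i] / bx[2]);
      }
      frames[isave] = fr;
      if (save_vel) {
        NumericMatrix vf(n, 3);
        for (int i = 0; i < n; ++i) {
          vf(i, 0) = vx[i];
          vf(i, 1) = vy[i];
          vf(i, 2) = vz[i];
        }
        vframes[isave] = vf;
      }
      times[isave] = step * dt;
      pe[isave] = E.e_bond + E.e_wf + E.e_el;
      ++isave;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix P(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = x[i];
    P(i, 1) = y[i];
    P(i, 2) = z[i];
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  return List::create(_["pos"] = P, _["vel"] = V, _["frames"] = frames,
                      _["vel_frames"] = vframes, _["times"] = times,
                      _["pe"] = pe, _["ke_trace"] = ke_trace,
                      _["n_rebuilds"] = nrebuild);
}

// ---------------------------------------------------------------------------
// steepest-descent relaxation with displacement cap (overlap removal after
// chain growth); not an energy minimizer to tolerance, just enough to start
// dynamics safely
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, NumericVector box, IntegerVector type,
                  NumericVector charge, IntegerMatrix bonds,
                  NumericVector bond_ref, double bond_k,
                  NumericMatrix eps_alpha, NumericMatrix sigma,
                  NumericMatrix mu, NumericMatrix nu, NumericMatrix Rcut,
                  double kq, double kappa, double rcoul, double rlist_cut,
                  int max_steps, double max_disp, double fmax_tol) {
  int n = pos.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> x(n), y(n), z(n), q(n);
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) {
    x[i] = wrap_coord(pos(i, 0), bx[0]);
    y[i] = wrap_coord(pos(i, 1), bx[1]);
    z[i] = wrap_coord(pos(i, 2), bx[2]);
    q[i] = charge[i];
    ty[i] = type[i];
  }
  PairTables t = make_tables(eps_alpha, sigma, mu, nu, Rcut, kq, kappa, rcoul);
  auto ex = build_excl(bonds, n);
  NList nl;
  std::vector<double> fxv(n), fyv(n), fzv(n);
  double last_e = 0.0;
  int it;
  for (it = 0; it < max_steps; ++it) {
    build_pairs(x, y, z, bx, rlist_cut, nl);
    EnergyOut E = compute_forces(x, y, z, bx, ty, q, bonds, bond_ref, bond_k, t,
                                 ex, nl, fxv, fyv, fzv, nullptr, nullptr, 0);
    last_e = E.e_bond + E.e_wf + E.e_el;
    double fmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double f2 = fxv[i] * fxv[i] + fyv[i] * fyv[i] + fzv[i] * fzv[i];
      if (f2 > fmax) fmax = f2;
    }
    fmax = std::sqrt(fmax);
    if (fmax < fmax_tol) break;
    double scale = max_disp / fmax;  // cap the largest per-bead move
    for (int i = 0; i < n; ++i) {
      x[i] += scale * fxv[i];
      y[i] += scale * fyv[i];
      z[i] += scale * fzv[i];
    }
  }
  NumericMatrix P(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = x[i] - bx[0] * std::floor(x[i] / bx[0]);
    P(i, 1) = y[i] - bx[1] * std::floor(y[i] / bx[1]);
    P(i, 2) = z[i] - bx[2] * std::floor(z[i] / bx[2]);
  }
  return List::create(_["pos"] = P, _["energy"] = last_e, _["iters"] = it);
}

// ---------------------------------------------------------------------------
// self-avoiding random-walk chain growth in a target z-slab
// returns positions for all chains or throws after bounded retries
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_grow_chains(IntegerVector chain_len, NumericVector bond_len,
                              NumericVector box, double zlo, double zhi,
                              double min_dist, double seed, int max_retry) {
  int nchain = chain_len.size();
  int ntot = 0;
  for (int c = 0; c < nchain; ++c) ntot += chain_len[c];
  double bx[3] = {box[0], box[1], box[2]};
  Rng rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  NumericMatrix out(ntot, 3);
  // occupancy grid with cell size >= min_dist
  double cs = std::max(min_dist, 0.25);
  int nc[3];
  for (int d = 0; d < 3; ++d) nc[d] = std::max(1, (int)std::floor(bx[d] / cs));
  std::vector<std::vector<int>> cells((size_t)nc[0] * nc[1] * nc[2]);
  std::vector<double> px, py, pz;
  px.reserve(ntot);
  auto cidx = [&](double xx, double L, int m) {
    double f = xx / L - std::floor(xx / L);
    int c = (int)(f * m);
    return c >= m ? m - 1 : c;
  };
  double md2 = min_dist * min_dist;
  auto clash = [&](double xx, double yy, double zz) {
    int ci = cidx(xx, bx[0], nc[0]), cj = cidx(yy, bx[1], nc[1]),
        ck = cidx(zz, bx[2], nc[2]);
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = (ck + dk + nc[2]) % nc[2];
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = (cj + dj + nc[1]) % nc[1];
        for (int di = -1; di <= 1; ++di) {
          int ii = (ci + di + nc[0]) % nc[0];
          for (int p : cells[((size_t)kk * nc[1] + jj) * nc[0] + ii]) {
            double dx = min_image(xx - px[p], bx[0]);
            double dy = min_image(yy - py[p], bx[1]);
            double dz = min_image(zz - pz[p], bx[2]);
            if (dx * dx + dy * dy + dz * dz < md2) return true;
          }
        }
      }
    }
    return false;
  };
  auto commit = [&](double xx, double yy, double zz) {
    xx -= bx[0] * std::floor(xx / bx[0]);
    yy -= bx[1] * std::floor(yy / bx[1]);
    zz -= bx[2] * std::floor(zz / bx[2]);
    px.push_back(xx);
    py.push_back(yy);
    pz.push_back(zz);
    int ci = cidx(xx, bx[0], nc[0]), cj = cidx(yy, bx[1], nc[1]),
        ck = cidx(zz, bx[2], nc[2]);
    cells[((size_t)ck * nc[1] + cj) * nc[0] + ci].push_back((int)px.size() - 1);
  };
  int at = 0;
  for (int c = 0; c < nchain; ++c) {
    int L = chain_len[c];
    double bl = bond_len[c];
    bool placed = false;
    for (int attempt = 0; attempt < max_retry && !placed; ++attempt) {
      std::vector<double> cx(L), cy(L), cz(L);
      cx[0] = rng.unif() * bx[0];
      cy[0] = rng.unif() * bx[1];
      cz[0] = zlo + rng.unif() * (zhi - zlo);
      if (clash(cx[0], cy[0], cz[0])) continue;
      bool ok = true;
      for (int b = 1; b < L && ok; ++b) {
        bool found = false;
        for (int tr = 0; tr < 50; ++tr) {
          // uniform direction on the sphere
          double u = 2.0 * rng.unif() - 1.0;
          double ph = 6.283185307179586 * rng.unif();
          double s = std::sqrt(1.0 - u * u);
          double xx = cx[b - 1] + bl * s * std::cos(ph);
          double yy = cy[b - 1] + bl * s * std::sin(ph);
          double zz = cz[b - 1] + bl * u;
          if (zz < zlo || zz > zhi) continue;  // keep the slab compact
          if (clash(xx, yy, zz)) continue;
          // also avoid beads of this partial chain (not yet committed)
          bool self = false;
          for (int p = 0; p < b - 1; ++p) {
            double dx = min_image(xx - cx[p], bx[0]);
            double dy = min_image(yy - cy[p], bx[1]);
            double dz = min_image(zz - cz[p], bx[2]);
            if (dx * dx + dy * dy + dz * dz < md2) {
              self = true;
              break;
            }
          }
          if (self) continue;
          cx[b] = xx;
          cy[b] = yy;
          cz[b] = zz;
          found = true;
          break;
        }
        if (!found) ok = false;
      }
      if (ok) {
        for (int b = 0; b < L; ++b) commit(cx[b], cy[b], cz[b]);
        placed = true;
      }
    }
    if (!placed)
      stop("failed to place chain %d after %d attempts; use a larger box",
           c + 1, max_retry);
    for (int b = 0; b < L; ++b) {
      out(at + b, 0) = px[at + b];
      out(at + b, 1) = py[at + b];
      out(at + b, 2) = pz[at + b];
    }
    at += L;
  }
  return out;
}
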