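// Forward Wright-Fisher engine with two sexes, autosomal or X-linked
// inheritance, purifying selection in exons, and exact tracking of
// archaic-ancestry intervals per haplotype.
//
// All randomness goes through R's RNG so a single set.seed() on the R side
// makes runs bit-reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Hap {
  // archaic ancestry tracts: half-open [ts, te), sorted, disjoint, merged
  std::vector<double> ts, te;
  // mutation ids, sorted by (position, id)
  std::vector<int> mut;
};

struct Pop {
  int N = 0;
  std::vector<int> sex;  // 0 = female, 1 = male
  std::vector<Hap> h1, h2;  // h2 unused for chrX males
  int generation = 0;
};

struct Engine {
  double L = 0;
  bool chrX = false;

  // exons (for mutation placement)
  std::vector<double> ex_s, ex_e, ex_cum;  // ex_cum[i] = total exonic bp through exon i
  double exon_total = 0;

  // recombination pieces tiling [0, L)
  std::vector<double> rc_s, rc_e, rc_rate, rc_cum;  // rc_cum[i] = Morgans through piece i
  double map_total = 0;  // expected crossovers per meiosis

  // DFE / fitness
  double shape_k = 0.186, scale_theta = 0.07068995, h = 0.5;
  double mu_exonic = 0;  // per exonic bp per generation (already scaled)
  double s_scale = 1;    // multiplies raw gamma draws (scaling factor Q)
  double eps = 1e-9;
  long clamp_count = 0;  // genotypes whose fitness hit the epsilon floor

  // global mutation store (shared between populations so ids never collide)
  std::vector<double> mpos, ms;  // ms holds the *scaled* selection coefficient

  Pop pop[2];      // 0 = recipient, 1 = source
  Pop scratch[2];  // reusable next-generation buffers (keeps vector capacity)
  std::vector<double> bp_scratch;  // crossover-position buffer
};

static inline bool mut_less(const Engine& E, int a, int b) {
  return E.mpos[a] < E.mpos[b] || (E.mpos[a] == E.mpos[b] && a < b);
}

// ---- fitness -------------------------------------------------------------

static double fitness_diploid(const Engine& E, const Hap& A, const Hap& B) {
  double w = 1.0;
  bool clamped = false;
  size_t i = 0, j = 0;
  const size_t na = A.mut.size(), nb = B.mut.size();
  while (i < na || j < nb) {
    double f;
    if (j >= nb || (i < na && mut_less(E, A.mut[i], B.mut[j]))) {
      f = 1.0 - E.h * E.ms[A.mut[i]];
      ++i;
    } else if (i >= na || (j < nb && mut_less(E, B.mut[j], A.mut[i]))) {
      f = 1.0 - E.h * E.ms[B.mut[j]];
      ++j;
    } else {  // same id on both haplotypes: homozygous
      f = 1.0 - E.ms[A.mut[i]];
      ++i;
      ++j;
    }
    if (f <= 0) { clamped = true; break; }
    w *= f;
  }
  if (clamped || w < E.eps) {
    if (clamped) ++const_cast<Engine&>(E).clamp_count;
    return E.eps;
  }
  return w;
}

static double fitness_hemizygous(const Engine& E, const Hap& A) {
  double w = 1.0;
  bool clamped = false;
  for (size_t i = 0; i < A.mut.size(); ++i) {
    double f = 1.0 - E.ms[A.mut[i]];  // full exposure, dominance irrelevant
    if (f <= 0) { clamped = true; break; }
    w *= f;
  }
  if (clamped || w < E.eps) {
    if (clamped) ++const_cast<Engine&>(E).clamp_count;
    return E.eps;
  }
  return w;
}

static double ind_fitness(const Engine& E, const Pop& P, int i) {
  if (E.chrX && P.sex[i] == 1) return fitness_hemizygous(E, P.h1[i]);
  return fitness_diploid(E, P.h1[i], P.h2[i]);
}

// ---- gamete formation ----------------------------------------------------

// map a uniform draw on the genetic map to a bp position
static double genetic_to_bp(const Engine& E, double g) {
  size_t lo = std::upper_bound(E.rc_cum.begin(), E.rc_cum.end(), g) - E.rc_cum.begin();
  if (lo >= E.rc_cum.size()) lo = E.rc_cum.size() - 1;
  double before = lo == 0 ? 0.0 : E.rc_cum[lo - 1];
  double rate = E.rc_rate[lo];
  if (rate <= 0) return E.rc_s[lo];
  return E.rc_s[lo] + (g - before) / rate;
}

static void append_tract(Hap& out, double a, double b) {
  if (b <= a) return;
  if (!out.ts.empty() && out.te.back() == a) {
    out.te.back() = b;
  } else {
    out.ts.push_back(a);
    out.te.push_back(b);
  }
}

static void copy_segment(const Engine& E, const Hap& src, double a, double b, Hap& out) {
  // tracts overlapping [a, b)
  for (size_t t = 0; t < src.ts.size(); ++t) {
    if (src.te[t] <= a) continue;
    if (src.ts[t] >= b) break;
    append_tract(out, std::max(src.ts[t], a), std::min(src.te[t], b));
  }
  // mutations with position in [a, b)
  auto lo = std::lower_bound(src.mut.begin(), src.mut.end(), a,
                             [&E](int id, double v) { return E.mpos[id] < v; });
  auto hi = std::lower_bound(src.mut.begin(), src.mut.end(), b,
                             [&E](int id, double v) { return E.mpos[id] < v; });
  out.mut.insert(out.mut.end(), lo, hi);
}

// recombinant gamete from a diploid parent
static void make_gamete(Engine& E, const Hap& A, const Hap& B, Hap& out) {
  out.ts.clear(); out.te.clear(); out.mut.clear();
  int k = E.map_total > 0 ? (int)R::rpois(E.map_total) : 0;
  std::vector<double>& bp = E.bp_scratch;
  bp.clear();
  for (int i = 0; i < k; ++i)
    bp.push_back(genetic_to_bp(E, unif_rand() * E.map_total));
  std::sort(bp.begin(), bp.end());
  int cur = unif_rand() < 0.5 ? 0 : 1;
  double a = 0.0;
  for (size_t i = 0; i <= bp.size(); ++i) {
    double b = i < bp.size() ? bp[i] : E.L;
    if (b > a) copy_segment(E, cur == 0 ? A : B, a, b, out);
    cur = 1 - cur;
    a = b;
  }
}

// add new deleterious mutations (exonic) to a gamete
static void mutate_gamete(Engine& E, Hap& g) {
  if (E.mu_exonic <= 0 || E.exon_total <= 0) return;
  int n = (int)R::rpois(E.mu_exonic * E.exon_total);
  if (n <= 0) return;
  for (int i = 0; i < n; ++i) {
    double u = unif_rand() * E.exon_total;
    size_t lo = std::upper_bound(E.ex_cum.begin(), E.ex_cum.end(), u) - E.ex_cum.begin();
    if (lo >= E.ex_cum.size()) lo = E.ex_cum.size() - 1;
    double before = lo == 0 ? 0.0 : E.ex_cum[lo - 1];
    double pos = E.ex_s[lo] + (u - before);
    double s = R::rgamma(E.shape_k, E.scale_theta) * E.s_scale;
    if (s <= 0) s = 1e-300;
    E.mpos.push_back(pos);
    E.ms.push_back(s);
    g.mut.push_back((int)(E.mpos.size() - 1));
  }
  std::sort(g.mut.begin(), g.mut.end(),
            [&E](int x, int y) { return mut_less(E, x, y); });
}

// weighted parent choice by cumulative-weight inversion on a fixed-order list
static int pick_weighted(const std::vector<int>& idx, const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  size_t lo = std::upper_bound(cum.begin(), cum.end(), u) - cum.begin();
  if (lo >= idx.size()) lo = idx.size() - 1;
  return idx[lo];
}

// fitness-ordered parent pools of a population
struct ParentPools {
  std::vector<int> fem, mal;
  std::vector<double> fcum, mcum;
};

static ParentPools build_pools(const Engine& E, const Pop& P) {
  ParentPools pp;
  double facc = 0, macc = 0;
  for (int i = 0; i < P.N; ++i) {
    double wi = ind_fitness(E, P, i);
    if (P.sex[i] == 0) {
      pp.fem.push_back(i); facc += wi; pp.fcum.push_back(facc);
    } else {
      pp.mal.push_back(i); macc += wi; pp.mcum.push_back(macc);
    }
  }
  return pp;
}

// one offspring of given sex from parents in P, written into h1/h2
static void make_offspring(Engine& E, const Pop& P, const ParentPools& pp,
                           int sex, Hap& h1, Hap& h2) {
  int mo = pick_weighted(pp.fem, pp.fcum);
  int fa = pick_weighted(pp.mal, pp.mcum);
  if (!E.chrX) {
    make_gamete(E, P.h1[mo], P.h2[mo], h1);
    mutate_gamete(E, h1);
    make_gamete(E, P.h1[fa], P.h2[fa], h2);
    mutate_gamete(E, h2);
  } else {
    // maternal X always recombines (female meiosis)
    make_gamete(E, P.h1[mo], P.h2[mo], h1);
    mutate_gamete(E, h1);
    h2.ts.clear(); h2.te.clear(); h2.mut.clear();
    if (sex == 0) {
      // daughter receives the father's single X intact (no male recombination)
      h2 = P.h1[fa];
      mutate_gamete(E, h2);
    }
    // son: single maternal X; h2 stays empty
  }
}

// ---- one Wright-Fisher generation -----------------------------------------

static void wf_step(Engine& E, int w, double female_fraction, bool bernoulli_sex) {
  Pop& P = E.pop[w];
  ParentPools pp = build_pools(E, P);
  if (pp.fem.empty() || pp.mal.empty())
    stop("reproduction error: population has no %s at generation %d",
         pp.fem.empty() ? "females" : "males", P.generation);

  Pop& Q = E.scratch[w];
  Q.N = P.N;
  Q.generation = P.generation + 1;
  Q.sex.resize(Q.N);
  Q.h1.resize(Q.N);
  Q.h2.resize(Q.N);

  int nf = (int)std::lround(female_fraction * P.N);
  for (int i = 0; i < Q.N; ++i) {
    if (bernoulli_sex)
      Q.sex[i] = unif_rand() < female_fraction ? 0 : 1;
    else
      Q.sex[i] = i < nf ? 0 : 1;
    make_offspring(E, P, pp, Q.sex[i], Q.h1[i], Q.h2[i]);
  }
  std::swap(P, Q);
}

// ---- helpers to build R return values -------------------------------------

static NumericMatrix tracts_matrix(const Hap& H) {
  NumericMatrix m(H.ts.size(), 2);
  for (size_t i = 0; i < H.ts.size(); ++i) {
    m(i, 0) = H.ts[i];
    m(i, 1) = H.te[i];
  }
  colnames(m) = CharacterVector::create("start", "end");
  return m;
}

static List hap_list(const Engine& E, const Hap& H) {
  NumericVector pos(H.mut.size()), s(H.mut.size());
  IntegerVector id(H.mut.size());
  for (size_t i = 0; i < H.mut.size(); ++i) {
    pos[i] = E.mpos[H.mut[i]];
    s[i] = E.ms[H.mut[i]];
    id[i] = H.mut[i];
  }
  return List::create(_["tracts"] = tracts_matrix(H), _["mut_pos"] = pos,
                      _["mut_s"] = s, _["mut_id"] = id);
}

// ---- exported interface ----------------------------------------------------

// [[Rcpp::export(name = ".engine_new")]]
SEXP engine_new(double L, bool chrX, NumericVector ex_s, NumericVector ex_e,
                NumericVector rc_s, NumericVector rc_e, NumericVector rc_rate,
                double shape_k, double scale_theta, double h, double mu_exonic,
                double s_scale, double eps) {
  Engine* E = new Engine();
  E->L = L;
  E->chrX = chrX;
  double cum = 0;
  for (int i = 0; i < ex_s.size(); ++i) {
    E->ex_s.push_back(ex_s[i]);
    E->ex_e.push_back(ex_e[i]);
    cum += ex_e[i] - ex_s[i];
    E->ex_cum.push_back(cum);
  }
  E->exon_total = cum;
  cum = 0;
  for (int i = 0; i < rc_s.size(); ++i) {
    E->rc_s.push_back(rc_s[i]);
    E->rc_e.push_back(rc_e[i]);
    E->rc_rate.push_back(rc_rate[i]);
    cum += rc_rate[i] * (rc_e[i] - rc_s[i]);
    E->rc_cum.push_back(cum);
  }
  E->map_total = cum;
  E->shape_k = shape_k;
  E->scale_theta = scale_theta;
  E->h = h;
  E->mu_exonic = mu_exonic;
  E->s_scale = s_scale;
  E->eps = eps;
  XPtr<Engine> p(E, true);
  return p;
}

// [[Rcpp::export(name = ".engine_init_pop")]]
void engine_init_pop(SEXP eng, int which, IntegerVector sexes) {
  XPtr<Engine> E(eng);
  Pop& P = E->pop[which];
  P.N = sexes.size();
  P.generation = 0;
  P.sex.assign(sexes.begin(), sexes.end());
  P.h1.assign(P.N, Hap());
  P.h2.assign(P.N, Hap());
}

// [[Rcpp::export(name = ".engine_set_hap")]]
void engine_set_hap(SEXP eng, int which, int ind, int hap, NumericMatrix tracts,
                    NumericVector mut_pos, NumericVector mut_s) {
  XPtr<Engine> E(eng);
  Pop& P = E->pop[which];
  Hap& H = hap == 1 ? P.h1[ind] : P.h2[ind];
  H.ts.clear(); H.te.clear(); H.mut.clear();
  for (int i = 0; i < tracts.nrow(); ++i) {
    H.ts.push_back(tracts(i, 0));
    H.te.push_back(tracts(i, 1));
  }
  for (int i = 0; i < mut_pos.size(); ++i) {
    E->mpos.push_back(mut_pos[i]);
    E->ms.push_back(mut_s[i]);
    H.mut.push_back((int)(E->mpos.size() - 1));
  }
  Engine& ER = *E;
  std::sort(H.mut.begin(), H.mut.end(),
            [&ER](int x, int y) { return mut_less(ER, x, y); });
}

// [[Rcpp::export(name = ".engine_get_pop")]]
List engine_get_pop(SEXP eng, int which) {
  XPtr<Engine> E(eng);
  Pop& P = E->pop[which];
  List inds(P.N);
  for (int i = 0; i < P.N; ++i) {
    bool hemi = E->chrX && P.sex[i] == 1;
    inds[i] = List::create(
        _["sex"] = P.sex[i] == 0 ? "female" : "male",
        _["h1"] = hap_list(*E, P.h1[i]),
        _["h2"] = hemi ? R_NilValue : (SEXP)hap_list(*E, P.h2[i]));
  }
  return List::create(_["generation"] = P.generation, _["n"] = P.N,
                      _["individuals"] = inds);
}

// [[Rcpp::export(name = ".engine_fitness")]]
NumericVector engine_fitness(SEXP eng, int which) {
  XPtr<Engine> E(eng);
  Pop& P = E->pop[which];
  NumericVector w(P.N);
  for (int i = 0; i < P.N; ++i) w[i] = ind_fitness(*E, P, i);
  return w;
}

// [[Rcpp::export(name = ".engine_step")]]
void engine_step(SEXP eng, int which, double female_fraction, bool bernoulli_sex) {
  XPtr<Engine> E(eng);
  wf_step(*E, which, female_fraction, bernoulli_sex);
}

// [[Rcpp::export(name = ".engine_run")]]
void engine_run(SEXP eng, int which, int generations, double female_fraction,
                bool bernoulli_sex) {
  XPtr<Engine> E(eng);
  for (int g = 0; g < generations; ++g) {
    wf_step(*E, which, female_fraction, bernoulli_sex);
    if (g % 200 == 199) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export(name = ".engine_mark_archaic")]]
void engine_mark_archaic(SEXP eng, int which) {
  XPtr<Engine> E(eng);
  Pop& P = E->pop[which];
  for (int i = 0; i < P.N; ++i) {
    P.h1[i].ts.assign(1, 0.0);
    P.h1[i].te.assign(1, E->L);
    if (!(E->chrX && P.sex[i] == 1)) {
      P.h2[i].ts.assign(1, 0.0);
      P.h2[i].te.assign(1, E->L);
    }
  }
}

// Introgression pulse: m recipient individuals are replaced by migrant
// offspring of source parents (parents drawn with replacement, weighted by
// fitness, as in Wright-Fisher migration). All source haplotypes are fully
// archaic-labeled at pulse time, so every migrant haplotype is too.
// [[Rcpp::export(name = ".engine_pulse")]]
List engine_pulse(SEXP eng, double pulse_fraction, double p_female, bool exact) {
  XPtr<Engine> E(eng);
  Pop& R_ = E->pop[0];
  Pop& S = E->pop[1];

  ParentPools pp = build_pools(*E, S);
  if (pp.fem.empty() || pp.mal.empty())
    stop("pulse error: source population lacks %s",
         pp.fem.empty() ? "females" : "males");

  std::vector<int> replaced;   // recipient indices
  std::vector<int> mig_sex;
  int n_female = 0;

  if (exact) {
    int m = (int)std::lround(pulse_fraction * R_.N);
    if (m <= 0) stop("configuration error: exact pulse size rounds to zero");
    int mf = (int)std::lround(p_female * m);
    std::vector<int> all(R_.N);
    for (int i = 0; i < R_.N; ++i) all[i] = i;
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (R_.N - i));
      std::swap(all[i], all[j]);
      replaced.push_back(all[i]);
      mig_sex.push_back(i < mf ? 0 : 1);
    }
    n_female = mf;
  } else {
    for (int i = 0; i < R_.N; ++i) {
      if (unif_rand() < pulse_fraction) {
        int sx = unif_rand() < p_female ? 0 : 1;
        replaced.push_back(i);
        mig_sex.push_back(sx);
        if (sx == 0) ++n_female;
      }
    }
  }

  for (size_t k = 0; k < replaced.size(); ++k) {
    int r = replaced[k];
    R_.sex[r] = mig_sex[k];
    make_offspring(*E, S, pp, mig_sex[k], R_.h1[r], R_.h2[r]);
  }

  int m = (int)replaced.size();
  int archaic_haps = E->chrX ? (2 * n_female + (m - n_female)) : 2 * m;
  return List::create(_["n_migrants"] = m, _["n_female"] = n_female,
                      _["archaic_haplotypes"] = archaic_haps,
                      _["replaced"] = wrap(replaced));
}

// [[Rcpp::export(name = ".engine_sample_haps")]]
List engine_sample_haps(SEXP eng, int which, int k) {
  XPtr<Engine> E(eng);
  Pop& P = E->pop[which];
  std::vector<std::pair<int, int> > slots;  // (individual, hap 1|2)
  for (int i = 0; i < P.N; ++i) {
    slots.push_back(std::make_pair(i, 1));
    if (!(E->chrX && P.sex[i] == 1)) slots.push_back(std::make_pair(i, 2));
  }
  int n = (int)slots.size();
  if (k > n) stop("sampling error: requested %d haplotypes, only %d available", k, n);
  List out(k);
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    std::swap(slots[i], slots[j]);
    const Hap& H = slots[i].second == 1 ? P.h1[slots[i].first] : P.h2[slots[i].first];
    out[i] = tracts_matrix(H);
  }
  return out;
}

// per-individual count of carried mutations with scaled s above a threshold
// [[Rcpp::export(name = ".engine_load_counts")]]
IntegerVector engine_load_counts(SEXP eng, int which, double s_min_scaled) {
  XPtr<Engine> E(eng);
  Pop& P = E->pop[which];
  IntegerVector out(P.N);
  for (int i = 0; i < P.N; ++i) {
    int c = 0;
    for (size_t j = 0; j < P.h1[i].mut.size(); ++j)
      if (E->ms[P.h1[i].mut[j]] > s_min_scaled) ++c;
    if (!(E->chrX && P.sex[i] == 1))
      for (size_t j = 0; j < P.h2[i].mut.size(); ++j)
        if (E->ms[P.h2[i].mut[j]] > s_min_scaled) ++c;
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export(name = ".engine_info")]]
List engine_info(SEXP eng) {
  XPtr<Engine> E(eng);
  return List::create(
      _["L"] = E->L, _["chrX"] = E->chrX, _["exon_total"] = E->exon_total,
      _["map_total"] = E->map_total, _["n_mutations_store"] = (double)E->mpos.size(),
      _["clamp_count"] = (double)E->clamp_count,
      _["gen_recipient"] = E->pop[0].generation,
      _["gen_source"] = E->pop[1].generation,
      _["n_recipient"] = E->pop[0].N, _["n_source"] = E->pop[1].N);
}
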