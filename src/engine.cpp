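// Forward-time Wright-Fisher engine with heterozygosity-suppressed
// recombination.  Haplotypes are sparse sorted vectors of derived-allele
// positions; per-meiosis recombination profiles are piecewise constant
// between window boundaries of the heterozygous sites, so a meiosis costs
// O(k) in the number of heterozygous sites rather than O(L).
// All randomness flows through R's RNG (RNGScope via Rcpp attributes).

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> ivec;
typedef std::pair<int, int> iint;

static long long g_rng_draws = 0;

static inline double unif01() { ++g_rng_draws; return unif_rand(); }

static inline int unif_idx(int n) {
  int k;
  do { k = (int)(unif01() * n); } while (k >= n);
  return k;
}

// symmetric difference of two sorted vectors (heterozygous positions)
static void sym_diff(const ivec &a, const ivec &b, ivec &out) {
  out.clear();
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
}

// Piecewise-constant window heterozygosity over [0, L).
// Window centred on i is [i - lo, i + W - lo), lo = floor(W/2); site j is
// inside the window of target i iff i is in [j - W + lo + 1, j + lo].
static void het_segments(const ivec &het, int W, int L,
                         ivec &bounds, ivec &hvals) {
  bounds.clear(); hvals.clear();
  int lo = W / 2;
  std::vector<iint> ev;
  ev.reserve(2 * het.size());
  for (int p : het) {
    int s = p - W + lo + 1, e = p + lo + 1;
    if (e <= 0 || s >= L) continue;
    ev.push_back(iint(std::max(s, 0), +1));
    ev.push_back(iint(std::min(e, L), -1));
  }
  std::sort(ev.begin(), ev.end());
  bounds.push_back(0);
  int h = 0, cur = 0;
  size_t i = 0;
  while (i < ev.size()) {
    int pos = ev[i].first;
    if (pos > cur) {
      bounds.push_back(pos);
      hvals.push_back(h);
      cur = pos;
    }
    while (i < ev.size() && ev[i].first == pos) { h += ev[i].second; ++i; }
  }
  if (cur < L) { bounds.push_back(L); hvals.push_back(h); }
}

struct Landscape {
  NumericVector r0;             // dense baseline, length L
  std::vector<double> cum;      // prefix sums, length L+1
  double rmax;
  std::vector<iint> zero_runs;  // maximal runs where r0 == 0
  void init(const NumericVector &v) {
    r0 = v;
    int L = v.size();
    cum.assign(L + 1, 0.0);
    rmax = 0.0;
    for (int i = 0; i < L; ++i) {
      cum[i + 1] = cum[i] + v[i];
      if (v[i] > rmax) rmax = v[i];
    }
    zero_runs.clear();
    int i = 0;
    while (i < L) {
      if (v[i] == 0.0) {
        int j = i;
        while (j < L && v[j] == 0.0) ++j;
        zero_runs.push_back(iint(i, j));
        i = j;
      } else ++i;
    }
  }
};

struct Params {
  int N, L, W, sd;              // sd = -1 for autosomal mode
  double E, mu_male, mu_female;
  bool reallocate, fixed_equal, redistribute, sexed, nrr_males_only;
};

struct Engine {
  Params par;
  Landscape male_ls, female_ls;
  std::vector<ivec> haps;       // 2N sparse haplotypes
  ivec sex;                     // per individual, 0 = female, 1 = male
  std::vector<unsigned char> seg_flag;  // per position: currently segregating
  ivec cnt_;                    // scratch derived-allele counts, length L
  int n_poly;
  int gen;

  // scratch
  ivec het_, bnd_, hv_, bps_, touched_;
  bool segs_ready_;             // bnd_/hv_ valid for the current parent

  bool hap_has(const ivec &h, int pos) const {
    return std::binary_search(h.begin(), h.end(), pos);
  }

  // suppression factor at one position, from the segment decomposition
  double factor_at(int pos) const {
    size_t k = std::upper_bound(bnd_.begin(), bnd_.end(), pos) -
               bnd_.begin() - 1;
    return std::max(0.0, 1.0 - par.E * hv_[k] / (double)par.W);
  }

  void parent_segments(int ind) {
    sym_diff(haps[2 * ind], haps[2 * ind + 1], het_);
    het_segments(het_, par.W, par.L, bnd_, hv_);
    segs_ready_ = true;
  }

  // one meiosis of individual `ind`; writes gamete into `gam`;
  // caller must have set segs_ready_ = false for a new parent
  void meiosis(int ind, ivec &gam) {
    const Landscape &ls = (par.sexed && sex[ind] == 1) ? male_ls : female_ls;
    sample_bps(ind, ls);
    form_gamete(haps[2 * ind], haps[2 * ind + 1], gam);
  }

  // Exact per-position Bernoulli breakpoint sampling: one homogeneous
  // Binomial(L, rmax) candidate draw, thinned by f(pos) * r0[pos] / rmax.
  // The window-heterozygosity segments are only computed when a candidate
  // actually occurs (expected crossovers per meiosis ~ r*L << 1).
  void sample_bps(int ind, const Landscape &ls) {
    bps_.clear();
    if (ls.rmax <= 0.0) return;
    if (!par.redistribute) {
      ++g_rng_draws;
      int n = (int)R::rbinom((double)par.L, ls.rmax);
      if (n <= 0) return;
      if (!segs_ready_) parent_segments(ind);
      ivec chosen;
      for (int k = 0; k < n; ++k) {
        int pos;
        do { pos = unif_idx(par.L); }
        while (std::find(chosen.begin(), chosen.end(), pos) != chosen.end());
        chosen.push_back(pos);
        if (unif01() < factor_at(pos) * ls.r0[pos] / ls.rmax)
          bps_.push_back(pos);
      }
      std::sort(bps_.begin(), bps_.end());
    } else {
      if (!segs_ready_) parent_segments(ind);
      // baseline-count semantics: draw events under r0, then relocate
      // them in proportion to the suppressed profile f * r0
      ivec base, chosen;
      ++g_rng_draws;
      int nb = (int)R::rbinom((double)par.L, ls.rmax);
      for (int k = 0; k < nb; ++k) {
        int pos;
        do { pos = unif_idx(par.L); }
        while (std::find(chosen.begin(), chosen.end(), pos) != chosen.end());
        chosen.push_back(pos);
        if (unif01() < ls.r0[pos] / ls.rmax) base.push_back(pos);
      }
      if (base.empty()) return;
      int nseg = (int)hv_.size();
      std::vector<double> mass(nseg);
      double tot = 0.0;
      for (int k = 0; k < nseg; ++k) {
        double f = std::max(0.0, 1.0 - par.E * hv_[k] / (double)par.W);
        mass[k] = f * (ls.cum[bnd_[k + 1]] - ls.cum[bnd_[k]]);
        tot += mass[k];
      }
      if (tot <= 0.0) return;
      for (size_t e = 0; e < base.size(); ++e) {
        double u = unif01() * tot, acc = 0.0;
        int k = 0;
        for (; k < nseg; ++k) { acc += mass[k]; if (u <= acc) break; }
        if (k >= nseg) k = nseg - 1;
        int a = bnd_[k], len = bnd_[k + 1] - a, pos;
        do { pos = a + unif_idx(len); }
        while (unif01() >= ls.r0[pos] / ls.rmax);
        bps_.push_back(pos);
      }
      std::sort(bps_.begin(), bps_.end());
    }
  }

  // copy alternating source-haplotype blocks delimited by breakpoints
  void form_gamete(const ivec &A, const ivec &B, ivec &gam) {
    gam.clear();
    bool fromA = unif01() < 0.5;
    if (bps_.empty()) {
      gam = fromA ? A : B;
      return;
    }
    int prev = 0;
    for (size_t k = 0; k <= bps_.size(); ++k) {
      int end = (k < bps_.size()) ? bps_[k] : par.L;
      if (end > prev) {
        const ivec &src = fromA ? A : B;
        ivec::const_iterator it =
          std::lower_bound(src.begin(), src.end(), prev);
        while (it != src.end() && *it < end) gam.push_back(*it++);
      }
      fromA = !fromA;
      prev = end;
    }
  }

  void mutate(ivec &gam, double mu) {
    if (mu <= 0.0) return;
    ++g_rng_draws;
    int n = (int)R::rpois(mu * par.L);
    if (n <= 0) return;
    ivec added;
    for (int k = 0; k < n; ++k) {
      for (int tries = 0; ; ++tries) {
        int pos = unif_idx(par.L);
        bool hit = seg_flag[pos] != 0 ||
          std::find(added.begin(), added.end(), pos) != added.end();
        if (!hit) { added.push_back(pos); break; }
        if (!par.reallocate) break;            // discard policy
        if (tries > 1000000)
          stop("mutation reallocation failed: sequence saturated");
      }
    }
    if (!added.empty()) {
      gam.insert(gam.end(), added.begin(), added.end());
      std::sort(gam.begin(), gam.end());
    }
  }

  void step() {
    ivec mothers, fathers;
    if (par.sexed) {
      for (int i = 0; i < par.N; ++i)
        (sex[i] == 1 ? fathers : mothers).push_back(i);
      if (mothers.empty() || fathers.empty())
        stop("a sex went extinct at generation %d (binomial sex ratio)", gen);
    }
    std::vector<ivec> nh(2 * par.N);
    ivec nsex(par.N, 0);
    ivec gamM, gamP;
    for (int o = 0; o < par.N; ++o) {
      if (par.sexed) {
        int mom = mothers[unif_idx((int)mothers.size())];
        int dad = fathers[unif_idx((int)fathers.size())];
        segs_ready_ = false;
        meiosis(mom, gamM);
        // paternal meiosis: segments depend on dad only, reused on retries
        segs_ready_ = false;
        int want = par.fixed_equal ? (o < par.N / 2 ? 1 : 0) : -1;
        int got = -2;
        for (int tries = 0; ; ++tries) {
          meiosis(dad, gamP);
          got = hap_has(gamP, par.sd) ? 1 : 0;
          if (want < 0 || got == want) break;
          if (tries > 100000)
            stop("paternal resampling failed to transmit required SD allele");
        }
        nsex[o] = got;
        mutate(gamM, par.mu_female);
        mutate(gamP, par.mu_male);
        nh[2 * o].swap(gamM);      // maternal haplotype first
        nh[2 * o + 1].swap(gamP);
      } else {
        int p1 = unif_idx(par.N), p2 = unif_idx(par.N);
        segs_ready_ = false;
        meiosis(p1, gamM);
        segs_ready_ = false;
        meiosis(p2, gamP);
        mutate(gamM, sex[p1] == 1 ? par.mu_male : par.mu_female);
        mutate(gamP, sex[p2] == 1 ? par.mu_male : par.mu_female);
        nh[2 * o].swap(gamM);
        nh[2 * o + 1].swap(gamP);
        nsex[o] = (o < par.N / 2) ? 1 : 0;  // bookkeeping only
      }
    }
    haps.swap(nh);
    sex.swap(nsex);
    ++gen;
    refresh_sites();
  }

  // drop lost sites, flip fixed sites back to ancestral, rebuild registry
  void refresh_sites() {
    touched_.clear();
    for (const ivec &h : haps)
      for (int p : h) {
        if (cnt_[p]++ == 0) touched_.push_back(p);
      }
    ivec fixed;
    std::fill(seg_flag.begin(), seg_flag.end(), 0);
    n_poly = 0;
    for (int p : touched_) {
      if (cnt_[p] >= 2 * par.N) fixed.push_back(p);
      else { seg_flag[p] = 1; ++n_poly; }
      cnt_[p] = 0;
    }
    if (!fixed.empty()) {
      std::sort(fixed.begin(), fixed.end());
      ivec tmp;
      for (ivec &h : haps) {
        tmp.clear();
        std::set_difference(h.begin(), h.end(), fixed.begin(), fixed.end(),
                            std::back_inserter(tmp));
        h.swap(tmp);
      }
    }
  }

  ivec poly_positions() const {
    ivec out;
    out.reserve(n_poly);
    for (int p = 0; p < par.L; ++p)
      if (seg_flag[p]) out.push_back(p);
    return out;
  }

  // ---- statistics -------------------------------------------------------

  // maximal interval containing sd where f == 0 or r0 == 0 for individual
  // `ind`; returns {sd, sd} (empty) when the SD position itself recombines
  iint zero_component(int ind, const Landscape &ls) {
    const ivec &A = haps[2 * ind], &B = haps[2 * ind + 1];
    sym_diff(A, B, het_);
    het_segments(het_, par.W, par.L, bnd_, hv_);
    std::vector<iint> z;
    for (size_t k = 0; k < hv_.size(); ++k) {
      if (par.E * hv_[k] >= (double)par.W) {
        if (!z.empty() && z.back().second == bnd_[k])
          z.back().second = bnd_[k + 1];
        else
          z.push_back(iint(bnd_[k], bnd_[k + 1]));
      }
    }
    // union with baseline-zero runs, then find the component holding sd
    std::vector<iint> all;
    all.reserve(z.size() + ls.zero_runs.size());
    std::merge(z.begin(), z.end(), ls.zero_runs.begin(), ls.zero_runs.end(),
               std::back_inserter(all));
    int lo = -1, hi = -1;
    for (size_t k = 0; k < all.size(); ++k) {
      int a = all[k].first, b = all[k].second;
      if (hi >= 0 && a <= hi) {            // extends current union interval
        if (b > hi) hi = b;
      } else {
        if (hi >= 0 && lo <= par.sd && par.sd < hi) break;
        lo = a; hi = b;
      }
    }
    if (hi >= 0 && lo <= par.sd && par.sd < hi) return iint(lo, hi);
    return iint(par.sd, par.sd);
  }

  int nrr_bp() {
    if (par.sd < 0) return NA_INTEGER;
    int lo = 0, hi = par.L;
    for (int i = 0; i < par.N; ++i) {
      bool male = sex[i] == 1;
      if (par.nrr_males_only && !male) continue;
      iint c = zero_component(i, male ? male_ls : female_ls);
      if (c.second <= c.first) return 0;
      if (c.first > lo) lo = c.first;
      if (c.second < hi) hi = c.second;
      if (hi <= lo) return 0;
    }
    return hi - lo;
  }

  // mean pairwise diversity per site within a pool of haplotype indices
  double pool_pi(const ivec &pool) {
    int n = (int)pool.size();
    if (n < 2) return NA_REAL;
    std::unordered_map<int, int> cnt;
    for (int hidx : pool)
      for (int p : haps[hidx]) ++cnt[p];
    double s = 0.0;
    for (std::unordered_map<int, int>::iterator it = cnt.begin();
         it != cnt.end(); ++it) {
      double c = it->second;
      s += c * (n - c);
    }
    return s / (n * (n - 1.0) / 2.0) / par.L;
  }

  void pools(ivec &xpool, ivec &ypool, ivec &allpool) {
    xpool.clear(); ypool.clear(); allpool.clear();
    for (int h = 0; h < 2 * par.N; ++h) {
      allpool.push_back(h);
      if (par.sd >= 0) {
        if (hap_has(haps[h], par.sd)) ypool.push_back(h);
        else xpool.push_back(h);
      }
    }
  }

  void divergences(double &dxx, double &dxy) {
    double sf = 0.0, sm = 0.0;
    int nf = 0, nm = 0;
    for (int i = 0; i < par.N; ++i) {
      sym_diff(haps[2 * i], haps[2 * i + 1], het_);
      if (sex[i] == 1) { sm += het_.size(); ++nm; }
      else             { sf += het_.size(); ++nf; }
    }
    dxx = nf ? sf / nf / par.L : NA_REAL;
    dxy = nm ? sm / nm / par.L : NA_REAL;
  }

  List profiles() {
    int L = par.L;
    int nm = 0, nf = 0;
    for (int i = 0; i < par.N; ++i) (sex[i] == 1 ? nm : nf)++;
    // allele counts among male-carried vs female-carried haplotypes
    std::unordered_map<int, int> cm, cf, hm, hf;
    for (int i = 0; i < par.N; ++i) {
      std::unordered_map<int, int> &c = (sex[i] == 1) ? cm : cf;
      for (int p : haps[2 * i]) ++c[p];
      for (int p : haps[2 * i + 1]) ++c[p];
      sym_diff(haps[2 * i], haps[2 * i + 1], het_);
      std::unordered_map<int, int> &hh = (sex[i] == 1) ? hm : hf;
      for (int p : het_) ++hh[p];
    }
    NumericVector fst(L, 0.0), het_xy(L, 0.0), het_xx(L, 0.0);
    std::unordered_set<int> seen;
    for (int pass = 0; pass < 2; ++pass) {
      std::unordered_map<int, int> &c = pass ? cf : cm;
      for (std::unordered_map<int, int>::iterator it = c.begin();
           it != c.end(); ++it) {
        int pos = it->first;
        if (!seen.insert(pos).second) continue;
        double pm = nm ? (cm.count(pos) ? cm[pos] : 0) / (2.0 * nm) : 0.0;
        double pf = nf ? (cf.count(pos) ? cf[pos] : 0) / (2.0 * nf) : 0.0;
        double hb = pm * (1 - pf) + pf * (1 - pm);
        double hw = pm * (1 - pm) + pf * (1 - pf);
        fst[pos] = hb > 0 ? (hb - hw) / hb : 0.0;
      }
    }
    for (std::unordered_map<int, int>::iterator it = hm.begin();
         it != hm.end(); ++it)
      het_xy[it->first] = nm ? it->second / (double)nm : 0.0;
    for (std::unordered_map<int, int>::iterator it = hf.begin();
         it != hf.end(); ++it)
      het_xx[it->first] = nf ? it->second / (double)nf : 0.0;
    // population-mean modified recombination profiles, by meiosis sex
    std::vector<double> dm(L + 1, 0.0), df(L + 1, 0.0);
    for (int i = 0; i < par.N; ++i) {
      sym_diff(haps[2 * i], haps[2 * i + 1], het_);
      het_segments(het_, par.W, par.L, bnd_, hv_);
      std::vector<double> &d = (par.sexed && sex[i] == 1) ? dm : df;
      for (size_t k = 0; k < hv_.size(); ++k) {
        double f = std::max(0.0, 1.0 - par.E * hv_[k] / (double)par.W);
        d[bnd_[k]] += f;
        d[bnd_[k + 1]] -= f;
      }
    }
    NumericVector rim(L, 0.0), rif(L, 0.0);
    double am = 0.0, af = 0.0;
    for (int i = 0; i < L; ++i) {
      am += dm[i]; af += df[i];
      rim[i] = nm ? male_ls.r0[i] * am / nm : 0.0;
      rif[i] = nf ? female_ls.r0[i] * af / nf : 0.0;
    }
    return List::create(_["generation"] = gen, _["fst"] = fst,
                        _["mean_ri_male"] = rim, _["mean_ri_female"] = rif,
                        _["het_xy"] = het_xy, _["het_xx"] = het_xx);
  }
};

// ---- R interface ---------------------------------------------------------

static Engine make_engine(List pop, List cfg, NumericVector male_r0,
                          NumericVector female_r0) {
  Engine eng;
  Params &p = eng.par;
  IntegerVector positions = pop["site_positions"];
  IntegerMatrix hm = pop["haplotypes"];
  IntegerVector sx = pop["sex_codes"];
  p.N = sx.size();
  p.L = as<int>(cfg["L"]);
  p.W = as<int>(cfg["W"]);
  p.E = as<double>(cfg["E"]);
  p.mu_male = as<double>(cfg["mu_male"]);
  p.mu_female = as<double>(cfg["mu_female"]);
  p.reallocate = as<bool>(cfg["reallocate"]);
  p.fixed_equal = as<bool>(cfg["fixed_equal"]);
  p.redistribute = as<bool>(cfg["redistribute"]);
  p.sexed = as<bool>(cfg["sexed"]);
  p.nrr_males_only = as<bool>(cfg["nrr_males_only"]);
  p.sd = as<int>(cfg["sd"]);
  eng.male_ls.init(male_r0);
  eng.female_ls.init(female_r0);
  eng.gen = as<int>(pop["generation"]);
  eng.sex.assign(sx.begin(), sx.end());
  eng.haps.assign(2 * p.N, ivec());
  for (int h = 0; h < 2 * p.N; ++h)
    for (int j = 0; j < hm.ncol(); ++j)
      if (hm(h, j) == 1) eng.haps[h].push_back(positions[j]);
  eng.seg_flag.assign(p.L, 0);
  eng.cnt_.assign(p.L, 0);
  eng.n_poly = 0;
  for (int j = 0; j < positions.size(); ++j) {
    eng.seg_flag[positions[j]] = 1;
    ++eng.n_poly;
  }
  eng.segs_ready_ = false;
  return eng;
}

static List export_population(Engine &eng) {
  ivec pos = eng.poly_positions();
  std::unordered_map<int, int> col;
  for (size_t j = 0; j < pos.size(); ++j) col[pos[j]] = (int)j;
  IntegerMatrix hm(2 * eng.par.N, (int)pos.size());
  for (int h = 0; h < 2 * eng.par.N; ++h)
    for (int p : eng.haps[h]) hm(h, col[p]) = 1;
  return List::create(
    _["site_positions"] = wrap(pos), _["haplotypes"] = hm,
    _["sex_codes"] = wrap(eng.sex), _["generation"] = eng.gen);
}

// [[Rcpp::export]]
List cpp_run(List pop, List cfg, NumericVector male_r0,
             NumericVector female_r0, int n_generations, int record_interval,
             IntegerVector profile_generations) {
  Engine eng = make_engine(pop, cfg, male_r0, female_r0);
  g_rng_draws = 0;
  std::unordered_set<int> want_prof(profile_generations.begin(),
                                    profile_generations.end());
  std::vector<int> rec_gen, rec_nrr, rec_nseg;
  std::vector<double> rec_dxx, rec_dxy, rec_pix, rec_piy, rec_piall;
  List prof_out;
  ivec xp, yp, ap;

  int target = eng.gen + n_generations;
  for (;;) {
    if (record_interval > 0 && eng.gen % record_interval == 0) {
      double dxx, dxy;
      eng.divergences(dxx, dxy);
      eng.pools(xp, yp, ap);
      rec_gen.push_back(eng.gen);
      rec_nrr.push_back(eng.nrr_bp());
      rec_nseg.push_back(eng.n_poly);
      rec_dxx.push_back(dxx);
      rec_dxy.push_back(dxy);
      rec_pix.push_back(eng.par.sd >= 0 ? eng.pool_pi(xp) : NA_REAL);
      rec_piy.push_back(eng.par.sd >= 0 ? eng.pool_pi(yp) : NA_REAL);
      rec_piall.push_back(eng.pool_pi(ap));
    }
    if (want_prof.count(eng.gen)) prof_out.push_back(eng.profiles());
    if (eng.gen >= target) break;
    eng.step();
    Rcpp::checkUserInterrupt();
  }

  List records = List::create(
    _["generation"] = wrap(rec_gen), _["nrr_bp"] = wrap(rec_nrr),
    _["dxx"] = wrap(rec_dxx), _["dxy"] = wrap(rec_dxy),
    _["pi_x"] = wrap(rec_pix), _["pi_y"] = wrap(rec_piy),
    _["pi_all"] = wrap(rec_piall), _["n_seg_sites"] = wrap(rec_nseg));
  return List::create(
    _["records"] = records, _["profiles"] = prof_out,
    _["population"] = export_population(eng),
    _["rng_draw_count"] = (double)g_rng_draws);
}

// [[Rcpp::export]]
List cpp_step(List pop, List cfg, NumericVector male_r0,
              NumericVector female_r0) {
  Engine eng = make_engine(pop, cfg, male_r0, female_r0);
  eng.step();
  return export_population(eng);
}

// [[Rcpp::export]]
List cpp_nrr(List pop, List cfg, NumericVector male_r0,
             NumericVector female_r0) {
  Engine eng = make_engine(pop, cfg, male_r0, female_r0);
  return List::create(_["nrr_bp"] = eng.nrr_bp());
}

// segment decomposition of the window-heterozygosity profile, for
// cross-checking the engine against the dense R implementation
// [[Rcpp::export]]
List cpp_window_segments(IntegerVector het_positions, double E, int W,
                         int L) {
  ivec het(het_positions.begin(), het_positions.end());
  std::sort(het.begin(), het.end());
  ivec bounds, hvals;
  het_segments(het, W, L, bounds, hvals);
  NumericVector fac(hvals.size());
  for (size_t k = 0; k < hvals.size(); ++k)
    fac[k] = std::max(0.0, 1.0 - E * hvals[k] / (double)W);
  return List::create(_["bounds"] = wrap(bounds), _["h"] = wrap(hvals),
                      _["factor"] = fac);
}
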