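// Microsimulation core: counter-based RNG substreams, adenoma-carcinoma
// natural-history generation, and scenario replay (screening + surveillance).
//
// All randomness flows through keyed SplitMix64 uniforms so that person i's
// natural history is bit-identical across scenarios and population sizes
// (common-random-numbers contract), and exam draws are shared per
// (person, exam index, lesion slot) so detection under a low-sensitivity
// profile is a subset of detection under a high-sensitivity profile.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t sm64_mix(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t stream_key(uint64_t seed, uint64_t person,
                                  uint64_t stream) {
  uint64_t k = sm64_mix(seed ^ 0x8f1bbcdcbfa53e0bULL);
  k = sm64_mix(k ^ (person * 0xd2b74407b1ce6e93ULL));
  k = sm64_mix(k ^ (stream * 0xca5a826395121157ULL));
  return k;
}

// uniform in (0,1): 53-bit mantissa, offset by half an ulp so 0 is excluded
static inline double u01(uint64_t key, uint64_t counter) {
  uint64_t z = sm64_mix(key + counter * 0x9e3779b97f4a7c15ULL);
  return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// streams (fixed protocol; the R fallback engine mirrors these)
static const uint64_t STR_MORT = 0;     // other-cause mortality (2 draws)
static const uint64_t STR_FRAILTY = 1;  // person frailty (1 draw)
static const uint64_t STR_NLESION = 2;  // lesion count (1 draw)
static const uint64_t STR_LESION = 3;   // per-lesion block of 8 draws
static const uint64_t STR_EXAM = 4;     // per-exam block of 64 draws

static const int LESION_BLOCK = 8;
static const int EXAM_BLOCK = 64;

// [[Rcpp::export]]
NumericVector cpp_uniforms(double seed, double person, double stream,
                           NumericVector counters) {
  uint64_t key = stream_key((uint64_t)seed, (uint64_t)person, (uint64_t)stream);
  int n = counters.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = u01(key, (uint64_t)counters[i]);
  return out;
}

// ------------------------------------------------- natural history ------

struct Preset {
  std::vector<double> age_breaks;   // K+1 breaks
  std::vector<double> base_hazard;  // K segment hazards (per year)
  int frailty_dist;                 // 0 gamma, 1 lognormal
  double frailty_var;
  int max_lesions;
  double growth_meanlog, growth_sdlog, reach_prob;
  double h_small, h_med, h_large;   // transformation hazards (-log(1-p))
  int sojourn_dist;                 // 0 lognormal, 1 exponential
  double sojourn_par1, sojourn_par2;
  double surv_clin_meanlog, surv_screen_meanlog, surv_sdlog;
};

static Preset read_preset(const List& p) {
  Preset ps;
  ps.age_breaks = as<std::vector<double> >(p["age_breaks"]);
  ps.base_hazard = as<std::vector<double> >(p["base_hazard"]);
  ps.frailty_dist = as<int>(p["frailty_dist"]);
  ps.frailty_var = as<double>(p["frailty_var"]);
  ps.max_lesions = as<int>(p["max_lesions"]);
  ps.growth_meanlog = as<double>(p["growth_meanlog"]);
  ps.growth_sdlog = as<double>(p["growth_sdlog"]);
  ps.reach_prob = as<double>(p["reach_prob"]);
  ps.h_small = -std::log(1.0 - as<double>(p["transform_small"]));
  ps.h_med = -std::log(1.0 - as<double>(p["transform_medium"]));
  ps.h_large = -std::log(1.0 - as<double>(p["transform_large"]));
  ps.sojourn_dist = as<int>(p["sojourn_dist"]);
  ps.sojourn_par1 = as<double>(p["sojourn_par1"]);
  ps.sojourn_par2 = as<double>(p["sojourn_par2"]);
  ps.surv_clin_meanlog = as<double>(p["surv_clin_meanlog"]);
  ps.surv_screen_meanlog = as<double>(p["surv_screen_meanlog"]);
  ps.surv_sdlog = as<double>(p["surv_sdlog"]);
  return ps;
}

static inline double cum_onset_hazard_total(const Preset& ps) {
  double H = 0.0;
  for (size_t k = 0; k + 1 < ps.age_breaks.size(); ++k)
    H += ps.base_hazard[k] * (ps.age_breaks[k + 1] - ps.age_breaks[k]);
  return H;
}

// invert cumulative baseline onset hazard at target value h (0 <= h <= Htot)
static inline double invert_onset(const Preset& ps, double h) {
  double acc = 0.0;
  for (size_t k = 0; k + 1 < ps.age_breaks.size(); ++k) {
    double w = ps.age_breaks[k + 1] - ps.age_breaks[k];
    double seg = ps.base_hazard[k] * w;
    if (h <= acc + seg || k + 2 == ps.age_breaks.size()) {
      if (ps.base_hazard[k] <= 0.0) return ps.age_breaks[k + 1];
      return ps.age_breaks[k] + (h - acc) / ps.base_hazard[k];
    }
    acc += seg;
  }
  return ps.age_breaks.back();
}

// time from lesion onset to malignant transformation, by inverting the
// piecewise-constant size-class hazard at an Exp(1) draw
static inline double transform_time(const Preset& ps, double t6, double t10,
                                    double E) {
  double H1 = ps.h_small * t6;
  if (E < H1) return E / ps.h_small;
  double H2 = H1 + ps.h_med * (t10 - t6);
  if (E < H2) return t6 + (E - H1) / ps.h_med;
  if (ps.h_large <= 0.0) return R_PosInf;
  return t10 + (E - H2) / ps.h_large;
}

static inline double q_sojourn(const Preset& ps, double u) {
  if (ps.sojourn_dist == 1) return R::qexp(u, ps.sojourn_par1, 1, 0);
  return R::qlnorm(u, ps.sojourn_par1, ps.sojourn_par2, 1, 0);
}

// [[Rcpp::export]]
List cpp_generate_population(List preset, NumericVector death_cdf,
                             double max_age, int n, double seed,
                             double person_offset) {
  Preset ps = read_preset(preset);
  double Htot = cum_onset_hazard_total(ps);
  int ncdf = death_cdf.size();  // death_cdf[a] = P(death age < a+1), a = 0..

  NumericVector oc_age(n), frailty(n);
  IntegerVector nles(n);
  std::vector<double> onset, t6v, t10v, tr_age, clin_age, sojournv, surv_u;
  std::vector<int> reach, owner;

  for (int i = 0; i < n; ++i) {
    uint64_t id = (uint64_t)(person_offset) + (uint64_t)i + 1ULL;
    uint64_t s = (uint64_t)seed;

    // other-cause death: discrete year from life-table CDF + uniform offset
    uint64_t km = stream_key(s, id, STR_MORT);
    double uy = u01(km, 0), uf = u01(km, 1);
    int yr = 0;
    while (yr < ncdf - 1 && death_cdf[yr] < uy) ++yr;
    oc_age[i] = yr + uf;
    if (oc_age[i] > max_age) oc_age[i] = max_age;

    // frailty (mean 1)
    uint64_t kf = stream_key(s, id, STR_FRAILTY);
    double th = 1.0;
    if (ps.frailty_var > 0.0) {
      double uth = u01(kf, 0);
      if (ps.frailty_dist == 0) {
        th = R::qgamma(uth, 1.0 / ps.frailty_var, ps.frailty_var, 1, 0);
      } else {
        double s2 = std::log(1.0 + ps.frailty_var);
        th = R::qlnorm(uth, -0.5 * s2, std::sqrt(s2), 1, 0);
      }
    }
    frailty[i] = th;

    // lesion count: Poisson with person rate th * Htot
    uint64_t kn = stream_key(s, id, STR_NLESION);
    int N = (int)R::qpois(u01(kn, 0), th * Htot, 1, 0);
    if (N > ps.max_lesions) N = ps.max_lesions;
    nles[i] = N;

    uint64_t kl = stream_key(s, id, STR_LESION);
    for (int j = 0; j < N; ++j) {
      uint64_t b = (uint64_t)j * LESION_BLOCK;
      double on = invert_onset(ps, u01(kl, b + 0) * Htot);
      double g = R::qlnorm(u01(kl, b + 1), ps.growth_meanlog,
                           ps.growth_sdlog, 1, 0);
      double t6 = std::log(6.0) / g;    // years from 1 mm to 6 mm
      double t10 = std::log(10.0) / g;  // years from 1 mm to 10 mm
      double E = -std::log(1.0 - u01(kl, b + 2));
      double tt = transform_time(ps, t6, t10, E);
      double ta = on + tt;
      double sj = q_sojourn(ps, u01(kl, b + 3));
      double su = u01(kl, b + 4);
      int rch = (u01(kl, b + 5) < ps.reach_prob) ? 1 : 0;
      if (ta > 3.0 * max_age) ta = R_PosInf;  // effectively never
      onset.push_back(on);
      t6v.push_back(t6);
      t10v.push_back(t10);
      tr_age.push_back(ta);
      sojournv.push_back(sj);
      clin_age.push_back(R_FINITE(ta) ? ta + sj : R_PosInf);
      surv_u.push_back(su);
      reach.push_back(rch);
      owner.push_back(i + 1);
    }
  }

  return List::create(
      _["oc_death_age"] = oc_age, _["frailty"] = frailty,
      _["n_lesions"] = nles, _["lesion_person"] = wrap(owner),
      _["onset_age"] = wrap(onset), _["t6"] = wrap(t6v),
      _["t10"] = wrap(t10v), _["transform_age"] = wrap(tr_age),
      _["sojourn"] = wrap(sojournv), _["clinical_age"] = wrap(clin_age),
      _["surv_u"] = wrap(surv_u), _["within_reach"] = wrap(reach));
}

// ---------------------------------------------------- scenario replay ----

// findings categories (row/col indices into the surveillance matrix)
static const int CAT_NOPRIOR = 0;
static const int CAT_NORMAL = 1;
// columns 1..5 of the 6x6 matrix are normal, 1-2 small, 3-4 small,
// 5-10 small / any large, >10

static inline int size_class(double dt, double t6, double t10) {
  if (dt < t6) return 0;
  if (dt < t10) return 1;
  return 2;
}

// [[Rcpp::export]]
List cpp_run_scenario(List pop, NumericVector sched_age,
                      IntegerVector sched_mod,  // 0 colonoscopy, 1 FIT
                      NumericVector colo_sens,  // small, med, large, preclin
                      NumericVector fit_sens,   // small, med, large, early, late
                      double fit_spec, int fit_per_lesion,
                      IntegerMatrix surv_table,  // 6x6, years, -1 undefined
                      double resume_gap, double surv_stop_age,
                      double pandemic_age, double delay_years,
                      double cutoff_age, List survival_pars, double seed) {
  NumericVector oc_age = pop["oc_death_age"];
  IntegerVector nles = pop["n_lesions"];
  NumericVector onset = pop["onset_age"], t6 = pop["t6"], t10 = pop["t10"],
                tr_age = pop["transform_age"], clin = pop["clinical_age"],
                sojourn = pop["sojourn"], surv_u = pop["surv_u"];
  IntegerVector reach = pop["within_reach"];

  double clin_ml = as<double>(survival_pars["clin_meanlog"]);
  double scr_ml = as<double>(survival_pars["screen_meanlog"]);
  double sdl = as<double>(survival_pars["sdlog"]);

  int n = oc_age.size();
  int K = sched_age.size();
  double delay_end = pandemic_age + delay_years;

  NumericVector death_age(n), dx_age(n), crc_death_age(n);
  IntegerVector dx_mode(n), crc_death(n), n_colos(n), n_fits(n);

  // lesion offsets
  std::vector<int> ptr(n + 1, 0);
  for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + nles[i];

  std::vector<char> removed;

  for (int i = 0; i < n; ++i) {
    uint64_t id_key = stream_key((uint64_t)seed, (uint64_t)(i + 1), STR_EXAM);
    int l0 = ptr[i], l1 = ptr[i + 1];
    removed.assign(l1 - l0, 0);
    double ocd = oc_age[i];

    int last_cat = CAT_NOPRIOR;
    bool in_surv = false, done = false;
    double surv_due = R_PosInf, resume_age = R_NegInf;
    int ridx = 0, exam_ct = 0, ncol = 0, nfit = 0;
    double p_dx = NA_REAL, p_crcd = NA_REAL;
    int p_mode = 0;

    // earliest clinical surfacing age among active (non-removed) lesions
    auto earliest_clinical = [&](int* who) {
      double best = R_PosInf;
      *who = -1;
      for (int j = l0; j < l1; ++j)
        if (!removed[j - l0] && clin[j] < best) { best = clin[j]; *who = j; }
      return best;
    };

    // run one colonoscopy at age a; returns true if screening process ends
    auto colonoscopy = [&](double a) {
      uint64_t base = (uint64_t)exam_ct * EXAM_BLOCK;
      ++exam_ct;
      ++ncol;
      int n_small = 0, n_large = 0, cancer_lesion = -1;
      for (int j = l0; j < l1; ++j) {
        if (removed[j - l0] || onset[j] > a || !reach[j]) continue;
        double u = u01(id_key, base + 1 + (uint64_t)(j - l0));
        if (a < tr_age[j]) {  // adenoma
          int sc = size_class(a - onset[j], t6[j], t10[j]);
          if (u < colo_sens[sc]) {
            removed[j - l0] = 1;
            if (sc == 2) ++n_large; else ++n_small;
          }
        } else if (a < clin[j]) {  // preclinical cancer
          if (u < colo_sens[3] && cancer_lesion < 0) cancer_lesion = j;
        }
      }
      if (cancer_lesion >= 0) {  // screen-detected diagnosis ends screening
        p_dx = a;
        p_mode = 1;
        p_crcd = a + R::qlnorm(surv_u[cancer_lesion], scr_ml, sdl, 1, 0);
        done = true;
        return;
      }
      int ndet = n_small + n_large;
      int cat;
      if (ndet == 0) cat = CAT_NORMAL;
      else if (ndet > 10) cat = 5;
      else if (n_large > 0 || ndet >= 5) cat = 4;
      else if (ndet >= 3) cat = 3;
      else cat = 2;
      int second = last_cat;
      last_cat = cat;
      if (cat == CAT_NORMAL) {
        if (in_surv) {
          int iv = surv_table(second, CAT_NORMAL);
          double prop = a + iv;
          // surveillance ends after a negative exam that schedules past the
          // stopping age; screening does not restart afterwards
          if (prop > surv_stop_age + 1e-9) { in_surv = false; done = true; }
          else surv_due = prop;
        } else {
          // normal first screening/diagnostic colonoscopy: resume original
          // modality resume_gap (10) years later
          resume_age = a + resume_gap;
        }
      } else {
        int iv = surv_table(second, cat);
        in_surv = true;
        surv_due = a + iv;  // scheduled even past the stop age: adenomas
                            // were detected at this exam
      }
    };

    while (!done) {
      double a;
      int mod;
      if (in_surv) {
        a = surv_due;
        // pandemic delay window also postpones due surveillance exams
        if (delay_years > 0 && a >= pandemic_age && a < delay_end)
          a = delay_end;
        mod = 0;
      } else {
        while (ridx < K && sched_age[ridx] < resume_age - 1e-9) ++ridx;
        if (ridx >= K) a = R_PosInf; else { a = sched_age[ridx]; mod = sched_mod[ridx]; }
      }
      if (a >= cutoff_age) a = R_PosInf;  // discontinued screening

      int who;
      double ec = earliest_clinical(&who);
      if (ec < a && ec < ocd) {  // cancer surfaces clinically first
        p_dx = ec;
        p_mode = 2;
        p_crcd = ec + R::qlnorm(surv_u[who], clin_ml, sdl, 1, 0);
        break;
      }
      if (!R_FINITE(a) || a >= ocd) break;  // no further exams in life

      if (mod == 1) {  // FIT
        uint64_t base = (uint64_t)exam_ct * EXAM_BLOCK;
        ++exam_ct;
        ++nfit;
        bool pos = false;
        if (fit_per_lesion) {
          pos = u01(id_key, base + 0) < (1.0 - fit_spec);  // other-cause bleed
          for (int j = l0; j < l1; ++j) {
            if (removed[j - l0] || onset[j] > a) continue;
            double s;
            if (a < tr_age[j]) s = fit_sens[size_class(a - onset[j], t6[j], t10[j])];
            else s = (a - tr_age[j] < 0.5 * sojourn[j]) ? fit_sens[3] : fit_sens[4];
            if (u01(id_key, base + 1 + (uint64_t)(j - l0)) < s) pos = true;
          }
        } else {  // per-person: sensitivity of the most advanced lesion
          double s = 1.0 - fit_spec;
          bool any = false;
          double best = -1.0;
          for (int j = l0; j < l1; ++j) {
            if (removed[j - l0] || onset[j] > a) continue;
            double rank, sj;
            if (a < tr_age[j]) {
              int sc = size_class(a - onset[j], t6[j], t10[j]);
              rank = sc;
              sj = fit_sens[sc];
            } else {
              bool late = (a - tr_age[j]) >= 0.5 * sojourn[j];
              rank = late ? 4 : 3;
              sj = late ? fit_sens[4] : fit_sens[3];
            }
            if (rank > best) { best = rank; s = sj; any = true; }
          }
          (void)any;
          pos = u01(id_key, base + 0) < s;
        }
        ++ridx;
        if (pos) colonoscopy(a);  // diagnostic colonoscopy at the same age
      } else {
        if (!in_surv) ++ridx;
        colonoscopy(a);
      }
    }

    // settle remaining clinical surfacing if screening ended without dx
    if (p_mode == 0) {
      int who;
      double ec = earliest_clinical(&who);
      if (ec < ocd) {
        p_dx = ec;
        p_mode = 2;
        p_crcd = ec + R::qlnorm(surv_u[who], clin_ml, sdl, 1, 0);
      }
    }

    double da = ocd;
    int crcd = 0;
    if (p_mode != 0 && R_FINITE(p_crcd) && p_crcd < ocd) { da = p_crcd; crcd = 1; }
    death_age[i] = da;
    dx_age[i] = (p_mode != 0) ? p_dx : NA_REAL;
    crc_death_age[i] = (p_mode != 0) ? p_crcd : NA_REAL;
    dx_mode[i] = p_mode;
    crc_death[i] = crcd;
    n_colos[i] = ncol;
    n_fits[i] = nfit;
  }

  return List::create(
      _["death_age"] = death_age, _["dx_age"] = dx_age,
      _["crc_death_age"] = crc_death_age, _["dx_mode"] = dx_mode,
      _["crc_death"] = crc_death, _["n_colonoscopies"] = n_colos,
      _["n_fits"] = n_fits);
}
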