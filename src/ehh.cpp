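// Extended haplotype homozygosity around a core site. Carriers of the core
// allele are partitioned into identity groups that refine site by site moving
// away from the core; EHH at an offset is the fraction of carrier pairs still
// identical over the interval. Haplotypes hitting a missing call drop out of
// the pair count from that offset outward.

#include <Rcpp.h>
#include <unordered_map>

using namespace Rcpp;

static void walk_side(const IntegerMatrix &haps, const NumericVector &pos,
                      std::vector<int> car, int core, int step,
                      double stop_below, std::vector<double> &out_pos,
                      std::vector<double> &out_ehh, bool &hit_edge) {
  int S = haps.ncol();
  int n = (int)car.size();
  std::vector<int> grp(n, 0);
  std::vector<char> alive(n, 1);
  int ngrp = 1;
  for (int j = core + step; j >= 0 && j < S; j += step) {
    std::unordered_map<long long, int> remap;
    std::unordered_map<int, int> gcount;
    int na = 0, newg = 0;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      int a = haps(car[i], j);
      if (a == NA_INTEGER) { alive[i] = 0; continue; }
      long long key = (long long)grp[i] * 2 + a;
      auto it = remap.find(key);
      int g;
      if (it == remap.end()) { g = newg++; remap[key] = g; } else g = it->second;
      grp[i] = g;
      ++gcount[g];
      ++na;
    }
    ngrp = newg;
    double ehh = 0.0;
    if (na >= 2) {
      double num = 0.0;
      for (auto &kv : gcount) num += (double)kv.second * (kv.second - 1) / 2.0;
      ehh = num / ((double)na * (na - 1) / 2.0);
    }
    out_pos.push_back(pos[j]);
    out_ehh.push_back(ehh);
    if (na < 2 || ehh < stop_below) { hit_edge = false; return; }
  }
  // exhausted the panel without dropping below stop_below
  hit_edge = true;
  (void)ngrp;
}

// Integrate EHH outward from the core with truncation at `cutoff` and the
// adjacent-site gap rule; returns {ihh, status} with status 0 ok, 2 too few
// carriers, 3 gap crossed before truncation, 5 panel border reached before
// EHH decayed below the cutoff (integral undefined, variant excluded).
static void ihh_side(const IntegerMatrix &haps, const NumericVector &pos,
                     const std::vector<int> &car, int core, int step,
                     double cutoff, double gap_limit, double &ihh,
                     int &status) {
  int S = haps.ncol();
  int n = (int)car.size();
  std::vector<int> grp(n, 0);
  std::vector<char> alive(n, 1);
  std::vector<int> remap(2 * n), gcount(n);
  int ngrp = 1;                        // current number of identity groups
  double prev_pos = pos[core], prev_ehh = 1.0, total = 0.0;
  for (int j = core + step; j >= 0 && j < S; j += step) {
    double gap = std::abs(pos[j] - prev_pos);
    if (gap > gap_limit) { status = 3; return; }
    std::fill(remap.begin(), remap.begin() + 2 * ngrp, -1);
    int na = 0, newg = 0;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      int a = haps(car[i], j);
      if (a == NA_INTEGER) { alive[i] = 0; continue; }
      int key = grp[i] * 2 + a;
      int g = remap[key];
      if (g < 0) { g = newg++; remap[key] = g; gcount[g] = 0; }
      grp[i] = g;
      ++gcount[g];
      ++na;
    }
    ngrp = newg > 0 ? newg : 1;
    double ehh = 0.0;
    if (na >= 2) {
      double num = 0.0;
      for (int g = 0; g < newg; ++g)
        num += (double)gcount[g] * (gcount[g] - 1) / 2.0;
      ehh = num / ((double)na * (na - 1) / 2.0);
    }
    total += gap * (prev_ehh + ehh) / 2.0;
    if (ehh < cutoff) { ihh = total; status = 0; return; }
    prev_pos = pos[j];
    prev_ehh = ehh;
  }
  // ran off the panel edge with EHH still at or above the cutoff; the
  // integral over the observable span is reported so the caller can either
  // exclude the variant (rehh border convention) or keep the truncation
  ihh = total;
  status = 5;
}

// [[Rcpp::export]]
List ihs_scan_cpp(IntegerMatrix haps, NumericVector pos, double maf_min,
                  double cutoff, double gap_limit, bool border_exclude) {
  int S = haps.ncol(), H = haps.nrow();
  NumericVector freq(S), ihh_a(S, NA_REAL), ihh_d(S, NA_REAL),
      uihs(S, NA_REAL);
  IntegerVector code(S);
  for (int j = 0; j < S; ++j) {
    std::vector<int> car0, car1;
    int nn = 0;
    for (int i = 0; i < H; ++i) {
      int a = haps(i, j);
      if (a == NA_INTEGER) continue;
      ++nn;
      if (a == 1) car1.push_back(i); else car0.push_back(i);
    }
    double f = nn ? (double)car1.size() / nn : NA_REAL;
    freq[j] = f;
    double maf = std::min(f, 1.0 - f);
    if (nn == 0 || !(maf > maf_min)) { code[j] = 1; continue; }
    if (car0.size() < 2 || car1.size() < 2) { code[j] = 2; continue; }
    double ia = 0, id = 0;
    int sa = 0, sd = 0, tmp = 0;
    double part = 0;
    // with border_exclude = false a status-5 side keeps its truncated
    // integral and does not stop the evaluation
    bool bad = false, border = false;
    double *acc[2] = {&ia, &id};
    std::vector<int> *cars[2] = {&car0, &car1};
    int *st[2] = {&sa, &sd};
    for (int a = 0; a < 2 && !bad; ++a) {
      for (int step = -1; step <= 1 && !bad; step += 2) {
        ihh_side(haps, pos, *cars[a], j, step, cutoff, gap_limit, part, tmp);
        if (tmp == 3) { *st[a] = 3; bad = true; break; }
        if (tmp == 5) {
          if (border_exclude) { *st[a] = 5; bad = true; break; }
          border = true;
        }
        *acc[a] += part;
      }
    }
    if (sa == 3 || sd == 3) { code[j] = 3; continue; }
    if (sa == 5 || sd == 5) { code[j] = 5; continue; }
    (void)border;
    ihh_a[j] = ia; ihh_d[j] = id;
    if (ia <= 0 || id <= 0) { code[j] = 4; continue; }
    uihs[j] = std::log(ia / id);
    code[j] = 0;
  }
  return List::create(_["freq"] = freq, _["ihh_a"] = ihh_a,
                      _["ihh_d"] = ihh_d, _["uihs"] = uihs,
                      _["code"] = code);
}

// [[Rcpp::export]]
List ehh_curve_cpp(IntegerMatrix haps, NumericVector pos, int core1,
                   int allele, double stop_below) {
  int core = core1 - 1;
  std::vector<int> car;
  for (int i = 0; i < haps.nrow(); ++i) {
    int a = haps(i, core);
    if (a != NA_INTEGER && a == allele) car.push_back(i);
  }
  std::vector<double> lp, le, rp, re;
  bool ledge = true, redge = true;
  if (car.size() >= 2) {
    walk_side(haps, pos, car, core, -1, stop_below, lp, le, ledge);
    walk_side(haps, pos, car, core, +1, stop_below, rp, re, redge);
  }
  return List::create(_["n_carriers"] = (int)car.size(),
                      _["core_pos"] = pos[core],
                      _["left_pos"] = NumericVector(lp.begin(), lp.end()),
                      _["left_ehh"] = NumericVector(le.begin(), le.end()),
                      _["right_pos"] = NumericVector(rp.begin(), rp.end()),
                      _["right_ehh"] = NumericVector(re.begin(), re.end()),
                      _["left_edge"] = ledge, _["right_edge"] = redge);
}
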