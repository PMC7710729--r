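// Forward-in-time Wright-Fisher simulator with recombination, infinite-sites
// mutation, multi-population demography (splits, epoch size changes, migration)
// and an optional selected allele (fitnesses 1, 1+hs, 1+s) planted from
// standing variation. Haplotypes are sparse sorted vectors of mutation ids;
// positions are continuous in [0, L) and discretized only at sampling time.

#include <Rcpp.h>
#include <random>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<int> Hap;

struct Sim {
  std::vector<double> mpos;            // position per mutation id
  std::mt19937_64 rng;
  double L;

  bool before(int a, int b) const { return mpos[a] < mpos[b]; }

  // copy ids of `src` with positions below hi starting at index i (i always
  // sits at the first id not yet consumed, so everything below hi belongs
  // to the current segment)
  void take_segment(const Hap &src, size_t &i, double hi, Hap &out,
                    bool active) {
    size_t j = std::lower_bound(src.begin() + i, src.end(), hi,
                                [this](int id, double v) {
                                  return mpos[id] < v;
                                }) - src.begin();
    if (active) out.insert(out.end(), src.begin() + i, src.begin() + j);
    i = j;
  }

  // meiosis: recombine parental haplotypes a/b with Poisson(r*L) crossovers
  void gamete(const Hap &a, const Hap &b, double rec_mean, Hap &out) {
    out.clear();
    std::poisson_distribution<int> pois(rec_mean);
    int nbr = rec_mean > 0 ? pois(rng) : 0;
    std::bernoulli_distribution coin0(0.5);
    if (nbr == 0) {            // no crossover: the gamete is one parent hap
      out = coin0(rng) ? a : b;
      return;
    }
    std::uniform_real_distribution<double> unif(0.0, L);
    std::vector<double> brk(nbr);
    for (int k = 0; k < nbr; ++k) brk[k] = unif(rng);
    std::sort(brk.begin(), brk.end());
    brk.push_back(L);
    std::bernoulli_distribution coin(0.5);
    bool use_a = coin(rng);
    size_t ia = 0, ib = 0;
    for (double hi : brk) {
      take_segment(a, ia, hi, out, use_a);
      take_segment(b, ib, hi, out, !use_a);
      use_a = !use_a;
    }
  }

  void mutate(Hap &h, double mut_mean) {
    if (mut_mean <= 0) return;
    std::poisson_distribution<int> pois(mut_mean);
    int k = pois(rng);
    if (k == 0) return;
    std::uniform_real_distribution<double> unif(0.0, L);
    for (int j = 0; j < k; ++j) {
      double p = unif(rng);
      int id = (int)mpos.size();
      mpos.push_back(p);
      auto it = std::lower_bound(h.begin(), h.end(), id,
                                 [this](int x, int y) { return before(x, y); });
      h.insert(it, id);
    }
  }
};

static bool carries(const Hap &h, int id, const std::vector<double> &mpos) {
  auto it = std::lower_bound(h.begin(), h.end(), id,
                             [&](int x, int y) { return mpos[x] < mpos[y]; });
  // equal positions only happen for the id itself (positions are unique)
  while (it != h.end() && mpos[*it] == mpos[id]) {
    if (*it == id) return true;
    ++it;
  }
  return false;
}

// [[Rcpp::export]]
List wf_simulate_cpp(int n_pops,
                     IntegerVector origin,      // 1-based parent pop, 0 = founder
                     IntegerVector split_gen,   // generation a pop appears (0 founder)
                     IntegerVector epoch_pop,   // 1-based, parallel epoch arrays
                     IntegerVector epoch_gen,
                     IntegerVector epoch_size,  // diploid sizes
                     NumericMatrix migration,   // m[dest, src] per generation
                     double mu, double rec, double L, int n_gen,
                     IntegerVector sample_sizes,
                     bool sweep, double sweep_pos, double sel_s, double sel_h,
                     double f0, int sweep_pop, int sweep_start,
                     double stop_freq, bool stop_at_absorption,
                     int seed) {
  Sim S;
  S.rng.seed((uint64_t)seed);
  S.L = L;
  double mut_mean = mu * L, rec_mean = rec * L;

  std::vector<std::vector<Hap>> pop(n_pops);     // pop -> haplotypes
  std::vector<int> cur_size(n_pops, 0);          // diploid size, 0 = not yet alive
  int sweep_id = -1;
  bool sweep_alive = false, sweep_planted = false;
  std::vector<double> traj;
  std::string outcome = "none";
  int end_gen = n_gen;

  auto pop_freq = [&](int p) -> double {
    if (sweep_id < 0 || pop[p].empty()) return 0.0;
    int c = 0;
    for (const Hap &h : pop[p]) c += carries(h, sweep_id, S.mpos) ? 1 : 0;
    return (double)c / pop[p].size();
  };

  // founders exist from generation 0 at their first epoch size
  for (int p = 0; p < n_pops; ++p) {
    if (split_gen[p] == 0) {
      for (int e = 0; e < epoch_pop.size(); ++e)
        if (epoch_pop[e] - 1 == p && epoch_gen[e] == 0) cur_size[p] = epoch_size[e];
      if (cur_size[p] < 2) stop("founder population needs an epoch at generation 0");
      pop[p].assign(2 * cur_size[p], Hap());
    }
  }

  for (int g = 1; g <= n_gen; ++g) {
    // epoch size changes taking effect this generation
    for (int e = 0; e < epoch_pop.size(); ++e)
      if (epoch_gen[e] == g && split_gen[epoch_pop[e] - 1] < g)
        cur_size[epoch_pop[e] - 1] = epoch_size[e];

    // plant the selected allele (standing variation at frequency f0)
    if (sweep && !sweep_planted && g == sweep_start) {
      int tp = sweep_pop - 1;
      if (cur_size[tp] == 0) stop("sweep population does not exist at sweep start");
      int n_h = (int)pop[tp].size();
      int k = std::max(1, (int)std::floor(f0 * n_h + 0.5));
      std::vector<int> idx(n_h);
      for (int i = 0; i < n_h; ++i) idx[i] = i;
      std::shuffle(idx.begin(), idx.end(), S.rng);
      sweep_id = (int)S.mpos.size();
      S.mpos.push_back(sweep_pos);
      for (int i = 0; i < k; ++i) {
        Hap &h = pop[tp][idx[i]];
        auto it = std::lower_bound(h.begin(), h.end(), sweep_id,
                                   [&](int x, int y) { return S.mpos[x] < S.mpos[y]; });
        h.insert(it, sweep_id);
      }
      sweep_planted = true;
      sweep_alive = true;
      traj.push_back((double)k / n_h);
    }

    // fitness weights for the sweep population (distribution built once
    // per generation; per-draw construction would be O(N) each)
    std::vector<double> wts;
    std::discrete_distribution<int> sel_draw;
    int tp = sweep_pop - 1;
    bool selecting = sweep_planted && sweep_alive && sel_s != 0.0;
    if (selecting) {
      int N = (int)pop[tp].size() / 2;
      wts.assign(N, 1.0);
      for (int i = 0; i < N; ++i) {
        int cnt = (carries(pop[tp][2 * i], sweep_id, S.mpos) ? 1 : 0) +
                  (carries(pop[tp][2 * i + 1], sweep_id, S.mpos) ? 1 : 0);
        wts[i] = cnt == 2 ? 1.0 + sel_s : (cnt == 1 ? 1.0 + sel_h * sel_s : 1.0);
      }
      sel_draw = std::discrete_distribution<int>(wts.begin(), wts.end());
    }

    std::vector<std::vector<Hap>> nxt(n_pops);
    for (int d = 0; d < n_pops; ++d) {
      int founding = (split_gen[d] == g);
      if (founding) {
        for (int e = 0; e < epoch_pop.size(); ++e)
          if (epoch_pop[e] - 1 == d && epoch_gen[e] == g) cur_size[d] = epoch_size[e];
        if (cur_size[d] < 2) stop("split population needs an epoch at its split generation");
      }
      if (cur_size[d] == 0 || split_gen[d] > g) continue;
      int N = cur_size[d];
      nxt[d].assign(2 * N, Hap());
      std::uniform_real_distribution<double> u01(0.0, 1.0);
      for (int c = 0; c < N; ++c) {
        for (int side = 0; side < 2; ++side) {
          // choose source population (founding pop draws from its parent)
          int s = d;
          if (founding) {
            s = origin[d] - 1;
          } else {
            double u = u01(S.rng), acc = 0.0;
            for (int q = 0; q < n_pops; ++q) {
              if (q == d || pop[q].empty()) continue;
              acc += migration(d, q);
              if (u < acc) { s = q; break; }
            }
          }
          if (pop[s].empty()) s = d;
          int Ns = (int)pop[s].size() / 2;
          int par;
          if (selecting && s == tp) {
            par = sel_draw(S.rng);
          } else {
            std::uniform_int_distribution<int> ui(0, Ns - 1);
            par = ui(S.rng);
          }
          S.gamete(pop[s][2 * par], pop[s][2 * par + 1], rec_mean,
                   nxt[d][2 * c + side]);
          S.mutate(nxt[d][2 * c + side], mut_mean);
        }
      }
    }
    pop.swap(nxt);

    if (sweep_planted && sweep_alive) {
      double f = pop_freq(tp);
      traj.push_back(f);
      if (f <= 0.0) {
        sweep_alive = false;
        outcome = "sweep_lost";
        if (stop_at_absorption) { end_gen = g; break; }
      } else if (stop_at_absorption && f >= 1.0) {
        outcome = "sweep_fixed";
        end_gen = g;
        break;
      } else if (stop_freq > 0 && f >= stop_freq) {
        outcome = "sweep_reached";
        end_gen = g;
        break;
      }
    }

    // purge mutations fixed in every haplotype (no longer segregating)
    if (g % 32 == 0 && !S.mpos.empty()) {
      std::vector<int> cnt(S.mpos.size(), 0);
      long H = 0;
      for (int p = 0; p < n_pops; ++p)
        for (const Hap &h : pop[p]) {
          ++H;
          for (int id : h) ++cnt[id];
        }
      std::vector<char> fixed(S.mpos.size(), 0);
      bool any = false;
      for (size_t id = 0; id < cnt.size(); ++id)
        if (cnt[id] == H && (int)id != sweep_id) { fixed[id] = 1; any = true; }
      if (any)
        for (int p = 0; p < n_pops; ++p)
          for (Hap &h : pop[p])
            h.erase(std::remove_if(h.begin(), h.end(),
                                   [&](int id) { return fixed[id]; }),
                    h.end());
    }
  }

  if (sweep_planted && sweep_alive && outcome == "none")
    outcome = traj.empty() ? "none" : "sweep_segregating";

  // ---- sample panel ----
  std::vector<const Hap *> samp;
  std::vector<int> samp_pop;
  for (int p = 0; p < n_pops; ++p) {
    int k = p < sample_sizes.size() ? sample_sizes[p] : 0;
    if (k == 0) continue;
    if ((int)pop[p].size() < 2 * k) stop("sample size exceeds population size");
    for (int i = 0; i < 2 * k; ++i) {
      samp.push_back(&pop[p][i]);
      samp_pop.push_back(p + 1);
    }
  }
  int H = (int)samp.size();

  // segregating sites within the sample
  std::unordered_map<int, int> count;
  for (const Hap *h : samp)
    for (int id : *h) ++count[id];
  std::vector<int> ids;
  for (auto &kv : count)
    if (kv.second > 0 && kv.second < H) ids.push_back(kv.first);
  std::sort(ids.begin(), ids.end(),
            [&](int a, int b) { return S.mpos[a] < S.mpos[b]; });
  int Ssites = (int)ids.size();

  IntegerMatrix mat(H, Ssites);
  std::unordered_map<int, int> col;
  for (int j = 0; j < Ssites; ++j) col[ids[j]] = j;
  for (int i = 0; i < H; ++i)
    for (int id : *samp[i]) {
      auto it = col.find(id);
      if (it != col.end()) mat(i, it->second) = 1;
    }

  NumericVector posn(Ssites);
  double prev = 0;
  for (int j = 0; j < Ssites; ++j) {
    double p = std::floor(S.mpos[ids[j]]) + 1.0;
    if (p <= prev) p = prev + 1.0;
    posn[j] = p;
    prev = p;
  }

  double final_freq = NA_REAL;
  int sweep_col = NA_INTEGER;
  if (sweep_planted) {
    int c = 0;
    for (const Hap *h : samp) c += carries(*h, sweep_id, S.mpos) ? 1 : 0;
    final_freq = traj.empty() ? NA_REAL : traj.back();
    auto it = col.find(sweep_id);
    if (it != col.end()) sweep_col = it->second + 1;
  }

  return List::create(_["haps"] = mat, _["positions"] = posn,
                      _["pop"] = IntegerVector(samp_pop.begin(), samp_pop.end()),
                      _["trajectory"] = NumericVector(traj.begin(), traj.end()),
                      _["outcome"] = outcome, _["final_freq"] = final_freq,
                      _["sweep_site"] = sweep_col, _["end_gen"] = end_gen);
}
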