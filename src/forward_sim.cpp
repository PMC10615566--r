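#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Haplotypes are stored site-major (L sites x n haplotype columns) so one
// gamete is a contiguous column and recombinant copying is cache-friendly.

// Copy a recombinant gamete from parent haplotype columns h1/h2 of `src`
// into column `col` of `dst`. `switches` holds 0-based site indices at which
// the template strand flips (sorted); `start` selects the first strand.
static void copy_gamete(const int* src, int L, int h1, int h2,
                        const std::vector<int>& switches, int start,
                        int* dst, int col) {
  const int* p1 = src + (size_t) h1 * L;
  const int* p2 = src + (size_t) h2 * L;
  int* out = dst + (size_t) col * L;
  int cur = start;
  int from = 0;
  size_t k = 0;
  while (from < L) {
    int to = (k < switches.size()) ? switches[k] : L;
    const int* p = (cur == 0) ? p1 : p2;
    std::copy(p + from, p + to, out + from);
    from = to;
    cur = 1 - cur;
    ++k;
  }
}

// Crossover site switches for one meiosis: Poisson number of crossovers with
// mean chrom_len_cM / 100, positions uniform on the cM map.
static void draw_switches(const NumericVector& cm, double chrom_len_cm,
                          std::vector<int>& switches) {
  switches.clear();
  int k = (int) R::rpois(chrom_len_cm / 100.0);
  if (k <= 0) return;
  for (int i = 0; i < k; ++i) {
    double pos = R::runif(0.0, chrom_len_cm);
    int j = (int) (std::lower_bound(cm.begin(), cm.end(), pos) - cm.begin());
    if (j > 0 && j < cm.size()) switches.push_back(j);
  }
  std::sort(switches.begin(), switches.end());
  switches.erase(std::unique(switches.begin(), switches.end()),
                 switches.end());
}

// Sample one diploid index from [lo, hi) using cumulative fitness weights.
static int sample_parent(const std::vector<double>& cum, int lo, int hi) {
  double base = (lo > 0 ? cum[lo - 1] : 0.0);
  double u = R::runif(0.0, cum[hi - 1] - base);
  int l = lo, r = hi - 1;
  while (l < r) {
    int m = (l + r) / 2;
    if (cum[m] - base > u) r = m; else l = m + 1;
  }
  return l;
}

// Forward Wright-Fisher simulation of one chromosome (see R docs of
// simulate_panel for the model). `founders` is site-major: L x n_founders.
// Returns a site-major haplotype matrix (L x 4*pop_size; two columns per
// diploid, pop 1 then pop 2) and optionally the founder-ancestry matrix.
// [[Rcpp::export]]
List cpp_forward_sim(IntegerMatrix founders, NumericVector cm,
                     int pop_size, int n_burnin, int split_gen,
                     double migration, int sweep_idx, double s,
                     int sweep_start, bool sweep_pop1, bool sweep_pop2,
                     bool track_ancestry) {
  const int L = founders.nrow();
  const int n_founders = founders.ncol();
  const int n_dip = 2 * pop_size;
  const int n_hap = 2 * n_dip;
  const double chrom_len_cm = cm[L - 1];
  const int T = n_burnin + split_gen;

  IntegerMatrix cur(L, n_hap), nxt(L, n_hap);
  IntegerMatrix anc_cur(track_ancestry ? L : 1, track_ancestry ? n_hap : 1);
  IntegerMatrix anc_nxt(track_ancestry ? L : 1, track_ancestry ? n_hap : 1);

  std::vector<int> switches;
  std::vector<int> fanc;
  if (track_ancestry) {
    fanc.resize((size_t) L * n_founders);
    for (int f = 0; f < n_founders; ++f)
      std::fill(fanc.begin() + (size_t) f * L,
                fanc.begin() + (size_t) (f + 1) * L, f);
  }

  // generation 0: each gamete recombines two random founder haplotypes
  for (int h = 0; h < n_hap; ++h) {
    int f1 = std::min((int) (R::unif_rand() * n_founders), n_founders - 1);
    int f2 = std::min((int) (R::unif_rand() * n_founders), n_founders - 1);
    draw_switches(cm, chrom_len_cm, switches);
    int start = (R::unif_rand() < 0.5) ? 0 : 1;
    copy_gamete(founders.begin(), L, f1, f2, switches, start,
                cur.begin(), h);
    if (track_ancestry)
      copy_gamete(fanc.data(), L, f1, f2, switches, start,
                  anc_cur.begin(), h);
  }

  std::vector<double> cum(n_dip);

  for (int t = 1; t <= T; ++t) {
    const int gens_left = T - t;       // generations before present after step
    const bool split_now = gens_left < split_gen;
    const bool sweep_now = (sweep_idx >= 0) && (s > 0.0) &&
                           (gens_left < sweep_start);

    double acc = 0.0;
    for (int d = 0; d < n_dip; ++d) {
      double w = 1.0;
      bool in_pop1 = d < pop_size;
      bool targeted = !split_now ? (sweep_pop1 || sweep_pop2)
                                 : (in_pop1 ? sweep_pop1 : sweep_pop2);
      if (sweep_now && targeted) {
        int dose = cur(sweep_idx, 2 * d) + cur(sweep_idx, 2 * d + 1);
        w = std::pow(1.0 + s, dose);
      }
      acc += w;
      cum[d] = acc;
    }

    for (int d = 0; d < n_dip; ++d) {
      int lo = 0, hi = n_dip, olo = 0, ohi = n_dip;
      if (split_now) {
        if (d < pop_size) { lo = 0; hi = pop_size; olo = pop_size; ohi = n_dip; }
        else             { lo = pop_size; hi = n_dip; olo = 0; ohi = pop_size; }
      }
      for (int g = 0; g < 2; ++g) {
        int plo = lo, phi = hi;
        if (split_now && migration > 0.0 && R::unif_rand() < migration) {
          plo = olo; phi = ohi;
        }
        int p = sample_parent(cum, plo, phi);
        draw_switches(cm, chrom_len_cm, switches);
        int start = (R::unif_rand() < 0.5) ? 0 : 1;
        copy_gamete(cur.begin(), L, 2 * p, 2 * p + 1, switches, start,
                    nxt.begin(), 2 * d + g);
        if (track_ancestry)
          copy_gamete(anc_cur.begin(), L, 2 * p, 2 * p + 1, switches, start,
                      anc_nxt.begin(), 2 * d + g);
      }
    }
    std::swap(cur, nxt);
    if (track_ancestry) std::swap(anc_cur, anc_nxt);
  }

  List out = List::create(_["haplotypes"] = cur);
  if (track_ancestry) out["ancestry"] = anc_cur;
  return out;
}

// Maximal runs where two ancestry columns carry the same founder id: the
// simulator's ground-truth IBD tracts (since founding). `anc` is site-major.
// [[Rcpp::export]]
DataFrame cpp_shared_ancestry_segments(IntegerMatrix anc, NumericVector cm,
                                       IntegerVector pair_i, IntegerVector pair_j,
                                       double min_cm) {
  const int L = anc.nrow();
  std::vector<int> oi, oj;
  std::vector<double> ostart, oend;
  for (int p = 0; p < pair_i.size(); ++p) {
    const int* a = anc.begin() + (size_t) pair_i[p] * L;
    const int* b = anc.begin() + (size_t) pair_j[p] * L;
    int run = -1;
    for (int j = 0; j <= L; ++j) {
      bool same = (j < L) && (a[j] == b[j]);
      if (same && run < 0) run = j;
      if (!same && run >= 0) {
        double len = cm[j - 1] - cm[run];
        if (len >= min_cm) {
          oi.push_back(pair_i[p] + 1); oj.push_back(pair_j[p] + 1);
          ostart.push_back(cm[run]); oend.push_back(cm[j - 1]);
        }
        run = -1;
      }
    }
  }
  return DataFrame::create(_["hap_i"] = oi, _["hap_j"] = oj,
                           _["start_cM"] = ostart, _["end_cM"] = oend);
}
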