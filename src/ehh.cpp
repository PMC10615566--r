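#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double choose2(double n) { return n * (n - 1.0) / 2.0; }

// Scratch buffers reused across cores to avoid per-marker allocation.
struct EhhWork {
  std::vector<int> group, newid, size, car;
  void reserve(int n) {
    group.resize(n);
    newid.resize(2 * n);
    size.resize(n);
  }
};

// One-sided EHH walk from a core over the carrier set, refining haplotype
// groups marker by marker. Returns the integrated haplotype homozygosity
// (trapezoid over cM, stopping at the first marker with EHH < cutoff, that
// marker's trapezoid included) and sets `edge` when the chromosome end is
// reached while EHH is still >= cutoff. With cutoff <= 0 the walk records
// the whole decay curve instead (used for EHH curves).
static double ehh_walk(const IntegerMatrix& hap, EhhWork& w,
                       int core, int dir, double cutoff,
                       const NumericVector& cm, bool& edge,
                       std::vector<double>* curve_cm,
                       std::vector<double>* curve_ehh) {
  const int n = (int) w.car.size();
  const int nrow = hap.nrow();
  const int L = hap.ncol();
  const double denom = choose2((double) n);
  std::fill(w.group.begin(), w.group.begin() + n, 0);
  int n_groups = 1;
  double ihh = 0.0, prev_ehh = 1.0;
  double prev_cm = cm[core];
  edge = false;

  int j = core + dir;
  while (j >= 0 && j < L) {
    const int* col = hap.begin() + (size_t) j * nrow;
    std::fill(w.newid.begin(), w.newid.begin() + 2 * n_groups, -1);
    int next = 0;
    for (int i = 0; i < n; ++i) {
      int key = 2 * w.group[i] + (col[w.car[i]] ? 1 : 0);
      if (w.newid[key] < 0) { w.newid[key] = next; w.size[next] = 0; ++next; }
      w.group[i] = w.newid[key];
      w.size[w.group[i]] += 1;
    }
    n_groups = next;
    double num = 0.0;
    for (int g = 0; g < n_groups; ++g) num += choose2((double) w.size[g]);
    double ehh = num / denom;
    ihh += 0.5 * (prev_ehh + ehh) * std::abs(cm[j] - prev_cm);
    if (curve_cm) {
      curve_cm->push_back(dir * std::abs(cm[j] - cm[core]));
      curve_ehh->push_back(ehh);
    }
    if (cutoff > 0.0 && ehh < cutoff) return ihh;
    if (ehh <= 0.0) return ihh;     // fully fragmented: nothing further
    prev_ehh = ehh;
    prev_cm = cm[j];
    j += dir;
  }
  edge = (cutoff > 0.0 && prev_ehh >= cutoff);
  return ihh;
}

static void carriers_of(const IntegerMatrix& hap, int core, int allele,
                        std::vector<int>& car) {
  const int nrow = hap.nrow();
  const int* col = hap.begin() + (size_t) core * nrow;
  car.clear();
  for (int r = 0; r < nrow; ++r)
    if (col[r] == allele) car.push_back(r);
}

// iHS scan core: per requested core variant, integrated EHH over ancestral
// (0) and derived (1) carriers, with undefined / edge-truncation flags.
// `hap` is haplotype-major (rows = haplotypes, columns = variants).
// [[Rcpp::export]]
DataFrame cpp_ihs_scan(IntegerMatrix hap, NumericVector cm,
                       IntegerVector cores, double cutoff) {
  const int m = cores.size();
  NumericVector ihh_a(m), ihh_d(m);
  LogicalVector edge(m), undef(m);
  EhhWork w;
  w.reserve(hap.nrow());
  for (int k = 0; k < m; ++k) {
    const int core = cores[k];
    bool e = false, any_edge = false, bad = false;
    double vals[2] = {0.0, 0.0};
    for (int allele = 0; allele <= 1; ++allele) {
      carriers_of(hap, core, allele, w.car);
      if (w.car.size() < 2) { bad = true; vals[allele] = NA_REAL; continue; }
      double left = ehh_walk(hap, w, core, -1, cutoff, cm, e, nullptr, nullptr);
      any_edge = any_edge || e;
      double right = ehh_walk(hap, w, core, +1, cutoff, cm, e, nullptr, nullptr);
      any_edge = any_edge || e;
      vals[allele] = left + right;
    }
    ihh_a[k] = vals[0];
    ihh_d[k] = vals[1];
    edge[k] = any_edge;
    undef[k] = bad || vals[0] == 0.0 || vals[1] == 0.0;
  }
  return DataFrame::create(_["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                           _["edge_truncated"] = edge, _["undefined"] = undef);
}

// Full EHH decay curve (both directions) for one core allele; no cutoff.
// [[Rcpp::export]]
DataFrame cpp_ehh_curve(IntegerMatrix hap, NumericVector cm, int core,
                        int allele) {
  EhhWork w;
  w.reserve(hap.nrow());
  carriers_of(hap, core, allele, w.car);
  if (w.car.size() < 2) stop("fewer than 2 carrier haplotypes at the core");
  bool e;
  std::vector<double> lcm, lehh, rcm, rehh;
  ehh_walk(hap, w, core, -1, -1.0, cm, e, &lcm, &lehh);
  carriers_of(hap, core, allele, w.car);
  ehh_walk(hap, w, core, +1, -1.0, cm, e, &rcm, &rehh);
  std::vector<double> dist, ehh;
  for (int i = (int) lcm.size() - 1; i >= 0; --i) {
    dist.push_back(lcm[i]); ehh.push_back(lehh[i]);
  }
  dist.push_back(0.0); ehh.push_back(1.0);
  for (size_t i = 0; i < rcm.size(); ++i) {
    dist.push_back(rcm[i]); ehh.push_back(rehh[i]);
  }
  return DataFrame::create(_["distance_cM"] = dist, _["ehh"] = ehh);
}
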