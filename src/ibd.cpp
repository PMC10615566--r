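#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pairwise IBD segment scan over phased haplotypes.
//
// For each haplotype pair: maximal runs of exact allele identity of at least
// `seed_snps` markers become seeds. Each seed is extended outward one
// mismatch at a time: a step crosses the next mismatching site and runs to
// the end of the following exact-match run; it is accepted when the step's
// marginal mismatch density (1 mismatch / cM spanned by the step) does not
// exceed `max_mismatch_per_cm`. Overlapping or touching extended segments of
// a pair are merged. Segments shorter than `min_cm` are dropped. Quality is
// the fraction of matching markers inside the reported segment.
// `hap` is site-major (rows = variants, columns = haplotypes) so each
// haplotype is contiguous.
// [[Rcpp::export]]
DataFrame cpp_detect_ibd(IntegerMatrix hap, NumericVector cm,
                         IntegerVector pair_i, IntegerVector pair_j,
                         double min_cm, double max_mismatch_per_cm,
                         int seed_snps) {
  const int L = hap.nrow();
  std::vector<int> oi, oj, ostart, oend;
  std::vector<double> oquality;

  std::vector<int> mism;            // mismatch column indices for the pair
  mism.reserve(L + 2);

  for (int p = 0; p < pair_i.size(); ++p) {
    const int* a = hap.begin() + (size_t) pair_i[p] * L;
    const int* b = hap.begin() + (size_t) pair_j[p] * L;
    mism.clear();
    mism.push_back(-1);                       // sentinels
    for (int j = 0; j < L; ++j)
      if (a[j] != b[j]) mism.push_back(j);
    mism.push_back(L);
    const int M = (int) mism.size();

    // candidate segments as [start_col, end_col] with mismatch bookkeeping
    std::vector<int> seg_s, seg_e, seg_nm;

    for (int k = 0; k + 1 < M; ++k) {
      int run_s = mism[k] + 1;
      int run_e = mism[k + 1] - 1;
      if (run_e - run_s + 1 < seed_snps) continue;

      int s = run_s, e = run_e, nm = 0;
      int kl = k, kr = k + 1;                 // flanking mismatch indices
      bool grew = true;
      while (grew) {
        grew = false;
        // extend right through mismatch at mism[kr]
        if (kr + 1 < M) {
          int ne = mism[kr + 1] - 1;          // end of following match run
          if (ne > mism[kr]) {                // run non-empty
            double dcm = cm[ne] - cm[e];
            if (dcm > 0.0 && 1.0 / dcm <= max_mismatch_per_cm) {
              e = ne; nm += 1; kr += 1; grew = true;
            }
          }
        }
        // extend left through mismatch at mism[kl]
        if (kl > 0) {
          int ns = mism[kl - 1] + 1;
          if (ns < mism[kl]) {
            double dcm = cm[s] - cm[ns];
            if (dcm > 0.0 && 1.0 / dcm <= max_mismatch_per_cm) {
              s = ns; nm += 1; kl -= 1; grew = true;
            }
          }
        }
      }
      // merge with previous candidate if overlapping/contiguous
      if (!seg_s.empty() && s <= seg_e.back() + 1) {
        if (e > seg_e.back()) {
          // recount mismatches of the union (cheap: unions are rare)
          int us = seg_s.back(), ue = e, unm = 0;
          for (int j = us; j <= ue; ++j)
            if (a[j] != b[j]) unm += 1;
          seg_e.back() = ue; seg_nm.back() = unm;
        }
      } else {
        seg_s.push_back(s); seg_e.push_back(e); seg_nm.push_back(nm);
      }
    }

    for (size_t q = 0; q < seg_s.size(); ++q) {
      double len = cm[seg_e[q]] - cm[seg_s[q]];
      if (len < min_cm) continue;
      int nsnp = seg_e[q] - seg_s[q] + 1;
      oi.push_back(pair_i[p] + 1); oj.push_back(pair_j[p] + 1);
      ostart.push_back(seg_s[q] + 1); oend.push_back(seg_e[q] + 1);
      oquality.push_back(1.0 - (double) seg_nm[q] / (double) nsnp);
    }
  }

  return DataFrame::create(_["hap_i"] = oi, _["hap_j"] = oj,
                           _["start_idx"] = ostart, _["end_idx"] = oend,
                           _["quality"] = oquality);
}
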