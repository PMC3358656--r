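#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive mismatch-bounded read mapping.
//
// For every (read, region) pair, scans all effective start positions of the
// region and records the minimum Hamming distance between the read and the
// window, provided it does not exceed max_mismatches. Positions are
// abandoned as soon as the running mismatch count exceeds the bound, which
// keeps the scan fast on divergent sequence.
//
// Returns a data frame of 1-based (read, region) index pairs with the
// minimum mismatch count for each accepted pair.

// [[Rcpp::export]]
DataFrame hamming_scan_cpp(CharacterVector reads, CharacterVector regions,
                           int max_mismatches) {
  const int n_reads = reads.size();
  const int n_regions = regions.size();
  std::vector<std::string> reg(n_regions);
  for (int k = 0; k < n_regions; ++k) reg[k] = as<std::string>(regions[k]);

  std::vector<int> out_read, out_region, out_mm;

  for (int j = 0; j < n_reads; ++j) {
    const std::string rd = as<std::string>(reads[j]);
    const int len = (int) rd.size();
    for (int k = 0; k < n_regions; ++k) {
      const std::string &g = reg[k];
      const int n_pos = (int) g.size() - len + 1;
      if (n_pos < 1) continue;
      int best = max_mismatches + 1;
      for (int s = 0; s < n_pos; ++s) {
        int mm = 0;
        const char *gp = g.data() + s;
        for (int b = 0; b < len; ++b) {
          if (rd[b] != gp[b]) {
            if (++mm >= best) break; // cannot improve on current best
          }
        }
        if (mm < best) {
          best = mm;
          if (best == 0) break; // perfect match; positions cannot beat it
        }
      }
      if (best <= max_mismatches) {
        out_read.push_back(j + 1);
        out_region.push_back(k + 1);
        out_mm.push_back(best);
      }
    }
    if (j % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(_["read"] = out_read,
                           _["region"] = out_region,
                           _["mismatches"] = out_mm);
}
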