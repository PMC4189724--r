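#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Window scanner for plant-style miRNA target scoring. Penalties: mismatch,
// G:U wobble, gap; doubled at seed-proximal miRNA positions. Mirrors the R
// reference scorer exactly; gapped windows report the best single gap.

static inline double pen(char m, char t, double mismatch, double gu) {
  switch (m) {
  case 'A': if (t == 'T') return 0.0; break;
  case 'C': if (t == 'G') return 0.0; break;
  case 'G': if (t == 'C') return 0.0; if (t == 'T') return gu; break;
  case 'T': if (t == 'A') return 0.0; if (t == 'G') return gu; break;
  }
  return mismatch;
}

// [[Rcpp::export(name = ".scan_targets_cpp")]]
DataFrame scan_targets_cpp(std::string mirna, std::string transcript,
                           double mismatch, double gu, double gap,
                           int dfrom, int dto, double cutoff,
                           bool gaps) {
  const int L = (int)mirna.size();
  const int n = (int)transcript.size();
  std::vector<double> wt(L + 1);
  for (int k = 1; k <= L; ++k) wt[k] = (k >= dfrom && k <= dto) ? 2.0 : 1.0;

  std::vector<int> starts, widths;
  std::vector<double> scores;

  // ungapped: miRNA position k faces transcript[o + L - k] (0-based o)
  for (int o = 0; o + L <= n; ++o) {
    double s = 0.0;
    for (int k = 1; k <= L && s <= cutoff; ++k) {
      s += pen(mirna[k - 1], transcript[o + L - k], mismatch, gu) * wt[k];
    }
    if (s <= cutoff) {
      starts.push_back(o + 1); widths.push_back(L); scores.push_back(s);
    }
  }
  if (gaps) {
    // one bulged target base: site width L+1, bulged site index b (1-based);
    // miRNA k faces site index L-k+1 (if < b) else L-k+2
    for (int o = 0; o + L + 1 <= n; ++o) {
      double best = R_PosInf;
      for (int b = 1; b <= L + 1; ++b) {
        int g = L + 2 - b;  // duplex position of the bulge
        double s = gap * wt[std::min(g, L)];
        for (int k = 1; k <= L && s <= best; ++k) {
          int f = (L - k + 1 < b) ? (L - k + 1) : (L - k + 2);
          s += pen(mirna[k - 1], transcript[o + f - 1], mismatch, gu) * wt[k];
        }
        if (s < best) best = s;
      }
      if (best <= cutoff) {
        starts.push_back(o + 1); widths.push_back(L + 1);
        scores.push_back(best);
      }
    }
    // one unpaired miRNA base g: site width L-1; miRNA k faces site index
    // L-k+1 (k > g) or L-k (k < g)
    for (int o = 0; o + L - 1 <= n; ++o) {
      double best = R_PosInf;
      for (int g = 1; g <= L; ++g) {
        double s = gap * wt[g];
        for (int k = 1; k <= L && s <= best; ++k) {
          if (k == g) continue;
          int f = (k > g) ? (L - k + 1) : (L - k);
          s += pen(mirna[k - 1], transcript[o + f - 1], mismatch, gu) * wt[k];
        }
        if (s < best) best = s;
      }
      if (best <= cutoff) {
        starts.push_back(o + 1); widths.push_back(L - 1);
        scores.push_back(best);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["width"] = widths,
                           _["score"] = scores);
}
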