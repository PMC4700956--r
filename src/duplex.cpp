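#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Expectation-scored miRNA/target duplex enumeration.  The miRNA is read
// 5'->3' (position 1..m); it pairs antiparallel against the target window,
// so miRNA position 1 faces the 3'-most base of the window.  Penalties:
// Watson-Crick match 0, G.U wobble w_gu, mismatch w_mm, gap w_gap; every
// per-position penalty is multiplied by seed_mult when the miRNA position
// lies in [seed_lo, seed_hi].  At most one gap per duplex:
//   gap_t: one miRNA position faces a gap (window is one base shorter);
//   gap_m: one unpaired target base is inserted between two miRNA
//          positions g and g+1 (window one base longer); its penalty is
//          indexed by the following miRNA position (g+1).

static inline bool wc_match(char m, char t) {
  // t is the target (mRNA sense) base the miRNA base pairs with
  switch (m) {
    case 'A': return t == 'T' || t == 'U';
    case 'C': return t == 'G';
    case 'G': return t == 'C';
    case 'T':
    case 'U': return t == 'A';
    default:  return false;
  }
}
static inline bool gu_wobble(char m, char t) {
  if (m == 'G' && (t == 'T' || t == 'U')) return true;
  if ((m == 'T' || m == 'U') && t == 'G') return true;
  return false;
}

struct Scorer {
  int seed_lo, seed_hi;
  double w_gu, w_mm, w_gap, seed_mult;
  inline double mult(int pos) const {
    return (pos >= seed_lo && pos <= seed_hi) ? seed_mult : 1.0;
  }
};

//' @noRd
// [[Rcpp::export(name = ".scan_duplexes_cpp")]]
DataFrame scan_duplexes_cpp(std::string mirna, std::string cds,
                            double max_expectation, int max_gaps,
                            int seed_lo, int seed_hi,
                            double w_gu, double w_mm, double w_gap,
                            double seed_mult) {
  int m = (int)mirna.size(), n = (int)cds.size();
  Scorer sc{seed_lo, seed_hi, w_gu, w_mm, w_gap, seed_mult};
  std::vector<int> r_start, r_end, r_gaps;
  std::vector<double> r_exp;
  std::vector<std::string> r_pair;

  // evaluate one alignment: columns described by (mir position, target idx)
  // tidx = -1 means gap on the target side (gap_t); mpos = 0 means an
  // inserted target base (gap_m) whose penalty index is given separately.
  // Returns penalty, fills pairing string (one char per column, miRNA 5'->3';
  // '|' match, 'o' G.U, 'x' mismatch, '-' gap_t, '^' gap_m insertion).

  // ungapped windows
  for (int s = 0; s + m <= n; ++s) {
    double pen = 0.0;
    std::string pairing(m, '?');
    for (int i = 1; i <= m; ++i) {
      char mb = mirna[i - 1];
      char tb = cds[s + m - i];        // antiparallel
      double p;
      char sym;
      if (wc_match(mb, tb)) { p = 0.0; sym = '|'; }
      else if (gu_wobble(mb, tb)) { p = w_gu; sym = 'o'; }
      else { p = w_mm; sym = 'x'; }
      pen += p * sc.mult(i);
      pairing[i - 1] = sym;
      if (pen > max_expectation) break;
    }
    if (pen <= max_expectation) {
      r_start.push_back(s); r_end.push_back(s + m);
      r_gaps.push_back(0); r_exp.push_back(pen); r_pair.push_back(pairing);
    }
  }

  if (max_gaps >= 1) {
    // gap_t: miRNA position g faces a gap; window length m-1
    for (int s = 0; s + (m - 1) <= n; ++s) {
      for (int g = 1; g <= m; ++g) {
        double pen = 0.0;
        std::string pairing(m, '?');
        int t = s + m - 2;             // 3'-most base of the window
        for (int i = 1; i <= m; ++i) {
          if (i == g) {
            pen += w_gap * sc.mult(i);
            pairing[i - 1] = '-';
            continue;
          }
          char mb = mirna[i - 1];
          char tb = cds[t--];
          double p; char sym;
          if (wc_match(mb, tb)) { p = 0.0; sym = '|'; }
          else if (gu_wobble(mb, tb)) { p = w_gu; sym = 'o'; }
          else { p = w_mm; sym = 'x'; }
          pen += p * sc.mult(i);
          pairing[i - 1] = sym;
          if (pen > max_expectation) break;
        }
        if (pen <= max_expectation) {
          r_start.push_back(s); r_end.push_back(s + m - 1);
          r_gaps.push_back(1); r_exp.push_back(pen); r_pair.push_back(pairing);
        }
      }
    }
    // gap_m: inserted target base after miRNA position g (1..m-1);
    // window length m+1
    for (int s = 0; s + (m + 1) <= n; ++s) {
      for (int g = 1; g <= m - 1; ++g) {
        double pen = 0.0;
        std::string pairing;
        pairing.reserve(m + 1);
        int t = s + m;                 // 3'-most base of the window
        for (int i = 1; i <= m; ++i) {
          char mb = mirna[i - 1];
          char tb = cds[t--];
          double p; char sym;
          if (wc_match(mb, tb)) { p = 0.0; sym = '|'; }
          else if (gu_wobble(mb, tb)) { p = w_gu; sym = 'o'; }
          else { p = w_mm; sym = 'x'; }
          pen += p * sc.mult(i);
          pairing.push_back(sym);
          if (i == g) {                // skip the inserted base
            pen += w_gap * sc.mult(g + 1);
            pairing.push_back('^');
            t--;
          }
          if (pen > max_expectation) break;
        }
        if (pen <= max_expectation) {
          r_start.push_back(s); r_end.push_back(s + m + 1);
          r_gaps.push_back(1); r_exp.push_back(pen); r_pair.push_back(pairing);
        }
      }
    }
  }

  return DataFrame::create(_["start"] = r_start, _["end"] = r_end,
                           _["n_gaps"] = r_gaps, _["expectation"] = r_exp,
                           _["pairing"] = r_pair,
                           _["stringsAsFactors"] = false);
}
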