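#include <Rcpp.h>
using namespace Rcpp;

// Minimum-energy nested (pseudoknot-free) RNA secondary structure under a
// simple per-pair energy model: each admissible base pair contributes a fixed
// energy (GC, AU, GU classes), hairpin loops must span >= min_loop unpaired
// bases, no stacking terms. O(n^3) interval DP with traceback to dot-bracket.

static inline double pair_e(char a, char b, double e_gc, double e_au,
                            double e_gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return e_gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return e_au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return e_gu;
  return 1.0; // not pairable: positive sentinel, never selected
}

// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq, double e_gc, double e_au, double e_gu,
                  int min_loop) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) {
    if (seq[i] == 'T') seq[i] = 'U';
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      stop("fold_mfe: non-ACGU character '%s' at position %d",
           std::string(1, c), i + 1);
  }
  // E[i][j]: min energy of subsequence i..j (0-based, inclusive)
  std::vector<std::vector<double>> E(n, std::vector<double>(n, 0.0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = E[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double pe = pair_e(seq[i], seq[k], e_gc, e_au, e_gu);
        if (pe > 0) continue;
        double cand = pe + (k - i > 1 ? E[i + 1][k - 1] : 0.0) +
                      (k < j ? E[k + 1][j] : 0.0);
        if (cand < best) best = cand;
      }
      E[i][j] = best;
    }
  }
  // traceback
  std::string db(n, '.');
  std::vector<std::pair<int, int>> stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  const double eps = 1e-9;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    if (std::abs(E[i][j] - E[i + 1][j]) < eps) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    bool placed = false;
    for (int k = i + min_loop + 1; k <= j && !placed; ++k) {
      double pe = pair_e(seq[i], seq[k], e_gc, e_au, e_gu);
      if (pe > 0) continue;
      double inner = (k - i > 1 ? E[i + 1][k - 1] : 0.0);
      double outer = (k < j ? E[k + 1][j] : 0.0);
      if (std::abs(E[i][j] - (pe + inner + outer)) < eps) {
        db[i] = '(';
        db[k] = ')';
        if (k - i > 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        placed = true;
      }
    }
    if (!placed) stack.push_back(std::make_pair(i + 1, j)); // numeric fallback
  }
  double mfe = (n > 0) ? E[0][n - 1] : 0.0;
  return List::create(Named("structure") = db, Named("mfe") = mfe);
}

// Minimum-penalty gapped alignment of a miRNA against a site, used by the
// target-site scanner for candidate windows. Penalties: mismatch 1, G:U
// wobble 0.5, gap 2; all doubled at miRNA positions in [w_lo, w_hi] (1-based
// from the miRNA 5' end). States: (i over miRNA, j over revcomp(site), g gaps
// used). Returns the minimal total penalty for aligning the full miRNA to the
// full site with at most max_gap gaps.
// mir and s are integer-coded: A=0, C=1, G=2, U/T=3.
// workspace-based DP over states (gap count g, miRNA prefix i, site prefix
// j); `work` must hold (max_gap+1)*(L+1)*(Ls+1) doubles
static double align_penalty_core(const int *mir, int L, const int *s, int Ls,
                                 int w_lo, int w_hi, int max_gap,
                                 std::vector<double> &work) {
  const double INF = 1e18;
  if (std::abs(L - Ls) > max_gap) return INF;
  int si = Ls + 1, gi = (L + 1) * (Ls + 1);
  size_t need = (size_t)(max_gap + 1) * gi;
  if (work.size() < need) work.resize(need);
  std::fill(work.begin(), work.begin() + need, INF);
  double *dp = work.data();
  for (int g = 0; g <= max_gap; ++g) dp[g * gi] = 0.0;
  for (int g = 0; g <= max_gap; ++g) {
    double *d = dp + g * gi;
    double *dn = (g < max_gap) ? dp + (g + 1) * gi : nullptr;
    for (int i = 0; i <= L; ++i) {
      double w = (i + 1 >= w_lo && i + 1 <= w_hi) ? 2.0 : 1.0;
      for (int j = 0; j <= Ls; ++j) {
        double cur = d[i * si + j];
        if (cur >= INF) continue;
        if (i < L && j < Ls) {
          int a = mir[i], b = s[j];
          double pen;
          if (a == b) pen = 0.0;                     // complementary
          else if ((a == 2 && b == 0) || (a == 3 && b == 1)) pen = 0.5 * w; // G:U
          else pen = 1.0 * w;
          double &tgt = d[(i + 1) * si + (j + 1)];
          if (cur + pen < tgt) tgt = cur + pen;
        }
        if (dn) {
          if (i < L && cur + 2.0 * w < dn[(i + 1) * si + j])
            dn[(i + 1) * si + j] = cur + 2.0 * w; // miRNA base bulged
          if (j < Ls && cur + 2.0 * w < dn[i * si + (j + 1)])
            dn[i * si + (j + 1)] = cur + 2.0 * w; // site base bulged
        }
      }
    }
  }
  double best = INF;
  for (int g = 0; g <= max_gap; ++g) best = std::min(best, dp[g * gi + L * si + Ls]);
  return best;
}

// [[Rcpp::export]]
double align_penalty_cpp(IntegerVector mir, IntegerVector s, int w_lo,
                         int w_hi, int max_gap) {
  std::vector<double> work;
  double r = align_penalty_core(INTEGER(mir), mir.size(), INTEGER(s), s.size(),
                                w_lo, w_hi, max_gap, work);
  return r >= 1e17 ? R_PosInf : r;
}

// Scan one transcript for candidate binding windows of one miRNA: all start
// positions and site lengths within max_gap of the miRNA length. Reports
// windows whose optimal weighted penalty or optimal raw (un-doubled) penalty
// falls under the respective ceiling. tx is integer-coded ALREADY
// reverse-complemented per-base (i.e. tx[j] is the coded complement of the
// transcript base at j), so equality means Watson-Crick pairing; windows are
// still indexed on the plus strand of the transcript.
// [[Rcpp::export]]
DataFrame scan_targets_cpp(IntegerVector mir, IntegerVector tx_comp, int w_lo,
                           int w_hi, int max_gap, double max_weighted,
                           double max_raw) {
  int L = mir.size(), n = tx_comp.size();
  std::vector<int> starts, lens;
  std::vector<double> weighted, raw;
  std::vector<double> work;
  std::vector<int> m(L), site;
  for (int i = 0; i < L; ++i) m[i] = mir[i];
  // miRNA 5' end pairs the 3' side of the site on the transcript plus
  // strand: align the miRNA against the reversed complemented window.
  for (int sl = L - max_gap; sl <= L + max_gap; ++sl) {
    if (sl < 1) continue;
    site.resize(sl);
    for (int st = 0; st + sl <= n; ++st) {
      for (int j = 0; j < sl; ++j) site[j] = tx_comp[st + sl - 1 - j];
      double w = align_penalty_core(m.data(), L, site.data(), sl, w_lo, w_hi,
                                    max_gap, work);
      double r = align_penalty_core(m.data(), L, site.data(), sl, 1, 0,
                                    max_gap, work);
      if (w <= max_weighted || r <= max_raw) {
        starts.push_back(st + 1);
        lens.push_back(sl);
        weighted.push_back(w);
        raw.push_back(r);
      }
    }
  }
  return DataFrame::create(Named("start") = starts, Named("site_len") = lens,
                           Named("weighted") = weighted, Named("raw") = raw);
}
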