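// Exhaustive alignment scorers by explicit enumeration of all monotone
// alignment paths. Exponential in the sequence lengths, intended as an
// exact reference for short sequences; the dynamic-programming aligners in
// R/alignment.R are the production implementation.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// move codes for gap bookkeeping: 1 = gap in t (consume s), 2 = gap in s
enum Move { NONE = 0, UP = 1, LEFT = 2 };

struct Enumerator {
  const int *s, *t;
  int ns, nt;
  double m, n;                 // match / mismatch values
  std::vector<double> ggaps;   // global gap values
  double lg, sg;               // local gap, semiglobal gap
  std::vector<double> bestG;
  double bestL, bestS;

  // state carried along a path:
  //   diagsum: sum of match/mismatch values over diagonal columns
  //   z: total gap columns
  //   lead_*: initial single-type gap run (free end gaps, semiglobal)
  //   trail_*: current trailing single-type gap run
  //   kad_end / kad_best: Kadane running maxima of the per-column local
  //     score (empty segment = 0), giving the best local alignment that is
  //     a contiguous sub-path of this path
  void walk(int i, int j, double diagsum, int z,
            bool lead_active, int lead_type, int lead_len,
            int trail_type, int trail_len,
            double kad_end, double kad_best) {
    if (i == ns && j == nt) {
      for (size_t k = 0; k < ggaps.size(); ++k) {
        double sc = diagsum + z * ggaps[k];
        if (sc > bestG[k]) bestG[k] = sc;
      }
      int z_int = z - lead_len - trail_len;
      double ssc = diagsum + z_int * sg;
      if (ssc > bestS) bestS = ssc;
      if (kad_best > bestL) bestL = kad_best;
      return;
    }
    if (i < ns && j < nt) {  // diagonal
      double sub = (s[i] == t[j]) ? m : n;
      double ke = kad_end + sub; if (ke < 0) ke = 0;
      double kb = (ke > kad_best) ? ke : kad_best;
      walk(i + 1, j + 1, diagsum + sub, z,
           false, lead_type, lead_len, NONE, 0, ke, kb);
    }
    for (int mv = UP; mv <= LEFT; ++mv) {
      if (mv == UP && i >= ns) continue;
      if (mv == LEFT && j >= nt) continue;
      bool la = lead_active;
      int lt = lead_type, ll = lead_len;
      if (la) {
        if (lt == NONE) { lt = mv; ll = 1; }
        else if (lt == mv) { ll += 1; }
        else { la = false; }
      }
      int tt, tl;
      if (trail_type == mv) { tt = mv; tl = trail_len + 1; }
      else { tt = mv; tl = 1; }
      double ke = kad_end + lg; if (ke < 0) ke = 0;
      double kb = (ke > kad_best) ? ke : kad_best;
      walk(i + (mv == UP), j + (mv == LEFT), diagsum, z + 1,
           la, lt, ll, tt, tl, ke, kb);
    }
  }
};

struct GlobalMatches {
  const int *s, *t;
  int ns, nt;
  double m, n, g;
  double best;
  int best_x;

  void walk(int i, int j, double score, int x) {
    if (i == ns && j == nt) {
      if (score > best || (score == best && x > best_x)) {
        if (score > best) { best = score; best_x = x; }
        else best_x = x;
      }
      return;
    }
    if (i < ns && j < nt) {
      bool eq = (s[i] == t[j]);
      walk(i + 1, j + 1, score + (eq ? m : n), x + (eq ? 1 : 0));
    }
    if (i < ns) walk(i + 1, j, score + g, x);
    if (j < nt) walk(i, j + 1, score + g, x);
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector bf_all_scores_cpp(IntegerVector s, IntegerVector t,
                                double match_value, double mismatch_value,
                                NumericVector global_gaps,
                                double local_gap, double semiglobal_gap) {
  Enumerator e;
  e.s = INTEGER(s); e.t = INTEGER(t);
  e.ns = s.size(); e.nt = t.size();
  e.m = match_value; e.n = mismatch_value;
  e.ggaps = as<std::vector<double> >(global_gaps);
  e.lg = local_gap; e.sg = semiglobal_gap;
  e.bestG.assign(e.ggaps.size(), R_NegInf);
  e.bestL = 0.0;          // the empty local alignment
  e.bestS = R_NegInf;
  e.walk(0, 0, 0.0, 0, true, NONE, 0, NONE, 0, 0.0, 0.0);
  NumericVector out(e.ggaps.size() + 2);
  for (size_t k = 0; k < e.ggaps.size(); ++k) out[k] = e.bestG[k];
  out[e.ggaps.size()] = e.bestL;
  out[e.ggaps.size() + 1] = e.bestS;
  return out;
}

// [[Rcpp::export]]
NumericVector bf_global_best_cpp(IntegerVector s, IntegerVector t,
                                 double match_value, double mismatch_value,
                                 double gap_value) {
  GlobalMatches e;
  e.s = INTEGER(s); e.t = INTEGER(t);
  e.ns = s.size(); e.nt = t.size();
  e.m = match_value; e.n = mismatch_value; e.g = gap_value;
  e.best = R_NegInf; e.best_x = 0;
  e.walk(0, 0, 0.0, 0);
  return NumericVector::create(e.best, (double)e.best_x);
}
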