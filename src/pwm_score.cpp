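#include <Rcpp.h>
using namespace Rcpp;

// Sequences are encoded 1=A, 2=C, 3=G, 4=T, 0=ambiguous (N etc.).
// `odds` is a 4 x w matrix of per-position odds P(base)/pi(base).
// Ambiguous bases contribute an odds factor of 1.

static inline double window_sum(const int *s, int L, const NumericMatrix &odds,
                                bool revcomp) {
  const int w = odds.ncol();
  if (L < w) return NA_REAL;
  double total = 0.0;
  for (int start = 0; start <= L - w; ++start) {
    double prod = 1.0;
    for (int k = 0; k < w; ++k) {
      int base = s[start + k];
      if (base == 0) continue;
      if (revcomp) {
        // reading the reverse strand: position w-1-k of the motif,
        // complemented base (1<->4, 2<->3)
        prod *= odds(4 - base, w - 1 - k);
      } else {
        prod *= odds(base - 1, k);
      }
    }
    total += prod;
  }
  return total;
}

// Mean odds over all start positions on both strands.
// [[Rcpp::export]]
double cpp_pwm_affinity(IntegerVector seq, NumericMatrix odds) {
  const int L = seq.size();
  const int w = odds.ncol();
  if (L < w) stop("sequence shorter than motif width");
  double fwd = window_sum(INTEGER(seq), L, odds, false);
  double rev = window_sum(INTEGER(seq), L, odds, true);
  return (fwd + rev) / (2.0 * (L - w + 1));
}

// Affinity of every sequence against every motif: nseq x nmotif matrix.
// [[Rcpp::export]]
NumericMatrix cpp_pwm_affinity_matrix(List seqs, List odds_list) {
  const int ns = seqs.size();
  const int nm = odds_list.size();
  NumericMatrix out(ns, nm);
  std::vector<NumericMatrix> mats;
  mats.reserve(nm);
  for (int j = 0; j < nm; ++j) mats.push_back(as<NumericMatrix>(odds_list[j]));
  for (int i = 0; i < ns; ++i) {
    IntegerVector s = seqs[i];
    const int L = s.size();
    for (int j = 0; j < nm; ++j) {
      const NumericMatrix &odds = mats[j];
      const int w = odds.ncol();
      if (L < w) { out(i, j) = NA_REAL; continue; }
      double fwd = window_sum(INTEGER(s), L, odds, false);
      double rev = window_sum(INTEGER(s), L, odds, true);
      out(i, j) = (fwd + rev) / (2.0 * (L - w + 1));
    }
  }
  return out;
}

// Best single-window log-odds over both strands (used for presence calls).
// [[Rcpp::export]]
double cpp_pwm_best_logodds(IntegerVector seq, NumericMatrix odds) {
  const int L = seq.size();
  const int w = odds.ncol();
  if (L < w) stop("sequence shorter than motif width");
  double best = R_NegInf;
  const int *s = INTEGER(seq);
  for (int strand = 0; strand < 2; ++strand) {
    bool rc = strand == 1;
    for (int start = 0; start <= L - w; ++start) {
      double lo = 0.0;
      for (int k = 0; k < w; ++k) {
        int base = s[start + k];
        if (base == 0) continue;
        double o = rc ? odds(4 - base, w - 1 - k) : odds(base - 1, k);
        lo += std::log(o);
      }
      if (lo > best) best = lo;
    }
  }
  return best;
}

// Best-window log-odds of every sequence against every motif.
// [[Rcpp::export]]
NumericMatrix cpp_pwm_best_matrix(List seqs, List odds_list) {
  const int ns = seqs.size();
  const int nm = odds_list.size();
  NumericMatrix out(ns, nm);
  for (int i = 0; i < ns; ++i) {
    IntegerVector s = seqs[i];
    for (int j = 0; j < nm; ++j) {
      NumericMatrix odds = odds_list[j];
      if (s.size() < odds.ncol()) { out(i, j) = NA_REAL; continue; }
      out(i, j) = cpp_pwm_best_logodds(s, odds);
    }
  }
  return out;
}
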