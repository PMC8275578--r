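#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov DNA simulator with controlled CpG transition.
// From any state except C the next base is drawn from base_freqs
// (A, C, G, T); from C the probability of G is cg_prob (per gene, already
// calibrated and clipped by the caller) and the remaining mass is spread
// over A, C, T proportionally to base_freqs. Uses R's RNG, so set.seed()
// governs.
// [[Rcpp::export]]
CharacterVector markov_sequences(IntegerVector lengths,
                                 NumericVector cg_prob,
                                 NumericVector base_freqs) {
  const int n = lengths.size();
  if (cg_prob.size() != n)
    stop("lengths and cg_prob must have equal length");
  if (base_freqs.size() != 4)
    stop("base_freqs must have 4 entries (A, C, G, T)");
  const char bases[4] = {'A', 'C', 'G', 'T'};
  const double piA = base_freqs[0], piC = base_freqs[1],
               piG = base_freqs[2], piT = base_freqs[3];
  const double cum[4] = {piA, piA + piC, piA + piC + piG, 1.0};

  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    const double q = cg_prob[i];
    const double rest = 1.0 - q;
    const double denom = piA + piC + piT;
    const double cumC[4] = {rest * piA / denom,
                            rest * (piA + piC) / denom,
                            rest * (piA + piC) / denom + q,
                            1.0};
    const int len = lengths[i];
    std::string s(len, 'A');
    int prev = 0;
    for (int j = 0; j < len; ++j) {
      const double u = unif_rand();
      const double* cc = (j > 0 && prev == 1) ? cumC : cum;
      int b = 0;
      while (b < 3 && u > cc[b]) ++b;
      s[j] = bases[b];
      prev = b;
    }
    out[i] = s;
  }
  return out;
}
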