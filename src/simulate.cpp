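#include <Rcpp.h>
using namespace Rcpp;

// Core loop for simulating an iterated match between two memory-one
// strategies. States are 0..3 over (CC, CD, DC, DD) from player X's
// perspective. `qx` must already be reordered to X's perspective
// (i.e. qx[state] is Y's cooperation probability given that state).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".sim_match_cpp")]]
IntegerVector sim_match_cpp(NumericVector px, NumericVector qx,
                            double p0x, double p0y, int rounds) {
  if (px.size() != 4 || qx.size() != 4)
    stop("strategy vectors must have length 4");
  if (rounds < 1)
    stop("rounds must be >= 1");
  IntegerVector out(rounds);
  bool xc = unif_rand() < p0x;
  bool yc = unif_rand() < p0y;
  int state = (xc ? 0 : 2) + (yc ? 0 : 1);
  out[0] = state + 1;
  for (int t = 1; t < rounds; ++t) {
    xc = unif_rand() < px[state];
    yc = unif_rand() < qx[state];
    state = (xc ? 0 : 2) + (yc ? 0 : 1);
    out[t] = state + 1;
  }
  return out;
}

// Long-run outcome frequencies of the induced Markov chain, by direct
// simulation; used as the Monte-Carlo oracle against the stationary solve.
// [[Rcpp::export(name = ".sim_chain_freq_cpp")]]
NumericVector sim_chain_freq_cpp(NumericMatrix M, int start, int steps) {
  if (M.nrow() != 4 || M.ncol() != 4)
    stop("M must be 4x4");
  if (start < 1 || start > 4)
    stop("start must be in 1..4");
  NumericVector counts(4);
  int state = start - 1;
  for (int t = 0; t < steps; ++t) {
    counts[state] += 1.0;
    double u = unif_rand(), acc = 0.0;
    int next = 3;
    for (int j = 0; j < 4; ++j) {
      acc += M(state, j);
      if (u < acc) { next = j; break; }
    }
    state = next;
  }
  return counts / (double)steps;
}
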