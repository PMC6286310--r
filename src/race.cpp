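#include <Rcpp.h>
using namespace Rcpp;

// Mutation-race trials in a diploid genome of G genes (2G alleles),
// H of them hRPGs. Each raw mutation hits one allele uniformly with
// replacement; a repeat hit on an already-mutated allele is a no-op.
// Allele layout: alleles 2g and 2g+1 belong to gene g; genes 0..H-1 are
// hRPGs. A trial resolves HRPG_HET_FIRST (event 1) when any hRPG allele
// is first hit, HOMOZYGOUS_FIRST (event 2) when both alleles of any
// non-hRPG gene have been hit, or stays UNRESOLVED (event 0) if a finite
// mutation budget is exhausted first. Draws come from R's seeded RNG
// stream (RNGScope), so results are reproducible via set.seed().
// [[Rcpp::export]]
List race_trials_cpp(int G, int H, int reps, int budget) {
  if (G < 1) stop("config error: G must be >= 1");
  if (H < 0 || H > G) stop("config error: need 0 <= H <= G");
  if (reps < 1) stop("config error: reps must be >= 1");
  IntegerVector event(reps), used(reps);
  std::vector<unsigned char> hit(2 * (size_t)G);
  const double nAllele = 2.0 * G;
  for (int r = 0; r < reps; ++r) {
    std::fill(hit.begin(), hit.end(), 0);
    int ev = 0, m = 0;
    while (ev == 0) {
      if (budget > 0 && m >= budget) break;
      int a = (int)(unif_rand() * nAllele);
      if (a >= 2 * G) a = 2 * G - 1; // guard against unif_rand() == 1
      ++m;
      if (hit[a]) continue; // no-op repeat hit
      int g = a >> 1;
      if (g < H) {
        ev = 1; // first hRPG allele hit: heterozygous hRPG
      } else {
        hit[a] = 1;
        if (hit[a ^ 1]) ev = 2; // partner already mutated: homozygous
      }
    }
    event[r] = ev;
    used[r] = m;
  }
  return List::create(_["event"] = event, _["mutations"] = used);
}

// Disturbed-gene counts: drop M uniform allele hits (with replacement)
// on 2G alleles and count genes whose two distinct alleles were both
// hit, repeated `reps` times.
// [[Rcpp::export]]
IntegerVector disturbed_trials_cpp(int G, int M, int reps) {
  if (G < 1) stop("config error: G must be >= 1");
  if (M < 0) stop("config error: M must be >= 0");
  if (reps < 1) stop("config error: reps must be >= 1");
  IntegerVector out(reps);
  std::vector<unsigned char> hit(2 * (size_t)G);
  const double nAllele = 2.0 * G;
  for (int r = 0; r < reps; ++r) {
    std::fill(hit.begin(), hit.end(), 0);
    int disturbed = 0;
    for (int m = 0; m < M; ++m) {
      int a = (int)(unif_rand() * nAllele);
      if (a >= 2 * G) a = 2 * G - 1;
      if (hit[a]) continue;
      hit[a] = 1;
      if (hit[a ^ 1]) ++disturbed;
    }
    out[r] = disturbed;
  }
  return out;
}
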