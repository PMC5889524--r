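#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Forward Wright-Fisher simulation of 2N haplotypes at L biallelic loci.
// Haplotypes are stored as columns (loci x haplotypes) so that copying a
// parental haplotype is a contiguous memcpy. Each generation every offspring
// haplotype recombines two uniformly chosen parental haplotypes; the
// crossover count is Poisson in the map length (Morgans) with uniform
// positions. Uses R's RNG so set.seed() governs determinism.
// [[Rcpp::export]]
IntegerMatrix wf_sim_core(IntegerMatrix init, NumericVector pos_morgan,
                          int n_generations) {
  const int L = init.nrow();
  const int twoN = init.ncol();
  const double lo = pos_morgan[0];
  const double len = pos_morgan[L - 1] - lo;
  std::vector<int> cur(init.begin(), init.end());
  std::vector<int> nxt((size_t)L * twoN);
  std::vector<double> xpos;

  for (int g = 0; g < n_generations; ++g) {
    for (int i = 0; i < twoN; ++i) {
      int p1 = (int)(unif_rand() * twoN);
      if (p1 == twoN) p1 = twoN - 1;
      int nx = (len > 0) ? (int)R::rpois(len) : 0;
      int *dst = &nxt[(size_t)i * L];
      if (nx == 0) {
        std::memcpy(dst, &cur[(size_t)p1 * L], sizeof(int) * L);
      } else {
        int p2 = (int)(unif_rand() * twoN);
        if (p2 == twoN) p2 = twoN - 1;
        xpos.resize(nx);
        for (int k = 0; k < nx; ++k) xpos[k] = lo + unif_rand() * len;
        std::sort(xpos.begin(), xpos.end());
        const int *s1 = &cur[(size_t)p1 * L];
        const int *s2 = &cur[(size_t)p2 * L];
        int src = 0, k = 0;
        for (int l = 0; l < L; ++l) {
          while (k < nx && xpos[k] <= pos_morgan[l]) { src ^= 1; ++k; }
          dst[l] = src == 0 ? s1[l] : s2[l];
        }
      }
    }
    cur.swap(nxt);
  }
  IntegerMatrix out(L, twoN);
  std::copy(cur.begin(), cur.end(), out.begin());
  return out;
}
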