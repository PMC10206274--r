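#include <Rcpp.h>
using namespace Rcpp;

// Batch meiosis for one chromosome. H holds phased parental haplotypes with
// two consecutive rows per parent (rows 2p and 2p+1 for 0-based parent p).
// gpos gives locus genetic positions in Morgans (increasing); chr_len_M is
// the chromosome genetic length. Crossover count per meiosis is
// Poisson(chr_len_M), positions uniform on the genetic map, no interference,
// no mutation; the starting haplotype is chosen at random.
// [[Rcpp::export]]
IntegerMatrix meiosis_batch_cpp(IntegerMatrix H, NumericVector gpos,
                                double chr_len_M, IntegerVector parent_idx) {
  const int L = gpos.size();
  if (H.ncol() != L) stop("haplotype/locus length mismatch");
  const int G = parent_idx.size();
  IntegerMatrix out(G, L);
  std::vector<double> cx;
  for (int g = 0; g < G; ++g) {
    int p = parent_idx[g];
    if (p < 0 || 2 * p + 1 >= H.nrow()) stop("parent index out of range");
    int ncx = (int)R::rpois(chr_len_M);
    cx.resize(ncx);
    for (int i = 0; i < ncx; ++i) cx[i] = R::unif_rand() * chr_len_M;
    std::sort(cx.begin(), cx.end());
    int h = (R::unif_rand() < 0.5) ? 0 : 1;
    int nextc = 0;
    for (int l = 0; l < L; ++l) {
      while (nextc < ncx && cx[nextc] <= gpos[l]) { h = 1 - h; ++nextc; }
      out(g, l) = H(2 * p + h, l);
    }
  }
  return out;
}
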