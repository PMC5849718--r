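#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampling for LDA over a token table.
//
// State vectors use 0-based indices internally; the R wrappers convert.
// All randomness is drawn from R's RNG so set.seed() controls everything.

static inline void conditional(const int d, const int w,
                               const IntegerMatrix &ndk, const IntegerMatrix &nkw,
                               const IntegerVector &nk,
                               const double alpha, const double beta,
                               const int K, const int W, double *p) {
  for (int k = 0; k < K; ++k) {
    p[k] = (ndk(d, k) + alpha) * (nkw(k, w) + beta) / (nk[k] + W * beta);
  }
}

// One full sweep over the tokens in order; mutates the (cloned) state.
static void sweep_inplace(IntegerVector &z, const IntegerVector &doc,
                          const IntegerVector &word,
                          IntegerMatrix &ndk, IntegerMatrix &nkw,
                          IntegerVector &nk,
                          const double alpha, const double beta) {
  const int n = z.size(), K = nk.size(), W = nkw.ncol();
  std::vector<double> p(K);
  for (int i = 0; i < n; ++i) {
    const int d = doc[i], w = word[i], kold = z[i];
    ndk(d, kold)--; nkw(kold, w)--; nk[kold]--;
    conditional(d, w, ndk, nkw, nk, alpha, beta, K, W, p.data());
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += p[k];
    double u = unif_rand() * tot, cum = 0.0;
    int knew = K - 1;
    for (int k = 0; k < K; ++k) {
      cum += p[k];
      if (u <= cum) { knew = k; break; }
    }
    z[i] = knew;
    ndk(d, knew)++; nkw(knew, w)++; nk[knew]++;
  }
}

// [[Rcpp::export(name = "lda_sweep_cpp")]]
List lda_sweep_cpp(IntegerVector z, IntegerVector doc, IntegerVector word,
                   IntegerMatrix ndk, IntegerMatrix nkw, IntegerVector nk,
                   double alpha, double beta) {
  IntegerVector z2 = clone(z);
  IntegerMatrix ndk2 = clone(ndk), nkw2 = clone(nkw);
  IntegerVector nk2 = clone(nk);
  sweep_inplace(z2, doc, word, ndk2, nkw2, nk2, alpha, beta);
  return List::create(_["z"] = z2, _["n_dk"] = ndk2, _["n_kw"] = nkw2, _["n_k"] = nk2);
}

// Collapsed conditional for token i (with that token removed), normalized.
// [[Rcpp::export(name = "lda_conditional_cpp")]]
NumericVector lda_conditional_cpp(IntegerVector z, IntegerVector doc,
                                  IntegerVector word,
                                  IntegerMatrix ndk, IntegerMatrix nkw,
                                  IntegerVector nk,
                                  double alpha, double beta, int i) {
  IntegerMatrix ndk2 = clone(ndk), nkw2 = clone(nkw);
  IntegerVector nk2 = clone(nk);
  const int K = nk.size(), W = nkw.ncol();
  const int d = doc[i], w = word[i], kold = z[i];
  ndk2(d, kold)--; nkw2(kold, w)--; nk2[kold]--;
  NumericVector p(K);
  conditional(d, w, ndk2, nkw2, nk2, alpha, beta, K, W, REAL(p));
  return p / sum(p);
}

// Burn-in plus retained sweeps, accumulating per-pixel topic counts over
// the retained samples (every token covering a pixel contributes).
// [[Rcpp::export(name = "lda_run_cpp")]]
List lda_run_cpp(IntegerVector z, IntegerVector doc, IntegerVector word,
                 IntegerVector pixel,
                 IntegerMatrix ndk, IntegerMatrix nkw, IntegerVector nk,
                 double alpha, double beta,
                 int burn_in, int n_samples, int n_pixels) {
  IntegerVector z2 = clone(z);
  IntegerMatrix ndk2 = clone(ndk), nkw2 = clone(nkw);
  IntegerVector nk2 = clone(nk);
  const int K = nk.size(), n = z.size();
  for (int s = 0; s < burn_in; ++s) {
    sweep_inplace(z2, doc, word, ndk2, nkw2, nk2, alpha, beta);
    if ((s & 31) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix acc(n_pixels, K);
  for (int s = 0; s < n_samples; ++s) {
    sweep_inplace(z2, doc, word, ndk2, nkw2, nk2, alpha, beta);
    for (int i = 0; i < n; ++i) acc(pixel[i], z2[i]) += 1.0;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["z"] = z2, _["n_dk"] = ndk2, _["n_kw"] = nkw2,
                      _["n_k"] = nk2, _["pixel_topic"] = acc);
}
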