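#include <Rcpp.h>
using namespace Rcpp;

// Burrows composite-disequilibrium machinery shared by the pairwise r2
// report and the delete-one jackknife. Genotypes are 0/1/2 with NA for
// missing; only pairs of loci on different chromosomes are used.

struct PairAccum {
  // upper-triangle cross-products over joint non-missing individuals
  std::vector<double> S, SXa, SXb, SXY, P2a, P2b;
  std::vector<int> a, b;
};

// r2 for one pair from its scalar accumulators; returns false when the pair
// is unusable (S < 2, or a locus monomorphic/non-polymorphic in the mask).
static inline bool pair_r2(double S, double sxa, double sxb, double sxy,
                           double p2a, double p2b, double &r2) {
  if (S < 2.0) return false;
  double pa = sxa / (2.0 * S), pb = sxb / (2.0 * S);
  double cov = (sxy - sxa * sxb / S) / (S - 1.0);
  double delta = 0.5 * cov;
  double pia = pa * (1.0 - pa) + (p2a / S - pa * pa);
  double pib = pb * (1.0 - pb) + (p2b / S - pb * pb);
  if (pia <= 0.0 || pib <= 0.0) return false;
  r2 = delta * delta / (pia * pib);
  return R_finite(r2);
}

static PairAccum accumulate_pairs(const IntegerMatrix &G,
                                  const IntegerVector &chrom) {
  int n = G.nrow(), L = G.ncol();
  PairAccum acc;
  for (int a = 0; a < L - 1; ++a) {
    for (int b = a + 1; b < L; ++b) {
      if (chrom[a] == chrom[b]) continue;
      double S = 0, sxa = 0, sxb = 0, sxy = 0, p2a = 0, p2b = 0;
      for (int i = 0; i < n; ++i) {
        int ga = G(i, a), gb = G(i, b);
        if (ga == NA_INTEGER || gb == NA_INTEGER) continue;
        S += 1.0;
        sxa += ga; sxb += gb; sxy += ga * gb;
        p2a += (ga == 2); p2b += (gb == 2);
      }
      acc.a.push_back(a + 1); acc.b.push_back(b + 1);
      acc.S.push_back(S); acc.SXa.push_back(sxa); acc.SXb.push_back(sxb);
      acc.SXY.push_back(sxy); acc.P2a.push_back(p2a); acc.P2b.push_back(p2b);
    }
  }
  return acc;
}

// [[Rcpp::export]]
List burrows_pairs_cpp(IntegerMatrix G, IntegerVector chrom) {
  PairAccum acc = accumulate_pairs(G, chrom);
  size_t P = acc.S.size();
  std::vector<int> ka, kb; std::vector<double> kr2, kS;
  for (size_t p = 0; p < P; ++p) {
    double r2;
    if (pair_r2(acc.S[p], acc.SXa[p], acc.SXb[p], acc.SXY[p],
                acc.P2a[p], acc.P2b[p], r2)) {
      ka.push_back(acc.a[p]); kb.push_back(acc.b[p]);
      kr2.push_back(r2); kS.push_back(acc.S[p]);
    }
  }
  return List::create(_["a"] = ka, _["b"] = kb, _["r2"] = kr2, _["S"] = kS);
}

// Full-sample weighted mean r2 / harmonic S plus the delete-one-individual
// leave-out statistics used by the jackknife confidence interval.
// [[Rcpp::export]]
List ld_jackknife_cpp(IntegerMatrix G, IntegerVector chrom) {
  int n = G.nrow();
  PairAccum acc = accumulate_pairs(G, chrom);
  size_t P = acc.S.size();

  double sw = 0, swr = 0, sinv = 0; long np = 0;
  for (size_t p = 0; p < P; ++p) {
    double r2;
    if (pair_r2(acc.S[p], acc.SXa[p], acc.SXb[p], acc.SXY[p],
                acc.P2a[p], acc.P2b[p], r2)) {
      sw += acc.S[p]; swr += acc.S[p] * r2; sinv += 1.0 / acc.S[p]; ++np;
    }
  }

  NumericVector loo_mean(n), loo_hS(n);
  for (int i = 0; i < n; ++i) {
    double swi = 0, swri = 0, sinvi = 0; long npi = 0;
    for (size_t p = 0; p < P; ++p) {
      int a = acc.a[p] - 1, b = acc.b[p] - 1;
      int ga = G(i, a), gb = G(i, b);
      double S = acc.S[p], sxa = acc.SXa[p], sxb = acc.SXb[p],
             sxy = acc.SXY[p], p2a = acc.P2a[p], p2b = acc.P2b[p];
      if (ga != NA_INTEGER && gb != NA_INTEGER) {
        S -= 1.0; sxa -= ga; sxb -= gb; sxy -= ga * gb;
        p2a -= (ga == 2); p2b -= (gb == 2);
      }
      double r2;
      if (pair_r2(S, sxa, sxb, sxy, p2a, p2b, r2)) {
        swi += S; swri += S * r2; sinvi += 1.0 / S; ++npi;
      }
    }
    loo_mean[i] = npi ? swri / swi : NA_REAL;
    loo_hS[i] = npi ? npi / sinvi : NA_REAL;
  }

  return List::create(
    _["mean_r2"] = np ? swr / sw : NA_REAL,
    _["harmonic_S"] = np ? np / sinv : NA_REAL,
    _["n_pairs"] = (double)np,
    _["loo_mean_r2"] = loo_mean,
    _["loo_harmonic_S"] = loo_hS);
}
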