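#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for hybrid-class classification.
//
// geno: N x L integer matrix of allele-1 dosages (0/1/2), -1 = missing.
// phi:  C x 3 matrix of gene-origin pair probabilities per class:
//       columns (pool1,pool1), (pool1,pool2), (pool2,pool2).
// p1, p2: initial (or fixed) allele-1 frequencies per locus and pool.
// update_freq: when true, frequencies are resampled each sweep from their
//       Jeffreys Beta(1/2 + nA, 1/2 + na) full conditionals.
//
// Latent state: class z_i (uniform prior), origin pair w_il, and for
// heterozygous calls with mixed origin the allocation of the "A" copy.
// Uses R's RNG so set.seed() governs the chain.
// [[Rcpp::export]]
List gibbs_core(IntegerMatrix geno, NumericMatrix phi,
                NumericVector p1, NumericVector p2,
                bool update_freq, int iterations, int burn_in) {
  const int N = geno.nrow(), L = geno.ncol(), C = phi.nrow();
  std::vector<double> f1(p1.begin(), p1.end());
  std::vector<double> f2(p2.begin(), p2.end());
  // pw[l*9 + g*3 + w] = P(g | w) at locus l
  std::vector<double> pw(L * 9);
  std::vector<int> z(N), w(N * L, 0);
  NumericMatrix occ(N, C), half1(N, C), half2(N, C);
  NumericVector th1(L), th2(L);
  std::vector<double> clik(C);

  // initial class assignment: uniform
  for (int i = 0; i < N; ++i)
    z[i] = (int)(unif_rand() * C) % C;

  const int kept = iterations - burn_in;
  const int half_at = burn_in + kept / 2;

  for (int it = 0; it < iterations; ++it) {
    // genotype probabilities given origin pair
    for (int l = 0; l < L; ++l) {
      double a = f1[l], b = f2[l];
      double* q = &pw[l * 9];
      q[0 * 3 + 0] = (1 - a) * (1 - a);       // g=0 | w=11
      q[0 * 3 + 1] = (1 - a) * (1 - b);       // g=0 | w=12
      q[0 * 3 + 2] = (1 - b) * (1 - b);       // g=0 | w=22
      q[1 * 3 + 0] = 2 * a * (1 - a);
      q[1 * 3 + 1] = a * (1 - b) + b * (1 - a);
      q[1 * 3 + 2] = 2 * b * (1 - b);
      q[2 * 3 + 0] = a * a;
      q[2 * 3 + 1] = a * b;
      q[2 * 3 + 2] = b * b;
    }
    // z_i | data, theta (w collapsed)
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < C; ++c) clik[c] = 1.0;
      int since_rescale = 0;
      for (int l = 0; l < L; ++l) {
        int g = geno(i, l);
        if (g < 0) continue;
        const double* q = &pw[l * 9 + g * 3];
        for (int c = 0; c < C; ++c)
          clik[c] *= phi(c, 0) * q[0] + phi(c, 1) * q[1] + phi(c, 2) * q[2];
        if (++since_rescale == 40) {
          double mx = 0;
          for (int c = 0; c < C; ++c) if (clik[c] > mx) mx = clik[c];
          if (mx > 0 && mx < 1e-200)
            for (int c = 0; c < C; ++c) clik[c] /= mx;
          since_rescale = 0;
        }
      }
      double tot = 0;
      for (int c = 0; c < C; ++c) tot += clik[c];
      double u = unif_rand() * tot, acc = 0;
      int pick = C - 1;
      for (int c = 0; c < C; ++c) {
        acc += clik[c];
        if (u <= acc) { pick = c; break; }
      }
      z[i] = pick;
    }
    // w_il | z, theta and frequency counts
    std::vector<double> nA1(L, 0.0), nTot1(L, 0.0), nA2(L, 0.0), nTot2(L, 0.0);
    for (int i = 0; i < N; ++i) {
      int c = z[i];
      for (int l = 0; l < L; ++l) {
        int g = geno(i, l);
        if (g < 0) continue;
        const double* q = &pw[l * 9 + g * 3];
        double w0 = phi(c, 0) * q[0], w1 = phi(c, 1) * q[1],
               w2 = phi(c, 2) * q[2];
        double tot = w0 + w1 + w2;
        double u = unif_rand() * tot;
        int wi = (u <= w0) ? 0 : (u <= w0 + w1 ? 1 : 2);
        w[i * L + l] = wi;
        if (!update_freq) continue;
        if (wi == 0) { nTot1[l] += 2; nA1[l] += g; }
        else if (wi == 2) { nTot2[l] += 2; nA2[l] += g; }
        else {
          nTot1[l] += 1; nTot2[l] += 1;
          if (g == 2) { nA1[l] += 1; nA2[l] += 1; }
          else if (g == 1) {
            // allocate the single A copy to pool1 or pool2
            double pA1 = f1[l] * (1 - f2[l]);
            double pA2 = f2[l] * (1 - f1[l]);
            if (unif_rand() * (pA1 + pA2) <= pA1) nA1[l] += 1;
            else nA2[l] += 1;
          }
        }
      }
    }
    if (update_freq) {
      for (int l = 0; l < L; ++l) {
        f1[l] = R::rbeta(0.5 + nA1[l], 0.5 + nTot1[l] - nA1[l]);
        f2[l] = R::rbeta(0.5 + nA2[l], 0.5 + nTot2[l] - nA2[l]);
      }
    }
    if (it >= burn_in) {
      for (int i = 0; i < N; ++i) {
        occ(i, z[i]) += 1.0;
        if (it < half_at) half1(i, z[i]) += 1.0;
        else half2(i, z[i]) += 1.0;
      }
      for (int l = 0; l < L; ++l) { th1[l] += f1[l]; th2[l] += f2[l]; }
    }
  }
  int n1 = half_at - burn_in, n2 = iterations - half_at;
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < C; ++c) {
      occ(i, c) /= kept;
      half1(i, c) /= n1;
      half2(i, c) /= n2;
    }
  for (int l = 0; l < L; ++l) { th1[l] /= kept; th2[l] /= kept; }
  return List::create(_["posterior"] = occ,
                      _["half1"] = half1, _["half2"] = half2,
                      _["theta1_mean"] = th1, _["theta2_mean"] = th2);
}
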