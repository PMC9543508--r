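#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// One gamete from parent haplotypes h0/h1: per chromosome, random starting
// haplotype and a single obligate crossover at a random internal inter-SNP
// interval (uniform over the Lc-1 intervals, in SNP-index space).
static inline void make_gamete_cpp(const uint8_t* h0, const uint8_t* h1,
                                   uint8_t* out, const int* clen,
                                   int n_chrom) {
  int off = 0;
  for (int c = 0; c < n_chrom; ++c) {
    int Lc = clen[c];
    const uint8_t* a = (unif_rand() < 0.5) ? h0 : h1;
    const uint8_t* b = (a == h0) ? h1 : h0;
    if (Lc == 1) {
      out[off] = a[off];
    } else {
      int k = 1 + (int)(unif_rand() * (Lc - 1));
      if (k > Lc - 1) k = Lc - 1;
      std::memcpy(out + off, a + off, k);
      std::memcpy(out + off + k, b + off + k, Lc - k);
    }
    off += Lc;
  }
}

static inline int sample_weighted(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
}

static void column_freqs(const std::vector<uint8_t>& hap, int nhap, int L,
                         std::vector<double>& out) {
  std::vector<int> cnt(L, 0);
  for (int h = 0; h < nhap; ++h) {
    const uint8_t* row = hap.data() + (size_t)h * L;
    for (int l = 0; l < L; ++l) cnt[l] += row[l];
  }
  out.resize(L);
  for (int l = 0; l < L; ++l) out[l] = (double)cnt[l] / nhap;
}

// [[Rcpp::export]]
List cpp_evolve(NumericVector founder_p, IntegerVector chrom_len, int N,
                int t, bool selfing, IntegerVector sel_idx,
                NumericVector sel_s, NumericVector sel_h,
                NumericVector sel_p0, int pool_n, int max_attempts) {
  const int L = founder_p.size();
  const int n_chrom = chrom_len.size();
  const int nsel = sel_idx.size();
  int tot = 0;
  for (int c = 0; c < n_chrom; ++c) tot += chrom_len[c];
  if (tot != L) stop("chrom_len does not sum to genome length");
  const int nhap = 2 * N;

  std::vector<uint8_t> cur((size_t)nhap * L), nxt((size_t)nhap * L);
  std::vector<double> founder_freq, final_freq, pool_freq;
  NumericMatrix traj(t + 1, nsel);
  std::vector<double> w(N), cum(N);

  int attempts = 0;
  bool success = false;
  while (!success) {
    if (++attempts > max_attempts)
      stop("conditioning failed after %d attempts", max_attempts);
    // founding: independent Bernoulli draws per allele copy
    for (int h = 0; h < nhap; ++h) {
      uint8_t* row = cur.data() + (size_t)h * L;
      for (int l = 0; l < L; ++l) row[l] = (unif_rand() < founder_p[l]);
    }
    // seed selected loci at p0, requiring at least one favored copy
    for (int s = 0; s < nsel; ++s) {
      int l = sel_idx[s];
      int copies = 0;
      while (copies == 0) {
        copies = 0;
        for (int h = 0; h < nhap; ++h) {
          uint8_t v = (unif_rand() < sel_p0[s]);
          cur[(size_t)h * L + l] = v;
          copies += v;
        }
      }
    }
    column_freqs(cur, nhap, L, founder_freq);
    for (int s = 0; s < nsel; ++s) traj(0, s) = founder_freq[sel_idx[s]];

    for (int g = 1; g <= t; ++g) {
      double totw = 0.0;
      if (nsel > 0) {
        for (int i = 0; i < N; ++i) {
          double wi = 1.0;
          for (int s = 0; s < nsel; ++s) {
            int l = sel_idx[s];
            int geno = cur[(size_t)(2 * i) * L + l] +
                       cur[(size_t)(2 * i + 1) * L + l];
            if (geno == 1) wi *= 1.0 + sel_h[s] * sel_s[s];
            else if (geno == 2) wi *= 1.0 + sel_s[s];
          }
          w[i] = wi;
          totw += wi;
          cum[i] = totw;
        }
        if (totw <= 0.0) stop("total fitness is zero");
      }
      for (int i = 0; i < N; ++i) {
        int sp = (nsel > 0) ? sample_weighted(cum) : (int)(unif_rand() * N);
        if (sp >= N) sp = N - 1;
        int pp;
        if (selfing) pp = sp;
        else {
          pp = (nsel > 0) ? sample_weighted(cum) : (int)(unif_rand() * N);
          if (pp >= N) pp = N - 1;
        }
        make_gamete_cpp(cur.data() + (size_t)(2 * sp) * L,
                        cur.data() + (size_t)(2 * sp + 1) * L,
                        nxt.data() + (size_t)(2 * i) * L,
                        chrom_len.begin(), n_chrom);
        make_gamete_cpp(cur.data() + (size_t)(2 * pp) * L,
                        cur.data() + (size_t)(2 * pp + 1) * L,
                        nxt.data() + (size_t)(2 * i + 1) * L,
                        chrom_len.begin(), n_chrom);
      }
      cur.swap(nxt);
      if (nsel > 0) {
        for (int s = 0; s < nsel; ++s) {
          int l = sel_idx[s], cnt = 0;
          for (int h = 0; h < nhap; ++h) cnt += cur[(size_t)h * L + l];
          traj(g, s) = (double)cnt / nhap;
        }
      }
    }
    // sweep conditioning: favored allele must exceed 0.5 at every locus
    success = true;
    for (int s = 0; s < nsel; ++s) {
      int l = sel_idx[s], cnt = 0;
      for (int h = 0; h < nhap; ++h) cnt += cur[(size_t)h * L + l];
      if ((double)cnt / nhap <= 0.5) { success = false; break; }
    }
  }
  column_freqs(cur, nhap, L, final_freq);

  List out = List::create(
      _["founder_freq"] = wrap(founder_freq),
      _["final_freq"] = wrap(final_freq),
      _["attempts"] = attempts,
      _["traj"] = traj);

  if (pool_n > 0) {
    // one extra round of reproduction: pool_n offspring grown from the
    // final generation for sequencing (bulked-seed sampling stage)
    double totw = 0.0;
    if (nsel > 0) {
      for (int i = 0; i < N; ++i) {
        double wi = 1.0;
        for (int s = 0; s < nsel; ++s) {
          int l = sel_idx[s];
          int geno = cur[(size_t)(2 * i) * L + l] +
                     cur[(size_t)(2 * i + 1) * L + l];
          if (geno == 1) wi *= 1.0 + sel_h[s] * sel_s[s];
          else if (geno == 2) wi *= 1.0 + sel_s[s];
        }
        totw += wi;
        cum[i] = totw;
      }
    }
    std::vector<uint8_t> pool((size_t)2 * pool_n * L);
    for (int i = 0; i < pool_n; ++i) {
      int sp = (nsel > 0) ? sample_weighted(cum) : (int)(unif_rand() * N);
      if (sp >= N) sp = N - 1;
      int pp;
      if (selfing) pp = sp;
      else {
        pp = (nsel > 0) ? sample_weighted(cum) : (int)(unif_rand() * N);
        if (pp >= N) pp = N - 1;
      }
      make_gamete_cpp(cur.data() + (size_t)(2 * sp) * L,
                      cur.data() + (size_t)(2 * sp + 1) * L,
                      pool.data() + (size_t)(2 * i) * L,
                      chrom_len.begin(), n_chrom);
      make_gamete_cpp(cur.data() + (size_t)(2 * pp) * L,
                      cur.data() + (size_t)(2 * pp + 1) * L,
                      pool.data() + (size_t)(2 * i + 1) * L,
                      chrom_len.begin(), n_chrom);
    }
    column_freqs(pool, 2 * pool_n, L, pool_freq);
    out["pool_freq"] = wrap(pool_freq);
  }
  return out;
}
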