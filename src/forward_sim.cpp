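#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Rescaled forward Wright-Fisher simulator with a single selected site.
//
// Genomes are bitsets over L discrete sites (derived allele = set bit).
// Diploid individuals carry two chromosomes; each offspring chromosome is an
// independent gamete (Poisson crossovers, Poisson mutations) from a parent
// drawn uniformly (neutral) or proportionally to fitness 1 + s*g/2 with g the
// count of beneficial alleles at the selected site (additive, genic scaling
// so alpha = 2Ns matches the usual coalescent parameterisation).

namespace {

typedef uint64_t word_t;

struct SimState {
  int L;            // number of sites
  int W;            // 64-bit words per chromosome
  int N;            // current diploid population size
  std::vector<word_t> cur, nxt;  // 2N x W, row-major
  double mu;        // expected mutations per chromosome per generation
  double rr;        // expected crossovers per meiosis

  SimState(int L_, int N_, double mu_, double rr_)
      : L(L_), W((L_ + 63) / 64), N(N_), mu(mu_), rr(rr_) {
    cur.assign((size_t)2 * N * W, 0);
    nxt.assign((size_t)2 * N * W, 0);
  }

  inline word_t *chrom(std::vector<word_t> &v, int c) { return v.data() + (size_t)c * W; }

  inline int get_bit(const word_t *c, int site) const {
    return (int)((c[site >> 6] >> (site & 63)) & 1ULL);
  }
  inline void flip_bit(word_t *c, int site) { c[site >> 6] ^= (1ULL << (site & 63)); }
  inline void clear_bit(word_t *c, int site) { c[site >> 6] &= ~(1ULL << (site & 63)); }
  inline void set_bit(word_t *c, int site) { c[site >> 6] |= (1ULL << (site & 63)); }

  // copy sites [from, to) of src into dst
  inline void copy_range(word_t *dst, const word_t *src, int from, int to) {
    if (from >= to) return;
    int w0 = from >> 6, w1 = (to - 1) >> 6;
    if (w0 == w1) {
      word_t mask = (~0ULL << (from & 63));
      int hi = to & 63;
      if (hi) mask &= (~0ULL >> (64 - hi));
      dst[w0] = (dst[w0] & ~mask) | (src[w0] & mask);
      return;
    }
    {  // head word
      word_t mask = (~0ULL << (from & 63));
      dst[w0] = (dst[w0] & ~mask) | (src[w0] & mask);
    }
    if (w1 > w0 + 1) std::memcpy(dst + w0 + 1, src + w0 + 1, (size_t)(w1 - w0 - 1) * 8);
    {  // tail word
      int hi = to & 63;
      word_t mask = hi ? (~0ULL >> (64 - hi)) : ~0ULL;
      dst[w1] = (dst[w1] & ~mask) | (src[w1] & mask);
    }
  }

  // one gamete from parent p into dst
  void make_gamete(word_t *dst, int p, bool avoid_site, int sel_site) {
    const word_t *a = chrom(cur, 2 * p), *b = chrom(cur, 2 * p + 1);
    if (unif_rand() < 0.5) std::swap(a, b);
    int k = (int)R::rpois(rr);
    if (k == 0) {
      std::memcpy(dst, a, (size_t)W * 8);
    } else {
      int bp[64];
      if (k > 64) k = 64;
      for (int i = 0; i < k; ++i) bp[i] = 1 + (int)(unif_rand() * (L - 1));
      std::sort(bp, bp + k);
      int pos = 0;
      const word_t *srcs[2] = {a, b};
      int which = 0;
      for (int i = 0; i < k; ++i) {
        copy_range(dst, srcs[which], pos, bp[i]);
        pos = bp[i];
        which ^= 1;
      }
      copy_range(dst, srcs[which], pos, L);
    }
    int m = (int)R::rpois(mu);
    for (int i = 0; i < m; ++i) {
      int site = (int)(unif_rand() * L);
      if (site >= L) site = L - 1;
      if (avoid_site && site == sel_site) continue;  // selected locus mutates only by injection
      flip_bit(dst, site);
    }
  }

  // advance one generation; returns beneficial-allele count if sel_site >= 0
  int step(int N_next, double s, int sel_site) {
    if ((int)nxt.size() < 2 * N_next * W) nxt.assign((size_t)2 * N_next * W, 0);
    bool selecting = (s > 0.0 && sel_site >= 0);
    static std::vector<double> cw;
    if (selecting) {
      cw.resize(N);
      double acc = 0;
      for (int i = 0; i < N; ++i) {
        int g = get_bit(chrom(cur, 2 * i), sel_site) + get_bit(chrom(cur, 2 * i + 1), sel_site);
        acc += 1.0 + 0.5 * s * g;
        cw[i] = acc;
      }
      double tot = cw[N - 1];
      for (int c = 0; c < 2 * N_next; ++c) {
        double u = unif_rand() * tot;
        int p = (int)(std::lower_bound(cw.begin(), cw.begin() + N, u) - cw.begin());
        if (p >= N) p = N - 1;
        make_gamete(chrom(nxt, c), p, sel_site >= 0, sel_site);
      }
    } else {
      for (int c = 0; c < 2 * N_next; ++c) {
        int p = (int)(unif_rand() * N);
        if (p >= N) p = N - 1;
        make_gamete(chrom(nxt, c), p, sel_site >= 0, sel_site);
      }
    }
    std::swap(cur, nxt);
    N = N_next;
    int cnt = 0;
    if (sel_site >= 0)
      for (int c = 0; c < 2 * N; ++c) cnt += get_bit(chrom(cur, c), sel_site);
    return cnt;
  }

  int count_allele(int site) {
    int cnt = 0;
    for (int c = 0; c < 2 * N; ++c) cnt += get_bit(chrom(cur, c), site);
    return cnt;
  }

  void clear_site(int site) {
    for (int c = 0; c < 2 * N; ++c) clear_bit(chrom(cur, c), site);
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_sweep_cpp")]]
List sim_sweep_cpp(int n_ind, int L, double mu, double rr,
                   IntegerVector phase_gens, IntegerVector phase_N,
                   std::string kind, int sel_site, double s, double f0,
                   int tau_gens, int n_retry, int max_sweep_gens) {
  if (phase_gens.size() != phase_N.size() || phase_N.size() < 1)
    stop("phase schedule malformed");
  int N0 = phase_N[0];
  SimState st(L, N0, mu, rr);

  // neutral schedule (burn-in + any demographic phases)
  for (int ph = 0; ph < phase_N.size(); ++ph) {
    int Nn = phase_N[ph];
    for (int g = 0; g < phase_gens[ph]; ++g) st.step(Nn, 0.0, -1);
  }

  int attempts = 0, sweep_gens = 0;
  double f_real = NA_REAL;
  bool fixed = false;
  if (kind != "none") {
    if (sel_site < 0 || sel_site >= L) stop("selected site out of range");
    int twoN = 2 * st.N;
    int target = 1;
    if (kind == "soft") {
      target = (int)std::ceil(f0 * twoN);
      if (target < 1) target = 1;
    } else if (kind != "hard") {
      stop("unknown sweep kind");
    }
    while (!fixed) {
      if (attempts++ > n_retry) stop("beneficial allele failed to fix within retry budget");
      st.clear_site(sel_site);
      {
        int c = (int)(unif_rand() * twoN);
        if (c >= twoN) c = twoN - 1;
        st.set_bit(st.chrom(st.cur, c), sel_site);
      }
      // standing phase: neutral drift from one copy up to the target count
      int cnt = 1, g = 0;
      bool reached = (cnt >= target);
      while (!reached) {
        cnt = st.step(st.N, 0.0, sel_site);
        if (cnt == 0) break;
        if (cnt >= target) reached = true;
        if (++g > max_sweep_gens) break;
      }
      if (!reached) continue;
      f_real = (double)cnt / twoN;
      // selection phase
      g = 0;
      while (true) {
        cnt = st.step(st.N, s, sel_site);
        ++sweep_gens;
        if (cnt == 0) break;
        if (cnt == twoN) { fixed = true; break; }
        if (++g > max_sweep_gens) break;
      }
    }
  }

  for (int g = 0; g < tau_gens; ++g) st.step(st.N, 0.0, -1);

  // sample n_ind distinct individuals (both chromosomes each)
  if (n_ind > st.N) stop("sample size exceeds population size");
  std::vector<int> idx(st.N);
  for (int i = 0; i < st.N; ++i) idx[i] = i;
  for (int i = 0; i < n_ind; ++i) {
    int j = i + (int)(unif_rand() * (st.N - i));
    if (j >= st.N) j = st.N - 1;
    std::swap(idx[i], idx[j]);
  }
  int nch = 2 * n_ind;
  // segregating sites within the sample
  std::vector<int> segsite;
  std::vector<int> counts(L, 0);
  for (int i = 0; i < n_ind; ++i) {
    const word_t *a = st.chrom(st.cur, 2 * idx[i]);
    const word_t *b = st.chrom(st.cur, 2 * idx[i] + 1);
    for (int sI = 0; sI < L; ++sI)
      counts[sI] += ((a[sI >> 6] >> (sI & 63)) & 1) + ((b[sI >> 6] >> (sI & 63)) & 1);
  }
  for (int sI = 0; sI < L; ++sI)
    if (counts[sI] > 0 && counts[sI] < nch) segsite.push_back(sI);
  int S = (int)segsite.size();
  IntegerMatrix haps(nch, S);
  NumericVector pos(S);
  for (int j = 0; j < S; ++j) pos[j] = (segsite[j] + 0.5) / L;
  for (int i = 0; i < n_ind; ++i) {
    const word_t *a = st.chrom(st.cur, 2 * idx[i]);
    const word_t *b = st.chrom(st.cur, 2 * idx[i] + 1);
    for (int j = 0; j < S; ++j) {
      haps(2 * i, j) = st.get_bit(a, segsite[j]);
      haps(2 * i + 1, j) = st.get_bit(b, segsite[j]);
    }
  }

  return List::create(_["haplotypes"] = haps, _["positions"] = pos,
                      _["segsites"] = S, _["attempts"] = attempts,
                      _["sweep_gens"] = sweep_gens, _["f_realized"] = f_real,
                      _["fixed"] = fixed);
}
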