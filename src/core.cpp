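#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity along a widening span.
//
// haps: haplotypes x SNPs 0/1 matrix. core: 0-based column. targets: 0-based
// columns ordered outward from the core. The span used for the value reported
// at targets[t] is the inclusive column range core..targets[t]; EHH is the
// probability that two haplotypes drawn without replacement are identical
// over that span, sum_g C(n_g,2) / C(n,2). Group labels are refined
// incrementally so the whole profile costs O(n * length(targets)).
// [[Rcpp::export]]
NumericVector ehh_profile_cpp(const IntegerMatrix& haps, int core,
                              const IntegerVector& targets) {
  const int n = haps.nrow();
  if (n < 2) stop("EHH needs at least 2 haplotypes");
  std::vector<int> gid(n, 0), newgid(n), lookup;
  int ngroups = 1;
  const double denom = (double)n * (n - 1) / 2.0;
  NumericVector out(targets.size());

  auto refine = [&](int col) {
    lookup.assign(2 * ngroups, -1);
    int ng = 0;
    for (int i = 0; i < n; ++i) {
      int a = haps(i, col);
      if (a != 0 && a != 1) stop("haplotype alleles must be 0/1");
      int key = gid[i] * 2 + a;
      if (lookup[key] < 0) lookup[key] = ng++;
      newgid[i] = lookup[key];
    }
    gid.swap(newgid);
    ngroups = ng;
  };

  refine(core);
  std::vector<int> cnt;
  for (int t = 0; t < targets.size(); ++t) {
    refine(targets[t]);
    cnt.assign(ngroups, 0);
    for (int i = 0; i < n; ++i) cnt[gid[i]]++;
    double s = 0.0;
    for (int g = 0; g < ngroups; ++g)
      s += (double)cnt[g] * (cnt[g] - 1) / 2.0;
    out[t] = s / denom;
  }
  return out;
}

// Discrete-generation Wright-Fisher evolution of one population of phased
// haplotypes under infinite-sites mutation, uniform crossover, and an
// optional additive selective sweep at one site (genotype fitnesses
// 1, 1+s, 1+2s). Columns are kept unsorted; fixed columns are dropped and
// their positions reported so fixed differences between populations can be
// reconstructed by the caller. Uses R's RNG throughout.
//
// haps:       parent haplotypes x active segregating sites (0/1)
// positions:  1-based bp of each column (need not be sorted)
// n_dip_out:  offspring population size in diploids (2*n_dip_out gametes)
// sel_pos:    bp of the selected site, or -1 for neutral evolution
// forbid:     positions that must never be re-used for new mutations
// [[Rcpp::export]]
List wf_evolve_cpp(const IntegerMatrix& haps, const IntegerVector& positions,
                   int n_dip_out, int n_gens, double mu, double rho, int L,
                   int sel_pos, double s, const IntegerVector& forbid) {
  const int n_in = haps.nrow();
  if (n_in < 2 || n_in % 2 != 0) stop("parent haplotype count must be even and >= 2");
  int m = positions.size();
  if (haps.ncol() != m) stop("positions length must match column count");
  const int n_off = 2 * n_dip_out;
  const int n_rows = std::max(n_in, n_off);

  // flat row-major buffers (stride = cap) with in-place column compaction
  size_t cap = (size_t)m + 4096;
  std::vector<unsigned char> buf_a(n_rows * cap), buf_b(n_rows * cap);
  unsigned char *cur = buf_a.data(), *nxt = buf_b.data();
  for (int i = 0; i < n_in; ++i)
    for (int j = 0; j < m; ++j) cur[i * cap + j] = (unsigned char)haps(i, j);
  std::vector<int> pos(positions.begin(), positions.end());
  pos.reserve(cap);

  std::unordered_set<int> used(pos.begin(), pos.end());
  used.insert(forbid.begin(), forbid.end());

  std::vector<int> fixed_out;
  bool sel_lost = false, sel_fixed = false;
  double sel_freq = 0.0;

  std::vector<double> cumw;
  std::vector<double> bps;
  std::vector<int> csum, keep;

  int n_par = n_in;
  for (int gen = 0; gen < n_gens; ++gen) {
    const int n_pdip = n_par / 2;

    // selected-site column (sweep may have fixed or been lost earlier)
    int sel_idx = -1;
    if (sel_pos > 0 && !sel_fixed) {
      for (int j = 0; j < m; ++j)
        if (pos[j] == sel_pos) { sel_idx = j; break; }
      if (sel_idx < 0) { sel_lost = true; break; }
    }

    // fitness-weighted parent sampling
    double wtot = 0.0;
    bool weighted = (sel_idx >= 0 && s > 0.0);
    if (weighted) {
      cumw.resize(n_pdip);
      for (int d = 0; d < n_pdip; ++d) {
        int g = cur[(2 * d) * cap + sel_idx] + cur[(2 * d + 1) * cap + sel_idx];
        wtot += 1.0 + s * g;
        cumw[d] = wtot;
      }
    }

    int nm = (int)R::rpois((double)n_off * mu * (double)L);
    if ((size_t)(m + nm) > cap) {  // grow both buffers, preserving rows
      size_t ncap = (size_t)(m + nm) + 4096;
      std::vector<unsigned char> na(n_rows * ncap), nb(n_rows * ncap);
      for (int i = 0; i < n_rows; ++i)
        std::copy(cur + i * cap, cur + i * cap + m, na.data() + i * ncap);
      buf_a.swap(na); buf_b.swap(nb);
      cur = buf_a.data(); nxt = buf_b.data();
      cap = ncap;
    }

    for (int j = 0; j < n_off; ++j) {
      int d;
      if (weighted) {
        double r = unif_rand() * wtot;
        d = (int)(std::lower_bound(cumw.begin(), cumw.end(), r) - cumw.begin());
        if (d >= n_pdip) d = n_pdip - 1;
      } else {
        d = (int)(unif_rand() * n_pdip);
        if (d >= n_pdip) d = n_pdip - 1;
      }
      int h1 = 2 * d + (unif_rand() < 0.5 ? 0 : 1);
      int h2 = (h1 % 2 == 0) ? h1 + 1 : h1 - 1;
      int k = (int)R::rpois(rho * L);
      unsigned char* o = nxt + j * cap;
      const unsigned char *p1 = cur + h1 * cap, *p2 = cur + h2 * cap;
      if (k == 0) {
        std::copy(p1, p1 + m, o);
      } else {
        bps.resize(k);
        for (int b = 0; b < k; ++b) bps[b] = 1.0 + unif_rand() * (L - 1);
        for (int c = 0; c < m; ++c) {
          int nb = 0;
          for (int b = 0; b < k; ++b) if (bps[b] < pos[c]) ++nb;
          o[c] = (nb % 2 == 0) ? p1[c] : p2[c];
        }
      }
      std::fill(o + m, o + m + nm, 0);  // slots for this generation's mutations
    }

    // infinite-sites mutations at uniform unused positions
    for (int u = 0; u < nm; ++u) {
      int p;
      int tries = 0;
      do {
        p = 1 + (int)(unif_rand() * L);
        if (p > L) p = L;
      } while (used.count(p) && ++tries < 10000);
      if (used.count(p)) continue;  // region saturated; skip this mutation
      used.insert(p);
      pos.push_back(p);
      int carrier = (int)(unif_rand() * n_off);
      if (carrier >= n_off) carrier = n_off - 1;
      nxt[carrier * cap + (pos.size() - 1)] = 1;
    }
    m = (int)pos.size();

    // prune lost and fixed columns (in-place forward compaction)
    csum.assign(m, 0);
    for (int i = 0; i < n_off; ++i) {
      const unsigned char* h = nxt + i * cap;
      for (int c = 0; c < m; ++c) csum[c] += h[c];
    }
    keep.clear();
    for (int c = 0; c < m; ++c) {
      if (csum[c] == 0) {
        if (pos[c] == sel_pos && !sel_fixed) sel_lost = true;
      } else if (csum[c] == n_off) {
        fixed_out.push_back(pos[c]);
        if (pos[c] == sel_pos) sel_fixed = true;
      } else {
        keep.push_back(c);
      }
    }
    if ((int)keep.size() < m) {
      for (int i = 0; i < n_off; ++i) {
        unsigned char* h = nxt + i * cap;
        for (size_t c = 0; c < keep.size(); ++c) h[c] = h[keep[c]];
      }
      for (size_t c = 0; c < keep.size(); ++c) pos[c] = pos[keep[c]];
      pos.resize(keep.size());
      m = (int)pos.size();
    }
    std::swap(cur, nxt);
    n_par = n_off;
    if (sel_lost) break;
  }

  // final selected-allele frequency
  if (sel_pos > 0) {
    if (sel_fixed) sel_freq = 1.0;
    else if (sel_lost) sel_freq = 0.0;
    else {
      for (int j = 0; j < m; ++j)
        if (pos[j] == sel_pos) {
          int c = 0;
          for (int i = 0; i < n_par; ++i) c += cur[i * cap + j];
          sel_freq = (double)c / n_par;
          break;
        }
    }
  }

  IntegerMatrix out(n_par, m);
  for (int i = 0; i < n_par; ++i)
    for (int j = 0; j < m; ++j) out(i, j) = cur[i * cap + j];
  return List::create(_["haps"] = out,
                      _["positions"] = IntegerVector(pos.begin(), pos.end()),
                      _["fixed"] = IntegerVector(fixed_out.begin(), fixed_out.end()),
                      _["sel_lost"] = sel_lost,
                      _["sel_fixed"] = sel_fixed,
                      _["sel_freq"] = sel_freq);
}

// Null distribution of Tajima's D under the standard neutral coalescent,
// conditioned on the observed number of segregating sites: for each
// replicate a Kingman genealogy of n samples is drawn (time units cancel),
// exactly S mutations are placed on branches with probability proportional
// to branch length, and D is computed from the resulting frequency spectrum.
// [[Rcpp::export]]
NumericVector tajima_null_cpp(int n, int S, int reps) {
  if (n < 2) stop("n must be >= 2");
  if (S < 1) stop("S must be >= 1");
  // Tajima's constants
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i <= n - 1; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  const double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  const double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  const double c1 = b1 - 1.0 / a1;
  const double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  const double e1 = c1 / a1;
  const double e2 = c2 / (a1 * a1 + a2);
  const double vden = std::sqrt(e1 * S + e2 * (double)S * (S - 1.0));

  NumericVector out(reps);
  std::vector<int> bsize(2 * n), sz(n);
  std::vector<double> blen(2 * n), pending(n), cum(2 * n);
  for (int r = 0; r < reps; ++r) {
    int k = n, nb = 0;
    for (int i = 0; i < n; ++i) { sz[i] = 1; pending[i] = 0.0; }
    while (k > 1) {
      double t = exp_rand() / (k * (k - 1.0) / 2.0);
      for (int i = 0; i < k; ++i) pending[i] += t;
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      bsize[nb] = sz[i]; blen[nb++] = pending[i];
      bsize[nb] = sz[j]; blen[nb++] = pending[j];
      sz[i] += sz[j]; pending[i] = 0.0;
      sz[j] = sz[k - 1]; pending[j] = pending[k - 1];
      --k;
    }
    double tot = 0.0;
    for (int b = 0; b < nb; ++b) { tot += blen[b]; cum[b] = tot; }
    double pisum = 0.0;
    for (int s = 0; s < S; ++s) {
      double u = unif_rand() * tot;
      int b = (int)(std::lower_bound(cum.begin(), cum.begin() + nb, u) -
                    cum.begin());
      if (b >= nb) b = nb - 1;
      pisum += 2.0 * bsize[b] * (double)(n - bsize[b]);
    }
    double pi = pisum / ((double)n * (n - 1.0));
    out[r] = (pi - S / a1) / vden;
  }
  return out;
}
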