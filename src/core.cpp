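#include <Rcpp.h>
using namespace Rcpp;

// Evolve one locus under JC69 along a cladewise-ordered tree.
// edge: 2-column matrix (1-based node ids, parents before children).
// elen: substitution branch lengths (expected subs/site).
// Returns ntip x L integer matrix with codes 1..4.
// [[Rcpp::export]]
IntegerMatrix cpp_jc_evolve(IntegerMatrix edge, NumericVector elen,
                            int ntip, int L) {
  int nedge = edge.nrow();
  int nnode = ntip + nedge / 2 + 1; // upper bound on node count
  // find max node id to size the buffer
  int maxid = ntip + 1;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > maxid) maxid = edge(e, 0);
    if (edge(e, 1) > maxid) maxid = edge(e, 1);
  }
  nnode = maxid;
  std::vector<unsigned char> seq((size_t)nnode * L);
  int root = ntip + 1;
  unsigned char *rootseq = &seq[(size_t)(root - 1) * L];
  for (int s = 0; s < L; ++s)
    rootseq[s] = (unsigned char)(1 + (int)(unif_rand() * 4.0));
  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    double d = elen[e];
    double pstay = 0.25 + 0.75 * std::exp(-4.0 * d / 3.0);
    unsigned char *ps = &seq[(size_t)(p - 1) * L];
    unsigned char *cs = &seq[(size_t)(c - 1) * L];
    if (d <= 0.0) {
      std::copy(ps, ps + L, cs);
      continue;
    }
    for (int s = 0; s < L; ++s) {
      if (unif_rand() < pstay) {
        cs[s] = ps[s];
      } else {
        int k = 1 + (int)(unif_rand() * 3.0);
        if (k > 3) k = 3;
        cs[s] = (unsigned char)(((ps[s] - 1 + k) & 3) + 1);
      }
    }
  }
  IntegerMatrix out(ntip, L);
  for (int t = 0; t < ntip; ++t) {
    unsigned char *ts = &seq[(size_t)t * L];
    for (int s = 0; s < L; ++s) out(t, s) = ts[s];
  }
  return out;
}

// Greedy left-to-right thinning: keep a position iff it is at least
// `spacing` beyond the last kept one (first always kept).
// [[Rcpp::export]]
LogicalVector cpp_thin_keep(IntegerVector positions, int spacing) {
  int n = positions.size();
  LogicalVector keep(n);
  long last = LONG_MIN;
  for (int i = 0; i < n; ++i) {
    if (last == LONG_MIN || positions[i] >= last + spacing) {
      keep[i] = true;
      last = positions[i];
    }
  }
  return keep;
}

static const int POPCNT4[16] = {0,1,1,2,1,2,2,3,1,2,2,3,2,3,3,4};

// Columns with at least two distinct non-gap alleles across all taxa.
// [[Rcpp::export]]
LogicalVector cpp_variable_sites(RawMatrix alleles) {
  int ntaxa = alleles.nrow(), nsites = alleles.ncol();
  LogicalVector out(nsites);
  for (int s = 0; s < nsites; ++s) {
    int mask = 0;
    for (int t = 0; t < ntaxa; ++t) {
      unsigned char a = alleles(t, s);
      if (a) mask |= 1 << (a - 1);
      if (POPCNT4[mask] >= 2) break;
    }
    out[s] = POPCNT4[mask] >= 2;
  }
  return out;
}

// next set bit at index >= from, or -1
static inline long next_bit(const uint64_t *bs, long nwords, long from,
                            long nbits) {
  if (from >= nbits) return -1;
  long w = from >> 6;
  uint64_t cur = bs[w] & (~0ULL << (from & 63));
  while (true) {
    if (cur) {
      long s = (w << 6) + __builtin_ctzll(cur);
      return s < nbits ? s : -1;
    }
    if (++w >= nwords) return -1;
    cur = bs[w];
  }
}

// ABBA-BABA scan core. alleles: raw matrix over the FULL concatenated
// alignment (ntaxa x nsites, codes 0..4, 0 = gap/ambiguity; column index =
// concatenated coordinate). trios: k x 3 matrix of 0-based row indices
// (P1, P2, P3); out_row: 0-based outgroup row. Per trio: biallelic filter
// over the 4 rows, greedy thinning at `spacing`, ABBA/BABA/BBAA
// classification polarized by the outgroup, block-jackknife SE of D over
// `n_blocks` contiguous blocks.
//
// Candidate sites per trio are computed as bitset unions of per-taxon
// difference masks against the outgroup, and greedy thinning skips
// directly to the next candidate bit past the spacing window, so work per
// trio scales with the number of retained SNPs rather than the alignment
// length.
//
// Returns k x 7: ABBA, BABA, BBAA, nSNPs, D, SE, ok(1/0).
// [[Rcpp::export]]
NumericMatrix cpp_dstat_trios(RawMatrix alleles, IntegerMatrix trios,
                              int out_row, int spacing, int n_blocks) {
  int ntaxa = alleles.nrow();
  long nsites = alleles.ncol();
  int k = trios.nrow();
  NumericMatrix res(k, 7);
  const Rbyte *A = &alleles[0]; // column-major: A[s*ntaxa + t]

  long nwords = (nsites + 63) / 64;
  // per-taxon bitsets: diff[t] = taxon differs from outgroup (both
  // non-gap); ng[t] = taxon non-gap
  std::vector<uint64_t> diffbs((size_t)ntaxa * nwords, 0);
  std::vector<uint64_t> ngbs((size_t)ntaxa * nwords, 0);
  for (long s = 0; s < nsites; ++s) {
    const Rbyte *col = A + s * ntaxa;
    unsigned char ao = col[out_row];
    uint64_t bit = 1ULL << (s & 63);
    long w = s >> 6;
    for (int t = 0; t < ntaxa; ++t) {
      unsigned char a = col[t];
      if (a) {
        ngbs[(size_t)t * nwords + w] |= bit;
        if (ao && a != ao) diffbs[(size_t)t * nwords + w] |= bit;
      }
    }
  }
  std::vector<uint64_t> cand(nwords);
  std::vector<unsigned char> pat(nsites / (spacing > 0 ? spacing : 1) + 64);

  for (int t = 0; t < k; ++t) {
    int i1 = trios(t, 0), i2 = trios(t, 1), i3 = trios(t, 2);
    const uint64_t *d1 = &diffbs[(size_t)i1 * nwords];
    const uint64_t *d2 = &diffbs[(size_t)i2 * nwords];
    const uint64_t *d3 = &diffbs[(size_t)i3 * nwords];
    const uint64_t *g1 = &ngbs[(size_t)i1 * nwords];
    const uint64_t *g2 = &ngbs[(size_t)i2 * nwords];
    const uint64_t *g3 = &ngbs[(size_t)i3 * nwords];
    for (long w = 0; w < nwords; ++w)
      cand[w] = (d1[w] | d2[w] | d3[w]) & g1[w] & g2[w] & g3[w];

    long last = -1; // last kept position; thinning anchor
    long nkept = 0;
    long abba = 0, baba = 0, bbaa = 0;
    long s = next_bit(cand.data(), nwords, 0, nsites);
    while (s >= 0) {
      const Rbyte *col = A + s * ntaxa;
      unsigned char a1 = col[i1], a2 = col[i2], a3 = col[i3],
                    a4 = col[out_row];
      int mask = (1 << (a1 - 1)) | (1 << (a2 - 1)) |
                 (1 << (a3 - 1)) | (1 << (a4 - 1));
      if (POPCNT4[mask] != 2) { // triallelic candidate: not a SNP-table row
        s = next_bit(cand.data(), nwords, s + 1, nsites);
        continue;
      }
      unsigned char code = 0;
      bool b1 = a1 != a4, b2 = a2 != a4, b3 = a3 != a4;
      if (!b1 && b2 && b3) { code = 1; ++abba; }
      else if (b1 && !b2 && b3) { code = 2; ++baba; }
      else if (b1 && b2 && !b3) { code = 3; ++bbaa; }
      pat[nkept++] = code;
      last = s;
      s = next_bit(cand.data(), nwords, last + spacing, nsites);
    }
    res(t, 0) = (double)abba;
    res(t, 1) = (double)baba;
    res(t, 2) = (double)bbaa;
    res(t, 3) = (double)nkept;
    if (nkept < n_blocks || abba + baba == 0) {
      res(t, 4) = NA_REAL; res(t, 5) = NA_REAL; res(t, 6) = 0;
      continue;
    }
    double D = (double)(abba - baba) / (double)(abba + baba);
    // contiguous blocks with sizes differing by <= 1
    int base = nkept / n_blocks, rem = nkept % n_blocks;
    std::vector<double> dj(n_blocks);
    int pos = 0;
    bool ok = true;
    for (int b = 0; b < n_blocks; ++b) {
      int sz = base + (b < rem ? 1 : 0);
      long ab = 0, ba = 0;
      for (int j = pos; j < pos + sz; ++j) {
        if (pat[j] == 1) ++ab;
        else if (pat[j] == 2) ++ba;
      }
      pos += sz;
      long rab = abba - ab, rba = baba - ba;
      if (rab + rba == 0) { ok = false; break; }
      dj[b] = (double)(rab - rba) / (double)(rab + rba);
    }
    if (!ok) {
      res(t, 4) = D; res(t, 5) = NA_REAL; res(t, 6) = 0;
      continue;
    }
    double mean = 0;
    for (int b = 0; b < n_blocks; ++b) mean += dj[b];
    mean /= n_blocks;
    double ss = 0;
    for (int b = 0; b < n_blocks; ++b) ss += (dj[b] - mean) * (dj[b] - mean);
    double var = ((double)(n_blocks - 1) / n_blocks) * ss;
    res(t, 4) = D;
    res(t, 5) = std::sqrt(var);
    res(t, 6) = 1;
  }
  return res;
}
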