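#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Suffix array by prefix doubling. Input values must already place the
// sentinel (unique minimum) at the last position.
// ---------------------------------------------------------------------------
static std::vector<int> suffix_array_doubling(const std::vector<int>& s) {
  int n = (int)s.size();
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = s[i]; }
  if (n == 1) return sa;
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// [[Rcpp::export]]
IntegerVector cpp_suffix_array(IntegerVector s) {
  std::vector<int> v(s.begin(), s.end());
  std::vector<int> sa = suffix_array_doubling(v);
  return IntegerVector(sa.begin(), sa.end());
}

// ---------------------------------------------------------------------------
// Plain bit vector with rank support.
// words: 32-bit payload words; dirs: cumulative popcount before every 8th
// word (256-bit superblocks).
// ---------------------------------------------------------------------------
static List build_bv(const std::vector<char>& bits) {
  int n = (int)bits.size();
  int nw = (n + 31) / 32;
  IntegerVector words(nw);
  for (int i = 0; i < n; ++i)
    if (bits[i]) words[i >> 5] = (int)(((uint32_t)words[i >> 5]) | (1u << (i & 31)));
  int nd = nw / 8 + 1;
  IntegerVector dirs(nd);
  int acc = 0;
  for (int j = 0; j < nw; ++j) {
    if ((j & 7) == 0) dirs[j >> 3] = acc;
    acc += __builtin_popcount((uint32_t)words[j]);
  }
  // superblocks past the last payload word hold the total count, so rank
  // queries at the very end of the vector stay correct
  for (int d = (nw + 7) / 8; d < nd; ++d) dirs[d] = acc;
  return List::create(_["words"] = words, _["dirs"] = dirs, _["len"] = n);
}

struct BV {
  IntegerVector words, dirs;
  int len;
  BV() : len(0) {}
  explicit BV(List l) {
    words = l["words"]; dirs = l["dirs"]; len = as<int>(l["len"]);
  }
  inline int get(int i) const {
    return (int)((((uint32_t)words[i >> 5]) >> (i & 31)) & 1u);
  }
  // number of set bits in [0, i)
  inline int rank1(int i) const {
    int sb = i >> 8;
    int cnt = dirs[sb];
    int wend = i >> 5;
    for (int j = sb << 3; j < wend; ++j)
      cnt += __builtin_popcount((uint32_t)words[j]);
    int rem = i & 31;
    if (rem) cnt += __builtin_popcount(((uint32_t)words[wend]) & ((1u << rem) - 1u));
    return cnt;
  }
  inline int rank0(int i) const { return i - rank1(i); }
};

// [[Rcpp::export]]
List cpp_build_bitvector(IntegerVector bits) {
  std::vector<char> b(bits.size());
  for (int i = 0; i < bits.size(); ++i) b[i] = bits[i] != 0;
  return build_bv(b);
}

// [[Rcpp::export]]
int cpp_bv_rank1(List bv, int i) { BV b(bv); return b.rank1(i); }

// ---------------------------------------------------------------------------
// Wavelet tree over {0,1,2,3} (two levels) for the BWT of h(T) + sentinel.
// The sentinel row stores bit pattern of symbol 0; rank queries for symbol 0
// correct for it using dollar_row.
// ---------------------------------------------------------------------------
struct WT {
  BV b1, b2l, b2r;
  int dollar_row;
  WT(List idx) {
    b1 = BV(as<List>(idx["wt_b1"]));
    b2l = BV(as<List>(idx["wt_b2l"]));
    b2r = BV(as<List>(idx["wt_b2r"]));
    dollar_row = as<int>(idx["dollar_row"]);
  }
  // count of symbol c among BWT[0, i), sentinel not counted as any symbol
  inline int occ(int c, int i) const {
    switch (c) {
      case 0: return b2l.rank0(b1.rank0(i)) - (dollar_row < i ? 1 : 0);
      case 1: return b2l.rank1(b1.rank0(i));
      case 2: return b2r.rank0(b1.rank1(i));
      default: return b2r.rank1(b1.rank1(i));
    }
  }
  // BWT symbol at row i; -1 for the sentinel row
  inline int access(int i) const {
    if (i == dollar_row) return -1;
    if (b1.get(i) == 0) return b2l.get(b1.rank0(i));
    return 2 + b2r.get(b1.rank1(i));
  }
};

// ---------------------------------------------------------------------------
// Build the FM layer: SA over h(T)+sentinel, BWT, wavelet bit vectors,
// text-position-regular SA samples (every s-th text position) and C array.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_build_fm(IntegerVector ht, int s) {
  int nh = ht.size();
  int n1 = nh + 1;
  std::vector<int> v(n1);
  for (int i = 0; i < nh; ++i) v[i] = ht[i] + 1;
  v[n1 - 1] = 0; // sentinel, unique minimum
  std::vector<int> sa = suffix_array_doubling(v);

  std::vector<char> bits1(n1), mark(n1);
  std::vector<char> bwt(n1);
  int dollar_row = -1;
  for (int i = 0; i < n1; ++i) {
    int p = sa[i];
    int c;
    if (p == 0) { c = 0; dollar_row = i; }
    else c = ht[p - 1];
    bwt[i] = (char)c;
  }
  // wavelet bits
  std::vector<char> b2l, b2r;
  b2l.reserve(n1); b2r.reserve(n1);
  for (int i = 0; i < n1; ++i) {
    int c = bwt[i];
    if (c >= 2) { bits1[i] = 1; b2r.push_back((char)(c == 3)); }
    else { bits1[i] = 0; b2l.push_back((char)(c == 1)); }
  }
  // SA samples at rows whose text position is a multiple of s
  std::vector<int> samples;
  for (int i = 0; i < n1; ++i) {
    if (sa[i] % s == 0) { mark[i] = 1; samples.push_back(sa[i]); }
  }
  // C array: C[c] = number of symbols in h(T)+sentinel smaller than c
  IntegerVector C(5);
  int cnt[4] = {0, 0, 0, 0};
  for (int i = 0; i < nh; ++i) cnt[ht[i]]++;
  C[0] = 1;
  for (int c = 1; c <= 4; ++c) C[c] = C[c - 1] + cnt[c - 1];

  return List::create(
    _["wt_b1"] = build_bv(bits1),
    _["wt_b2l"] = build_bv(b2l),
    _["wt_b2r"] = build_bv(b2r),
    _["mark"] = build_bv(mark),
    _["sa_samples"] = IntegerVector(samples.begin(), samples.end()),
    _["dollar_row"] = dollar_row,
    _["C"] = C,
    _["nprime"] = n1);
}

// [[Rcpp::export]]
int cpp_wt_access(List idx, int i) { WT wt(idx); return wt.access(i); }

// [[Rcpp::export]]
int cpp_wt_occ(List idx, int c, int i) { WT wt(idx); return wt.occ(c, i); }

// ---------------------------------------------------------------------------
// Backward search. Processes the query right to left; optionally replaces the
// first w_aux refinement steps (the last w_aux query symbols) with one lookup
// in the precomputed auxiliary table.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_backward_search(List idx, IntegerVector f, bool use_aux) {
  WT wt(idx);
  IntegerVector C = idx["C"];
  int n1 = as<int>(idx["nprime"]);
  int len = f.size();
  int l = 0, r = n1;
  int j = len - 1;
  if (use_aux && idx.containsElementNamed("aux_l")) {
    int w_aux = as<int>(idx["w_aux"]);
    if (w_aux > 0 && len >= w_aux) {
      IntegerVector aux_l = idx["aux_l"], aux_r = idx["aux_r"];
      int u = 0;
      for (int t = len - w_aux; t < len; ++t) u = u * 4 + f[t];
      l = aux_l[u]; r = aux_r[u];
      j = len - w_aux - 1;
    }
  }
  for (; j >= 0 && l < r; --j) {
    int c = f[j];
    l = C[c] + wt.occ(c, l);
    r = C[c] + wt.occ(c, r);
  }
  if (l > r) l = r;
  return IntegerVector::create(l, r);
}

// [[Rcpp::export]]
List cpp_build_aux(List idx, int w_aux) {
  int tbl = 1;
  for (int i = 0; i < w_aux; ++i) tbl *= 4;
  IntegerVector aux_l(tbl), aux_r(tbl);
  IntegerVector buf(w_aux);
  for (int u = 0; u < tbl; ++u) {
    int x = u;
    for (int t = w_aux - 1; t >= 0; --t) { buf[t] = x & 3; x >>= 2; }
    IntegerVector iv = cpp_backward_search(idx, buf, false);
    aux_l[u] = iv[0]; aux_r[u] = iv[1];
  }
  return List::create(_["aux_l"] = aux_l, _["aux_r"] = aux_r);
}

// ---------------------------------------------------------------------------
// locate: LF-walk each row of the interval to the nearest sampled row.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_locate(List idx, int l, int r) {
  WT wt(idx);
  IntegerVector C = idx["C"];
  BV mark(as<List>(idx["mark"]));
  IntegerVector samples = idx["sa_samples"];
  std::vector<int> out;
  out.reserve(std::max(0, r - l));
  for (int i = l; i < r; ++i) {
    int row = i, steps = 0;
    while (!mark.get(row)) {
      int c = wt.access(row); // never the sentinel row: text position 0 is sampled
      row = C[c] + wt.occ(c, row);
      ++steps;
    }
    out.push_back(samples[mark.rank1(row)] + steps);
  }
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// 3-bit packed text, 8 symbols per 32-bit word (24 payload bits).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_pack_text(IntegerVector syms) {
  int n = syms.size();
  int nw = (n + 7) / 8;
  IntegerVector words(nw);
  for (int i = 0; i < n; ++i)
    words[i >> 3] = (int)(((uint32_t)words[i >> 3]) | (((uint32_t)syms[i]) << (3 * (i & 7))));
  return words;
}

// [[Rcpp::export]]
IntegerVector cpp_unpack_text(IntegerVector words, int n, int from, int len) {
  if (from < 0 || from + len > n) stop("unpack range out of bounds");
  IntegerVector out(len);
  for (int i = 0; i < len; ++i) {
    int p = from + i;
    out[i] = (int)((((uint32_t)words[p >> 3]) >> (3 * (p & 7))) & 7u);
  }
  return out;
}

// Hamming distance between the packed text window starting at pos and a
// packed pattern; returns -1 as soon as the running count exceeds k.
// Blocks of 8 symbols are compared word-wise.
// [[Rcpp::export]]
int cpp_hamming_verify(IntegerVector twords, int n, IntegerVector pwords, int m,
                       int pos, int k) {
  if (pos < 0 || pos + m > n) stop("verification window out of text range");
  int nb = (m + 7) / 8;
  int ntw = twords.size();
  int dist = 0;
  for (int b = 0; b < nb; ++b) {
    int q = pos + 8 * b;
    int wi = q >> 3, off = q & 7;
    uint32_t tw = ((uint32_t)twords[wi]) >> (3 * off);
    if (off && wi + 1 < ntw) tw |= ((uint32_t)twords[wi + 1]) << (24 - 3 * off);
    tw &= 0xFFFFFFu;
    uint32_t pw = ((uint32_t)pwords[b]) & 0xFFFFFFu;
    int rem = m - 8 * b;
    if (rem < 8) { uint32_t msk = (1u << (3 * rem)) - 1u; tw &= msk; pw &= msk; }
    uint32_t d = tw ^ pw;
    d = d | (d >> 1) | (d >> 2);
    dist += __builtin_popcount(d & 0x249249u);
    if (dist > k) return -1;
  }
  return dist;
}

// ---------------------------------------------------------------------------
// Brute-force k-mismatch scanner over an unpacked symbol vector. Reference
// oracle, independent of the index and of the packed-text comparator.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_kmismatch_scan(IntegerVector text, IntegerVector pat, int k) {
  int n = text.size(), m = pat.size();
  std::vector<int> pos, dist;
  for (int i = 0; i + m <= n; ++i) {
    int d = 0;
    for (int j = 0; j < m; ++j) {
      if (text[i + j] != pat[j]) { if (++d > k) break; }
    }
    if (d <= k) { pos.push_back(i); dist.push_back(d); }
  }
  return List::create(_["pos"] = IntegerVector(pos.begin(), pos.end()),
                      _["dist"] = IntegerVector(dist.begin(), dist.end()));
}
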