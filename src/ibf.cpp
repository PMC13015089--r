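#include "epsmatch.h"
using namespace Rcpp;

// Per-hash seeds are fixed constants so that an index written by one session
// can be queried by another.
static const uint64_t IBF_SEED[8] = {
    0x8F462907'5BA1B2F1ULL, 0x1B5A8E79'D2C4F063ULL, 0x9C1F8B3A'7E6D5C41ULL,
    0x3D7E6A58'94B0C2D9ULL, 0x5E0D9C47'A3F18B26ULL, 0x7A2B4C6D'8E9F0135ULL,
    0x2C4E6F81'93A5B7D9ULL, 0x4F6A8C0E'25B7D931ULL};

static inline uint64_t hash_pos(double value, int j, uint64_t m) {
  return mix64((uint64_t)value + IBF_SEED[j]) % m;
}

static inline bool get_bit(const Rbyte* bits, uint64_t idx) {
  return (bits[idx >> 3] >> (idx & 7)) & 1;
}

static inline void set_bit(Rbyte* bits, uint64_t idx) {
  bits[idx >> 3] |= (Rbyte)(1u << (idx & 7));
}

// Interleaved layout: for hash position p, the b bin bits occupy
// bit indices [p*b, (p+1)*b).
// [[Rcpp::export]]
RawVector cpp_ibf_build(List bin_values, double m, int h) {
  const int b = bin_values.size();
  const uint64_t mm = (uint64_t)m;
  const uint64_t nbits = mm * (uint64_t)b;
  RawVector raw((R_xlen_t)((nbits + 7) / 8));
  Rbyte* bits = raw.begin();
  for (int i = 0; i < b; ++i) {
    NumericVector vals = bin_values[i];
    for (double v : vals) {
      if (NumericVector::is_na(v)) continue;
      for (int j = 0; j < h; ++j)
        set_bit(bits, hash_pos(v, j, mm) * (uint64_t)b + (uint64_t)i);
    }
  }
  return raw;
}

// [[Rcpp::export]]
NumericVector cpp_ibf_hash_positions(double value, int h, double m) {
  NumericVector out(h);
  for (int j = 0; j < h; ++j) out[j] = (double)hash_pos(value, j, (uint64_t)m);
  return out;
}

static inline void membership_mask(const Rbyte* bits, int b, uint64_t m, int h,
                                   double value, std::vector<uint64_t>& mask) {
  const int words = (b + 63) / 64;
  for (int w = 0; w < words; ++w) mask[w] = ~0ULL;
  for (int j = 0; j < h; ++j) {
    const uint64_t base = hash_pos(value, j, m) * (uint64_t)b;
    for (int w = 0; w < words; ++w) {
      uint64_t acc = 0;
      const int lo = w * 64, hi = std::min(b, lo + 64);
      for (int i = lo; i < hi; ++i)
        if (get_bit(bits, base + (uint64_t)i)) acc |= (1ULL << (i - lo));
      mask[w] &= acc;
    }
  }
}

// Shared k-mer counts per bin across a whole value vector.
// [[Rcpp::export]]
IntegerVector cpp_ibf_counts(RawVector raw, int b, double m, int h,
                             NumericVector values) {
  const Rbyte* bits = raw.begin();
  const uint64_t mm = (uint64_t)m;
  const int words = (b + 63) / 64;
  std::vector<uint64_t> mask(words);
  IntegerVector counts(b);
  for (double v : values) {
    if (NumericVector::is_na(v)) continue;
    membership_mask(bits, b, mm, h, v, mask);
    for (int w = 0; w < words; ++w) {
      uint64_t word = mask[w];
      while (word) {
        int bit = __builtin_ctzll(word);
        counts[w * 64 + bit] += 1;
        word &= word - 1;
      }
    }
  }
  return counts;
}

// Maximum per-bin shared k-mer count over sliding query windows of
// `window` residues advanced by `stride`.  `positions` are the 0-based
// window starts of `values` in the segment (invalid k-mers already removed).
// [[Rcpp::export]]
IntegerVector cpp_ibf_window_max(RawVector raw, int b, double m, int h,
                                 NumericVector values, IntegerVector positions,
                                 int window, int stride, int span,
                                 int seg_len) {
  const Rbyte* bits = raw.begin();
  const uint64_t mm = (uint64_t)m;
  const int words = (b + 63) / 64;
  const int V = values.size();
  // Pre-compute the membership mask of every value once.
  std::vector<uint64_t> masks((size_t)V * words);
  std::vector<uint64_t> tmp(words);
  for (int v = 0; v < V; ++v) {
    membership_mask(bits, b, mm, h, values[v], tmp);
    for (int w = 0; w < words; ++w) masks[(size_t)v * words + w] = tmp[w];
  }
  std::vector<int> starts;
  if (seg_len <= window) {
    starts.push_back(0);
  } else {
    for (int s = 0; s <= seg_len - window; s += stride) starts.push_back(s);
    if (starts.back() != seg_len - window) starts.push_back(seg_len - window);
  }
  IntegerVector best(b);
  std::vector<int> counts(b);
  const int* pbeg = positions.begin();
  const int* pend = pbeg + V;
  for (int s : starts) {
    std::fill(counts.begin(), counts.end(), 0);
    const int lo = s, hi = s + window - span;  // k-mer start range in window
    // positions are sorted ascending; restrict to [lo, hi]
    const int vlo = (int)(std::lower_bound(pbeg, pend, lo) - pbeg);
    const int vhi = (int)(std::upper_bound(pbeg, pend, hi) - pbeg);
    for (int v = vlo; v < vhi; ++v) {
      for (int w = 0; w < words; ++w) {
        uint64_t word = masks[(size_t)v * words + w];
        while (word) {
          int bit = __builtin_ctzll(word);
          counts[w * 64 + bit] += 1;
          word &= word - 1;
        }
      }
    }
    for (int i = 0; i < b; ++i)
      if (counts[i] > best[i]) best[i] = counts[i];
  }
  return best;
}
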