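#include "epsmatch.h"
using namespace Rcpp;

static std::vector<int> care_positions(const std::string& shape) {
  std::vector<int> care;
  for (size_t i = 0; i < shape.size(); ++i)
    if (shape[i] == '1') care.push_back((int)i);
  return care;
}

// Canonical gapped k-mer value of the window starting at p, or -1 if the
// window covers a non-ACGT residue.  The value is min(forward, revcomp)
// of the 2-bit packed care-position residues; the reverse-complement
// extraction reads the complemented window back-to-front under the same
// shape, so a window and its reverse complement always share one value.
static inline int64_t canonical_value(const std::vector<int>& enc, int p,
                                      int span, const std::vector<int>& care) {
  for (int i = 0; i < span; ++i)
    if (enc[p + i] < 0) return -1;
  uint64_t f = 0, r = 0;
  for (int c : care) f = (f << 2) | (uint64_t)enc[p + c];
  for (int c : care) r = (r << 2) | (uint64_t)(3 - enc[p + span - 1 - c]);
  return (int64_t)std::min(f, r);
}

static std::vector<int> encode_seq(const std::string& seq) {
  std::vector<int> enc(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) enc[i] = base_code(seq[i]);
  return enc;
}

// [[Rcpp::export]]
List cpp_kmer_stream(std::string seq, std::string shape) {
  const int span = (int)shape.size();
  const std::vector<int> care = care_positions(shape);
  const int L = (int)seq.size();
  const int nrec = std::max(0, L - span + 1);
  IntegerVector pos(nrec);
  NumericVector val(nrec);
  LogicalVector valid(nrec);
  std::vector<int> enc = encode_seq(seq);
  for (int p = 0; p < nrec; ++p) {
    pos[p] = p;
    int64_t canon = canonical_value(enc, p, span, care);
    if (canon < 0) {
      val[p] = NA_REAL;
      valid[p] = false;
    } else {
      // 53-bit slice of the mixed value: exactly representable as double
      val[p] = (double)(mix64((uint64_t)canon) >> 11);
      valid[p] = true;
    }
  }
  return List::create(_["position"] = pos, _["value"] = val,
                      _["valid"] = valid);
}

// [[Rcpp::export]]
double cpp_distinct_count(std::string seq, std::string shape) {
  const int span = (int)shape.size();
  const std::vector<int> care = care_positions(shape);
  const int L = (int)seq.size();
  std::unordered_set<uint64_t> seen;
  std::vector<int> enc = encode_seq(seq);
  for (int p = 0; p + span <= L; ++p) {
    int64_t canon = canonical_value(enc, p, span, care);
    if (canon >= 0) seen.insert((uint64_t)canon);
  }
  return (double)seen.size();
}
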