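#include "epsmatch.h"
using namespace Rcpp;

// Exact (non-probabilistic) ungapped q-gram positions of a set of sequences.
// Values are 2-bit packed; windows touching a non-ACGT residue are skipped.
// [[Rcpp::export]]
DataFrame cpp_qgram_positions(CharacterVector seqs, int q) {
  std::vector<int> seg, pos;
  std::vector<double> val;
  const uint64_t qmask = (q == 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);
  for (int s = 0; s < seqs.size(); ++s) {
    std::string str = as<std::string>(seqs[s]);
    uint64_t v = 0;
    int run = 0;
    for (int i = 0; i < (int)str.size(); ++i) {
      int c = base_code(str[i]);
      if (c < 0) {
        run = 0;
        v = 0;
        continue;
      }
      v = ((v << 2) | (uint64_t)c) & qmask;
      if (++run >= q) {
        seg.push_back(s + 1);
        pos.push_back(i - q + 1);
        val.push_back((double)v);
      }
    }
  }
  return DataFrame::create(_["segment"] = seg, _["position"] = pos,
                           _["value"] = val);
}

struct Hit {
  int d;     // diagonal = ref_pos - query_pos
  int qpos;  // query position of the q-gram
};

struct Region {
  int qs, qe, dmin, dmax, votes;
};

static Region make_region(const std::vector<Hit>& hb, size_t a, size_t b,
                          int q) {
  Region r;
  r.qs = hb[a].qpos;
  r.qe = hb[b - 1].qpos + q;
  r.dmin = hb[a].d;
  r.dmax = hb[a].d;
  r.votes = (int)(b - a);
  for (size_t i = a; i < b; ++i) {
    r.dmin = std::min(r.dmin, hb[i].d);
    r.dmax = std::max(r.dmax, hb[i].d);
  }
  return r;
}

// Parallelogram q-gram counting.  Every shared q-gram between the
// reference and a query votes at (diagonal d = ref_pos - query_pos,
// query position).  Votes are counted inside parallelograms of `window`
// query residues (each maximal epsilon-match contains an l_min-stretch
// with at most e_max errors, whose surviving q-gram starts span less than
// l_min query positions and at most e_band + 1 adjacent diagonals; a
// window of 2 l_min at stride l_min/2 always contains that stretch whole)
// crossed with diagonal buckets of power-of-two width
// 2^ceil(log2(2 (e_band + 1))) evaluated at two half-offset phases, so
// every (e_band + 1)-wide diagonal span falls whole into some bucket.
// Parallelograms reaching `threshold` votes are emitted; qualifying
// windows sharing hits are unioned, and overlapping regions merged.
// [[Rcpp::export]]
DataFrame cpp_swift_scan(std::string ref, CharacterVector queries, int q,
                         int threshold, int e_band, int window) {
  const uint64_t qmask = (q == 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);
  // index query q-grams
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (int s = 0; s < queries.size(); ++s) {
    std::string str = as<std::string>(queries[s]);
    uint64_t v = 0;
    int run = 0;
    for (int i = 0; i < (int)str.size(); ++i) {
      int c = base_code(str[i]);
      if (c < 0) {
        run = 0;
        v = 0;
        continue;
      }
      v = ((v << 2) | (uint64_t)c) & qmask;
      if (++run >= q) index[v].push_back({s, i - q + 1});
    }
  }
  // scan the reference, collect hits per query segment
  std::vector<std::vector<Hit>> hits(queries.size());
  {
    uint64_t v = 0;
    int run = 0;
    for (int i = 0; i < (int)ref.size(); ++i) {
      int c = base_code(ref[i]);
      if (c < 0) {
        run = 0;
        v = 0;
        continue;
      }
      v = ((v << 2) | (uint64_t)c) & qmask;
      if (++run >= q) {
        auto it = index.find(v);
        if (it == index.end()) continue;
        const int rpos = i - q + 1;
        for (auto& sp : it->second)
          hits[sp.first].push_back({rpos - sp.second, sp.second});
      }
    }
  }
  // bucket width: smallest power of two >= 2 * (e_band + 1)
  int delta = 2;
  while (delta < 2 * (e_band + 1)) delta <<= 1;
  const int half = delta / 2;

  std::vector<int> o_seg, o_qs, o_qe, o_dmin, o_dmax, o_votes;
  for (int s = 0; s < (int)hits.size(); ++s) {
    auto& hv = hits[s];
    if (hv.empty()) continue;
    std::vector<Region> regions;
    for (int phase = 0; phase < 2; ++phase) {
      const int off = phase * half;
      // (bucket, qpos)-sorted view of the hits for this phase
      std::vector<Hit> hb(hv);
      auto bucket_of = [&](const Hit& h) {
        // bias keeps the floor division stable for negative diagonals
        return (int)(((int64_t)h.d + off + (1LL << 30)) / delta);
      };
      std::sort(hb.begin(), hb.end(), [&](const Hit& a, const Hit& b) {
        int ba = bucket_of(a), bb = bucket_of(b);
        return ba != bb ? ba < bb : a.qpos < b.qpos;
      });
      size_t g0 = 0;
      while (g0 < hb.size()) {
        size_t g1 = g0 + 1;
        while (g1 < hb.size() && bucket_of(hb[g1]) == bucket_of(hb[g0])) ++g1;
        // sliding query windows over this bucket's hits (sorted by qpos)
        size_t ra = 0, rb = 0;  // current merged qualifying hit range
        bool active = false;
        size_t j = g0;
        for (size_t i = g0; i < g1; ++i) {
          if (j < i + 1) j = i + 1;
          while (j < g1 && hb[j].qpos < hb[i].qpos + window) ++j;
          if ((int)(j - i) >= threshold) {
            if (active && i <= rb) {
              rb = std::max(rb, j);
            } else {
              if (active) {
                regions.push_back(make_region(hb, ra, rb, q));
              }
              ra = i;
              rb = j;
              active = true;
            }
          }
        }
        if (active) regions.push_back(make_region(hb, ra, rb, q));
        g0 = g1;
      }
    }
    // merge overlapping regions across phases/buckets
    std::vector<bool> dead(regions.size(), false);
    bool changed = true;
    while (changed) {
      changed = false;
      for (size_t a = 0; a < regions.size(); ++a) {
        if (dead[a]) continue;
        for (size_t b = a + 1; b < regions.size(); ++b) {
          if (dead[b]) continue;
          if (regions[a].qs < regions[b].qe && regions[b].qs < regions[a].qe &&
              regions[a].dmin <= regions[b].dmax + 1 &&
              regions[b].dmin <= regions[a].dmax + 1) {
            regions[a].qs = std::min(regions[a].qs, regions[b].qs);
            regions[a].qe = std::max(regions[a].qe, regions[b].qe);
            regions[a].dmin = std::min(regions[a].dmin, regions[b].dmin);
            regions[a].dmax = std::max(regions[a].dmax, regions[b].dmax);
            regions[a].votes = std::max(regions[a].votes, regions[b].votes);
            dead[b] = true;
            changed = true;
          }
        }
      }
    }
    for (size_t a = 0; a < regions.size(); ++a) {
      if (dead[a]) continue;
      o_seg.push_back(s + 1);
      o_qs.push_back(regions[a].qs);
      o_qe.push_back(regions[a].qe);
      o_dmin.push_back(regions[a].dmin);
      o_dmax.push_back(regions[a].dmax);
      o_votes.push_back(regions[a].votes);
    }
  }
  return DataFrame::create(_["segment"] = o_seg, _["qstart"] = o_qs,
                           _["qend"] = o_qe, _["dmin"] = o_dmin,
                           _["dmax"] = o_dmax, _["votes"] = o_votes);
}
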