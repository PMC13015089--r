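#include "epsmatch.h"
using namespace Rcpp;

// Alignment column codes along a traceback path (path order).
enum { OP_M = 0, OP_X = 1, OP_I = 2, OP_D = 3 };
// OP_I consumes a query residue (gap in the reference row),
// OP_D consumes a reference residue (gap in the query row).

struct EMatch {
  int qs, qe, rs, re, n, e, score;
};

// Extract every maximal epsilon-feasible sub-interval of one alignment path.
// An interval [a, b] of columns is feasible when both endpoint columns are
// match columns, its length n = b - a + 1 is at least lmin and its error
// columns e satisfy e * lmin <= emax * n (integer arithmetic).  Intervals
// contained in another feasible interval are dropped.
static std::vector<EMatch> extract_eps(const std::vector<uint8_t>& ops, int q0,
                                       int r0, int lmin, int emax, int mat,
                                       int mis, int gap) {
  const int N = (int)ops.size();
  std::vector<int> qoff(N + 1), roff(N + 1), err(N + 1), sc(N + 1);
  for (int i = 0; i < N; ++i) {
    qoff[i + 1] = qoff[i] + (ops[i] == OP_M || ops[i] == OP_X || ops[i] == OP_I);
    roff[i + 1] = roff[i] + (ops[i] == OP_M || ops[i] == OP_X || ops[i] == OP_D);
    err[i + 1] = err[i] + (ops[i] != OP_M);
    sc[i + 1] = sc[i] + (ops[i] == OP_M ? mat : (ops[i] == OP_X ? mis : gap));
  }
  std::vector<int> mcols;
  for (int i = 0; i < N; ++i)
    if (ops[i] == OP_M) mcols.push_back(i);
  // For a fixed start a, any feasible (a, b) with b below the largest
  // feasible end is contained in (a, b_max), so only b_max survives.
  std::vector<std::pair<int, int>> feas;
  for (size_t ia = 0; ia < mcols.size(); ++ia) {
    const int a = mcols[ia];
    int bmax = -1;
    for (size_t ib = ia; ib < mcols.size(); ++ib) {
      const int b = mcols[ib];
      const int nlen = b - a + 1;
      if (nlen < lmin) continue;
      const int e = err[b + 1] - err[a];
      if ((int64_t)e * lmin <= (int64_t)emax * nlen) bmax = b;
    }
    if (bmax >= 0) feas.push_back({a, bmax});
  }
  // keep only maximal intervals
  std::sort(feas.begin(), feas.end(), [](const std::pair<int, int>& x,
                                         const std::pair<int, int>& y) {
    return x.first != y.first ? x.first < y.first : x.second > y.second;
  });
  std::vector<EMatch> out;
  int best_b = -1;
  for (auto& ab : feas) {
    if (ab.second <= best_b) continue;
    best_b = ab.second;
    EMatch m;
    m.qs = q0 + qoff[ab.first];
    m.qe = q0 + qoff[ab.second + 1];
    m.rs = r0 + roff[ab.first];
    m.re = r0 + roff[ab.second + 1];
    m.n = ab.second - ab.first + 1;
    m.e = err[ab.second + 1] - err[ab.first];
    m.score = sc[ab.second + 1] - sc[ab.first];
    out.push_back(m);
  }
  return out;
}

// X-drop extension of an alignment path endpoint.  Starting at query/ref
// offsets (q0, r0), a small banded DP walks outward (dir = -1 left,
// +1 right), following per-cell optimal scores until every cell of a row
// falls more than xdrop below the best score seen.  The deepest explored
// row's best cell is taken as the endpoint -- the epsilon extraction
// afterwards trims the low-scoring tail -- so maximal epsilon-matches
// whose borders cost score (e.g. an indel cluster near the end) are still
// reachable from a shorter score-optimal core.
static std::vector<uint8_t> xdrop_extend(const std::string& ref,
                                         const std::string& query, int q0,
                                         int r0, int dir, int band,
                                         int max_cols, int mat, int mis,
                                         int gap, int xdrop, int& dq_out,
                                         int& dr_out) {
  const int W = 2 * band + 1;
  const int NEG = INT_MIN / 4;
  const int qavail = dir < 0 ? q0 : (int)query.size() - q0;
  const int ravail = dir < 0 ? r0 : (int)ref.size() - r0;
  const int maxi = std::min(max_cols, qavail);
  std::vector<int> H((size_t)(maxi + 1) * W, NEG);
  std::vector<uint8_t> dirm((size_t)(maxi + 1) * W, 0);
  auto qch = [&](int i) {  // i-th query char outward (1-based)
    return dir < 0 ? query[q0 - i] : query[q0 + i - 1];
  };
  auto rch = [&](int j) {
    return dir < 0 ? ref[r0 - j] : ref[r0 + j - 1];
  };
  H[band] = 0;
  int best = 0;
  int deep_i = 0, deep_d = band, deep_total = 0, deep_score = 0;
  bool stopped = false;
  for (int i = 0; i <= maxi && !stopped; ++i) {
    int row_best = NEG;
    for (int dI = 0; dI < W; ++dI) {
      const int j = i + dI - band;  // ref chars consumed
      if (j < 0 || j > ravail) continue;
      if (i == 0 && dI == band) {
        row_best = std::max(row_best, 0);
        continue;
      }
      int h = NEG;
      uint8_t d = 0;
      if (i > 0 && j > 0) {
        const int ph = H[(size_t)(i - 1) * W + dI];
        if (ph > NEG / 2) {
          const int ca = base_code(qch(i));
          const int cb = base_code(rch(j));
          const int s = ph + ((ca >= 0 && ca == cb) ? mat : mis);
          if (s > h) {
            h = s;
            d = 1;
          }
        }
      }
      if (i > 0 && dI + 1 < W) {
        const int ph = H[(size_t)(i - 1) * W + dI + 1];
        if (ph > NEG / 2 && ph + gap > h) {
          h = ph + gap;
          d = 2;
        }
      }
      if (dI > 0 && j > 0) {
        const int ph = H[(size_t)i * W + dI - 1];
        if (ph > NEG / 2 && ph + gap > h) {
          h = ph + gap;
          d = 3;
        }
      }
      if (h <= NEG / 2) continue;
      if (h < best - xdrop) continue;  // pruned by the X-drop bound
      H[(size_t)i * W + dI] = h;
      dirm[(size_t)i * W + dI] = d;
      if (h > row_best) row_best = h;
      if (h > best) best = h;
      // deepest endpoint by consumed columns, ties to higher score
      if (i + j > deep_total || (i + j == deep_total && h > deep_score)) {
        deep_i = i;
        deep_d = dI;
        deep_total = i + j;
        deep_score = h;
      }
    }
    if (row_best < best - xdrop) stopped = true;
  }
  // traceback from the deepest endpoint
  std::vector<uint8_t> ops;
  int i = deep_i, dI = deep_d;
  while (!(i == 0 && dI == band) && dirm[(size_t)i * W + dI] != 0) {
    const uint8_t d = dirm[(size_t)i * W + dI];
    if (d == 1) {
      const int j = i + dI - band;
      const int ca = base_code(qch(i));
      const int cb = base_code(rch(j));
      ops.push_back((ca >= 0 && ca == cb) ? OP_M : OP_X);
      i -= 1;
    } else if (d == 2) {
      ops.push_back(OP_I);
      i -= 1;
      dI += 1;
    } else {
      ops.push_back(OP_D);
      dI -= 1;
    }
  }
  dq_out = deep_i;
  dr_out = deep_i + deep_d - band;
  // the traceback pushes the outermost column first
  return ops;
}

// Extend a traceback path on both ends and return the extended path with
// its new start coordinates.
static void extend_path(const std::string& ref, const std::string& query,
                        std::vector<uint8_t>& ops, int& q0, int& r0,
                        int band, int max_cols, int mat, int mis, int gap,
                        int xdrop) {
  int dq = 0, dr = 0;
  // left: walk outward from the path start; the outermost-first traceback
  // order is already path order for a left segment
  std::vector<uint8_t> left =
      xdrop_extend(ref, query, q0, r0, -1, band, max_cols, mat, mis, gap,
                   xdrop, dq, dr);
  if (!left.empty()) {
    left.insert(left.end(), ops.begin(), ops.end());
    ops.swap(left);
    q0 -= dq;
    r0 -= dr;
  }
  // right: walk outward from the path end; reverse into path order
  int q1 = q0, r1 = r0;
  for (uint8_t op : ops) {
    if (op == OP_M || op == OP_X || op == OP_I) ++q1;
    if (op == OP_M || op == OP_X || op == OP_D) ++r1;
  }
  std::vector<uint8_t> right =
      xdrop_extend(ref, query, q1, r1, +1, band, max_cols, mat, mis, gap,
                   xdrop, dq, dr);
  std::reverse(right.begin(), right.end());
  ops.insert(ops.end(), right.begin(), right.end());
}

static DataFrame matches_frame(const std::vector<EMatch>& ms) {
  const int n = (int)ms.size();
  IntegerVector rs(n), re(n), qs(n), qe(n), len(n), err(n), sc(n);
  for (int i = 0; i < n; ++i) {
    rs[i] = ms[i].rs;
    re[i] = ms[i].re;
    qs[i] = ms[i].qs;
    qe[i] = ms[i].qe;
    len[i] = ms[i].n;
    err[i] = ms[i].e;
    sc[i] = ms[i].score;
  }
  return DataFrame::create(_["rstart"] = rs, _["rend"] = re, _["qstart"] = qs,
                           _["qend"] = qe, _["length"] = len,
                           _["errors"] = err, _["score"] = sc);
}

// Banded Waterman-Eggert over query rows [qlo, qhi) and diagonals
// d = ref_pos - query_pos in [dlo, dhi].  Non-intersecting local alignments
// are reported in score order until the best score drops below min_score;
// cells of a reported path are masked before the matrix is recomputed.
// Each path is post-processed into its maximal epsilon-feasible intervals.
// [[Rcpp::export]]
DataFrame cpp_banded_we(std::string ref, std::string query, int qlo, int qhi,
                        int dlo, int dhi, int lmin, int emax, int mat, int mis,
                        int gap, int min_score, int max_rounds, int xdrop) {
  const int n = (int)ref.size();
  qlo = std::max(0, qlo);
  qhi = std::min((int)query.size(), qhi);
  const int m = qhi - qlo;
  const int W = dhi - dlo + 1;
  if (m < 0 || W <= 0) return matches_frame({});
  const int NEG = INT_MIN / 4;
  std::vector<int> H((size_t)(m + 1) * W, NEG);
  std::vector<uint8_t> dir((size_t)(m + 1) * W, 0);
  std::vector<uint8_t> used((size_t)(m + 1) * W, 0);
  std::vector<EMatch> results;
  for (int round = 0; round < max_rounds; ++round) {
    int best = NEG, bi = -1, bd = -1;
    for (int i = 0; i <= m; ++i) {
      const size_t row = (size_t)i * W;
      for (int dI = 0; dI < W; ++dI) {
        const int j = qlo + i + dlo + dI;  // reference residues consumed
        if (j < 0 || j > n) {
          H[row + dI] = NEG;
          dir[row + dI] = 0;
          continue;
        }
        if (used[row + dI]) {
          H[row + dI] = 0;
          dir[row + dI] = 0;
          continue;
        }
        int h = 0;
        uint8_t d = 0;
        if (i > 0 && j > 0) {
          const int ph = H[row - W + dI];
          if (ph > NEG / 2) {
            const int ca = base_code(query[qlo + i - 1]);
            const int cb = base_code(ref[j - 1]);
            const int s = ph + ((ca >= 0 && ca == cb) ? mat : mis);
            if (s > h) {
              h = s;
              d = 1;
            }
          }
        }
        if (i > 0 && dI + 1 < W) {  // consume query residue (gap in ref)
          const int ph = H[row - W + dI + 1];
          if (ph > NEG / 2 && ph + gap > h) {
            h = ph + gap;
            d = 2;
          }
        }
        if (dI > 0 && j > 0) {  // consume reference residue (gap in query)
          const int ph = H[row + dI - 1];
          if (ph > NEG / 2 && ph + gap > h) {
            h = ph + gap;
            d = 3;
          }
        }
        H[row + dI] = h;
        dir[row + dI] = d;
        if (h > best) {
          best = h;
          bi = i;
          bd = dI;
        }
      }
    }
    if (best < min_score) break;
    // traceback, masking the path
    std::vector<uint8_t> ops;
    int i = bi, dI = bd;
    while (dir[(size_t)i * W + dI] != 0) {
      const size_t idx = (size_t)i * W + dI;
      const uint8_t d = dir[idx];
      used[idx] = 1;
      if (d == 1) {
        const int j = qlo + i + dlo + dI;
        const int ca = base_code(query[qlo + i - 1]);
        const int cb = base_code(ref[j - 1]);
        ops.push_back((ca >= 0 && ca == cb) ? OP_M : OP_X);
        i -= 1;  // same dI
      } else if (d == 2) {
        ops.push_back(OP_I);
        i -= 1;
        dI += 1;
      } else {
        ops.push_back(OP_D);
        dI -= 1;
      }
    }
    if (ops.empty()) break;  // safety: nothing to mask, avoid livelock
    std::reverse(ops.begin(), ops.end());
    int q0 = qlo + i;
    int r0 = qlo + i + dlo + dI;
    extend_path(ref, query, ops, q0, r0, 2 * emax + 4, 2 * lmin + 2 * xdrop,
                mat, mis, gap, xdrop);
    for (auto& mres : extract_eps(ops, q0, r0, lmin, emax, mat, mis, gap))
      results.push_back(mres);
  }
  return matches_frame(results);
}

// Exhaustive full-matrix Waterman-Eggert enumerator.  Independent of the
// banded engine above (its own dynamic program and traceback); used as the
// reference implementation that the filter pipeline is compared against.
// [[Rcpp::export]]
DataFrame cpp_full_we(std::string ref, std::string query, int lmin, int emax,
                      int mat, int mis, int gap, int min_score,
                      int max_rounds, int xdrop) {
  const int n = (int)ref.size();
  const int m = (int)query.size();
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> dir((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> used((size_t)(m + 1) * (n + 1), 0);
  std::vector<EMatch> results;
  for (int round = 0; round < max_rounds; ++round) {
    int best = -1, bi = -1, bj = -1;
    for (int i = 0; i <= m; ++i) {
      const size_t row = (size_t)i * (n + 1);
      for (int j = 0; j <= n; ++j) {
        if (used[row + j]) {
          H[row + j] = 0;
          dir[row + j] = 0;
          continue;
        }
        int h = 0;
        uint8_t d = 0;
        if (i > 0 && j > 0) {
          const int ca = base_code(query[i - 1]);
          const int cb = base_code(ref[j - 1]);
          const int s = H[row - (n + 1) + j - 1] + ((ca >= 0 && ca == cb) ? mat : mis);
          if (s > h) {
            h = s;
            d = 1;
          }
        }
        if (i > 0) {
          const int s = H[row - (n + 1) + j] + gap;
          if (s > h) {
            h = s;
            d = 2;
          }
        }
        if (j > 0) {
          const int s = H[row + j - 1] + gap;
          if (s > h) {
            h = s;
            d = 3;
          }
        }
        H[row + j] = h;
        dir[row + j] = d;
        if (h > best) {
          best = h;
          bi = i;
          bj = j;
        }
      }
    }
    if (best < min_score) break;
    std::vector<uint8_t> ops;
    int i = bi, j = bj;
    while (dir[(size_t)i * (n + 1) + j] != 0) {
      const size_t idx = (size_t)i * (n + 1) + j;
      const uint8_t d = dir[idx];
      used[idx] = 1;
      if (d == 1) {
        const int ca = base_code(query[i - 1]);
        const int cb = base_code(ref[j - 1]);
        ops.push_back((ca >= 0 && ca == cb) ? OP_M : OP_X);
        --i;
        --j;
      } else if (d == 2) {
        ops.push_back(OP_I);
        --i;
      } else {
        ops.push_back(OP_D);
        --j;
      }
    }
    if (ops.empty()) break;
    std::reverse(ops.begin(), ops.end());
    int q0 = i, r0 = j;
    extend_path(ref, query, ops, q0, r0, 2 * emax + 4, 2 * lmin + 2 * xdrop,
                mat, mis, gap, xdrop);
    for (auto& mres : extract_eps(ops, q0, r0, lmin, emax, mat, mis, gap))
      results.push_back(mres);
  }
  return matches_frame(results);
}
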