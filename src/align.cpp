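#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode; -1 for N or anything non-ACGT
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

// Ungapped x-drop extension of an exact seed match.
// Returns (sstart, send, qstart, qend, score, matches), 0-based half-open.
// The reported extent is trimmed to the maximum-scoring prefix/suffix, so
// block ends sit at the local score maximum, not where the x-drop fired.
struct Block { int ss, se, qs, qe, score, matches; };

static Block extend_seed(const std::vector<int>& S, const std::vector<int>& Q,
                         int sp, int qp, int k, int match, int mismatch, int xdrop) {
  int score = k * match, matches = k;
  // right extension
  int best = score, best_s = sp + k, best_q = qp + k, bm = matches;
  int cs = score, cm = matches;
  int i = sp + k, j = qp + k;
  while (i < (int)S.size() && j < (int)Q.size()) {
    if (S[i] >= 0 && S[i] == Q[j]) { cs += match; cm += 1; }
    else cs += mismatch;
    ++i; ++j;
    if (cs > best) { best = cs; best_s = i; best_q = j; bm = cm; }
    if (best - cs > xdrop) break;
  }
  int se = best_s, qe = best_q;
  score = best; matches = bm;
  // left extension
  best = score; cs = score; cm = matches;
  int best_s2 = sp, best_q2 = qp;
  i = sp - 1; j = qp - 1;
  while (i >= 0 && j >= 0) {
    if (S[i] >= 0 && S[i] == Q[j]) { cs += match; cm += 1; }
    else cs += mismatch;
    if (cs > best) { best = cs; best_s2 = i; best_q2 = j; matches = cm; }
    if (best - cs > xdrop) break;
    --i; --j;
  }
  Block b; b.ss = best_s2; b.se = se; b.qs = best_q2; b.qe = qe;
  b.score = best; b.matches = matches;
  return b;
}

// Seed-and-extend of each query against one subject sequence.
// Exact k-mer seeds (k-mers containing N are never seeded), ungapped x-drop
// extension. two_hit requires a second seed on the same diagonal within
// two_hit_window bp before an extension is triggered.
// [[Rcpp::export]]
DataFrame cpp_seed_extend_multi(std::string subject, CharacterVector queries,
                                int k, int match, int mismatch, int xdrop,
                                int min_score, bool two_hit, int two_hit_window) {
  std::vector<int> S = encode(subject);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // index subject k-mers
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(S.size() / 2 + 16);
  {
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < (int)S.size(); ++i) {
      if (S[i] < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)S[i]) & mask;
      if (++run >= k) idx[h].push_back(i - k + 1);
    }
  }
  std::vector<int> out_q, out_ss, out_se, out_qs, out_qe, out_sc, out_m;
  // per-diagonal bookkeeping uses generation-stamped flat arrays (diagonal
  // index = sp - qp + maxQ) so nothing needs clearing between queries
  size_t maxQ = 0;
  for (int qi = 0; qi < queries.size(); ++qi)
    maxQ = std::max(maxQ, (size_t)LENGTH(STRING_ELT(queries, qi)));
  size_t ndiag = S.size() + maxQ + 2;
  std::vector<int> seed_pos(ndiag, 0), seed_gen(ndiag, -1);
  std::vector<int> cov_end(ndiag, 0), cov_gen(ndiag, -1);
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::vector<int> Q = encode(as<std::string>(queries[qi]));
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < (int)Q.size(); ++j) {
      if (Q[j] < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)Q[j]) & mask;
      if (++run < k) continue;
      int qp = j - k + 1;
      auto it = idx.find(h);
      if (it == idx.end()) continue;
      for (int sp : it->second) {
        size_t d = (size_t)((int64_t)sp - (int64_t)qp + (int64_t)maxQ);
        if (cov_gen[d] == qi && qp < cov_end[d]) continue;
        if (two_hit) {
          if (seed_gen[d] != qi || qp - seed_pos[d] > two_hit_window) {
            seed_gen[d] = qi; seed_pos[d] = qp;  // first (or stale) hit
            continue;
          }
          if (qp - seed_pos[d] < k) continue;  // overlapping word
        }
        Block b = extend_seed(S, Q, sp, qp, k, match, mismatch, xdrop);
        cov_gen[d] = qi; cov_end[d] = b.qe;
        if (b.score >= min_score) {
          out_q.push_back(qi + 1);
          out_ss.push_back(b.ss); out_se.push_back(b.se);
          out_qs.push_back(b.qs); out_qe.push_back(b.qe);
          out_sc.push_back(b.score); out_m.push_back(b.matches);
        }
      }
    }
  }
  return DataFrame::create(_["query"] = out_q,
                           _["sstart"] = out_ss, _["send"] = out_se,
                           _["qstart"] = out_qs, _["qend"] = out_qe,
                           _["score"] = out_sc, _["matches"] = out_m);
}

// Sliding-window identity scan over alignment columns.
// status: 1 = match, 0 = mismatch or gap column, -1 = excluded column.
// A window never spans an excluded column; all columns of a qualifying
// window (>= min_matches matching columns) are marked.
// [[Rcpp::export]]
LogicalVector cpp_window_scan(IntegerVector status, int window, int min_matches) {
  int n = status.size();
  LogicalVector marked(n, false);
  int start = 0;
  while (start < n) {
    while (start < n && status[start] < 0) ++start;
    int end = start;
    while (end < n && status[end] >= 0) ++end;  // [start, end) excluded-free
    if (end - start >= window) {
      int sum = 0;
      for (int i = start; i < start + window; ++i) sum += status[i];
      int mark_until = -1;
      for (int w = start; w + window <= end; ++w) {
        if (w > start) sum += status[w + window - 1] - status[w - 1];
        if (sum >= min_matches) {
          int from = std::max(w, mark_until + 1);
          for (int i = from; i < w + window; ++i) marked[i] = true;
          mark_until = w + window - 1;
        }
      }
    }
    start = end;
  }
  return marked;
}

// Maximum-score collinear chaining by iterated DP extraction.
// Blocks must belong to one (ref seq, query seq, strand) group and be sorted
// by rstart (ties by qstart). Linking is allowed when block j strictly
// precedes block i on both genomes and both gaps are <= max_gap; the link
// cost is gap_open + per_bp * (ref_gap + query_gap). The best-scoring chain
// is extracted, its blocks removed, and the DP repeated until all blocks are
// assigned. Returns a chain id (1 = best score) per block.
// [[Rcpp::export]]
IntegerVector cpp_chain_blocks(IntegerVector rstart, IntegerVector rend,
                               IntegerVector qstart, IntegerVector qend,
                               NumericVector score,
                               double gap_open, double per_bp, double max_gap) {
  int n = rstart.size();
  IntegerVector chain(n, NA_INTEGER);
  std::vector<double> best(n);
  std::vector<int> pred(n);
  int assigned = 0, cid = 0;
  while (assigned < n) {
    ++cid;
    int top = -1;
    double topscore = -1e300;
    for (int i = 0; i < n; ++i) {
      if (chain[i] != NA_INTEGER) continue;
      best[i] = score[i]; pred[i] = -1;
      for (int j = 0; j < i; ++j) {
        if (chain[j] != NA_INTEGER) continue;
        double rgap = (double)rstart[i] - rend[j];
        double qgap = (double)qstart[i] - qend[j];
        if (rgap < 0 || qgap < 0 || rgap > max_gap || qgap > max_gap) continue;
        double cand = best[j] - gap_open - per_bp * (rgap + qgap) + score[i];
        if (cand > best[i]) { best[i] = cand; pred[i] = j; }
      }
      if (best[i] > topscore) { topscore = best[i]; top = i; }
    }
    for (int i = top; i >= 0; i = pred[i]) { chain[i] = cid; ++assigned; }
  }
  return chain;
}
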