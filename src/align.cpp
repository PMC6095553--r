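#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <unordered_map>
#include <vector>
#include <queue>
using namespace Rcpp;

// 2-bit base encoding; anything not ACGT (incl. N) -> -1 and never matches.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int> encode_seq(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// Exact k-mer seed matches between query and subject, plus strand only.
// Returns a 2-column matrix of 1-based start positions (q_start, s_start).
// k-mers containing N never match.
// [[Rcpp::export]]
IntegerMatrix cpp_find_seeds(std::string query, std::string subject, int k) {
  std::vector<int> q = encode_seq(query), s = encode_seq(subject);
  int nq = (int)q.size(), ns = (int)s.size();
  std::vector<int> qs, ss;
  if (k < 1 || k > 31 || nq < k || ns < k) {
    IntegerMatrix out(0, 2);
    colnames(out) = CharacterVector::create("q_start", "s_start");
    return out;
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // hash subject k-mers
  std::unordered_map<uint64_t, std::vector<int>> tab;
  tab.reserve(ns * 2);
  {
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < ns; ++j) {
      if (s[j] < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)s[j]) & mask;
      run = std::min(run + 1, k);
      if (run == k) tab[h].push_back(j - k + 1);
    }
  }
  {
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < nq; ++i) {
      if (q[i] < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)q[i]) & mask;
      run = std::min(run + 1, k);
      if (run == k) {
        auto it = tab.find(h);
        if (it != tab.end()) {
          for (int j : it->second) { qs.push_back(i - k + 2); ss.push_back(j + 1); }
        }
      }
    }
  }
  IntegerMatrix out((int)qs.size(), 2);
  for (size_t r = 0; r < qs.size(); ++r) { out(r, 0) = qs[r]; out(r, 1) = ss[r]; }
  colnames(out) = CharacterVector::create("q_start", "s_start");
  return out;
}

struct Ext { int qa, qb, sa, sb, score, matches, len; };

static Ext ungapped_extend_core(const std::vector<int> &q,
                                const std::vector<int> &s,
                                int i0, int j0, int k,
                                int match, int mismatch, int xdrop) {
  int nq = (int)q.size(), ns = (int)s.size();
  int score = k * match;
  // right extension
  int best = score, best_re = i0 + k - 1; // inclusive 0-based query end
  {
    int cur = score;
    int i = i0 + k, j = j0 + k;
    while (i < nq && j < ns) {
      cur += (q[i] >= 0 && q[i] == s[j]) ? match : mismatch;
      if (cur > best) { best = cur; best_re = i; }
      if (best - cur > xdrop) break;
      ++i; ++j;
    }
  }
  // left extension
  int best2 = best, best_ls = i0;
  {
    int cur = best;
    int i = i0 - 1, j = j0 - 1;
    while (i >= 0 && j >= 0) {
      cur += (q[i] >= 0 && q[i] == s[j]) ? match : mismatch;
      if (cur > best2) { best2 = cur; best_ls = i; }
      if (best2 - cur > xdrop) break;
      --i; --j;
    }
  }
  int qa = best_ls, qb = best_re;
  int sa = j0 - (i0 - qa), sb = j0 + k - 1 + (qb - (i0 + k - 1));
  int len = qb - qa + 1, matches = 0;
  for (int t = 0; t < len; ++t)
    if (q[qa + t] >= 0 && q[qa + t] == s[sa + t]) ++matches;
  Ext e; e.qa = qa; e.qb = qb; e.sa = sa; e.sb = sb;
  e.score = best2; e.matches = matches; e.len = len;
  return e;
}

// Ungapped x-drop extension of an exact seed (1-based coords, length k).
// Returns c(q_start, q_end, s_start, s_end, score, matches, length).
// [[Rcpp::export]]
IntegerVector cpp_ungapped_extend(std::string query, std::string subject,
                                  int q_start, int s_start, int k,
                                  int match, int mismatch, int xdrop) {
  std::vector<int> q = encode_seq(query), s = encode_seq(subject);
  Ext e = ungapped_extend_core(q, s, q_start - 1, s_start - 1, k,
                               match, mismatch, xdrop);
  return IntegerVector::create(
    _["q_start"] = e.qa + 1, _["q_end"] = e.qb + 1,
    _["s_start"] = e.sa + 1, _["s_end"] = e.sb + 1,
    _["score"] = e.score, _["matches"] = e.matches, _["length"] = e.len);
}

// Batched ungapped extension with per-diagonal coverage pruning.  Seeds must
// be sorted by (s_start - q_start, q_start); a seed already covered by the
// previous extension on the same diagonal is skipped.  Returns a matrix with
// one row per retained extension.
// [[Rcpp::export]]
IntegerMatrix cpp_extend_seeds(std::string query, std::string subject,
                               IntegerVector q_starts, IntegerVector s_starts,
                               int k, int match, int mismatch, int xdrop) {
  std::vector<int> q = encode_seq(query), s = encode_seq(subject);
  int nseed = q_starts.size();
  std::vector<Ext> out;
  long long cur_diag = LLONG_MIN;
  int last_q_end = -1; // 0-based inclusive
  for (int r = 0; r < nseed; ++r) {
    int i0 = q_starts[r] - 1, j0 = s_starts[r] - 1;
    long long diag = (long long)j0 - (long long)i0;
    if (diag == cur_diag && i0 + k - 1 <= last_q_end) continue;
    Ext e = ungapped_extend_core(q, s, i0, j0, k, match, mismatch, xdrop);
    cur_diag = diag;
    last_q_end = e.qb;
    out.push_back(e);
  }
  IntegerMatrix m((int)out.size(), 7);
  for (size_t r = 0; r < out.size(); ++r) {
    m(r, 0) = out[r].qa + 1; m(r, 1) = out[r].qb + 1;
    m(r, 2) = out[r].sa + 1; m(r, 3) = out[r].sb + 1;
    m(r, 4) = out[r].score; m(r, 5) = out[r].matches; m(r, 6) = out[r].len;
  }
  colnames(m) = CharacterVector::create("q_start", "q_end", "s_start",
                                        "s_end", "score", "matches", "length");
  return m;
}

// Smith-Waterman local alignment with affine gaps (Gotoh), with traceback.
// Gap of length L costs gap_open + gap_extend * L. N never matches.
// Returns c(score, a_start, a_end, b_start, b_end, length, matches, gaps),
// 1-based inclusive coordinates; all zeros when the best score is <= 0.
// [[Rcpp::export]]
IntegerVector cpp_sw_local(std::string a, std::string b,
                           int match, int mismatch,
                           int gap_open, int gap_extend) {
  std::vector<int> x = encode_seq(a), y = encode_seq(b);
  int n = (int)x.size(), m = (int)y.size();
  if ((double)n * (double)m > 4e7)
    stop("sequences too long for exact local alignment (n*m > 4e7 cells)");
  const int NEG = -1000000000;
  const int go = -(gap_open + gap_extend), ge = -gap_extend;
  // DP matrices: M (match state), X (gap in b, consuming a), Y (gap in a)
  std::vector<int> M((n + 1) * (m + 1), 0), X((n + 1) * (m + 1), NEG),
                   Y((n + 1) * (m + 1), NEG);
  // traceback: 0 stop, 1 diag from M, 2 from X, 3 from Y; plus per-state moves
  std::vector<uint8_t> tbM((n + 1) * (m + 1), 0), tbX((n + 1) * (m + 1), 0),
                       tbY((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = (x[i - 1] >= 0 && x[i - 1] == y[j - 1]) ? match : mismatch;
      // X: gap in b (vertical), consumes a[i]
      int xo = M[idx(i - 1, j)] + go, xe = X[idx(i - 1, j)] + ge;
      if (xo >= xe) { X[idx(i, j)] = xo; tbX[idx(i, j)] = 1; }
      else { X[idx(i, j)] = xe; tbX[idx(i, j)] = 2; }
      // Y: gap in a (horizontal), consumes b[j]
      int yo = M[idx(i, j - 1)] + go, ye = Y[idx(i, j - 1)] + ge;
      if (yo >= ye) { Y[idx(i, j)] = yo; tbY[idx(i, j)] = 1; }
      else { Y[idx(i, j)] = ye; tbY[idx(i, j)] = 3; }
      // M: diagonal from best of three, floored at 0 (local)
      int dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)],
          dY = Y[idx(i - 1, j - 1)];
      int dbest = dM; uint8_t dsrc = 1;
      if (dX > dbest) { dbest = dX; dsrc = 2; }
      if (dY > dbest) { dbest = dY; dsrc = 3; }
      int v = dbest + sub;
      if (v <= 0) { M[idx(i, j)] = 0; tbM[idx(i, j)] = 0; }
      else { M[idx(i, j)] = v; tbM[idx(i, j)] = dsrc; }
      int cellbest = std::max(M[idx(i, j)], std::max(X[idx(i, j)], Y[idx(i, j)]));
      if (M[idx(i, j)] >= cellbest && M[idx(i, j)] > best) {
        best = M[idx(i, j)]; bi = i; bj = j;
      }
    }
  }
  if (best <= 0)
    return IntegerVector::create(_["score"] = 0, _["a_start"] = 0,
      _["a_end"] = 0, _["b_start"] = 0, _["b_end"] = 0, _["length"] = 0,
      _["matches"] = 0, _["gaps"] = 0);
  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 1; // 1=M, 2=X, 3=Y
  int len = 0, matches = 0, gaps = 0;
  int ai_end = bi, bj_end = bj, ai_start = bi, bj_start = bj;
  while (true) {
    if (state == 1) {
      uint8_t src = tbM[idx(i, j)];
      ++len;
      if (x[i - 1] >= 0 && x[i - 1] == y[j - 1]) ++matches;
      ai_start = i; bj_start = j;
      --i; --j;
      if (src == 0) break;
      state = src;
      if (state == 1 && (i == 0 || j == 0 || M[idx(i, j)] == 0)) break;
      if (i == 0 || j == 0) break;
    } else if (state == 2) {
      ++len; ++gaps;
      uint8_t src = tbX[idx(i, j)];
      ai_start = i;
      --i;
      state = (src == 1) ? 1 : 2;
      if (i == 0) break;
    } else {
      ++len; ++gaps;
      uint8_t src = tbY[idx(i, j)];
      bj_start = j;
      --j;
      state = (src == 1) ? 1 : 3;
      if (j == 0) break;
    }
  }
  return IntegerVector::create(
    _["score"] = best, _["a_start"] = ai_start, _["a_end"] = ai_end,
    _["b_start"] = bj_start, _["b_end"] = bj_end,
    _["length"] = len, _["matches"] = matches, _["gaps"] = gaps);
}

// ---- DCJ breadth-first-search oracle -------------------------------------
// Genomes are perfect matchings on the 2n gene extremities (tail 2g, head
// 2g+1 for gene g in 0..n-1); a DCJ move cuts two adjacencies and rejoins
// the four ends the two alternative ways. BFS from the identity circular
// genome (+1 +2 ... +n) gives exact minimal operation counts. n <= 8.

static uint64_t encode_matching(const std::vector<int> &p) {
  uint64_t code = 0;
  for (size_t e = 0; e < p.size(); ++e)
    code |= ((uint64_t)p[e]) << (4 * e);
  return code;
}

static std::vector<int> matching_from_order(const IntegerVector &ord) {
  int n = ord.size();
  std::vector<int> p(2 * n, 0);
  for (int i = 0; i < n; ++i) {
    int gi = ord[i], gj = ord[(i + 1) % n];
    // right extremity of gi: head if +, tail if -
    int e1 = (gi > 0) ? (2 * (gi - 1) + 1) : (2 * (-gi - 1));
    // left extremity of gj: tail if +, head if -
    int e2 = (gj > 0) ? (2 * (gj - 1)) : (2 * (-gj - 1) + 1);
    p[e1] = e2; p[e2] = e1;
  }
  return p;
}

// Exact minimal DCJ operation counts (BFS from identity) for each signed
// circular order in `orders` (rows; genes 1..n with sign). n <= 8.
// [[Rcpp::export]]
IntegerVector cpp_dcj_bfs(IntegerMatrix orders) {
  int nrow = orders.nrow(), n = orders.ncol();
  if (n > 8) stop("BFS oracle supports at most 8 genes");
  std::unordered_map<uint64_t, int> dist;
  dist.reserve(1 << 21);
  std::vector<int> ident(n);
  for (int g = 0; g < n; ++g) ident[g] = g + 1;
  IntegerVector iv(ident.begin(), ident.end());
  std::vector<int> p0 = matching_from_order(iv);
  uint64_t s0 = encode_matching(p0);
  dist[s0] = 0;
  std::queue<uint64_t> Q;
  Q.push(s0);
  // queried states
  std::vector<uint64_t> want(nrow);
  std::unordered_map<uint64_t, int> remaining;
  for (int r = 0; r < nrow; ++r) {
    IntegerVector row = orders(r, _);
    want[r] = encode_matching(matching_from_order(row));
    remaining[want[r]] += 1;
  }
  size_t found = 0;
  for (auto &kv : remaining) if (dist.count(kv.first)) ++found;
  while (!Q.empty() && found < remaining.size()) {
    uint64_t cur = Q.front(); Q.pop();
    int d = dist[cur];
    // decode matching
    std::vector<int> p(2 * n);
    for (int e = 0; e < 2 * n; ++e) p[e] = (int)((cur >> (4 * e)) & 0xF);
    // adjacency list (e < partner)
    std::vector<std::pair<int, int>> adj;
    for (int e = 0; e < 2 * n; ++e) if (e < p[e]) adj.push_back({e, p[e]});
    int na = (int)adj.size();
    for (int u = 0; u < na; ++u) {
      for (int v = u + 1; v < na; ++v) {
        int a = adj[u].first, b = adj[u].second;
        int c = adj[v].first, dd = adj[v].second;
        for (int mode = 0; mode < 2; ++mode) {
          std::vector<int> q = p;
          if (mode == 0) { q[a] = c; q[c] = a; q[b] = dd; q[dd] = b; }
          else { q[a] = dd; q[dd] = a; q[b] = c; q[c] = b; }
          uint64_t s = encode_matching(q);
          auto it = dist.find(s);
          if (it == dist.end()) {
            dist[s] = d + 1;
            if (remaining.count(s)) ++found;
            Q.push(s);
          }
        }
      }
    }
  }
  IntegerVector out(nrow);
  for (int r = 0; r < nrow; ++r) {
    auto it = dist.find(want[r]);
    out[r] = (it == dist.end()) ? NA_INTEGER : it->second;
  }
  return out;
}
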