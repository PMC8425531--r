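// Core routines for mutation-history estimation: Levenshtein distance,
// block partition against a cyclic pattern, greedy reverse-history
// contraction, and an exact minimal-mutation search over single-block
// duplication histories (iterative deepening over the mutation budget).
#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static int lev(const std::string &a, const std::string &b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int c = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      c = std::min(c, prev[j] + 1);
      c = std::min(c, cur[j - 1] + 1);
      cur[j] = c;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
  const int n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i % a.size()]);
    std::string y = as<std::string>(b[i % b.size()]);
    out[i] = lev(x, y);
  }
  return out;
}

static bool is_power_of(const std::string &seg, const std::string &y);

static std::vector<std::string> rotations(const std::string &pat) {
  std::vector<std::string> out;
  std::unordered_set<std::string> seen;
  for (size_t r = 0; r < pat.size(); ++r) {
    std::string rot = pat.substr(r) + pat.substr(0, r);
    if (seen.insert(rot).second) out.push_back(rot);
  }
  return out;
}

// Partition s into consecutive blocks, each scored by Levenshtein distance
// to one rotation of the pattern.  Minimises total distance, then total
// deviation of block lengths from the pattern length; rotation ties
// resolve to the lexicographically smallest rotation.  Equivalent to
// cutting the optimal wraparound alignment path against cyclic
// repetitions of the pattern at period boundaries.
struct Partition {
  std::vector<std::string> blocks;
  std::string rotation;
  int cost;
  int dev;
};

// lev(s[j .. j+l), q) for every l = 0..maxl in one pass
static void lev_prefixes(const std::string &s, int j, int maxl,
                         const std::string &q, std::vector<int> &out) {
  const int m = (int)q.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int c = 0; c <= m; ++c) prev[c] = c;
  out[0] = m;
  for (int l = 1; l <= maxl; ++l) {
    cur[0] = l;
    const char ch = s[j + l - 1];
    for (int c = 1; c <= m; ++c) {
      int v = prev[c - 1] + (ch != q[c - 1] ? 1 : 0);
      v = std::min(v, prev[c] + 1);
      v = std::min(v, cur[c - 1] + 1);
      cur[c] = v;
    }
    std::swap(prev, cur);
    out[l] = prev[m];
  }
}

static bool partition_one(const std::string &s, const std::string &q,
                          bool adj_first, Partition &out) {
  const int n = (int)s.size(), p = (int)q.size();
  const int lmax = std::min(n, p + 4);
  const int INF = 1 << 28;
  // bcost[j][l] = lev(s[j .. j+l), q)
  std::vector<std::vector<int>> bcost(n, std::vector<int>(lmax + 1));
  for (int j = 0; j < n; ++j)
    lev_prefixes(s, j, std::min(lmax, n - j), q, bcost[j]);
  // state: position i with a block of length l ending at i; objectives,
  // lexicographic: total distance to the rotation; number of adjacent
  // block pairs that are NOT identical (clusters the copies of a variant
  // so reverse-history reduction sees them as one lineage); total
  // deviation of block lengths from the pattern length
  auto idx = [&](int i, int l) { return i * (lmax + 1) + l; };
  std::vector<int> cost((n + 1) * (lmax + 1), INF), adj(cost.size(), INF),
      dev(cost.size(), INF), back(cost.size(), -1);
  for (int l = 1; l <= std::min(lmax, n); ++l) {
    const int h = idx(l, l);
    cost[h] = bcost[0][l];
    adj[h] = 0;
    dev[h] = std::abs(l - p);
    back[h] = 0;
  }
  for (int i = 1; i <= n; ++i) {
    for (int l = 1; l <= lmax && l < i; ++l) {
      const int j = i - l;
      const int cc = bcost[j][l];
      const int dd = std::abs(l - p);
      for (int l2 = 1; l2 <= lmax && l2 <= j; ++l2) {
        const int prev = idx(j, l2);
        if (cost[prev] >= INF) continue;
        const int differs =
            (l2 != l || s.compare(j - l2, l2, s, j, l) != 0) ? 1 : 0;
        const int nc = cost[prev] + cc;
        const int na = adj[prev] + differs;
        const int nd = dev[prev] + dd;
        const int t2 = adj_first ? na : nd;
        const int t3 = adj_first ? nd : na;
        const int here = idx(i, l);
        const int h2 = adj_first ? adj[here] : dev[here];
        const int h3 = adj_first ? dev[here] : adj[here];
        if (nc < cost[here] || (nc == cost[here] && t2 < h2) ||
            (nc == cost[here] && t2 == h2 && t3 < h3)) {
          cost[here] = nc;
          adj[here] = na;
          dev[here] = nd;
          back[here] = l2;
        }
      }
    }
  }
  int bl = -1, bc = INF, ba = INF, bd = INF;
  for (int l = 1; l <= lmax && l <= n; ++l) {
    const int here = idx(n, l);
    if (cost[here] >= INF) continue;
    const int t2 = adj_first ? adj[here] : dev[here];
    const int t3 = adj_first ? dev[here] : adj[here];
    const int h2 = adj_first ? ba : bd;
    const int h3 = adj_first ? bd : ba;
    if (cost[here] < bc || (cost[here] == bc && t2 < h2) ||
        (cost[here] == bc && t2 == h2 && t3 < h3)) {
      bc = cost[here];
      ba = adj[here];
      bd = dev[here];
      bl = l;
    }
  }
  if (bl < 0) return false;
  std::vector<std::string> blocks;
  int i = n, l = bl;
  while (l > 0) {
    blocks.push_back(s.substr(i - l, l));
    const int l2 = back[idx(i, l)];
    i -= l;
    l = l2;
  }
  std::reverse(blocks.begin(), blocks.end());
  out.blocks = blocks;
  out.rotation = q;
  out.cost = bc;
  out.dev = bd;
  return true;
}

static Partition best_partition(const std::string &s, const std::string &pat,
                                bool adj_first) {
  Partition best;
  best.cost = 1 << 28;
  best.dev = 1 << 28;
  bool have = false;
  std::vector<std::string> rots = rotations(pat);
  std::sort(rots.begin(), rots.end());
  for (const std::string &q : rots) {
    Partition cur;
    if (!partition_one(s, q, adj_first, cur)) continue;
    if (!have || cur.cost < best.cost ||
        (cur.cost == best.cost && cur.dev < best.dev)) {
      best = cur;
      have = true;
    }
  }
  if (!have) stop("partition failed");
  return best;
}

// [[Rcpp::export]]
List cpp_partition_blocks(std::string s, std::string pattern) {
  // block lengths track the pattern length (period boundaries of the
  // wraparound alignment); clustering ties resolve after that
  Partition p = best_partition(s, pattern, false);
  return List::create(_["blocks"] = wrap(p.blocks), _["rotation"] = p.rotation,
                      _["cost"] = p.cost);
}

static int min_rotation_dist(const std::string &s, const std::string &pat) {
  int best = 1 << 28;
  for (const std::string &q : rotations(pat)) best = std::min(best, lev(s, q));
  return best;
}


// Exact min over length-p center strings R of lev(A, R) + lev(B, R):
// three-way alignment DP where the center is free.  Used for the root of
// the reduction tree, where two surviving lineages may both derive from a
// root seen in neither (e.g. one copy gained an insertion, another a
// deletion, and both were then duplicated).
static int median2_cost(const std::string &A, const std::string &B, int p) {
  const int a = (int)A.size(), b = (int)B.size();
  const int INF = 1 << 28;
  std::vector<std::vector<std::vector<int>>> f(
      a + 1, std::vector<std::vector<int>>(b + 1, std::vector<int>(p + 1, INF)));
  f[0][0][0] = 0;
  for (int i = 0; i <= a; ++i) {
    for (int j = 0; j <= b; ++j) {
      for (int l = 0; l <= p; ++l) {
        const int v = f[i][j][l];
        if (v >= INF) continue;
        if (i < a) f[i + 1][j][l] = std::min(f[i + 1][j][l], v + 1);
        if (j < b) f[i][j + 1][l] = std::min(f[i][j + 1][l], v + 1);
        if (l < p) {
          // center char aligned to both (best char: 0 if equal, else 1),
          // to one side (cost 1), or to neither (cost 2)
          if (i < a && j < b)
            f[i + 1][j + 1][l + 1] = std::min(f[i + 1][j + 1][l + 1],
                                              v + (A[i] == B[j] ? 0 : 1));
          if (i < a) f[i + 1][j][l + 1] = std::min(f[i + 1][j][l + 1], v + 1);
          if (j < b) f[i][j + 1][l + 1] = std::min(f[i][j + 1][l + 1], v + 1);
          f[i][j][l + 1] = std::min(f[i][j][l + 1], v + 2);
        }
      }
    }
  }
  return f[a][b][p];
}

// Cheapest reduction of a block list to one surviving block by un-doing
// adjacent duplications.  Equal adjacent blocks collapse free; on the
// collapsed list the optimum over all ordered duplication trees with
// contents lifted from the blocks is found by interval DP (R[i][j][k] =
// min cost to reduce blocks i..j to survivor k); overly diverse lists
// fall back to greedy pairing.  Returns min over survivors of
// (reduction cost + ||survivor| - p|), the cheapest length-p root.
static int reduce_blocks(const std::vector<std::string> &raw, int p) {
  std::vector<std::string> blocks;
  for (const std::string &b : raw)
    if (blocks.empty() || blocks.back() != b) blocks.push_back(b);
  const int r = (int)blocks.size();
  const int INF = 1 << 28;
  if (r <= 12) {
    std::vector<std::vector<int>> D(r, std::vector<int>(r, 0));
    for (int i = 0; i < r; ++i)
      for (int j = i + 1; j < r; ++j) D[i][j] = D[j][i] = lev(blocks[i], blocks[j]);
    std::vector<std::vector<std::vector<int>>> R(
        r, std::vector<std::vector<int>>(r, std::vector<int>(r, INF)));
    for (int i = 0; i < r; ++i) R[i][i][i] = 0;
    for (int len = 2; len <= r; ++len) {
      for (int i = 0; i + len - 1 < r; ++i) {
        const int j = i + len - 1;
        for (int mid = i; mid < j; ++mid) {
          for (int k = i; k <= mid; ++k) {
            if (R[i][mid][k] >= INF) continue;
            for (int k2 = mid + 1; k2 <= j; ++k2) {
              if (R[mid + 1][j][k2] >= INF) continue;
              const int base = R[i][mid][k] + R[mid + 1][j][k2] + D[k][k2];
              if (base < R[i][j][k]) R[i][j][k] = base;
              if (base < R[i][j][k2]) R[i][j][k2] = base;
            }
          }
        }
      }
    }
    int best = INF;
    for (int k = 0; k < r; ++k)
      best = std::min(best, R[0][r - 1][k] + std::abs((int)blocks[k].size() - p));
    // root as a Steiner point: the final merge may join two lineages that
    // both derive from a length-p root surviving in neither
    if (r >= 2) {
      std::unordered_map<std::string, int> med;
      for (int t = 0; t + 1 < r; ++t) {
        for (int k1 = 0; k1 <= t; ++k1) {
          if (R[0][t][k1] >= INF) continue;
          for (int k2 = t + 1; k2 < r; ++k2) {
            if (R[t + 1][r - 1][k2] >= INF) continue;
            const std::string key = blocks[k1] + "\x01" + blocks[k2];
            auto it = med.find(key);
            if (it == med.end())
              it = med.emplace(key, median2_cost(blocks[k1], blocks[k2], p)).first;
            best = std::min(best, R[0][t][k1] + R[t + 1][r - 1][k2] + it->second);
          }
        }
      }
    }
    return best;
  }
  // greedy pairing fallback: contract the closest adjacent pair, keep the
  // longer-lived member (ties keep the left one)
  std::vector<std::string> bl = blocks;
  int m = 0;
  while (bl.size() > 1) {
    int bi = -1, bcost = INF;
    for (size_t i = 0; i + 1 < bl.size(); ++i) {
      const int c = lev(bl[i], bl[i + 1]);
      if (c < bcost) {
        bi = (int)i;
        bcost = c;
      }
    }
    m += bcost;
    bl.erase(bl.begin() + bi + 1);
  }
  return m + std::abs((int)bl[0].size() - p);
}

// Minimal reduction cost for one anchor: every rotation and both
// partition flavours are tiled and reduced, and the cheapest feasible
// history wins (the rotation that best matches the region's phase is not
// known in advance, and a poorly phased tiling smears one indel across
// two block junctions).
static int min_m_for_anchor(const std::string &s, const std::string &anchor,
                            int p, bool all_rotations, int stop_at) {
  int best = 1 << 28;
  std::vector<std::string> rots =
      all_rotations ? rotations(anchor) : std::vector<std::string>{anchor};
  for (const std::string &q : rots) {
    for (const bool adj_first : {false, true}) {
      Partition part;
      if (!partition_one(s, q, adj_first, part)) continue;
      const int red = reduce_blocks(part.blocks, p);
      if (red < best) best = red;
      const int via = part.cost + std::abs((int)q.size() - p);
      if (via < best) best = via;
      if (best <= stop_at) return best;
    }
  }
  return best;
}

// m = 0 exactly when the region is a perfect power of a length-p word,
// which must then be its first p characters; otherwise m >= 1.
static int min_possible_m(const std::string &s, int p) {
  const int n = (int)s.size();
  if (n % p != 0 || n < p) return 1;
  return is_power_of(s, s.substr(0, p)) ? 0 : 1;
}

// Mutation-index estimator.  d is the block count of the pattern-anchored
// partition.  m is the cheapest feasible history found over a small set of
// candidate tiling anchors -- the pattern itself plus region prefixes,
// suffixes and the modal partition block (lengths p-1..p+1), which recover
// histories whose effective repeat unit is an early-mutated variant of the
// pattern -- each scored as partition + lifted-tree reduction + cheapest
// length-p root; the pattern-anchored partition cost (root, duplicate,
// then mutate each block independently) is a further feasible history.
// [[Rcpp::export]]
List cpp_greedy_index(std::string s, std::string pattern) {
  Partition part0 = best_partition(s, pattern, false);
  const int d = (int)part0.blocks.size();
  const int p = (int)pattern.size();
  const int n = (int)s.size();

  const int floor_m = min_possible_m(s, p);
  int m = min_m_for_anchor(s, pattern, p, true, floor_m);

  std::unordered_set<std::string> anchors;
  anchors.insert(pattern);
  // modal block of the pattern-anchored partition (ties: first seen)
  std::unordered_map<std::string, int> freq;
  std::string modal;
  int fbest = 0;
  for (const std::string &b : part0.blocks) {
    const int f = ++freq[b];
    if (f > fbest) {
      fbest = f;
      modal = b;
    }
  }
  std::vector<std::string> cands;
  if (!modal.empty()) cands.push_back(modal);
  for (int L = std::max(1, p - 1); L <= std::min(n, p + 1); ++L) {
    cands.push_back(s.substr(0, L));
    cands.push_back(s.substr(n - L, L));
  }
  for (const std::string &a : cands) {
    if (m <= floor_m) break;  // m is provably minimal; nothing to gain
    if (!anchors.insert(a).second) continue;
    // candidate anchors are already in phase with the region; the pattern
    // anchor above covers all rotations
    const int cand = min_m_for_anchor(s, a, p, false, floor_m);
    if (cand < m) m = cand;
  }
  return List::create(_["m"] = m, _["d"] = d, _["rotation"] = part0.rotation,
                      _["partition_cost"] = part0.cost);
}

// ---------------------------------------------------------------------------
// Exact search: minimal total point mutations over all single-block
// duplication histories producing s from some length-p root.  A history is
// an ordered binary tree whose leaves, left to right, concatenate to s;
// every internal node carries the block content at the moment it duplicated
// and each edge costs the edit distance between its endpoints' contents.
// Iterative deepening over the total budget; intermediate contents are
// enumerated from edit balls, memoised per (interval, content, budget).

struct ExactCtx {
  std::string s;
  std::unordered_map<std::string, int> memo;
  std::unordered_map<std::string, std::vector<std::pair<std::string, int>>> balls;
  long long work;
  long long work_limit;
};

static const int EINF = 1 << 27;

// All strings within edit distance r of y, with their exact distances
// (breadth-first layers of the unit-edit graph).
static const std::vector<std::pair<std::string, int>> &edit_ball(ExactCtx &ctx,
                                                                 const std::string &y,
                                                                 int r) {
  std::string key = y + "\x01" + std::to_string(r);
  auto it = ctx.balls.find(key);
  if (it != ctx.balls.end()) return it->second;
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::unordered_map<std::string, int> dist;
  std::vector<std::string> frontier{y};
  dist[y] = 0;
  for (int layer = 1; layer <= r; ++layer) {
    std::vector<std::string> next;
    for (const std::string &x : frontier) {
      const int L = (int)x.size();
      for (int i = 0; i < L; ++i) {
        for (char b : BASES) {
          if (x[i] == b) continue;
          std::string z = x;
          z[i] = b;
          if (dist.emplace(z, layer).second) next.push_back(z);
        }
      }
      if (L > 1) {
        for (int i = 0; i < L; ++i) {
          std::string z = x.substr(0, i) + x.substr(i + 1);
          if (dist.emplace(z, layer).second) next.push_back(z);
        }
      }
      for (int i = 0; i <= L; ++i) {
        for (char b : BASES) {
          std::string z = x.substr(0, i) + b + x.substr(i);
          if (dist.emplace(z, layer).second) next.push_back(z);
        }
      }
    }
    frontier.swap(next);
  }
  std::vector<std::pair<std::string, int>> out(dist.begin(), dist.end());
  std::sort(out.begin(), out.end(),
            [](const std::pair<std::string, int> &a, const std::pair<std::string, int> &b) {
              return a.second < b.second || (a.second == b.second && a.first < b.first);
            });
  return ctx.balls.emplace(key, std::move(out)).first->second;
}

static bool is_power_of(const std::string &seg, const std::string &y) {
  const size_t L = y.size();
  if (L == 0 || seg.size() % L != 0) return false;
  for (size_t i = 0; i < seg.size(); ++i)
    if (seg[i] != y[i % L]) return false;
  return true;
}

// Minimal edits for a block with content y to generate s[i..j), capped at
// budget (returns > budget when infeasible within the budget).
static int solve(ExactCtx &ctx, int i, int j, const std::string &y, int budget) {
  if (budget < 0) return EINF;
  if ((int)y.size() > (j - i) + budget) return EINF;  // deletions alone can't shrink enough
  std::string key = y;
  key += '\x01';
  key += std::to_string(i);
  key += ',';
  key += std::to_string(j);
  key += ',';
  key += std::to_string(budget);
  auto it = ctx.memo.find(key);
  if (it != ctx.memo.end()) return it->second;
  if (++ctx.work > ctx.work_limit) stop("exact history search exceeded its work limit");
  const std::string seg = ctx.s.substr(i, j - i);
  int best = lev(y, seg);  // leaf: no further duplication below this block
  if (j - i >= 2 && best > 0) {
    const auto &ball = edit_ball(ctx, y, budget);
    for (const auto &cand : ball) {
      const std::string &y2 = cand.first;
      const int d0 = cand.second;
      if (d0 >= best) break;  // sorted by distance; no improvement possible
      if (y2.empty()) continue;
      const int rem = budget < best - 1 ? budget - d0 : best - 1 - d0;
      if (rem < 0) continue;
      if (rem == 0 && !is_power_of(seg, y2)) continue;
      for (int k = i + 1; k < j; ++k) {
        const int l = solve(ctx, i, k, y2, rem);
        if (l > rem) continue;
        const int r = solve(ctx, k, j, y2, rem - l);
        if (d0 + l + r < best) best = d0 + l + r;
        if (best == 0) break;
      }
      if (best == 0) break;
    }
  }
  ctx.memo[key] = best;
  return best;
}

// [[Rcpp::export]]
int cpp_exact_min_mutations(std::string s, int p, int upper,
                            double work_limit = 5e7) {
  ExactCtx ctx;
  ctx.s = s;
  ctx.work = 0;
  ctx.work_limit = (long long)work_limit;
  const int n = (int)s.size();
  if (n == 0 || p < 1) stop("invalid input");
  int best = upper;  // the greedy estimate is always a feasible history
  for (int b = 0; b < upper; ++b) {
    std::unordered_set<std::string> tried;
    const int kmax = std::min(n, p + 2 * b + 1);
    for (int k = 1; k <= kmax; ++k) {
      const auto &ball = edit_ball(ctx, s.substr(0, k), b);
      for (const auto &cand : ball) {
        const std::string &y = cand.first;
        if (y.empty() || !tried.insert(y).second) continue;
        const int croot = std::abs((int)y.size() - p);
        if (croot > b) continue;
        const int v = solve(ctx, 0, n, y, b - croot);
        if (croot + v < best) best = croot + v;
        if (best <= b) break;
      }
      if (best <= b) break;
    }
    if (best <= b) return best;
  }
  return best;
}
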