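#include <Rcpp.h>
#include "bn_core.h"
using namespace Rcpp;

// Iterative DFS: is there a directed path from -> to, optionally ignoring
// the single edge (skipI, skipJ)?  Direct edges count as paths.
bool pathExists(const Adj &adj, int n, int from, int to, int skipI, int skipJ) {
  std::vector<int> stack;
  std::vector<char> seen(n, 0);
  stack.push_back(from);
  seen[from] = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int w = 0; w < n; ++w) {
      if (!adj[v * n + w]) continue;
      if (v == skipI && w == skipJ) continue;
      if (w == to) return true;
      if (!seen[w]) {
        seen[w] = 1;
        stack.push_back(w);
      }
    }
  }
  return false;
}

bool isAcyclicCore(const Adj &adj, int n) {
  // Kahn's algorithm
  std::vector<int> indeg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj[i * n + j]) indeg[j]++;
  std::vector<int> queue;
  for (int j = 0; j < n; ++j)
    if (indeg[j] == 0) queue.push_back(j);
  int removed = 0;
  while (!queue.empty()) {
    int v = queue.back();
    queue.pop_back();
    removed++;
    for (int w = 0; w < n; ++w)
      if (adj[v * n + w] && --indeg[w] == 0) queue.push_back(w);
  }
  return removed == n;
}

void enumerateMoves(const Adj &adj, int n, int fanIn, std::vector<Move> &out) {
  out.clear();
  std::vector<int> indeg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj[i * n + j]) indeg[j]++;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (adj[i * n + j]) {
        out.push_back({2, i, j}); // deletion always keeps a DAG a DAG
        // reversal: i <- j; cycle iff another path i ~> j survives
        if (indeg[i] + 1 <= fanIn && !pathExists(adj, n, i, j, i, j))
          out.push_back({3, i, j});
      } else {
        // addition i -> j; a path j ~> i (incl. the edge j -> i) forbids it
        if (indeg[j] + 1 <= fanIn && !pathExists(adj, n, j, i, -1, -1))
          out.push_back({1, i, j});
      }
    }
  }
}

int countMoves(const Adj &adj, int n, int fanIn) {
  std::vector<Move> tmp;
  enumerateMoves(adj, n, fanIn, tmp);
  return (int)tmp.size();
}

static inline bool adjacentPair(const Adj &adj, int n, int a, int b) {
  return adj[a * n + b] || adj[b * n + a];
}

static inline void compel(std::vector<int> &st, int n, int a, int b) {
  st[a * n + b] = 1;
  st[b * n + a] = 0;
}

// CPDAG of a DAG: mark v-structure edges compelled, then close under the
// Meek orientation rules R1-R3 (sufficient when starting from the
// v-structure pattern of a DAG).
void dagToCpdagCore(const Adj &adj, int n, std::vector<int> &st) {
  st.assign(n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj[i * n + j]) { st[i * n + j] = 2; st[j * n + i] = 2; }
  // v-structures a -> j <- b with a, b non-adjacent
  for (int j = 0; j < n; ++j) {
    for (int a = 0; a < n; ++a) {
      if (!adj[a * n + j]) continue;
      for (int b = a + 1; b < n; ++b) {
        if (!adj[b * n + j]) continue;
        if (!adjacentPair(adj, n, a, b)) {
          compel(st, n, a, j);
          compel(st, n, b, j);
        }
      }
    }
  }
  bool changed = true;
  while (changed) {
    changed = false;
    // R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
    for (int a = 0; a < n; ++a)
      for (int b = 0; b < n; ++b) {
        if (st[a * n + b] != 1) continue;
        for (int c = 0; c < n; ++c) {
          if (c == a || st[b * n + c] != 2) continue;
          if (!adjacentPair(adj, n, a, c)) {
            compel(st, n, b, c);
            changed = true;
          }
        }
      }
    // R2: a -> b -> c with a - c  =>  a -> c
    for (int a = 0; a < n; ++a)
      for (int c = 0; c < n; ++c) {
        if (st[a * n + c] != 2) continue;
        for (int b = 0; b < n; ++b) {
          if (st[a * n + b] == 1 && st[b * n + c] == 1) {
            compel(st, n, a, c);
            changed = true;
            break;
          }
        }
      }
    // R3: a - b, a - c, a - d, c -> b, d -> b, c and d non-adjacent => a -> b
    for (int a = 0; a < n; ++a)
      for (int b = 0; b < n; ++b) {
        if (st[a * n + b] != 2) continue;
        bool done = false;
        for (int c = 0; c < n && !done; ++c) {
          if (st[a * n + c] != 2 || st[c * n + b] != 1) continue;
          for (int d = c + 1; d < n && !done; ++d) {
            if (st[a * n + d] != 2 || st[d * n + b] != 1) continue;
            if (!adjacentPair(adj, n, c, d)) {
              compel(st, n, a, b);
              changed = true;
              done = true;
            }
          }
        }
      }
  }
}

// TS-equivalence class representative: two dummy parents are attached to
// every intervened node, the augmented DAG is converted to its CPDAG, and
// the dummies are stripped.  All edges at an intervened node come out
// directed.
void tsCpdagCore(const Adj &adj, int n, const std::vector<int> &intervened,
                 std::vector<int> &st) {
  int m = (int)intervened.size();
  int N = n + 2 * m;
  Adj aug(N * N, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      aug[i * N + j] = adj[i * n + j];
  for (int k = 0; k < m; ++k) {
    int d1 = n + 2 * k, d2 = n + 2 * k + 1;
    aug[d1 * N + intervened[k]] = 1;
    aug[d2 * N + intervened[k]] = 1;
  }
  std::vector<int> stAug;
  dagToCpdagCore(aug, N, stAug);
  st.assign(n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      st[i * n + j] = stAug[i * N + j];
}

static Adj adjFromR(const LogicalMatrix &m) {
  int n = m.nrow();
  Adj adj(n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      adj[i * n + j] = m(i, j) ? 1 : 0;
  return adj;
}

// [[Rcpp::export]]
bool is_acyclic_cpp(LogicalMatrix adjacency) {
  int n = adjacency.nrow();
  if (adjacency.ncol() != n) stop("adjacency matrix must be square");
  Adj adj = adjFromR(adjacency);
  return isAcyclicCore(adj, n);
}

// [[Rcpp::export]]
List neighbor_moves_cpp(LogicalMatrix adjacency, int fan_in) {
  int n = adjacency.nrow();
  Adj adj = adjFromR(adjacency);
  std::vector<Move> moves;
  enumerateMoves(adj, n, fan_in, moves);
  int k = (int)moves.size();
  IntegerVector kind(k), from(k), to(k);
  for (int q = 0; q < k; ++q) {
    kind[q] = moves[q].kind;
    from[q] = moves[q].i + 1;
    to[q] = moves[q].j + 1;
  }
  return List::create(_["kind"] = kind, _["from"] = from, _["to"] = to,
                      _["count"] = k);
}

// [[Rcpp::export]]
IntegerMatrix dag_to_cpdag_cpp(LogicalMatrix adjacency) {
  int n = adjacency.nrow();
  Adj adj = adjFromR(adjacency);
  if (!isAcyclicCore(adj, n)) stop("input graph is cyclic");
  std::vector<int> st;
  dagToCpdagCore(adj, n, st);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = st[i * n + j];
  return out;
}

// [[Rcpp::export]]
IntegerMatrix ts_cpdag_cpp(LogicalMatrix adjacency, IntegerVector intervened0) {
  int n = adjacency.nrow();
  Adj adj = adjFromR(adjacency);
  if (!isAcyclicCore(adj, n)) stop("input graph is cyclic");
  std::vector<int> iv(intervened0.begin(), intervened0.end());
  std::vector<int> st;
  tsCpdagCore(adj, n, iv, st);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = st[i * n + j];
  return out;
}

// All labeled DAGs on n nodes with in-degree <= fan_in, by filtering every
// directed graph on the off-diagonal cells.  Guarded upstream to n <= 5.
// [[Rcpp::export]]
List enumerate_dags_cpp(int n, int fan_in) {
  int cells = n * (n - 1);
  if (cells > 24) stop("enumeration limited to small n");
  std::vector<std::pair<int, int>> pos;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) pos.push_back({i, j});
  List out;
  uint32_t total = 1u << cells;
  for (uint32_t mask = 0; mask < total; ++mask) {
    Adj adj(n * n, 0);
    std::vector<int> indeg(n, 0);
    bool ok = true;
    for (int c = 0; c < cells && ok; ++c) {
      if (mask & (1u << c)) {
        adj[pos[c].first * n + pos[c].second] = 1;
        if (++indeg[pos[c].second] > fan_in) ok = false;
      }
    }
    if (!ok || !isAcyclicCore(adj, n)) continue;
    LogicalMatrix m(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        m(i, j) = adj[i * n + j] == 1;
    out.push_back(m);
  }
  return out;
}
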