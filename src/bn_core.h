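#ifndef BN_CORE_H
#define BN_CORE_H

#include <vector>
#include <cstdint>

// Adjacency: n*n row-major ints, adj[i*n+j] = 1 iff directed edge i -> j.
typedef std::vector<int> Adj;

struct Move {
  int kind; // 1 = add, 2 = delete, 3 = reverse
  int i;
  int j;
};

bool pathExists(const Adj &adj, int n, int from, int to, int skipI, int skipJ);
bool isAcyclicCore(const Adj &adj, int n);
void enumerateMoves(const Adj &adj, int n, int fanIn, std::vector<Move> &out);
int countMoves(const Adj &adj, int n, int fanIn);

// CPDAG status matrix st (n*n): 0 = no edge, 1 = compelled i -> j,
// 2 = undirected (stored in both cells of the pair).
void dagToCpdagCore(const Adj &adj, int n, std::vector<int> &st);
void tsCpdagCore(const Adj &adj, int n, const std::vector<int> &intervened,
                 std::vector<int> &st);

#endif
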