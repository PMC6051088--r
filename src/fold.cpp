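#include <Rcpp.h>
using namespace Rcpp;

// Base encoding used throughout src/: A=0, C=1, G=2, U=3.

static inline int pair_weight(int a, int b) {
  // G-C = 3, A-U = 2, G-U = 1, otherwise unpairable (0)
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1;
  return 0;
}

static void fill_dp(const std::vector<int>& s, int min_loop,
                    std::vector<int>& M, int n) {
  // M is n x n, row-major; M[i*n+j] = best score on s[i..j]
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[(i + 1) * n + j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(s[i], s[k]);
        if (w == 0) continue;
        int inner = (k - i > 1) ? M[(i + 1) * n + (k - 1)] : 0;
        int right = (k < j) ? M[(k + 1) * n + j] : 0;
        int cand = w + inner + right;
        if (cand > best) best = cand;
      }
      M[i * n + j] = best;
    }
  }
}

// [[Rcpp::export(name = ".cpp_fold")]]
List cpp_fold(IntegerVector seq, int min_loop) {
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  if (n == 0) return List::create(_["score"] = 0, _["pairs"] = IntegerMatrix(0, 2));
  std::vector<int> M((size_t)n * n, 0);
  fill_dp(s, min_loop, M, n);

  // traceback, deterministic: at (i,j) prefer pairing i with the smallest k
  // achieving the optimum, else leave i unpaired
  std::vector<std::pair<int,int> > stack, pairs;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    int target = M[i * n + j];
    bool done = false;
    for (int k = i + min_loop + 1; k <= j && !done; ++k) {
      int w = pair_weight(s[i], s[k]);
      if (w == 0) continue;
      int inner = (k - i > 1) ? M[(i + 1) * n + (k - 1)] : 0;
      int right = (k < j) ? M[(k + 1) * n + j] : 0;
      if (w + inner + right == target) {
        pairs.push_back(std::make_pair(i, k));
        if (k - i > 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        done = true;
      }
    }
    if (!done) stack.push_back(std::make_pair(i + 1, j));
  }

  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first + 1;   // 1-based for R
    pm(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["score"] = M[0 * n + (n - 1)], _["pairs"] = pm);
}

// [[Rcpp::export(name = ".cpp_fold_score_many")]]
IntegerVector cpp_fold_score_many(IntegerMatrix seqs, int min_loop) {
  // one sequence per row; score only, no traceback
  int m = seqs.nrow(), n = seqs.ncol();
  IntegerVector out(m);
  std::vector<int> s(n);
  std::vector<int> M;
  for (int r = 0; r < m; ++r) {
    for (int c = 0; c < n; ++c) s[c] = seqs(r, c);
    M.assign((size_t)n * n, 0);
    fill_dp(s, min_loop, M, n);
    out[r] = (n > 0) ? M[0 * n + (n - 1)] : 0;
  }
  return out;
}

// Altschul-Erickson dinucleotide-preserving shuffle.  The sequence is an
// Eulerian walk on the 4-vertex multigraph of dinucleotide edges; a shuffle
// re-orders each vertex's out-edges, keeping a randomly chosen set of "last
// edges" that must form an arborescence into the final vertex so the walk
// completes.  Uses R's RNG so results respect set.seed().
// [[Rcpp::export(name = ".cpp_dinuc_shuffle")]]
IntegerMatrix cpp_dinuc_shuffle(IntegerVector seq, int n_shuffles) {
  int n = seq.size();
  IntegerMatrix out(n_shuffles, n);
  if (n < 2) {
    for (int r = 0; r < n_shuffles; ++r)
      for (int c = 0; c < n; ++c) out(r, c) = seq[c];
    return out;
  }
  int sink = seq[n - 1];
  std::vector<int> edges[4];  // out-edge target lists, in sequence order
  for (int i = 0; i + 1 < n; ++i) edges[seq[i]].push_back(seq[i + 1]);

  std::vector<int> shuffled[4];
  for (int r = 0; r < n_shuffles; ++r) {
    for (int tries = 0; tries < 1000; ++tries) {
      for (int v = 0; v < 4; ++v) {
        shuffled[v] = edges[v];
        for (int i = (int)shuffled[v].size() - 1; i > 0; --i) {
          int j = (int)(unif_rand() * (i + 1));
          if (j > i) j = i;
          std::swap(shuffled[v][i], shuffled[v][j]);
        }
      }
      // last-edge of every non-sink vertex with out-edges must lead to sink
      bool ok = true;
      for (int v = 0; v < 4 && ok; ++v) {
        if (v == sink || shuffled[v].empty()) continue;
        int cur = v, steps = 0;
        while (cur != sink && steps < 8) {
          if (shuffled[cur].empty()) { ok = false; break; }
          cur = shuffled[cur].back();
          ++steps;
        }
        if (cur != sink) ok = false;
      }
      if (!ok) continue;
      // walk, consuming out-edges in order
      std::vector<size_t> next(4, 0);
      int cur = seq[0], pos = 0;
      out(r, pos++) = cur;
      while (pos < n) {
        if (next[cur] >= shuffled[cur].size()) { ok = false; break; }
        cur = shuffled[cur][next[cur]++];
        out(r, pos++) = cur;
      }
      if (ok) break;
    }
  }
  return out;
}
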