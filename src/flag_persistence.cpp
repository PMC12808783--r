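// Persistent homology of the clique (flag) complex filtration induced by an
// ordered edge list, with Betti curves read off the barcode.
//
// Filtration convention: step 0 is the empty graph on n vertices; step k
// (1-based) contains the first k edges of the supplied list. A p-simplex
// enters at the step of its latest edge. Homology is over GF(2); pairs come
// from standard left-to-right column reduction of each boundary matrix, with
// columns ordered by (entry step, lexicographic vertex order) — the same
// total order used for row indices, so pivots are well defined.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

namespace {

typedef std::vector<int> Column; // sorted ascending; pivot = back()

struct Simplex {
  std::array<int, 5> v; // vertices, ascending; only first (dim+1) used
  int step;
};

// encode up to 5 vertices (< 4096 each) into one key
inline uint64_t simplex_key(const int* v, int nv) {
  uint64_t k = 0;
  for (int i = 0; i < nv; ++i) k = (k << 12) | (uint64_t)(v[i] + 1);
  return k;
}

struct BitAdj {
  int words;
  std::vector<uint64_t> bits; // n * words
  BitAdj(int n) : words((n + 63) / 64), bits((size_t)n * words, 0) {}
  void set(int i, int j) { bits[(size_t)i * words + (j >> 6)] |= (1ULL << (j & 63)); }
  const uint64_t* row(int i) const { return &bits[(size_t)i * words]; }
};

// enumerate all cliques of exactly `size` vertices; cand = common neighbours
void enum_cliques(const BitAdj& adj, int n, int size,
                  std::vector<int>& cur, std::vector<uint64_t>& cand,
                  const IntegerMatrix& estep, std::vector<Simplex>& out) {
  if ((int)cur.size() == size) {
    Simplex s;
    int st = 0;
    for (size_t a = 0; a < cur.size(); ++a) {
      s.v[a] = cur[a];
      for (size_t b = a + 1; b < cur.size(); ++b)
        st = std::max(st, estep(cur[a], cur[b]));
    }
    s.step = st;
    out.push_back(s);
    return;
  }
  int start = cur.empty() ? 0 : cur.back() + 1;
  int words = adj.words;
  for (int w = start >> 6; w < words; ++w) {
    uint64_t word = cand[w];
    if (w == (start >> 6)) word &= ~((start & 63) ? ((1ULL << (start & 63)) - 1) : 0);
    while (word) {
      int j = (w << 6) + __builtin_ctzll(word);
      word &= word - 1;
      if (j >= n) break;
      // remaining candidates must exceed j and neighbour j
      std::vector<uint64_t> next(words);
      const uint64_t* aj = adj.row(j);
      for (int t = 0; t < words; ++t) next[t] = cand[t] & aj[t];
      cur.push_back(j);
      enum_cliques(adj, n, size, cur, next, estep, out);
      cur.pop_back();
    }
  }
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix flag_betti_curves_cpp(int n_vertices, IntegerMatrix edges, int max_dim) {
  const int n = n_vertices;
  const int K = edges.nrow();
  if (n > 4000) stop("too many vertices for the persistence engine");
  if (max_dim < 0 || max_dim > 3) stop("max_dim must be in 0..3");

  IntegerMatrix estep(n, n); // 1-based step of each edge, 0 = absent
  BitAdj adj(n);
  for (int k = 0; k < K; ++k) {
    int i = edges(k, 0) - 1, j = edges(k, 1) - 1;
    if (i < 0 || j < 0 || i >= n || j >= n || i == j)
      stop("invalid edge at filtration position %d", k + 1);
    if (estep(i, j) != 0) stop("duplicate edge at filtration position %d", k + 1);
    estep(i, j) = estep(j, i) = k + 1;
    adj.set(i, j);
    adj.set(j, i);
  }

  // simplices[d] = d-simplices sorted by (step, lex); simplices[0] = vertices
  const int top = max_dim + 1; // boundaries of (max_dim+1)-simplices kill max_dim cycles
  std::vector<std::vector<Simplex>> simplices(top + 1);
  for (int i = 0; i < n; ++i) {
    Simplex s; s.v[0] = i; s.step = 0;
    simplices[0].push_back(s);
  }
  for (int d = 1; d <= top; ++d) {
    std::vector<int> cur;
    std::vector<uint64_t> cand(adj.words, ~0ULL);
    enum_cliques(adj, n, d + 1, cur, cand, estep, simplices[d]);
    std::sort(simplices[d].begin(), simplices[d].end(),
              [d](const Simplex& a, const Simplex& b) {
                if (a.step != b.step) return a.step < b.step;
                for (int t = 0; t <= d; ++t)
                  if (a.v[t] != b.v[t]) return a.v[t] < b.v[t];
                return false;
              });
  }

  // index maps for rows of each boundary matrix
  std::vector<std::unordered_map<uint64_t, int>> index(top + 1);
  for (int d = 0; d < top; ++d) { // only needed as rows, i.e. up to top-1
    index[d].reserve(simplices[d].size() * 2);
    for (size_t s = 0; s < simplices[d].size(); ++s)
      index[d][simplex_key(simplices[d][s].v.data(), d + 1)] = (int)s;
  }

  // intervals per homology dimension: (birth_step, death_step), death K+1 = essential
  std::vector<std::vector<std::pair<int, int>>> intervals(max_dim + 1);
  // positive[d][s]: d-simplex s creates a d-cycle; row_paired[d][s]: killed later
  std::vector<std::vector<char>> positive(top + 1), row_paired(top + 1);
  positive[0].assign(n, 1);
  for (int d = 0; d <= top; ++d) row_paired[d].assign(simplices[d].size(), 0);

  for (int d = 1; d <= top; ++d) {
    const std::vector<Simplex>& cols = simplices[d];
    const size_t ncol = cols.size();
    const int nrow = (int)simplices[d - 1].size();
    positive[d].assign(ncol, 0);
    std::vector<int> pivot_owner(nrow, -1);      // pivot row -> slot in stored
    std::vector<Column> stored;                  // reduced negative columns, sparse ascending
    stored.reserve(std::min((size_t)nrow, ncol));
    // dense GF(2) accumulator for the column being reduced
    const int words = (nrow + 63) / 64;
    std::vector<uint64_t> buf(words, 0);
    for (size_t c = 0; c < ncol; ++c) {
      int face[5];
      int hi = -1; // upper bound on the highest set bit
      for (int omit = 0; omit <= d; ++omit) {
        int t = 0;
        for (int a = 0; a <= d; ++a) if (a != omit) face[t++] = cols[c].v[a];
        int r = index[d - 1].at(simplex_key(face, d));
        buf[r >> 6] ^= (1ULL << (r & 63));
        hi = std::max(hi, r);
      }
      int piv = -1;
      for (;;) {
        // highest set bit at or below hi
        piv = -1;
        for (int w = hi >> 6; w >= 0; --w) {
          uint64_t word = buf[w];
          if (w == (hi >> 6)) {
            int rem = hi & 63;
            if (rem < 63) word &= (1ULL << (rem + 1)) - 1;
          }
          if (word) { piv = (w << 6) + 63 - __builtin_clzll(word); break; }
        }
        if (piv < 0) break; // column reduced to zero: positive
        int owner = pivot_owner[piv];
        if (owner < 0) break; // new pivot: negative column
        for (int r : stored[owner]) buf[r >> 6] ^= (1ULL << (r & 63));
        hi = piv - 1; // stored column's top bit was piv; it cancels
      }
      if (piv < 0) {
        positive[d][c] = 1;
      } else {
        Column col;
        for (int w = 0; w <= (piv >> 6); ++w) {
          uint64_t word = buf[w];
          while (word) {
            col.push_back((w << 6) + __builtin_ctzll(word));
            word &= word - 1;
          }
        }
        pivot_owner[piv] = (int)stored.size();
        stored.push_back(std::move(col));
        row_paired[d - 1][piv] = 1;
        if (d - 1 <= max_dim) {
          int birth = simplices[d - 1][piv].step;
          int death = cols[c].step;
          if (birth < death) intervals[d - 1].push_back({birth, death});
        }
        // clear the accumulator for the next column
        for (int w = 0; w <= (piv >> 6); ++w) buf[w] = 0;
      }
    }
  }

  // essential classes: positive, never paired as a row
  for (int d = 0; d <= max_dim; ++d) {
    for (size_t s = 0; s < simplices[d].size(); ++s)
      if (positive[d][s] && !row_paired[d][s])
        intervals[d].push_back({simplices[d][s].step, K + 1});
  }

  IntegerMatrix betti(max_dim + 1, K + 1);
  for (int d = 0; d <= max_dim; ++d) {
    std::vector<int> diff(K + 2, 0);
    for (auto& iv : intervals[d]) {
      diff[iv.first] += 1;
      if (iv.second <= K + 1) diff[std::min(iv.second, K + 1)] -= 1;
    }
    int run = 0;
    for (int j = 0; j <= K; ++j) {
      run += diff[j];
      betti(d, j) = run;
    }
  }
  return betti;
}
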