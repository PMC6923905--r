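// Core data structure and graph algorithms: 2-bit k-mer encoding, the
// coverage-annotated de Bruijn graph hash, bottleneck (widest), shortest and
// greedy path searches, per-read coverage profiling, and a banded global
// aligner used by the evaluation module.
#include <Rcpp.h>
#include <cstdint>
#include <queue>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// reverse complement of a 2-bit packed k-mer
static inline uint64_t revcomp_code(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// returns -1 on invalid characters
static inline int64_t encode_kmer(const std::string& s) {
  uint64_t x = 0;
  for (char c : s) {
    int b = base_code(c);
    if (b < 0) return -1;
    x = (x << 2) | (uint64_t)b;
  }
  return (int64_t)x;
}

struct Node {
  uint32_t count;
  uint8_t in_mask;   // predecessor characters (prepended to the (k-1)-prefix)
  uint8_t out_mask;  // successor characters (appended to the (k-1)-suffix)
  Node() : count(0), in_mask(0), out_mask(0) {}
};

struct DBG {
  int k;
  bool canonical;
  long long total_instances;
  std::unordered_map<uint64_t, Node> map;
  DBG(int k_, bool canon) : k(k_), canonical(canon), total_instances(0) {}
  uint64_t kmask() const { return (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL); }
  uint64_t canon(uint64_t m) const {
    if (!canonical) return m;
    uint64_t rc = revcomp_code(m, k);
    return std::min(m, rc);
  }
  const Node* find(uint64_t literal) const {
    auto it = map.find(canon(literal));
    return (it == map.end()) ? nullptr : &it->second;
  }
  int coverage(uint64_t literal) const {
    const Node* n = find(literal);
    return n ? (int)n->count : 0;
  }
  // successor (forward = true) / predecessor characters valid for the literal
  // orientation of m.  In canonical mode edges are stored in the canonical
  // orientation; the reverse-complement view swaps and complements the masks.
  uint8_t edge_mask(uint64_t m, bool forward) const {
    uint64_t c = canon(m);
    auto it = map.find(c);
    if (it == map.end()) return 0;
    const Node& n = it->second;
    if (m == c) return forward ? n.out_mask : n.in_mask;
    uint8_t raw = forward ? n.in_mask : n.out_mask;  // opposite side, complemented
    uint8_t out = 0;
    for (int b = 0; b < 4; ++b)
      if (raw & (1 << (3 - b))) out |= (1 << b);
    return out;
  }
  // neighbors of the literal k-mer m; returns (code, coverage) pairs in
  // A < C < G < T character order
  void neighbors(uint64_t m, bool forward,
                 std::vector<std::pair<uint64_t, int>>& out) const {
    out.clear();
    uint8_t mask = edge_mask(m, forward);
    if (!mask) return;
    for (int b = 0; b < 4; ++b) {
      if (!(mask & (1 << b))) continue;
      uint64_t m2;
      if (forward)
        m2 = ((m << 2) | (uint64_t)b) & kmask();
      else
        m2 = (m >> 2) | ((uint64_t)b << (2 * (k - 1)));
      int cov = coverage(m2);
      if (cov > 0) out.emplace_back(m2, cov);
    }
  }
};

static DBG* get_graph(SEXP ptr) {
  Rcpp::XPtr<DBG> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_build_graph(CharacterVector seqs, int k, bool canonical) {
  DBG* g = new DBG(k, canonical);
  uint64_t kmask = g->kmask();
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int n = (int)LENGTH(STRING_ELT(seqs, r));
    if (n < k) continue;
    uint64_t code = 0;
    int valid = 0;          // consecutive valid bases ending at current char
    bool prev_ok = false;   // previous window valid
    uint64_t prev_code = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      if (b < 0) {
        valid = 0;
        prev_ok = false;
        continue;
      }
      code = ((code << 2) | (uint64_t)b) & kmask;
      if (++valid < k) { prev_ok = false; continue; }
      // window ending at i (start i - k + 1) is valid
      uint64_t c = g->canon(code);
      g->map[c].count++;
      g->total_instances++;
      if (prev_ok) {
        // adjacency prev_code -> code: out char is s[i], in char is s[i-k]
        int out_c = b;
        int in_c = base_code(s[i - k]);
        uint64_t cu = g->canon(prev_code);
        Node& nu = g->map[cu];
        if (prev_code == cu) nu.out_mask |= (1 << out_c);
        else nu.in_mask |= (1 << (3 - out_c));
        Node& nv = g->map[c];
        if (code == c) nv.in_mask |= (1 << in_c);
        else nv.out_mask |= (1 << (3 - in_c));
      }
      prev_ok = true;
      prev_code = code;
    }
  }
  Rcpp::XPtr<DBG> p(g, true);
  return p;
}

// [[Rcpp::export]]
SEXP cpp_graph_from_table(CharacterVector kmers, IntegerVector counts,
                          CharacterVector in_chars, CharacterVector out_chars,
                          int k, bool canonical, double total_instances) {
  DBG* g = new DBG(k, canonical);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    if ((int)km.size() != k) stop("k-mer '%s' does not have length k = %d", km.c_str(), k);
    int64_t code = encode_kmer(km);
    if (code < 0) stop("k-mer '%s' contains characters outside {A,C,G,T}", km.c_str());
    Node& n = g->map[(uint64_t)code];
    if (counts[i] < 1) stop("vertex '%s' has non-positive count", km.c_str());
    n.count = (uint32_t)counts[i];
    std::string ic = as<std::string>(in_chars[i]);
    std::string oc = as<std::string>(out_chars[i]);
    for (char c : ic) {
      if (c == '-') continue;
      int b = base_code(c);
      if (b < 0) stop("invalid in-edge character '%c' at vertex '%s'", c, km.c_str());
      n.in_mask |= (1 << b);
    }
    for (char c : oc) {
      if (c == '-') continue;
      int b = base_code(c);
      if (b < 0) stop("invalid out-edge character '%c' at vertex '%s'", c, km.c_str());
      n.out_mask |= (1 << b);
    }
  }
  g->total_instances = (long long)total_instances;
  Rcpp::XPtr<DBG> p(g, true);
  return p;
}

static std::string mask_string(uint8_t mask) {
  std::string s;
  for (int b = 0; b < 4; ++b)
    if (mask & (1 << b)) s.push_back(BASES[b]);
  if (s.empty()) s = "-";
  return s;
}

// [[Rcpp::export]]
DataFrame cpp_graph_table(SEXP ptr) {
  DBG* g = get_graph(ptr);
  std::vector<uint64_t> keys;
  keys.reserve(g->map.size());
  for (auto& kv : g->map) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());  // 2-bit encoding sorts lexicographically
  R_xlen_t n = (R_xlen_t)keys.size();
  CharacterVector km(n), ic(n), oc(n);
  IntegerVector ct(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const Node& nd = g->map[keys[i]];
    km[i] = decode_kmer(keys[i], g->k);
    ct[i] = (int)nd.count;
    ic[i] = mask_string(nd.in_mask);
    oc[i] = mask_string(nd.out_mask);
  }
  return DataFrame::create(_["kmer"] = km, _["count"] = ct,
                           _["in_chars"] = ic, _["out_chars"] = oc,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_graph_info(SEXP ptr) {
  DBG* g = get_graph(ptr);
  return List::create(_["k"] = g->k, _["canonical"] = g->canonical,
                      _["n_vertices"] = (double)g->map.size(),
                      _["total_instances"] = (double)g->total_instances);
}

// [[Rcpp::export]]
IntegerVector cpp_coverage(SEXP ptr, CharacterVector kmers) {
  DBG* g = get_graph(ptr);
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    int64_t code = encode_kmer(km);
    out[i] = (code < 0) ? 0 : g->coverage((uint64_t)code);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_counts(SEXP ptr) {
  DBG* g = get_graph(ptr);
  IntegerVector out((R_xlen_t)g->map.size());
  R_xlen_t i = 0;
  for (auto& kv : g->map) out[i++] = (int)kv.second.count;
  return out;
}

// [[Rcpp::export]]
List cpp_neighbors(SEXP ptr, std::string kmer, bool forward) {
  DBG* g = get_graph(ptr);
  int64_t code = encode_kmer(kmer);
  if (code < 0) stop("k-mer contains characters outside {A,C,G,T}");
  std::vector<std::pair<uint64_t, int>> nb;
  g->neighbors((uint64_t)code, forward, nb);
  CharacterVector km(nb.size());
  IntegerVector cov(nb.size());
  for (size_t i = 0; i < nb.size(); ++i) {
    km[i] = decode_kmer(nb[i].first, g->k);
    cov[i] = nb[i].second;
  }
  return List::create(_["kmer"] = km, _["coverage"] = cov);
}

// Coverage of every k-mer window of `seq`; -1 marks windows containing
// characters outside {A,C,G,T}.
// [[Rcpp::export]]
IntegerVector cpp_profile(SEXP ptr, std::string seq) {
  DBG* g = get_graph(ptr);
  int k = g->k;
  int n = (int)seq.size();
  if (n < k) return IntegerVector(0);
  IntegerVector out(n - k + 1);
  uint64_t code = 0, kmask = g->kmask();
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { valid = 0; } else {
      code = ((code << 2) | (uint64_t)b) & kmask;
      ++valid;
    }
    if (i >= k - 1) out[i - k + 1] = (valid >= k) ? g->coverage(code) : -1;
  }
  return out;
}

struct PathResult {
  bool found;
  std::vector<uint64_t> path;
  int width;
};

static List path_to_list(const DBG* g, const PathResult& r) {
  if (!r.found)
    return List::create(_["found"] = false);
  CharacterVector km(r.path.size());
  for (size_t i = 0; i < r.path.size(); ++i) km[i] = decode_kmer(r.path[i], g->k);
  return List::create(_["found"] = true, _["kmers"] = km,
                      _["width"] = r.width, _["length"] = (int)r.path.size());
}

// Bottleneck-path (widest path) search: a Dijkstra variant on a max-priority
// queue keyed by (width desc, length asc, insertion order asc).  Width of a
// path is the minimum vertex coverage including both endpoints.  Paths are
// bounded at max_len vertices.
static PathResult widest_search(const DBG* g, uint64_t src, uint64_t dst,
                                int max_len, long max_pops) {
  PathResult res{false, {}, 0};
  struct State { int w; int len; uint64_t parent; bool popped; };
  struct QE {
    int w; int len; uint64_t code; uint64_t parent; uint64_t seq;
  };
  struct Cmp {
    bool operator()(const QE& a, const QE& b) const {
      if (a.w != b.w) return a.w < b.w;
      if (a.len != b.len) return a.len > b.len;
      return a.seq > b.seq;
    }
  };
  int cov_src = g->coverage(src);
  if (cov_src <= 0 || g->coverage(dst) <= 0) return res;
  if (src == dst) {
    res.found = true;
    res.path = {src};
    res.width = cov_src;
    return res;
  }
  std::unordered_map<uint64_t, State> states;
  std::unordered_map<uint64_t, uint64_t> final_parent;
  std::priority_queue<QE, std::vector<QE>, Cmp> pq;
  uint64_t ticket = 0;
  states[src] = {cov_src, 1, src, false};
  pq.push({cov_src, 1, src, src, ticket++});
  std::vector<std::pair<uint64_t, int>> nb;
  long pops = 0;
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    auto& st = states[top.code];
    if (st.popped) continue;
    if (top.w != st.w || top.len != st.len) continue;  // stale entry
    st.popped = true;
    final_parent[top.code] = top.parent;
    if (top.code == dst) {
      res.found = true;
      res.width = top.w;
      uint64_t cur = dst;
      while (true) {
        res.path.push_back(cur);
        uint64_t par = final_parent[cur];
        if (par == cur) break;
        cur = par;
      }
      std::reverse(res.path.begin(), res.path.end());
      return res;
    }
    if (++pops > max_pops) return res;
    if (top.len >= max_len) continue;
    g->neighbors(top.code, true, nb);
    for (auto& pr : nb) {
      int w2 = std::min(top.w, pr.second);
      int l2 = top.len + 1;
      auto it = states.find(pr.first);
      if (it == states.end()) {
        states[pr.first] = {w2, l2, top.code, false};
        pq.push({w2, l2, pr.first, top.code, ticket++});
      } else if (!it->second.popped &&
                 (w2 > it->second.w ||
                  (w2 == it->second.w && l2 < it->second.len))) {
        it->second.w = w2;
        it->second.len = l2;
        it->second.parent = top.code;
        pq.push({w2, l2, pr.first, top.code, ticket++});
      }
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_widest_path(SEXP ptr, std::string src, std::string dst, int max_len,
                     double max_pops = 500000) {
  DBG* g = get_graph(ptr);
  int64_t s = encode_kmer(src), d = encode_kmer(dst);
  if (s < 0 || d < 0) stop("source/destination k-mer contains invalid characters");
  PathResult r = widest_search(g, (uint64_t)s, (uint64_t)d, max_len, (long)max_pops);
  return path_to_list(g, r);
}

// Unweighted BFS shortest path, successors expanded in A < C < G < T order.
static PathResult shortest_search(const DBG* g, uint64_t src, uint64_t dst,
                                  int max_len) {
  PathResult res{false, {}, 0};
  if (g->coverage(src) <= 0 || g->coverage(dst) <= 0) return res;
  if (src == dst) {
    res.found = true;
    res.path = {src};
    res.width = g->coverage(src);
    return res;
  }
  std::unordered_map<uint64_t, uint64_t> parent;
  std::queue<std::pair<uint64_t, int>> q;  // (code, path length in vertices)
  parent[src] = src;
  q.push({src, 1});
  std::vector<std::pair<uint64_t, int>> nb;
  while (!q.empty()) {
    auto [code, len] = q.front();
    q.pop();
    if (len >= max_len) continue;
    g->neighbors(code, true, nb);
    for (auto& pr : nb) {
      if (parent.count(pr.first)) continue;
      parent[pr.first] = code;
      if (pr.first == dst) {
        uint64_t cur = dst;
        while (true) {
          res.path.push_back(cur);
          if (parent[cur] == cur) break;
          cur = parent[cur];
        }
        std::reverse(res.path.begin(), res.path.end());
        res.found = true;
        res.width = g->coverage(res.path[0]);
        for (uint64_t c : res.path) res.width = std::min(res.width, g->coverage(c));
        return res;
      }
      q.push({pr.first, len + 1});
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_shortest_path(SEXP ptr, std::string src, std::string dst, int max_len) {
  DBG* g = get_graph(ptr);
  int64_t s = encode_kmer(src), d = encode_kmer(dst);
  if (s < 0 || d < 0) stop("source/destination k-mer contains invalid characters");
  PathResult r = shortest_search(g, (uint64_t)s, (uint64_t)d, max_len);
  return path_to_list(g, r);
}

// Greedy maximum-coverage descent with backtracking: depth-first search that
// orders successors by coverage (descending, ties by character), marks
// vertices globally visited, and backtracks after `b` successive vertices
// without reaching the destination.  Aborts when the reachable search space
// is exhausted.
static PathResult greedy_search(const DBG* g, uint64_t src, uint64_t dst,
                                int b, int max_len) {
  PathResult res{false, {}, 0};
  if (g->coverage(src) <= 0 || g->coverage(dst) <= 0) return res;
  if (src == dst) {
    res.found = true;
    res.path = {src};
    res.width = g->coverage(src);
    return res;
  }
  int limit = std::min(b, max_len);
  struct Frame { uint64_t code; std::vector<uint64_t> succ; size_t next; };
  std::unordered_set<uint64_t> visited;
  std::vector<Frame> stack;
  std::vector<std::pair<uint64_t, int>> nb;
  auto expand = [&](uint64_t code) {
    g->neighbors(code, true, nb);
    std::stable_sort(nb.begin(), nb.end(),
                     [](const std::pair<uint64_t, int>& a,
                        const std::pair<uint64_t, int>& b2) {
                       return a.second > b2.second;
                     });
    Frame f;
    f.code = code;
    for (auto& pr : nb) f.succ.push_back(pr.first);
    f.next = 0;
    return f;
  };
  visited.insert(src);
  stack.push_back(expand(src));
  while (!stack.empty()) {
    Frame& f = stack.back();
    if ((int)stack.size() >= limit || f.next >= f.succ.size()) {
      stack.pop_back();
      continue;
    }
    uint64_t nxt = f.succ[f.next++];
    if (visited.count(nxt)) continue;
    visited.insert(nxt);
    if (nxt == dst) {
      res.found = true;
      for (auto& fr : stack) res.path.push_back(fr.code);
      res.path.push_back(dst);
      res.width = g->coverage(res.path[0]);
      for (uint64_t c : res.path) res.width = std::min(res.width, g->coverage(c));
      return res;
    }
    stack.push_back(expand(nxt));
  }
  return res;
}

// [[Rcpp::export]]
List cpp_greedy_path(SEXP ptr, std::string src, std::string dst, int b,
                     int max_len) {
  DBG* g = get_graph(ptr);
  int64_t s = encode_kmer(src), d = encode_kmer(dst);
  if (s < 0 || d < 0) stop("source/destination k-mer contains invalid characters");
  PathResult r = greedy_search(g, (uint64_t)s, (uint64_t)d, b, max_len);
  return path_to_list(g, r);
}

// Banded global (Needleman-Wunsch) alignment of b against a with linear gap
// penalties.  The band of half-width `band` follows the (0,0)-(n,m) diagonal.
// At equal scores the traceback prefers diagonal (match/mismatch), then a gap
// in b (deletion relative to a), then a gap in a (insertion).
// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, double match,
                      double mismatch, double gap, int band) {
  const double NEG = -1e18;
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<int> lo(n + 1), hi(n + 1);
  for (int i = 0; i <= n; ++i) {
    int ci = (int)std::llround((double)i * m / n);
    lo[i] = std::max(0, ci - band);
    hi[i] = std::min(m, ci + band);
  }
  int W = 2 * band + 1;
  std::vector<double> prev(W, NEG), cur(W, NEG);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);  // 1 diag, 2 up, 3 left
  // row 0
  for (int j = lo[0]; j <= hi[0]; ++j) {
    prev[j - lo[0]] = gap * j;
    tb[j - lo[0]] = (j == 0) ? 0 : 3;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int j = lo[i]; j <= hi[i]; ++j) {
      int off = j - lo[i];
      double best = NEG;
      uint8_t dir = 0;
      if (j > 0 && j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) {
        double sc = prev[j - 1 - lo[i - 1]] +
                    (a[i - 1] == b[j - 1] ? match : mismatch);
        if (sc > best) { best = sc; dir = 1; }
      }
      if (j >= lo[i - 1] && j <= hi[i - 1]) {
        double sc = prev[j - lo[i - 1]] + gap;
        if (sc > best) { best = sc; dir = 2; }
      }
      if (j > 0 && j - 1 >= lo[i]) {
        double sc = cur[off - 1] + gap;
        if (sc > best) { best = sc; dir = 3; }
      }
      cur[off] = best;
      tb[(size_t)i * W + off] = dir;
    }
    std::swap(prev, cur);
  }
  double score = prev[m - lo[n]];
  bool edge_hit = false;
  // traceback
  std::string aa, bb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if ((j == hi[i] && hi[i] < m) || (j == lo[i] && lo[i] > 0)) edge_hit = true;
    uint8_t dir = tb[(size_t)i * W + (j - lo[i])];
    if (dir == 1) {
      aa.push_back(a[i - 1]);
      bb.push_back(b[j - 1]);
      --i; --j;
    } else if (dir == 2) {
      aa.push_back(a[i - 1]);
      bb.push_back('-');
      --i;
    } else {
      aa.push_back('-');
      bb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = score, _["a_aln"] = aa, _["b_aln"] = bb,
                      _["edge_hit"] = edge_hit);
}
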