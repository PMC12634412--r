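// Compacted de Bruijn graph construction over canonical k-mers.
// k is restricted to odd values <= 63 so a k-mer packs into 2 bits/base in a
// 128-bit word and no k-mer can equal its own reverse complement.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <set>
#include <string>
#include <tuple>
#include <vector>

using namespace Rcpp;

namespace {

// 128-bit packing supports k up to 63 at 2 bits/base
typedef unsigned __int128 kmer_t;

inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

inline kmer_t rc_bits(kmer_t x, int k) {
  kmer_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (kmer_t)(3 - (int)(x & 3));
    x >>= 2;
  }
  return r;
}

inline std::string bits2seq(kmer_t x, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'N');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = B[(int)(x & 3)];
    x >>= 2;
  }
  return s;
}

// Call fn(canonical_kmer) for every k-mer of seq not containing an
// ambiguous base; the rolling window resets at each invalid character.
template <typename F>
void each_canonical(const std::string& seq, int k, kmer_t mask, F fn) {
  kmer_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (char c : seq) {
    int b = base2bits(c);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (kmer_t)b) & mask;
    rev = (rev >> 2) | ((kmer_t)(3 - b) << shift);
    if (++run >= k) fn(std::min(fwd, rev));
  }
}

struct Oriented {
  int idx;     // index into the sorted canonical k-mer table
  int strand;  // 0: sequence == canonical form; 1: reverse complement
  bool operator==(const Oriented& o) const {
    return idx == o.idx && strand == o.strand;
  }
};

struct KmerTable {
  std::vector<kmer_t> kmer;  // sorted canonical values
  std::vector<double> count;
  int k;
  kmer_t mask;

  int find(kmer_t canon) const {
    auto it = std::lower_bound(kmer.begin(), kmer.end(), canon);
    if (it == kmer.end() || *it != canon) return -1;
    return (int)(it - kmer.begin());
  }
  kmer_t oriented_value(const Oriented& o) const {
    return o.strand ? rc_bits(kmer[o.idx], k) : kmer[o.idx];
  }
  // Successors of the oriented k-mer in the bidirected graph (at most 4).
  std::vector<Oriented> succs(const Oriented& o) const {
    std::vector<Oriented> out;
    kmer_t cur = oriented_value(o);
    for (kmer_t b = 0; b < 4; ++b) {
      kmer_t nx = ((cur << 2) | b) & mask;
      kmer_t nrc = rc_bits(nx, k);
      kmer_t canon = std::min(nx, nrc);
      int j = find(canon);
      if (j >= 0) out.push_back({j, nx == canon ? 0 : 1});
    }
    return out;
  }
};

inline Oriented flip(const Oriented& o) { return {o.idx, 1 - o.strand}; }

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_kmer_table(CharacterVector reads, int k) {
  if (k < 1 || k > 63 || k % 2 == 0) stop("k must be odd and between 1 and 63");
  kmer_t mask = (((kmer_t)1) << (2 * k)) - 1;
  std::vector<kmer_t> all;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) continue;
    each_canonical(s, k, mask, [&](kmer_t c) { all.push_back(c); });
  }
  std::sort(all.begin(), all.end());
  std::vector<std::string> km;
  std::vector<int> cnt;
  for (size_t i = 0; i < all.size();) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    km.push_back(bits2seq(all[i], k));
    cnt.push_back((int)(j - i));
    i = j;
  }
  return DataFrame::create(_["kmer"] = km, _["count"] = cnt,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_build_unitigs(CharacterVector reads, int k, int min_count) {
  if (k < 1 || k > 63 || k % 2 == 0) stop("k must be odd and between 1 and 63");
  if (min_count < 1) stop("min_count must be >= 1");
  kmer_t mask = (((kmer_t)1) << (2 * k)) - 1;

  // count canonical k-mers (sorted table -> fully deterministic layout)
  std::vector<kmer_t> all;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) continue;
    each_canonical(s, k, mask, [&](kmer_t c) { all.push_back(c); });
  }
  std::sort(all.begin(), all.end());

  KmerTable tab;
  tab.k = k;
  tab.mask = mask;
  for (size_t i = 0; i < all.size();) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    if ((int)(j - i) >= min_count) {
      tab.kmer.push_back(all[i]);
      tab.count.push_back((double)(j - i));
    }
    i = j;
  }
  all.clear();
  all.shrink_to_fit();
  const int n = (int)tab.kmer.size();

  // unique forward extension o -> t such that t's unique predecessor is o
  auto unique_succ = [&](const Oriented& o, Oriented& out) -> bool {
    std::vector<Oriented> s = tab.succs(o);
    if (s.size() != 1) return false;
    if (tab.succs(flip(s[0])).size() != 1) return false;
    out = s[0];
    return true;
  };

  std::vector<char> visited(n, 0);
  std::vector<int> uid(n, -1);
  std::vector<std::string> useq;
  std::vector<double> umean;
  std::vector<int> ulen;
  std::vector<char> ucirc;
  std::vector<Oriented> ufirst, ulast;

  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    // walk backwards to find the start of the maximal non-branching path
    Oriented cur{i, 0};
    bool circular = false;
    while (true) {
      std::vector<Oriented> preds = tab.succs(flip(cur));
      if (preds.size() != 1) break;
      Oriented p = flip(preds[0]);
      if (tab.succs(p).size() != 1) break;
      if (p.idx == i) { circular = true; break; }
      cur = p;
    }
    // walk forward collecting the path
    std::vector<Oriented> path{cur};
    visited[cur.idx] = 1;
    while (true) {
      Oriented nxt;
      if (!unique_succ(path.back(), nxt)) break;
      if (visited[nxt.idx]) break;
      path.push_back(nxt);
      visited[nxt.idx] = 1;
    }
    int u = (int)useq.size();
    std::string s = bits2seq(tab.oriented_value(path[0]), k);
    double tot = tab.count[path[0].idx];
    uid[path[0].idx] = u;
    for (size_t p = 1; p < path.size(); ++p) {
      kmer_t v = tab.oriented_value(path[p]);
      s.push_back("ACGT"[(int)(v & 3)]);
      tot += tab.count[path[p].idx];
      uid[path[p].idx] = u;
    }
    useq.push_back(s);
    ulen.push_back((int)s.size());
    umean.push_back(tot / (double)path.size());
    ucirc.push_back(circular ? 1 : 0);
    ufirst.push_back(path[0]);
    ulast.push_back(path.back());
  }

  // links between unitig ends (each physical link found from both sides;
  // keep the canonical representative)
  auto end_orientation = [&](const Oriented& t, int v) -> char {
    // entering unitig v via oriented k-mer t
    if (t == ufirst[v]) return '+';
    if (flip(t) == ulast[v]) return '-';
    // single-kmer unitig where first == last covers both above; anything
    // else would mean t is interior, impossible at a junction
    return '?';
  };
  std::set<std::tuple<int, char, int, char>> links;
  auto add_link = [&](int u, char ou, int v, char ov) {
    // canonical form: (u,ou,v,ov) vs reverse complement (v,~ov,u,~ou)
    std::tuple<int, char, int, char> fwd(u, ou, v, ov);
    std::tuple<int, char, int, char> rev(v, ov == '+' ? '-' : '+', u,
                                         ou == '+' ? '-' : '+');
    links.insert(std::min(fwd, rev));
  };
  for (int u = 0; u < (int)useq.size(); ++u) {
    for (const Oriented& t : tab.succs(ulast[u])) {
      char ov = end_orientation(t, uid[t.idx]);
      if (ov != '?') add_link(u, '+', uid[t.idx], ov);
    }
    for (const Oriented& t : tab.succs(flip(ufirst[u]))) {
      char ov = end_orientation(t, uid[t.idx]);
      if (ov != '?') add_link(u, '-', uid[t.idx], ov);
    }
  }

  size_t ne = links.size();
  CharacterVector fo(ne), to_o(ne);
  IntegerVector fr(ne), to(ne);
  size_t i = 0;
  for (const auto& l : links) {
    fr[i] = std::get<0>(l) + 1;
    fo[i] = std::string(1, std::get<1>(l));
    to[i] = std::get<2>(l) + 1;
    to_o[i] = std::string(1, std::get<3>(l));
    ++i;
  }
  return List::create(
      _["sequence"] = useq, _["length"] = ulen, _["mean_count"] = umean,
      _["circular"] = LogicalVector(ucirc.begin(), ucirc.end()),
      _["edge_from"] = fr, _["edge_to"] = to, _["edge_from_orient"] = fo,
      _["edge_to_orient"] = to_o);
}

// For each sequence in seqs, does it share at least one canonical k-mer
// with ref?
// [[Rcpp::export]]
LogicalVector cpp_shares_kmer(CharacterVector seqs, std::string ref, int k) {
  if (k < 1 || k > 63 || k % 2 == 0) stop("k must be odd and between 1 and 63");
  if ((int)ref.size() < k) stop("reference sequence shorter than k");
  kmer_t mask = (((kmer_t)1) << (2 * k)) - 1;
  std::vector<kmer_t> refk;
  each_canonical(ref, k, mask, [&](kmer_t c) { refk.push_back(c); });
  std::sort(refk.begin(), refk.end());
  refk.erase(std::unique(refk.begin(), refk.end()), refk.end());
  LogicalVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    bool hit = false;
    if ((int)s.size() >= k) {
      each_canonical(s, k, mask, [&](kmer_t c) {
        if (!hit && std::binary_search(refk.begin(), refk.end(), c)) hit = true;
      });
    }
    out[i] = hit;
  }
  return out;
}

// Multiplicities of the distinct canonical k-mers (order unspecified);
// used to estimate the coverage mode for the toy assembler's cutoff.
// [[Rcpp::export]]
IntegerVector cpp_kmer_counts(CharacterVector reads, int k) {
  if (k < 1 || k > 63 || k % 2 == 0) stop("k must be odd and between 1 and 63");
  kmer_t mask = (((kmer_t)1) << (2 * k)) - 1;
  std::vector<kmer_t> all;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) continue;
    each_canonical(s, k, mask, [&](kmer_t c) { all.push_back(c); });
  }
  std::sort(all.begin(), all.end());
  std::vector<int> cnt;
  for (size_t i = 0; i < all.size();) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    cnt.push_back((int)(j - i));
    i = j;
  }
  return IntegerVector(cnt.begin(), cnt.end());
}
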