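#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// 2-bit packed canonical k-mers; k up to 63 fits in 126 bits.
typedef unsigned __int128 kmer_t;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// Append canonical (min of forward, reverse-complement) k-mers of s to out.
// Windows containing non-ACGT letters are skipped.
static void enum_canonical(const std::string& s, int k, std::vector<kmer_t>& out) {
  const int n = (int)s.size();
  if (n < k) return;
  const kmer_t mask = ((((kmer_t)1) << (2 * k)) - 1);
  const int shift_rev = 2 * (k - 1);
  kmer_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    const int b = base2bit(s[i]);
    if (b < 0) {
      valid = 0;
      fwd = 0;
      rev = 0;
      continue;
    }
    fwd = ((fwd << 2) | (kmer_t)b) & mask;
    rev = (rev >> 2) | (((kmer_t)(3 - b)) << shift_rev);
    if (++valid >= k) out.push_back(fwd < rev ? fwd : rev);
  }
}

static std::string decode(kmer_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[(int)(x & 3)];
    x >>= 2;
  }
  return s;
}

static std::vector<kmer_t> kmer_set(const std::string& s, int k) {
  std::vector<kmer_t> v;
  enum_canonical(s, k, v);
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return v;
}

static void check_k(int k) {
  if (k < 1 || k > 63) stop("k must be between 1 and 63");
}

// Marker extraction over a whole graph.
//
// node_frag: per node, a list with one CharacterVector per (distinct) member;
//            each vector holds the member's eligible subsequences (window
//            fragments after synteny masking). A candidate marker must occur
//            in every member's fragments.
// node_full: per node, CharacterVector of the node's (distinct) member
//            windowed sequences, unmasked. Uniqueness is enforced against
//            these: a candidate of node i survives only if it occurs in no
//            other node's full sequences.
// precap:    cap on candidates kept per node before the global uniqueness
//            pass (0 = unlimited); max_per_node caps the final marker set
//            (0 = unlimited). Both take the lexicographically smallest packed
//            k-mers, so results are deterministic.
// [[Rcpp::export]]
List cpp_extract_markers(List node_frag, List node_full, int k, int max_per_node,
                         int precap) {
  check_k(k);
  const int n_nodes = node_frag.size();
  if (node_full.size() != n_nodes) stop("node_frag / node_full length mismatch");

  // 1. per-node candidates: intersection over members
  std::vector<std::vector<kmer_t> > cand(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    List members = node_frag[i];
    const int nm = members.size();
    std::vector<kmer_t> acc;
    for (int m = 0; m < nm; ++m) {
      CharacterVector frags = members[m];
      std::vector<kmer_t> cur;
      for (int f = 0; f < frags.size(); ++f) {
        std::string s = as<std::string>(frags[f]);
        enum_canonical(s, k, cur);
      }
      std::sort(cur.begin(), cur.end());
      cur.erase(std::unique(cur.begin(), cur.end()), cur.end());
      if (m == 0) {
        acc.swap(cur);
      } else {
        std::vector<kmer_t> tmp;
        std::set_intersection(acc.begin(), acc.end(), cur.begin(), cur.end(),
                              std::back_inserter(tmp));
        acc.swap(tmp);
      }
      if (acc.empty()) break;
    }
    if (precap > 0 && (int)acc.size() > precap) acc.resize(precap);
    cand[i].swap(acc);
  }

  // 2. flat sorted candidate index
  size_t total = 0;
  for (int i = 0; i < n_nodes; ++i) total += cand[i].size();
  std::vector<kmer_t> ck(total);
  std::vector<int> cn(total);
  std::vector<size_t> ord(total);
  {
    size_t p = 0;
    for (int i = 0; i < n_nodes; ++i)
      for (size_t j = 0; j < cand[i].size(); ++j) {
        ck[p] = cand[i][j];
        cn[p] = i;
        ++p;
      }
  }
  for (size_t i = 0; i < total; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return ck[a] < ck[b] || (ck[a] == ck[b] && cn[a] < cn[b]); });
  std::vector<kmer_t> sk(total);
  std::vector<int> sn(total);
  for (size_t i = 0; i < total; ++i) {
    sk[i] = ck[ord[i]];
    sn[i] = cn[ord[i]];
  }
  std::vector<char> alive(total, 1);
  // identical candidate in >1 node: both occur in both nodes' sequences
  for (size_t i = 1; i < total; ++i)
    if (sk[i] == sk[i - 1]) alive[i] = alive[i - 1] = 0;

  // 3. global uniqueness: k-mers of any node's full sequences kill other
  //    nodes' candidates
  std::vector<kmer_t> buf;
  for (int i = 0; i < n_nodes; ++i) {
    CharacterVector seqs = node_full[i];
    buf.clear();
    for (int m = 0; m < seqs.size(); ++m) {
      std::string s = as<std::string>(seqs[m]);
      enum_canonical(s, k, buf);
    }
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    for (size_t j = 0; j < buf.size(); ++j) {
      size_t lo = std::lower_bound(sk.begin(), sk.end(), buf[j]) - sk.begin();
      for (size_t p = lo; p < total && sk[p] == buf[j]; ++p)
        if (sn[p] != i) alive[p] = 0;
    }
  }

  // 4. collect survivors per node
  std::vector<std::vector<kmer_t> > keep(n_nodes);
  for (size_t p = 0; p < total; ++p)
    if (alive[p]) keep[sn[p]].push_back(sk[p]);
  List out(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    std::vector<kmer_t>& v = keep[i];
    std::sort(v.begin(), v.end());
    size_t nk = v.size();
    if (max_per_node > 0 && nk > (size_t)max_per_node) nk = (size_t)max_per_node;
    CharacterVector res(nk);
    for (size_t j = 0; j < nk; ++j) res[j] = decode(v[j], k);
    out[i] = res;
  }
  return out;
}

// Number of sequences in `seqs` that contain each marker (canonical match).
// [[Rcpp::export]]
IntegerVector cpp_marker_presence(CharacterVector markers, List seqs, int k) {
  check_k(k);
  const int nm = markers.size();
  std::vector<kmer_t> mk(nm);
  for (int i = 0; i < nm; ++i) {
    std::string s = as<std::string>(markers[i]);
    if ((int)s.size() != k) stop("marker length differs from k");
    std::vector<kmer_t> one;
    enum_canonical(s, k, one);
    if (one.size() != 1) stop("marker contains non-ACGT letters");
    mk[i] = one[0];
  }
  std::vector<size_t> ord(nm);
  for (int i = 0; i < nm; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) { return mk[a] < mk[b]; });
  std::vector<kmer_t> sk(nm);
  for (int i = 0; i < nm; ++i) sk[i] = mk[ord[i]];

  IntegerVector counts(nm, 0);
  std::vector<char> seen(nm);
  std::vector<kmer_t> buf;
  for (int s = 0; s < seqs.size(); ++s) {
    std::fill(seen.begin(), seen.end(), 0);
    std::string str = as<std::string>(seqs[s]);
    buf.clear();
    enum_canonical(str, k, buf);
    for (size_t j = 0; j < buf.size(); ++j) {
      size_t lo = std::lower_bound(sk.begin(), sk.end(), buf[j]) - sk.begin();
      for (size_t p = lo; p < (size_t)nm && sk[p] == buf[j]; ++p) {
        if (!seen[p]) {
          seen[p] = 1;
          counts[ord[p]] += 1;
        }
      }
    }
  }
  return counts;
}

// Canonical form of each k-mer string (min of itself and its reverse
// complement); used when normalizing external k-mer count tables.
// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector kmers) {
  const int n = kmers.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    const int k = (int)s.size();
    check_k(k);
    std::vector<kmer_t> one;
    enum_canonical(s, k, one);
    if (one.size() != 1) stop("k-mer contains non-ACGT letters");
    out[i] = decode(one[0], k);
  }
  return out;
}
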