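// Core scanning and shuffling loops.
//
// Degenerate pattern matching: mismatches are counted only at fixed (non-N)
// pattern positions, and an N in the *sequence* at a fixed position counts
// as a mismatch.  Dinucleotide shuffling follows the exact-count
// Altschul-Erickson construction (random Eulerian trail on the dinucleotide
// multigraph, selected via uniformly sampled per-vertex last edges), which
// conserves the dinucleotide multiset and both terminal characters exactly.
// All randomness comes from R's RNG so results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

static const char *ALPHA = "ACGTN";

static inline int base_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  case 'N': return 4;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  default: return 0;
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = comp_base(s[s.size() - 1 - i]);
    if (c == 0) stop("invalid character in sequence: '%c'", s[s.size() - 1 - i]);
    out[i] = c;
  }
  return out;
}

struct FixedPattern {
  std::vector<int> pos;
  std::vector<char> ch;
  int len;
};

static FixedPattern parse_fixed(const std::string &pat) {
  FixedPattern fp;
  fp.len = (int)pat.size();
  for (int i = 0; i < fp.len; ++i) {
    char c = pat[i];
    if (base_idx(c) < 0) stop("invalid character in pattern: '%c'", c);
    if (c != 'N') {
      fp.pos.push_back(i);
      fp.ch.push_back(c);
    }
  }
  if (fp.pos.empty()) stop("pattern has no fixed (non-N) position");
  return fp;
}

// mismatch count at one offset (0-based); caller guarantees range
static inline int mm_at(const std::string &s, const FixedPattern &fp, int off,
                        int stop_above) {
  int mm = 0;
  const size_t nf = fp.pos.size();
  for (size_t k = 0; k < nf; ++k) {
    if (s[off + fp.pos[k]] != fp.ch[k]) {
      if (++mm > stop_above) return mm;
    }
  }
  return mm;
}

static bool scan_positive_one(const std::string &s, const FixedPattern &fp,
                              int max_mm) {
  int n_off = (int)s.size() - fp.len;
  for (int o = 0; o <= n_off; ++o)
    if (mm_at(s, fp, o, max_mm) <= max_mm) return true;
  return false;
}

// strand_mode: 0 = forward, 1 = revcomp, 2 = both
// [[Rcpp::export]]
LogicalVector C_scan_positive(CharacterVector seqs, std::string pattern,
                              int max_mismatch, int strand_mode) {
  FixedPattern fwd = parse_fixed(pattern);
  FixedPattern rc = parse_fixed(revcomp_str(pattern));
  int n = seqs.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    bool pos = false;
    if (strand_mode == 0 || strand_mode == 2)
      pos = scan_positive_one(s, fwd, max_mismatch);
    if (!pos && (strand_mode == 1 || strand_mode == 2))
      pos = scan_positive_one(s, rc, max_mismatch);
    out[i] = pos;
  }
  return out;
}

// Minimum mismatch count over all offsets (and strands); NA when the
// sequence is shorter than the pattern.
// [[Rcpp::export]]
IntegerVector C_min_mismatches(CharacterVector seqs, std::string pattern,
                               int strand_mode) {
  FixedPattern fwd = parse_fixed(pattern);
  FixedPattern rc = parse_fixed(revcomp_str(pattern));
  int nf = (int)fwd.pos.size();
  int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int n_off = (int)s.size() - fwd.len;
    if (n_off < 0) {
      out[i] = NA_INTEGER;
      continue;
    }
    int best = nf + 1;
    for (int o = 0; o <= n_off; ++o) {
      if (strand_mode == 0 || strand_mode == 2) {
        int m = mm_at(s, fwd, o, best);
        if (m < best) best = m;
      }
      if (strand_mode == 1 || strand_mode == 2) {
        int m = mm_at(s, rc, o, best);
        if (m < best) best = m;
      }
      if (best == 0) break;
    }
    out[i] = best;
  }
  return out;
}

// First qualifying match: offset (0-based in the forward sequence), strand
// (0 forward / 1 revcomp), mismatch count; NA row when no qualifying match.
// Forward strand offsets are scanned first, then the reverse complement.
// [[Rcpp::export]]
IntegerMatrix C_best_match(CharacterVector seqs, std::string pattern,
                           int max_mismatch, int strand_mode) {
  FixedPattern fwd = parse_fixed(pattern);
  FixedPattern rc = parse_fixed(revcomp_str(pattern));
  int n = seqs.size();
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int n_off = (int)s.size() - fwd.len;
    int off = NA_INTEGER, strand = NA_INTEGER, mm = NA_INTEGER;
    if (n_off >= 0) {
      if (strand_mode == 0 || strand_mode == 2) {
        for (int o = 0; o <= n_off; ++o) {
          int m = mm_at(s, fwd, o, max_mismatch);
          if (m <= max_mismatch) { off = o; strand = 0; mm = m; break; }
        }
      }
      if (off == NA_INTEGER && (strand_mode == 1 || strand_mode == 2)) {
        for (int o = 0; o <= n_off; ++o) {
          int m = mm_at(s, rc, o, max_mismatch);
          if (m <= max_mismatch) { off = o; strand = 1; mm = m; break; }
        }
      }
    }
    out(i, 0) = off;
    out(i, 1) = strand;
    out(i, 2) = mm;
  }
  return out;
}

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Altschul-Erickson exact dinucleotide shuffle of one sequence.
static std::string dinuc_shuffle_one(const std::string &s) {
  int L = (int)s.size();
  if (L <= 2) return s;
  std::vector<std::vector<int> > adj(5);
  for (int i = 0; i < L; ++i)
    if (base_idx(s[i]) < 0) stop("invalid character in sequence: '%c'", s[i]);
  for (int i = 0; i + 1 < L; ++i)
    adj[base_idx(s[i])].push_back(base_idx(s[i + 1]));
  int last = base_idx(s[L - 1]);

  // sample per-vertex last edges until they form an arborescence toward
  // `last` (uniform over Eulerian trails by the last-edge tree theorem)
  int last_edge_pos[5];
  for (int tries = 0;; ++tries) {
    if (tries > 100000) stop("dinucleotide shuffle failed to converge");
    bool ok = true;
    for (int u = 0; u < 5; ++u) {
      last_edge_pos[u] = -1;
      if (u != last && !adj[u].empty())
        last_edge_pos[u] = runif_int((int)adj[u].size());
    }
    for (int u = 0; u < 5 && ok; ++u) {
      if (last_edge_pos[u] < 0) continue;
      int v = u, steps = 0;
      while (v != last) {
        if (last_edge_pos[v] < 0 || ++steps > 5) { ok = false; break; }
        v = adj[v][last_edge_pos[v]];
      }
    }
    if (ok) break;
  }

  // per-vertex edge order: shuffled non-last edges, then the last edge
  std::vector<std::vector<int> > order(5);
  for (int u = 0; u < 5; ++u) {
    if (adj[u].empty()) continue;
    std::vector<int> rest;
    rest.reserve(adj[u].size());
    for (int j = 0; j < (int)adj[u].size(); ++j)
      if (j != last_edge_pos[u]) rest.push_back(adj[u][j]);
    for (int j = (int)rest.size() - 1; j > 0; --j) {
      int k = runif_int(j + 1);
      std::swap(rest[j], rest[k]);
    }
    if (last_edge_pos[u] >= 0) rest.push_back(adj[u][last_edge_pos[u]]);
    order[u].swap(rest);
  }

  std::string out;
  out.reserve(L);
  out.push_back(s[0]);
  int cur = base_idx(s[0]);
  std::vector<size_t> ptr(5, 0);
  for (int i = 1; i < L; ++i) {
    int v = order[cur][ptr[cur]++];
    out.push_back(ALPHA[v]);
    cur = v;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector C_dinuc_shuffle(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = dinuc_shuffle_one(as<std::string>(seqs[i]));
  return out;
}

// One permutation = every target independently re-shuffled, then the
// motif-positive count recomputed under the same matching criteria.
// Returns the per-permutation positive counts.
// [[Rcpp::export]]
IntegerVector C_permutation_counts(CharacterVector targets, std::string pattern,
                                   int max_mismatch, int strand_mode,
                                   int n_perm) {
  if (n_perm < 1) stop("n_perm must be >= 1");
  FixedPattern fwd = parse_fixed(pattern);
  FixedPattern rc = parse_fixed(revcomp_str(pattern));
  int n = targets.size();
  std::vector<std::string> seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = as<std::string>(targets[i]);
  IntegerVector counts(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    if (p % 256 == 0) checkUserInterrupt();
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      std::string sh = dinuc_shuffle_one(seqs[i]);
      bool pos = false;
      if (strand_mode == 0 || strand_mode == 2)
        pos = scan_positive_one(sh, fwd, max_mismatch);
      if (!pos && (strand_mode == 1 || strand_mode == 2))
        pos = scan_positive_one(sh, rc, max_mismatch);
      if (pos) ++cnt;
    }
    counts[p] = cnt;
  }
  return counts;
}
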