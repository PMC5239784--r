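#include <Rcpp.h>
using namespace Rcpp;

// Consecutive-run alignment score with greedy 5'-first mismatch leniency.
// pattern: 1 = match, 0 = forgivable mismatch, -1 = unforgivable mismatch
// (ambiguous nts). A mismatch run of length 1 consisting of a forgivable
// mismatch may be "forgiven" while budget remains: it contributes 0 and the
// flanking match runs fuse into one. Runs of >= 2 mismatches never forgiven.
static double score_pattern_core(const int* p, int n, int budget) {
  double score = 0.0;
  long cur = 0; // length of the current (possibly fused) match run
  int i = 0;
  while (i < n) {
    if (p[i] == 1) {
      int j = i;
      while (j < n && p[j] == 1) ++j;
      cur += (j - i);
      i = j;
    } else {
      int j = i;
      while (j < n && p[j] != 1) ++j;
      int len = j - i;
      if (len == 1 && p[i] == 0 && budget > 0) {
        --budget; // forgiven: contributes 0, flanks fuse
      } else {
        score += (double)cur * cur;
        cur = 0;
        score -= (double)len * len;
      }
      i = j;
    }
  }
  score += (double)cur * cur;
  return score;
}

// [[Rcpp::export]]
double score_pattern_cpp(IntegerVector pattern, int budget) {
  return score_pattern_core(INTEGER(pattern), pattern.size(), budget);
}

static inline int pat_code(char r, char g) {
  if (r == 'N' || g == 'N') return -1;
  return (r == g) ? 1 : 0;
}

// Enumerate every ungapped placement of `gene` against `read` restricted to
// the window [ws, we] (1-based, inclusive). Offset o is the read coordinate
// aligned with gene position 1 (may fall outside the window: partial
// overhangs are allowed). Leniency budget per offset: `count` if >= 0, else
// ceil(frac * overlap).
// [[Rcpp::export]]
DataFrame enumerate_offsets_cpp(std::string read, std::string gene,
                                int ws, int we, int min_overlap,
                                double frac, int count) {
  int lg = (int)gene.size();
  std::vector<int> off, rs_v, re_v, ov_v, mm_v;
  std::vector<double> sc_v;
  int o_lo = ws - lg + min_overlap;
  int o_hi = we - min_overlap + 1;
  std::vector<int> pat;
  pat.reserve(we - ws + 1 > 0 ? we - ws + 1 : 0);
  for (int o = o_lo; o <= o_hi; ++o) {
    int rs = std::max(o, ws);
    int re = std::min(o + lg - 1, we);
    int ov = re - rs + 1;
    if (ov < min_overlap) continue;
    pat.clear();
    int mm = 0;
    for (int r = rs; r <= re; ++r) {
      int code = pat_code(read[r - 1], gene[r - o]);
      if (code != 1) ++mm;
      pat.push_back(code);
    }
    int budget = count >= 0 ? count : (int)std::ceil(frac * ov);
    double sc = score_pattern_core(pat.data(), ov, budget);
    off.push_back(o); rs_v.push_back(rs); re_v.push_back(re);
    ov_v.push_back(ov); mm_v.push_back(mm); sc_v.push_back(sc);
  }
  return DataFrame::create(_["offset"] = off, _["read_start"] = rs_v,
                           _["read_end"] = re_v, _["overlap"] = ov_v,
                           _["n_mismatch"] = mm_v, _["score"] = sc_v);
}

static inline int nt_idx(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}

// Asymmetric SHM distance: sum of squared mismatch-run lengths plus a
// per-mutation weight looked up in w[parent_nt, child_nt].
// [[Rcpp::export]]
double shm_dist_cpp(std::string parent, std::string child, NumericMatrix w) {
  int n = (int)parent.size();
  if ((int)child.size() != n)
    stop("parent and child sequences must have equal length");
  double d = 0.0;
  int i = 0;
  while (i < n) {
    if (parent[i] == child[i]) { ++i; continue; }
    int j = i;
    while (j < n && parent[j] != child[j]) {
      int pi = nt_idx(parent[j]), ci = nt_idx(child[j]);
      if (pi < 0 || ci < 0) stop("sequences must be over {A,C,G,T}");
      d += w(pi, ci);
      ++j;
    }
    int len = j - i;
    d += (double)len * len;
    i = j;
  }
  return d;
}

// All pairwise directed SHM distances: out(i, j) = distance with sequence i
// as parent of sequence j. Sequences must share one length.
// [[Rcpp::export]]
NumericMatrix shm_dist_matrix_cpp(CharacterVector seqs, NumericMatrix w) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) out(i, j) = shm_dist_cpp(s[i], s[j], w);
  return out;
}
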