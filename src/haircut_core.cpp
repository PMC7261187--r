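#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exhaustive ungapped placement of each read at every offset of every
// reference, forward orientation only. The read must be fully contained in
// the reference from its offset (no 3' overhang). status: 0 = aligned,
// 1 = unaligned, 2 = ambiguous (tie in mismatches across placements).
// [[Rcpp::export]]
DataFrame align_reads_cpp(CharacterVector reads, CharacterVector refs,
                          int max_mismatches) {
  int n = reads.size(), nref = refs.size();
  if (nref == 0) stop("empty reference set");
  std::vector<std::string> R(nref);
  for (int j = 0; j < nref; ++j) R[j] = as<std::string>(refs[j]);

  IntegerVector ref_idx(n, NA_INTEGER), pos(n, NA_INTEGER),
      mm_out(n, NA_INTEGER), status(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int L = (int)rd.size();
    int best = max_mismatches + 1, nbest = 0, bref = -1, bpos = -1;
    for (int j = 0; j < nref; ++j) {
      int reflen = (int)R[j].size();
      for (int o = 0; o + L <= reflen; ++o) {
        int mm = 0;
        const char *a = rd.c_str(), *b = R[j].c_str() + o;
        for (int k = 0; k < L; ++k) {
          if (a[k] != b[k] && ++mm > best) break;
        }
        if (mm < best) {
          best = mm; nbest = 1; bref = j; bpos = o;
        } else if (mm == best && best <= max_mismatches) {
          ++nbest;
        }
      }
    }
    if (best > max_mismatches) {
      status[i] = 1;
    } else if (nbest > 1) {
      status[i] = 2;
    } else {
      status[i] = 0;
      ref_idx[i] = bref + 1;
      pos[i] = bpos + 1;  // 1-based
      mm_out[i] = best;
    }
  }
  return DataFrame::create(_["ref_idx"] = ref_idx, _["position"] = pos,
                           _["mismatches"] = mm_out, _["status"] = status);
}

static inline int hamming(const std::string &a, const std::string &b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) d += (a[i] != b[i]);
  return d;
}

// umi_tools-style directional adjacency clustering, run independently within
// each stratum (rows must arrive sorted by stratum id). Directed edge
// u -> v iff Hamming(u, v) == 1 and count(u) >= 2 * count(v) - 1. Roots are
// taken in descending count (ties lexicographic by UMI); each cluster is the
// set of unvisited nodes reachable from its root. Returns, per input row,
// the 1-based global row index of its cluster's root.
// [[Rcpp::export]]
IntegerVector umi_cluster_cpp(IntegerVector stratum, CharacterVector umis,
                              IntegerVector counts) {
  int n = umis.size();
  IntegerVector rep(n);
  int i0 = 0;
  while (i0 < n) {
    int i1 = i0;
    while (i1 < n && stratum[i1] == stratum[i0]) ++i1;
    int k = i1 - i0;
    std::vector<std::string> U(k);
    std::vector<int> C(k);
    size_t ulen = 0;
    for (int i = 0; i < k; ++i) {
      U[i] = as<std::string>(umis[i0 + i]);
      C[i] = counts[i0 + i];
      if (i == 0) ulen = U[i].size();
      else if (U[i].size() != ulen) stop("mixed UMI lengths within a stratum");
    }
    std::vector<int> ord(k);
    for (int i = 0; i < k; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (C[a] != C[b]) return C[a] > C[b];
      return U[a] < U[b];
    });
    std::vector<int> root(k, -1);
    for (int oi = 0; oi < k; ++oi) {
      int r = ord[oi];
      if (root[r] >= 0) continue;
      root[r] = r;
      std::vector<int> queue{r};
      while (!queue.empty()) {
        int u = queue.back();
        queue.pop_back();
        for (int v = 0; v < k; ++v) {
          if (root[v] >= 0) continue;
          if (C[u] >= 2 * C[v] - 1 && hamming(U[u], U[v]) == 1) {
            root[v] = r;
            queue.push_back(v);
          }
        }
      }
    }
    for (int i = 0; i < k; ++i) rep[i0 + i] = i0 + root[i] + 1;
    i0 = i1;
  }
  return rep;
}

// Length of the maximal 3'-terminal suffix that (a) begins with an A,
// (b) has non-A content <= max_nona_frac, and (c) is at least min_run long.
// Returns 0 when no qualifying suffix exists.
// [[Rcpp::export]]
IntegerVector polya_suffix_cpp(CharacterVector seqs, int min_run,
                               double max_nona_frac) {
  int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int len = (int)s.size(), nona = 0, best = 0;
    for (int L = 1; L <= len; ++L) {
      char c = s[len - L];
      if (c != 'A') ++nona;
      if (c == 'A' && (double)nona <= max_nona_frac * (double)L + 1e-9)
        best = L;
    }
    out[i] = (best >= min_run) ? best : 0;
  }
  return out;
}

// Mismatches between the first nchar(pattern) bases of each sequence and
// pattern; NA when the sequence is shorter than the pattern.
// [[Rcpp::export]]
IntegerVector prefix_mismatch_cpp(CharacterVector seqs, std::string pattern) {
  int n = seqs.size(), plen = (int)pattern.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < plen) {
      out[i] = NA_INTEGER;
      continue;
    }
    int mm = 0;
    for (int k = 0; k < plen; ++k) mm += (s[k] != pattern[k]);
    out[i] = mm;
  }
  return out;
}
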