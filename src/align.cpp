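// Seed-and-extend local alignment core.
//
// Affine gap convention: a gap of length L costs gap_open + (L-1)*gap_extend,
// i.e. the first gapped base pays gap_open. Scores are integers.
// Coordinates returned here are 0-based; the R layer converts to 1-based.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

// collapse C onto T for three-letter bisulfite comparison
static inline int collapse_code(int code, bool bisulfite) {
  if (bisulfite && code == 1) return 3;
  return code;
}

struct AlnResult {
  int score = NEG_INF;
  int ref_start = -1;   // 0-based leftmost aligned reference base
  int ref_end = -1;     // 0-based inclusive
  int q_start = -1;
  int q_end = -1;
  std::string cigar;    // M/I/D over the aligned region (no clips)
};

// Banded affine-gap Smith-Waterman of query against target, cells restricted
// to |(j - i) - diag| <= band (i over query, j over target, both 0-based).
// band < 0 disables banding (full matrix). Traceback gives one optimal
// alignment; among equal-score cells the one with the smallest (end_j, end_i)
// in row-major scan order is taken and the traceback prefers diagonal moves.
static AlnResult sw_align(const std::vector<int>& q, const std::vector<int>& t,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int diag, int band) {
  const int m = (int)q.size(), n = (int)t.size();
  const int width = (band < 0) ? n : std::min(n, 2 * band + 1);
  // H, E (gap in query: consumes target, horizontal), F (gap in target)
  std::vector<int> H((size_t)(m + 1) * (width + 2), 0);
  std::vector<int> E((size_t)(m + 1) * (width + 2), NEG_INF);
  std::vector<int> F((size_t)(m + 1) * (width + 2), NEG_INF);
  // column window for row i: j in [lo(i), hi(i)] (0-based target index)
  auto lo = [&](int i) { return (band < 0) ? 0 : std::max(0, i - 1 + diag - band); };
  auto hi = [&](int i) { return (band < 0) ? n - 1 : std::min(n - 1, i - 1 + diag + band); };
  auto idx = [&](int i, int j) { // j is a target index valid for row i
    int off = (band < 0) ? j : (j - lo(i));
    return (size_t)i * (width + 2) + off + 1;
  };
  auto getH = [&](int i, int j) -> int {
    if (i < 0 || j < 0) return 0;
    if (i == 0) return 0;
    if (j < lo(i) || j > hi(i)) return (j < 0) ? 0 : NEG_INF;
    return H[idx(i, j)];
  };
  auto getE = [&](int i, int j) -> int {
    if (i <= 0 || j < lo(i) || j > hi(i)) return NEG_INF;
    return E[idx(i, j)];
  };
  auto getF = [&](int i, int j) -> int {
    if (i <= 0 || j < lo(i) || j > hi(i)) return NEG_INF;
    return F[idx(i, j)];
  };

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = lo(i); j <= hi(i); ++j) {
      int s = (q[i - 1] == t[j]) ? match : mismatch;
      int e = std::max(getH(i, j - 1) + gap_open, getE(i, j - 1) + gap_extend);
      int f = std::max(getH(i - 1, j) + gap_open, getF(i - 1, j) + gap_extend);
      int h = std::max(0, getH(i - 1, j - 1) + s);
      h = std::max(h, std::max(e, f));
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  AlnResult res;
  res.score = best;
  if (best <= 0 || bi < 0) { res.score = 0; return res; }

  // traceback from (bi, bj)
  std::string ops;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (I in target dir -> D op), 2 = F (-> I op)
  while (i > 0 && j >= 0) {
    if (state == 0) {
      int h = getH(i, j);
      if (h == 0) break;
      int s = (q[i - 1] == t[j]) ? match : mismatch;
      if (getH(i - 1, j - 1) + s == h) { ops.push_back('M'); --i; --j; }
      else if (getE(i, j) == h) state = 1;
      else if (getF(i, j) == h) state = 2;
      else break; // unreachable
    } else if (state == 1) { // gap in query: target base consumed -> D
      int e = getE(i, j);
      ops.push_back('D');
      if (getH(i, j - 1) + gap_open == e) state = 0;
      --j;
    } else { // gap in target: query base consumed -> I
      int f = getF(i, j);
      ops.push_back('I');
      if (getH(i - 1, j) + gap_open == f) state = 0;
      --i;
    }
  }
  res.q_end = bi - 1;
  res.ref_end = bj;
  res.q_start = i;       // first aligned query base, 0-based
  res.ref_start = j + 1; // traceback overshoots by one target step
  // ops are reversed; run-length encode
  std::reverse(ops.begin(), ops.end());
  std::string cig;
  for (size_t p = 0; p < ops.size();) {
    size_t r = p;
    while (r < ops.size() && ops[r] == ops[p]) ++r;
    cig += std::to_string(r - p);
    cig.push_back(ops[p]);
    p = r;
  }
  res.cigar = cig;
  return res;
}

static std::vector<int> encode_seq(const std::string& s, bool bisulfite) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i)
    v[i] = collapse_code(base_code(s[i]), bisulfite);
  return v;
}

// [[Rcpp::export]]
List sw_pair_cpp(std::string query, std::string target,
                 int match, int mismatch, int gap_open, int gap_extend,
                 bool bisulfite = false) {
  std::vector<int> q = encode_seq(query, bisulfite);
  std::vector<int> t = encode_seq(target, bisulfite);
  AlnResult r = sw_align(q, t, match, mismatch, gap_open, gap_extend, 0, -1);
  return List::create(
    _["score"] = r.score,
    _["target_start"] = r.ref_start,
    _["target_end"] = r.ref_end,
    _["query_start"] = r.q_start,
    _["query_end"] = r.q_end,
    _["cigar"] = r.cigar);
}

// [[Rcpp::export]]
List align_batch_cpp(CharacterVector reads,
                     CharacterVector ref_names, CharacterVector ref_seqs,
                     int k, int match, int mismatch, int gap_open,
                     int gap_extend, double min_score_frac, bool bisulfite,
                     int band_base, double band_frac) {
  const int nref = ref_seqs.size();
  std::vector<std::vector<int>> refs(nref);
  std::vector<std::string> rnames(nref);
  for (int r = 0; r < nref; ++r) {
    refs[r] = encode_seq(as<std::string>(ref_seqs[r]), bisulfite);
    rnames[r] = as<std::string>(ref_names[r]);
  }

  // k-mer index over (collapsed) references; 2-bit packing, k <= 15
  if (k < 4 || k > 15) stop("k must be in [4, 15]");
  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> index;
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  for (int r = 0; r < nref; ++r) {
    const std::vector<int>& s = refs[r];
    if ((int)s.size() < k) continue;
    uint32_t kmer = 0;
    int run = 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      if (s[j] < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint32_t)s[j]) & mask;
      if (++run >= k) index[kmer].emplace_back(r, j - k + 1);
    }
  }

  const int n = reads.size();
  IntegerVector out_ref(n), out_start(n), out_alen(n), out_score(n);
  IntegerVector out_qstart(n), out_qend(n);
  CharacterVector out_cigar(n);

  std::vector<std::pair<int, int>> cands; // (ref, diag)
  for (int ri = 0; ri < n; ++ri) {
    std::string rs = as<std::string>(reads[ri]);
    std::vector<int> q = encode_seq(rs, bisulfite);
    const int m = (int)q.size();
    out_ref[ri] = NA_INTEGER;
    if (m < k) continue;
    const int band = band_base + (int)std::ceil(band_frac * m);
    const int min_score = (int)std::ceil(min_score_frac * match * m);

    // seeds at stride k plus the final window
    cands.clear();
    for (int p = 0; p <= m - k; p += k) {
      int pp = std::min(p, m - k);
      uint32_t kmer = 0;
      bool ok = true;
      for (int x = 0; x < k; ++x) {
        if (q[pp + x] < 0) { ok = false; break; }
        kmer = ((kmer << 2) | (uint32_t)q[pp + x]) & mask;
      }
      if (!ok) continue;
      auto it = index.find(kmer);
      if (it == index.end()) continue;
      for (auto& hit : it->second)
        cands.emplace_back(hit.first, hit.second - pp);
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    // merge nearby diagonals on the same reference into one candidate
    std::vector<std::pair<int, int>> merged;
    for (auto& c : cands) {
      if (!merged.empty() && merged.back().first == c.first &&
          c.second - merged.back().second <= band / 2)
        continue;
      merged.push_back(c);
      if (merged.size() >= 24) break;
    }

    AlnResult best;
    int best_ref = -1;
    for (auto& c : merged) {
      AlnResult a = sw_align(q, refs[c.first], match, mismatch, gap_open,
                             gap_extend, c.second, band);
      if (a.score <= 0) continue;
      bool take = false;
      if (a.score > best.score) take = true;
      else if (a.score == best.score && best_ref >= 0) {
        if (rnames[c.first] < rnames[best_ref]) take = true;
        else if (rnames[c.first] == rnames[best_ref] &&
                 (a.ref_end < best.ref_end ||
                  (a.ref_end == best.ref_end && a.q_end < best.q_end)))
          take = true;
      }
      if (take) { best = a; best_ref = c.first; }
    }
    if (best_ref < 0 || best.score < min_score) continue;
    out_ref[ri] = best_ref + 1;
    out_start[ri] = best.ref_start;                 // 0-based
    out_alen[ri] = best.ref_end - best.ref_start + 1;
    out_score[ri] = best.score;
    out_qstart[ri] = best.q_start;
    out_qend[ri] = best.q_end;
    out_cigar[ri] = best.cigar;
  }

  return List::create(
    _["ref_idx"] = out_ref, _["start0"] = out_start,
    _["aligned_length"] = out_alen, _["score"] = out_score,
    _["query_start0"] = out_qstart, _["query_end0"] = out_qend,
    _["cigar"] = out_cigar);
}

// Longest 3' suffix of each read matching a prefix of the adapter with at
// least min_overlap bases and Hamming error rate <= max_error_rate.
// Returns the number of bases to keep (new read length).
// [[Rcpp::export]]
IntegerVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                               int min_overlap, double max_error_rate) {
  const int alen = (int)adapter.size();
  const int n = reads.size();
  IntegerVector keep(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    const int L = (int)s.size();
    int cut = 0; // bases removed
    int omax = std::min(L, alen);
    for (int o = omax; o >= min_overlap; --o) { // longest first
      int mis = 0, allow = (int)std::floor(max_error_rate * o);
      for (int p = 0; p < o && mis <= allow; ++p)
        if (s[L - o + p] != adapter[p]) ++mis;
      if (mis <= allow) { cut = o; break; }
    }
    keep[i] = L - cut;
  }
  return keep;
}
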