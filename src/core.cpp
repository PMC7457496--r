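#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---------- small sequence utilities ----------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

// 2-bit encode the k-mer starting at pos; returns false if any non-ACGT base.
static inline bool encode_kmer(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int t = 0; t < k; ++t) {
    int c = base_code(s[pos + t]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// ---------- SSR scan (MISA-style perfect tandem runs) ----------

// Minimal period check: TRUE when motif is not a whole-number repetition of a
// shorter unit (e.g. "ATAT" has period 2 and is rejected at unit size 4).
static bool minimal_motif(const std::string& s, int pos, int u) {
  for (int d = 1; d < u; ++d) {
    if (u % d != 0) continue;
    bool rep = true;
    for (int t = d; t < u && rep; ++t)
      if (s[pos + t] != s[pos + t - d]) rep = false;
    if (rep) return false;
  }
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_scan_ssrs(std::string s, IntegerVector min_reps) {
  int n = (int)s.size();
  std::vector<int> v_start, v_unit, v_reps;
  std::vector<std::string> v_motif;
  for (int u = 1; u <= 6; ++u) {
    if (u > (int)min_reps.size()) break;
    int need = min_reps[u - 1];
    int i = 0;
    while (i + u < n) {
      // extend run of positions t with s[t] == s[t+u]
      if (s[i] == s[i + u] && base_code(s[i]) >= 0) {
        int j = i;
        while (j + u < n && s[j] == s[j + u] && base_code(s[j]) >= 0) ++j;
        // tandem substring is s[i .. j+u), total length (j - i) + u
        int total = (j - i) + u;
        int reps = total / u;
        if (reps >= need && minimal_motif(s, i, u)) {
          v_start.push_back(i);
          v_unit.push_back(u);
          v_reps.push_back(reps);
          v_motif.push_back(s.substr(i, u));
        }
        i = j + 1;  // next possible distinct run
      } else {
        ++i;
      }
    }
  }
  return DataFrame::create(_["start"] = v_start, _["unit"] = v_unit,
                           _["repeats"] = v_reps, _["motif"] = v_motif,
                           _["stringsAsFactors"] = false);
}

// ---------- maximal repeat pairs by per-diagonal mismatch windows ----------

// All maximal intervals along every diagonal of the s-vs-t comparison with at
// most max_ham mismatches and length >= min_len.  Non-ACGT bases always count
// as mismatches.  min_diag restricts the scanned diagonals (j - i >= min_diag)
// so self-comparisons can skip the trivial main diagonal and its mirror half.
// [[Rcpp::export]]
DataFrame cpp_diag_repeats(std::string s, std::string t, int min_len,
                           int max_ham, int min_diag) {
  int n = (int)s.size(), m = (int)t.size();
  std::vector<int> v_i, v_j, v_len, v_ham;
  std::vector<int> P;  // mismatch offsets along the current diagonal
  for (int d = std::max(min_diag, -(n - 1)); d <= m - 1; ++d) {
    int i0 = std::max(0, -d);
    int L = std::min(n - i0, m - (i0 + d));
    if (L < min_len) continue;
    P.clear();
    for (int t2 = 0; t2 < L; ++t2) {
      char a = s[i0 + t2], b = t[i0 + d + t2];
      if (a != b || base_code(a) < 0) P.push_back(t2);
    }
    int k = (int)P.size();
    if (k <= max_ham) {
      if (L >= min_len) {
        v_i.push_back(i0); v_j.push_back(i0 + d);
        v_len.push_back(L); v_ham.push_back(k);
      }
      continue;
    }
    for (int w = 0; w + max_ham <= k; ++w) {
      int lo = (w == 0) ? 0 : P[w - 1] + 1;
      int hi = (w + max_ham == k) ? L - 1 : P[w + max_ham] - 1;
      int len = hi - lo + 1;
      if (len >= min_len) {
        v_i.push_back(i0 + lo); v_j.push_back(i0 + d + lo);
        v_len.push_back(len); v_ham.push_back(max_ham);
      }
    }
  }
  return DataFrame::create(_["i"] = v_i, _["j"] = v_j, _["len"] = v_len,
                           _["ham"] = v_ham);
}

// ---------- seeded exact-match runs (IR detection work-horse) ----------

// Maximal exact match runs between s and t seeded by shared k-mers.
// Returns 0-based start in s, start in t, and run length (>= min_len).
// [[Rcpp::export]]
DataFrame cpp_exact_runs(std::string s, std::string t, int k, int min_len) {
  int n = (int)s.size(), m = (int)t.size();
  std::vector<int> v_i, v_j, v_len;
  if (n < k || m < k) {
    return DataFrame::create(_["i"] = v_i, _["j"] = v_j, _["len"] = v_len);
  }
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve((size_t)m * 2);
  uint64_t key;
  for (int j = 0; j + k <= m; ++j)
    if (encode_kmer(t, j, k, key)) idx[key].push_back(j);
  // group seed hits per diagonal
  std::unordered_map<int64_t, std::vector<int> > diag;  // d = j - i -> i list
  for (int i = 0; i + k <= n; ++i) {
    if (!encode_kmer(s, i, k, key)) continue;
    auto it = idx.find(key);
    if (it == idx.end()) continue;
    for (int j : it->second) diag[(int64_t)j - i].push_back(i);
  }
  for (auto& kv : diag) {
    int64_t d = kv.first;
    std::vector<int>& hits = kv.second;
    std::sort(hits.begin(), hits.end());
    int covered_to = -1;  // rightmost s-position already inside a reported run
    for (int i : hits) {
      if (i <= covered_to) continue;
      int a = i, b = i + k;  // [a, b) exact by seed
      while (a > 0 && a + d > 0 && s[a - 1] == t[a - 1 + d] &&
             base_code(s[a - 1]) >= 0) --a;
      while (b < n && b + d < m && s[b] == t[b + d] && base_code(s[b]) >= 0) ++b;
      covered_to = b - 1;
      if (b - a >= min_len) {
        v_i.push_back(a); v_j.push_back((int)(a + d)); v_len.push_back(b - a);
      }
    }
  }
  return DataFrame::create(_["i"] = v_i, _["j"] = v_j, _["len"] = v_len);
}

// ---------- k-mer membership profile ----------

// For each k-mer start position of q, is that k-mer present in any reference
// sequence (either strand)?
// [[Rcpp::export]]
LogicalVector cpp_kmer_member(std::string q, CharacterVector refs, int k) {
  std::unordered_set<uint64_t> set;
  uint64_t key;
  for (int r = 0; r < refs.size(); ++r) {
    std::string ref = as<std::string>(refs[r]);
    for (int pass = 0; pass < 2; ++pass) {
      for (int j = 0; j + k <= (int)ref.size(); ++j)
        if (encode_kmer(ref, j, k, key)) set.insert(key);
      ref = revcomp_str(ref);
    }
  }
  int n = (int)q.size();
  int np = std::max(0, n - k + 1);
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    out[i] = encode_kmer(q, i, k, key) && set.count(key) > 0;
  }
  return out;
}

// Strand-specific variant: k-mer of q present in ref's forward strand only.
// [[Rcpp::export]]
LogicalVector cpp_kmer_member_stranded(std::string q, std::string ref, int k) {
  std::unordered_set<uint64_t> set;
  uint64_t key;
  for (int j = 0; j + k <= (int)ref.size(); ++j)
    if (encode_kmer(ref, j, k, key)) set.insert(key);
  int np = std::max(0, (int)q.size() - k + 1);
  LogicalVector out(np);
  for (int i = 0; i < np; ++i)
    out[i] = encode_kmer(q, i, k, key) && set.count(key) > 0;
  return out;
}

// ---------- local (Smith-Waterman) alignment ----------

struct AlnResult {
  int score, read_start, read_end, ref_start, ref_end;
  int matches, mismatches, ins, dels;
  bool ok;
};

// Local alignment of read vs ref window; linear gap cost.  Free clipping of
// both read and reference ends (the reference is a window around a seeded
// diagonal, so clipping its ends is the semi-global contract).
static AlnResult sw_align(const std::string& read, const std::string& ref,
                          int match, int mismatch, int gapcost) {
  int m = (int)read.size(), n = (int)ref.size();
  AlnResult res; res.ok = false; res.score = 0;
  if (m == 0 || n == 0) return res;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);  // 0 stop,1 diag,2 up(ins),3 left(del)
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      bool eq = read[i - 1] == ref[j - 1] && base_code(read[i - 1]) >= 0;
      int sc_d = H[(size_t)(i - 1) * (n + 1) + (j - 1)] + (eq ? match : -mismatch);
      int sc_u = H[(size_t)(i - 1) * (n + 1) + j] - gapcost;      // read base consumed: insertion
      int sc_l = H[(size_t)i * (n + 1) + (j - 1)] - gapcost;      // ref base consumed: deletion
      int v = 0; uint8_t dir = 0;
      if (sc_d > v) { v = sc_d; dir = 1; }
      if (sc_l > v) { v = sc_l; dir = 3; }
      if (sc_u > v) { v = sc_u; dir = 2; }
      H[(size_t)i * (n + 1) + j] = v;
      tb[(size_t)i * (n + 1) + j] = dir;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return res;
  int i = bi, j = bj;
  res.matches = res.mismatches = res.ins = res.dels = 0;
  while (i > 0 && j > 0) {
    uint8_t dir = tb[(size_t)i * (n + 1) + j];
    if (dir == 0) break;
    if (dir == 1) {
      bool eq = read[i - 1] == ref[j - 1] && base_code(read[i - 1]) >= 0;
      if (eq) ++res.matches; else ++res.mismatches;
      --i; --j;
    } else if (dir == 2) { ++res.ins; --i; }
    else { ++res.dels; --j; }
  }
  res.score = best;
  res.read_start = i; res.read_end = bi;   // [start, end) 0-based in read
  res.ref_start = j; res.ref_end = bj;     // [start, end) 0-based in window
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_sw_one(std::string read, std::string ref, int match, int mismatch,
                int gapcost) {
  AlnResult r = sw_align(read, ref, match, mismatch, gapcost);
  return List::create(_["ok"] = r.ok, _["score"] = r.score,
                      _["read_start"] = r.read_start, _["read_end"] = r.read_end,
                      _["ref_start"] = r.ref_start, _["ref_end"] = r.ref_end,
                      _["matches"] = r.matches, _["mismatches"] = r.mismatches,
                      _["insertions"] = r.ins, _["deletions"] = r.dels);
}

// ---------- seeded read mapping ----------

// Map each read against ref (both strands).  Seeds: exact seed_k-mers.  Each
// cluster of nearby candidate diagonals gets one local alignment on a padded
// window.  All co-optimal placements are reported (n_placements column);
// 'primary' marks the leftmost-reference-start, plus-strand-preferred one.
// If ref is shorter than brute_max, unseeded reads fall back to a full-width
// alignment so very short reads still map.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, std::string ref, int seed_k,
                        int match, int mismatch, int gapcost, int brute_max) {
  int n = (int)ref.size();
  std::unordered_map<uint64_t, std::vector<int> > idx;
  uint64_t key;
  for (int j = 0; j + seed_k <= n; ++j)
    if (encode_kmer(ref, j, seed_k, key)) idx[key].push_back(j);

  std::vector<int> o_read, o_start, o_end, o_match, o_mm, o_ins, o_del,
      o_alnread, o_score, o_nplace;
  std::vector<int> o_strand;       // +1 / -1
  std::vector<int> o_primary;      // 0/1

  const int pad = 12;
  struct Plc { int start, end, strand, matches, mm, ins, del, alnread, score; };

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int m = (int)fwd.size();
    std::vector<Plc> best_places;
    int best_score = 0;
    for (int st = 0; st < 2; ++st) {
      std::string rd = (st == 0) ? fwd : revcomp_str(fwd);
      // candidate diagonals
      std::vector<int> diags;
      if (m >= seed_k) {
        for (int p = 0; p + seed_k <= m; ++p) {
          if (!encode_kmer(rd, p, seed_k, key)) continue;
          auto it = idx.find(key);
          if (it == idx.end()) continue;
          for (int j : it->second) diags.push_back(j - p);
        }
      }
      std::sort(diags.begin(), diags.end());
      diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
      std::vector<std::pair<int, int> > windows;  // ref [a, b)
      if (diags.empty()) {
        if (n <= brute_max) windows.push_back(std::make_pair(0, n));
      } else {
        int lo = diags[0], hi = diags[0];
        for (size_t q = 1; q <= diags.size(); ++q) {
          if (q < diags.size() && diags[q] - hi <= pad) { hi = diags[q]; continue; }
          int a = std::max(0, lo - pad);
          int b = std::min(n, hi + m + pad);
          windows.push_back(std::make_pair(a, b));
          if (q < diags.size()) { lo = hi = diags[q]; }
        }
      }
      for (auto& w : windows) {
        AlnResult r = sw_align(rd, ref.substr(w.first, w.second - w.first),
                               match, mismatch, gapcost);
        if (!r.ok) continue;
        Plc p;
        p.start = w.first + r.ref_start; p.end = w.first + r.ref_end;
        p.strand = (st == 0) ? 1 : -1;
        p.matches = r.matches; p.mm = r.mismatches;
        p.ins = r.ins; p.del = r.dels;
        p.alnread = r.matches + r.mismatches + r.ins;
        p.score = r.score;
        if (r.score > best_score) {
          best_score = r.score;
          best_places.clear();
          best_places.push_back(p);
        } else if (r.score == best_score && best_score > 0) {
          bool dup = false;
          for (auto& bp : best_places)
            if (bp.start == p.start && bp.strand == p.strand) dup = true;
          if (!dup) best_places.push_back(p);
        }
      }
    }
    if (best_places.empty()) continue;
    // primary: leftmost ref start, then + strand
    int prim = 0;
    for (size_t q = 1; q < best_places.size(); ++q) {
      const Plc& a = best_places[q], & b = best_places[prim];
      if (a.start < b.start || (a.start == b.start && a.strand > b.strand))
        prim = (int)q;
    }
    for (size_t q = 0; q < best_places.size(); ++q) {
      const Plc& p = best_places[q];
      o_read.push_back(ri + 1);
      o_start.push_back(p.start); o_end.push_back(p.end);
      o_strand.push_back(p.strand);
      o_match.push_back(p.matches); o_mm.push_back(p.mm);
      o_ins.push_back(p.ins); o_del.push_back(p.del);
      o_alnread.push_back(p.alnread); o_score.push_back(p.score);
      o_nplace.push_back((int)best_places.size());
      o_primary.push_back((int)q == prim ? 1 : 0);
    }
  }
  return DataFrame::create(
      _["read"] = o_read, _["start"] = o_start, _["end"] = o_end,
      _["strand"] = o_strand, _["matches"] = o_match,
      _["mismatches"] = o_mm, _["insertions"] = o_ins, _["deletions"] = o_del,
      _["aligned_read_bases"] = o_alnread, _["score"] = o_score,
      _["n_placements"] = o_nplace, _["primary"] = o_primary);
}
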