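#include <Rcpp.h>
#include <vector>
#include <set>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Maximal repeat-pair scanner. A pair (p1, p2, len) relates seq[p1, p1+len)
// to seq[p2, p2+len) (direct orientation) or to its reverse complement
// (palindromic). Copies may not overlap (p1 + len <= p2) and a pair is
// maximal when no one-base extension on either side keeps the Hamming
// distance <= max_mismatch while staying within bounds and non-overlapping.
//
// Candidate diagonals come from shared exact k-mers with
// k = floor((min_len - max_mismatch) / (max_mismatch + 1)); by pigeonhole any
// reportable pair contains such a seed, so the diagonal set is complete. Each
// candidate diagonal is then scanned once for maximal mismatch-bounded
// windows. Ns never match anything.

static inline int enc(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return 4; }
}

struct Hit { int p1, p2, len, mm, kind; }; // kind 0 direct 1 interspersed 2 palindromic

// enumerate maximal windows with <= mm mismatches from the 0/1 mismatch vector
static void maximal_windows(const std::vector<uint8_t>& mis, int mm,
                            std::vector<std::pair<int,int> >& out) {
  const int len = (int)mis.size();
  if (len == 0) return;
  std::vector<int> q; q.push_back(-1);
  for (int i = 0; i < len; ++i) if (mis[i]) q.push_back(i);
  q.push_back(len);
  const int r = (int)q.size() - 2; // number of mismatches
  if (r <= mm) { out.push_back(std::make_pair(0, len - 1)); return; }
  for (int j = 0; j + mm + 1 <= r + 1; ++j) {
    int s = q[j] + 1, e = q[j + mm + 1] - 1;
    if (s <= e) out.push_back(std::make_pair(s, e));
  }
}

static void scan_direct_diag(const std::vector<int>& s, int d, int min_len,
                             int mm, int max_span, std::vector<Hit>& hits) {
  const int n = (int)s.size();
  const int len = n - d;
  if (len < min_len || d < min_len) return;
  std::vector<uint8_t> mis(len);
  std::vector<int> pre(len + 1, 0);
  for (int i = 0; i < len; ++i) {
    mis[i] = !(s[i] < 4 && s[i + d] < 4 && s[i] == s[i + d]);
    pre[i + 1] = pre[i] + mis[i];
  }
  std::vector<std::pair<int,int> > wins;
  maximal_windows(mis, mm, wins);
  for (size_t w = 0; w < wins.size(); ++w) {
    int a = wins[w].first, e = wins[w].second;
    int wl = e - a + 1;
    if (wl < min_len) continue;
    if (wl <= d) {
      int span = d - wl;
      if (span > max_span) continue;
      Hit h; h.p1 = a; h.p2 = a + d; h.len = wl;
      h.mm = pre[e + 1] - pre[a]; h.kind = span == 0 ? 0 : 1;
      hits.push_back(h);
    } else {
      // tandem run longer than the period: every length-d sub-window is a
      // maximal non-overlapping pair (extension would overlap the copies)
      for (int t = a; t + d - 1 <= e; ++t) {
        Hit h; h.p1 = t; h.p2 = t + d; h.len = d;
        h.mm = pre[t + d] - pre[t]; h.kind = 0;
        hits.push_back(h);
      }
    }
  }
}

static void scan_pal_diag(const std::vector<int>& s, int c, int min_len,
                          int mm, int max_span, std::vector<Hit>& hits) {
  const int n = (int)s.size();
  int a_lo = std::max(0, c - (n - 1));
  int a_hi = (c - 1) / 2;
  if (a_hi - a_lo + 1 < min_len) return;
  const int len = a_hi - a_lo + 1;
  std::vector<uint8_t> mis(len);
  std::vector<int> pre(len + 1, 0);
  for (int i = 0; i < len; ++i) {
    int a = a_lo + i, b = c - a;
    mis[i] = !(s[a] < 4 && s[b] < 4 && s[a] == 3 - s[b]);
    pre[i + 1] = pre[i] + mis[i];
  }
  std::vector<std::pair<int,int> > wins;
  maximal_windows(mis, mm, wins);
  for (size_t w = 0; w < wins.size(); ++w) {
    int a = wins[w].first, e = wins[w].second;
    int wl = e - a + 1;
    if (wl < min_len) continue;
    int p1 = a_lo + a, p2 = c - (a_lo + e);
    int span = p2 - (p1 + wl);
    if (span < 0 || span > max_span) continue;
    Hit h; h.p1 = p1; h.p2 = p2; h.len = wl;
    h.mm = pre[e + 1] - pre[a]; h.kind = 2;
    hits.push_back(h);
  }
}

// [[Rcpp::export]]
DataFrame repeat_pairs_cpp(std::string seq, int min_len, int max_mismatch,
                           int max_span, bool do_direct, bool do_palindromic,
                           bool use_seeds) {
  const int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  std::vector<Hit> hits;

  std::set<int> diag, adiag;
  if (use_seeds && n > 0) {
    int k = (min_len - max_mismatch) / (max_mismatch + 1);
    if (k < 4) k = 4;
    if (k > 31) k = 31;
    std::unordered_map<uint64_t, std::vector<int> > fwd;
    uint64_t code = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (int i = 0; i < n; ++i) {
      if (s[i] >= 4) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)s[i]) & mask;
      if (++run >= k) fwd[code].push_back(i - k + 1);
    }
    if (do_direct) {
      for (std::unordered_map<uint64_t, std::vector<int> >::iterator it = fwd.begin();
           it != fwd.end(); ++it) {
        const std::vector<int>& v = it->second;
        for (size_t i = 0; i < v.size(); ++i)
          for (size_t j = i + 1; j < v.size(); ++j) {
            int d = v[j] - v[i];
            if (d >= min_len) diag.insert(d);
          }
      }
    }
    if (do_palindromic) {
      // reverse-complement k-mer of window starting at b
      code = 0; run = 0;
      uint64_t rc = 0;
      for (int b = 0; b < n; ++b) {
        if (s[b] >= 4) { run = 0; code = 0; rc = 0; continue; }
        code = ((code << 2) | (uint64_t)s[b]) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - s[b]) << (2 * (k - 1)));
        if (++run >= k) {
          int bstart = b - k + 1;
          std::unordered_map<uint64_t, std::vector<int> >::iterator it = fwd.find(rc);
          if (it != fwd.end()) {
            const std::vector<int>& v = it->second;
            for (size_t i = 0; i < v.size(); ++i)
              adiag.insert(v[i] + bstart + k - 1);
          }
        }
      }
    }
  } else {
    if (do_direct) for (int d = min_len; d <= n - min_len; ++d) diag.insert(d);
    if (do_palindromic)
      for (int c = 2 * min_len - 1; c <= 2 * n - 3; ++c) adiag.insert(c);
  }

  if (do_direct)
    for (std::set<int>::iterator it = diag.begin(); it != diag.end(); ++it)
      scan_direct_diag(s, *it, min_len, max_mismatch, max_span, hits);
  if (do_palindromic)
    for (std::set<int>::iterator it = adiag.begin(); it != adiag.end(); ++it)
      scan_pal_diag(s, *it, min_len, max_mismatch, max_span, hits);

  const int m = (int)hits.size();
  IntegerVector p1(m), p2(m), len(m), mm(m), kind(m);
  for (int i = 0; i < m; ++i) {
    p1[i] = hits[i].p1; p2[i] = hits[i].p2; len[i] = hits[i].len;
    mm[i] = hits[i].mm; kind[i] = hits[i].kind;
  }
  return DataFrame::create(_["pos1"] = p1, _["pos2"] = p2, _["length"] = len,
                           _["mismatches"] = mm, _["kind_code"] = kind);
}
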