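#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

// 2-bit encoding; anything that is not an uppercase ACGT (in particular 'N')
// is "invalid": it never matches any letter, including itself.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline bool bases_match(char a, char b) {
  return a == b && base_code(a) >= 0;
}

// ---------------------------------------------------------------------------
// Myers' bit-vector edit distance (unit-cost Levenshtein), blocked variant
// for patterns longer than one machine word. The pattern is laid out along
// the bit-vectors; the text is streamed column by column. Horizontal deltas
// are carried between 64-bit blocks; the score is tracked at the pattern's
// last row (bit m-1 of the top block). Bits above row m-1 in the top block
// hold garbage but carries in the block recurrence only propagate upward,
// so they never contaminate valid rows.
// ---------------------------------------------------------------------------

static int myers_distance(const char *a, size_t m, const char *b, size_t n) {
  if (m == 0) return (int)n;
  if (n == 0) return (int)m;
  if (m > n) { std::swap(a, b); std::swap(m, n); }

  const int W = 64;
  const size_t B = (m + W - 1) / W;
  const uint64_t ONE = 1ULL;

  std::vector<uint64_t> Peq(4 * B, 0ULL);
  for (size_t i = 0; i < m; ++i) {
    int c = base_code(a[i]);
    if (c >= 0) Peq[(size_t)c * B + i / W] |= ONE << (i % W);
  }

  std::vector<uint64_t> VP(B, ~0ULL), VN(B, 0ULL);
  int score = (int)m;
  const uint64_t top_bit = ONE << ((m - 1) % W);
  const uint64_t high_bit = ONE << (W - 1);

  for (size_t j = 0; j < n; ++j) {
    int c = base_code(b[j]);
    int hin = 1;  // boundary row: D[0][j] = j
    for (size_t bl = 0; bl < B; ++bl) {
      uint64_t Eq = (c >= 0) ? Peq[(size_t)c * B + bl] : 0ULL;
      uint64_t Pv = VP[bl], Mv = VN[bl];
      uint64_t Xv = Eq | Mv;
      if (hin < 0) Eq |= ONE;
      uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
      uint64_t Ph = Mv | ~(Xh | Pv);
      uint64_t Mh = Pv & Xh;
      uint64_t probe = (bl == B - 1) ? top_bit : high_bit;
      int hout = 0;
      if (Ph & probe) hout = 1;
      else if (Mh & probe) hout = -1;
      Ph <<= 1;
      Mh <<= 1;
      if (hin < 0) Mh |= ONE;
      else if (hin > 0) Ph |= ONE;
      VP[bl] = Mh | ~(Xv | Ph);
      VN[bl] = Ph & Xv;
      hin = hout;
    }
    score += hin;  // delta at row m (from the top block's probe bit)
  }
  return score;
}

// [[Rcpp::export]]
int cpp_edit_distance(const std::string &a, const std::string &b) {
  return myers_distance(a.data(), a.size(), b.data(), b.size());
}

// ---------------------------------------------------------------------------
// Maximal exact match enumeration between x and y via a k-mer hash of x.
// A MEM of length >= l_min contains, at its left end, a k-mer match
// (k = min(l_min, 31)) whose immediate left neighbours differ (or hit a
// boundary or an invalid base). Enumerating left-maximal k-mer matches and
// extending each to the right therefore yields every MEM exactly once.
// Candidate matches are always verified by direct base comparison during
// extension; the hash only proposes seed positions.
// Only k-mer start positions of x in [ref_from, ref_to) are indexed, so a
// block decomposition of the reference partitions the MEM set exactly.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_find_mems(const std::string &x, const std::string &y,
                            int l_min, int ref_from, int ref_to) {
  const size_t n = x.size(), ny = y.size();
  std::vector<int> out_i, out_j, out_l;

  const int k = std::min(l_min, 31);
  if (l_min >= 1 && n >= (size_t)k && ny >= (size_t)k) {
    if (ref_to < 0 || (size_t)ref_to > n) ref_to = (int)n;
    if (ref_from < 0) ref_from = 0;

    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

    // hash of x k-mers -> chained position lists
    std::unordered_map<uint64_t, int> head;
    head.reserve(n * 2 + 16);
    std::vector<int> nxt((size_t)std::max(0, ref_to - ref_from), -1);

    uint64_t code = 0;
    int run = 0;
    for (int i = 0; i < ref_to + k - 1 && (size_t)i < n; ++i) {
      int c = base_code(x[(size_t)i]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        int start = i - k + 1;
        if (start >= ref_from && start < ref_to) {
          auto it = head.find(code);
          int prev = (it == head.end()) ? -1 : it->second;
          nxt[(size_t)(start - ref_from)] = prev;
          head[code] = start;
        }
      }
    }

    // stream y k-mers, look up, check left-maximality, extend right
    code = 0; run = 0;
    for (size_t jj = 0; jj < ny; ++jj) {
      int c = base_code(y[jj]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      int j = (int)jj - k + 1;
      auto it = head.find(code);
      if (it == head.end()) continue;
      for (int i = it->second; i >= 0; i = nxt[(size_t)(i - ref_from)]) {
        // verify seed (hash collisions impossible with 2-bit codes, but the
        // contract is exactness: compare directly)
        bool okseed = true;
        for (int p = 0; p < k; ++p)
          if (x[(size_t)(i + p)] != y[(size_t)(j + p)]) { okseed = false; break; }
        if (!okseed) continue;
        if (i > 0 && j > 0 && bases_match(x[(size_t)(i - 1)], y[(size_t)(j - 1)]))
          continue;  // not left-maximal
        int len = k;
        while ((size_t)(i + len) < n && (size_t)(j + len) < ny &&
               bases_match(x[(size_t)(i + len)], y[(size_t)(j + len)]))
          ++len;
        if (len >= l_min) { out_i.push_back(i); out_j.push_back(j); out_l.push_back(len); }
      }
    }
  }

  IntegerMatrix res((int)out_i.size(), 3);
  for (size_t r = 0; r < out_i.size(); ++r) {
    res((int)r, 0) = out_i[r];
    res((int)r, 1) = out_j[r];
    res((int)r, 2) = out_l[r];
  }
  return res;
}

// ---------------------------------------------------------------------------
// Greedy co-linear chaining. Anchors must arrive sorted by (ref_start,
// query_start). Each anchor is consumed at most once. From the current chain
// end, eligible successors are the unused anchors within merge_max_gap in
// both sequences; they are tried in increasing (ref gap + query gap) order
// (ties: smaller query_start) and the first one that keeps both spans <= u
// and the chain identity >= t is appended. Chain identity is
// 1 - gap_edit / max(ref_span, query_span), with gap_edit the summed edit
// distance of the paired gap substrings.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_merge_anchors(const std::string &x, const std::string &y,
                       IntegerVector rs, IntegerVector qs, IntegerVector alen,
                       double t, int u, int max_gap, int min_cov) {
  const int n = rs.size();
  std::vector<char> used((size_t)n, 0);
  IntegerVector chain_id(n, -1);
  std::vector<int> chain_gap, cand;
  const double eps = 1e-9;

  for (int s = 0; s < n; ++s) {
    if (used[(size_t)s]) continue;
    used[(size_t)s] = 1;
    std::vector<int> members{s};
    int cs_r = rs[s], ce_r = rs[s] + alen[s];
    int cs_q = qs[s], ce_q = qs[s] + alen[s];
    long gap_edit = 0, cov = alen[s];

    for (;;) {
      // anchors with ref_start in [ce_r, ce_r + max_gap]
      int lo = (int)(std::lower_bound(rs.begin(), rs.end(), ce_r) - rs.begin());
      cand.clear();
      for (int j = lo; j < n && rs[j] <= ce_r + max_gap; ++j) {
        if (used[(size_t)j]) continue;
        if (qs[j] < ce_q || qs[j] - ce_q > max_gap) continue;
        cand.push_back(j);
      }
      if (cand.empty()) break;
      std::sort(cand.begin(), cand.end(), [&](int a, int b) {
        int ga = (rs[a] - ce_r) + (qs[a] - ce_q);
        int gb = (rs[b] - ce_r) + (qs[b] - ce_q);
        if (ga != gb) return ga < gb;
        return qs[a] < qs[b];
      });
      int best = -1;
      long best_gap = 0;
      for (int idx : cand) {
        int gx = rs[idx] - ce_r, gy = qs[idx] - ce_q;
        int new_re = rs[idx] + alen[idx], new_qe = qs[idx] + alen[idx];
        long span = std::max((long)(new_re - cs_r), (long)(new_qe - cs_q));
        if (new_re - cs_r > u || new_qe - cs_q > u) continue;
        // cheap lower bound before paying for the edit distance
        long lb = gap_edit + std::abs(gx - gy);
        if ((double)lb > (1.0 - t) * (double)span + eps) continue;
        long ge = gap_edit +
          myers_distance(x.data() + ce_r, (size_t)gx, y.data() + ce_q, (size_t)gy);
        if ((double)ge > (1.0 - t) * (double)span + eps) continue;
        best = idx; best_gap = ge;
        break;
      }
      if (best < 0) break;
      used[(size_t)best] = 1;
      members.push_back(best);
      gap_edit = best_gap;
      ce_r = rs[best] + alen[best];
      ce_q = qs[best] + alen[best];
      cov += alen[best];
    }

    if (cov >= min_cov && ce_r - cs_r <= u && ce_q - cs_q <= u) {
      int id = (int)chain_gap.size();
      for (int mj : members) chain_id[mj] = id;
      chain_gap.push_back((int)gap_edit);
    }
  }

  return List::create(_["chain_id"] = chain_id,
                      _["gap_edit"] = IntegerVector(chain_gap.begin(), chain_gap.end()));
}
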