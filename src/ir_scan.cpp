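#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Inverted-repeat scanner.
//
// Sequence is encoded A=0, C=1, G=2, T=3, N=4. An arm pair is an ungapped
// alignment of a left arm [a, b] against the reverse complement of a right
// arm, i.e. position p pairs with position q = c - p for a fixed diagonal
// constant c. A window [a, b] on diagonal c is accepted iff
//   - ends are complementary matches, no N anywhere in the window,
//   - arm length b - a + 1 >= min_arm_len,
//   - matches >= ceil(min_arm_identity * len - 1e-9),
//   - it contains an exact match run of >= seed_len,
//   - element span c + 1 - 2a lies in [min_element_len, max_element_len],
//   - arms do not overlap (b <= (c - 1) / 2).
// Accepted windows on one diagonal are grouped by transitive overlap and
// each group reports its best window by score (matches - penalty *
// mismatches, BLAST-like +1/-mismatch_penalty weighting), then longest
// arm, then smallest element span. Scoring rather than length keeps a
// clean TIR arm from creeping into flanking sequence on the identity
// budget it has banked, which would shift the element junctions and break
// the TSD search. The exact-seed requirement makes seeded enumeration
// complete: every accepted window contains a seed hit.

static inline int comp4(int x) { return 3 - x; }

struct Champ {
  int a, b, len, matches, score, bmax;
};

// [[Rcpp::export(name = ".ir_scan_cpp")]]
DataFrame ir_scan_cpp(IntegerVector seq,
                      int min_element_len, int max_element_len,
                      int min_arm_len, double min_arm_identity,
                      int seed_len, int mismatch_penalty) {
  const int n = seq.size();
  const int K = seed_len;
  std::vector<int> out_ls, out_le, out_rs, out_re, out_len;
  std::vector<double> out_id;

  if (n >= min_element_len && n >= 2 * K) {
    const int* s = INTEGER(seq);

    // --- seed pairs: s[i..i+K) equals revcomp(s[j..j+K)) ---------------
    const uint32_t space = 1u << (2 * K);  // K <= 10 enforced in R
    const uint32_t maskK = space - 1u;
    std::vector<int32_t> fcode(n - K + 1, -1), rcode(n - K + 1, -1);
    {
      uint32_t f = 0, r = 0;
      int valid = 0;  // length of current N-free stretch
      for (int p = 0; p < n; ++p) {
        if (s[p] > 3) { valid = 0; f = 0; r = 0; continue; }
        f = ((f << 2) | (uint32_t)s[p]) & maskK;
        r = (r >> 2) | ((uint32_t)comp4(s[p]) << (2 * (K - 1)));
        ++valid;
        if (valid >= K) { fcode[p - K + 1] = (int32_t)f; rcode[p - K + 1] = (int32_t)r; }
      }
    }
    // bucket forward positions by code (counting sort)
    std::vector<int32_t> cnt(space + 1, 0);
    for (int p = 0; p + K <= n; ++p)
      if (fcode[p] >= 0) ++cnt[(uint32_t)fcode[p] + 1];
    for (uint32_t v = 0; v < space; ++v) cnt[v + 1] += cnt[v];
    std::vector<int32_t> bucket(cnt[space]);
    {
      std::vector<int32_t> fill(cnt.begin(), cnt.end() - 1);
      for (int p = 0; p + K <= n; ++p)
        if (fcode[p] >= 0) bucket[fill[(uint32_t)fcode[p]]++] = p;
    }

    std::vector<int> diags;
    for (int j = 0; j + K <= n; ++j) {
      if (rcode[j] < 0) continue;
      uint32_t code = (uint32_t)rcode[j];
      int lo = cnt[code], hi = cnt[code + 1];
      // i in [j - (max_element_len - K), j - K]
      int imin = j - (max_element_len - K), imax = j - K;
      if (imax < 0) continue;
      int it = (int)(std::lower_bound(bucket.begin() + lo, bucket.begin() + hi,
                                      imin) - bucket.begin());
      for (; it < hi && bucket[it] <= imax; ++it)
        diags.push_back(bucket[it] + j + K - 1);
    }
    std::sort(diags.begin(), diags.end());
    diags.erase(std::unique(diags.begin(), diags.end()), diags.end());

    // --- per-diagonal window enumeration -------------------------------
    std::vector<int> state, run, mis, forb, nextSeed;
    std::vector<Champ> champs;
    for (size_t di = 0; di < diags.size(); ++di) {
      const int c = diags[di];
      const int p_hi = (c - 1) / 2;
      int p_lo = c - n + 1; if (p_lo < 0) p_lo = 0;
      // element span = c + 1 - 2a must be <= max_element_len
      int a_lo = (c + 1 - max_element_len + 1) / 2;  // ceil for positives
      if (a_lo > p_lo) p_lo = a_lo;
      const int a_hi = (c + 1 - min_element_len) / 2;  // floor
      const int k = p_hi - p_lo + 1;
      if (k < min_arm_len || a_hi < p_lo) continue;

      state.assign(k, 0); run.assign(k, 0);
      mis.assign(k, 0); forb.assign(k, 0); nextSeed.assign(k + 1, k);
      bool any_seed = false;
      for (int t = 0; t < k; ++t) {
        const int p = p_lo + t, q = c - p;
        const int xp = s[p], xq = s[q];
        int st;
        if (xp > 3 || xq > 3) st = 2;
        else st = (xp == comp4(xq)) ? 1 : 0;
        state[t] = st;
        run[t] = (st == 1) ? ((t > 0 ? run[t - 1] : 0) + 1) : 0;
        mis[t] = (t > 0 ? mis[t - 1] : 0) + (st == 0 ? 1 : 0);
        forb[t] = (t > 0 ? forb[t - 1] : 0) + (st == 2 ? 1 : 0);
        if (run[t] >= K) any_seed = true;
      }
      if (!any_seed) continue;
      for (int t = k - 1; t >= 0; --t)
        nextSeed[t] = (run[t] >= K) ? t : nextSeed[t + 1];

      // per-a champion window (best score) and extent (largest valid b)
      champs.clear();
      const int ta_hi = std::min(a_hi - p_lo, k - 1);
      for (int ta = 0; ta <= ta_hi; ++ta) {
        if (state[ta] != 1) continue;
        if (ta + K - 1 >= k) break;
        const int ps = nextSeed[ta + K - 1];
        if (ps >= k) continue;
        const int tb_min = std::max(ta + min_arm_len - 1, ps);
        const int mis0 = (ta > 0 ? mis[ta - 1] : 0);
        const int forb0 = (ta > 0 ? forb[ta - 1] : 0);
        Champ best;
        best.a = -1;
        for (int tb = tb_min; tb < k; ++tb) {
          if (forb[tb] - forb0 > 0) break;  // forbidden from here on
          if (state[tb] != 1) continue;
          const int len = tb - ta + 1;
          const int matches = len - (mis[tb] - mis0);
          const int req = (int)std::ceil(min_arm_identity * len - 1e-9);
          if (matches < req) continue;
          const int score = matches - mismatch_penalty * (len - matches);
          if (best.a < 0 || score > best.score ||
              (score == best.score && len > best.len)) {
            best.a = ta; best.b = tb; best.len = len;
            best.matches = matches; best.score = score;
          }
          best.bmax = tb;
        }
        if (best.a >= 0) champs.push_back(best);
      }
      if (champs.empty()) continue;

      // group by transitive overlap of window extents [a, bmax]
      size_t g0 = 0;
      while (g0 < champs.size()) {
        size_t g1 = g0;
        int gmax_b = champs[g0].bmax;
        while (g1 + 1 < champs.size() && champs[g1 + 1].a <= gmax_b) {
          ++g1;
          gmax_b = std::max(gmax_b, champs[g1].bmax);
        }
        // best by (score, longest arm, then largest a = smallest span)
        size_t bi = g0;
        for (size_t t = g0 + 1; t <= g1; ++t) {
          const Champ &x = champs[t], &y = champs[bi];
          if (x.score > y.score ||
              (x.score == y.score &&
               (x.len > y.len || (x.len == y.len && x.a > y.a))))
            bi = t;
        }
        const int a = p_lo + champs[bi].a, b = p_lo + champs[bi].b;
        out_ls.push_back(a);
        out_le.push_back(b + 1);
        out_rs.push_back(c - b);
        out_re.push_back(c - a + 1);
        out_len.push_back(champs[bi].len);
        out_id.push_back((double)champs[bi].matches / champs[bi].len);
        g0 = g1 + 1;
      }
    }
  }

  return DataFrame::create(
    _["left_start"] = wrap(out_ls), _["left_end"] = wrap(out_le),
    _["right_start"] = wrap(out_rs), _["right_end"] = wrap(out_re),
    _["arm_len"] = wrap(out_len), _["arm_identity"] = wrap(out_id));
}

// Hamming comparison of two equal-length encoded windows, treating N as a
// mismatch. Used by the copy-counting verifier.
// [[Rcpp::export(name = ".hamming_matches_cpp")]]
int hamming_matches_cpp(IntegerVector a, IntegerVector b) {
  const int n = a.size();
  const int* x = INTEGER(a);
  const int* y = INTEGER(b);
  int m = 0;
  for (int i = 0; i < n; ++i)
    if (x[i] == y[i] && x[i] <= 3) ++m;
  return m;
}

// Range lookup of query codes in a sorted code vector: for query i the
// matching index positions are (lo[i], hi[i]] (1-based R convention).
// Avoids findInterval's per-call sortedness revalidation on big indexes.
// [[Rcpp::export(name = ".lookup_range_cpp")]]
List lookup_range_cpp(NumericVector sorted, NumericVector q) {
  const int nq = q.size();
  IntegerVector lo(nq), hi(nq);
  const double* b = REAL(sorted);
  const double* e = b + sorted.size();
  for (int i = 0; i < nq; ++i) {
    lo[i] = (int)(std::lower_bound(b, e, q[i]) - b);
    hi[i] = (int)(std::upper_bound(b, e, q[i]) - b);
  }
  return List::create(_["lo"] = lo, _["hi"] = hi);
}
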