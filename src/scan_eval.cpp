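#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Evaluate candidate subTIR pairs against the 3'-palindrome and terminal
// TT windows (the hot path of scan_genome, see eval_strand for the
// commented logic).  All coordinates 0-based; pal_* sorted by pal_end.
// [[Rcpp::export]]
DataFrame eval_pairs_cpp(std::string subject,
                         IntegerVector c_start, IntegerVector c_end,
                         IntegerVector c_mm,
                         IntegerVector p_i, IntegerVector p_j,
                         NumericVector p_id,
                         IntegerVector pal_start, IntegerVector pal_end,
                         IntegerVector pal_q,
                         IntegerVector tts,
                         int off5_lo, int off5_hi, int off3_lo, int off3_hi,
                         int poff_lo, int poff_hi, int slack,
                         bool require_pal,
                         int min_len, int max_len,
                         int arm_cap, int pal_cap) {
  const char* s = subject.c_str();
  const int n = (int) subject.size();
  const int npal = pal_end.size();
  const int ntt = tts.size();
  const double off5_mid = 0.5 * (off5_lo + off5_hi);
  const double off3_mid = 0.5 * (off3_lo + off3_hi);

  std::vector<int> o_start, o_end, o_s5, o_e5, o_sub;
  std::vector<double> o_score, o_id;

  // first tt position >= lo and <= hi, else -1
  auto find_tt = [&](int lo, int hi) -> int {
    hi = std::min(hi, n - 2);
    if (ntt == 0) return -1;
    int k = (int) (std::lower_bound(tts.begin(), tts.end(), lo) - tts.begin());
    if (k >= ntt || tts[k] > hi) return -1;
    return tts[k];
  };
  auto t_run_before = [&](int pos) {
    int run = 0;
    while (pos - run - 1 >= 0 && s[pos - run - 1] == 'T') ++run;
    return run;
  };
  auto t_run_at = [&](int pos) {
    int run = 0;
    while (pos + run < n && s[pos + run] == 'T') ++run;
    return run;
  };

  const int np = p_i.size();
  for (int k = 0; k < np; ++k) {
    int i = p_i[k] - 1, j = p_j[k] - 1;
    int s5 = c_start[i], e5 = c_end[i];
    int s3 = c_start[j], e3 = c_end[j];
    int lo = std::max(e3 + std::max(0, off3_lo - poff_hi) - slack, e3 + 2);
    int hi = e3 + off3_hi - poff_lo + slack;
    // palindrome candidates with pal_end in [lo, hi] and pal_start >= e3;
    // keep the smallest consistent element end (best stem achieving it)
    int plo = (int) (std::lower_bound(pal_end.begin(), pal_end.end(), lo) -
                     pal_end.begin());
    bool has_pal = false; int pal_best_q = 0; int e = -1;
    for (int p = plo; p < npal && pal_end[p] <= hi; ++p) {
      if (pal_start[p] < e3) continue;
      int pe = pal_end[p];
      int cand = find_tt(std::max(e3 + off3_lo - slack, pe + poff_lo - slack),
                         std::min(e3 + off3_hi + slack, pe + poff_hi + slack));
      if (cand < 0) continue;
      if (!has_pal || cand < e || (cand == e && pal_q[p] > pal_best_q)) {
        has_pal = true; pal_best_q = pal_q[p]; e = cand;
      }
    }
    if (!has_pal) {
      if (require_pal) continue;
      e = find_tt(e3 + off3_lo - slack, e3 + off3_hi + slack);
      if (e < 0) continue;
    }
    // element start: rightmost position preceded by TT in the 5' window
    int b_lo = s5 - off5_hi - slack;
    int b_hi = s5 - std::max(off5_lo - slack, 0);
    int t_hi = (int) (std::upper_bound(tts.begin(), tts.end(), b_hi - 2) -
                      tts.begin()) - 1;
    if (t_hi < 0 || tts[t_hi] < b_lo - 2) continue;
    int b = tts[t_hi] + 2;
    if (b < 0 || e <= b) continue;
    int len = e - b;
    if (len < min_len || len > max_len) continue;
    int lrun = t_run_before(b), rrun = t_run_at(e);
    int si = b - std::max(0, lrun - 1);
    int ei = e + std::max(0, rrun - 1);
    double cent = 0.25 * std::abs((s5 - b) - off5_mid) +
      0.10 * std::abs((e - e3) - off3_mid);
    double iso = 0.0;
    if (si >= 2 && s[si - 2] != 'T') iso += 0.5;
    if (ei + 1 < n && s[ei + 1] != 'T') iso += 0.5;
    // a genuine insertion carries at least two element Ts plus the
    // host's T at each terminus; chance boundaries rarely reach 3+3
    double run_bonus = (lrun >= 3 && rrun >= 3) ? 0.75 : 0.0;
    // stem length earns nothing (long chance palindromes are common in
    // AT-rich sequence); mismatches and cross-end identity carry the
    // signal, the stem-loop quality enters at half weight
    double score = 12.0 * p_id[k] - c_mm[i] - c_mm[j] +
      0.5 * std::min(pal_best_q, pal_cap) + 4.0 + iso +
      run_bonus - cent - 1e-6 * len;
    (void) arm_cap;
    o_start.push_back(si); o_end.push_back(ei); o_score.push_back(score);
    o_s5.push_back(s5); o_e5.push_back(e5); o_sub.push_back(i + 1);
    o_id.push_back(p_id[k]);
  }
  return DataFrame::create(_["start"] = wrap(o_start), _["end"] = wrap(o_end),
                           _["score"] = wrap(o_score),
                           _["subtir5_start"] = wrap(o_s5),
                           _["subtir5_end"] = wrap(o_e5),
                           _["sub_idx"] = wrap(o_sub),
                           _["pair_identity"] = wrap(o_id));
}

// Greedy non-overlapping selection within one sequence: rows must be
// supplied in acceptance (score-descending) order; returns keep flags.
// [[Rcpp::export]]
LogicalVector greedy_select_cpp(IntegerVector start, IntegerVector end) {
  int n = start.size();
  LogicalVector keep(n);
  std::vector<std::pair<int, int>> kept;   // sorted by start
  for (int r = 0; r < n; ++r) {
    // find first kept interval with kept.start < end[r] and kept.end > start[r]
    bool clash = false;
    auto it = std::lower_bound(kept.begin(), kept.end(),
                               std::make_pair(start[r], -1));
    if (it != kept.begin()) {
      auto prev = std::prev(it);
      if (prev->second > start[r]) clash = true;
    }
    if (!clash && it != kept.end() && it->first < end[r]) clash = true;
    if (!clash) {
      keep[r] = true;
      kept.insert(std::lower_bound(kept.begin(), kept.end(),
                                   std::make_pair(start[r], end[r])),
                  std::make_pair(start[r], end[r]));
    }
  }
  return keep;
}
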