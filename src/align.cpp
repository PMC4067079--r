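#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Waterman-Eggert style enumeration of non-overlapping local alignments.
// Affine gaps: a gap of length k costs gap_open + k * gap_extend.
// After a hit is accepted its subject interval is masked and the DP is
// recomputed, so reported hits never share subject positions.  Ties on
// the optimal cell are broken toward the smallest query end, then the
// smallest subject end (row-major scan keeps the first maximum).
// Traceback preference: diagonal, then gap-in-subject, then gap-in-query.
// Used as the exhaustive oracle for the seed-and-extend empty-site search.
// [[Rcpp::export]]
DataFrame waterman_eggert_cpp(std::string query, std::string subject,
                              double match, double mismatch,
                              double gap_open, double gap_extend,
                              double min_score, int max_hits) {
  const int n = (int) query.size(), m = (int) subject.size();
  std::vector<bool> masked(m + 1, false);
  std::vector<double> H((n + 1) * (m + 1)), E((n + 1) * (m + 1)), F((n + 1) * (m + 1));
  // 0 = stop, 1 = diag, 2 = gap in subject (up, consumes query),
  // 3 = gap in query (left, consumes subject)
  std::vector<unsigned char> TB((n + 1) * (m + 1));
  std::vector<unsigned char> TE((n + 1) * (m + 1)), TF((n + 1) * (m + 1)); // 1 = opened here
  std::vector<double> score_out;
  std::vector<int> qs, qe, ss, se, nmatch, ncols;
  const double NEG = -1e18;

  for (int hit = 0; hit < max_hits; ++hit) {
    double best = 0; int bi = -1, bj = -1;
    for (int i = 0; i <= n; ++i) {
      double* Hi = &H[i * (m + 1)]; double* Ei = &E[i * (m + 1)]; double* Fi = &F[i * (m + 1)];
      unsigned char* TBi = &TB[i * (m + 1)];
      for (int j = 0; j <= m; ++j) {
        if (i == 0 || j == 0) { Hi[j] = 0; Ei[j] = NEG; Fi[j] = NEG; TBi[j] = 0; continue; }
        if (masked[j]) { Hi[j] = 0; Ei[j] = NEG; Fi[j] = NEG; TBi[j] = 0; continue; }
        double* Hup = &H[(i - 1) * (m + 1)];
        double* Eup = &E[(i - 1) * (m + 1)];
        // gap in subject: consume query base i (move up)
        double e_open = Hup[j] - (gap_open + gap_extend);
        double e_ext  = Eup[j] - gap_extend;
        Ei[j] = e_open >= e_ext ? e_open : e_ext;
        TE[i * (m + 1) + j] = e_open >= e_ext ? 1 : 0;
        // gap in query: consume subject base j (move left)
        double f_open = Hi[j - 1] - (gap_open + gap_extend);
        double f_ext  = Fi[j - 1] - gap_extend;
        Fi[j] = f_open >= f_ext ? f_open : f_ext;
        TF[i * (m + 1) + j] = f_open >= f_ext ? 1 : 0;
        double diag = Hup[j - 1] +
          (query[i - 1] == subject[j - 1] ? match : mismatch);
        double h = 0; unsigned char t = 0;
        if (diag >= h) { h = diag; t = 1; }
        if (Ei[j] > h) { h = Ei[j]; t = 2; }
        if (Fi[j] > h) { h = Fi[j]; t = 3; }
        Hi[j] = h; TBi[j] = t;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best < min_score || bi < 0) break;
    // traceback
    int i = bi, j = bj, mtc = 0, cols = 0, state = 0; // state 0=H, 2=E, 3=F
    while (i > 0 && j > 0) {
      if (state == 0) {
        unsigned char t = TB[i * (m + 1) + j];
        if (t == 0) break;
        if (t == 1) {
          ++cols; if (query[i - 1] == subject[j - 1]) ++mtc;
          --i; --j;
        } else state = (int) t;
      } else if (state == 2) {
        unsigned char opened = TE[i * (m + 1) + j];
        ++cols; --i;
        if (opened) state = 0;
      } else {
        unsigned char opened = TF[i * (m + 1) + j];
        ++cols; --j;
        if (opened) state = 0;
      }
    }
    score_out.push_back(best);
    qs.push_back(i); qe.push_back(bi);       // 0-based half-open on query
    ss.push_back(j); se.push_back(bj);       // 0-based half-open on subject
    nmatch.push_back(mtc); ncols.push_back(cols);
    for (int k = j + 1; k <= bj; ++k) masked[k] = true;
  }
  return DataFrame::create(_["score"] = wrap(score_out),
                           _["q_start"] = wrap(qs), _["q_end"] = wrap(qe),
                           _["s_start"] = wrap(ss), _["s_end"] = wrap(se),
                           _["matches"] = wrap(nmatch), _["columns"] = wrap(ncols));
}

static inline int base2bits(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; default: return -1; }
}

// 0-based subject positions whose k-mer occurs anywhere in the query.
// k-mers containing N are skipped on both sides.
// [[Rcpp::export]]
IntegerVector kmer_seed_positions_cpp(std::string query, std::string subject, int k) {
  const int nq = (int) query.size(), ns = (int) subject.size();
  std::vector<int> out;
  if (k < 1 || k > 31 || nq < k || ns < k) return wrap(out);
  std::unordered_set<std::uint64_t> qk;
  const std::uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::uint64_t h = 0; int run = 0;
  for (int i = 0; i < nq; ++i) {
    int b = base2bits(query[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (std::uint64_t) b) & mask; ++run;
    if (run >= k) qk.insert(h);
  }
  h = 0; run = 0;
  for (int i = 0; i < ns; ++i) {
    int b = base2bits(subject[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (std::uint64_t) b) & mask; ++run;
    if (run >= k && qk.count(h)) out.push_back(i - k + 1);
  }
  return wrap(out);
}
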