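#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// A/C/G/T complement; everything else (incl. N) complements to nothing,
// so assembly gaps can never seed a stem.
static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return '\0';
  }
}

static inline bool pair_ok(const char* s, int i, int j) {
  char c = comp_base(s[i]);
  return c != '\0' && c == s[j];
}

struct Hit { int offset, arm, loop, mm; };

// Maximal-hairpin scan over anti-diagonals.  A hairpin (o, a, l) pairs
// positions (o+k, o+2a+l-1-k); all hairpins on the anti-diagonal
// d = 2o + 2a + l - 1 share their pairing structure, so for each (d, l)
// the valid arm lengths form a prefix and at most one maximal hit exists.
// Maximality: neither the outward extension (o-1, a+1, l) nor the inward
// extension (o, a+1, l-2) satisfies the constraints.
// trim_terminal: after maximality, trim mismatched outermost pairs back
// (used by genome scans; the exported contract keeps raw maximal hits)
// [[Rcpp::export]]
DataFrame hairpin_scan_cpp(std::string seq, int min_arm, int max_arm,
                           int min_loop, int max_loop, int max_mm,
                           bool trim_terminal = false) {
  const char* s = seq.c_str();
  const int n = (int) seq.size();
  std::vector<Hit> hits;
  if (n < 2 * min_arm + min_loop || min_arm < 1) {
    return DataFrame::create(_["offset"] = IntegerVector(0),
                             _["arm_len"] = IntegerVector(0),
                             _["loop_len"] = IntegerVector(0),
                             _["mismatches"] = IntegerVector(0));
  }
  for (int d = 1; d <= 2 * n - 3; ++d) {
    for (int l = min_loop; l <= max_loop; ++l) {
      if (((d - 1 - l) & 1) != 0) continue;      // parity: d - l - 1 must be even
      int p = (d - l - 1) / 2;                   // innermost left index
      if (p < 0 || d - p >= n) continue;
      // grow the stem outward, tracking cumulative mismatches
      int mm = 0, best_a = 0, best_mm = 0;
      int a_cap = std::min(max_arm, std::min(p + 1, n - (d - p)));
      for (int a = 1; a <= a_cap; ++a) {
        int li = p - (a - 1), ri = d - li;
        if (!pair_ok(s, li, ri)) ++mm;
        if (mm > max_mm) break;
        best_a = a; best_mm = mm;
      }
      if (best_a < min_arm) continue;
      int o = p - (best_a - 1);
      // outward extension (same loop): blocked by bounds/max_arm/budget?
      bool out_ok = false;
      if (best_a + 1 <= max_arm && o - 1 >= 0 && d - (o - 1) < n) {
        int add = pair_ok(s, o - 1, d - (o - 1)) ? 0 : 1;
        out_ok = (best_mm + add) <= max_mm;
      }
      if (out_ok) continue;   // defensive; cannot happen given prefix growth
      // inward extension (steal a pair from the loop)
      bool in_ok = false;
      if (l >= 2 && l - 2 >= min_loop && best_a + 1 <= max_arm) {
        int add = pair_ok(s, p + 1, d - (p + 1)) ? 0 : 1;
        in_ok = (best_mm + add) <= max_mm;
      }
      if (in_ok) continue;
      if (trim_terminal) {
        while (best_a > min_arm && best_mm > 0 &&
               !pair_ok(s, o, d - o)) {
          ++o; --best_a; --best_mm;
        }
      }
      hits.push_back({o, best_a, l, best_mm});
    }
  }
  std::sort(hits.begin(), hits.end(), [](const Hit& x, const Hit& y) {
    if (x.offset != y.offset) return x.offset < y.offset;
    if (x.arm != y.arm) return x.arm > y.arm;
    return x.loop < y.loop;
  });
  int m = (int) hits.size();
  IntegerVector off(m), arm(m), loop(m), mm(m);
  for (int i = 0; i < m; ++i) {
    off[i] = hits[i].offset; arm[i] = hits[i].arm;
    loop[i] = hits[i].loop;  mm[i] = hits[i].mm;
  }
  return DataFrame::create(_["offset"] = off, _["arm_len"] = arm,
                           _["loop_len"] = loop, _["mismatches"] = mm);
}

// Ungapped identity between two short segments; if lengths differ the
// shorter is slid along the longer and the best window is taken.
static double slide_identity(const std::string& a, const std::string& b) {
  const std::string& shrt = a.size() <= b.size() ? a : b;
  const std::string& lng  = a.size() <= b.size() ? b : a;
  int ns = (int) shrt.size(), nl = (int) lng.size();
  if (ns == 0) return 0.0;
  int best = 0;
  for (int off = 0; off <= nl - ns; ++off) {
    int m = 0;
    for (int i = 0; i < ns; ++i) if (shrt[i] == lng[off + i]) ++m;
    if (m > best) best = m;
  }
  return (double) best / (double) ns;
}

// [[Rcpp::export]]
double slide_identity_cpp(std::string a, std::string b) {
  return slide_identity(a, b);
}

// 2-bit packing for fast slid comparisons of short (<= 28 bp) segments;
// sequences containing non-ACGT fall back to the string path
struct Packed { std::uint64_t bits; int len; bool ok; };

static Packed pack_seq(const std::string& s) {
  Packed p{0, (int) s.size(), true};
  if (p.len > 28) { p.ok = false; return p; }
  for (int i = 0; i < p.len; ++i) {
    int b;
    switch (s[i]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: p.ok = false; return p;
    }
    p.bits |= ((std::uint64_t) b) << (2 * i);
  }
  return p;
}

static double packed_slide_identity(const Packed& a, const Packed& b) {
  const Packed& s = a.len <= b.len ? a : b;
  const Packed& l = a.len <= b.len ? b : a;
  int best = 0;
  const std::uint64_t smask = (s.len == 32) ? ~0ULL : ((1ULL << (2 * s.len)) - 1);
  for (int off = 0; off <= l.len - s.len; ++off) {
    std::uint64_t eq = ~(s.bits ^ (l.bits >> (2 * off)));
    eq &= eq >> 1;
    eq &= 0x5555555555555555ULL & smask;
    int m = __builtin_popcountll(eq);
    if (m > best) best = m;
  }
  return (double) best / (double) s.len;
}

// Candidate subTIR pairing for genome scans: candidates are hairpin hits
// (start, end, mm, seq); emit index pairs whose span fits the element
// length bounds, whose combined arm mismatches fit the budget and whose
// subTIR sequences agree (best of direct / reverse-complement, slid).
// [[Rcpp::export]]
DataFrame pair_candidates_cpp(IntegerVector start, IntegerVector end,
                              IntegerVector mm, CharacterVector seqs,
                              CharacterVector seqs_rc,
                              int min_span, int max_span,
                              double min_identity, int mm_budget) {
  int n = start.size();
  std::vector<int> ii, jj; std::vector<double> id;
  std::vector<std::string> sq(n), sqrc(n);
  std::vector<Packed> pk(n), pkrc(n);
  for (int i = 0; i < n; ++i) {
    sq[i] = as<std::string>(seqs[i]); sqrc[i] = as<std::string>(seqs_rc[i]);
    pk[i] = pack_seq(sq[i]); pkrc[i] = pack_seq(sqrc[i]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (start[j] - start[i] > max_span) break;   // inputs sorted by start
      int span = end[j] - start[i];
      if (span > max_span || span < min_span) continue;
      if (mm[i] + mm[j] > mm_budget) continue;
      double best;
      if (pk[i].ok && pk[j].ok && pkrc[j].ok) {
        double d1 = packed_slide_identity(pk[i], pk[j]);
        double d2 = packed_slide_identity(pk[i], pkrc[j]);
        best = d1 > d2 ? d1 : d2;
      } else {
        double d1 = slide_identity(sq[i], sq[j]);
        double d2 = slide_identity(sq[i], sqrc[j]);
        best = d1 > d2 ? d1 : d2;
      }
      if (best < min_identity) continue;
      ii.push_back(i + 1); jj.push_back(j + 1); id.push_back(best);
    }
  }
  return DataFrame::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                           _["pair_identity"] = wrap(id));
}

// vectorised reverse complement over {A,C,G,T,N}
// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string s = as<std::string>(x[k]);
    std::string r(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i) {
      char c = s[s.size() - 1 - i];
      char cc = comp_base(c);
      r[i] = cc ? cc : 'N';
    }
    out[k] = r;
  }
  return out;
}

// For each call's subTIR, the number of calls (including itself) whose
// subTIR agrees at >= min_identity (best orientation, slid).
// [[Rcpp::export]]
IntegerVector subtir_copy_counts_cpp(CharacterVector seqs, CharacterVector seqs_rc,
                                     double min_identity) {
  int n = seqs.size();
  std::vector<std::string> sq(n), rc(n);
  for (int i = 0; i < n; ++i) { sq[i] = as<std::string>(seqs[i]); rc[i] = as<std::string>(seqs_rc[i]); }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = std::max(slide_identity(sq[i], sq[j]), slide_identity(sq[i], rc[j]));
      if (d >= min_identity) { out[i]++; out[j]++; }
    }
  }
  return out;
}

// Number of disjoint calls (including self) sharing both the subTIR
// (>= min_identity, best orientation) and a similar span (within 10% or
// 20 bp).  Genuine copies of a family recur at a consistent length at
// distinct loci; chimeric pairings of subTIRs from neighbouring copies
// produce mutually overlapping variants, which do not count.  Calls are
// compared within a span-sorted window, keeping the pass near-linear.
// [[Rcpp::export]]
IntegerVector length_support_cpp(CharacterVector seqs, CharacterVector seqs_rc,
                                 IntegerVector start, IntegerVector end,
                                 IntegerVector seqid_code,
                                 double min_identity) {
  int n = seqs.size();
  std::vector<std::string> sq(n), rc(n);
  for (int i = 0; i < n; ++i) { sq[i] = as<std::string>(seqs[i]); rc[i] = as<std::string>(seqs_rc[i]); }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return (end[a] - start[a]) < (end[b] - start[b]);
  });
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 1;
  for (int a = 0; a < n; ++a) {
    int i = ord[a];
    int si = end[i] - start[i];
    for (int b = a + 1; b < n; ++b) {
      int j = ord[b];
      int sj = end[j] - start[j];
      int tol = std::max(20, (int) (0.1 * si));
      if (sj - si > tol) break;          // span-sorted
      if (seqid_code[i] == seqid_code[j] &&
          start[i] < end[j] && end[i] > start[j]) continue;  // overlapping
      double d = std::max(slide_identity(sq[i], sq[j]), slide_identity(sq[i], rc[j]));
      if (d >= min_identity) { out[i]++; out[j]++; }
    }
  }
  return out;
}

// Drop container calls explained by a substantially shorter call of the
// same subTIR family and comparable score lying inside them (chimeric
// pairings of subTIRs from two copies contain the genuine per-copy
// call; a long element containing unrelated short junk is unaffected
// because the family identity fails).
// [[Rcpp::export]]
LogicalVector contained_chimera_cpp(IntegerVector start, IntegerVector end,
                                    NumericVector score,
                                    CharacterVector subtir,
                                    CharacterVector subtir_rc,
                                    IntegerVector seqid_code,
                                    double min_identity, double slack,
                                    int min_shorter) {
  int n = start.size();
  std::vector<std::string> sq(n), rc(n);
  for (int i = 0; i < n; ++i) { sq[i] = as<std::string>(subtir[i]); rc[i] = as<std::string>(subtir_rc[i]); }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (seqid_code[a] != seqid_code[b]) return seqid_code[a] < seqid_code[b];
    return start[a] < start[b];
  });
  LogicalVector drop(n);
  for (int a = 0; a < n; ++a) {
    int i = ord[a];
    int len_i = end[i] - start[i];
    for (int b = 0; b < n; ++b) {
      int j = ord[b];
      if (j == i || seqid_code[j] != seqid_code[i]) continue;
      if (start[j] < start[i] - 3 || start[j] > end[i]) continue;
      if (end[j] > end[i] + 3) continue;
      if ((end[j] - start[j]) > len_i - min_shorter) continue;
      if (score[j] < score[i] - slack) continue;
      double d = std::max(slide_identity(sq[i], sq[j]), slide_identity(sq[i], rc[j]));
      if (d >= min_identity) { drop[i] = true; break; }
    }
  }
  return drop;
}
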