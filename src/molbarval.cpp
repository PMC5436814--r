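#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// IUPAC expansion bitmasks: A=1, C=2, G=4, T=8. N in a *target* matches
// nothing, so targets are restricted to the 4 concrete bases.
static int iupac_mask(char c) {
  switch (c) {
  case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
  case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4; case 'W': return 1|8;
  case 'K': return 4|8; case 'M': return 1|2;
  case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8; case 'V': return 1|2|4;
  case 'N': return 1|2|4|8;
  default: return -1;
  }
}

static int base_mask(char c) {
  switch (c) {
  case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
  default: return 0;  // N or anything else in the target matches nothing
  }
}

// [[Rcpp::export]]
LogicalVector cpp_iupac_match(CharacterVector primer_base, CharacterVector target_base) {
  R_xlen_t n = primer_base.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *p = CHAR(STRING_ELT(primer_base, i));
    const char *t = CHAR(STRING_ELT(target_base, i));
    int pm = iupac_mask(p[0]);
    if (pm < 0) stop("invalid IUPAC code: '%s'", p);
    out[i] = (pm & base_mask(t[0])) != 0;
  }
  return out;
}

// All start positions (0-based) where a degenerate primer matches the target
// with at most max_mismatch mismatches. N in the target matches nothing.
// [[Rcpp::export]]
DataFrame cpp_primer_scan(std::string target, std::string primer, int max_mismatch) {
  int n = (int) target.size(), m = (int) primer.size();
  std::vector<int> pmask(m);
  for (int j = 0; j < m; ++j) {
    pmask[j] = iupac_mask(primer[j]);
    if (pmask[j] < 0) stop("invalid IUPAC code in primer: '%c'", primer[j]);
  }
  std::vector<int> starts, mms;
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      if (!(pmask[j] & base_mask(target[i + j]))) {
        if (++mm > max_mismatch) break;
      }
    }
    if (mm <= max_mismatch) { starts.push_back(i); mms.push_back(mm); }
  }
  return DataFrame::create(_["start"] = starts, _["mismatches"] = mms);
}

// Locate a degenerate primer whose start lies in [0, window) of each read.
// Returns, per read, the 0-based start of the best (fewest-mismatch,
// then leftmost) hit, or -1.
// [[Rcpp::export]]
IntegerVector cpp_locate_primer_5p(CharacterVector reads, std::string primer,
                                   int max_mismatch, int window) {
  int m = (int) primer.size();
  std::vector<int> pmask(m);
  for (int j = 0; j < m; ++j) {
    pmask[j] = iupac_mask(primer[j]);
    if (pmask[j] < 0) stop("invalid IUPAC code in primer: '%c'", primer[j]);
  }
  R_xlen_t n = reads.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = (int) std::strlen(s);
    int best = -1, best_mm = max_mismatch + 1;
    int last_start = std::min(window - 1, len - m);
    for (int st = 0; st <= last_start; ++st) {
      int mm = 0;
      for (int j = 0; j < m; ++j) {
        if (!(pmask[j] & base_mask(s[st + j]))) { if (++mm > max_mismatch) break; }
      }
      if (mm <= max_mismatch && mm < best_mm) { best = st; best_mm = mm; if (mm == 0) break; }
    }
    out[i] = best;
  }
  return out;
}

// Locate a degenerate primer (already reverse-complemented by the caller)
// whose end lies within `window` of each read's 3' end. Returns the 0-based
// start of the best hit, or -1.
// [[Rcpp::export]]
IntegerVector cpp_locate_primer_3p(CharacterVector reads, std::string primer_rc,
                                   int max_mismatch, int window) {
  int m = (int) primer_rc.size();
  std::vector<int> pmask(m);
  for (int j = 0; j < m; ++j) {
    pmask[j] = iupac_mask(primer_rc[j]);
    if (pmask[j] < 0) stop("invalid IUPAC code in primer: '%c'", primer_rc[j]);
  }
  R_xlen_t n = reads.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    int len = (int) std::strlen(s);
    int best = -1, best_mm = max_mismatch + 1;
    // scan from the rightmost admissible start leftwards
    int first_start = std::max(0, len - m - window + 1);
    for (int st = len - m; st >= first_start; --st) {
      if (st < 0) break;
      int mm = 0;
      for (int j = 0; j < m; ++j) {
        if (!(pmask[j] & base_mask(s[st + j]))) { if (++mm > max_mismatch) break; }
      }
      if (mm <= max_mismatch && mm < best_mm) { best = st; best_mm = mm; if (mm == 0) break; }
    }
    out[i] = best;
  }
  return out;
}

// Merge paired reads. r2rc/q2rev must already be the reverse complement of
// R2 and its reversed quality string. Candidate overlaps run from the
// largest (full overlap of the shorter read) down to min_overlap; the best
// candidate minimises the mismatch rate, ties going to the larger overlap.
// Disagreements resolve to the higher-quality base carrying the lower
// quality; agreements take the max quality capped at Q41 (Phred+33).
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector r2rc,
                     CharacterVector q1, CharacterVector q2rev,
                     int min_overlap, double max_mismatch_rate) {
  R_xlen_t n = r1.size();
  CharacterVector merged(n), mqual(n);
  LogicalVector ok(n);
  IntegerVector overlap_len(n), n_mismatch(n);
  const char QCAP = (char)(41 + 33);
  std::string buf, qbuf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(r1, i));
    const char *b = CHAR(STRING_ELT(r2rc, i));
    const char *qa = CHAR(STRING_ELT(q1, i));
    const char *qb = CHAR(STRING_ELT(q2rev, i));
    int la = (int) std::strlen(a), lb = (int) std::strlen(b);
    int omax = std::min(la, lb);
    int best_o = -1, best_mm = 0;
    double best_rate = 1e18;
    for (int o = omax; o >= min_overlap; --o) {
      int allow = (int) std::floor(max_mismatch_rate * o);
      int mm = 0;
      const char *atail = a + (la - o);
      bool fail = false;
      for (int j = 0; j < o; ++j) {
        if (atail[j] != b[j]) {
          if (++mm > allow) { fail = true; break; }
        }
      }
      if (fail) continue;
      double rate = (double) mm / (double) o;
      if (rate < best_rate) { best_rate = rate; best_o = o; best_mm = mm; }
      if (mm == 0) break;  // cannot do better
    }
    if (best_o < 0) {
      merged[i] = NA_STRING; mqual[i] = NA_STRING;
      ok[i] = false; overlap_len[i] = 0; n_mismatch[i] = NA_INTEGER;
      continue;
    }
    int o = best_o;
    buf.assign(a, la - o);
    qbuf.assign(qa, la - o);
    const char *atail = a + (la - o);
    const char *qtail = qa + (la - o);
    for (int j = 0; j < o; ++j) {
      char ba = atail[j], bb = b[j], pa = qtail[j], pb = qb[j];
      if (ba == bb) {
        char q = pa > pb ? pa : pb;
        buf.push_back(ba);
        qbuf.push_back(q > QCAP ? QCAP : q);
      } else if (pa >= pb) {
        buf.push_back(ba); qbuf.push_back(pb);
      } else {
        buf.push_back(bb); qbuf.push_back(pa);
      }
    }
    buf.append(b + o, lb - o);
    qbuf.append(qb + o, lb - o);
    merged[i] = buf; mqual[i] = qbuf;
    ok[i] = true; overlap_len[i] = o; n_mismatch[i] = best_mm;
  }
  return List::create(_["merged"] = merged, _["quality"] = mqual, _["ok"] = ok,
                      _["overlap"] = overlap_len, _["mismatches"] = n_mismatch);
}

// Inject substitution errors at a uniform per-base rate, using R's RNG so
// results are reproducible under set.seed(). Substituted base is drawn
// uniformly from the three alternatives.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  if (error_rate <= 0) return clone(seqs);
  RNGScope scope;
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    buf.assign(s);
    for (size_t j = 0; j < buf.size(); ++j) {
      if (unif_rand() < error_rate) {
        char cur = buf[j];
        char sub = cur;
        while (sub == cur) sub = bases[(int)(unif_rand() * 4) & 3];
        buf[j] = sub;
      }
    }
    out[i] = buf;
  }
  return out;
}

// Phred+33 quality strings with linear mean decay along the cycle and
// Gaussian jitter, clamped to [2, 41].
// [[Rcpp::export]]
CharacterVector cpp_sim_quality(IntegerVector lengths, double q_start,
                                double decay, double jitter_sd) {
  R_xlen_t n = lengths.size();
  CharacterVector out(n);
  RNGScope scope;
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    int len = lengths[i];
    buf.assign((size_t) len, '!');
    for (int j = 0; j < len; ++j) {
      double q = q_start - decay * j;
      if (jitter_sd > 0) q += norm_rand() * jitter_sd;
      int qi = (int) std::lround(q);
      if (qi < 2) qi = 2;
      if (qi > 41) qi = 41;
      buf[j] = (char)(qi + 33);
    }
    out[i] = buf;
  }
  return out;
}
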