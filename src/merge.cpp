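// Paired-end read merging: exhaustive suffix/prefix overlap scan with a
// best-so-far bound. Kept in C++ because the end-to-end pipeline merges
// hundreds of thousands of pairs.
#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp(char b) {
  switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector fwd, CharacterVector rev,
                     CharacterVector fq, CharacterVector rq,
                     int min_overlap, double max_mismatch_frac,
                     int qual_cap) {
  const int n = fwd.size();
  CharacterVector out_seq(n), out_qual(n), status(n);
  IntegerVector overlap_len(n);
  NumericVector mean_q(n);
  IntegerVector min_q(n);

  for (int r = 0; r < n; ++r) {
    std::string f = as<std::string>(fwd[r]);
    std::string rv = as<std::string>(rev[r]);
    std::string fqs = as<std::string>(fq[r]);
    std::string rqs = as<std::string>(rq[r]);
    if (f.size() != fqs.size() || rv.size() != rqs.size()) {
      status[r] = "bad_input"; out_seq[r] = NA_STRING; out_qual[r] = NA_STRING;
      overlap_len[r] = NA_INTEGER; mean_q[r] = NA_REAL; min_q[r] = NA_INTEGER;
      continue;
    }
    // reverse-complement the reverse read (and reverse its qualities)
    std::string rc(rv.rbegin(), rv.rend());
    for (size_t i = 0; i < rc.size(); ++i) rc[i] = comp(rc[i]);
    std::string rcq(rqs.rbegin(), rqs.rend());

    const int lf = (int)f.size(), lr = (int)rc.size();
    const int max_ov = std::min(lf, lr);
    int best_matches = -1, best_ov = 0, n_best = 0;
    // scan overlap lengths descending; an overlap shorter than the current
    // best match count can neither beat nor tie it
    for (int ov = max_ov; ov >= min_overlap && ov >= 1; --ov) {
      if (ov < best_matches) break;
      // epsilon guards the floor against binary representation of e.g. 0.1
      const int allowed = (int)std::floor(max_mismatch_frac * ov + 1e-9);
      int mism = 0;
      const char *pf = f.data() + (lf - ov);
      const char *pr = rc.data();
      bool feasible = true;
      for (int i = 0; i < ov; ++i) {
        if (pf[i] != pr[i] && ++mism > allowed) { feasible = false; break; }
      }
      if (!feasible) continue;
      const int matches = ov - mism;
      if (matches > best_matches) {
        best_matches = matches; best_ov = ov; n_best = 1;
      } else if (matches == best_matches) {
        ++n_best;
      }
    }
    if (best_matches < 0) {
      status[r] = "no_overlap"; out_seq[r] = NA_STRING; out_qual[r] = NA_STRING;
      overlap_len[r] = NA_INTEGER; mean_q[r] = NA_REAL; min_q[r] = NA_INTEGER;
      continue;
    }
    if (n_best > 1) {
      status[r] = "ambiguous"; out_seq[r] = NA_STRING; out_qual[r] = NA_STRING;
      overlap_len[r] = NA_INTEGER; mean_q[r] = NA_REAL; min_q[r] = NA_INTEGER;
      continue;
    }
    const int ov = best_ov;
    const int mlen = lf + lr - ov;
    std::string seq(mlen, 'N');
    std::vector<int> qual(mlen, 0);
    for (int i = 0; i < lf - ov; ++i) { seq[i] = f[i]; qual[i] = fqs[i] - 33; }
    for (int i = 0; i < ov; ++i) {
      const int fi = lf - ov + i;
      const int q1 = fqs[fi] - 33, q2 = rcq[i] - 33;
      const char b1 = f[fi], b2 = rc[i];
      if (b1 == b2) {
        seq[fi] = b1;
        qual[fi] = std::min(q1 + q2, qual_cap);
      } else {
        // disagreeing bases: higher-Phred call wins (forward on ties)
        seq[fi] = (q2 > q1) ? b2 : b1;
        qual[fi] = std::max(q1, q2);
      }
    }
    for (int i = ov; i < lr; ++i) {
      seq[lf - ov + i] = rc[i];
      qual[lf - ov + i] = rcq[i] - 33;
    }
    double qsum = 0; int qmin = 1000;
    std::string qstr(mlen, '!');
    for (int i = 0; i < mlen; ++i) {
      qsum += qual[i];
      if (qual[i] < qmin) qmin = qual[i];
      qstr[i] = (char)(std::min(qual[i], 93) + 33);
    }
    status[r] = "merged";
    out_seq[r] = seq;
    out_qual[r] = qstr;
    overlap_len[r] = ov;
    mean_q[r] = qsum / mlen;
    min_q[r] = qmin;
  }
  return List::create(_["status"] = status, _["seq"] = out_seq,
                      _["qual"] = out_qual, _["overlap_len"] = overlap_len,
                      _["mean_q"] = mean_q, _["min_q"] = min_q);
}
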