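#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps of one read against a
// window of the reference. Scoring: match +1, mismatch -4, gap of length L
// costs open + L * extend (defaults 6 + L). Local alignment soft-clips read
// ends that do not extend (e.g. across a novel junction). Ties in the best
// cell resolve to the smallest reference end, then smallest read end, so
// placement is deterministic.
//
// Returns per read: score, ref_start/ref_end (0-based half-open, in full
// reference coordinates), read_start/read_end (0-based half-open), cigar
// (S/M/I/D with soft-clips covering the unaligned read ends).
// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref,
                     IntegerVector win_start, IntegerVector win_end,
                     double match = 1.0, double mismatch = -4.0,
                     double gap_open = 6.0, double gap_extend = 1.0) {
  int nr = reads.size();
  IntegerVector out_score(nr), out_rs(nr), out_re(nr), out_qs(nr), out_qe(nr);
  CharacterVector out_cigar(nr);
  int refL = (int) ref.size();

  for (int r = 0; r < nr; ++r) {
    std::string q = as<std::string>(reads[r]);
    int ws = std::max(0, win_start[r]);
    int we = std::min(refL, win_end[r]);
    int m = (int) q.size();
    int n = we - ws;
    if (n <= 0 || m == 0) {
      out_score[r] = 0; out_rs[r] = NA_INTEGER; out_re[r] = NA_INTEGER;
      out_qs[r] = NA_INTEGER; out_qe[r] = NA_INTEGER; out_cigar[r] = NA_STRING;
      continue;
    }
    // H: best ending in match/mismatch; E: gap in read (D); F: gap in ref (I)
    const double NEG = -1e9;
    std::vector<double> H((m + 1) * (n + 1), 0.0);
    std::vector<double> E((m + 1) * (n + 1), NEG);
    std::vector<double> F((m + 1) * (n + 1), NEG);
    std::vector<signed char> tb((m + 1) * (n + 1), 0); // 0 stop,1 diag,2 E(D),3 F(I)
    std::vector<signed char> tbE((m + 1) * (n + 1), 0); // 1 open, 2 extend
    std::vector<signed char> tbF((m + 1) * (n + 1), 0);
    double best = 0.0; int bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
      for (int j = 1; j <= n; ++j) {
        int idx = i * (n + 1) + j;
        int up = (i - 1) * (n + 1) + j;
        int left = i * (n + 1) + (j - 1);
        int diag = (i - 1) * (n + 1) + (j - 1);
        double eo = H[left] - gap_open - gap_extend;
        double ee = E[left] - gap_extend;
        E[idx] = std::max(eo, ee);
        tbE[idx] = (eo >= ee) ? 1 : 2;
        double fo = H[up] - gap_open - gap_extend;
        double fe = F[up] - gap_extend;
        F[idx] = std::max(fo, fe);
        tbF[idx] = (fo >= fe) ? 1 : 2;
        double s = (q[i - 1] == ref[ws + j - 1] &&
                    q[i - 1] != 'N') ? match : mismatch;
        double d = H[diag] + s;
        double h = 0.0; signed char t = 0;
        if (d >= h) { h = d; t = 1; }
        if (E[idx] > h) { h = E[idx]; t = 2; }
        if (F[idx] > h) { h = F[idx]; t = 3; }
        H[idx] = h; tb[idx] = t;
        if (h > best || (h == best && (j < bj || (j == bj && i < bi)))) {
          if (h > 0) { best = h; bi = i; bj = j; }
        }
      }
    }
    if (best <= 0.0) {
      out_score[r] = 0; out_rs[r] = NA_INTEGER; out_re[r] = NA_INTEGER;
      out_qs[r] = NA_INTEGER; out_qe[r] = NA_INTEGER; out_cigar[r] = NA_STRING;
      continue;
    }
    // traceback
    std::string ops;
    int i = bi, j = bj;
    int state = 0; // 0: in H
    while (i > 0 && j > 0) {
      int idx = i * (n + 1) + j;
      if (state == 0) {
        signed char t = tb[idx];
        if (t == 0) break;
        if (t == 1) { ops.push_back('M'); --i; --j; }
        else if (t == 2) state = 2;
        else state = 3;
      } else if (state == 2) { // E: gap in read -> D (ref consumed)
        ops.push_back('D');
        signed char t = tbE[idx];
        --j;
        if (t == 1) state = 0;
      } else { // F: gap in ref -> I (read consumed)
        ops.push_back('I');
        signed char t = tbF[idx];
        --i;
        if (t == 1) state = 0;
      }
    }
    int qs = i, qe = bi;          // read [qs, qe)
    int rs = ws + j, re = ws + bj; // ref [rs, re)
    // RLE cigar with soft clips
    std::string cigar;
    char buf[32];
    if (qs > 0) { snprintf(buf, sizeof(buf), "%dS", qs); cigar += buf; }
    int runlen = 0; char runop = 0;
    for (int kk = (int) ops.size() - 1; kk >= 0; --kk) {
      char op = ops[kk];
      if (op == runop) ++runlen;
      else {
        if (runlen) { snprintf(buf, sizeof(buf), "%d%c", runlen, runop); cigar += buf; }
        runop = op; runlen = 1;
      }
    }
    if (runlen) { snprintf(buf, sizeof(buf), "%d%c", runlen, runop); cigar += buf; }
    if (qe < m) { snprintf(buf, sizeof(buf), "%dS", m - qe); cigar += buf; }
    out_score[r] = (int) best;
    out_rs[r] = rs; out_re[r] = re; out_qs[r] = qs; out_qe[r] = qe;
    out_cigar[r] = cigar;
  }
  return List::create(_["score"] = out_score, _["ref_start"] = out_rs,
                      _["ref_end"] = out_re, _["read_start"] = out_qs,
                      _["read_end"] = out_qe, _["cigar"] = out_cigar);
}
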