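#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Affine-gap Smith-Waterman with iterated query-masking declumping.
//
// A gap of length k costs gap_open + k * gap_extend. After each reported
// alignment every query position it consumed (aligned or inside a deletion)
// is masked, and the DP is re-run, so successive alignments are mutually
// non-overlapping on the query. Tie-breaks are deterministic: the best cell
// is the first maximum in row-major order; traceback prefers diagonal over
// gap-in-query over gap-in-target.

static const int NEG = INT_MIN / 4;

struct Cell { int H, E, F; };

static int score_lookup(const std::vector<int>& lut, const IntegerMatrix& sm,
                        char a, char b) {
  int ia = lut[(unsigned char)a], ib = lut[(unsigned char)b];
  if (ia < 0 || ib < 0) return NEG;
  return sm(ia, ib);
}

// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(std::string query, std::string target, IntegerMatrix submat,
                  int gap_open, int gap_extend, int max_alignments,
                  int min_score) {
  int m = (int)query.size(), n = (int)target.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if ((double)m * (double)n > 6e7)
    stop("sequence pair too large for the built-in aligner");

  List dn = submat.attr("dimnames");
  CharacterVector rn = dn[0];
  std::vector<int> lut(256, -1);
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }

  std::vector<bool> masked(m + 1, false);
  List out;

  for (int round = 0; round < max_alignments; ++round) {
    // DP matrices, (m+1) x (n+1); row i ~ query[i-1]
    std::vector<std::vector<Cell>> M(m + 1, std::vector<Cell>(n + 1));
    for (int j = 0; j <= n; ++j) M[0][j] = {0, NEG, NEG};
    int best = 0, bi = -1, bj = -1;
    for (int i = 1; i <= m; ++i) {
      M[i][0] = {0, NEG, NEG};
      bool mi = masked[i];
      for (int j = 1; j <= n; ++j) {
        // E: gap in query (consume target j only)
        int E = std::max(M[i][j - 1].H - gap_open - gap_extend,
                         M[i][j - 1].E - gap_extend);
        // F: gap in target (consume query i) -- forbidden on masked rows
        int F;
        if (mi) F = NEG;
        else F = std::max(M[i - 1][j].H - gap_open - gap_extend,
                          M[i - 1][j].F - gap_extend);
        int diag;
        if (mi) diag = NEG;
        else {
          int s = score_lookup(lut, submat, query[i - 1], target[j - 1]);
          diag = (s == NEG) ? NEG : M[i - 1][j - 1].H + s;
        }
        int H = 0;
        if (diag > H) H = diag;
        if (E > H) H = E;
        if (F > H) H = F;
        M[i][j] = {H, E, F};
        if (H > best) { best = H; bi = i; bj = j; }
      }
    }
    if (best < min_score || bi < 0) break;

    // traceback from (bi,bj) in state H until H == 0
    std::string qa, ta;
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (true) {
      if (state == 0) {
        int H = M[i][j].H;
        if (H == 0) break;
        int s = score_lookup(lut, submat, query[i - 1], target[j - 1]);
        if (!masked[i] && s != NEG && H == M[i - 1][j - 1].H + s) {
          qa.push_back(query[i - 1]); ta.push_back(target[j - 1]);
          --i; --j;
        } else if (H == M[i][j].E) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        qa.push_back('-'); ta.push_back(target[j - 1]);
        int E = M[i][j].E;
        --j;
        // prefer closing the gap when both predecessors reproduce E
        if (E == M[i][j].H - gap_open - gap_extend) state = 0;
        else state = 1;
      } else {
        qa.push_back(query[i - 1]); ta.push_back('-');
        int F = M[i][j].F;
        --i;
        if (F == M[i][j].H - gap_open - gap_extend) state = 0;
        else state = 2;
      }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(ta.begin(), ta.end());
    int qs = i + 1, ts = j + 1; // 1-based starts

    int nid = 0, nmis = 0, naln = 0;
    for (size_t k = 0; k < qa.size(); ++k) {
      if (qa[k] != '-' && ta[k] != '-') {
        ++naln;
        if (qa[k] == ta[k]) ++nid; else ++nmis;
      }
    }
    // mask consumed query rows
    for (int q = qs; q <= bi; ++q) masked[q] = true;

    out.push_back(List::create(
        _["query_aligned"] = qa, _["target_aligned"] = ta,
        _["query_start"] = qs, _["query_end"] = bi,
        _["target_start"] = ts, _["target_end"] = bj,
        _["score"] = best, _["n_identical"] = nid, _["n_mismatch"] = nmis,
        _["n_aligned"] = naln, _["alignment_len"] = (int)qa.size()));
  }
  return out;
}
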