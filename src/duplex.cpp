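#include <Rcpp.h>
using namespace Rcpp;

// Local complementarity alignment of a miRNA (antiparallel) against a 3'UTR,
// Gotoh affine gaps, seed positions (miRNA 5' positions 2-8 by default)
// up-weighted.  The miRNA is processed reversed (3'->5') so both strands
// advance left-to-right in the DP; emitted coordinates are converted back.
// pair_scores is 4x4 [mirna base, utr base]; gap of length L costs
// gap_open + (L-1)*gap_extend.

struct Cell { double h, e, f; };

// [[Rcpp::export(name = ".cpp_duplex_align")]]
List cpp_duplex_align(IntegerVector mirna, IntegerVector utr,
                      NumericMatrix pair_scores, IntegerVector seed_positions,
                      double seed_multiplier, double gap_open,
                      double gap_extend, double min_score, int max_hits) {
  int m = mirna.size(), n = utr.size();
  const double NEG = -1e18;

  // row i (1-based) of the DP corresponds to miRNA 5' position m - i + 1
  std::vector<double> rowmult(m + 1, 1.0);
  for (int k = 0; k < seed_positions.size(); ++k) {
    int p = seed_positions[k];
    if (p >= 1 && p <= m) rowmult[m - p + 1] = seed_multiplier;
  }
  std::vector<int> mr(m + 1);
  for (int i = 1; i <= m; ++i) mr[i] = mirna[m - i];

  std::vector<bool> masked(n + 1, false);
  std::vector<Cell> dp((size_t)(m + 1) * (n + 1));
  List hits;

  for (int hit = 0; hit < max_hits; ++hit) {
    double best = 0.0; int bi = -1, bj = -1;
    for (int j = 0; j <= n; ++j) dp[j] = (Cell){0.0, NEG, NEG};
    for (int i = 1; i <= m; ++i) {
      dp[(size_t)i * (n + 1)] = (Cell){0.0, NEG, NEG};
      for (int j = 1; j <= n; ++j) {
        Cell& c = dp[(size_t)i * (n + 1) + j];
        if (masked[j]) { c.h = 0.0; c.e = NEG; c.f = NEG; continue; }
        const Cell& up = dp[(size_t)(i - 1) * (n + 1) + j];
        const Cell& lf = dp[(size_t)i * (n + 1) + j - 1];
        const Cell& di = dp[(size_t)(i - 1) * (n + 1) + j - 1];
        c.e = std::max(lf.h - gap_open, lf.e - gap_extend);
        c.f = std::max(up.h - gap_open, up.f - gap_extend);
        double sc = pair_scores(mr[i], utr[j - 1]) * rowmult[i];
        c.h = std::max(0.0, std::max(di.h + sc, std::max(c.e, c.f)));
        if (c.h > best + 1e-9) { best = c.h; bi = i; bj = j; }
      }
    }
    if (best <= min_score || bi < 0) break;

    // traceback from (bi, bj) in state H
    std::vector<int> pi, pj, ptype;  // aligned (non-gap) columns only
    int i = bi, j = bj, state = 0;   // 0=H 1=E 2=F
    while (i > 0 && j > 0) {
      Cell c = dp[(size_t)i * (n + 1) + j];
      if (state == 0) {
        if (c.h <= 1e-12) break;
        const Cell& di = dp[(size_t)(i - 1) * (n + 1) + j - 1];
        double sc = pair_scores(mr[i], utr[j - 1]) * rowmult[i];
        if (std::abs(c.h - (di.h + sc)) < 1e-9) {
          pi.push_back(i); pj.push_back(j);
          int a = mr[i], b = utr[j - 1];
          bool wc = (a == 0 && b == 3) || (a == 3 && b == 0) ||
                    (a == 2 && b == 1) || (a == 1 && b == 2);
          bool wob = (a == 2 && b == 3) || (a == 3 && b == 2);
          ptype.push_back(wc ? 2 : (wob ? 1 : 0));
          --i; --j;
        } else if (std::abs(c.h - c.e) < 1e-9) state = 1;
        else if (std::abs(c.h - c.f) < 1e-9) state = 2;
        else break;
      } else if (state == 1) {
        const Cell& lf = dp[(size_t)i * (n + 1) + j - 1];
        if (std::abs(c.e - (lf.h - gap_open)) < 1e-9) { --j; state = 0; }
        else { --j; state = 1; }
      } else {
        const Cell& up = dp[(size_t)(i - 1) * (n + 1) + j];
        if (std::abs(c.f - (up.h - gap_open)) < 1e-9) { --i; state = 0; }
        else { --i; state = 2; }
      }
    }
    if (pi.empty()) break;

    int utr_lo = n + 1, utr_hi = 0;
    IntegerMatrix pm(pi.size(), 2);
    IntegerVector pt(pi.size());
    // traceback collected pairs high->low; reverse so DP order is ascending
    int np = (int)pi.size();
    for (int r = 0; r < np; ++r) {
      int ii = pi[np - 1 - r], jj = pj[np - 1 - r];
      pm(r, 0) = m - ii + 1;  // original miRNA 5'->3' position (descending)
      pm(r, 1) = jj;
      pt[r] = ptype[np - 1 - r];
      if (jj < utr_lo) utr_lo = jj;
      if (jj > utr_hi) utr_hi = jj;
    }
    for (int jj = utr_lo; jj <= utr_hi; ++jj) masked[jj] = true;
    hits.push_back(List::create(
        _["score"] = best, _["utr_start"] = utr_lo, _["utr_end"] = utr_hi,
        _["mirna_start"] = pm(np - 1, 0), _["mirna_end"] = pm(0, 0),
        _["pairs"] = pm, _["pair_type"] = pt));
  }
  return hits;
}
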