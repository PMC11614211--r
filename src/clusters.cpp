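#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 4-connected component labelling on an (nr x nc) grid stored column-major.
// With separate_last_row = true the final grid row (the appended voltage
// trace) has no vertical neighbours: it forms its own connectivity domain.

static const int DR[4] = {-1, 1, 0, 0};
static const int DC[4] = {0, 0, -1, 1};

// [[Rcpp::export]]
IntegerMatrix cpp_label_clusters(LogicalMatrix mask, bool separate_last_row) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.push_back(r0 + c0 * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int k = 0; k < 4; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (DR[k] != 0 && separate_last_row && (r == nr - 1 || rr == nr - 1))
            continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Maximum absolute cluster mass per permutation. permT holds one t-map per
// row (grid flattened column-major); positive and negative clusters are
// formed separately at +/- thr and the largest |sum of t| is returned.

// [[Rcpp::export]]
NumericVector cpp_perm_max_mass(NumericMatrix permT, double thr, int nr,
                                int nc, bool separate_last_row) {
  int nPerm = permT.nrow();
  int p = nr * nc;
  if (permT.ncol() != p) stop("t-map width does not match the grid size");
  NumericVector out(nPerm);
  std::vector<int> stamp(p, -1);
  std::vector<int> stack;
  for (int pe = 0; pe < nPerm; ++pe) {
    double best = 0.0;
    for (int s = 0; s < 2; ++s) {
      int tag = pe * 2 + s;
      double sgn = (s == 0) ? 1.0 : -1.0;
      for (int idx = 0; idx < p; ++idx) {
        if (stamp[idx] == tag) continue;
        if (sgn * permT(pe, idx) <= thr) continue;
        double mass = 0.0;
        stamp[idx] = tag;
        stack.push_back(idx);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          mass += sgn * permT(pe, cur);
          int r = cur % nr, c = cur / nr;
          for (int k = 0; k < 4; ++k) {
            int rr = r + DR[k], cc = c + DC[k];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (DR[k] != 0 && separate_last_row && (r == nr - 1 || rr == nr - 1))
              continue;
            int nidx = rr + cc * nr;
            if (stamp[nidx] == tag) continue;
            if (sgn * permT(pe, nidx) > thr) {
              stamp[nidx] = tag;
              stack.push_back(nidx);
            }
          }
        }
        if (mass > best) best = mass;
      }
    }
    out[pe] = best;
  }
  return out;
}
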