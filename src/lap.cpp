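#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Rectangular minimum-cost linear assignment by shortest augmenting paths
// (Jonker-Volgenant style with dual updates), O(nr * nc * path length).
// Requires nrow(cost) <= ncol(cost); every row receives exactly one column,
// every column at most one row. Returns the 1-based column index per row.
//
// Infeasible (all-infinite row alternatives) aborts with an error; callers
// encode forbidden pairs as large finite penalties and check the solution.
// [[Rcpp::export]]
IntegerVector lap_solve_cpp(NumericMatrix cost) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (nr > nc)
    stop("assignment requires nrow(cost) <= ncol(cost)");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(nr, 0.0), v(nc, 0.0);   // dual potentials
  std::vector<int> col4row(nr, -1), row4col(nc, -1);
  std::vector<double> shortest(nc);
  std::vector<char> scanned(nc);
  std::vector<int> pred(nc);

  for (int curRow = 0; curRow < nr; ++curRow) {
    double minVal = 0.0;
    int i = curRow, sink = -1;
    std::fill(shortest.begin(), shortest.end(), INF);
    std::fill(scanned.begin(), scanned.end(), 0);
    std::fill(pred.begin(), pred.end(), -1);

    while (sink == -1) {
      double lowest = INF;
      int jLow = -1;
      for (int j = 0; j < nc; ++j) {
        if (scanned[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) {
          shortest[j] = r;
          pred[j] = i;
        }
        if (shortest[j] < lowest) {
          lowest = shortest[j];
          jLow = j;
        }
      }
      if (jLow == -1 || !R_finite(lowest))
        stop("infeasible assignment problem (no finite augmenting path)");
      scanned[jLow] = 1;
      minVal = lowest;
      if (row4col[jLow] == -1) {
        sink = jLow;
      } else {
        i = row4col[jLow];
      }
    }

    // dual updates over the scanned subtree
    u[curRow] += minVal;
    for (int r = 0; r < nr; ++r) {
      if (r != curRow && col4row[r] != -1 && scanned[col4row[r]])
        u[r] += minVal - shortest[col4row[r]];
    }
    for (int j = 0; j < nc; ++j) {
      if (scanned[j]) v[j] -= minVal - shortest[j];
    }

    // augment along the predecessor chain from the sink
    int j = sink;
    while (true) {
      int r = pred[j];
      row4col[j] = r;
      int jNext = col4row[r];
      col4row[r] = j;
      if (r == curRow) break;
      j = jNext;
    }
  }

  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) out[r] = col4row[r] + 1;
  return out;
}
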