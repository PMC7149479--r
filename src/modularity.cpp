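#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive maximum Newman-Girvan weighted modularity over all set
// partitions of the nodes (restricted-growth enumeration with incremental
// community aggregates). Intended as an oracle for small graphs; guarded
// at 13 nodes (Bell(13) ~ 2.8e7).
namespace {

struct Search {
  int n;
  const double* W;      // n x n symmetric weight matrix, zero diagonal
  std::vector<double> k;  // weighted degrees
  double two_m;
  std::vector<int> memb;
  std::vector<double> win;   // within-community weight (both orders)
  std::vector<double> dsum;  // community degree sums
  double best;

  double q_now(int ncomm) const {
    double q = 0.0;
    for (int c = 0; c < ncomm; ++c) {
      double dc = dsum[c] / two_m;
      q += win[c] / two_m - dc * dc;
    }
    return q;
  }

  void rec(int i, int ncomm) {
    if (i == n) {
      double q = q_now(ncomm);
      if (q > best) best = q;
      return;
    }
    for (int c = 0; c <= ncomm && c < n; ++c) {
      double cross = 0.0;
      for (int j = 0; j < i; ++j)
        if (memb[j] == c) cross += W[i * n + j];
      memb[i] = c;
      win[c] += 2.0 * cross;
      dsum[c] += k[i];
      rec(i + 1, std::max(ncomm, c + 1));
      win[c] -= 2.0 * cross;
      dsum[c] -= k[i];
    }
    memb[i] = -1;
  }
};

}  // namespace

// [[Rcpp::export]]
double best_partition_modularity_cpp(NumericMatrix W) {
  int n = W.nrow();
  if (n != W.ncol()) stop("weight matrix must be square");
  if (n > 13) stop("exhaustive modularity oracle is limited to 13 nodes");
  Search s;
  s.n = n;
  s.W = W.begin();
  s.k.assign(n, 0.0);
  double total = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j && W(i, j) != 0.0) stop("self-loops are not supported");
      s.k[i] += W(i, j);
      total += W(i, j);
    }
  if (total <= 0.0) stop("graph has no edges");
  s.two_m = total;  // total already counts both orders
  s.memb.assign(n, -1);
  s.win.assign(n, 0.0);
  s.dsum.assign(n, 0.0);
  s.best = -1.0;
  s.rec(0, 0);
  return s.best;
}
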