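#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Minimum-image squared distance, orthorhombic box.
static inline double mi_dist2(const double* p, const double* q,
                              const double* box) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = p[k] - q[k];
    d -= box[k] * std::round(d / box[k]);
    s += d * d;
  }
  return s;
}

// Cell-list search for pairs (i in A, j in B) with minimum-image distance
// strictly below cutoff. A and B are n x 3 coordinate matrices in nm.
// Returns a 2-column integer matrix of 1-based index pairs.
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(NumericMatrix A, NumericMatrix B,
                                NumericVector box, double cutoff) {
  const int na = A.nrow(), nb = B.nrow();
  const double bx[3] = {box[0], box[1], box[2]};
  const double cut2 = cutoff * cutoff;

  int nc[3];
  double csz[3];
  for (int k = 0; k < 3; ++k) {
    nc[k] = std::max(1, (int)std::floor(bx[k] / cutoff));
    csz[k] = bx[k] / nc[k];
  }
  const int ncells = nc[0] * nc[1] * nc[2];

  // wrap a coordinate into [0, box) and find its cell index per axis
  auto cell_of = [&](double v, int k) {
    double w = v - bx[k] * std::floor(v / bx[k]);
    int c = (int)(w / csz[k]);
    if (c >= nc[k]) c = nc[k] - 1;
    return c;
  };

  std::vector<std::vector<int> > cells(ncells);
  std::vector<double> bpos(3 * nb), apos(3 * na);
  for (int j = 0; j < nb; ++j) {
    for (int k = 0; k < 3; ++k) bpos[3 * j + k] = B(j, k);
    int cx = cell_of(B(j, 0), 0), cy = cell_of(B(j, 1), 1),
        cz = cell_of(B(j, 2), 2);
    cells[(cx * nc[1] + cy) * nc[2] + cz].push_back(j);
  }
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) apos[3 * i + k] = A(i, k);

  std::vector<int> out_i, out_j;
  std::vector<int> axis_cells[3];
  for (int i = 0; i < na; ++i) {
    // distinct neighbour cells per axis (handles nc < 3)
    for (int k = 0; k < 3; ++k) {
      axis_cells[k].clear();
      int c = cell_of(A(i, k), k);
      for (int d = -1; d <= 1; ++d) {
        int cc = ((c + d) % nc[k] + nc[k]) % nc[k];
        bool seen = false;
        for (size_t m = 0; m < axis_cells[k].size(); ++m)
          if (axis_cells[k][m] == cc) { seen = true; break; }
        if (!seen) axis_cells[k].push_back(cc);
      }
    }
    for (size_t ax = 0; ax < axis_cells[0].size(); ++ax)
      for (size_t ay = 0; ay < axis_cells[1].size(); ++ay)
        for (size_t az = 0; az < axis_cells[2].size(); ++az) {
          const std::vector<int>& cell =
            cells[(axis_cells[0][ax] * nc[1] + axis_cells[1][ay]) * nc[2] +
                  axis_cells[2][az]];
          for (size_t m = 0; m < cell.size(); ++m) {
            int j = cell[m];
            if (mi_dist2(&apos[3 * i], &bpos[3 * j], bx) < cut2) {
              out_i.push_back(i + 1);
              out_j.push_back(j + 1);
            }
          }
        }
  }

  IntegerMatrix out(out_i.size(), 2);
  for (size_t r = 0; r < out_i.size(); ++r) {
    out(r, 0) = out_i[r];
    out(r, 1) = out_j[r];
  }
  return out;
}
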