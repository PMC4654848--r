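// Hot loops of the PC-family skeleton search: partial-correlation
// conditional-independence tests and the per-order edge scans. Conditioning
// sets stay small (max_order defaults to 5), so submatrix inversion uses a
// stack-allocated Gauss-Jordan solver.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int MAX_DIM = 16; // conditioning size + 2, generous bound
static const double R_BOUND = 1.0 - 1e-12;

// In-place Gauss-Jordan inversion with partial pivoting; a is m x m
// row-major, overwritten; inv receives the inverse. Returns false when
// numerically singular.
static bool inv_small(double* a, int m, double* inv) {
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < m; ++c) inv[r * m + c] = (r == c) ? 1.0 : 0.0;
  for (int col = 0; col < m; ++col) {
    int piv = col;
    double best = std::fabs(a[col * m + col]);
    for (int r = col + 1; r < m; ++r) {
      double v = std::fabs(a[r * m + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-12) return false;
    if (piv != col) {
      for (int c = 0; c < m; ++c) {
        std::swap(a[piv * m + c], a[col * m + c]);
        std::swap(inv[piv * m + c], inv[col * m + c]);
      }
    }
    double d = a[col * m + col];
    for (int c = 0; c < m; ++c) { a[col * m + c] /= d; inv[col * m + c] /= d; }
    for (int r = 0; r < m; ++r) {
      if (r == col) continue;
      double f = a[r * m + col];
      if (f == 0.0) continue;
      for (int c = 0; c < m; ++c) {
        a[r * m + c] -= f * a[col * m + c];
        inv[r * m + c] -= f * inv[col * m + c];
      }
    }
  }
  return true;
}

// Partial correlation of idx[0], idx[1] given idx[2..m-1], from the p x p
// correlation matrix R (column-major, as stored by R). NaN when singular.
static double pcor_idx(const double* R, int p, const int* idx, int m) {
  if (m == 2) return R[idx[0] + (size_t)p * idx[1]];
  double A[MAX_DIM * MAX_DIM], Ainv[MAX_DIM * MAX_DIM];
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < m; ++c)
      A[r * m + c] = R[idx[r] + (size_t)p * idx[c]];
  if (!inv_small(A, m, Ainv)) return NA_REAL;
  double den = Ainv[0] * Ainv[m + 1];
  if (!(den > 0)) return NA_REAL;
  double r = -Ainv[1] / std::sqrt(den);
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  return r;
}

// Decision rule: independent iff |fisher_z(r)| * sqrt(n - ell - 3) <= t.
// Boundary conventions: NaN (singular) and |r| ~ 1 are dependent; when
// n - ell - 3 < 1 no valid statistic exists, so the pair stays dependent.
static bool ci_indep(double r, int n, int ell, double t) {
  if (ISNAN(r)) return false;
  if (std::fabs(r) >= R_BOUND) return false;
  double df = (double)n - ell - 3.0;
  if (df < 1.0) return false;
  double z = 0.5 * std::log((1.0 + r) / (1.0 - r));
  return std::fabs(z) * std::sqrt(df) <= t;
}

// Depth-first enumeration of size-ell conditioning sets in lexicographic
// order with shared prefixes: conditioning on one variable at a time updates
// the conditional correlation matrix of the pair and the remaining
// candidates via the partial-correlation recursion (algebraically identical
// to submatrix inversion), so each tested subset costs O(1) at the leaves
// instead of a fresh matrix inversion.
//
// M: (csize+2) x (csize+2) row-major conditional correlation matrix over
// [a, b, cand[0..csize-1]] given `prefix`. Degenerate conditioning
// (|r| -> 1) yields NaN entries, which the decision rule treats as
// dependent.
static bool dfs_sep(const double* M, int csize, const int* cand, int ell_rem,
                    int ell_total, int n, double t, std::vector<int>& prefix,
                    double* ws, size_t stride, long long& ntests,
                    std::vector<int>& sep, const char* dup, int n_outside) {
  int dim = csize + 2;
  if (dup && n_outside == 0) {
    // every completion drawn purely from `dup` repeats a test already done
    // from the other endpoint; descend only if an outside candidate remains
    bool any_outside = false;
    for (int k = 0; k < csize; ++k)
      if (!dup[cand[k]]) { any_outside = true; break; }
    if (!any_outside) return false;
  }
  if (ell_rem == 1) {
    double rab = M[1]; // M[0, 1]
    for (int k = 0; k < csize; ++k) {
      if (dup && n_outside == 0 && dup[cand[k]]) continue; // duplicate subset
      int zi = 2 + k;
      ++ntests;
      double raz = M[zi];           // M[0, zi]
      double rbz = M[dim + zi];     // M[1, zi]
      double den = (1.0 - raz * raz) * (1.0 - rbz * rbz);
      double r = NA_REAL;
      if (den > 1e-24) {
        r = (rab - raz * rbz) / std::sqrt(den);
        if (r > 1.0) r = 1.0;
        if (r < -1.0) r = -1.0;
      }
      if (ci_indep(r, n, ell_total, t)) {
        sep = prefix;
        sep.push_back(cand[k]);
        return true;
      }
    }
    return false;
  }
  if (ell_rem == 2) {
    // last branching level: the leaf test only reads the pair's two rows, so
    // condition those rows on z1 directly instead of building the full
    // conditional matrix
    double rab = M[1];
    for (int k = 0; k < csize; ++k) {
      int rem = csize - k - 1;
      if (rem < 1) break;
      int zi = 2 + k;
      double raz1 = M[zi], rbz1 = M[dim + zi];
      double da = 1.0 - raz1 * raz1, db = 1.0 - rbz1 * rbz1;
      double rab2 = std::numeric_limits<double>::quiet_NaN();
      if (da * db > 1e-24) {
        rab2 = (rab - raz1 * rbz1) / std::sqrt(da * db);
        if (rab2 > 1.0) rab2 = 1.0;
        if (rab2 < -1.0) rab2 = -1.0;
      }
      bool z1_in_dup = dup && dup[cand[k]];
      for (int q = k + 1; q < csize; ++q) {
        if (dup && n_outside == 0 && z1_in_dup && dup[cand[q]]) continue;
        int qi = 2 + q;
        ++ntests;
        double rz = M[zi * dim + qi]; // r(z1, z2)
        double dz = 1.0 - rz * rz;
        double ra = std::numeric_limits<double>::quiet_NaN();
        double rb = ra, r = ra;
        if (da * dz > 1e-24) {
          ra = (M[qi] - raz1 * rz) / std::sqrt(da * dz);
          if (ra > 1.0) ra = 1.0;
          if (ra < -1.0) ra = -1.0;
        }
        if (db * dz > 1e-24) {
          rb = (M[dim + qi] - rbz1 * rz) / std::sqrt(db * dz);
          if (rb > 1.0) rb = 1.0;
          if (rb < -1.0) rb = -1.0;
        }
        if (!ISNAN(rab2) && !ISNAN(ra) && !ISNAN(rb)) {
          double den = (1.0 - ra * ra) * (1.0 - rb * rb);
          if (den > 1e-24) {
            r = (rab2 - ra * rb) / std::sqrt(den);
            if (r > 1.0) r = 1.0;
            if (r < -1.0) r = -1.0;
          }
        }
        if (ci_indep(r, n, ell_total, t)) {
          sep = prefix;
          sep.push_back(cand[k]);
          sep.push_back(cand[q]);
          return true;
        }
      }
    }
    return false;
  }
  for (int k = 0; k < csize; ++k) {
    int rem = csize - k - 1;
    if (rem < ell_rem - 1) break;
    int zi = 2 + k;
    int dim2 = rem + 2;
    double* M2 = ws;
    for (int x = 0; x < dim2; ++x) {
      int ox = (x < 2) ? x : (zi + 1 + (x - 2));
      double rxz = M[ox * dim + zi];
      double dx = 1.0 - rxz * rxz;
      for (int y = x; y < dim2; ++y) {
        int oy = (y < 2) ? y : (zi + 1 + (y - 2));
        double ryz = M[oy * dim + zi];
        double den = dx * (1.0 - ryz * ryz);
        double v;
        if (den > 1e-24) {
          v = (M[ox * dim + oy] - rxz * ryz) / std::sqrt(den);
          if (v > 1.0) v = 1.0;
          if (v < -1.0) v = -1.0;
        } else {
          v = std::numeric_limits<double>::quiet_NaN();
        }
        M2[x * dim2 + y] = v;
        M2[y * dim2 + x] = v;
      }
    }
    prefix.push_back(cand[k]);
    int n_out2 = n_outside + ((dup && !dup[cand[k]]) ? 1 : 0);
    if (dfs_sep(M2, rem, cand + k + 1, ell_rem - 1, ell_total, n, t, prefix,
                ws + stride, stride, ntests, sep, dup, n_out2))
      return true;
    prefix.pop_back();
  }
  return false;
}

// First size-ell subset of nbrs (already in ordering order, enumerated
// lexicographically) that separates a and b; fills sep and returns true.
static bool find_sepset(const double* R, int p, int n, double t, int a, int b,
                        const std::vector<int>& nbrs, int ell, long long& ntests,
                        std::vector<int>& sep, const char* dup = nullptr) {
  if (ell == 0) {
    ++ntests;
    double r = R[a + (size_t)p * b];
    if (ci_indep(r, n, 0, t)) { sep.clear(); return true; }
    return false;
  }
  int m = (int)nbrs.size();
  if (m < ell) return false;
  int dim = m + 2;
  size_t stride = (size_t)dim * dim;
  std::vector<double> ws(stride * (size_t)(ell + 1));
  // base matrix over [a, b, nbrs...]
  double* M = ws.data();
  int ox;
  for (int x = 0; x < dim; ++x) {
    ox = (x < 2) ? (x == 0 ? a : b) : nbrs[x - 2];
    for (int y = 0; y < dim; ++y) {
      int oy = (y < 2) ? (y == 0 ? a : b) : nbrs[y - 2];
      M[x * dim + y] = R[ox + (size_t)p * oy];
    }
  }
  std::vector<int> prefix;
  prefix.reserve(ell);
  sep.clear();
  return dfs_sep(M, m, nbrs.data(), ell, ell, n, t, prefix, ws.data() + stride,
                 stride, ntests, sep, dup, 0);
}

// Neighbours of a (excluding b) in ordering order.
static void gather_nbrs(const int* adj, int p, const IntegerVector& ord,
                        int a, int b, std::vector<int>& nbrs) {
  nbrs.clear();
  for (int k = 0; k < p; ++k) {
    int v = ord[k];
    if (v != b && v != a && adj[a + (size_t)p * v]) nbrs.push_back(v);
  }
}

static List scan_result(LogicalMatrix adj, long long ntests,
                        const std::vector<int>& rem_i,
                        const std::vector<int>& rem_j,
                        const std::vector<std::vector<int>>& seps) {
  int nrem = (int)rem_i.size();
  IntegerVector ri(nrem), rj(nrem);
  List sl(nrem);
  for (int k = 0; k < nrem; ++k) {
    ri[k] = rem_i[k] + 1;
    rj[k] = rem_j[k] + 1;
    IntegerVector s((int)seps[k].size());
    for (int q = 0; q < (int)seps[k].size(); ++q) s[q] = seps[k][q] + 1;
    sl[k] = s;
  }
  return List::create(
      _["adj"] = adj, _["n_tests"] = (double)ntests,
      _["removed_i"] = ri, _["removed_j"] = rj, _["sepsets"] = sl);
}

// One full order-ell pass of the classic PC scan: ordered pairs (a, b)
// following `ord` (0-based permutation), conditioning sets from the current
// neighbours of a, immediate adjacency updates.
// [[Rcpp::export]]
List pc_scan_order_cpp(NumericMatrix R, int n, LogicalMatrix adj_in, int ell,
                       double t, IntegerVector ord) {
  int p = R.nrow();
  LogicalMatrix adj = clone(adj_in);
  int* A = adj.begin();
  const double* Rp = R.begin();
  long long ntests = 0;
  std::vector<int> nbrs, sep;
  std::vector<int> rem_i, rem_j;
  std::vector<std::vector<int>> seps;
  nbrs.reserve(p);
  for (int ai = 0; ai < p; ++ai) {
    int a = ord[ai];
    for (int bi = 0; bi < p; ++bi) {
      int b = ord[bi];
      if (a == b || !A[a + (size_t)p * b]) continue;
      gather_nbrs(A, p, ord, a, b, nbrs);
      if ((int)nbrs.size() < ell) continue;
      if (find_sepset(Rp, p, n, t, a, b, nbrs, ell, ntests, sep)) {
        A[a + (size_t)p * b] = 0;
        A[b + (size_t)p * a] = 0;
        rem_i.push_back(a);
        rem_j.push_back(b);
        seps.push_back(sep);
      }
    }
  }
  return scan_result(adj, ntests, rem_i, rem_j, seps);
}

// One order-ell pass over an explicit edge list (the tier schedule of
// PriorPC): edges are visited in the given row order; for each edge still
// present, conditioning sets are drawn first from the neighbours of the
// first endpoint, then from the second, in the shared working graph.
// [[Rcpp::export]]
List tier_scan_cpp(NumericMatrix R, int n, LogicalMatrix adj_in,
                   IntegerMatrix edges, int ell, double t,
                   IntegerVector ord) {
  int p = R.nrow();
  LogicalMatrix adj = clone(adj_in);
  int* A = adj.begin();
  const double* Rp = R.begin();
  long long ntests = 0;
  std::vector<int> nbrs, sep;
  std::vector<int> rem_i, rem_j;
  std::vector<std::vector<int>> seps;
  nbrs.reserve(p);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    if (!A[a + (size_t)p * b]) continue;
    bool removed = false;
    bool side_a_ran = false;
    std::vector<char> dup_mask(p, 0);
    for (int side = 0; side < 2 && !removed; ++side) {
      int x = side == 0 ? a : b;
      int y = side == 0 ? b : a;
      gather_nbrs(A, p, ord, x, y, nbrs);
      if ((int)nbrs.size() < ell) continue;
      // conditioning sets fully contained in the first side's neighbour set
      // were already tested there (partial correlation is symmetric in the
      // pair), so the second side skips them
      const char* dup = nullptr;
      if (side == 1 && side_a_ran) {
        dup = dup_mask.data();
      } else if (side == 0) {
        side_a_ran = true;
        for (int q = 0; q < (int)nbrs.size(); ++q) dup_mask[nbrs[q]] = 1;
      }
      if (find_sepset(Rp, p, n, t, x, y, nbrs, ell, ntests, sep, dup)) {
        A[a + (size_t)p * b] = 0;
        A[b + (size_t)p * a] = 0;
        rem_i.push_back(x);
        rem_j.push_back(y);
        seps.push_back(sep);
        removed = true;
      }
    }
  }
  return scan_result(adj, ntests, rem_i, rem_j, seps);
}

// Partial correlation from a correlation (or covariance) matrix; i, j, Y are
// 1-based indices. Exposed for cross-checking the R implementation.
// [[Rcpp::export]]
double pcor_from_cor_cpp(NumericMatrix R, int i, int j, IntegerVector Y) {
  int m = Y.size() + 2;
  if (m > MAX_DIM) stop("conditioning set too large");
  int idx[MAX_DIM];
  idx[0] = i - 1;
  idx[1] = j - 1;
  for (int k = 0; k < Y.size(); ++k) idx[2 + k] = Y[k] - 1;
  return pcor_idx(R.begin(), R.nrow(), idx, m);
}
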