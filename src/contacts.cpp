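#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lattice vectors are ROWS of the 3x3 box matrix: cartesian x = f %*% M.

static void invert3(const double M[3][3], double Minv[3][3]) {
  double det =
    M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
    M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
    M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  if (std::fabs(det) < 1e-12)
    stop("degenerate box: lattice vectors are coplanar");
  double id = 1.0 / det;
  Minv[0][0] =  (M[1][1] * M[2][2] - M[1][2] * M[2][1]) * id;
  Minv[0][1] = -(M[0][1] * M[2][2] - M[0][2] * M[2][1]) * id;
  Minv[0][2] =  (M[0][1] * M[1][2] - M[0][2] * M[1][1]) * id;
  Minv[1][0] = -(M[1][0] * M[2][2] - M[1][2] * M[2][0]) * id;
  Minv[1][1] =  (M[0][0] * M[2][2] - M[0][2] * M[2][0]) * id;
  Minv[1][2] = -(M[0][0] * M[1][2] - M[0][2] * M[1][0]) * id;
  Minv[2][0] =  (M[1][0] * M[2][1] - M[1][1] * M[2][0]) * id;
  Minv[2][1] = -(M[0][0] * M[2][1] - M[0][1] * M[2][0]) * id;
  Minv[2][2] =  (M[0][0] * M[1][1] - M[0][1] * M[1][0]) * id;
}

static bool is_orthorhombic(const double M[3][3]) {
  return std::fabs(M[0][1]) < 1e-10 && std::fabs(M[0][2]) < 1e-10 &&
         std::fabs(M[1][0]) < 1e-10 && std::fabs(M[1][2]) < 1e-10 &&
         std::fabs(M[2][0]) < 1e-10 && std::fabs(M[2][1]) < 1e-10;
}

// Minimum-image displacement b - a. Fractional rounding gives the candidate
// image; for non-orthorhombic cells the 27 neighbouring images of that
// candidate are searched as well (rounding alone can miss the true image in
// skewed cells such as the truncated octahedron).
static void mi_disp(const double M[3][3], const double Minv[3][3], bool ortho,
                    const double *a, const double *b, double *out) {
  double d[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double f[3], n[3];
  for (int j = 0; j < 3; ++j)
    f[j] = d[0] * Minv[0][j] + d[1] * Minv[1][j] + d[2] * Minv[2][j];
  for (int j = 0; j < 3; ++j) n[j] = std::nearbyint(f[j]);
  double d0[3];
  for (int j = 0; j < 3; ++j)
    d0[j] = d[j] - (n[0] * M[0][j] + n[1] * M[1][j] + n[2] * M[2][j]);
  if (ortho) {
    out[0] = d0[0]; out[1] = d0[1]; out[2] = d0[2];
    return;
  }
  double best = d0[0] * d0[0] + d0[1] * d0[1] + d0[2] * d0[2];
  out[0] = d0[0]; out[1] = d0[1]; out[2] = d0[2];
  for (int s0 = -1; s0 <= 1; ++s0)
    for (int s1 = -1; s1 <= 1; ++s1)
      for (int s2 = -1; s2 <= 1; ++s2) {
        if (s0 == 0 && s1 == 0 && s2 == 0) continue;
        double dd[3];
        for (int j = 0; j < 3; ++j)
          dd[j] = d0[j] - (s0 * M[0][j] + s1 * M[1][j] + s2 * M[2][j]);
        double r2 = dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2];
        if (r2 < best) {
          best = r2;
          out[0] = dd[0]; out[1] = dd[1]; out[2] = dd[2];
        }
      }
}

static void as_c_mat(const NumericMatrix &box, double M[3][3]) {
  if (box.nrow() != 3 || box.ncol() != 3)
    stop("box must be a 3x3 matrix of lattice vectors (rows)");
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) M[i][j] = box(i, j);
}

// [[Rcpp::export]]
NumericMatrix mi_disp_cpp(NumericMatrix box, NumericMatrix a, NumericMatrix b) {
  double M[3][3], Minv[3][3];
  as_c_mat(box, M);
  invert3(M, Minv);
  bool ortho = is_orthorhombic(M);
  int n = a.nrow();
  if (b.nrow() != n) stop("a and b must have the same number of rows");
  NumericMatrix out(n, 3);
  double pa[3], pb[3], d[3];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) { pa[j] = a(i, j); pb[j] = b(i, j); }
    mi_disp(M, Minv, ortho, pa, pb, d);
    for (int j = 0; j < 3; ++j) out(i, j) = d[j];
  }
  return out;
}

// Minimum-image distances from one point to each row of `set`.
// [[Rcpp::export]]
NumericVector mi_dist_to_set_cpp(NumericMatrix box, NumericVector p,
                                 NumericMatrix set) {
  double M[3][3], Minv[3][3];
  as_c_mat(box, M);
  invert3(M, Minv);
  bool ortho = is_orthorhombic(M);
  int n = set.nrow();
  NumericVector out(n);
  double a[3] = { p[0], p[1], p[2] }, b[3], d[3];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) b[j] = set(i, j);
    mi_disp(M, Minv, ortho, a, b, d);
    out[i] = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  }
  return out;
}

static IntegerMatrix edges_from_counts(const std::vector<int> &cnt, int nmol,
                                       int min_contacts) {
  std::vector<std::pair<int, int> > ed;
  for (int i = 0; i < nmol; ++i)
    for (int j = i + 1; j < nmol; ++j)
      if (cnt[(size_t)i * nmol + j] >= min_contacts)
        ed.push_back(std::make_pair(i + 1, j + 1));
  IntegerMatrix out((int)ed.size(), 2);
  for (size_t k = 0; k < ed.size(); ++k) {
    out(k, 0) = ed[k].first;
    out(k, 1) = ed[k].second;
  }
  return out;
}

// All-pairs contact search with explicit 27-image minimum. molid is 1-based.
// [[Rcpp::export]]
IntegerMatrix contact_edges_brute_cpp(NumericMatrix coords, IntegerVector molid,
                                      NumericMatrix box, double cutoff,
                                      int nmol, int min_contacts) {
  double M[3][3], Minv[3][3];
  as_c_mat(box, M);
  invert3(M, Minv);
  bool ortho = is_orthorhombic(M);
  int nat = coords.nrow();
  double cut2 = cutoff * cutoff;
  std::vector<int> cnt((size_t)nmol * nmol, 0);
  double a[3], b[3], d[3];
  for (int i = 0; i < nat; ++i) {
    int mi = molid[i] - 1;
    for (int j = i + 1; j < nat; ++j) {
      int mj = molid[j] - 1;
      if (mi == mj) continue;
      int lo = mi < mj ? mi : mj, hi = mi < mj ? mj : mi;
      size_t key = (size_t)lo * nmol + hi;
      if (cnt[key] >= min_contacts) continue;
      for (int k = 0; k < 3; ++k) { a[k] = coords(i, k); b[k] = coords(j, k); }
      mi_disp(M, Minv, ortho, a, b, d);
      if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] <= cut2) cnt[key]++;
    }
  }
  return edges_from_counts(cnt, nmol, min_contacts);
}

// Perpendicular widths of the cell (distance between opposite faces).
// [[Rcpp::export]]
NumericVector box_widths_cpp(NumericMatrix box) {
  double M[3][3];
  as_c_mat(box, M);
  double vol =
    M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
    M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
    M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  vol = std::fabs(vol);
  NumericVector w(3);
  for (int i = 0; i < 3; ++i) {
    int j = (i + 1) % 3, k = (i + 2) % 3;
    double cx = M[j][1] * M[k][2] - M[j][2] * M[k][1];
    double cy = M[j][2] * M[k][0] - M[j][0] * M[k][2];
    double cz = M[j][0] * M[k][1] - M[j][1] * M[k][0];
    double area = std::sqrt(cx * cx + cy * cy + cz * cz);
    w[i] = vol / area;
  }
  return w;
}

// Cell-list contact search. Cells are built in fractional space; pairs are
// gathered from the 27 neighbouring cells and distances refined with the
// minimum-image displacement. Requires >= 3 cells per lattice direction.
// [[Rcpp::export]]
IntegerMatrix contact_edges_cell_cpp(NumericMatrix coords, IntegerVector molid,
                                     NumericMatrix box, double cutoff,
                                     int nmol, int min_contacts) {
  double M[3][3], Minv[3][3];
  as_c_mat(box, M);
  invert3(M, Minv);
  bool ortho = is_orthorhombic(M);
  NumericVector w = box_widths_cpp(box);
  int nc[3];
  for (int i = 0; i < 3; ++i) {
    nc[i] = (int)std::floor(w[i] / cutoff);
    if (nc[i] > 64) nc[i] = 64;
    if (nc[i] < 3)
      stop("cutoff too large for cell-list search in this box; use method = \"brute\"");
  }
  int nat = coords.nrow();
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int> > cells(ncell);
  std::vector<int> ci(nat), cj(nat), ck(nat);
  for (int i = 0; i < nat; ++i) {
    double f[3];
    for (int j = 0; j < 3; ++j) {
      f[j] = coords(i, 0) * Minv[0][j] + coords(i, 1) * Minv[1][j] +
             coords(i, 2) * Minv[2][j];
      f[j] -= std::floor(f[j]);
      if (f[j] >= 1.0) f[j] = 0.0;
    }
    int c0 = std::min((int)(f[0] * nc[0]), nc[0] - 1);
    int c1 = std::min((int)(f[1] * nc[1]), nc[1] - 1);
    int c2 = std::min((int)(f[2] * nc[2]), nc[2] - 1);
    ci[i] = c0; cj[i] = c1; ck[i] = c2;
    cells[(c0 * nc[1] + c1) * nc[2] + c2].push_back(i);
  }
  double cut2 = cutoff * cutoff;
  std::vector<int> cnt((size_t)nmol * nmol, 0);
  double a[3], b[3], d[3];
  for (int i = 0; i < nat; ++i) {
    int mi = molid[i] - 1;
    for (int d0 = -1; d0 <= 1; ++d0)
      for (int d1 = -1; d1 <= 1; ++d1)
        for (int d2 = -1; d2 <= 1; ++d2) {
          int e0 = (ci[i] + d0 + nc[0]) % nc[0];
          int e1 = (cj[i] + d1 + nc[1]) % nc[1];
          int e2 = (ck[i] + d2 + nc[2]) % nc[2];
          const std::vector<int> &cell = cells[(e0 * nc[1] + e1) * nc[2] + e2];
          for (size_t q = 0; q < cell.size(); ++q) {
            int j = cell[q];
            if (j <= i) continue;
            int mj = molid[j] - 1;
            if (mi == mj) continue;
            int lo = mi < mj ? mi : mj, hi = mi < mj ? mj : mi;
            size_t key = (size_t)lo * nmol + hi;
            if (cnt[key] >= min_contacts) continue;
            for (int k = 0; k < 3; ++k) {
              a[k] = coords(i, k);
              b[k] = coords(j, k);
            }
            mi_disp(M, Minv, ortho, a, b, d);
            if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] <= cut2) cnt[key]++;
          }
        }
  }
  return edges_from_counts(cnt, nmol, min_contacts);
}
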