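// Low-level P1 finite-element kernels for the shock-field Laplace solver.
// All geometry is in mm; conductivity tensors arrive in S/mm so that
// assembled conductances are in S and nodal reactions in A when potentials
// are in V.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Signed volume of tetrahedra (positive for positively oriented elements).
// [[Rcpp::export]]
NumericVector tet_volumes_cpp(const NumericMatrix& nodes,
                              const IntegerMatrix& elems) {
  const int m = elems.nrow();
  NumericVector vol(m);
  for (int e = 0; e < m; ++e) {
    const int a = elems(e, 0) - 1, b = elems(e, 1) - 1,
              c = elems(e, 2) - 1, d = elems(e, 3) - 1;
    const double x1 = nodes(b, 0) - nodes(a, 0), y1 = nodes(b, 1) - nodes(a, 1), z1 = nodes(b, 2) - nodes(a, 2);
    const double x2 = nodes(c, 0) - nodes(a, 0), y2 = nodes(c, 1) - nodes(a, 1), z2 = nodes(c, 2) - nodes(a, 2);
    const double x3 = nodes(d, 0) - nodes(a, 0), y3 = nodes(d, 1) - nodes(a, 1), z3 = nodes(d, 2) - nodes(a, 2);
    vol[e] = (x1 * (y2 * z3 - z2 * y3) - y1 * (x2 * z3 - z2 * x3) +
              z1 * (x2 * y3 - y2 * x3)) / 6.0;
  }
  return vol;
}

// Gradients of the four linear shape functions of one tet, written into g[4][3].
// Returns the signed volume.
static inline double shape_gradients(const NumericMatrix& nodes, const IntegerMatrix& elems,
                                     int e, double g[4][3]) {
  const int n0 = elems(e, 0) - 1, n1 = elems(e, 1) - 1,
            n2 = elems(e, 2) - 1, n3 = elems(e, 3) - 1;
  const double x0 = nodes(n0, 0), y0 = nodes(n0, 1), z0 = nodes(n0, 2);
  double J[3][3] = {
    {nodes(n1, 0) - x0, nodes(n2, 0) - x0, nodes(n3, 0) - x0},
    {nodes(n1, 1) - y0, nodes(n2, 1) - y0, nodes(n3, 1) - y0},
    {nodes(n1, 2) - z0, nodes(n2, 2) - z0, nodes(n3, 2) - z0}};
  const double det =
    J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
    J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
    J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
  // inverse transpose of J times reference gradients
  double inv[3][3];
  inv[0][0] = (J[1][1] * J[2][2] - J[1][2] * J[2][1]) / det;
  inv[0][1] = (J[0][2] * J[2][1] - J[0][1] * J[2][2]) / det;
  inv[0][2] = (J[0][1] * J[1][2] - J[0][2] * J[1][1]) / det;
  inv[1][0] = (J[1][2] * J[2][0] - J[1][0] * J[2][2]) / det;
  inv[1][1] = (J[0][0] * J[2][2] - J[0][2] * J[2][0]) / det;
  inv[1][2] = (J[0][2] * J[1][0] - J[0][0] * J[1][2]) / det;
  inv[2][0] = (J[1][0] * J[2][1] - J[1][1] * J[2][0]) / det;
  inv[2][1] = (J[0][1] * J[2][0] - J[0][0] * J[2][1]) / det;
  inv[2][2] = (J[0][0] * J[1][1] - J[0][1] * J[1][0]) / det;
  // gradient of shape i (i=1..3) is row i of inv; shape 0 is minus their sum
  for (int k = 0; k < 3; ++k) {
    g[1][k] = inv[0][k];
    g[2][k] = inv[1][k];
    g[3][k] = inv[2][k];
    g[0][k] = -(inv[0][k] + inv[1][k] + inv[2][k]);
  }
  return det / 6.0;
}

// Element stiffness triplets for the anisotropic Laplacian.
// tensors: m x 6 matrix with per-element symmetric conductivity tensor
// components (xx, yy, zz, xy, xz, yz) in S/mm.
// [[Rcpp::export]]
List assemble_triplets_cpp(const NumericMatrix& nodes,
                           const IntegerMatrix& elems,
                           const NumericMatrix& tensors) {
  const int m = elems.nrow();
  const R_xlen_t nt = (R_xlen_t)m * 16;
  IntegerVector ti(nt), tj(nt);
  NumericVector tx(nt);
  double g[4][3];
  R_xlen_t pos = 0;
  for (int e = 0; e < m; ++e) {
    const double vol = shape_gradients(nodes, elems, e, g);
    const double sxx = tensors(e, 0), syy = tensors(e, 1), szz = tensors(e, 2);
    const double sxy = tensors(e, 3), sxz = tensors(e, 4), syz = tensors(e, 5);
    double sg[4][3]; // sigma * grad
    for (int a = 0; a < 4; ++a) {
      sg[a][0] = sxx * g[a][0] + sxy * g[a][1] + sxz * g[a][2];
      sg[a][1] = sxy * g[a][0] + syy * g[a][1] + syz * g[a][2];
      sg[a][2] = sxz * g[a][0] + syz * g[a][1] + szz * g[a][2];
    }
    for (int a = 0; a < 4; ++a) {
      for (int b = 0; b < 4; ++b) {
        const double kab = vol * (g[a][0] * sg[b][0] + g[a][1] * sg[b][1] +
                                  g[a][2] * sg[b][2]);
        ti[pos] = elems(e, a);
        tj[pos] = elems(e, b);
        tx[pos] = kab;
        ++pos;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// Assemble the stiffness matrix directly in compressed sparse column form
// (0-based p/i slots of a dgCMatrix).  Two passes: count raw entries per
// column, scatter, then sort and merge duplicates column-wise (columns hold
// a few hundred raw entries at most, so the local sorts are cache-friendly).
// [[Rcpp::export]]
List assemble_csc_cpp(const NumericMatrix& nodes,
                      const IntegerMatrix& elems,
                      const NumericMatrix& tensors) {
  const int n = nodes.nrow();
  const int m = elems.nrow();
  // persistent scratch: page-fault cost of the large raw-entry buffers is
  // paid once per session, not once per assembly
  static std::vector<long long> colcnt, colptr, fill;
  static std::vector<int> rows;
  static std::vector<double> vals;
  colcnt.assign(n + 1, 0);
  for (int e = 0; e < m; ++e)
    for (int b = 0; b < 4; ++b)
      colcnt[elems(e, b)] += 4; // elems is 1-based: counts land in col+1 slot
  colptr.assign(n + 1, 0);
  for (int c = 0; c < n; ++c) colptr[c + 1] = colptr[c] + colcnt[c + 1];
  const long long nraw = colptr[n];
  if ((long long)rows.size() < nraw) rows.resize(nraw);
  if ((long long)vals.size() < nraw) vals.resize(nraw);
  fill.assign(colptr.begin(), colptr.end() - 1);

  double g[4][3];
  for (int e = 0; e < m; ++e) {
    const double vol = shape_gradients(nodes, elems, e, g);
    const double sxx = tensors(e, 0), syy = tensors(e, 1), szz = tensors(e, 2);
    const double sxy = tensors(e, 3), sxz = tensors(e, 4), syz = tensors(e, 5);
    double sg[4][3];
    for (int a = 0; a < 4; ++a) {
      sg[a][0] = sxx * g[a][0] + sxy * g[a][1] + sxz * g[a][2];
      sg[a][1] = sxy * g[a][0] + syy * g[a][1] + syz * g[a][2];
      sg[a][2] = sxz * g[a][0] + syz * g[a][1] + szz * g[a][2];
    }
    for (int b = 0; b < 4; ++b) {
      const int col = elems(e, b) - 1;
      for (int a = 0; a < 4; ++a) {
        const double kab = vol * (g[a][0] * sg[b][0] + g[a][1] * sg[b][1] +
                                  g[a][2] * sg[b][2]);
        const long long pos = fill[col]++;
        rows[pos] = elems(e, a) - 1;
        vals[pos] = kab;
      }
    }
  }

  // sort + merge each column
  static std::vector<int> out_i;
  static std::vector<double> out_x;
  out_i.clear();
  out_x.clear();
  out_i.reserve((size_t)n * 16);
  out_x.reserve((size_t)n * 16);
  IntegerVector p_out(n + 1);
  std::vector<std::pair<int, double> > buf;
  for (int c = 0; c < n; ++c) {
    const long long lo = colptr[c], hi = colptr[c + 1];
    buf.clear();
    for (long long k = lo; k < hi; ++k)
      buf.push_back(std::make_pair(rows[k], vals[k]));
    std::sort(buf.begin(), buf.end());
    for (size_t k = 0; k < buf.size(); ++k) {
      if (!out_i.empty() && (long long)out_i.size() > (long long)p_out[c] &&
          out_i.back() == buf[k].first) {
        out_x.back() += buf[k].second;
      } else {
        out_i.push_back(buf[k].first);
        out_x.push_back(buf[k].second);
      }
    }
    p_out[c + 1] = (int)out_i.size();
  }
  return List::create(_["p"] = p_out,
                      _["i"] = IntegerVector(out_i.begin(), out_i.end()),
                      _["x"] = NumericVector(out_x.begin(), out_x.end()));
}

// Per-element potential gradient (V/mm), m x 3.
// [[Rcpp::export]]
NumericMatrix elem_gradients_cpp(const NumericMatrix& nodes,
                                 const IntegerMatrix& elems,
                                 const NumericVector& u) {
  const int m = elems.nrow();
  NumericMatrix grad(m, 3);
  double g[4][3];
  for (int e = 0; e < m; ++e) {
    shape_gradients(nodes, elems, e, g);
    double gx = 0, gy = 0, gz = 0;
    for (int a = 0; a < 4; ++a) {
      const double ua = u[elems(e, a) - 1];
      gx += g[a][0] * ua;
      gy += g[a][1] * ua;
      gz += g[a][2] * ua;
    }
    grad(e, 0) = gx;
    grad(e, 1) = gy;
    grad(e, 2) = gz;
  }
  return grad;
}

// One Gauss-Seidel sweep on a symmetric CSC matrix (columns double as rows).
// u is updated in place; rows with mask == TRUE are skipped (Dirichlet,
// value held at whatever u currently carries, normally 0 in the reduced
// homogeneous system).
// [[Rcpp::export]]
void gs_sweep_cpp(const IntegerVector& p, const IntegerVector& i,
                  const NumericVector& x, const NumericVector& b,
                  NumericVector& u, const LogicalVector& mask,
                  const bool forward) {
  const int n = p.size() - 1;
  const int start = forward ? 0 : n - 1;
  const int stop = forward ? n : -1;
  const int step = forward ? 1 : -1;
  for (int r = start; r != stop; r += step) {
    if (mask[r]) continue;
    double diag = 0.0, sum = b[r];
    for (int k = p[r]; k < p[r + 1]; ++k) {
      const int c = i[k];
      if (c == r) diag = x[k];
      else sum -= x[k] * u[c];
    }
    if (diag != 0.0) u[r] = sum / diag;
  }
}

// y = A x for symmetric CSC with Dirichlet masking: masked entries of the
// input are treated as zero and masked rows of the output are zeroed.
// [[Rcpp::export]]
NumericVector masked_matvec_cpp(const IntegerVector& p, const IntegerVector& i,
                                const NumericVector& x, const NumericVector& v,
                                const LogicalVector& mask) {
  const int n = p.size() - 1;
  NumericVector y(n);
  for (int col = 0; col < n; ++col) {
    const double vc = mask[col] ? 0.0 : v[col];
    if (vc == 0.0) continue;
    for (int k = p[col]; k < p[col + 1]; ++k) y[i[k]] += x[k] * vc;
  }
  for (int r = 0; r < n; ++r) if (mask[r]) y[r] = 0.0;
  return y;
}

// For each element, count how many of its four nodes are flagged.
// [[Rcpp::export]]
IntegerVector elem_node_counts_cpp(const IntegerMatrix& elems,
                                   const LogicalVector& flag) {
  const int m = elems.nrow();
  IntegerVector cnt(m);
  for (int e = 0; e < m; ++e) {
    int c = 0;
    for (int a = 0; a < 4; ++a) if (flag[elems(e, a) - 1]) ++c;
    cnt[e] = c;
  }
  return cnt;
}

// Volume-weighted accumulation of element gradients onto a subset of nodes.
// Returns nodes x 4 matrix: weighted sums of (gx, gy, gz) and total weight.
// elem_sel: logical, elements that participate; node_map: 1-based index into
// the output rows for each mesh node, 0 if the node is not requested.
// [[Rcpp::export]]
NumericMatrix accumulate_nodal_gradients_cpp(const IntegerMatrix& elems,
                                             const NumericMatrix& grad,
                                             const NumericVector& vol,
                                             const LogicalVector& elem_sel,
                                             const IntegerVector& node_map,
                                             const int n_out) {
  NumericMatrix out(n_out, 4);
  const int m = elems.nrow();
  for (int e = 0; e < m; ++e) {
    if (!elem_sel[e]) continue;
    const double w = vol[e];
    for (int a = 0; a < 4; ++a) {
      const int nm = node_map[elems(e, a) - 1];
      if (nm == 0) continue;
      out(nm - 1, 0) += w * grad(e, 0);
      out(nm - 1, 1) += w * grad(e, 1);
      out(nm - 1, 2) += w * grad(e, 2);
      out(nm - 1, 3) += w;
    }
  }
  return out;
}
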