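// Convex-hull volume in arbitrary dimension (randomized incremental /
// beneath-beyond with simplicial facets) and the Curveball trade chain.
// Both are hot loops: hull volumes are evaluated per grid cell per null
// replicate, and null ensembles run 10^4-10^6 trades. Facet planes are
// found by Gaussian elimination on flat arrays rather than library SVD
// calls; in 9-D trait space a single hull touches thousands of facets.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Unit null vector of the (d-1) x d row-major matrix A (destroyed).
// Returns false when the null space is not one-dimensional.
static bool null_vector(std::vector<double>& A, int d, double* nrm,
                        double tol) {
  const int rows = d - 1;
  std::vector<int> pivot_col(rows, -1);
  std::vector<char> used(d, 0);
  int r = 0;
  for (int c = 0; c < d && r < rows; ++c) {
    int pi = -1;
    double pv = tol;
    for (int i = r; i < rows; ++i) {
      double a = std::fabs(A[i * d + c]);
      if (a > pv) { pv = a; pi = i; }
    }
    if (pi < 0) continue; // (near-)free column
    if (pi != r)
      for (int k = c; k < d; ++k) std::swap(A[r * d + k], A[pi * d + k]);
    for (int i = r + 1; i < rows; ++i) {
      double f = A[i * d + c] / A[r * d + c];
      if (f != 0.0)
        for (int k = c; k < d; ++k) A[i * d + k] -= f * A[r * d + k];
    }
    pivot_col[r] = c;
    used[c] = 1;
    ++r;
  }
  if (r < rows) return false; // affinely dependent vertices
  int freec = -1;
  for (int c = 0; c < d; ++c)
    if (!used[c]) { freec = c; break; }
  for (int c = 0; c < d; ++c) nrm[c] = 0.0;
  nrm[freec] = 1.0;
  for (int i = rows - 1; i >= 0; --i) {
    const int pc = pivot_col[i];
    double acc = 0.0;
    for (int k = pc + 1; k < d; ++k) acc += A[i * d + k] * nrm[k];
    nrm[pc] = -acc / A[i * d + pc];
  }
  double nn = 0.0;
  for (int c = 0; c < d; ++c) nn += nrm[c] * nrm[c];
  nn = std::sqrt(nn);
  for (int c = 0; c < d; ++c) nrm[c] /= nn;
  return true;
}

// determinant of a d x d row-major matrix by LU with partial pivoting
static double det_inplace(std::vector<double>& M, int d) {
  double det = 1.0;
  for (int c = 0; c < d; ++c) {
    int pi = c;
    double pv = std::fabs(M[c * d + c]);
    for (int i = c + 1; i < d; ++i) {
      double a = std::fabs(M[i * d + c]);
      if (a > pv) { pv = a; pi = i; }
    }
    if (pv == 0.0) return 0.0;
    if (pi != c) {
      for (int k = c; k < d; ++k) std::swap(M[c * d + k], M[pi * d + k]);
      det = -det;
    }
    det *= M[c * d + c];
    for (int i = c + 1; i < d; ++i) {
      double f = M[i * d + c] / M[c * d + c];
      if (f != 0.0)
        for (int k = c + 1; k < d; ++k) M[i * d + k] -= f * M[c * d + k];
    }
  }
  return det;
}

struct HullState {
  int d;
  std::vector<int> verts;      // nfac * d vertex indices
  std::vector<double> normals; // nfac * d
  std::vector<double> offsets; // nfac
  std::vector<char> alive;
  int n_dead;

  explicit HullState(int dim) : d(dim), n_dead(0) {}
  int size() const { return (int)offsets.size(); }
  void add(const int* v, const double* n, double off) {
    verts.insert(verts.end(), v, v + d);
    normals.insert(normals.end(), n, n + d);
    offsets.push_back(off);
    alive.push_back(1);
  }
  void compact() {
    int w = 0;
    for (int f = 0; f < size(); ++f) {
      if (!alive[f]) continue;
      if (w != f) {
        std::copy(&verts[f * d], &verts[f * d] + d, &verts[w * d]);
        std::copy(&normals[f * d], &normals[f * d] + d, &normals[w * d]);
        offsets[w] = offsets[f];
      }
      ++w;
    }
    verts.resize(w * d);
    normals.resize(w * d);
    offsets.resize(w);
    alive.assign(w, 1);
    n_dead = 0;
  }
};

// [[Rcpp::export(name = ".convhull_volume_cpp")]]
List convhull_volume_cpp(const arma::mat& Xin) {
  const int n = Xin.n_rows, d = Xin.n_cols;
  if (d < 1) stop("point matrix must have at least one column");

  if (d == 1) {
    double vol = Xin.col(0).max() - Xin.col(0).min();
    return List::create(_["volume"] = vol, _["degenerate"] = (vol <= 0.0),
                        _["n_facets"] = 2);
  }
  List degenerate_out = List::create(
      _["volume"] = 0.0, _["degenerate"] = true, _["n_facets"] = 0);
  if (n < d + 1) return degenerate_out;

  // row-major copy for cache-friendly point access
  std::vector<double> X((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) X[i * d + c] = Xin(i, c);

  double scale = 1.0;
  for (size_t k = 0; k < X.size(); ++k)
    scale = std::max(scale, std::fabs(X[k]));
  const double rank_tol = 1e-8 * scale;
  const double vis_tol = 1e-9 * scale;
  const double elim_tol = 1e-12 * scale;

  // greedy affinely-independent initial simplex via Gram-Schmidt residuals
  std::vector<double> centroid(d, 0.0);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) centroid[c] += X[i * d + c] / n;
  int first = 0;
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int c = 0; c < d; ++c) {
      double v = X[i * d + c] - centroid[c];
      s += v * v;
    }
    if (s > best) { best = s; first = i; }
  }
  std::vector<int> simplex(1, first);
  std::vector<double> Q; // orthonormal affine-span basis, k vectors of length d
  std::vector<double> v(d), proj(d);
  while ((int)simplex.size() < d + 1) {
    int pick = -1;
    double best_res = rank_tol;
    std::vector<double> best_dir(d);
    const int k = (int)simplex.size() - 1;
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < d; ++c)
        v[c] = X[i * d + c] - X[first * d + c];
      for (int b = 0; b < k; ++b) {
        double dp = 0.0;
        for (int c = 0; c < d; ++c) dp += Q[b * d + c] * v[c];
        for (int c = 0; c < d; ++c) v[c] -= dp * Q[b * d + c];
      }
      double res = 0.0;
      for (int c = 0; c < d; ++c) res += v[c] * v[c];
      res = std::sqrt(res);
      if (res > best_res) {
        best_res = res;
        pick = i;
        for (int c = 0; c < d; ++c) best_dir[c] = v[c] / res;
      }
    }
    if (pick < 0) return degenerate_out; // rank-deficient point set
    simplex.push_back(pick);
    Q.insert(Q.end(), best_dir.begin(), best_dir.end());
  }

  std::vector<double> inner(d, 0.0); // strictly interior reference point
  for (int i = 0; i <= d; ++i)
    for (int c = 0; c < d; ++c) inner[c] += X[simplex[i] * d + c] / (d + 1.0);

  std::vector<double> A((size_t)(d - 1) * d), nrm(d);
  HullState H(d);
  std::vector<int> fv(d);

  // returns false on a degenerate candidate facet
  // (plane fit into nrm/off, oriented away from the interior point)
  struct PlaneFit {
    const std::vector<double>& X;
    const std::vector<double>& inner;
    int d;
    double elim_tol;
    bool operator()(const int* vv, std::vector<double>& A, double* nrm,
                    double& off) const {
      for (int i = 1; i < d; ++i)
        for (int c = 0; c < d; ++c)
          A[(i - 1) * d + c] = X[vv[i] * d + c] - X[vv[0] * d + c];
      if (!null_vector(A, d, nrm, elim_tol)) return false;
      off = 0.0;
      for (int c = 0; c < d; ++c) off += nrm[c] * X[vv[0] * d + c];
      double di = 0.0;
      for (int c = 0; c < d; ++c) di += nrm[c] * inner[c];
      if (di > off) {
        for (int c = 0; c < d; ++c) nrm[c] = -nrm[c];
        off = -off;
      }
      return true;
    }
  } fit_plane = {X, inner, d, elim_tol};

  double off;
  for (int skip = 0; skip <= d; ++skip) {
    int w = 0;
    for (int i = 0; i <= d; ++i)
      if (i != skip) fv[w++] = simplex[i];
    if (!fit_plane(fv.data(), A, nrm.data(), off)) return degenerate_out;
    H.add(fv.data(), nrm.data(), off);
  }

  std::vector<char> used(n, 0);
  for (int i = 0; i <= d; ++i) used[simplex[i]] = 1;

  // insert far points first: fewer facet updates, better conditioning
  std::vector<std::pair<double, int> > order;
  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    double s = 0.0;
    for (int c = 0; c < d; ++c) {
      double w = X[i * d + c] - inner[c];
      s += w * w;
    }
    order.push_back(std::make_pair(-s, i));
  }
  std::sort(order.begin(), order.end());

  std::vector<int> visible;
  std::vector<std::vector<int> > ridges;
  std::vector<int> cand_verts;
  std::vector<double> cand_norms, cand_offs;

  for (size_t oi = 0; oi < order.size(); ++oi) {
    const int p = order[oi].second;
    const double* pt = &X[p * d];
    visible.clear();
    for (int f = 0; f < H.size(); ++f) {
      if (!H.alive[f]) continue;
      double dp = -H.offsets[f];
      const double* nf = &H.normals[f * d];
      for (int c = 0; c < d; ++c) dp += nf[c] * pt[c];
      if (dp > vis_tol) visible.push_back(f);
    }
    if (visible.empty()) continue; // interior or coplanar point

    // horizon = ridges appearing exactly once among visible facets
    ridges.clear();
    for (size_t vi = 0; vi < visible.size(); ++vi) {
      const int* vv = &H.verts[visible[vi] * d];
      for (int skip = 0; skip < d; ++skip) {
        std::vector<int> r;
        r.reserve(d - 1);
        for (int k = 0; k < d; ++k)
          if (k != skip) r.push_back(vv[k]);
        std::sort(r.begin(), r.end());
        ridges.push_back(r);
      }
    }
    std::sort(ridges.begin(), ridges.end());

    // candidate replacement facets first; reject the point wholesale on
    // any degeneracy so the facet complex stays closed
    cand_verts.clear();
    cand_norms.clear();
    cand_offs.clear();
    bool ok = true;
    for (size_t ri = 0; ri < ridges.size() && ok;) {
      size_t rj = ri + 1;
      while (rj < ridges.size() && ridges[rj] == ridges[ri]) ++rj;
      if (rj - ri == 1) { // horizon ridge
        for (int k = 0; k < d - 1; ++k) fv[k] = ridges[ri][k];
        fv[d - 1] = p;
        if (!fit_plane(fv.data(), A, nrm.data(), off)) {
          ok = false;
          break;
        }
        cand_verts.insert(cand_verts.end(), fv.begin(), fv.end());
        cand_norms.insert(cand_norms.end(), nrm.begin(), nrm.end());
        cand_offs.push_back(off);
      }
      ri = rj;
    }
    if (!ok || cand_offs.empty()) continue;
    for (size_t vi = 0; vi < visible.size(); ++vi) {
      H.alive[visible[vi]] = 0;
      ++H.n_dead;
    }
    for (size_t f = 0; f < cand_offs.size(); ++f)
      H.add(&cand_verts[f * d], &cand_norms[f * d], cand_offs[f]);
    if (H.n_dead > H.size() / 2 && H.size() > 4 * (d + 1)) H.compact();
  }

  double dfact = 1.0;
  for (int k = 2; k <= d; ++k) dfact *= k;
  double vol = 0.0;
  int nfac = 0;
  std::vector<double> M((size_t)d * d);
  for (int f = 0; f < H.size(); ++f) {
    if (!H.alive[f]) continue;
    ++nfac;
    const int* vv = &H.verts[f * d];
    for (int i = 0; i < d; ++i)
      for (int c = 0; c < d; ++c)
        M[i * d + c] = X[vv[i] * d + c] - inner[c];
    vol += std::fabs(det_inplace(M, d)) / dfact;
  }
  return List::create(_["volume"] = vol, _["degenerate"] = (vol <= 0.0),
                      _["n_facets"] = nfac);
}

// One Curveball trade on rows i and j (0-based): the columns held by
// exactly one of the two rows are pooled and reallocated uniformly,
// preserving both row sums (and trivially all column sums).
static void trade_rows(arma::imat& m, int i, int j) {
  const int nc = m.n_cols;
  std::vector<int> pool; // columns unique to either row
  int na = 0;            // how many the first row must keep
  for (int c = 0; c < nc; ++c) {
    int a = m(i, c), b = m(j, c);
    if (a == 1 && b == 0) { pool.push_back(c); ++na; }
    else if (a == 0 && b == 1) pool.push_back(c);
  }
  const int np = (int)pool.size();
  if (na == 0 || na == np) return; // nothing tradeable
  // Fisher-Yates partial shuffle with R's RNG
  for (int k = 0; k < na; ++k) {
    int idx = k + (int)(R::unif_rand() * (np - k));
    if (idx >= np) idx = np - 1;
    std::swap(pool[k], pool[idx]);
  }
  for (int k = 0; k < np; ++k) {
    int c = pool[k];
    m(i, c) = (k < na) ? 1 : 0;
    m(j, c) = (k < na) ? 0 : 1;
  }
}

// [[Rcpp::export(name = ".curveball_chain_cpp")]]
arma::imat curveball_chain_cpp(arma::imat m, int n_trades) {
  const int nr = m.n_rows;
  if (nr < 2) stop("need at least two rows");
  for (int t = 0; t < n_trades; ++t) {
    int i = (int)(R::unif_rand() * nr); if (i >= nr) i = nr - 1;
    int j = (int)(R::unif_rand() * (nr - 1)); if (j >= nr - 1) j = nr - 2;
    if (j >= i) ++j;
    trade_rows(m, i, j);
  }
  return m;
}
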