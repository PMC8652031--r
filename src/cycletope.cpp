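// Core numerical kernels: Vietoris-Rips H1 persistence via boundary-matrix
// reduction over Z/2, Laplacian Eigenmaps on a symmetric kNN graph, and the
// per-series scoring path (delay embedding -> eigenmap -> max H1 persistence)
// that the permutation-null loop hammers thousands of times per run.

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct EdgeRec {
  double w;
  int u, v;
};

// Maximum H1 persistence (radius scale: distance threshold / 2) of the full
// Rips filtration on a Euclidean point cloud. Field coefficients Z/2,
// filtration capped at the cloud diameter (the complete complex), so every
// 1-cycle dies and no infinite bars remain.
double rips_h1_max_impl(const arma::mat& P) {
  const int n = static_cast<int>(P.n_rows);
  if (n < 3) return 0.0;
  const int m = n * (n - 1) / 2;

  std::vector<EdgeRec> edges;
  edges.reserve(m);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = arma::norm(P.row(i) - P.row(j), 2);
      edges.push_back(EdgeRec{d, i, j});
    }
  }
  std::sort(edges.begin(), edges.end(), [](const EdgeRec& a, const EdgeRec& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.u != b.u) return a.u < b.u;
    return a.v < b.v;
  });

  // rank of each vertex pair in the sorted edge order
  std::vector<int> rank(static_cast<size_t>(n) * n, -1);
  std::vector<double> ew(m);
  for (int e = 0; e < m; ++e) {
    rank[static_cast<size_t>(edges[e].u) * n + edges[e].v] = e;
    ew[e] = edges[e].w;
  }

  // Triangles in filtration order. A triangle enters at the length of its
  // longest edge, so bucketing by max-edge rank is a counting sort that
  // reproduces the (value, max-edge) filtration order exactly.
  const size_t n_tri = static_cast<size_t>(n) * (n - 1) * (n - 2) / 6;
  std::vector<int> bucket_count(m, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int rij = rank[static_cast<size_t>(i) * n + j];
      for (int k = j + 1; k < n; ++k) {
        const int rik = rank[static_cast<size_t>(i) * n + k];
        const int rjk = rank[static_cast<size_t>(j) * n + k];
        ++bucket_count[std::max(rij, std::max(rik, rjk))];
      }
    }
  }
  std::vector<int> bucket_start(m + 1, 0);
  for (int e = 0; e < m; ++e) bucket_start[e + 1] = bucket_start[e] + bucket_count[e];
  // per triangle: the two non-maximal boundary edges (the bucket gives the third)
  std::vector<int> tri_lo1(n_tri), tri_lo2(n_tri);
  {
    std::vector<int> fill_pos(bucket_start.begin(), bucket_start.end() - 1);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const int rij = rank[static_cast<size_t>(i) * n + j];
        for (int k = j + 1; k < n; ++k) {
          const int rik = rank[static_cast<size_t>(i) * n + k];
          const int rjk = rank[static_cast<size_t>(j) * n + k];
          int a = rij, b = rik, c = rjk;
          if (a > b) std::swap(a, b);
          if (b > c) std::swap(b, c);
          if (a > b) std::swap(a, b);
          const int pos = fill_pos[c]++;
          tri_lo1[pos] = a;
          tri_lo2[pos] = b;
        }
      }
    }
  }

  // Standard persistence reduction restricted to the triangle columns: the
  // boundary of a triangle lives in the edge rows, and a reduced non-zero
  // column pairs its pivot (creator) edge with the triangle that kills it.
  // Columns are bitsets over edge ranks so each merge is a few word XORs.
  const int words = (m + 63) / 64;
  std::vector<int> pivot_owner(m, -1);
  std::vector<uint64_t> colstore;  // reduced non-zero columns, `words` each
  colstore.reserve(static_cast<size_t>(words) * 256);
  std::vector<uint64_t> col(words);

  // first set bit at or below `from`, -1 if none
  auto lowbit_from = [&](const std::vector<uint64_t>& c, int from) -> int {
    int w = from >> 6;
    uint64_t word = c[w] & (~0ULL >> (63 - (from & 63)));
    while (true) {
      if (word) return (w << 6) + 63 - __builtin_clzll(word);
      if (--w < 0) return -1;
      word = c[w];
    }
  };

  double best = 0.0;
  for (int e_max = 0; e_max < m; ++e_max) {
    const double tri_w = ew[e_max];
    for (int t = bucket_start[e_max]; t < bucket_start[e_max + 1]; ++t) {
      std::fill(col.begin(), col.end(), 0ULL);
      col[e_max >> 6] ^= 1ULL << (e_max & 63);
      col[tri_lo1[t] >> 6] ^= 1ULL << (tri_lo1[t] & 63);
      col[tri_lo2[t] >> 6] ^= 1ULL << (tri_lo2[t] & 63);
      int low = e_max;
      while (low >= 0 && pivot_owner[low] >= 0) {
        const uint64_t* other =
            &colstore[static_cast<size_t>(pivot_owner[low]) * words];
        for (int w = 0; w <= (low >> 6); ++w) col[w] ^= other[w];
        low = lowbit_from(col, low);
      }
      if (low >= 0) {
        pivot_owner[low] = static_cast<int>(colstore.size() / words);
        colstore.insert(colstore.end(), col.begin(), col.end());
        const double pers = (tri_w - ew[low]) / 2.0;
        if (pers > best) best = pers;
      }
    }
  }
  return best;
}

// Laplacian Eigenmap of a point cloud onto the eigenvectors of the symmetric
// normalized graph Laplacian for the 2nd and 3rd smallest eigenvalues.
// Graph: symmetric kNN (edge if either endpoint selects the other), heat
// kernel weights exp(-d^2/heat^2); heat <= 0 requests the median pairwise
// distance. Disconnected graphs are reduced to the largest component, with
// excluded points mapped to its centroid. Returns an empty matrix when the
// cloud is degenerate (all points coincide, or the usable component is < 3).
arma::mat le_impl(const arma::mat& P, int k, double heat) {
  const int n = static_cast<int>(P.n_rows);
  if (n < 3) return arma::mat();

  arma::mat D(n, n, arma::fill::zeros);
  std::vector<double> alld;
  alld.reserve(static_cast<size_t>(n) * (n - 1) / 2);
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = arma::norm(P.row(i) - P.row(j), 2);
      D(i, j) = D(j, i) = d;
      alld.push_back(d);
      if (d > dmax) dmax = d;
    }
  }
  if (dmax < 1e-14) return arma::mat();

  if (heat <= 0.0) {
    std::vector<double> tmp(alld);
    const size_t mid = tmp.size() / 2;
    std::nth_element(tmp.begin(), tmp.begin() + mid, tmp.end());
    heat = tmp[mid];
    if (heat < 1e-14) heat = dmax;
  }

  const int kk = std::min(k, n - 1);
  arma::umat adj(n, n, arma::fill::zeros);
  std::vector<int> idxbuf(n);
  for (int i = 0; i < n; ++i) {
    int nn = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) idxbuf[nn++] = j;
    std::partial_sort(idxbuf.begin(), idxbuf.begin() + kk, idxbuf.begin() + nn,
                      [&](int a, int b) {
                        if (D(i, a) != D(i, b)) return D(i, a) < D(i, b);
                        return a < b;
                      });
    for (int q = 0; q < kk; ++q) {
      const int j = idxbuf[q];
      adj(i, j) = adj(j, i) = 1;
    }
  }

  // connected components via BFS
  std::vector<int> comp(n, -1);
  int ncomp = 0;
  std::vector<int> queue;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    queue.clear();
    queue.push_back(s);
    comp[s] = ncomp;
    for (size_t qi = 0; qi < queue.size(); ++qi) {
      const int u = queue[qi];
      for (int v = 0; v < n; ++v) {
        if (adj(u, v) && comp[v] < 0) {
          comp[v] = ncomp;
          queue.push_back(v);
        }
      }
    }
    ++ncomp;
  }
  std::vector<int> csize(ncomp, 0);
  for (int i = 0; i < n; ++i) ++csize[comp[i]];
  const int big =
      static_cast<int>(std::max_element(csize.begin(), csize.end()) - csize.begin());
  arma::uvec keep(csize[big]);
  int p = 0;
  for (int i = 0; i < n; ++i)
    if (comp[i] == big) keep(p++) = i;
  const int nc = static_cast<int>(keep.n_elem);
  if (nc < 3) return arma::mat();

  arma::mat W(nc, nc, arma::fill::zeros);
  for (int a = 0; a < nc; ++a) {
    for (int b = a + 1; b < nc; ++b) {
      if (adj(keep(a), keep(b))) {
        const double d = D(keep(a), keep(b));
        W(a, b) = W(b, a) = std::exp(-(d * d) / (heat * heat));
      }
    }
  }
  arma::vec deg = arma::sum(W, 1);
  arma::vec dsq = 1.0 / arma::sqrt(deg);
  arma::mat L = arma::eye(nc, nc) - (dsq * dsq.t()) % W;
  L = 0.5 * (L + L.t());  // enforce exact symmetry

  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, L)) return arma::mat();

  arma::mat out(n, 2);
  arma::mat sub = evec.cols(1, 2);
  arma::rowvec centroid = arma::mean(sub, 0);
  for (int i = 0; i < n; ++i) out.row(i) = centroid;
  for (int a = 0; a < nc; ++a) out.row(keep(a)) = sub.row(a);
  return out;
}

arma::mat embed3_impl(const arma::vec& x, int lag) {
  const int N = static_cast<int>(x.n_elem);
  const int npts = N - 2 * lag;
  arma::mat E(npts, 3);
  for (int i = 0; i < npts; ++i) {
    const int t = i + 2 * lag;
    E(i, 0) = x(t);
    E(i, 1) = x(t - lag);
    E(i, 2) = x(t - 2 * lag);
  }
  return E;
}

}  // namespace

// [[Rcpp::export]]
double cpp_rips_h1_max(const arma::mat& points) {
  return rips_h1_max_impl(points);
}

// [[Rcpp::export]]
SEXP cpp_laplacian_eigenmap(const arma::mat& points, int k, double heat) {
  arma::mat out = le_impl(points, k, heat);
  if (out.n_rows == 0) return R_NilValue;
  return wrap(out);
}

// [[Rcpp::export]]
NumericVector cpp_score_series(const arma::vec& x, const IntegerVector& lags,
                               int k, double heat) {
  NumericVector out(lags.size());
  const int N = static_cast<int>(x.n_elem);
  for (int q = 0; q < lags.size(); ++q) {
    const int lag = lags[q];
    if (lag < 1 || N - 2 * lag < 3) {
      out[q] = NA_REAL;
      continue;
    }
    arma::mat E = embed3_impl(x, lag);
    arma::mat Y = le_impl(E, k, heat);
    out[q] = (Y.n_rows == 0) ? 0.0 : rips_h1_max_impl(Y);
  }
  return out;
}
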