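#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---- connected components ----------------------------------------------
//
// Label the foreground of a 3-D binary mask under 6/18/26-adjacency.
// Breadth-first flooding; labels are assigned in increasing linear-index
// order of the first voxel of each component, so labelling is deterministic.

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets for the requested adjacency
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }

  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), kk = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t t = 0; t < dx.size(); ++t) {
        int ii = i + dx[t], jj = j + dy[t], kz = kk + dz[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kz < 0 || kz >= nz) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kz);
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---- exact Euclidean distance transform --------------------------------
//
// Separable lower-envelope-of-parabolas transform on squared distances,
// generalised to anisotropic sample spacing (samples of axis pass lie at
// x_i = i * s). Exact for squared Euclidean distance to the nearest
// foreground voxel centre.

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // infinite parabolas never win
    double xq = q * s;
    while (k >= 0) {
      double xv = v[k] * s;
      double sx = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sx <= z[k]) { --k; continue; }
      break;
    }
    ++k; v[k] = q;
    z[k] = (k == 0) ? -INF
                    : ((f[q] + xq * xq) - (f[v[k - 1]] + v[k - 1] * s * v[k - 1] * s)) /
                          (2.0 * (xq - v[k - 1] * s));
    z[k + 1] = INF;
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[j + 1] < xq) ++j;
    double xv = v[j] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d2(n);
  for (R_xlen_t i = 0; i < n; ++i) d2[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // axis 0 (stride 1)
  f.resize(nx); d.resize(nx);
  for (int kz = 0; kz < nz; ++kz)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * kz);
      for (int i = 0; i < nx; ++i) f[i] = d2[base + i];
      dt1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d2[base + i] = d[i];
    }
  // axis 1 (stride nx)
  f.resize(ny); d.resize(ny);
  for (int kz = 0; kz < nz; ++kz)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * kz;
      for (int j = 0; j < ny; ++j) f[j] = d2[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d2[base + (R_xlen_t)nx * j] = d[j];
    }
  // axis 2 (stride nx*ny)
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int kz = 0; kz < nz; ++kz) f[kz] = d2[base + (R_xlen_t)nx * ny * kz];
      dt1d(f, d, nz, spacing[2]);
      for (int kz = 0; kz < nz; ++kz) d2[base + (R_xlen_t)nx * ny * kz] = d[kz];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(d2[i]);
  return out;
}

// ---- sliding box sums ---------------------------------------------------
//
// Sum of x over the axis-aligned window [i-lo, i+hi] applied along all
// three axes in turn (values outside the grid contribute zero). Running
// sums give O(N) per axis.

static void boxsum_axis(std::vector<double>& x, int nline, R_xlen_t nlines,
                        const std::vector<R_xlen_t>& bases, R_xlen_t stride,
                        int lo, int hi) {
  std::vector<double> line(nline), out(nline);
  for (R_xlen_t b = 0; b < nlines; ++b) {
    R_xlen_t base = bases[b];
    for (int i = 0; i < nline; ++i) line[i] = x[base + stride * i];
    double s = 0.0;
    for (int i = 0; i <= hi && i < nline; ++i) s += line[i];
    for (int i = 0; i < nline; ++i) {
      out[i] = s;
      int add = i + hi + 1, rem = i - lo;
      if (add < nline) s += line[add];
      if (rem >= 0) s -= line[rem];
    }
    for (int i = 0; i < nline; ++i) x[base + stride * i] = out[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_box_sum(NumericVector vals, IntegerVector dims,
                          int lo, int hi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> x(vals.begin(), vals.end());

  std::vector<R_xlen_t> bases;
  bases.reserve((R_xlen_t)ny * nz);
  for (int kz = 0; kz < nz; ++kz)
    for (int j = 0; j < ny; ++j)
      bases.push_back((R_xlen_t)nx * (j + (R_xlen_t)ny * kz));
  boxsum_axis(x, nx, bases.size(), bases, 1, lo, hi);

  bases.clear();
  for (int kz = 0; kz < nz; ++kz)
    for (int i = 0; i < nx; ++i)
      bases.push_back(i + (R_xlen_t)nx * ny * kz);
  boxsum_axis(x, ny, bases.size(), bases, nx, lo, hi);

  bases.clear();
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      bases.push_back(i + (R_xlen_t)nx * j);
  boxsum_axis(x, nz, bases.size(), bases, (R_xlen_t)nx * ny, lo, hi);

  return NumericVector(x.begin(), x.end());
}

// ---- exact k-NN class probability ---------------------------------------
//
// For each query row, the proportion of WMH labels among the k training
// rows nearest in squared Euclidean distance. Exact exhaustive search;
// distance ties broken by lower training-row index (the (d, index) pair is
// ordered lexicographically), so results are reproducible across runs and
// row permutations.

// [[Rcpp::export]]
NumericVector cpp_knn_prob(NumericMatrix train, IntegerVector labels,
                           NumericMatrix query, int k) {
  const int ntr = train.nrow(), d = train.ncol(), nq = query.nrow();
  if (k < 1 || k > ntr) stop("k must be between 1 and nrow(train)");
  if (query.ncol() != d) stop("feature dimension mismatch");

  NumericVector out(nq);
  const double* trcol = REAL(train);   // column-major, contiguous per feature
  std::vector<double> dist(ntr);
  std::vector<std::pair<double, int> > cand(ntr);

  for (int iq = 0; iq < nq; ++iq) {
    // feature-outer accumulation: contiguous, vectorizable inner loops,
    // summation order identical to a per-pair loop over features
    {
      const double qj = query(iq, 0);
      const double* col = trcol;
      for (int t = 0; t < ntr; ++t) { double v = qj - col[t]; dist[t] = v * v; }
    }
    for (int j = 1; j < d; ++j) {
      const double qj = query(iq, j);
      const double* col = trcol + (size_t)ntr * j;
      for (int t = 0; t < ntr; ++t) { double v = qj - col[t]; dist[t] += v * v; }
    }
    // bounded max-heap of the k smallest (distance, index) pairs;
    // lexicographic order gives the lower-index tie-break
    cand.clear();
    for (int t = 0; t < k; ++t) cand.push_back(std::make_pair(dist[t], t));
    std::make_heap(cand.begin(), cand.end());
    for (int t = k; t < ntr; ++t) {
      if (dist[t] < cand.front().first) {
        std::pop_heap(cand.begin(), cand.end());
        cand.back() = std::make_pair(dist[t], t);
        std::push_heap(cand.begin(), cand.end());
      }
    }
    int pos = 0;
    for (int t = 0; t < k; ++t) pos += labels[cand[t].second];
    out[iq] = (double)pos / k;
  }
  return out;
}
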