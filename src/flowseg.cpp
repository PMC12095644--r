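// Low-level image kernels: separable correlation with reflective boundaries,
// windowed Shannon entropy, bilinear sampling/resizing for the pyramidal flow,
// and the digital-topology primitives (8-connected labelling, 4-connected
// hole filling, distance-peak seeding, marker-controlled watershed).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// half-sample symmetric reflection: indices ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// correlation along one dimension (1 = rows, 2 = cols) with an odd-length
// kernel indexed -r..r: out(i) = sum_u k[u+r] * x(i+u); reflective borders
// [[Rcpp::export]]
NumericMatrix conv1_reflect(const NumericMatrix& x, const NumericVector& k, int dim) {
  const int nr = x.nrow(), nc = x.ncol(), r = (k.size() - 1) / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> kk(k.begin(), k.end());
  const double* px = x.begin();
  double* po = out.begin();
  if (dim == 1) {
    for (int j = 0; j < nc; ++j) {
      const double* col = px + (size_t)j * nr;
      double* oc = po + (size_t)j * nr;
      const int lo = std::min(r, nr), hi = std::max(lo, nr - r);
      for (int i = 0; i < lo; ++i) {
        double s = 0.0;
        for (int u = -r; u <= r; ++u) s += kk[u + r] * col[reflect_idx(i + u, nr)];
        oc[i] = s;
      }
      for (int i = lo; i < hi; ++i) {
        double s = 0.0;
        const double* p = col + i - r;
        for (int u = 0; u <= 2 * r; ++u) s += kk[u] * p[u];
        oc[i] = s;
      }
      for (int i = hi; i < nr; ++i) {
        double s = 0.0;
        for (int u = -r; u <= r; ++u) s += kk[u + r] * col[reflect_idx(i + u, nr)];
        oc[i] = s;
      }
    }
  } else {
    // accumulate whole shifted columns: contiguous, vectorizable
    std::fill(po, po + (size_t)nr * nc, 0.0);
    for (int j = 0; j < nc; ++j) {
      double* oc = po + (size_t)j * nr;
      for (int u = -r; u <= r; ++u) {
        const double* col = px + (size_t)reflect_idx(j + u, nc) * nr;
        const double w = kk[u + r];
        for (int i = 0; i < nr; ++i) oc[i] += w * col[i];
      }
    }
  }
  return out;
}

// Shannon entropy (bits) of the binned intensity histogram in a disk window,
// reflective boundary. Intensities are assumed in [0,1]; values outside are
// clamped into the end bins.
// [[Rcpp::export]]
NumericMatrix local_entropy_cpp(const NumericMatrix& x, int radius, int nbins) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix bin(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int b = (int)std::floor(x(i, j) * nbins);
      if (b < 0) b = 0;
      if (b >= nbins) b = nbins - 1;
      bin(i, j) = b;
    }
  std::vector<int> dy, dx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dy.push_back(a); dx.push_back(b); }
  const int m = (int)dy.size();
  const double inv_m = 1.0 / m, log2m = std::log2((double)m);
  NumericMatrix out(nr, nc);
  std::vector<int> hist(nbins, 0), used;
  used.reserve(m);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      used.clear();
      for (int t = 0; t < m; ++t) {
        int b = bin(reflect_idx(i + dy[t], nr), reflect_idx(j + dx[t], nc));
        if (hist[b] == 0) used.push_back(b);
        ++hist[b];
      }
      double s = 0.0;
      for (size_t t = 0; t < used.size(); ++t) {
        int c = hist[used[t]];
        s += c * std::log2((double)c);
        hist[used[t]] = 0;
      }
      out(i, j) = log2m - inv_m * s;  // = -sum p log2 p
    }
  return out;
}

static inline double sample_bilinear(const NumericMatrix& x, double ri, double cj) {
  const int nr = x.nrow(), nc = x.ncol();
  if (ri < 0) ri = 0; else if (ri > nr - 1) ri = nr - 1;
  if (cj < 0) cj = 0; else if (cj > nc - 1) cj = nc - 1;
  int r0 = (int)std::floor(ri), c0 = (int)std::floor(cj);
  if (r0 > nr - 2) r0 = nr - 2 >= 0 ? nr - 2 : 0;
  if (c0 > nc - 2) c0 = nc - 2 >= 0 ? nc - 2 : 0;
  double fr = ri - r0, fc = cj - c0;
  if (nr == 1) { r0 = 0; fr = 0.0; }
  if (nc == 1) { c0 = 0; fc = 0.0; }
  const int r1 = (nr == 1) ? r0 : r0 + 1, c1 = (nc == 1) ? c0 : c0 + 1;
  return (1 - fr) * ((1 - fc) * x(r0, c0) + fc * x(r0, c1)) +
         fr * ((1 - fc) * x(r1, c0) + fc * x(r1, c1));
}

// sample x at (i + dr(i,j), j + dc(i,j)); zero displacement reproduces x exactly
// [[Rcpp::export]]
NumericMatrix warp_bilinear(const NumericMatrix& x, const NumericMatrix& dr,
                            const NumericMatrix& dc) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = dr(i, j), b = dc(i, j);
      if (a == 0.0 && b == 0.0) out(i, j) = x(i, j);
      else out(i, j) = sample_bilinear(x, i + a, j + b);
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix resize_bilinear(const NumericMatrix& x, int nr2, int nc2) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr2, nc2);
  const double sr = (double)nr / nr2, sc = (double)nc / nc2;
  for (int j = 0; j < nc2; ++j)
    for (int i = 0; i < nr2; ++i)
      out(i, j) = sample_bilinear(x, (i + 0.5) * sr - 0.5, (j + 0.5) * sc - 0.5);
  return out;
}

// connected-component labelling of a binary mask, raster-order label ids
// (first-encountered pixel order), connectivity 8 (objects) or 4
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int *dy = connectivity == 8 ? dy8 : dy4;
  const int *dx = connectivity == 8 ? dx8 : dx4;
  const int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int t = 0; t < nn; ++t) {
          int qi = pi + dy[t], qj = pj + dx[t];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  return lab;
}

// fill interior holes: background is 4-connected; any background pixel not
// reachable from the image border becomes foreground
// [[Rcpp::export]]
IntegerMatrix fill_holes_cpp(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix reach(nr, nc);
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if ((i == 0 || i == nr - 1 || j == 0 || j == nc - 1) &&
          mask(i, j) == 0 && reach(i, j) == 0) {
        reach(i, j) = 1;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          int p = stack.back(); stack.pop_back();
          int pi = p % nr, pj = p / nr;
          const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
          for (int t = 0; t < 4; ++t) {
            int qi = pi + dy[t], qj = pj + dx[t];
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) == 0 && reach(qi, qj) == 0) {
              reach(qi, qj) = 1;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = (mask(i, j) != 0 || reach(i, j) == 0) ? 1 : 0;
  return out;
}

// seeds for declumping: local maxima of the distance transform within a disk
// footprint, thinned so accepted peaks are >= min_distance apart. Plateaus and
// ties resolve deterministically: candidates are ranked by (-distance, raster
// index) and greedily accepted.
// [[Rcpp::export]]
IntegerMatrix distance_peaks_cpp(const NumericMatrix& dist, int footprint_radius,
                                 double min_distance) {
  const int nr = dist.nrow(), nc = dist.ncol();
  std::vector<int> dy, dx;
  for (int a = -footprint_radius; a <= footprint_radius; ++a)
    for (int b = -footprint_radius; b <= footprint_radius; ++b)
      if ((a != 0 || b != 0) && a * a + b * b <= footprint_radius * footprint_radius) {
        dy.push_back(a); dx.push_back(b);
      }
  struct Cand { double d; int i, j; };
  std::vector<Cand> cands;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = dist(i, j);
      if (v <= 0) continue;
      bool ismax = true;
      for (size_t t = 0; t < dy.size() && ismax; ++t) {
        int qi = i + dy[t], qj = j + dx[t];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        if (dist(qi, qj) > v) ismax = false;
      }
      if (ismax) cands.push_back({v, i, j});
    }
  std::stable_sort(cands.begin(), cands.end(), [nr](const Cand& a, const Cand& b) {
    if (a.d != b.d) return a.d > b.d;
    return (a.i + a.j * nr) < (b.i + b.j * nr);
  });
  IntegerMatrix seeds(nr, nc);
  std::vector<std::pair<int, int> > acc;
  const double md2 = min_distance * min_distance;
  for (size_t t = 0; t < cands.size(); ++t) {
    bool ok = true;
    for (size_t s = 0; s < acc.size() && ok; ++s) {
      double di = cands[t].i - acc[s].first, dj = cands[t].j - acc[s].second;
      if (di * di + dj * dj < md2) ok = false;
    }
    if (ok) {
      acc.push_back(std::make_pair(cands[t].i, cands[t].j));
      seeds(cands[t].i, cands[t].j) = (int)acc.size();
    }
  }
  return seeds;
}

// marker-controlled watershed on the negated distance transform, restricted to
// the foreground: priority flood from the seeds, always expanding the pixel
// with the largest distance value (FIFO tie-break => deterministic).
// [[Rcpp::export]]
IntegerMatrix marker_watershed_cpp(const NumericMatrix& dist, const IntegerMatrix& seeds,
                                   const IntegerMatrix& mask) {
  const int nr = dist.nrow(), nc = dist.ncol();
  IntegerMatrix lab(nr, nc);
  struct Node { double d; long long order; int idx; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.d != b.d) return a.d < b.d;       // max-heap on distance
      return a.order > b.order;               // FIFO among equals
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long counter = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0 && mask(i, j) != 0) {
        lab(i, j) = seeds(i, j);
        pq.push({dist(i, j), counter++, i + j * nr});
      }
  const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int pi = nd.idx % nr, pj = nd.idx / nr;
    int l = lab(pi, pj);
    for (int t = 0; t < 8; ++t) {
      int qi = pi + dy[t], qj = pj + dx[t];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
        lab(qi, qj) = l;
        pq.push({dist(qi, qj), counter++, qi + qj * nr});
      }
    }
  }
  return lab;
}
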