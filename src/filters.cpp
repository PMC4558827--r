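#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 2-D moving order-statistic filter with window truncation at the
// borders. Window sizes must be odd; x is frames x bins. q = 0.5 gives
// the running median (with mid-pair averaging on even counts); lower q
// estimate the noise floor robustly even when ridges fill much of the
// window.
// [[Rcpp::export(name = ".quantile_filter2")]]
NumericMatrix quantile_filter2(const NumericMatrix& x, int win_row,
                               int win_col, double q) {
  const int nr = x.nrow(), nc = x.ncol();
  if (win_row < 1 || win_col < 1 || win_row % 2 == 0 || win_col % 2 == 0)
    stop("window sizes must be positive odd integers");
  if (q < 0.0 || q > 1.0) stop("q must lie in [0, 1]");
  const int hr = win_row / 2, hc = win_col / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)win_row * win_col);
  for (int j = 0; j < nc; ++j) {
    const int c0 = std::max(0, j - hc), c1 = std::min(nc - 1, j + hc);
    for (int i = 0; i < nr; ++i) {
      const int r0 = std::max(0, i - hr), r1 = std::min(nr - 1, i + hr);
      buf.clear();
      for (int c = c0; c <= c1; ++c)
        for (int r = r0; r <= r1; ++r)
          buf.push_back(x(r, c));
      const size_t n = buf.size();
      size_t k = (size_t)(q * (n - 1));
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      double v = buf[k];
      if (q == 0.5 && n % 2 == 0) {
        // median convention: average the two middle order statistics
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        v = 0.5 * (v + buf[n / 2]);
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Mean-shift filtering in the joint spatial-range domain with a flat
// kernel: the window is a square spatial box of half-width hs, and only
// pixels whose (original) color lies within hr of the current color
// estimate contribute. The window is subsampled on a stride-2 lattice
// anchored at the window center (a quarter of the pixels), which leaves
// the mean estimate essentially unchanged while quartering the cost.
// Each pixel's state converges to a local mode.
// lab: npix x 3 matrix (row-major pixel order: column-major image with
// nrow = height). Returns npix x 5 (x, y, c1, c2, c3) of converged states.
// [[Rcpp::export(name = ".meanshift_filter")]]
NumericMatrix meanshift_filter(const NumericMatrix& lab, int height, int width,
                               double hs, double hr, int max_iter,
                               double tol) {
  const int npix = height * width;
  if (lab.nrow() != npix || lab.ncol() != 3)
    stop("lab must be (height*width) x 3");
  NumericMatrix out(npix, 5);
  const float hr2 = (float)(hr * hr), tol2 = (float)(tol * tol);
  const int ihs = (int)std::ceil(hs);
  std::vector<float> c1(npix), c2(npix), c3(npix);
  for (int i = 0; i < npix; ++i) {
    c1[i] = (float)lab(i, 0); c2[i] = (float)lab(i, 1);
    c3[i] = (float)lab(i, 2);
  }
  for (int px = 0; px < npix; ++px) {
    // image stored column-major: pixel px -> row r, col c
    float sx = (float)(px / height);  // column index
    float sy = (float)(px % height);  // row index
    float m1 = c1[px], m2 = c2[px], m3 = c3[px];
    for (int it = 0; it < max_iter; ++it) {
      const int cx = (int)std::floor(sx), cy = (int)std::floor(sy);
      const int x0 = std::max(0, cx - ihs), x1 = std::min(width - 1, cx + ihs);
      const int y0 = std::max(0, cy - ihs), y1 = std::min(height - 1, cy + ihs);
      // stride-2 lattice aligned to the window center so the center
      // pixel itself is always sampled
      const int xs = x0 + ((cx - x0) & 1), ys = y0 + ((cy - y0) & 1);
      float n = 0, ax = 0, ay = 0, a1 = 0, a2 = 0, a3 = 0;
      for (int xx = xs; xx <= x1; xx += 2) {
        const int base = xx * height;
        for (int yy = ys; yy <= y1; yy += 2) {
          const int q = base + yy;
          const float d1 = c1[q] - m1, d2 = c2[q] - m2, d3 = c3[q] - m3;
          if (d1 * d1 + d2 * d2 + d3 * d3 <= hr2) {
            n += 1; ax += xx; ay += yy;
            a1 += c1[q]; a2 += c2[q]; a3 += c3[q];
          }
        }
      }
      if (n == 0) break;
      ax /= n; ay /= n; a1 /= n; a2 /= n; a3 /= n;
      const float ds = (ax - sx) * (ax - sx) + (ay - sy) * (ay - sy);
      const float dc = (a1 - m1) * (a1 - m1) + (a2 - m2) * (a2 - m2) +
                       (a3 - m3) * (a3 - m3);
      sx = ax; sy = ay; m1 = a1; m2 = a2; m3 = a3;
      if (ds + dc < tol2) break;
    }
    out(px, 0) = sx; out(px, 1) = sy;
    out(px, 2) = m1; out(px, 3) = m2; out(px, 4) = m3;
  }
  return out;
}

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Group converged modes into regions: 4-adjacent pixels whose converged
// colors differ by at most merge_dist join the same region. Returns an
// integer label matrix (height x width) with labels 1..K.
// [[Rcpp::export(name = ".group_modes")]]
IntegerMatrix group_modes(const NumericMatrix& modes, int height, int width,
                          double merge_dist) {
  const int npix = height * width;
  if (modes.nrow() != npix) stop("modes must have height*width rows");
  const double d2max = merge_dist * merge_dist;
  std::vector<int> parent(npix);
  for (int i = 0; i < npix; ++i) parent[i] = i;
  auto unite = [&](int a, int b) {
    a = uf_find(parent, a); b = uf_find(parent, b);
    if (a != b) parent[b] = a;
  };
  auto close = [&](int a, int b) {
    const double d1 = modes(a, 2) - modes(b, 2);
    const double d2 = modes(a, 3) - modes(b, 3);
    const double d3 = modes(a, 4) - modes(b, 4);
    return d1 * d1 + d2 * d2 + d3 * d3 <= d2max;
  };
  for (int xx = 0; xx < width; ++xx) {
    for (int yy = 0; yy < height; ++yy) {
      const int p = xx * height + yy;
      if (yy + 1 < height && close(p, p + 1)) unite(p, p + 1);
      if (xx + 1 < width && close(p, p + height)) unite(p, p + height);
    }
  }
  IntegerMatrix labels(height, width);
  std::vector<int> remap(npix, 0);
  int next = 0;
  for (int i = 0; i < npix; ++i) {
    const int root = uf_find(parent, i);
    if (remap[root] == 0) remap[root] = ++next;
    labels[i] = remap[root];
  }
  return labels;
}

// Merge regions smaller than min_region into their most similar
// adjacent region (by mean converged color), repeating until every
// region reaches min_region or no merge is possible. labels: height x
// width (1-based region ids); colors: npix x 3 converged mode colors.
// Returns a relabeled matrix with consecutive ids 1..K.
// [[Rcpp::export(name = ".merge_small_regions_cpp")]]
IntegerMatrix merge_small_regions_cpp(const IntegerMatrix& labels,
                                      const NumericMatrix& colors,
                                      int min_region) {
  const int height = labels.nrow(), width = labels.ncol();
  const int npix = height * width;
  int nreg = 0;
  for (int i = 0; i < npix; ++i) nreg = std::max(nreg, labels[i]);
  std::vector<int> parent(nreg);
  std::vector<double> size(nreg, 0), s1(nreg, 0), s2(nreg, 0), s3(nreg, 0);
  for (int r = 0; r < nreg; ++r) parent[r] = r;
  for (int i = 0; i < npix; ++i) {
    const int r = labels[i] - 1;
    size[r] += 1;
    s1[r] += colors(i, 0); s2[r] += colors(i, 1); s3[r] += colors(i, 2);
  }
  // pixel-level adjacency edges between distinct regions
  std::vector<std::pair<int,int> > edges;
  for (int xx = 0; xx < width; ++xx)
    for (int yy = 0; yy < height; ++yy) {
      const int p = xx * height + yy;
      if (yy + 1 < height && labels[p] != labels[p + 1])
        edges.push_back(std::make_pair(labels[p] - 1, labels[p + 1] - 1));
      if (xx + 1 < width && labels[p] != labels[p + height])
        edges.push_back(std::make_pair(labels[p] - 1,
                                       labels[p + height] - 1));
    }
  std::sort(edges.begin(), edges.end());
  edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
  for (int pass = 0; pass < 200; ++pass) {
    bool changed = false;
    // best (closest-color) neighbor of each small root
    std::vector<int> best(nreg, -1);
    std::vector<double> bestd(nreg, 1e30);
    for (size_t e = 0; e < edges.size(); ++e) {
      int a = uf_find(parent, edges[e].first);
      int b = uf_find(parent, edges[e].second);
      if (a == b) continue;
      const double d1 = s1[a] / size[a] - s1[b] / size[b];
      const double d2 = s2[a] / size[a] - s2[b] / size[b];
      const double d3 = s3[a] / size[a] - s3[b] / size[b];
      const double d = d1 * d1 + d2 * d2 + d3 * d3;
      if (size[a] < min_region && d < bestd[a]) { bestd[a] = d; best[a] = b; }
      if (size[b] < min_region && d < bestd[b]) { bestd[b] = d; best[b] = a; }
    }
    for (int r = 0; r < nreg; ++r) {
      if (best[r] < 0) continue;
      int a = uf_find(parent, r);
      if (size[a] >= min_region) continue;
      int b = uf_find(parent, best[r]);
      if (a == b) continue;
      parent[b] = a;
      size[a] += size[b]; s1[a] += s1[b]; s2[a] += s2[b]; s3[a] += s3[b];
      changed = true;
    }
    if (!changed) break;
    bool any_small = false;
    for (int r = 0; r < nreg; ++r)
      if (parent[r] == r && size[r] > 0 && size[r] < min_region)
        any_small = true;
    if (!any_small) break;
  }
  IntegerMatrix out(height, width);
  std::vector<int> remap(nreg, 0);
  int next = 0;
  for (int i = 0; i < npix; ++i) {
    const int root = uf_find(parent, labels[i] - 1);
    if (remap[root] == 0) remap[root] = ++next;
    out[i] = remap[root];
  }
  return out;
}
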