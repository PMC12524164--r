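#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>

using namespace Rcpp;

// Union-find over pixel indices; used for connected-component labeling.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Label connected components of a binary mask.
// connectivity: 4 or 8. Labels are 1..k in column-major order of each
// component's first pixel, so relabeling is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  const int n = nr * nc;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // column-major index = r + c*nr
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int idx = r + c * nr;
      if (r > 0 && mask(r - 1, c)) uf_union(parent, idx, (r - 1) + c * nr);
      if (c > 0 && mask(r, c - 1)) uf_union(parent, idx, r + (c - 1) * nr);
      if (connectivity == 8) {
        if (r > 0 && c > 0 && mask(r - 1, c - 1))
          uf_union(parent, idx, (r - 1) + (c - 1) * nr);
        if (r + 1 < nr && c > 0 && mask(r + 1, c - 1))
          uf_union(parent, idx, (r + 1) + (c - 1) * nr);
      }
    }
  }

  IntegerMatrix labels(nr, nc);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) { labels(r, c) = 0; continue; }
      int root = uf_find(parent, r + c * nr);
      if (remap[root] == 0) remap[root] = ++next;
      labels(r, c) = remap[root];
    }
  }
  return labels;
}

// Fill background holes of at most max_hole_px pixels. Holes are
// 4-connected background components not touching the image border.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask, int max_hole_px) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix inv(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      inv(r, c) = !mask(r, c);
  IntegerMatrix lab = cpp_label_components(inv, 4);
  int k = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > k) k = lab(r, c);
  std::vector<int> size(k + 1, 0);
  std::vector<bool> touches(k + 1, false);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      size[l]++;
      if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) touches[l] = true;
    }
  }
  LogicalMatrix out = clone(mask);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l > 0 && !touches[l] && size[l] <= max_hole_px) out(r, c) = true;
    }
  }
  return out;
}

// Geodesic distance (in pixels) from seed pixels, constrained to the
// domain mask, over the 8-neighbour graph with steps 1 and sqrt(2).
// Computed by iterated forward/backward chamfer sweeps until fixpoint,
// which converges exactly to the graph shortest path.
// [[Rcpp::export]]
NumericMatrix cpp_geodesic_distance(const LogicalMatrix& domain,
                                    const LogicalMatrix& seeds) {
  const int nr = domain.nrow(), nc = domain.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("domain and seeds must share shape");
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) && domain(r, c)) dist(r, c) = 0.0;
  const double sq2 = std::sqrt(2.0);
  bool changed = true;
  int iter = 0;
  while (changed && iter < 100) {
    changed = false;
    ++iter;
    // forward sweep
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!domain(r, c)) continue;
        double d = dist(r, c);
        if (r > 0 && domain(r - 1, c) && dist(r - 1, c) + 1.0 < d)
          d = dist(r - 1, c) + 1.0;
        if (c > 0 && domain(r, c - 1) && dist(r, c - 1) + 1.0 < d)
          d = dist(r, c - 1) + 1.0;
        if (r > 0 && c > 0 && domain(r - 1, c - 1) &&
            dist(r - 1, c - 1) + sq2 < d)
          d = dist(r - 1, c - 1) + sq2;
        if (r + 1 < nr && c > 0 && domain(r + 1, c - 1) &&
            dist(r + 1, c - 1) + sq2 < d)
          d = dist(r + 1, c - 1) + sq2;
        if (d < dist(r, c)) { dist(r, c) = d; changed = true; }
      }
    }
    // backward sweep
    for (int c = nc - 1; c >= 0; --c) {
      for (int r = nr - 1; r >= 0; --r) {
        if (!domain(r, c)) continue;
        double d = dist(r, c);
        if (r + 1 < nr && domain(r + 1, c) && dist(r + 1, c) + 1.0 < d)
          d = dist(r + 1, c) + 1.0;
        if (c + 1 < nc && domain(r, c + 1) && dist(r, c + 1) + 1.0 < d)
          d = dist(r, c + 1) + 1.0;
        if (r + 1 < nr && c + 1 < nc && domain(r + 1, c + 1) &&
            dist(r + 1, c + 1) + sq2 < d)
          d = dist(r + 1, c + 1) + sq2;
        if (r > 0 && c + 1 < nc && domain(r - 1, c + 1) &&
            dist(r - 1, c + 1) + sq2 < d)
          d = dist(r - 1, c + 1) + sq2;
        if (d < dist(r, c)) { dist(r, c) = d; changed = true; }
      }
    }
  }
  return dist;
}

static inline int at(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c);
}

// Zhang-Suen thinning to a one-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_skeletonize(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      img(r, c) = mask(r, c) ? 1 : 0;

  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(img, r - 1, c),     p3 = at(img, r - 1, c + 1);
          int p4 = at(img, r, c + 1),     p5 = at(img, r + 1, c + 1);
          int p6 = at(img, r + 1, c),     p7 = at(img, r + 1, c - 1);
          int p8 = at(img, r, c - 1),     p9 = at(img, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i].first, kill[i].second) = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = img(r, c) == 1;
  return out;
}

// Arc length (in pixels) of a thinned skeleton restricted to the pixels
// with the given label: each 8-adjacent pixel pair contributes one edge
// (1 for orthogonal, sqrt(2) for diagonal); isolated pixels count 1.
// [[Rcpp::export]]
NumericVector cpp_skeleton_lengths(const LogicalMatrix& skel,
                                   const IntegerMatrix& labels,
                                   int n_labels) {
  const int nr = skel.nrow(), nc = skel.ncol();
  if (labels.nrow() != nr || labels.ncol() != nc)
    stop("skeleton and labels must share shape");
  NumericVector len(n_labels);
  LogicalVector seen(n_labels);
  const double sq2 = std::sqrt(2.0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!skel(r, c)) continue;
      int l = labels(r, c);
      if (l < 1 || l > n_labels) continue;
      seen[l - 1] = true;
      // forward edges only, each pair counted once
      if (r + 1 < nr && skel(r + 1, c) && labels(r + 1, c) == l)
        len[l - 1] += 1.0;
      if (c + 1 < nc && skel(r, c + 1) && labels(r, c + 1) == l)
        len[l - 1] += 1.0;
      if (r + 1 < nr && c + 1 < nc && skel(r + 1, c + 1) &&
          labels(r + 1, c + 1) == l)
        len[l - 1] += sq2;
      if (r > 0 && c + 1 < nc && skel(r - 1, c + 1) &&
          labels(r - 1, c + 1) == l)
        len[l - 1] += sq2;
    }
  }
  for (int i = 0; i < n_labels; ++i)
    if (seen[i] && len[i] == 0.0) len[i] = 1.0;
  return len;
}

// 1-D lower envelope of parabolas (squared-distance transform).
static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    if (f[q] >= 1e29) continue;
    double s;
    while (true) {
      if (f[v[k]] >= 1e29) { // empty cell so far
        if (k == 0) { v[0] = q; z[0] = -1e30; z[1] = 1e30; s = -1e30; break; }
        --k; continue;
      }
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    if (f[v[k]] < 1e29 || k > 0) {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = 1e30;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = (f[v[k]] >= 1e29) ? 1e30 : dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest TRUE pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix g(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // columns first
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? 0.0 : 1e30;
    edt_1d(f, d, v, z, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  // then rows
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    edt_1d(f, d, v, z, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  return out;
}

// Binary dilation with a Euclidean disc of radius rad_px.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disc(const LogicalMatrix& mask, double rad_px) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  bool any = false;
  for (int i = 0; i < nr * nc; ++i) if (mask[i]) { any = true; break; }
  if (!any) return out;
  NumericMatrix d2 = cpp_edt_sq(mask);
  double r2 = rad_px * rad_px;
  for (int i = 0; i < nr * nc; ++i) out[i] = d2[i] <= r2;
  return out;
}

// Binary erosion with a Euclidean disc of radius rad_px. Pixels outside
// the image border count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_erode_disc(const LogicalMatrix& mask, double rad_px) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix inv(nr, nc);
  bool anybg = false;
  for (int i = 0; i < nr * nc; ++i) {
    inv[i] = !mask[i];
    if (inv[i]) anybg = true;
  }
  LogicalMatrix out(nr, nc);
  double r2 = rad_px * rad_px;
  NumericMatrix d2 = anybg ? cpp_edt_sq(inv) : NumericMatrix(nr, nc);
  if (!anybg) std::fill(d2.begin(), d2.end(), 1e30);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double border = std::min(std::min(r, nr - 1 - r),
                               std::min(c, nc - 1 - c)) + 1.0;
      out(r, c) = mask(r, c) && d2(r, c) > r2 && border * border > r2;
    }
  }
  return out;
}
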