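// Low-level image primitives shared by the segmentation and granulometry
// code: separable min/max filtering with square structuring elements
// (van Herk / Gil-Werman, O(n) per pixel independent of SE size),
// connected-component labelling, an exact Euclidean feature transform
// (Felzenszwalb-Huttenlocher lower envelopes with site labels), hole
// filling by border flood fill, and Bridson Poisson-disc sampling with a
// spatially varying radius for the phantom generator.
//
// Matrices follow R's column-major layout; a pixel is (row i, col j) with
// 0-based indices internally.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 1-D running min/max over a centred window of odd width k with edge
// replication. Classic van Herk: prefix/suffix extrema over blocks of k.
static void run_minmax_1d(const double *x, double *out, int n, int k, bool do_max) {
  int r = k / 2;
  int np = n + 2 * r;
  std::vector<double> p(np), g(np), h(np);
  for (int i = 0; i < np; ++i) {
    int j = i - r;
    if (j < 0) j = 0;
    if (j >= n) j = n - 1;
    p[i] = x[j];
  }
  for (int i = 0; i < np; ++i) {
    if (i % k == 0) g[i] = p[i];
    else g[i] = do_max ? std::max(g[i - 1], p[i]) : std::min(g[i - 1], p[i]);
  }
  for (int i = np - 1; i >= 0; --i) {
    if (i % k == k - 1 || i == np - 1) h[i] = p[i];
    else h[i] = do_max ? std::max(h[i + 1], p[i]) : std::min(h[i + 1], p[i]);
  }
  for (int i = 0; i < n; ++i) {
    int lo = i, hi = i + 2 * r; // window [i-r, i+r] in padded coordinates
    out[i] = do_max ? std::max(h[lo], g[hi]) : std::min(h[lo], g[hi]);
  }
}

// [[Rcpp::export(name = ".cpp_sq_filter")]]
NumericMatrix cpp_sq_filter(NumericMatrix img, int k, bool do_max) {
  if (k < 1 || k % 2 == 0) stop("structuring element width must be a positive odd integer");
  int nr = img.nrow(), nc = img.ncol();
  if (k > nr || k > nc) stop("structuring element larger than image");
  NumericMatrix out(nr, nc);
  if (k == 1) { std::copy(img.begin(), img.end(), out.begin()); return out; }
  std::vector<double> buf(std::max(nr, nc)), res(std::max(nr, nc));
  // columns first (contiguous in memory)
  for (int j = 0; j < nc; ++j) {
    const double *col = &img[(size_t)j * nr];
    run_minmax_1d(col, &out[(size_t)j * nr], nr, k, do_max);
  }
  // then rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = out(i, j);
    run_minmax_1d(buf.data(), res.data(), nc, k, do_max);
    for (int j = 0; j < nc; ++j) out(i, j) = res[j];
  }
  return out;
}

// Connected components of a logical mask, 4- or 8-connectivity.
// Labels are 1..n in scan order of the first pixel encountered.
// [[Rcpp::export(name = ".cpp_label")]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int d = 0; d < nnb; ++d) {
          int ni = ci + di8[d], nj = cj + dj8[d];
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Exact Euclidean feature transform. `sites` holds positive labels at site
// pixels, 0 elsewhere. Returns the distance (in pixels) from every pixel to
// its nearest site and the label of that site. Two-pass: nearest site within
// each column, then Felzenszwalb lower envelope along rows.
// [[Rcpp::export(name = ".cpp_feature_transform")]]
List cpp_feature_transform(IntegerMatrix sites) {
  int nr = sites.nrow(), nc = sites.ncol();
  bool any_site = false;
  for (int idx = 0; idx < nr * nc; ++idx)
    if (sites[idx] > 0) { any_site = true; break; }
  NumericMatrix dist(nr, nc);
  IntegerMatrix lab(nr, nc);
  if (!any_site) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    return List::create(_["dist"] = dist, _["label"] = lab);
  }
  // BIG is a finite sentinel for "no site in this column"; any true site
  // beats it in the envelope, so the result is exact when a site exists.
  const double BIG = 4.0 * ((double)nr + nc) * ((double)nr + nc) + 10.0;
  NumericMatrix d1(nr, nc);     // vertical distance to nearest site in column
  IntegerMatrix l1(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double d = BIG; int l = 0;
    for (int i = 0; i < nr; ++i) {
      if (sites(i, j) > 0) { d = 0; l = sites(i, j); }
      else if (d < BIG) d += 1;
      d1(i, j) = d; l1(i, j) = l;
    }
    d = BIG; l = 0;
    for (int i = nr - 1; i >= 0; --i) {
      if (sites(i, j) > 0) { d = 0; l = sites(i, j); }
      else if (d < BIG) d += 1;
      if (d < d1(i, j)) { d1(i, j) = d; l1(i, j) = l; }
    }
  }
  const double INF = 1e30;
  std::vector<int> v(nc);
  std::vector<double> z(nc + 1), f(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double d = std::min(d1(i, j), BIG);
      f[j] = d * d;
    }
    int kk = 0;
    v[0] = 0;
    z[0] = -INF; z[1] = INF;
    for (int q = 1; q < nc; ++q) {
      double s;
      while (true) {
        int p = v[kk];
        s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * q - 2.0 * p);
        if (s <= z[kk] && kk > 0) { --kk; }
        else break;
      }
      if (s <= z[kk] && kk == 0) {
        v[0] = q; z[0] = -INF; z[1] = INF;
      } else {
        ++kk;
        v[kk] = q;
        z[kk] = s;
        z[kk + 1] = INF;
      }
    }
    int q = 0;
    for (int j = 0; j < nc; ++j) {
      while (q < kk && z[q + 1] < j) ++q;
      int p = v[q];
      double dd = (j - (double)p) * (j - (double)p) + f[p];
      dist(i, j) = std::sqrt(dd);
      lab(i, j) = l1(i, p);
    }
  }
  return List::create(_["dist"] = dist, _["label"] = lab);
}

// Fill interior holes: background connected (4-conn) to the image border
// stays background, everything else becomes foreground.
// [[Rcpp::export(name = ".cpp_fill_holes")]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside((size_t)nr * nc, 0);
  std::vector<int> stack;
  auto push_bg = [&](int i, int j) {
    size_t idx = (size_t)i + (size_t)j * nr;
    if (!mask(i, j) && !outside[idx]) { outside[idx] = 1; stack.push_back((int)idx); }
  };
  for (int i = 0; i < nr; ++i) { push_bg(i, 0); push_bg(i, nc - 1); }
  for (int j = 0; j < nc; ++j) { push_bg(0, j); push_bg(nr - 1, j); }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int ci = idx % nr, cj = idx / nr;
    for (int d = 0; d < 4; ++d) {
      int ni = ci + di[d], nj = cj + dj[d];
      if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
      push_bg(ni, nj);
    }
  }
  LogicalMatrix out(nr, nc);
  for (size_t idx = 0; idx < (size_t)nr * nc; ++idx)
    out[idx] = mask[idx] || !outside[idx];
  return out;
}

// Per-label pixel statistics for a label map: area, centroid and second
// moments (for equivalent-ellipse axes). Returns a matrix with one row per
// label 1..max(label): n, sum_i, sum_j, sum_ii, sum_jj, sum_ij.
// [[Rcpp::export(name = ".cpp_label_stats")]]
NumericMatrix cpp_label_stats(IntegerMatrix lab, int nlab) {
  NumericMatrix out(nlab, 6);
  int nr = lab.nrow(), nc = lab.ncol();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l <= 0 || l > nlab) continue;
      out(l - 1, 0) += 1;
      out(l - 1, 1) += i;
      out(l - 1, 2) += j;
      out(l - 1, 3) += (double)i * i;
      out(l - 1, 4) += (double)j * j;
      out(l - 1, 5) += (double)i * j;
    }
  }
  return out;
}

// Bridson Poisson-disc sampling with spatially varying minimum distance.
// `rmap` gives the local radius (in pixels) at every pixel; points are
// confined to `domain`. Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".cpp_poisson_disc")]]
NumericMatrix cpp_poisson_disc(LogicalMatrix domain, NumericMatrix rmap, int k_tries) {
  int nr = domain.nrow(), nc = domain.ncol();
  double rmin = R_PosInf, rmax = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (domain(i, j)) {
        rmin = std::min(rmin, rmap(i, j));
        rmax = std::max(rmax, rmap(i, j));
      }
  if (!R_FINITE(rmin) || rmin <= 0) stop("empty domain or non-positive radius map");
  double cell = rmin / std::sqrt(2.0);
  int gr = (int)std::ceil(nr / cell), gc = (int)std::ceil(nc / cell);
  std::vector<std::vector<int> > grid((size_t)gr * gc);
  std::vector<double> py, px;
  std::vector<int> active;
  RNGScope scope;
  // initial point: random domain pixel
  for (int tries = 0; tries < 10000; ++tries) {
    int i = (int)std::floor(unif_rand() * nr);
    int j = (int)std::floor(unif_rand() * nc);
    if (i >= nr) i = nr - 1;
    if (j >= nc) j = nc - 1;
    if (domain(i, j)) {
      py.push_back(i + 0.5); px.push_back(j + 0.5);
      grid[(size_t)(int)(py[0] / cell) * gc + (int)(px[0] / cell)].push_back(0);
      active.push_back(0);
      break;
    }
  }
  if (py.empty()) stop("could not place an initial point in the domain");
  auto ok_here = [&](double y, double x, double r) {
    int gi = (int)(y / cell), gj = (int)(x / cell);
    int rad = (int)std::ceil(rmax / cell) + 1;
    for (int a = std::max(0, gi - rad); a <= std::min(gr - 1, gi + rad); ++a)
      for (int b = std::max(0, gj - rad); b <= std::min(gc - 1, gj + rad); ++b)
        for (int idx : grid[(size_t)a * gc + b]) {
          double dy = py[idx] - y, dx = px[idx] - x;
          int pi = std::min(nr - 1, std::max(0, (int)py[idx]));
          int pj = std::min(nc - 1, std::max(0, (int)px[idx]));
          double rr = std::max(r, (double)rmap(pi, pj));
          if (dy * dy + dx * dx < rr * rr) return false;
        }
    return true;
  };
  while (!active.empty()) {
    int ai = (int)std::floor(unif_rand() * active.size());
    if (ai >= (int)active.size()) ai = (int)active.size() - 1;
    int p = active[ai];
    int pi = std::min(nr - 1, std::max(0, (int)py[p]));
    int pj = std::min(nc - 1, std::max(0, (int)px[p]));
    double r = rmap(pi, pj);
    bool placed = false;
    for (int t = 0; t < k_tries; ++t) {
      double ang = unif_rand() * 2 * M_PI;
      double rad = r * (1 + unif_rand());
      double y = py[p] + rad * std::sin(ang);
      double x = px[p] + rad * std::cos(ang);
      int yi = (int)y, xj = (int)x;
      if (yi < 0 || xj < 0 || yi >= nr || xj >= nc || !domain(yi, xj)) continue;
      double rloc = rmap(yi, xj);
      if (!ok_here(y, x, rloc)) continue;
      int id = (int)py.size();
      py.push_back(y); px.push_back(x);
      grid[(size_t)(int)(y / cell) * gc + (int)(x / cell)].push_back(id);
      active.push_back(id);
      placed = true;
      break;
    }
    if (!placed) { active[ai] = active.back(); active.pop_back(); }
  }
  NumericMatrix out((int)py.size(), 2);
  for (int i = 0; i < (int)py.size(); ++i) { out(i, 0) = py[i]; out(i, 1) = px[i]; }
  return out;
}
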