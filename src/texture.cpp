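#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Texture-matrix builders operate on a discretized 2-D slice: integer levels
// 1..ng inside the mask, 0 outside. Counts are returned unnormalized; the R
// layer normalizes and computes the named features.

// [[Rcpp::export]]
NumericMatrix cpp_glcm(const IntegerMatrix& img, int ng, int dr, int dc) {
  NumericMatrix out(ng, ng);
  int nr = img.nrow(), nc = img.ncol();
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int i = img(r, c);
      if (i <= 0) continue;
      int r2 = r + dr, c2 = c + dc;
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int j = img(r2, c2);
      if (j <= 0) continue;
      out(i - 1, j - 1) += 1.0;  // symmetric accumulation
      out(j - 1, i - 1) += 1.0;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm(const IntegerMatrix& img, int ng, int dr, int dc) {
  int nr = img.nrow(), nc = img.ncol();
  int maxlen = std::max(nr, nc);
  NumericMatrix out(ng, maxlen);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      // start of a line: predecessor out of bounds
      int rp = r - dr, cp = c - dc;
      if (rp >= 0 && rp < nr && cp >= 0 && cp < nc) continue;
      int cur = 0, len = 0;
      int rr = r, cc = c;
      while (rr >= 0 && rr < nr && cc >= 0 && cc < nc) {
        int v = img(rr, cc);
        if (v == cur && v > 0) {
          ++len;
        } else {
          if (cur > 0 && len > 0) out(cur - 1, len - 1) += 1.0;
          cur = v;
          len = (v > 0) ? 1 : 0;
        }
        rr += dr; cc += dc;
      }
      if (cur > 0 && len > 0) out(cur - 1, len - 1) += 1.0;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_glszm(const IntegerMatrix& img, int ng) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<char> seen(nr * nc, 0);
  std::vector<std::pair<int,int> > zones;  // (level, size)
  int maxsize = 1;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int lev = img(r, c);
      if (lev <= 0 || seen[r + nr * c]) continue;
      // BFS over 8-connected equal-level pixels
      int size = 0;
      std::queue<std::pair<int,int> > q;
      q.push(std::make_pair(r, c));
      seen[r + nr * c] = 1;
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        ++size;
        for (int a = -1; a <= 1; ++a) {
          for (int b = -1; b <= 1; ++b) {
            if (a == 0 && b == 0) continue;
            int r2 = p.first + a, c2 = p.second + b;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (seen[r2 + nr * c2] || img(r2, c2) != lev) continue;
            seen[r2 + nr * c2] = 1;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
      zones.push_back(std::make_pair(lev, size));
      if (size > maxsize) maxsize = size;
    }
  }
  NumericMatrix out(ng, maxsize);
  for (size_t z = 0; z < zones.size(); ++z)
    out(zones[z].first - 1, zones[z].second - 1) += 1.0;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gldm(const IntegerMatrix& img, int ng, int alpha) {
  int nr = img.nrow(), nc = img.ncol();
  // dependence of a pixel = 1 + number of masked Chebyshev-1 neighbours within
  // gray-level tolerance alpha of the centre
  int maxdep = 10;  // up to 1 + 8 neighbours + 1 slack
  NumericMatrix out(ng, maxdep);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int i = img(r, c);
      if (i <= 0) continue;
      int dep = 1;
      for (int a = -1; a <= 1; ++a) {
        for (int b = -1; b <= 1; ++b) {
          if (a == 0 && b == 0) continue;
          int r2 = r + a, c2 = c + b;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int j = img(r2, c2);
          if (j > 0 && std::abs(i - j) <= alpha) ++dep;
        }
      }
      out(i - 1, dep - 1) += 1.0;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(const IntegerMatrix& img, int ng) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(ng, 2);  // col 0: n_i, col 1: s_i
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int i = img(r, c);
      if (i <= 0) continue;
      double sum = 0.0; int cnt = 0;
      for (int a = -1; a <= 1; ++a) {
        for (int b = -1; b <= 1; ++b) {
          if (a == 0 && b == 0) continue;
          int r2 = r + a, c2 = c + b;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int j = img(r2, c2);
          if (j > 0) { sum += j; ++cnt; }
        }
      }
      if (cnt == 0) continue;  // isolated pixel: no valid neighbourhood
      out(i - 1, 0) += 1.0;
      out(i - 1, 1) += std::fabs((double)i - sum / cnt);
    }
  }
  return out;
}

// 6-connected 3-D component labelling for tumor-mask cleanup.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const LogicalVector& mask, const IntegerVector& dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int i = v % d1, j = (v / d1) % d2, k = v / (d1 * d2);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int i2 = i + di[t], j2 = j + dj[t], k2 = k + dk[t];
        if (i2 < 0 || i2 >= d1 || j2 < 0 || j2 >= d2 || k2 < 0 || k2 >= d3)
          continue;
        int w = i2 + d1 * (j2 + d2 * k2);
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Trilinear resampling on the volume's own voxel grid. For output voxel x
// (0-based index) the sampling point is  M x + off (+ disp(x)),  in voxel
// units of the input. Points outside the grid get `fill`.
// [[Rcpp::export]]
NumericVector cpp_resample3(const NumericVector& vol, const IntegerVector& dim,
                            const NumericMatrix& M, const NumericVector& off,
                            Nullable<NumericVector> disp,
                            double fill, bool clampEdge = false) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = d1 * d2 * d3;
  NumericVector out(n);
  bool hasDisp = disp.isNotNull();
  NumericVector dsp;
  if (hasDisp) dsp = disp.get();
  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        int idx = i + d1 * (j + d2 * k);
        double x = i, y = j, z = k;
        if (hasDisp) {
          x += dsp[idx];
          y += dsp[idx + n];
          z += dsp[idx + 2 * n];
        }
        double tx = M(0,0)*x + M(0,1)*y + M(0,2)*z + off[0];
        double ty = M(1,0)*x + M(1,1)*y + M(1,2)*z + off[1];
        double tz = M(2,0)*x + M(2,1)*y + M(2,2)*z + off[2];
        if (!std::isfinite(tx) || !std::isfinite(ty) || !std::isfinite(tz)) {
          out[idx] = fill;
          continue;
        }
        if (tx < 0 || tx > d1 - 1 || ty < 0 || ty > d2 - 1 ||
            tz < 0 || tz > d3 - 1) {
          if (!clampEdge) {
            out[idx] = fill;
            continue;
          }
          tx = std::min(std::max(tx, 0.0), (double)(d1 - 1));
          ty = std::min(std::max(ty, 0.0), (double)(d2 - 1));
          tz = std::min(std::max(tz, 0.0), (double)(d3 - 1));
        }
        int x0 = (int)std::floor(tx), y0 = (int)std::floor(ty),
            z0 = (int)std::floor(tz);
        int x1 = std::min(x0 + 1, d1 - 1), y1 = std::min(y0 + 1, d2 - 1),
            z1 = std::min(z0 + 1, d3 - 1);
        double fx = tx - x0, fy = ty - y0, fz = tz - z0;
        double c000 = vol[x0 + d1 * (y0 + d2 * z0)];
        double c100 = vol[x1 + d1 * (y0 + d2 * z0)];
        double c010 = vol[x0 + d1 * (y1 + d2 * z0)];
        double c110 = vol[x1 + d1 * (y1 + d2 * z0)];
        double c001 = vol[x0 + d1 * (y0 + d2 * z1)];
        double c101 = vol[x1 + d1 * (y0 + d2 * z1)];
        double c011 = vol[x0 + d1 * (y1 + d2 * z1)];
        double c111 = vol[x1 + d1 * (y1 + d2 * z1)];
        double c00 = c000 * (1 - fx) + c100 * fx;
        double c10 = c010 * (1 - fx) + c110 * fx;
        double c01 = c001 * (1 - fx) + c101 * fx;
        double c11 = c011 * (1 - fx) + c111 * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[idx] = c0 * (1 - fz) + c1 * fz;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Trilinear point sampling (for metric evaluation at sparse sample points).
// pts: 3 x m matrix of 0-based voxel coordinates; outside -> NA.
// [[Rcpp::export]]
NumericVector cpp_sample3(const NumericVector& vol, const IntegerVector& dim,
                          const NumericMatrix& pts) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int m = pts.ncol();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    double tx = pts(0, s), ty = pts(1, s), tz = pts(2, s);
    if (!std::isfinite(tx) || !std::isfinite(ty) || !std::isfinite(tz) ||
        tx < 0 || tx > d1 - 1 || ty < 0 || ty > d2 - 1 ||
        tz < 0 || tz > d3 - 1) {
      out[s] = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(tx), y0 = (int)std::floor(ty),
        z0 = (int)std::floor(tz);
    int x1 = std::min(x0 + 1, d1 - 1), y1 = std::min(y0 + 1, d2 - 1),
        z1 = std::min(z0 + 1, d3 - 1);
    double fx = tx - x0, fy = ty - y0, fz = tz - z0;
    double c00 = vol[x0 + d1*(y0 + d2*z0)] * (1-fx) + vol[x1 + d1*(y0 + d2*z0)] * fx;
    double c10 = vol[x0 + d1*(y1 + d2*z0)] * (1-fx) + vol[x1 + d1*(y1 + d2*z0)] * fx;
    double c01 = vol[x0 + d1*(y0 + d2*z1)] * (1-fx) + vol[x1 + d1*(y0 + d2*z1)] * fx;
    double c11 = vol[x0 + d1*(y1 + d2*z1)] * (1-fx) + vol[x1 + d1*(y1 + d2*z1)] * fx;
    double c0 = c00 * (1-fy) + c10 * fy;
    double c1 = c01 * (1-fy) + c11 * fy;
    out[s] = c0 * (1-fz) + c1 * fz;
  }
  return out;
}

static void smooth_axis(std::vector<double>& v, int d1, int d2, int d3,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double ksum = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    ksum += kern[t + radius];
  }
  for (size_t t = 0; t < kern.size(); ++t) kern[t] /= ksum;
  int dims[3] = {d1, d2, d3};
  int len = dims[axis];
  std::vector<double> line(len);
  int n = d1 * d2 * d3;
  std::vector<double> out(n);
  int stride = (axis == 0) ? 1 : (axis == 1 ? d1 : d1 * d2);
  // enumerate every line along `axis` via the two remaining axes
  int oa = (axis == 0) ? 1 : 0;
  int ob = (axis == 2) ? 1 : 2;
  int la = dims[oa], lb = dims[ob];
  int sa = (oa == 0) ? 1 : (oa == 1 ? d1 : d1 * d2);
  int sb = (ob == 0) ? 1 : (ob == 1 ? d1 : d1 * d2);
  for (int a = 0; a < la; ++a) {
    for (int b = 0; b < lb; ++b) {
      int base = a * sa + b * sb;
      for (int t = 0; t < len; ++t) line[t] = v[base + t * stride];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0;
        for (int u = -radius; u <= radius; ++u) {
          int p = t + u;
          if (p < 0) p = -p;                    // reflect
          if (p > len - 1) p = 2 * (len - 1) - p;
          if (p < 0) p = 0;
          acc += kern[u + radius] * line[p];
        }
        out[base + t * stride] = acc;
      }
    }
  }
  v = out;
}

// Separable Gaussian smoothing with reflective boundaries; sigma per axis in
// voxel units.
// [[Rcpp::export]]
NumericVector cpp_smooth3(const NumericVector& vol, const IntegerVector& dim,
                          const NumericVector& sigma) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  smooth_axis(v, d1, d2, d3, 0, sigma[0]);
  smooth_axis(v, d1, d2, d3, 1, sigma[1]);
  smooth_axis(v, d1, d2, d3, 2, sigma[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}
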