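#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Gaussian transform on a regular lattice: out_i = sum_j exp(-|f_i - f_j|^2 / 2) v_j
// via B-spline splatting, a spectrally deconvolved separable blur, and
// B-spline slicing; also returns each point's effective lattice self-weight
// so callers can exclude the j = i term exactly.

// centered uniform B-spline of degree p
static double bspline_val(int p, double x) {
  if (p == 0) return (x >= -0.5 && x < 0.5) ? 1.0 : 0.0;
  double h = (p + 1) * 0.5;
  if (x <= -h || x >= h) return 0.0;
  return ((h + x) * bspline_val(p - 1, x + 0.5) +
          (h - x) * bspline_val(p - 1, x - 0.5)) / p;
}

static void bspline_weights(double g, int p, int &left, double *w) {
  if (p % 2 == 1) left = (int)std::floor(g) - (p - 1) / 2;
  else            left = (int)std::floor(g + 0.5) - p / 2;
  for (int o = 0; o <= p; ++o) w[o] = bspline_val(p, g - (left + o));
}

// Expand the tensor-product corner indices and weights of one point;
// buffers must hold S^d entries. Returns the corner count.
static int expand_corners(const int *left, const double *wts, int d, int S,
                          const int *stride,
                          long *cidx, double *cw, long *tidx, double *tw) {
  cidx[0] = 0; cw[0] = 1.0;
  int cnt = 1;
  for (int a = 0; a < d; ++a) {
    int ncnt = 0;
    for (int e = 0; e < cnt; ++e) {
      for (int o = 0; o < S; ++o) {
        tidx[ncnt] = cidx[e] + (long)(left[a] + o) * stride[a];
        tw[ncnt] = cw[e] * wts[a * S + o];
        ++ncnt;
      }
    }
    std::copy(tidx, tidx + ncnt, cidx);
    std::copy(tw, tw + ncnt, cw);
    cnt = ncnt;
  }
  return cnt;
}

// [[Rcpp::export(name = "lattice_gauss_transform_cpp")]]
List lattice_gauss_transform(NumericMatrix feat, NumericMatrix vals,
                             double spacing, NumericVector blur, int order = 3) {
  const int N = feat.nrow(), d = feat.ncol(), K = vals.ncol();
  const int R = blur.size() - 1, S = order + 1;
  double corners_d = 1.0;
  for (int a = 0; a < d; ++a) corners_d *= S;
  if (corners_d > 5e5) stop("B-spline order too high for this dimensionality");
  const int corners = (int)corners_d;

  std::vector<double> fmin(d, R_PosInf);
  for (int a = 0; a < d; ++a)
    for (int i = 0; i < N; ++i) fmin[a] = std::min(fmin[a], feat(i, a));
  std::vector<int> left((size_t)N * d);
  std::vector<double> wts((size_t)N * d * S);
  std::vector<int> nd(d, 1), stride(d), minL(d, INT_MAX);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < d; ++a) {
      double g = (feat(i, a) - fmin[a]) / spacing + order;
      int L; double w[8];
      bspline_weights(g, order, L, w);
      left[(size_t)i * d + a] = L;
      for (int o = 0; o < S; ++o) wts[((size_t)i * d + a) * S + o] = w[o];
      nd[a] = std::max(nd[a], L + S + 1);
      minL[a] = std::min(minL[a], L);
    }
  // trim unused lower planes
  for (int a = 0; a < d; ++a) nd[a] -= minL[a];
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < d; ++a) left[(size_t)i * d + a] -= minL[a];
  long T = 1;
  for (int a = 0; a < d; ++a) { stride[a] = (int)T; T *= nd[a]; }
  if (T * (long)K > 200000000L) stop("lattice too large; increase spacing");
  std::vector<double> grid((size_t)T * K, 0.0);
  std::vector<unsigned char> occ((size_t)T, 0);
  std::vector<long> cidx(corners), tidx(corners);
  std::vector<double> cw(corners), tw(corners);

  // splat
  for (int i = 0; i < N; ++i) {
    int cnt = expand_corners(&left[(size_t)i * d], &wts[(size_t)i * d * S],
                             d, S, stride.data(),
                             cidx.data(), cw.data(), tidx.data(), tw.data());
    for (int c = 0; c < cnt; ++c) {
      const double w = cw[c];
      if (w == 0) continue;
      const size_t base = (size_t)cidx[c] * K;
      occ[cidx[c]] = 1;
      for (int k = 0; k < K; ++k) grid[base + k] += w * vals(i, k);
    }
  }

  // separable blur along each axis (zero boundary), skipping empty lines
  int ndmax = 1;
  for (int a = 0; a < d; ++a) ndmax = std::max(ndmax, nd[a]);
  std::vector<double> line((size_t)ndmax);
  for (int a = 0; a < d; ++a) {
    const int na = nd[a], sa = stride[a];
    for (long outer = 0; outer < T / na; ++outer) {
      long rem = outer, start = 0;
      for (int b = 0; b < d; ++b) {
        if (b == a) continue;
        long q = rem % nd[b]; rem /= nd[b];
        start += q * stride[b];
      }
      int lo = na, hi = -1;
      for (int p = 0; p < na; ++p)
        if (occ[start + (long)p * sa]) { if (p < lo) lo = p; if (p > hi) hi = p; }
      if (hi < 0) continue;
      const int olo = std::max(0, lo - R), ohi = std::min(na - 1, hi + R);
      for (int k = 0; k < K; ++k) {
        for (int p = lo; p <= hi; ++p)
          line[p] = grid[(size_t)(start + (long)p * sa) * K + k];
        for (int p = olo; p <= ohi; ++p) {
          double acc = 0.0;
          const int t0 = std::max(lo, p - R), t1 = std::min(hi, p + R);
          for (int t = t0; t <= t1; ++t) acc += blur[std::abs(p - t)] * line[t];
          grid[(size_t)(start + (long)p * sa) * K + k] = acc;
        }
      }
      for (int p = olo; p <= ohi; ++p) occ[start + (long)p * sa] = 1;
    }
  }

  // slice + separable per-point lattice self-weight
  NumericMatrix out(N, K);
  NumericVector selfw(N);
  for (int i = 0; i < N; ++i) {
    int cnt = expand_corners(&left[(size_t)i * d], &wts[(size_t)i * d * S],
                             d, S, stride.data(),
                             cidx.data(), cw.data(), tidx.data(), tw.data());
    for (int c = 0; c < cnt; ++c) {
      const double w = cw[c];
      if (w == 0) continue;
      const size_t base = (size_t)cidx[c] * K;
      for (int k = 0; k < K; ++k) out(i, k) += w * grid[base + k];
    }
    double sw = 1.0;
    for (int a = 0; a < d; ++a) {
      const double *wa = &wts[((size_t)i * d + a) * S];
      double acc = 0.0;
      for (int o1 = 0; o1 < S; ++o1)
        for (int o2 = 0; o2 < S; ++o2) {
          int off = o1 - o2; if (off < 0) off = -off;
          if (off <= R) acc += wa[o1] * blur[off] * wa[o2];
        }
      sw *= acc;
    }
    selfw[i] = sw;
  }
  return List::create(_["values"] = out, _["self_weight"] = selfw);
}
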