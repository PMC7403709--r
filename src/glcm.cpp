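#include <Rcpp.h>
using namespace Rcpp;

// Symmetrised gray-level co-occurrence counts for K pixel offsets in one pass.
// q holds levels in [0, G-1]; pairs with either pixel outside the image are
// skipped. Each ordered pair (i,j) increments both (i,j) and (j,i), i.e. the
// result is C + C^T for the ordered count matrix C.
// [[Rcpp::export]]
IntegerVector glcm_counts_cpp(const IntegerMatrix& q, int G,
                              const IntegerVector& dr, const IntegerVector& dc) {
  const int H = q.nrow(), W = q.ncol(), K = dr.size();
  const int* qp = q.begin();
  for (R_xlen_t t = 0; t < static_cast<R_xlen_t>(H) * W; ++t) {
    if (qp[t] < 0 || qp[t] >= G) stop("quantized values must lie in [0, G-1]");
  }
  IntegerVector out(static_cast<R_xlen_t>(G) * G * K);
  for (int k = 0; k < K; ++k) {
    int* cnt = out.begin() + static_cast<R_xlen_t>(k) * G * G;
    const int a = dr[k], b = dc[k];
    const int r0 = std::max(0, -a), r1 = std::min(H, H - a);
    const int c0 = std::max(0, -b), c1 = std::min(W, W - b);
    for (int c = c0; c < c1; ++c) {
      const int* p1 = qp + static_cast<R_xlen_t>(c) * H;
      const int* p2 = qp + static_cast<R_xlen_t>(c + b) * H + a;
      for (int r = r0; r < r1; ++r) {
        const int i = p1[r], j = p2[r];
        ++cnt[i + G * j];
        ++cnt[j + G * i];
      }
    }
  }
  out.attr("dim") = Dimension(G, G, K);
  return out;
}

// Accumulate the transmittance field of anti-aliased filled ellipses drawn
// over an H x W canvas: T(p) = prod_k (1 - alpha_k(p)), where alpha_k is 1
// inside nucleus k, 0 outside, with a ~1 px soft edge. Because all nuclei
// share one colour, the composited image is col + (bg - col) * T, so a
// single field suffices for any number of overlapping nuclei.
// [[Rcpp::export]]
NumericMatrix nuclei_transmittance_cpp(int height, int width,
                                       const NumericVector& cx,
                                       const NumericVector& cy,
                                       const NumericVector& radius,
                                       const NumericVector& theta,
                                       const NumericVector& aspect) {
  NumericMatrix T(height, width);
  std::fill(T.begin(), T.end(), 1.0);
  const int n = cx.size();
  for (int k = 0; k < n; ++k) {
    const double a = radius[k] * std::sqrt(aspect[k]);
    const double b = radius[k] / std::sqrt(aspect[k]);
    const double rmax = std::max(a, b), rmin = std::min(a, b);
    const double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    const int r0 = std::max(0, (int)std::floor(cy[k] - rmax - 1));
    const int r1 = std::min(height - 1, (int)std::ceil(cy[k] + rmax));
    const int c0 = std::max(0, (int)std::floor(cx[k] - rmax - 1));
    const int c1 = std::min(width - 1, (int)std::ceil(cx[k] + rmax));
    for (int c = c0; c <= c1; ++c) {
      const double dx = c + 0.5 - cx[k];
      double* col = &T(0, c);
      for (int r = r0; r <= r1; ++r) {
        const double dy = r + 0.5 - cy[k];
        const double u = (dx * ct + dy * st) / a;
        const double v = (-dx * st + dy * ct) / b;
        const double d = std::sqrt(u * u + v * v);
        double alpha = 0.5 + (1.0 - d) * rmin;
        if (alpha <= 0.0) continue;
        if (alpha > 1.0) alpha = 1.0;
        col[r] *= 1.0 - alpha;
      }
    }
  }
  return T;
}

// Compose the final RGB tile: channel = clamp(nuc + (bg - nuc) * T + noise).
// [[Rcpp::export]]
NumericVector compose_channels_cpp(const NumericMatrix& T,
                                   const NumericMatrix& noise,
                                   const NumericVector& bg,
                                   const NumericVector& nuc) {
  const int H = T.nrow(), W = T.ncol();
  const R_xlen_t n = static_cast<R_xlen_t>(H) * W;
  NumericVector out(n * 3);
  const double* tp = T.begin();
  const double* np = noise.begin();
  const bool has_noise = noise.size() == n;
  for (int ch = 0; ch < 3; ++ch) {
    double* o = out.begin() + ch * n;
    const double base = nuc[ch], span = bg[ch] - nuc[ch];
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = base + span * tp[i] + (has_noise ? np[i] : 0.0);
      o[i] = v < 0.0 ? 0.0 : (v > 255.0 ? 255.0 : v);
    }
  }
  out.attr("dim") = Dimension(H, W, 3);
  return out;
}
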