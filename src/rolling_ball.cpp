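#include <Rcpp.h>
using namespace Rcpp;

// Grayscale opening with a non-flat ball structuring element: the classic
// rolling-ball background estimate. The ball has radius `radius` in both the
// spatial plane and the intensity axis; kernel height at planar distance d is
// sqrt(radius^2 - d^2). Out-of-image kernel support is simply skipped
// (equivalent to restricting the minimum/maximum to in-bounds pixels).

static void ball_kernel(double radius, std::vector<int> &dr,
                        std::vector<int> &dc, std::vector<double> &hgt) {
  int r = (int)std::floor(radius);
  for (int i = -r; i <= r; ++i) {
    for (int j = -r; j <= r; ++j) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 <= radius * radius) {
        dr.push_back(i);
        dc.push_back(j);
        hgt.push_back(std::sqrt(radius * radius - d2));
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix rolling_ball_background(NumericMatrix img, double radius) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> dr, dc;
  std::vector<double> hgt;
  ball_kernel(radius, dr, dc, hgt);
  size_t K = hgt.size();

  NumericMatrix ero(H, W), bg(H, W);
  // erosion: min over kernel of img(p+o) - b(o)
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double m = R_PosInf;
      for (size_t k = 0; k < K; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        double v = img(rr, cc) - hgt[k];
        if (v < m) m = v;
      }
      ero(r, c) = m;
    }
  }
  // dilation of the erosion: max over kernel of ero(p+o) + b(o)
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double m = R_NegInf;
      for (size_t k = 0; k < K; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        double v = ero(rr, cc) + hgt[k];
        if (v > m) m = v;
      }
      bg(r, c) = m;
    }
  }
  return bg;
}
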