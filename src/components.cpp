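#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 4-connected component labeling of a binary mask by flood fill.
// mask: logical matrix; returns integer matrix of labels (0 = background),
// labels assigned in raster order of each component's first pixel.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// One-pass image finalization: img <- clamp(round(a*img + b + noise), 0,
// maxval), with noise ~ N(0, noise_sd) drawn from R's RNG (so results are
// reproducible under set.seed). Modifies img in place.
// [[Rcpp::export(name = ".finalize_image")]]
void finalize_image(NumericMatrix img, double a, double b,
                    double noise_sd, double maxval) {
  const R_xlen_t n = img.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = a * img[i] + b + R::rnorm(0.0, noise_sd);
    v = std::nearbyint(v);
    img[i] = v < 0 ? 0 : (v > maxval ? maxval : v);
  }
}

// Per-blob Gaussian accumulation: adds peak * exp(-d^2 / (2 sigma^2))
// around each center onto img (modified in place), truncated at 4 sigma.
// centers in pixel coordinates (x_px = column, y_px = row), 1-based.
// [[Rcpp::export(name = ".add_gaussian_blobs")]]
void add_gaussian_blobs(NumericMatrix img, const NumericMatrix &centers_px,
                        double sigma_px, double peak) {
  const int nr = img.nrow(), nc = img.ncol();
  const double inv2s2 = 1.0 / (2.0 * sigma_px * sigma_px);
  const int halo = (int)std::ceil(4.0 * sigma_px);
  for (int i = 0; i < centers_px.nrow(); ++i) {
    const double cx = centers_px(i, 0), cy = centers_px(i, 1);
    const int c0 = std::max(0, (int)std::floor(cx - halo) - 1);
    const int c1 = std::min(nc - 1, (int)std::ceil(cx + halo) - 1);
    const int r0 = std::max(0, (int)std::floor(cy - halo) - 1);
    const int r1 = std::min(nr - 1, (int)std::ceil(cy + halo) - 1);
    for (int c = c0; c <= c1; ++c) {
      const double dx = (c + 1) - cx;
      for (int r = r0; r <= r1; ++r) {
        const double dy = (r + 1) - cy;
        img(r, c) += peak * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
}
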