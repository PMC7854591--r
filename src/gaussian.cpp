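#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Separable 3D Gaussian filter with replicate boundary handling.
// Kernel half-width is ceil(2*sigma), the usual truncation for 3D
// volume filtering.
// [[Rcpp::export]]
NumericVector gaussian_blur_cpp(NumericVector vol, IntegerVector dims,
                                double sigma) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (vol.size() != n) stop("volume length does not match dims");
    if (sigma <= 0) stop("sigma must be positive");

    const int r = (int)std::ceil(2.0 * sigma);
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) {
        k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
        ksum += k[i + r];
    }
    for (double &w : k) w /= ksum;

    NumericVector a = clone(vol);
    NumericVector b(n);

    // helper lambda per axis
    auto pass = [&](NumericVector &src, NumericVector &dst, int axis) {
        int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
        R_xlen_t stride = axis == 0 ? 1 :
            (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
        int n1 = axis == 0 ? ny : nx;
        int n2 = axis == 2 ? ny : nz;
        for (int j2 = 0; j2 < n2; ++j2) {
            for (int j1 = 0; j1 < n1; ++j1) {
                R_xlen_t base;
                if (axis == 0)
                    base = (R_xlen_t)nx * (j1 + (R_xlen_t)ny * j2);
                else if (axis == 1)
                    base = j1 + (R_xlen_t)nx * ny * j2;
                else
                    base = j1 + (R_xlen_t)nx * j2;
                for (int p = 0; p < len; ++p) {
                    double acc = 0.0;
                    for (int i = -r; i <= r; ++i) {
                        int q = p + i;
                        if (q < 0) q = 0;
                        if (q >= len) q = len - 1;
                        acc += k[i + r] * src[base + stride * q];
                    }
                    dst[base + stride * p] = acc;
                }
            }
        }
    };

    pass(a, b, 0);
    pass(b, a, 1);
    pass(a, b, 2);
    return b;
}
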