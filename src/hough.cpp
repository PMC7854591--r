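#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Center-voting stage of the spherical Hough transform: every edge voxel
// casts votes along +/- its gradient direction at distances rmin..rmax
// (step voxels) into a 3D accumulator at the working-grid resolution.
// Voting both ways makes the detector agnostic to the contrast polarity
// (positive vs negative staining).
// [[Rcpp::export]]
NumericVector hough_vote_cpp(IntegerVector edge_idx, NumericVector gx,
                             NumericVector gy, NumericVector gz,
                             IntegerVector dims, double rmin, double rmax,
                             double step) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector acc(n, 0.0);

    for (R_xlen_t e = 0; e < edge_idx.size(); ++e) {
        R_xlen_t i = (R_xlen_t)edge_idx[e] - 1; // 1-based from R
        double g1 = gx[i], g2 = gy[i], g3 = gz[i];
        double norm = std::sqrt(g1 * g1 + g2 * g2 + g3 * g3);
        if (norm <= 0) continue;
        g1 /= norm; g2 /= norm; g3 /= norm;
        int x = (int)(i % nx);
        int y = (int)((i / nx) % ny);
        int z = (int)(i / ((R_xlen_t)nx * ny));
        for (double r = rmin; r <= rmax + 1e-9; r += step) {
            for (int s = -1; s <= 1; s += 2) {
                int cx = (int)std::lround(x + s * r * g1);
                int cy = (int)std::lround(y + s * r * g2);
                int cz = (int)std::lround(z + s * r * g3);
                if (cx < 0 || cx >= nx || cy < 0 || cy >= ny ||
                    cz < 0 || cz >= nz) continue;
                acc[cx + (R_xlen_t)nx * (cy + (R_xlen_t)ny * cz)] += 1.0;
            }
        }
    }
    return acc;
}
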