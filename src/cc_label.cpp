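#include <Rcpp.h>
#include <vector>
#include "neighbors.h"

using namespace Rcpp;

// Connected-component labelling of a 3D logical mask.
// Labels are assigned in raster-scan order of the first voxel of each
// component, so the result is deterministic. Returns an integer vector of
// the same length as `mask` (dim attribute is reattached on the R side).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");
    auto off = neighbor_offsets(connectivity);

    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> stack;
    int next = 0;

    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int x = (int)(cur % nx);
            int y = (int)((cur / nx) % ny);
            int z = (int)(cur / ((R_xlen_t)nx * ny));
            for (const auto &d : off) {
                int xx = x + d[0], yy = y + d[1], zz = z + d[2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz) continue;
                R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                if (mask[j] && lab[j] == 0) {
                    lab[j] = next;
                    stack.push_back(j);
                }
            }
        }
    }
    return lab;
}
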