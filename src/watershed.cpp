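#include <Rcpp.h>
#include <vector>
#include <queue>
#include "neighbors.h"

using namespace Rcpp;

// Marker-free priority-flood watershed (Meyer-style flooding) of a scalar
// priority image restricted to a mask. Catchment basins are seeded at the
// regional minima of the priority image (plateau-aware) and flooded in
// increasing priority order. Every masked voxel is assigned to a basin:
// voxels where basins meet are absorbed by the basin that reaches them
// first in the (deterministic) flooding order, so no watershed-line voxels
// remain background. Ties are broken by insertion order, which makes the
// result reproducible.
//
// Returns integer labels (0 outside the mask), numbered in raster order of
// each minimum's first voxel.

struct QItem {
    double value;
    unsigned long long order;
    R_xlen_t idx;
    int label;
};
struct QCmp {
    bool operator()(const QItem &a, const QItem &b) const {
        if (a.value != b.value) return a.value > b.value;
        return a.order > b.order;
    }
};

// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector priority, LogicalVector mask,
                            IntegerVector dims, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (priority.size() != n || mask.size() != n)
        stop("priority/mask length does not match dims");
    auto off = neighbor_offsets(connectivity);

    // 1. plateau labelling: components of equal value within the mask
    std::vector<int> plateau(n, 0);
    std::vector<R_xlen_t> stack;
    std::vector<char> plateau_is_min;
    std::vector<R_xlen_t> plateau_first;
    int np = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || plateau[i] != 0) continue;
        ++np;
        plateau[i] = np;
        plateau_is_min.push_back(1);
        plateau_first.push_back(i);
        stack.push_back(i);
        double val = priority[i];
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
                if (!mask[j]) continue;
                if (priority[j] == val) {
                    if (plateau[j] == 0) {
                        plateau[j] = np;
                        stack.push_back(j);
                    }
                } else if (priority[j] < val) {
                    plateau_is_min[np - 1] = 0;
                }
            }
        }
    }

    // 2. seeds: minima plateaus, numbered by raster order of first voxel
    IntegerVector lab(n, 0);
    std::vector<int> plateau_label(np, 0);
    int nlab = 0;
    for (int p = 0; p < np; ++p)
        if (plateau_is_min[p]) plateau_label[p] = ++nlab;

    std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
    unsigned long long order = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i]) continue;
        int pl = plateau[i];
        if (pl > 0 && plateau_label[pl - 1] > 0) {
            int L = plateau_label[pl - 1];
            lab[i] = L;
            pq.push({priority[i], order++, i, L});
        }
    }

    // 3. flood
    while (!pq.empty()) {
        QItem it = pq.top();
        pq.pop();
        int x = (int)(it.idx % nx);
        int y = (int)((it.idx / nx) % ny);
        int z = (int)(it.idx / ((R_xlen_t)nx * ny));
        for (const auto &d : off) {
            int xx = x + d[0], yy = y + d[1], zz = z + d[2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                zz < 0 || zz >= nz) continue;
            R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (!mask[j] || lab[j] != 0) continue;
            lab[j] = it.label;
            pq.push({priority[j], order++, j, it.label});
        }
    }
    return lab;
}
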