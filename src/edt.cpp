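#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes along x, y, z. Distances are measured
// in voxel units to the nearest TRUE voxel of `feature`; voxels of an
// all-FALSE input get +Inf.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled function f, result in d.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z) {
    const int n = (int)f.size();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        if (f[v[k]] == INF) { // first finite sample
            v[k] = q;
            z[k] = -INF;
            z[k + 1] = INF;
            continue;
        }
        double s;
        while (true) {
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * q - 2.0 * v[k]);
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        if (f[v[0]] == INF) { d[q] = INF; continue; }
        while (z[k + 1] < q) ++k;
        double dq = (double)q - v[k];
        d[q] = dq * dq + f[v[k]];
    }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (feature.size() != n) stop("feature length does not match dims");

    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x
    for (int zz = 0; zz < nz; ++zz)
        for (int yy = 0; yy < ny; ++yy) {
            R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            for (int x = 0; x < nx; ++x) f[x] = out[base + x];
            f.resize(nx); d.resize(nx);
            dt1d(f, d, v, z);
            for (int x = 0; x < nx; ++x) out[base + x] = d[x];
            f.resize(nmax); d.resize(nmax);
        }
    // pass along y
    for (int zz = 0; zz < nz; ++zz)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
            for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
            f.resize(ny); d.resize(ny);
            dt1d(f, d, v, z);
            for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
            f.resize(nmax); d.resize(nmax);
        }
    // pass along z
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int yy = 0; yy < ny; ++yy)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = x + (R_xlen_t)nx * yy;
            for (int z2 = 0; z2 < nz; ++z2) f[z2] = out[base + stride * z2];
            f.resize(nz); d.resize(nz);
            dt1d(f, d, v, z);
            for (int z2 = 0; z2 < nz; ++z2) out[base + stride * z2] = d[z2];
            f.resize(nmax); d.resize(nmax);
        }
    return out;
}
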