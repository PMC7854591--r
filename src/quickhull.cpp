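#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>

using namespace Rcpp;

// 3D convex hull by the quickhull algorithm, plus scanline voxelization of
// the resulting polytope. Written for point sets that are voxel centers on
// an integer lattice (well-conditioned, no exact-arithmetic predicates
// needed; a fixed epsilon on the lattice scale is sufficient).

namespace {

struct Vec3 {
    double x, y, z;
};
inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
    return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
    return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
    return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
    int a, b, c;          // vertex indices, outward CCW
    Vec3 n;               // unit outward normal
    double d;             // n . x = d on the plane
    bool alive;
    std::vector<int> outside;
    int far_pt;
    double far_dist;
};

struct Hull {
    const std::vector<Vec3> &P;
    std::vector<Face> faces;
    Vec3 interior;
    double eps;

    Hull(const std::vector<Vec3> &pts, double e) : P(pts), eps(e) {}

    void make_face(int a, int b, int c) {
        Face f;
        f.a = a; f.b = b; f.c = c;
        Vec3 n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
        double ln = norm(n);
        if (ln <= 0) { f.alive = false; faces.push_back(f); return; }
        n.x /= ln; n.y /= ln; n.z /= ln;
        double d = dot(n, P[a]);
        if (dot(n, interior) > d) { // flip to outward
            std::swap(f.b, f.c);
            n.x = -n.x; n.y = -n.y; n.z = -n.z;
            d = -d;
        }
        f.n = n; f.d = d; f.alive = true;
        f.far_pt = -1; f.far_dist = 0;
        faces.push_back(f);
    }

    void assign_outside(Face &f, const std::vector<int> &cand) {
        for (int p : cand) {
            double dist = dot(f.n, P[p]) - f.d;
            if (dist > eps) {
                f.outside.push_back(p);
                if (dist > f.far_dist) { f.far_dist = dist; f.far_pt = p; }
            }
        }
    }
};

} // namespace

// [[Rcpp::export]]
List quickhull_cpp(NumericMatrix pts) {
    const int n = pts.nrow();
    if (n < 4) stop("convex hull needs at least 4 non-coplanar points");
    std::vector<Vec3> P(n);
    double scale = 1.0;
    for (int i = 0; i < n; ++i) {
        P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
        scale = std::max(scale, std::max(std::fabs(P[i].x),
                 std::max(std::fabs(P[i].y), std::fabs(P[i].z))));
    }
    const double eps = 1e-9 * scale;

    // initial simplex: two extreme points, farthest from line, from plane
    int i0 = 0, i1 = 0;
    for (int i = 1; i < n; ++i) {
        if (P[i].x < P[i0].x) i0 = i;
        if (P[i].x > P[i1].x) i1 = i;
    }
    if (i0 == i1) { // all same x: use y then z extent
        for (int i = 1; i < n; ++i) {
            if (P[i].y < P[i0].y) i0 = i;
            if (P[i].y > P[i1].y) i1 = i;
        }
    }
    // farthest from segment i0-i1
    int i2 = -1;
    double best = eps;
    Vec3 u = sub(P[i1], P[i0]);
    double lu = norm(u);
    if (lu <= eps) stop("convex hull needs at least 4 non-coplanar points");
    for (int i = 0; i < n; ++i) {
        Vec3 w = cross(u, sub(P[i], P[i0]));
        double d = norm(w) / lu;
        if (d > best) { best = d; i2 = i; }
    }
    if (i2 < 0) stop("convex hull needs at least 4 non-coplanar points");
    // farthest from plane (i0,i1,i2)
    Vec3 pn = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
    double lpn = norm(pn);
    pn.x /= lpn; pn.y /= lpn; pn.z /= lpn;
    double pd = dot(pn, P[i0]);
    int i3 = -1;
    best = eps;
    for (int i = 0; i < n; ++i) {
        double d = std::fabs(dot(pn, P[i]) - pd);
        if (d > best) { best = d; i3 = i; }
    }
    if (i3 < 0) stop("convex hull needs at least 4 non-coplanar points");

    Hull H(P, eps);
    H.interior = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                  (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                  (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};
    H.make_face(i0, i1, i2);
    H.make_face(i0, i1, i3);
    H.make_face(i0, i2, i3);
    H.make_face(i1, i2, i3);
    {
        std::vector<int> all(n);
        for (int i = 0; i < n; ++i) all[i] = i;
        for (auto &f : H.faces) if (f.alive) H.assign_outside(f, all);
    }

    // main loop
    while (true) {
        int fi = -1;
        double fd = 0;
        for (size_t i = 0; i < H.faces.size(); ++i)
            if (H.faces[i].alive && H.faces[i].far_pt >= 0 &&
                H.faces[i].far_dist > fd) {
                fd = H.faces[i].far_dist;
                fi = (int)i;
            }
        if (fi < 0) break;
        int p = H.faces[fi].far_pt;

        // visible faces
        std::vector<int> visible;
        for (size_t i = 0; i < H.faces.size(); ++i) {
            Face &f = H.faces[i];
            if (f.alive && dot(f.n, P[p]) - f.d > eps)
                visible.push_back((int)i);
        }
        // horizon edges: directed edges of visible faces whose reverse is
        // not an edge of any visible face
        std::map<std::pair<int, int>, int> count;
        for (int vi : visible) {
            Face &f = H.faces[vi];
            int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
            for (auto &ed : e) {
                int lo = std::min(ed[0], ed[1]), hi = std::max(ed[0], ed[1]);
                count[{lo, hi}]++;
            }
        }
        std::vector<std::pair<int, int>> horizon;
        for (int vi : visible) {
            Face &f = H.faces[vi];
            int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
            for (auto &ed : e) {
                int lo = std::min(ed[0], ed[1]), hi = std::max(ed[0], ed[1]);
                if (count[{lo, hi}] == 1)
                    horizon.push_back({ed[0], ed[1]}); // keep orientation
            }
        }
        // gather candidate points and kill visible faces
        std::vector<int> cand;
        for (int vi : visible) {
            Face &f = H.faces[vi];
            f.alive = false;
            for (int q : f.outside) if (q != p) cand.push_back(q);
            f.outside.clear();
        }
        // new faces
        size_t first_new = H.faces.size();
        for (auto &ed : horizon) H.make_face(ed.first, ed.second, p);
        for (size_t i = first_new; i < H.faces.size(); ++i)
            if (H.faces[i].alive) H.assign_outside(H.faces[i], cand);
        if (H.faces.size() > 50000000) stop("quickhull runaway");
    }

    // collect results
    int nf = 0;
    for (auto &f : H.faces) if (f.alive) ++nf;
    IntegerMatrix faces(nf, 3);
    NumericMatrix normals(nf, 3);
    NumericVector offsets(nf);
    double area = 0.0, volume = 0.0;
    int r = 0;
    for (auto &f : H.faces) {
        if (!f.alive) continue;
        faces(r, 0) = f.a + 1; faces(r, 1) = f.b + 1; faces(r, 2) = f.c + 1;
        normals(r, 0) = f.n.x; normals(r, 1) = f.n.y; normals(r, 2) = f.n.z;
        offsets[r] = f.d;
        Vec3 ab = sub(P[f.b], P[f.a]), ac = sub(P[f.c], P[f.a]);
        Vec3 cr = cross(ab, ac);
        area += 0.5 * norm(cr);
        // signed tetra volume w.r.t. interior point
        Vec3 a0 = sub(P[f.a], H.interior), b0 = sub(P[f.b], H.interior),
             c0 = sub(P[f.c], H.interior);
        volume += dot(a0, cross(b0, c0)) / 6.0;
        ++r;
    }
    return List::create(_["faces"] = faces, _["normals"] = normals,
                        _["offsets"] = offsets, _["area"] = area,
                        _["volume"] = std::fabs(volume));
}

// Voxelize a convex polytope given by half-spaces {x : n.x <= d} onto a
// grid whose voxel (i,j,k) (1-based in R, passed 0-based origin) has center
// origin + (i,j,k). Scanline along x: per (y,z) column the feasible x range
// is an interval.
// [[Rcpp::export]]
LogicalVector hull_fill_cpp(NumericMatrix normals, NumericVector offsets,
                            IntegerVector dims, NumericVector origin) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    const int nf = normals.nrow();
    const double tol = 1e-7;
    LogicalVector out(n, false);

    for (int z = 0; z < nz; ++z) {
        double pz = origin[2] + z;
        for (int y = 0; y < ny; ++y) {
            double py = origin[1] + y;
            double xlo = -1e300, xhi = 1e300;
            bool feasible = true;
            for (int f = 0; f < nf && feasible; ++f) {
                double a = normals(f, 0);
                double b = offsets[f] - normals(f, 1) * py -
                           normals(f, 2) * pz;
                if (a > tol) {
                    xhi = std::min(xhi, b / a);
                } else if (a < -tol) {
                    xlo = std::max(xlo, b / a);
                } else if (b < -tol) {
                    feasible = false;
                }
            }
            if (!feasible || xhi < xlo - tol) continue;
            // convert to voxel indices: origin[0] + x in [xlo, xhi]
            int x0 = (int)std::ceil(xlo - origin[0] - tol);
            int x1 = (int)std::floor(xhi - origin[0] + tol);
            if (x0 < 0) x0 = 0;
            if (x1 >= nx) x1 = nx - 1;
            R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            for (int x = x0; x <= x1; ++x) out[base + x] = true;
        }
    }
    return out;
}
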