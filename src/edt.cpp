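#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Separable squared Euclidean distance transform with anisotropic sampling
// (lower envelope of parabolas, Felzenszwalb & Huttenlocher). Distances are
// returned squared; taking the square root is left to the caller so that
// tolerance comparisons can be done on exact squared values.

static const double EDT_INF = 1e30;

// 1D pass along a line with grid step `w` (mm). `f` holds squared distances
// on input and output. Intersections `z` are kept in index units.
static void dt1d(double *f, int n, double w,
                 double *d, int *v, double *z) {
    const double w2 = w * w;
    const double inf = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -inf;
    z[1] = inf;
    for (int q = 1; q < n; ++q) {
        const double fq = f[q] + (double)q * q * w2;
        double s;
        for (;;) {
            const int p = v[k];
            s = (fq - (f[p] + (double)p * p * w2)) / (2.0 * w2 * (q - p));
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = inf;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        const int p = v[k];
        const double dq = (double)(q - p) * w;
        d[q] = dq * dq + f[p];
    }
    for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
    if (dims.size() != 3 || spacing.size() != 3)
        stop("dims and spacing must have length 3");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    if ((R_xlen_t)nx * ny * nz != mask.size())
        stop("mask length does not match dims");

    NumericVector out(mask.size());
    double *g = REAL(out);
    for (R_xlen_t i = 0; i < mask.size(); ++i)
        g[i] = mask[i] ? 0.0 : EDT_INF;

    const int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x
    for (int kz = 0; kz < nz; ++kz)
        for (int ky = 0; ky < ny; ++ky) {
            double *line = g + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz);
            dt1d(line, nx, spacing[0], d.data(), v.data(), z.data());
        }
    // pass along y
    for (int kz = 0; kz < nz; ++kz)
        for (int kx = 0; kx < nx; ++kx) {
            const R_xlen_t base = kx + (R_xlen_t)nx * ny * kz;
            for (int ky = 0; ky < ny; ++ky) f[ky] = g[base + (R_xlen_t)nx * ky];
            dt1d(f.data(), ny, spacing[1], d.data(), v.data(), z.data());
            for (int ky = 0; ky < ny; ++ky) g[base + (R_xlen_t)nx * ky] = f[ky];
        }
    // pass along z
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int ky = 0; ky < ny; ++ky)
        for (int kx = 0; kx < nx; ++kx) {
            const R_xlen_t base = kx + (R_xlen_t)nx * ky;
            for (int kz = 0; kz < nz; ++kz) f[kz] = g[base + nxy * kz];
            dt1d(f.data(), nz, spacing[2], d.data(), v.data(), z.data());
            for (int kz = 0; kz < nz; ++kz) g[base + nxy * kz] = f[kz];
        }

    out.attr("dim") = dims;
    return out;
}
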