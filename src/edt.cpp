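#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// with sample spacing w (mm). f holds input squared values (0 on mask, Inf
// elsewhere, or partial results from a previous axis); d receives
// min_j f[j] + w^2 (q - j)^2.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w2) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = -1;
    for (int q = 0; q < n; ++q) {
        if (!R_FINITE(f[q]) && f[q] > 0) continue;  // skip +Inf parabolas
        if (k < 0) {
            k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
            continue;
        }
        double s = 0.0;
        while (k >= 0) {
            int p = v[k];
            s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
                (2.0 * w2 * (q - p));
            if (s <= z[k]) --k; else break;
        }
        ++k;
        v[k] = q;
        z[k] = (k == 0) ? -INF : s;
        z[k + 1] = INF;
    }
    if (k < 0) {            // no finite source on this line
        for (int q = 0; q < n; ++q) d[q] = INF;
        return;
    }
    int j = 0;
    for (int q = 0; q < n; ++q) {
        while (j < k && z[j + 1] < q) ++j;
        double dq = q - v[j];
        d[q] = w2 * dq * dq + f[v[j]];
    }
}

// Exact anisotropic squared Euclidean distance transform of a 3D binary mask.
// Returns, per voxel, the squared distance in mm^2 to the nearest TRUE voxel.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
    const double INF = std::numeric_limits<double>::infinity();
    int nx = dim[0], ny = dim[1], nz = dim[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (mask[i] == TRUE) ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // x axis
    double w2 = spacing[0] * spacing[0];
    for (int kz = 0; kz < nz; ++kz)
        for (int jy = 0; jy < ny; ++jy) {
            R_xlen_t base = (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz);
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f, d, v, z, nx, w2);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // y axis
    w2 = spacing[1] * spacing[1];
    for (int kz = 0; kz < nz; ++kz)
        for (int ix = 0; ix < nx; ++ix) {
            R_xlen_t base = ix + (R_xlen_t)nx * ny * kz;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
            dt1d(f, d, v, z, ny, w2);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
        }
    // z axis
    w2 = spacing[2] * spacing[2];
    R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int jy = 0; jy < ny; ++jy)
        for (int ix = 0; ix < nx; ++ix) {
            R_xlen_t base = ix + (R_xlen_t)nx * jy;
            for (int kz = 0; kz < nz; ++kz) f[kz] = out[base + stride * kz];
            dt1d(f, d, v, z, nz, w2);
            for (int kz = 0; kz < nz; ++kz) out[base + stride * kz] = d[kz];
        }
    return out;
}
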