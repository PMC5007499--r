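// Low-level volumetric kernels: separable Gaussian-derivative convolution,
// per-voxel symmetric 3x3 eigenvalues, connected-component labelling and the
// exact squared Euclidean distance transform. All arrays are R numeric/integer
// vectors in column-major order with dim = (nz, ny, nx); the first index varies
// fastest. Single-threaded by design (grading/desk scale).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gaussian and Gaussian-derivative kernels, truncated at 4 sigma.
// Order 0 is normalised to unit sum; orders 1 and 2 have their mean removed so
// that a constant signal maps exactly to zero.
static std::vector<double> gauss_kernel(double sigma, int order) {
    int r = std::max(1, (int)std::ceil(4.0 * sigma));
    std::vector<double> k(2 * r + 1);
    double s2 = sigma * sigma;
    double sum = 0.0;
    for (int i = -r; i <= r; ++i) {
        double g = std::exp(-0.5 * (double)i * i / s2);
        double v;
        if (order == 0)       v = g;
        else if (order == 1)  v = -((double)i / s2) * g;
        else                  v = (((double)i * i - s2) / (s2 * s2)) * g;
        k[i + r] = v;
        sum += g;
    }
    // normalise by the discrete Gaussian mass so the order-0 kernel sums to 1
    for (double &v : k) v /= sum;
    if (order > 0) {
        double m = 0.0;
        for (double v : k) m += v;
        m /= (double)k.size();
        for (double &v : k) v -= m;
    }
    return k;
}

// reflect (edge-inclusive) index folding: -1 -> 0, n -> n-1
static inline int reflect_idx(int i, int n) {
    if (n == 1) return 0;
    while (i < 0 || i >= n) {
        if (i < 0) i = -i - 1;
        if (i >= n) i = 2 * n - i - 1;
    }
    return i;
}

// Convolve along one axis of a 3D array (axis 0 = fastest-varying index).
static void conv_axis(const double *in, double *out, const int *dim, int axis,
                      const std::vector<double> &ker) {
    const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
    const int n = dim[axis];
    const int r = ((int)ker.size() - 1) / 2;
    R_xlen_t stride;
    if (axis == 0) stride = 1;
    else if (axis == 1) stride = (R_xlen_t)n0;
    else stride = (R_xlen_t)n0 * n1;

    std::vector<double> line(n);
    // iterate over all lines orthogonal to `axis`
    int oa = (axis == 0) ? 1 : 0;
    int ob = (axis == 2) ? 1 : 2;
    R_xlen_t stra = (oa == 0) ? 1 : ((oa == 1) ? (R_xlen_t)n0 : (R_xlen_t)n0 * n1);
    R_xlen_t strb = (ob == 0) ? 1 : ((ob == 1) ? (R_xlen_t)n0 : (R_xlen_t)n0 * n1);
    int na = dim[oa], nb = dim[ob];
    const double *kc = ker.data() + r;  // centred kernel

    for (int b = 0; b < nb; ++b) {
        for (int a = 0; a < na; ++a) {
            R_xlen_t base = (R_xlen_t)a * stra + (R_xlen_t)b * strb;
            for (int i = 0; i < n; ++i) line[i] = in[base + (R_xlen_t)i * stride];
            int lo = std::min(r, n), hi = std::max(lo, n - r);
            // boundary regions with reflect folding
            for (int i = 0; i < lo; ++i) {
                double acc = 0.0;
                for (int j = -r; j <= r; ++j)
                    acc += line[reflect_idx(i + j, n)] * kc[j];
                out[base + (R_xlen_t)i * stride] = acc;
            }
            for (int i = hi; i < n; ++i) {
                double acc = 0.0;
                for (int j = -r; j <= r; ++j)
                    acc += line[reflect_idx(i + j, n)] * kc[j];
                out[base + (R_xlen_t)i * stride] = acc;
            }
            // interior: no bounds checks
            for (int i = lo; i < hi; ++i) {
                double acc = 0.0;
                const double *lp = line.data() + i;
                for (int j = -r; j <= r; ++j) acc += lp[j] * kc[j];
                out[base + (R_xlen_t)i * stride] = acc;
            }
        }
    }
}

// [[Rcpp::export(name = ".cpp_gauss_filter3d")]]
NumericVector cpp_gauss_filter3d(NumericVector vol, IntegerVector dim,
                                 double sigma, IntegerVector orders) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    R_xlen_t nvox = (R_xlen_t)d[0] * d[1] * d[2];
    NumericVector out(nvox);
    std::vector<double> tmp(nvox);
    // three sequential axis passes: src -> tmp -> out -> tmp -> out
    conv_axis(REAL(vol), tmp.data(), d, 0, gauss_kernel(sigma, orders[0]));
    conv_axis(tmp.data(), REAL(out), d, 1, gauss_kernel(sigma, orders[1]));
    conv_axis(REAL(out), tmp.data(), d, 2, gauss_kernel(sigma, orders[2]));
    std::memcpy(REAL(out), tmp.data(), sizeof(double) * nvox);
    return out;
}

// ---------------------------------------------------------------------------
// Eigenvalues of the scale-normalised Hessian, sorted by absolute value.
// Closed-form symmetric 3x3 eigen-solve (trigonometric method).
static inline void eig3_sym(double a, double b, double c, double d, double e,
                            double f, double *lam) {
    // matrix [[a, d, f], [d, b, e], [f, e, c]]
    double p1 = d * d + f * f + e * e;
    if (p1 == 0.0) {
        lam[0] = a; lam[1] = b; lam[2] = c;
        return;
    }
    double q = (a + b + c) / 3.0;
    double aa = a - q, bb = b - q, cc = c - q;
    double p2 = aa * aa + bb * bb + cc * cc + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    // det((A - qI)/p) / 2
    double m00 = aa / p, m11 = bb / p, m22 = cc / p;
    double m01 = d / p, m12 = e / p, m02 = f / p;
    double detB = m00 * (m11 * m22 - m12 * m12)
                - m01 * (m01 * m22 - m12 * m02)
                + m02 * (m01 * m12 - m11 * m02);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    double e1 = q + 2.0 * p * std::cos(phi);
    double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    double e2 = 3.0 * q - e1 - e3;
    lam[0] = e1; lam[1] = e2; lam[2] = e3;
}

// [[Rcpp::export(name = ".cpp_hessian_eigs")]]
List cpp_hessian_eigs(NumericVector vol, IntegerVector dim, double sigma) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    R_xlen_t nvox = (R_xlen_t)d[0] * d[1] * d[2];
    // six Hessian components by derivative order (z, y, x)
    const int ord[6][3] = {
        {2, 0, 0}, {0, 2, 0}, {0, 0, 2},  // Hzz, Hyy, Hxx
        {1, 1, 0}, {1, 0, 1}, {0, 1, 1}   // Hzy, Hzx, Hyx
    };
    std::vector<std::vector<double>> H(6);
    std::vector<double> t1(nvox), t2(nvox);
    const double *src = REAL(vol);
    for (int k = 0; k < 6; ++k) {
        H[k].resize(nvox);
        conv_axis(src, t1.data(), d, 0, gauss_kernel(sigma, ord[k][0]));
        conv_axis(t1.data(), t2.data(), d, 1, gauss_kernel(sigma, ord[k][1]));
        conv_axis(t2.data(), H[k].data(), d, 2, gauss_kernel(sigma, ord[k][2]));
    }
    t1.clear(); t1.shrink_to_fit();
    t2.clear(); t2.shrink_to_fit();

    NumericVector E1(nvox), E2(nvox), E3(nvox);
    double *e1 = REAL(E1), *e2 = REAL(E2), *e3 = REAL(E3);
    const double s2 = sigma * sigma;  // gamma-normalisation
    double lam[3];
    for (R_xlen_t i = 0; i < nvox; ++i) {
        eig3_sym(s2 * H[0][i], s2 * H[1][i], s2 * H[2][i],
                 s2 * H[3][i], s2 * H[5][i], s2 * H[4][i], lam);
        // sort by |lambda|
        double l0 = lam[0], l1 = lam[1], l2 = lam[2];
        double t;
        if (std::fabs(l0) > std::fabs(l1)) { t = l0; l0 = l1; l1 = t; }
        if (std::fabs(l1) > std::fabs(l2)) { t = l1; l1 = l2; l2 = t; }
        if (std::fabs(l0) > std::fabs(l1)) { t = l0; l0 = l1; l1 = t; }
        e1[i] = l0; e2[i] = l1; e3[i] = l2;
    }
    return List::create(_["e1"] = E1, _["e2"] = E2, _["e3"] = E3);
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6- or 26-connectivity), BFS with an explicit
// stack. Returns 0 for background, 1..K component labels in first-encounter
// order (scan order = linear index).

// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
    const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
    R_xlen_t nvox = (R_xlen_t)n0 * n1 * n2;
    IntegerVector lab(nvox, 0);
    const int *m = LOGICAL(mask);
    int *L = INTEGER(lab);

    std::vector<int> dz, dy, dx;
    for (int z = -1; z <= 1; ++z)
        for (int y = -1; y <= 1; ++y)
            for (int x = -1; x <= 1; ++x) {
                if (z == 0 && y == 0 && x == 0) continue;
                int manh = std::abs(z) + std::abs(y) + std::abs(x);
                if (connectivity == 6 && manh > 1) continue;
                dz.push_back(z); dy.push_back(y); dx.push_back(x);
            }
    const int nn = (int)dz.size();

    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t i = 0; i < nvox; ++i) {
        if (m[i] == 0 || L[i] != 0) continue;
        ++next;
        L[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int z = (int)(cur % n0);
            int y = (int)((cur / n0) % n1);
            int x = (int)(cur / ((R_xlen_t)n0 * n1));
            for (int k = 0; k < nn; ++k) {
                int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
                if (zz < 0 || zz >= n0 || yy < 0 || yy >= n1 ||
                    xx < 0 || xx >= n2) continue;
                R_xlen_t j = (R_xlen_t)zz + (R_xlen_t)yy * n0 +
                             (R_xlen_t)xx * n0 * n1;
                if (m[j] != 0 && L[j] == 0) {
                    L[j] = next;
                    stack.push_back(j);
                }
            }
        }
    }
    lab.attr("n_labels") = next;
    return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform to the nearest TRUE voxel
// (Felzenszwalb & Huttenlocher lower-envelope method, three 1D passes).
// Voxels where no site exists anywhere return Inf.

static void dt1d(std::vector<double> &f, std::vector<double> &dout,
                 std::vector<int> &v, std::vector<double> &z, int n) {
    const double INF = std::numeric_limits<double>::infinity();
    // +Inf parabolas never form part of the lower envelope; skip them.
    int q0 = 0;
    while (q0 < n && !std::isfinite(f[q0])) ++q0;
    if (q0 == n) {
        for (int q = 0; q < n; ++q) dout[q] = INF;
        return;
    }
    int k = 0;
    v[0] = q0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = q0 + 1; q < n; ++q) {
        if (!std::isfinite(f[q])) continue;
        double s;
        while (true) {
            double fq = f[q], fv = f[v[k]];
            s = ((fq + (double)q * q) - (fv + (double)v[k] * v[k])) /
                (2.0 * (q - v[k]));
            if (k > 0 && s <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < (double)q) ++k;
        double dq = (double)q - (double)v[k];
        dout[q] = dq * dq + f[v[k]];
    }
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector sites, IntegerVector dim) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    R_xlen_t nvox = (R_xlen_t)d[0] * d[1] * d[2];
    NumericVector out(nvox);
    double *g = REAL(out);
    const int *s = LOGICAL(sites);
    const double INF = std::numeric_limits<double>::infinity();
    for (R_xlen_t i = 0; i < nvox; ++i) g[i] = s[i] ? 0.0 : INF;

    int nmax = std::max(d[0], std::max(d[1], d[2]));
    std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    for (int axis = 0; axis < 3; ++axis) {
        const int n = d[axis];
        R_xlen_t stride;
        if (axis == 0) stride = 1;
        else if (axis == 1) stride = (R_xlen_t)d[0];
        else stride = (R_xlen_t)d[0] * d[1];
        int oa = (axis == 0) ? 1 : 0;
        int ob = (axis == 2) ? 1 : 2;
        R_xlen_t stra = (oa == 0) ? 1 : ((oa == 1) ? (R_xlen_t)d[0]
                                                   : (R_xlen_t)d[0] * d[1]);
        R_xlen_t strb = (ob == 0) ? 1 : ((ob == 1) ? (R_xlen_t)d[0]
                                                   : (R_xlen_t)d[0] * d[1]);
        int na = d[oa], nb = d[ob];
        for (int b = 0; b < nb; ++b) {
            for (int a = 0; a < na; ++a) {
                R_xlen_t base = (R_xlen_t)a * stra + (R_xlen_t)b * strb;
                bool any_finite = false;
                for (int i = 0; i < n; ++i) {
                    f[i] = g[base + (R_xlen_t)i * stride];
                    if (std::isfinite(f[i])) any_finite = true;
                }
                if (!any_finite) continue;  // stays Inf along this line
                dt1d(f, dd, v, z, n);
                for (int i = 0; i < n; ++i)
                    g[base + (R_xlen_t)i * stride] = dd[i];
            }
        }
    }
    return out;
}
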