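#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hard-pulse Bloch propagation: each time sample applies the exact rotation
// generated by the effective field (b1x, b1y, omega), all in Hz, over dt
// seconds.  The rotation vector is a = -2*pi*dt * (b1x, b1y, omega), i.e.
// a positive longitudinal offset precesses the transverse magnetization
// clockwise (free-precession phase -2*pi*f*t).

static inline void rot_from_axis(double ax, double ay, double az, double R[9]) {
    double th2 = ax * ax + ay * ay + az * az;
    if (th2 < 1e-24) {
        R[0] = 1.0; R[1] = -az; R[2] = ay;
        R[3] = az;  R[4] = 1.0; R[5] = -ax;
        R[6] = -ay; R[7] = ax;  R[8] = 1.0;
        return;
    }
    double th = std::sqrt(th2);
    double ux = ax / th, uy = ay / th, uz = az / th;
    double c = std::cos(th), s = std::sin(th), C = 1.0 - c;
    R[0] = c + ux * ux * C;      R[1] = ux * uy * C - uz * s; R[2] = ux * uz * C + uy * s;
    R[3] = uy * ux * C + uz * s; R[4] = c + uy * uy * C;      R[5] = uy * uz * C - ux * s;
    R[6] = uz * ux * C - uy * s; R[7] = uz * uy * C + ux * s; R[8] = c + uz * uz * C;
}

static inline void matvec(const double R[9], const double v[3], double out[3]) {
    out[0] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2];
    out[1] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2];
    out[2] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2];
}

static inline void matTvec(const double R[9], const double v[3], double out[3]) {
    out[0] = R[0] * v[0] + R[3] * v[1] + R[6] * v[2];
    out[1] = R[1] * v[0] + R[4] * v[1] + R[7] * v[2];
    out[2] = R[2] * v[0] + R[5] * v[1] + R[8] * v[2];
}

static inline void cross(const double a[3], const double b[3], double out[3]) {
    out[0] = a[1] * b[2] - a[2] * b[1];
    out[1] = a[2] * b[0] - a[0] * b[2];
    out[2] = a[0] * b[1] - a[1] * b[0];
}

// d(R(a) v)/da_j contracted with adjoint lam: g[j] = lam . (dR/da_j) v.
// Exact formula (derivative of the exponential map) away from the origin;
// second-order Taylor branch near |a| = 0.
static inline void rot_jac_contract(const double a[3], const double R[9],
                                    const double v[3], const double w[3],
                                    const double lam[3], double g[3]) {
    double th2 = a[0] * a[0] + a[1] * a[1] + a[2] * a[2];
    if (th2 < 1e-8) {
        // dR/da_j ~ E_j + (E_j A + A E_j)/2 with A = [a]x, E_j = [e_j]x
        double av[3], tmp1[3], tmp2[3];
        cross(a, v, av);
        for (int j = 0; j < 3; j++) {
            double ej[3] = {0.0, 0.0, 0.0};
            ej[j] = 1.0;
            double d[3];
            cross(ej, v, d);              // E_j v
            cross(ej, av, tmp1);          // E_j (A v)
            cross(a, d, tmp2);            // A (E_j v)
            g[j] = lam[0] * (d[0] + 0.5 * (tmp1[0] + tmp2[0]))
                 + lam[1] * (d[1] + 0.5 * (tmp1[1] + tmp2[1]))
                 + lam[2] * (d[2] + 0.5 * (tmp1[2] + tmp2[2]));
        }
        return;
    }
    // dR/da_j = (a_j [a]x + [a x (I - R) e_j]x) R / |a|^2   (Gallego & Yezzi)
    double aw[3];
    cross(a, w, aw); // [a]x R v
    for (int j = 0; j < 3; j++) {
        // (I - R) e_j = e_j - R[, j]
        double col[3] = {R[j], R[3 + j], R[6 + j]};
        double imr[3] = {-col[0], -col[1], -col[2]};
        imr[j] += 1.0;
        double axe[3], t[3];
        cross(a, imr, axe);
        cross(axe, w, t); // [a x (I-R)e_j]x w
        g[j] = (lam[0] * (a[j] * aw[0] + t[0])
              + lam[1] * (a[j] * aw[1] + t[1])
              + lam[2] * (a[j] * aw[2] + t[2])) / th2;
    }
}

// Batch forward simulation.  B1x, B1y, Om are Nsim x Nt matrices (Hz);
// returns Nsim x 3 final magnetization starting from (0, 0, 1).
// [[Rcpp::export(name = ".bloch_run")]]
NumericMatrix bloch_run(const NumericMatrix& B1x, const NumericMatrix& B1y,
                        const NumericMatrix& Om, double dt) {
    int ns = B1x.nrow(), nt = B1x.ncol();
    NumericMatrix M(ns, 3);
    const double k = -2.0 * M_PI * dt;
    for (int i = 0; i < ns; i++) {
        double m[3] = {0.0, 0.0, 1.0};
        double R[9], out[3];
        for (int n = 0; n < nt; n++) {
            rot_from_axis(k * B1x(i, n), k * B1y(i, n), k * Om(i, n), R);
            matvec(R, m, out);
            m[0] = out[0]; m[1] = out[1]; m[2] = out[2];
        }
        M(i, 0) = m[0]; M(i, 1) = m[1]; M(i, 2) = m[2];
    }
    return M;
}

// Forward + reverse (vector-Jacobian product).  Mbar is Nsim x 3, the
// gradient of the scalar objective with respect to the final magnetization.
// Returns final M plus d(objective)/d(B1x, B1y, Om) as Nsim x Nt matrices.
// [[Rcpp::export(name = ".bloch_run_vjp")]]
List bloch_run_vjp(const NumericMatrix& B1x, const NumericMatrix& B1y,
                   const NumericMatrix& Om, double dt,
                   const NumericMatrix& Mbar) {
    int ns = B1x.nrow(), nt = B1x.ncol();
    NumericMatrix M(ns, 3), Gx(ns, nt), Gy(ns, nt), Gz(ns, nt);
    const double k = -2.0 * M_PI * dt;
    std::vector<double> states(3 * (nt + 1));
    for (int i = 0; i < ns; i++) {
        states[0] = 0.0; states[1] = 0.0; states[2] = 1.0;
        double R[9];
        for (int n = 0; n < nt; n++) {
            rot_from_axis(k * B1x(i, n), k * B1y(i, n), k * Om(i, n), R);
            matvec(R, &states[3 * n], &states[3 * (n + 1)]);
        }
        M(i, 0) = states[3 * nt];
        M(i, 1) = states[3 * nt + 1];
        M(i, 2) = states[3 * nt + 2];
        double lam[3] = {Mbar(i, 0), Mbar(i, 1), Mbar(i, 2)};
        for (int n = nt - 1; n >= 0; n--) {
            double a[3] = {k * B1x(i, n), k * B1y(i, n), k * Om(i, n)};
            rot_from_axis(a[0], a[1], a[2], R);
            double g[3];
            rot_jac_contract(a, R, &states[3 * n], &states[3 * (n + 1)], lam, g);
            Gx(i, n) = k * g[0];
            Gy(i, n) = k * g[1];
            Gz(i, n) = k * g[2];
            double nl[3];
            matTvec(R, lam, nl);
            lam[0] = nl[0]; lam[1] = nl[1]; lam[2] = nl[2];
        }
    }
    return List::create(_["M"] = M, _["Gb1x"] = Gx, _["Gb1y"] = Gy,
                        _["Gom"] = Gz);
}
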