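/* Compiled core for the CA1 pyramidal-neuron conductance model:
 * right-hand side, adaptive Dormand-Prince RK45 with cubic-Hermite dense
 * output, and a fixed-step RK4 integrator used as a numerical cross-check.
 *
 * Parameter vector layout (length 51):
 *   [0]     C (capacitance)
 *   [1..8]  gNaT gNaP gCaT gCaH gKDR gKM gL gH
 *   [9..13] ENa ECa EK EL EH
 *   [14]    p (fast fraction of the H-current)
 *   [15..50] 12 gates x (V_x, k_x, tau_x) in the order
 *            mNaT hNaT mNaP mCaT hCaT mCaH hCaH mKDR hKDR mKM mH nH
 *            (tau of mNaT/mNaP unused: instantaneous; tau of hNaT unused:
 *             voltage-dependent closed form)
 * Stimulus vector (length 4): bias, pulse amplitude, pulse on, pulse off.
 * State vector (length 11): V, hNaT, mCaT, hCaT, mCaH, hCaH, mKDR, hKDR,
 *                           mKM, mH, nH.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NSTATE 11

static R_INLINE double boltz(double V, double Vx, double kx)
{
    return 1.0 / (1.0 + exp(-(V - Vx) / kx));
}

static R_INLINE double tau_hnat(double V)
{
    return 0.2 + 0.007 * exp(exp(-(V - 40.6) / 51.4));
}

static void ca1_rhs(double t, const double *y, double *dy,
                    const double *pp, const double *stim)
{
    const double V = y[0];
    const double Cm = pp[0];
    const double *g = pp + 1;   /* gNaT gNaP gCaT gCaH gKDR gKM gL gH */
    const double *E = pp + 9;   /* ENa ECa EK EL EH */
    const double pH = pp[14];
    const double *gt = pp + 15; /* 12 x (Vx, kx, tau) */

    const double mNaT = boltz(V, gt[0], gt[1]);
    const double mNaP = boltz(V, gt[6], gt[7]);

    const double hNaT = y[1], mCaT = y[2], hCaT = y[3], mCaH = y[4],
                 hCaH = y[5], mKDR = y[6], hKDR = y[7], mKM = y[8],
                 mH = y[9], nH = y[10];

    const double INaT = g[0] * mNaT * mNaT * mNaT * hNaT * (V - E[0]);
    const double INaP = g[1] * mNaP * (V - E[0]);
    const double ICaT = g[2] * mCaT * mCaT * hCaT * (V - E[1]);
    const double ICaH = g[3] * mCaH * mCaH * hCaH * (V - E[1]);
    const double IKDR = g[4] * mKDR * hKDR * (V - E[2]);
    const double IKM  = g[5] * mKM * (V - E[2]);
    const double IL   = g[6] * (V - E[3]);
    const double IH   = g[7] * (pH * mH + (1.0 - pH) * nH) * (V - E[4]);

    double Iapp = stim[0];
    if (t >= stim[2] && t < stim[3]) Iapp += stim[1];

    dy[0] = (Iapp - INaT - INaP - ICaT - ICaH - IKDR - IKM - IL - IH) / Cm;

    /* dynamic gates: dx/dt = (x_inf - x)/tau_x */
    dy[1]  = (boltz(V, gt[3],  gt[4])  - hNaT) / tau_hnat(V);
    dy[2]  = (boltz(V, gt[9],  gt[10]) - mCaT) / gt[11];
    dy[3]  = (boltz(V, gt[12], gt[13]) - hCaT) / gt[14];
    dy[4]  = (boltz(V, gt[15], gt[16]) - mCaH) / gt[17];
    dy[5]  = (boltz(V, gt[18], gt[19]) - hCaH) / gt[20];
    dy[6]  = (boltz(V, gt[21], gt[22]) - mKDR) / gt[23];
    dy[7]  = (boltz(V, gt[24], gt[25]) - hKDR) / gt[26];
    dy[8]  = (boltz(V, gt[27], gt[28]) - mKM)  / gt[29];
    dy[9]  = (boltz(V, gt[30], gt[31]) - mH)   / gt[32];
    dy[10] = (boltz(V, gt[33], gt[34]) - nH)   / gt[35];
}

SEXP C_ca1_rhs(SEXP y_, SEXP t_, SEXP par_, SEXP stim_)
{
    SEXP out = PROTECT(allocVector(REALSXP, NSTATE));
    ca1_rhs(asReal(t_), REAL(y_), REAL(out), REAL(par_), REAL(stim_));
    UNPROTECT(1);
    return out;
}

/* Dormand-Prince 5(4) coefficients */
static const double c2 = 1.0 / 5.0, c3 = 3.0 / 10.0, c4 = 4.0 / 5.0,
                    c5 = 8.0 / 9.0;
static const double a21 = 1.0 / 5.0;
static const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
static const double a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0;
static const double a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
                    a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0;
static const double a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0,
                    a63 = 46732.0 / 5247.0, a64 = 49.0 / 176.0,
                    a65 = -5103.0 / 18656.0;
static const double b1 = 35.0 / 384.0, b3 = 500.0 / 1113.0,
                    b4 = 125.0 / 192.0, b5 = -2187.0 / 6784.0,
                    b6 = 11.0 / 84.0;
static const double e1 = 71.0 / 57600.0, e3 = -71.0 / 16695.0,
                    e4 = 71.0 / 1920.0, e5 = -17253.0 / 339200.0,
                    e6 = 22.0 / 525.0, e7 = -1.0 / 40.0;

/* Integrate from tout[0] to tout[n-1]; y0 is the state at tout[0].
 * Output: n x NSTATE matrix of states at the requested times, via cubic
 * Hermite interpolation inside accepted steps. Returns R_NilValue-free
 * list(y = matrix, nstep, naccept). Errors on non-finite state or step
 * count exhaustion. */
SEXP C_ca1_dopri(SEXP y0_, SEXP tout_, SEXP par_, SEXP stim_,
                 SEXP rtol_, SEXP atol_, SEXP hmax_, SEXP maxstep_)
{
    const double *tout = REAL(tout_);
    const int nout = LENGTH(tout_);
    const double *pp = REAL(par_), *stim = REAL(stim_);
    const double rtol = asReal(rtol_), atol = asReal(atol_);
    const double hmax = asReal(hmax_);
    const double maxstep = asReal(maxstep_);

    SEXP ym = PROTECT(allocMatrix(REALSXP, nout, NSTATE));
    double *Y = REAL(ym);

    double y[NSTATE], ynew[NSTATE], yerr[NSTATE], ytmp[NSTATE];
    double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
           k6[NSTATE], k7[NSTATE];
    int i;

    for (i = 0; i < NSTATE; i++) y[i] = REAL(y0_)[i];
    double t = tout[0], tend = tout[nout - 1];
    for (i = 0; i < NSTATE; i++) Y[i * nout + 0] = y[i];
    int iout = 1;

    ca1_rhs(t, y, k1, pp, stim); /* FSAL */

    double h = 1e-3;
    long nstep = 0, naccept = 0;
    double errold = 1e-4;

    while (t < tend && iout < nout) {
        if (h > hmax) h = hmax;
        if (t + h > tend) h = tend - t;
        if (++nstep > (long) maxstep) {
            UNPROTECT(1);
            error("ca1 solver: step limit (%.0f) exceeded at t = %g",
                  maxstep, t);
        }

        for (i = 0; i < NSTATE; i++) ytmp[i] = y[i] + h * a21 * k1[i];
        ca1_rhs(t + c2 * h, ytmp, k2, pp, stim);
        for (i = 0; i < NSTATE; i++)
            ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
        ca1_rhs(t + c3 * h, ytmp, k3, pp, stim);
        for (i = 0; i < NSTATE; i++)
            ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
        ca1_rhs(t + c4 * h, ytmp, k4, pp, stim);
        for (i = 0; i < NSTATE; i++)
            ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                                  a54 * k4[i]);
        ca1_rhs(t + c5 * h, ytmp, k5, pp, stim);
        for (i = 0; i < NSTATE; i++)
            ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                  a64 * k4[i] + a65 * k5[i]);
        ca1_rhs(t + h, ytmp, k6, pp, stim);
        for (i = 0; i < NSTATE; i++)
            ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                  b5 * k5[i] + b6 * k6[i]);
        ca1_rhs(t + h, ynew, k7, pp, stim);
        for (i = 0; i < NSTATE; i++)
            yerr[i] = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                           e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);

        double errnorm = 0.0;
        for (i = 0; i < NSTATE; i++) {
            double sk = atol + rtol * fmax(fabs(y[i]), fabs(ynew[i]));
            double e = yerr[i] / sk;
            errnorm += e * e;
        }
        errnorm = sqrt(errnorm / NSTATE);
        if (!R_FINITE(errnorm)) errnorm = 1e10;

        if (errnorm <= 1.0) { /* accept */
            naccept++;
            /* dense output: cubic Hermite on [t, t+h] */
            while (iout < nout && tout[iout] <= t + h + 1e-12) {
                double s = (tout[iout] - t) / h;
                if (s < 0) s = 0;
                if (s > 1) s = 1;
                double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
                double h10 = s * (1 - s) * (1 - s);
                double h01 = s * s * (3 - 2 * s);
                double h11 = s * s * (s - 1);
                for (i = 0; i < NSTATE; i++)
                    Y[i * nout + iout] =
                        h00 * y[i] + h10 * h * k1[i] +
                        h01 * ynew[i] + h11 * h * k7[i];
                iout++;
            }
            t += h;
            for (i = 0; i < NSTATE; i++) {
                y[i] = ynew[i];
                k1[i] = k7[i];
                if (!R_FINITE(y[i])) {
                    UNPROTECT(1);
                    error("ca1 solver: non-finite state at t = %g", t);
                }
            }
            /* PI step-size controller */
            double fac = 0.9 * pow(errnorm, -0.7 / 5.0) *
                         pow(errold, 0.4 / 5.0);
            if (fac < 0.2) fac = 0.2;
            if (fac > 5.0) fac = 5.0;
            h *= fac;
            errold = fmax(errnorm, 1e-4);
        } else {
            double fac = fmax(0.2, 0.9 * pow(errnorm, -0.2));
            h *= fac;
        }
        if (h < 1e-12) {
            UNPROTECT(1);
            error("ca1 solver: step size underflow at t = %g", t);
        }
    }

    SEXP res = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(res, 0, ym);
    SET_VECTOR_ELT(res, 1, ScalarReal((double) nstep));
    SET_VECTOR_ELT(res, 2, ScalarReal((double) naccept));
    SEXP nm = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nm, 0, mkChar("y"));
    SET_STRING_ELT(nm, 1, mkChar("nstep"));
    SET_STRING_ELT(nm, 2, mkChar("naccept"));
    setAttrib(res, R_NamesSymbol, nm);
    UNPROTECT(3);
    return res;
}

/* Fixed-step classical RK4 from tout[0] to tout[n-1] with internal step dt;
 * states reported at the requested output times (which must lie on the
 * internal grid up to rounding). Numerical oracle for the adaptive solver. */
SEXP C_ca1_rk4(SEXP y0_, SEXP tout_, SEXP dt_, SEXP par_, SEXP stim_)
{
    const double *tout = REAL(tout_);
    const int nout = LENGTH(tout_);
    const double dt = asReal(dt_);
    const double *pp = REAL(par_), *stim = REAL(stim_);

    SEXP ym = PROTECT(allocMatrix(REALSXP, nout, NSTATE));
    double *Y = REAL(ym);

    double y[NSTATE], ytmp[NSTATE];
    double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE];
    int i;
    for (i = 0; i < NSTATE; i++) y[i] = REAL(y0_)[i];

    double t = tout[0];
    for (i = 0; i < NSTATE; i++) Y[i * nout + 0] = y[i];
    int iout = 1;
    const double tend = tout[nout - 1];
    const long nsteps = (long) ceil((tend - t) / dt - 1e-9);

    for (long s = 0; s < nsteps; s++) {
        double hstep = fmin(dt, tend - t);
        ca1_rhs(t, y, k1, pp, stim);
        for (i = 0; i < NSTATE; i++) ytmp[i] = y[i] + 0.5 * hstep * k1[i];
        ca1_rhs(t + 0.5 * hstep, ytmp, k2, pp, stim);
        for (i = 0; i < NSTATE; i++) ytmp[i] = y[i] + 0.5 * hstep * k2[i];
        ca1_rhs(t + 0.5 * hstep, ytmp, k3, pp, stim);
        for (i = 0; i < NSTATE; i++) ytmp[i] = y[i] + hstep * k3[i];
        ca1_rhs(t + hstep, ytmp, k4, pp, stim);
        for (i = 0; i < NSTATE; i++)
            y[i] += hstep / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
        t += hstep;
        while (iout < nout && tout[iout] <= t + 1e-9) {
            for (i = 0; i < NSTATE; i++) Y[i * nout + iout] = y[i];
            iout++;
        }
    }

    UNPROTECT(1);
    return ym;
}

/* Rcpp-generated entry points (src/RcppExports.cpp) */
SEXP _ganpop_cpp_nn_forward(SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP _ganpop_cpp_nn_backward(SEXP, SEXP, SEXP);
SEXP _ganpop_cpp_adam_step(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                           SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_ca1_rhs",   (DL_FUNC) &C_ca1_rhs,   4},
    {"C_ca1_dopri", (DL_FUNC) &C_ca1_dopri, 8},
    {"C_ca1_rk4",   (DL_FUNC) &C_ca1_rk4,   5},
    {"_ganpop_cpp_nn_forward",  (DL_FUNC) &_ganpop_cpp_nn_forward,  5},
    {"_ganpop_cpp_nn_backward", (DL_FUNC) &_ganpop_cpp_nn_backward, 3},
    {"_ganpop_cpp_adam_step",   (DL_FUNC) &_ganpop_cpp_adam_step,  13},
    {NULL, NULL, 0}
};

void R_init_ganpop(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
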