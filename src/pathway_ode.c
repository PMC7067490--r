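/* Mass-action signaling network right-hand side with forward sensitivities,
 * in the deSolve compiled-model convention.
 *
 * Every reaction flux has the form v_j = k[KI_j] * MOD_j * x[I1_j] * x[I2_j]
 * (absent factors = 1), where MOD_j is a constant input (ligand, cetuximab or
 * inhibitor concentration). The state vector is x (NS species) followed by
 * ns sensitivity columns d x / d theta_s; sensitivity parameters are either
 * rate constants (SENSK_s = k index) or pure initial-condition parameters
 * (SENSK_s = -1), whose effect enters through the initial sensitivity values
 * set on the R side.
 *
 * Parameter block layout (doubles, packed by the R side):
 *   [0] n species, [1] nr reactions, [2] ns sens parameters, [3] nk rate
 *   constants; then K[nk], KI[nr], I1[nr], I2[nr], MOD[nr], S[n*nr]
 *   (column-major), SENSK[ns].
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define P_MAX 12000
#define N_MAX 24
#define R_MAX 40

static double parms[P_MAX];

void pathway_init(void (*odeparms)(int *, double *))
{
    int N = P_MAX;
    odeparms(&N, parms);
}

void pathway_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const int n  = (int) parms[0];
    const int nr = (int) parms[1];
    const int ns = (int) parms[2];
    const int nk = (int) parms[3];
    const double *K     = parms + 4;
    const double *KI    = K + nk;
    const double *I1    = KI + nr;
    const double *I2    = I1 + nr;
    const double *MOD   = I2 + nr;
    const double *S     = MOD + nr;
    const double *SENSK = S + n * nr;

    double base[R_MAX], kk[R_MAX];
    double A[N_MAX * N_MAX];
    int i, j, s;

    if (n > N_MAX || nr > R_MAX)
        error("pathway_derivs: model exceeds compiled size limits");

    /* fluxes and state derivatives */
    for (j = 0; j < nr; j++) {
        int a = (int) I1[j], b = (int) I2[j];
        double f = MOD[j];
        if (a >= 0) f *= y[a];
        if (b >= 0) f *= y[b];
        base[j] = f;
        kk[j] = K[(int) KI[j]];
    }
    for (i = 0; i < n; i++) ydot[i] = 0.0;
    for (j = 0; j < nr; j++) {
        double v = kk[j] * base[j];
        const double *Sj = S + (size_t) j * n;
        for (i = 0; i < n; i++) ydot[i] += Sj[i] * v;
    }

    if (ns == 0) return;

    /* A = S dv/dx (n x n, column-major A[i + n*col]) */
    for (i = 0; i < n * n; i++) A[i] = 0.0;
    for (j = 0; j < nr; j++) {
        int a = (int) I1[j], b = (int) I2[j];
        const double *Sj = S + (size_t) j * n;
        double km = kk[j] * MOD[j];
        if (a >= 0) {
            double d = km * (b >= 0 ? y[b] : 1.0);
            for (i = 0; i < n; i++) A[i + n * a] += Sj[i] * d;
        }
        if (b >= 0) {
            double d = km * (a >= 0 ? y[a] : 1.0);
            for (i = 0; i < n; i++) A[i + n * b] += Sj[i] * d;
        }
    }

    for (s = 0; s < ns; s++) {
        const double *Sx = y + n * (1 + s);
        double *Sdot = ydot + n * (1 + s);
        int ks = (int) SENSK[s];
        for (i = 0; i < n; i++) {
            double acc = 0.0;
            for (j = 0; j < n; j++) acc += A[i + n * j] * Sx[j];
            Sdot[i] = acc;
        }
        if (ks >= 0) {
            for (j = 0; j < nr; j++) {
                if ((int) KI[j] == ks) {
                    const double *Sj = S + (size_t) j * n;
                    for (i = 0; i < n; i++) Sdot[i] += Sj[i] * base[j];
                }
            }
        }
    }
}

/* Full analytic Jacobian of the augmented system (column-major, nrowpd rows).
 * d(xdot)/dx = A; d(Sxdot_s)/dx picks up second derivatives of v through A;
 * d(Sxdot_s)/d(Sx_s) = A (block diagonal).
 */
void pathway_jac(int *neq, double *t, double *y, int *ml, int *mu,
                 double *pd, int *nrowpd, double *yout, int *ip)
{
    const int n  = (int) parms[0];
    const int nr = (int) parms[1];
    const int ns = (int) parms[2];
    const int nk = (int) parms[3];
    const double *K     = parms + 4;
    const double *KI    = K + nk;
    const double *I1    = KI + nr;
    const double *I2    = I1 + nr;
    const double *MOD   = I2 + nr;
    const double *S     = MOD + nr;
    const double *SENSK = S + n * nr;
    const int N = *neq, LD = *nrowpd;

    double A[N_MAX * N_MAX], kk[R_MAX];
    int i, j, s, c;

    if (n > N_MAX || nr > R_MAX)
        error("pathway_jac: model exceeds compiled size limits");

    for (i = 0; i < LD * N; i++) pd[i] = 0.0;
    for (j = 0; j < nr; j++) kk[j] = K[(int) KI[j]];

    for (i = 0; i < n * n; i++) A[i] = 0.0;
    for (j = 0; j < nr; j++) {
        int a = (int) I1[j], b = (int) I2[j];
        const double *Sj = S + (size_t) j * n;
        double km = kk[j] * MOD[j];
        if (a >= 0) {
            double d = km * (b >= 0 ? y[b] : 1.0);
            for (i = 0; i < n; i++) A[i + n * a] += Sj[i] * d;
        }
        if (b >= 0) {
            double d = km * (a >= 0 ? y[a] : 1.0);
            for (i = 0; i < n; i++) A[i + n * b] += Sj[i] * d;
        }
    }

    /* top-left block and sensitivity diagonal blocks: A */
    for (c = 0; c < n; c++)
        for (i = 0; i < n; i++)
            pd[i + (size_t) LD * c] = A[i + n * c];
    for (s = 0; s < ns; s++) {
        int off = n * (1 + s);
        for (c = 0; c < n; c++)
            for (i = 0; i < n; i++)
                pd[off + i + (size_t) LD * (off + c)] = A[i + n * c];
    }

    /* d(Sxdot_s)/dx_t: second-derivative terms (only two-reactant reactions
     * contribute) plus d b_s / dx for rate-constant sensitivity parameters */
    for (s = 0; s < ns; s++) {
        int off = n * (1 + s);
        const double *Sx = y + off;
        int ks = (int) SENSK[s];
        for (j = 0; j < nr; j++) {
            int a = (int) I1[j], b = (int) I2[j];
            const double *Sj = S + (size_t) j * n;
            double km = kk[j] * MOD[j];
            if (a >= 0 && b >= 0) {
                /* d/dx_b of km*(x_b*Sx_a + x_a*Sx_b) = km*Sx_a, and sym. */
                double da = km * Sx[b];  /* coefficient on column a */
                double db = km * Sx[a];  /* coefficient on column b */
                for (i = 0; i < n; i++) {
                    pd[off + i + (size_t) LD * a] += Sj[i] * da;
                    pd[off + i + (size_t) LD * b] += Sj[i] * db;
                }
            }
            if (ks >= 0 && (int) KI[j] == ks) {
                /* b_s = sum_j S_j * MOD_j * x_a x_b; derivative wrt states */
                if (a >= 0) {
                    double d = MOD[j] * (b >= 0 ? y[b] : 1.0);
                    for (i = 0; i < n; i++)
                        pd[off + i + (size_t) LD * a] += Sj[i] * d;
                }
                if (b >= 0) {
                    double d = MOD[j] * (a >= 0 ? y[a] : 1.0);
                    for (i = 0; i < n; i++)
                        pd[off + i + (size_t) LD * b] += Sj[i] * d;
                }
            }
        }
    }
}

static const R_CMethodDef cMethods[] = {
    {"pathway_init",   (DL_FUNC) &pathway_init,   1},
    {"pathway_derivs", (DL_FUNC) &pathway_derivs, 6},
    {"pathway_jac",    (DL_FUNC) &pathway_jac,    9},
    {NULL, NULL, 0}
};

void R_init_egfrsig(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
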