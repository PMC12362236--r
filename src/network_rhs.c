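/* Mass-action radiolysis network: compiled right-hand side for deSolve,
 * plus a fixed-step backward-Euler integrator used as an independent
 * cross-check of the adaptive solver.
 *
 * The network (reactant indices, event-rate constants, stoichiometry and
 * radiolytic source vector) is loaded into static storage with
 * C_set_network() before a solve; the per-segment dose rate is the single
 * deSolve parameter (read by initmod). Rates are evaluated with
 * concentrations clamped at zero so that tiny negative solver excursions
 * cannot feed back into the dynamics.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

static int nspec = 0, nrx = 0;
static int *ri1 = NULL, *ri2 = NULL;   /* 0-based; ri2 = -1: single factor */
static double *rk = NULL;              /* event-rate constants (pools folded) */
static double *Smat = NULL;            /* nspec x nrx, column-major */
static double *gsrc = NULL;            /* source per unit dose rate, M/Gy */
static double doserate = 0.0;          /* Gy/s for the current segment */

static void free_network(void)
{
    if (ri1) { R_Free(ri1); ri1 = NULL; }
    if (ri2) { R_Free(ri2); ri2 = NULL; }
    if (rk)  { R_Free(rk);  rk  = NULL; }
    if (Smat){ R_Free(Smat); Smat = NULL; }
    if (gsrc){ R_Free(gsrc); gsrc = NULL; }
}

SEXP C_set_network(SEXP i1_, SEXP i2_, SEXP k_, SEXP S_, SEXP g_)
{
    free_network();
    nrx = LENGTH(k_);
    nspec = LENGTH(g_);
    if (LENGTH(S_) != nspec * nrx)
        error("stoichiometry matrix has wrong dimension");
    ri1 = R_Calloc(nrx ? nrx : 1, int);
    ri2 = R_Calloc(nrx ? nrx : 1, int);
    rk  = R_Calloc(nrx ? nrx : 1, double);
    Smat = R_Calloc((nspec * nrx) ? nspec * nrx : 1, double);
    gsrc = R_Calloc(nspec, double);
    for (int j = 0; j < nrx; j++) {
        ri1[j] = INTEGER(i1_)[j] - 1;       /* R 1-based -> 0-based */
        ri2[j] = INTEGER(i2_)[j] - 1;       /* 0 -> -1 means absent */
        rk[j] = REAL(k_)[j];
    }
    for (int m = 0; m < nspec * nrx; m++) Smat[m] = REAL(S_)[m];
    for (int i = 0; i < nspec; i++) gsrc[i] = REAL(g_)[i];
    return ScalarInteger(nspec);
}

/* deSolve initializer: the lone parameter is the segment dose rate */
void initmod(void (*odeparms)(int *, double *))
{
    int N = 1;
    odeparms(&N, &doserate);
}

static void rhs(const double *y, double *ydot)
{
    for (int i = 0; i < nspec; i++)
        ydot[i] = gsrc[i] * doserate;
    for (int j = 0; j < nrx; j++) {
        double v = y[ri1[j]];
        double r;
        if (ri2[j] >= 0) {
            /* bimolecular: clamp factors so tiny negative excursions
             * cannot produce wrong-sign rates */
            double w = y[ri2[j]];
            if (v < 0) v = 0;
            if (w < 0) w = 0;
            r = rk[j] * v * w;
        } else {
            /* (pseudo-)first-order terms stay linear through zero: the
             * kink of a clamp at 0 destabilises the stiff solver when the
             * decay constant is large */
            r = rk[j] * v;
        }
        if (r == 0) continue;
        const double *col = Smat + (size_t)j * nspec;
        for (int i = 0; i < nspec; i++)
            ydot[i] += col[i] * r;
    }
}

void derivs(int *neq, double *t, double *y, double *ydot,
            double *yout, int *ip)
{
    (void) t; (void) yout; (void) ip;
    if (*neq != nspec)
        error("state dimension does not match loaded network");
    rhs(y, ydot);
}

/* R-callable single evaluation (used for R-vs-C equivalence tests) */
SEXP C_eval_rhs(SEXP y_, SEXP rate_)
{
    if (LENGTH(y_) != nspec) error("state dimension mismatch");
    double saved = doserate;
    doserate = REAL(rate_)[0];
    SEXP out = PROTECT(allocVector(REALSXP, nspec));
    rhs(REAL(y_), REAL(out));
    doserate = saved;
    UNPROTECT(1);
    return out;
}

/* ---- fixed-step backward Euler with chord-Newton iteration ---------- */

static int lu_decomp(double *A, int n, int *piv)
{
    for (int k = 0; k < n; k++) {
        int p = k;
        double mx = fabs(A[k + k * n]);
        for (int i = k + 1; i < n; i++)
            if (fabs(A[i + k * n]) > mx) { mx = fabs(A[i + k * n]); p = i; }
        if (mx == 0.0) return 1;
        piv[k] = p;
        if (p != k)
            for (int j = 0; j < n; j++) {
                double tmp = A[k + j * n];
                A[k + j * n] = A[p + j * n];
                A[p + j * n] = tmp;
            }
        for (int i = k + 1; i < n; i++) {
            A[i + k * n] /= A[k + k * n];
            double f = A[i + k * n];
            for (int j = k + 1; j < n; j++)
                A[i + j * n] -= f * A[k + j * n];
        }
    }
    return 0;
}

static void lu_solve(const double *A, int n, const int *piv, double *b)
{
    for (int k = 0; k < n; k++) {
        if (piv[k] != k) {
            double tmp = b[k]; b[k] = b[piv[k]]; b[piv[k]] = tmp;
        }
        for (int i = k + 1; i < n; i++)
            b[i] -= A[i + k * n] * b[k];
    }
    for (int i = n - 1; i >= 0; i--) {
        for (int j = i + 1; j < n; j++)
            b[i] -= A[i + j * n] * b[j];
        b[i] /= A[i + i * n];
    }
}

/* Newton matrix I - dt*J at state y, by forward differences on the rhs */
static void newton_matrix(const double *y, double dt, double *A,
                          double *f0, double *ypert, double *fpert)
{
    int n = nspec;
    rhs(y, f0);
    for (int j = 0; j < n; j++) {
        for (int i = 0; i < n; i++) ypert[i] = y[i];
        double h = 1e-7 * fabs(y[j]) + 1e-16;
        ypert[j] += h;
        rhs(ypert, fpert);
        for (int i = 0; i < n; i++)
            A[i + j * n] = ((i == j) ? 1.0 : 0.0)
                - dt * (fpert[i] - f0[i]) / h;
    }
}

/* Integrate from t=0 to t_end with fixed step dt at constant dose rate. */
SEXP C_be_solve(SEXP y0_, SEXP tend_, SEXP dt_, SEXP rate_)
{
    int n = nspec;
    if (LENGTH(y0_) != n) error("state dimension mismatch");
    double tend = REAL(tend_)[0], dt = REAL(dt_)[0];
    double saved = doserate;
    doserate = REAL(rate_)[0];
    long nstep = (long) llround(tend / dt);

    SEXP out = PROTECT(allocVector(REALSXP, n));
    double *y = REAL(out);
    for (int i = 0; i < n; i++) y[i] = REAL(y0_)[i];

    double *A = R_Calloc((size_t)n * n, double);
    int *piv = R_Calloc(n, int);
    double *f = R_Calloc(n, double), *res = R_Calloc(n, double);
    double *ynew = R_Calloc(n, double);
    double *w1 = R_Calloc(n, double), *w2 = R_Calloc(n, double);

    newton_matrix(y, dt, A, f, w1, w2);
    if (lu_decomp(A, n, piv)) error("singular Newton matrix");

    for (long s = 0; s < nstep; s++) {
        for (int i = 0; i < n; i++) ynew[i] = y[i];
        int ok = 0;
        for (int refresh = 0; refresh < 3 && !ok; refresh++) {
            for (int it = 0; it < 8; it++) {
                rhs(ynew, f);
                double nrm = 0.0;
                for (int i = 0; i < n; i++) {
                    res[i] = ynew[i] - y[i] - dt * f[i];
                    double sc = fabs(ynew[i]) * 1e-10 + 1e-22;
                    double e = fabs(res[i]) / sc;
                    if (e > nrm) nrm = e;
                }
                if (nrm < 1.0) { ok = 1; break; }
                lu_solve(A, n, piv, res);
                for (int i = 0; i < n; i++) ynew[i] -= res[i];
            }
            if (!ok) {
                newton_matrix(ynew, dt, A, f, w1, w2);
                if (lu_decomp(A, n, piv)) error("singular Newton matrix");
            }
        }
        if (!ok) {
            doserate = saved;
            error("backward-Euler Newton iteration failed at step %ld", s);
        }
        for (int i = 0; i < n; i++) y[i] = ynew[i];
    }

    R_Free(A); R_Free(piv); R_Free(f); R_Free(res);
    R_Free(ynew); R_Free(w1); R_Free(w2);
    doserate = saved;
    UNPROTECT(1);
    return out;
}
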