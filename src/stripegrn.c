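/* Reaction-diffusion core for 3-gene networks on a 1-D cell field.
 *
 * Two entry points:
 *   - C_grn_derivs: right-hand side consumed by deSolve (dllname route);
 *     model parameters are staged beforehand with C_grn_set_model.
 *   - C_euler_integrate: self-contained fixed-step Euler integrator used as
 *     an independent numerical oracle; it does not share state or derivative
 *     code with the deSolve route.
 *
 * State layout is gene-major: y[i*N + n] = concentration of gene i in cell n,
 * i in {0,1,2}, n in {0..N-1}.  Zero-flux boundaries: the missing-neighbour
 * diffusion term is dropped at the two ends of the field.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>
#include <string.h>

#define MAX_CELLS 4096

/* staged model parameters for the deSolve route */
static double g_W[12];          /* 3x4 row-major: rows A,B,C; cols M,A,B,C */
static double g_D[3];
static double g_delta[3];
static double g_a = 5.0;
static double g_b = 5.0;
static double g_M[MAX_CELLS];
static int    g_N = 0;

SEXP C_grn_set_model(SEXP W, SEXP D, SEXP delta, SEXP a, SEXP b, SEXP M)
{
    int N = LENGTH(M);
    if (LENGTH(W) != 12 || LENGTH(D) != 3 || LENGTH(delta) != 3)
        error("model parameter vectors have wrong length");
    if (N < 2 || N > MAX_CELLS)
        error("number of cells must be in [2, %d]", MAX_CELLS);
    memcpy(g_W, REAL(W), 12 * sizeof(double));
    memcpy(g_D, REAL(D), 3 * sizeof(double));
    memcpy(g_delta, REAL(delta), 3 * sizeof(double));
    g_a = asReal(a);
    g_b = asReal(b);
    memcpy(g_M, REAL(M), N * sizeof(double));
    g_N = N;
    return R_NilValue;
}

/* deSolve-compatible derivative: dy/dt = g(u) + D*Laplacian - delta*y */
void C_grn_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const int N = g_N;
    if (N <= 0 || *neq != 3 * N)
        error("model parameters not staged for this state size");
    for (int i = 0; i < 3; i++) {
        const double *w = g_W + 4 * i;
        const double Di = g_D[i], di = g_delta[i];
        const double *gi = y + i * N;
        double *dgi = ydot + i * N;
        for (int n = 0; n < N; n++) {
            double u = w[0] * g_M[n] + w[1] * y[n] + w[2] * y[N + n] +
                       w[3] * y[2 * N + n];
            double act = 1.0 / (1.0 + exp(g_a - g_b * u));
            double diff = 0.0;
            if (n > 0)     diff += gi[n - 1] - gi[n];
            if (n < N - 1) diff += gi[n + 1] - gi[n];
            dgi[n] = act + Di * diff - di * gi[n];
        }
    }
}

/* Independent fixed-step Euler oracle.
 * times must be non-negative and non-decreasing; each is snapped to the
 * nearest multiple of dt.  Returns a length(times) x 3N matrix. */
SEXP C_euler_integrate(SEXP W, SEXP D, SEXP delta, SEXP a, SEXP b,
                       SEXP M, SEXP y0, SEXP times, SEXP dt)
{
    const int N = LENGTH(M);
    const int neq = LENGTH(y0);
    const int nt = LENGTH(times);
    if (neq != 3 * N) error("y0 must have length 3 * length(M)");
    const double *w = REAL(W), *dd = REAL(D), *de = REAL(delta);
    const double *mm = REAL(M), *tt = REAL(times);
    const double aa = asReal(a), bb = asReal(b), h = asReal(dt);
    if (h <= 0) error("dt must be positive");

    SEXP out = PROTECT(allocMatrix(REALSXP, nt, neq));
    double *res = REAL(out);
    double *y = (double *) R_alloc(neq, sizeof(double));
    double *dy = (double *) R_alloc(neq, sizeof(double));
    memcpy(y, REAL(y0), neq * sizeof(double));

    long step = 0;
    for (int k = 0; k < nt; k++) {
        long target = (long) llround(tt[k] / h);
        if (target < step) error("times must be non-decreasing");
        for (; step < target; step++) {
            for (int i = 0; i < 3; i++) {
                const double *gi = y + i * N;
                double *dgi = dy + i * N;
                const double wi0 = w[4 * i], wi1 = w[4 * i + 1],
                             wi2 = w[4 * i + 2], wi3 = w[4 * i + 3];
                for (int n = 0; n < N; n++) {
                    double u = wi0 * mm[n] + wi1 * y[n] + wi2 * y[N + n] +
                               wi3 * y[2 * N + n];
                    double act = 1.0 / (1.0 + exp(aa - bb * u));
                    double diff = 0.0;
                    if (n > 0)     diff += gi[n - 1] - gi[n];
                    if (n < N - 1) diff += gi[n + 1] - gi[n];
                    dgi[n] = act + dd[i] * diff - de[i] * gi[n];
                }
            }
            for (int j = 0; j < neq; j++) y[j] += h * dy[j];
            if ((step & 0xFFFF) == 0) R_CheckUserInterrupt();
        }
        for (int j = 0; j < neq; j++) res[k + (long) nt * j] = y[j];
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_grn_set_model",    (DL_FUNC) &C_grn_set_model,    6},
    {"C_euler_integrate",  (DL_FUNC) &C_euler_integrate,  9},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"C_grn_derivs", (DL_FUNC) &C_grn_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_stripegrn(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
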