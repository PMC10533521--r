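/* Method-of-lines right-hand side of the flagellar reaction-diffusion
 * system, called from deSolve's stiff integrators.
 *
 * State layout (interleaved so the Jacobian is banded):
 *   y[3*i] = gamma_i, y[3*i+1] = nplus_i, y[3*i+2] = nminus_i,
 * for i = 0..m-1 on m equally spaced arclength points of [0, 1].
 *
 * gamma_t is solvable in closed form at every node: penalized at the
 * base (gamma_t,0 = -gamma_0), centred Laplacian in the interior, and a
 * one-sided stencil at the free tip (ghost node from gamma_s(1) = 0).
 * The motor rate equations use the substituted gamma_t; when FEEDBACK
 * is off the detachment exponent is frozen at its equilibrium value,
 * giving the pure shear-diffusion limit.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double parms[8];
#define MU_A     parms[0]
#define MU       parms[1]
#define ETA      parms[2]
#define ZETA     parms[3]
#define FSTAR    parms[4]
#define W2       parms[5]   /* squared inverse grid spacing factor */
#define NPTS     parms[6]
#define FEEDBACK parms[7]

void rd_init(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void rd_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int m = (int) NPTS;
    for (int i = 0; i < m; i++) {
        double g  = y[3 * i];
        double np = y[3 * i + 1];
        double nm = y[3 * i + 2];
        double nbar = np + nm;
        double ntil = nm - np;
        double gt;

        /* Guard against non-physical transient iterates of the implicit
         * solver (nbar <= 0, or exponent overflow): clip to large finite
         * values so Newton can recover; physical trajectories keep
         * nbar > 0 and moderate exponents. */
        if (nbar < 1e-10) nbar = 1e-10;

        if (i == 0) {
            gt = -g;                       /* basal penalization */
        } else {
            double lap;
            if (i == m - 1)
                lap = 2.0 * W2 * (y[3 * (m - 2)] - g);
            else
                lap = W2 * (y[3 * (i + 1)] - 2.0 * g + y[3 * (i - 1)]);
            gt = (lap - MU * g + MU_A * ntil) / (MU_A * ZETA * nbar);
        }

        double ep, em;
        if (FEEDBACK > 0.5) {
            double ap = FSTAR * (1.0 + ZETA * gt);
            double am = FSTAR * (1.0 - ZETA * gt);
            if (ap > 500.0) ap = 500.0;
            if (am > 500.0) am = 500.0;
            ep = exp(ap);
            em = exp(am);
        } else {
            ep = em = exp(FSTAR);
        }

        ydot[3 * i]     = gt;
        ydot[3 * i + 1] = ETA * (1.0 - np) - (1.0 - ETA) * np * ep;
        ydot[3 * i + 2] = ETA * (1.0 - nm) - (1.0 - ETA) * nm * em;
    }
}

static const R_CMethodDef CEntries[] = {
    {"rd_init",   (DL_FUNC) &rd_init,   1},
    {"rd_derivs", (DL_FUNC) &rd_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_flagellaRD(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
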