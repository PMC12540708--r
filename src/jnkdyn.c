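/* Compiled kernels for the JNK signaling model.
 *
 * jnk_initmod / jnk_derivs: deSolve-compatible right-hand side of the
 * seven-species model (mass-action or Hill-promoter target equation).
 * The stimulus c is piecewise-constant and passed as a parameter; the R
 * side integrates segment-by-segment between stimulus switch times.
 *
 * target_scan: batch integration of the (linear-in-target) target-gene
 * equation dx/dt = f(t) - alpha * x against a stored forcing f sampled on
 * a uniform fine grid, for a whole vector of alpha values and a set of
 * forcing columns (one per promoter-affinity K, or a single column for
 * mass action). The update uses the exact solution for piecewise-linear
 * forcing, so accuracy is limited only by the forcing interpolation.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

static double parms[24];
#define beta_j      parms[0]
#define alpha_j     parms[1]
#define beta_jp     parms[2]
#define n_phos      parms[3]
#define T_half      parms[4]
#define alpha_junp  parms[5]
#define beta_jmi    parms[6]
#define beta_mj     parms[7]
#define alpha_jm    parms[8]
#define beta_t      parms[9]
#define beta_tj     parms[10]
#define alpha_m     parms[11]
#define beta_jnkp   parms[12]
#define alpha_jnkp  parms[13]
#define alpha_djnkp parms[14]
#define Td          parms[15]
#define beta_md     parms[16]
#define alpha_dusp  parms[17]
#define beta_dusp   parms[18]
#define alpha_dp    parms[19]
#define n_target    parms[20]
#define K_aff       parms[21]
#define c_value     parms[22]
#define use_hill    parms[23]

void jnk_initmod(void (*odeparms)(int *, double *))
{
    int n = 24;
    odeparms(&n, parms);
}

/* Hill activation with the convention 0^n / (0 + K^n) = 0. */
static double hill(double x, double K, double n)
{
    double xn, Kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    Kn = pow(K, n);
    return xn / (xn + Kn);
}

/* State order: inactive_cJun, pJun, cJun_mRNA, target_gene, active_JNK,
 * DUSP1_mRNA, DUSP1. */
void jnk_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double hJ = hill(y[4], T_half, n_phos);
    double hD = hill(y[6], Td, n_phos);
    double phos = beta_jp * y[0] * hJ;
    double prod;

    ydot[0] = beta_j * y[2] - alpha_j * y[0] - phos;
    ydot[1] = phos - alpha_junp * y[1];
    ydot[2] = beta_jmi + beta_mj * y[1] - alpha_jm * y[2];
    if (use_hill > 0.5)
        prod = beta_t + beta_tj * hill(y[1], K_aff, n_target);
    else
        prod = beta_t + beta_tj * y[1];
    ydot[3] = prod - alpha_m * y[3];
    ydot[4] = beta_jnkp * c_value - alpha_jnkp * y[4] - alpha_djnkp * y[4] * hD;
    ydot[5] = beta_md * y[1] - alpha_dusp * y[5];
    ydot[6] = beta_dusp * y[5] - alpha_dp * y[6];
}

/* Exact-update batch integrator for dx/dt = f(t) - a x with f piecewise
 * linear on a uniform grid of step dt.
 *
 * f:      ntime x nk column-major matrix of forcing values
 * alpha:  nalpha decay rates (all > 0)
 * x0:     nalpha initial conditions (steady state beta_t / alpha)
 * outidx: nout 1-based indices into the time grid at which to store x
 * out:    nout x nalpha x nk array (column-major)
 */
SEXP jnk_target_scan(SEXP f_, SEXP dt_, SEXP alpha_, SEXP x0_,
                     SEXP outidx_, SEXP ntime_)
{
    int ntime = INTEGER(ntime_)[0];
    int nk = (int)(XLENGTH(f_) / ntime);
    int nalpha = (int)XLENGTH(alpha_);
    int nout = (int)XLENGTH(outidx_);
    double dt = REAL(dt_)[0];
    double *f = REAL(f_);
    double *alpha = REAL(alpha_);
    double *x0 = REAL(x0_);
    int *outidx = INTEGER(outidx_);

    SEXP out_ = PROTECT(alloc3DArray(REALSXP, nout, nalpha, nk));
    double *out = REAL(out_);

    /* per-alpha propagator coefficients */
    double *E = (double *) R_alloc(nalpha, sizeof(double));
    double *A = (double *) R_alloc(nalpha, sizeof(double));
    double *B = (double *) R_alloc(nalpha, sizeof(double));
    for (int a = 0; a < nalpha; a++) {
        double ad = alpha[a] * dt;
        E[a] = exp(-ad);
        A[a] = (1.0 - E[a] * (1.0 + ad)) / (alpha[a] * ad);
        B[a] = (1.0 - E[a]) / alpha[a] - A[a];
    }

    for (int k = 0; k < nk; k++) {
        double *fk = f + (size_t)k * ntime;
        for (int a = 0; a < nalpha; a++) {
            double x = x0[a];
            int io = 0;
            double *oa = out + (size_t)k * nout * nalpha + (size_t)a * nout;
            if (io < nout && outidx[io] == 1) { oa[io] = x; io++; }
            for (int i = 1; i < ntime; i++) {
                x = E[a] * x + A[a] * fk[i - 1] + B[a] * fk[i];
                if (io < nout && outidx[io] == i + 1) { oa[io] = x; io++; }
            }
        }
    }
    UNPROTECT(1);
    return out_;
}
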