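#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void jnk_initmod(void (*odeparms)(int *, double *));
void jnk_derivs(int *, double *, double *, double *, double *, int *);
SEXP jnk_target_scan(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"jnk_target_scan", (DL_FUNC) &jnk_target_scan, 6},
    {NULL, NULL, 0}
};

void R_init_jnkdyn(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    /* jnk_initmod / jnk_derivs are looked up by name from deSolve */
    R_useDynamicSymbols(dll, TRUE);
}
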