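#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void camito_init(void (*odeparms)(int *, double *));
void camito_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);
SEXP camito_flux_matrix(SEXP y_mat, SEXP pvec);

static const R_CallMethodDef call_entries[] = {
    {"camito_flux_matrix", (DL_FUNC) &camito_flux_matrix, 2},
    {NULL, NULL, 0}
};

/* registered so deSolve's getNativeSymbolInfo() lookup finds them */
static const R_CMethodDef c_entries[] = {
    {"camito_derivs", (DL_FUNC) &camito_derivs, 6},
    {"camito_init",   (DL_FUNC) &camito_init,   1},
    {NULL, NULL, 0}
};

void R_init_camito(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
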