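#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_set_network(SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_eval_rhs(SEXP, SEXP);
SEXP C_be_solve(SEXP, SEXP, SEXP, SEXP);
void initmod(void (*)(int *, double *));
void derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef call_entries[] = {
    {"C_set_network", (DL_FUNC) &C_set_network, 5},
    {"C_eval_rhs",    (DL_FUNC) &C_eval_rhs,    2},
    {"C_be_solve",    (DL_FUNC) &C_be_solve,    4},
    {NULL, NULL, 0}
};

/* deSolve resolves these by name through getNativeSymbolInfo() */
static const R_CMethodDef c_entries[] = {
    {"initmod", (DL_FUNC) &initmod, 0},
    {"derivs",  (DL_FUNC) &derivs,  0},
    {NULL, NULL, 0}
};

void R_init_flashros(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
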