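#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void qnetuq_initmod(void (*odeparms)(int *, double *));
void qnetuq_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);
void qnetuq_setparms(double *p, int *np);
void qnetuq_derivs_eval(double *t, double *y, double *ydot, double *yout);

static const R_CMethodDef CEntries[] = {
    {"qnetuq_setparms",    (DL_FUNC) &qnetuq_setparms,    2},
    {"qnetuq_derivs_eval", (DL_FUNC) &qnetuq_derivs_eval, 4},
    {NULL, NULL, 0}
};

void R_init_qnetuq(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    /* deSolve looks up derivs/initmod by name at run time */
    R_useDynamicSymbols(dll, TRUE);
}
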