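#include <R.h>
#include <R_ext/Rdynload.h>

void hpt_initparms(void (*odeparms)(int *, double *));
void hpt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"hpt_initparms", (DL_FUNC) &hpt_initparms, 1},
    {"hpt_derivs",    (DL_FUNC) &hpt_derivs,    6},
    {NULL, NULL, 0}
};

void R_init_hptsim(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
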