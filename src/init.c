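#include <R.h>
#include <R_ext/Rdynload.h>

void azi_init(void (*odeparms)(int *, double *));
void azi_rhs(int *neq, double *t, double *y, double *ydot,
             double *yout, int *ip);

void R_init_aziflow(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
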