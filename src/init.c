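#include <R.h>
#include <R_ext/Rdynload.h>

void ner_init(void (*odeparms)(int *, double *));
void ner_derivs(int *, double *, double *, double *, double *, int *);
void ner_flip_derivs(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"ner_init", (DL_FUNC) &ner_init, 1},
    {"ner_derivs", (DL_FUNC) &ner_derivs, 6},
    {"ner_flip_derivs", (DL_FUNC) &ner_flip_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_nercontrol(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
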