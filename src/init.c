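#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_h5_write(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_h5_read_meta(SEXP);
SEXP C_h5_read_traces(SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef call_entries[] = {
    {"C_h5_write",       (DL_FUNC) &C_h5_write,       8},
    {"C_h5_read_meta",   (DL_FUNC) &C_h5_read_meta,   1},
    {"C_h5_read_traces", (DL_FUNC) &C_h5_read_traces, 4},
    {NULL, NULL, 0}
};

void R_init_mealfp(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
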