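#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <R_ext/Rdynload.h>

/* Endpoint of the per-generation drift of a species-mean trait.
 *
 * Each generation the mean moves by the sample mean of Ne draws from
 * N(0, s2), i.e. by one N(0, s2/Ne) increment; `sd` is sqrt(s2/Ne).
 * Returns n_rep independent endpoints after n_gen generations, using R's
 * RNG so results are reproducible under set.seed().
 */
SEXP C_drift_endpoints(SEXP mean0, SEXP sd, SEXP n_gen, SEXP n_rep)
{
    double m0 = asReal(mean0);
    double s = asReal(sd);
    double ngd = asReal(n_gen);
    int nr = asInteger(n_rep);
    if (ngd < 0 || !R_FINITE(ngd)) error("invalid generation count");
    if (nr < 1) error("invalid replicate count");
    R_xlen_t ng = (R_xlen_t) ngd;

    SEXP out = PROTECT(allocVector(REALSXP, nr));
    double *po = REAL(out);
    GetRNGstate();
    for (int r = 0; r < nr; r++) {
        double acc = 0.0;
        for (R_xlen_t g = 0; g < ng; g++)
            acc += norm_rand();
        po[r] = m0 + s * acc;
    }
    PutRNGstate();
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_drift_endpoints", (DL_FUNC) &C_drift_endpoints, 4},
    {NULL, NULL, 0}
};

void R_init_evoscales(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
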