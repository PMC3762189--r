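/* Compiled mass-action right-hand side for deSolve.
 *
 * The reaction network is packed into the parameter vector as
 *   p[0] = n_species
 *   p[1] = n_elementary_reactions
 *   then, per elementary reaction:
 *     k, reactant1 (1-based), reactant2 (0 if unimolecular),
 *     n_stoich, then n_stoich pairs (species index, coefficient).
 * The vector is zero-padded to ARPKIN_PARMS_LEN so that a single
 * fixed-length initializer can be used for every network variant.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define ARPKIN_PARMS_LEN 4096

static double parms[ARPKIN_PARMS_LEN];

void arpkin_initmod(void (*odeparms)(int *, double *))
{
    int n = ARPKIN_PARMS_LEN;
    odeparms(&n, parms);
}

void arpkin_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    int nsp = (int) parms[0];
    int nrx = (int) parms[1];
    int pos = 2, j, s;

    for (j = 0; j < nsp; j++) ydot[j] = 0.0;

    for (j = 0; j < nrx; j++) {
        double k = parms[pos];
        int r1 = (int) parms[pos + 1];
        int r2 = (int) parms[pos + 2];
        int nst = (int) parms[pos + 3];
        double v = k * y[r1 - 1];
        if (r2 > 0) v *= y[r2 - 1];
        pos += 4;
        for (s = 0; s < nst; s++) {
            ydot[(int) parms[pos] - 1] += parms[pos + 1] * v;
            pos += 2;
        }
    }
}

void arpkin_gray_morph(double *img, int *nx_, int *ny_, int *radius_,
                       int *do_max_, double *out);

static const R_CMethodDef cMethods[] = {
    {"arpkin_initmod",    (DL_FUNC) &arpkin_initmod,    1},
    {"arpkin_derivs",     (DL_FUNC) &arpkin_derivs,     6},
    {"arpkin_gray_morph", (DL_FUNC) &arpkin_gray_morph, 6},
    {NULL, NULL, 0}
};

void R_init_arpkin(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
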