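/* Compiled right-hand side of the batch-segment mole balances for
 * deSolve.  The parameter vector packs, in order:
 *   [0] ns (species), [1] nr (reactions),
 *   [2 .. 2+nr)            forward rate constants k_j(T)
 *   [2+nr .. 2+2nr)        1/K_eq,j  (0 for irreversible steps)
 *   then column-major ns x nr blocks: nu, forward orders, reverse orders.
 */
#include <R.h>
#include <math.h>

#define MAXP 512
static double p[MAXP];

void azi_init(void (*odeparms)(int *, double *))
{
    int n = MAXP;
    odeparms(&n, p);
}

void azi_rhs(int *neq, double *t, double *y, double *ydot,
             double *yout, int *ip)
{
    const int ns = (int) p[0], nr = (int) p[1];
    const double *k = p + 2, *Kinv = p + 2 + nr;
    const double *nu = p + 2 + 2 * nr;
    const double *ord = nu + ns * nr;
    const double *rord = ord + ns * nr;
    double cc[64];

    for (int i = 0; i < ns; i++) {
        cc[i] = y[i] > 0 ? y[i] : 0;   /* clip only for rate evaluation */
        ydot[i] = 0;
    }
    for (int j = 0; j < nr; j++) {
        double fwd = k[j];
        for (int i = 0; i < ns; i++) {
            double o = ord[j * ns + i];
            if (o == 1.0)      fwd *= cc[i];
            else if (o == 2.0) fwd *= cc[i] * cc[i];
            else if (o != 0.0) fwd *= pow(cc[i], o);
        }
        double r = fwd;
        if (Kinv[j] > 0) {
            double rev = k[j] * Kinv[j];
            for (int i = 0; i < ns; i++) {
                double o = rord[j * ns + i];
                if (o == 1.0)      rev *= cc[i];
                else if (o == 2.0) rev *= cc[i] * cc[i];
                else if (o != 0.0) rev *= pow(cc[i], o);
            }
            r -= rev;
        }
        for (int i = 0; i < ns; i++)
            ydot[i] += nu[j * ns + i] * r;
    }
}
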