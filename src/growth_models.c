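/* Compiled right-hand sides for the two growth models, used through
 * deSolve's compiled-model interface (dllname = "cybgrowth").
 *
 * Parameter vectors are laid out by the R wrappers (see R/simulate.R),
 * zero-padded to the fixed lengths the init functions request:
 *   MMM:        n, beta[n], k[n], d            (padded to 2*MAXPOOL + 2)
 *   cybernetic: n, vmax[n], ks[n], ve[n], ke[n], alpha, beta, d, mode
 *                                              (padded to 4*MAXPOOL + 5)
 * where n <= MAXPOOL is the number of substrate pools and mode is 0 (standard
 * enzyme dilution, -(sum v_j r_j) * E_i) or 1 (as-printed, -(sum v_j r_j) * P).
 * The payload is packed at the front of the padded vector, so the fixed-offset
 * reads below use n-dependent offsets into the packed region.
 *
 * Substrate and enzyme levels are clamped at zero before evaluating rates so
 * that small negative excursions of the integrator cannot generate spurious
 * fluxes; the post-hoc clipping policy lives on the R side.
 */
#include <R.h>

#define MAXPOOL 16

static double mmm_p[2 * MAXPOOL + 2];
static double cyb_p[4 * MAXPOOL + 5];

void cybgrowth_mmm_init(void (*odeparms)(int *, double *))
{
    int n = 2 * MAXPOOL + 2;
    for (int i = 0; i < n; i++) mmm_p[i] = 0.0;
    /* R side always sends exactly 2n+2 values; request the max and let
       odeparms copy what is there */
    n = 2 * MAXPOOL + 2;
    odeparms(&n, mmm_p);
}

void cybgrowth_mmm_derivs(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    int n = (int) mmm_p[0];
    double P = y[0];
    double growth = 0.0;
    for (int i = 0; i < n; i++) {
        double S = y[1 + i] > 0.0 ? y[1 + i] : 0.0;
        double beta = mmm_p[1 + i];
        double k = mmm_p[1 + n + i];
        double rate = beta * S * S / (k + S) * P;
        ydot[1 + i] = -rate;
        growth += rate;
    }
    ydot[0] = growth - mmm_p[1 + 2 * n] * P;
}

void cybgrowth_cyb_init(void (*odeparms)(int *, double *))
{
    int n = 4 * MAXPOOL + 5;
    for (int i = 0; i < n; i++) cyb_p[i] = 0.0;
    odeparms(&n, cyb_p);
}

void cybgrowth_cyb_derivs(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    int n = (int) cyb_p[0];
    const double *vmax = cyb_p + 1;
    const double *ks = cyb_p + 1 + n;
    const double *ve = cyb_p + 1 + 2 * n;
    const double *ke = cyb_p + 1 + 3 * n;
    double alpha = cyb_p[1 + 4 * n];
    double beta = cyb_p[2 + 4 * n];
    double d = cyb_p[3 + 4 * n];
    int as_printed = (int) cyb_p[4 + 4 * n];

    double P = y[0];
    double r[MAXPOOL], re[MAXPOOL];
    double rsum = 0.0, rmax = 0.0;
    for (int i = 0; i < n; i++) {
        double S = y[1 + i] > 0.0 ? y[1 + i] : 0.0;
        double E = y[1 + n + i] > 0.0 ? y[1 + n + i] : 0.0;
        r[i] = vmax[i] * E * S / (ks[i] + S);
        re[i] = ve[i] * S / (ke[i] + S);
        rsum += r[i];
        if (r[i] > rmax) rmax = r[i];
    }
    double growth = 0.0;
    for (int i = 0; i < n; i++) {
        double v = rmax > 0.0 ? r[i] / rmax : 0.0;
        growth += v * r[i];
        ydot[1 + i] = -r[i] * v * P;
    }
    ydot[0] = growth * P - d * P;
    for (int i = 0; i < n; i++) {
        double E = y[1 + n + i] > 0.0 ? y[1 + n + i] : 0.0;
        double u = rsum > 0.0 ? r[i] / rsum : 0.0;
        double dilution = as_printed ? growth * P : growth * E;
        ydot[1 + n + i] = u * re[i] - dilution - alpha * E + beta;
    }
}
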