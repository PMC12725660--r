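/* Four-state glucose regulation model with a transient glucose store.
 *
 * States:  y[0] = G   blood glucose (mg/dL)
 *          y[1] = I   blood insulin (ng/mL)
 *          y[2] = stG transient glucose store (mg/dL-equivalent)
 *          y[3] = AG  cumulative glucose uptake (mg/dL-equivalent)
 *
 * Parameters (in order): k1..k8, f (exogenous infusion, mg/dL/min).
 * The infusion is piecewise-constant; the R layer re-initialises the
 * solver at every rate switch so f is constant within one solver call.
 *
 * Fluxes (reported through yout):
 *   flux1 = k1 / (1 + I + k8*G)   endogenous glucose production
 *   flux2 = k2 * G * I            insulin-dependent uptake
 *   flux3 = k3 * G                insulin secretion
 *   flux4 = k4 * I                insulin clearance
 *   flux5 = k5 * G * (k7 - stG)   insulin-independent uptake into stG
 *   flux6 = k6 * stG * I          insulin-dependent consumption of stG
 */

#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[9];

void stg_init(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void stg_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double k1 = parms[0], k2 = parms[1], k3 = parms[2], k4 = parms[3];
    double k5 = parms[4], k6 = parms[5], k7 = parms[6], k8 = parms[7];
    double f  = parms[8];
    double G = y[0], I = y[1], stG = y[2];

    double flux1 = k1 / (1.0 + I + k8 * G);
    double flux2 = k2 * G * I;
    double flux3 = k3 * G;
    double flux4 = k4 * I;
    double flux5 = k5 * G * (k7 - stG);
    double flux6 = k6 * stG * I;

    ydot[0] = flux1 - flux2 - flux5 + f;
    ydot[1] = flux3 - flux4;
    ydot[2] = flux5 - flux6;
    ydot[3] = flux2 - flux1 + flux5;

    if (ip[0] >= 7) {
        yout[0] = flux1;
        yout[1] = flux2;
        yout[2] = flux3;
        yout[3] = flux4;
        yout[4] = flux5;
        yout[5] = flux6;
        yout[6] = f;
    }
}

/* Variant taking the infusion from a forcing function (piecewise-constant
 * dose replay in the estimation objective: one solver call instead of one
 * per interval). */
static double forc[1];

void stg_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void stg_derivs_forc(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    parms[8] = forc[0];
    stg_derivs(neq, t, y, ydot, yout, ip);
}

/* Analytic Jacobian (full), speeds up lsoda's stiff phases. */
void stg_jac(int *neq, double *t, double *y, int *ml, int *mu,
             double *pd, int *nrowpd, double *yout, int *ip)
{
    double k1 = parms[0], k2 = parms[1], k3 = parms[2], k4 = parms[3];
    double k5 = parms[4], k6 = parms[5], k7 = parms[6], k8 = parms[7];
    double G = y[0], I = y[1], stG = y[2];
    int nr = *nrowpd;

    double den  = 1.0 + I + k8 * G;
    double d1dG = -k1 * k8 / (den * den);
    double d1dI = -k1 / (den * den);

    /* column-major: pd[i + j*nr] = d(ydot_i)/d(y_j) */
    pd[0 + 0 * nr] = d1dG - k2 * I - k5 * (k7 - stG);
    pd[1 + 0 * nr] = k3;
    pd[2 + 0 * nr] = k5 * (k7 - stG);
    pd[3 + 0 * nr] = -d1dG + k2 * I + k5 * (k7 - stG);

    pd[0 + 1 * nr] = d1dI - k2 * G;
    pd[1 + 1 * nr] = -k4;
    pd[2 + 1 * nr] = -k6 * stG;
    pd[3 + 1 * nr] = -d1dI + k2 * G;

    pd[0 + 2 * nr] = k5 * G;
    pd[1 + 2 * nr] = 0.0;
    pd[2 + 2 * nr] = -k5 * G - k6 * I;
    pd[3 + 2 * nr] = k5 * G;

    pd[0 + 3 * nr] = 0.0;
    pd[1 + 3 * nr] = 0.0;
    pd[2 + 3 * nr] = 0.0;
    pd[3 + 3 * nr] = 0.0;
}
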