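/* Compiled right-hand side of the ocular TMDD disease model, for use with
 * deSolve (dllname = "ocutmdd"). Parameter layout must match rhs_parms() on
 * the R side; state layout: y[0..4] free drug (venous, ICB plasma, ICB
 * interstitial, AH, vitreous), y[5..8] free TNF-alpha, y[9..12] complex
 * (same four compartments). Amounts pmol, volumes L, time h.
 */
#include <R.h>
#include <math.h>

#define NPAR 30
static double p[NPAR];

void ocutmdd_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static double cfrac(double tnf, double cx)
{
    double tot = tnf + cx;
    double f;
    if (tot <= 0.0) return 0.0;
    f = cx / tot;
    if (f < 0.0) f = 0.0;
    if (f > 1.0) f = 1.0;
    return f;
}

void ocutmdd_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double V[5], C[5];
    double Q_AH, Q_AV, Q_VA, f_sch, sigma;
    double kon = p[19], koff = p[20], kdegc = p[21], kdeg = p[22];
    double sf = p[23], base = p[25], release = p[26];
    int k;

    for (k = 0; k < 5; k++) {
        V[k] = p[k];
        C[k] = y[k] / V[k];
    }

    if (p[24] > 0.5) { /* disease active: recovery driven by local complex fraction */
        double f_ah  = cfrac(y[8], y[12]); /* AH */
        double f_ici = cfrac(y[7], y[11]); /* ICB interstitial */
        double f_icp = cfrac(y[6], y[10]); /* ICB plasma */
        Q_AH  = p[6]  + (p[5]  - p[6])  * f_ah;
        f_sch = p[12] + (p[11] - p[12]) * f_ah;
        Q_AV  = p[8]  + (p[7]  - p[8])  * f_ici;
        Q_VA  = p[10] + (p[9]  - p[10]) * f_ici;
        sigma = p[14] + (p[13] - p[14]) * f_icp;
    } else {
        Q_AH = p[5]; f_sch = p[11]; Q_AV = p[7]; Q_VA = p[9]; sigma = p[13];
    }

    if (p[27] > -1e29 && *t >= p[27]) { /* post-injection IOP transient */
        double m = 1.0 + p[28] * exp(-(*t - p[27]) / p[29]);
        Q_VA *= m;
        Q_AH *= m;
    }

    /* free drug transport */
    ydot[0] = p[15] * (C[1] - C[0]) + f_sch * Q_AH * C[3] +
              p[17] * C[2] - p[18] * C[0];
    ydot[1] = p[15] * (C[0] - C[1]) - Q_AH * (1.0 - sigma) * C[1] +
              p[16] * (C[2] - C[1]);
    ydot[2] = p[16] * (C[1] - C[2]) + (1.0 - f_sch) * Q_AH * C[3] -
              p[17] * C[2];
    ydot[3] = Q_AH * (1.0 - sigma) * C[1] + Q_VA * C[4] -
              (Q_AV + Q_AH) * C[3];
    ydot[4] = release + Q_AV * C[3] - Q_VA * C[4];

    /* turnover + full TMDD in the four TNF-bearing compartments */
    for (k = 0; k < 4; k++) {
        double bind = kon * y[5 + k] * C[k];
        double diss = koff * y[9 + k];
        ydot[k]     += -bind + diss;
        ydot[5 + k]  = sf * kdeg * base * V[k] - kdeg * y[5 + k] - bind + diss;
        ydot[9 + k]  = bind - diss - kdegc * y[9 + k];
    }
}
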