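/* ODE right-hand side for the coupled hematopoiesis / Ara-C / blast / G-CSF
 * model, in the deSolve compiled-model convention.
 *
 * State layout (n_tr transit compartments, n_tr passed as a parameter):
 *   y[0]              x_prol   proliferating progenitors (10^9 cells/L-eq)
 *   y[1 .. n_tr]      x_tr_i   transit compartments
 *   y[n_tr+1]         x_wbc    circulating WBC (10^9 cells/L)
 *   y[n_tr+2]         a_ara    Ara-C amount, central compartment (mg)
 *   y[n_tr+3]         g_depot  subcutaneous G-CSF depot (ug)
 *   y[n_tr+4]         g_circ   circulating G-CSF above baseline (x baseline)
 *   y[n_tr+5]         l_prol   proliferating leukemic blasts (10^9 cells)
 *   y[n_tr+6]         l_mat    post-mitotic leukemic blasts (10^9 cells)
 *
 * The Ara-C infusion rate (mg/day) is piecewise constant and is passed as a
 * parameter; the R driver integrates piecewise between dosing breakpoints.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 21

static double parms[N_PARMS];

#define p_ntr      parms[0]   /* number of transit compartments            */
#define p_B        parms[1]   /* WBC baseline (10^9/L)                     */
#define p_gamma    parms[2]   /* feedback exponent                         */
#define p_ktr      parms[3]   /* transit rate (1/day)                      */
#define p_slope    parms[4]   /* Ara-C effect slope (per mg/L)             */
#define p_pl       parms[5]   /* blast proliferation rate (1/day)          */
#define p_al       parms[6]   /* blast self-renewal fraction               */
#define p_dl       parms[7]   /* mature blast death rate (1/day)           */
#define p_ks       parms[8]   /* blast feedback coefficient (L/10^9 cells) */
#define p_ecap     parms[9]   /* cap on the Ara-C effect                   */
#define p_ke_ara   parms[10]  /* Ara-C elimination rate (1/day)            */
#define p_v_ara    parms[11]  /* Ara-C central volume (L)                  */
#define p_ka_g     parms[12]  /* G-CSF sc absorption rate (1/day)          */
#define p_ke_g     parms[13]  /* G-CSF linear elimination rate (1/day)     */
#define p_kw_g     parms[14]  /* G-CSF WBC-mediated clearance (1/day per 10^9/L) */
#define p_gscale   parms[15]  /* depot-to-effect scaling (ug)              */
#define p_beta1    parms[16]  /* G-CSF exponent on proliferation           */
#define p_beta2    parms[17]  /* G-CSF exponent on transit/release         */
#define p_lfw      parms[18]  /* blast weight in the shared feedback       */
#define p_lsens    parms[19]  /* blast Ara-C sensitivity relative to slope */
#define p_ara_rate parms[20]  /* current infusion rate (mg/day)            */

void cytotwin_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void cytotwin_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const int ntr = (int) (p_ntr + 0.5);
    const int iw = ntr + 1, ia = ntr + 2, id = ntr + 3, ig = ntr + 4,
              il = ntr + 5, im = ntr + 6;
    int j;

    /* guarded states: the solver may probe tiny negatives */
    double xw = y[iw] > 1e-8 ? y[iw] : 1e-8;
    double g  = y[ig] > 0.0  ? y[ig] : 0.0;

    double conc = (y[ia] > 0.0 ? y[ia] : 0.0) / p_v_ara;
    double E = p_slope * conc;
    if (E > p_ecap) E = p_ecap;

    double gf1 = pow(1.0 + g, p_beta1);
    double gf2 = pow(1.0 + g, p_beta2);
    double fb  = pow(p_B / xw, p_gamma);

    /* healthy lineage: proliferation with feedback, G-CSF boost, drug
     * inhibition; transit chain and release G-CSF boosted; first-order
     * removal of circulating cells at the baseline transit rate */
    ydot[0] = p_ktr * y[0] * (fb * gf1 * (1.0 - E) - gf2);
    for (j = 1; j <= ntr; j++)
        ydot[j] = p_ktr * gf2 * (y[j - 1] - y[j]);
    ydot[iw] = p_ktr * gf2 * y[ntr] - p_ktr * y[iw];

    /* Ara-C one-compartment PK with constant-rate infusion input */
    ydot[ia] = p_ara_rate - p_ke_ara * y[ia];

    /* G-CSF: sc depot, effect compartment with WBC-mediated clearance */
    ydot[id] = -p_ka_g * y[id];
    ydot[ig] = p_ka_g * y[id] / p_gscale - (p_ke_g + p_kw_g * xw) * y[ig];

    /* leukemic blasts: self-renewing proliferative pool + post-mitotic
     * pool, shared cytokine feedback s, drug kill on divisions */
    double lp = y[il] > 0.0 ? y[il] : 0.0;
    double lm = y[im] > 0.0 ? y[im] : 0.0;
    double s = 1.0 / (1.0 + p_ks * (xw + p_lfw * (lp + lm)));
    double El = p_lsens * p_slope * conc;      /* reduced blast sensitivity */
    if (El > p_ecap) El = p_ecap;
    ydot[il] = p_pl * y[il] * (2.0 * p_al * s * (1.0 - El) - 1.0);
    ydot[im] = 2.0 * p_pl * lp * (1.0 - p_al * s) * (1.0 - El) - p_dl * y[im];
}
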