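/* Compiled right-hand side of the whole-body DAP/D3G disposition model.
 * Mirrors the symbolic definition in R/ode.R (.ode_equations); the two are
 * held in lockstep by an equivalence test. State and parameter order must
 * match .state_names and ode_parameter_vector().
 */
#include <R.h>

#define NPARMS 31
static double parms[NPARMS];

#define Vgu          parms[0]
#define Vki          parms[1]
#define Vli          parms[2]
#define Vlu          parms[3]
#define Vbl          parms[4]
#define Vre          parms[5]
#define Qgu          parms[6]
#define Qki          parms[7]
#define Qh           parms[8]
#define Qha          parms[9]
#define Qlu          parms[10]
#define PSre         parms[11]
#define Kp_DAP       parms[12]
#define Kp_re_DAP    parms[13]
#define Kp_D3G       parms[14]
#define ka           parms[15]
#define f_absorption parms[16]
#define f_renal      parms[17]
#define f_cirrhosis  parms[18]
#define Km           parms[19]
#define Vmax_li      parms[20]
#define f_ki_Vmax    parms[21]
#define k_DAPEX_ki   parms[22]
#define k_D3GEX_ki   parms[23]
#define k_feces      parms[24]
#define GFR_ref      parms[25]
#define FPG          parms[26]
#define RTG0         parms[27]
#define Imax         parms[28]
#define IC50         parms[29]
#define MW_DAP       parms[30]

void dapasim_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* state indices (amounts in umol); urinary glucose excretion is a pure
 * readout of the plasma profile and is accumulated outside the solver */
enum { DAP_lumen, DAP_feces_transit, DAP_feces, DAP_gu, DAP_li, DAP_ki,
       DAP_lu, DAP_re, DAP_bl, DAP_urine, D3G_bl, D3G_ki, D3G_urine };

void dapasim_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double C_bl = y[DAP_bl] / Vbl;
    double C_gu = y[DAP_gu] / Vgu;
    double C_li = y[DAP_li] / Vli;
    double C_ki = y[DAP_ki] / Vki;
    double C_lu = y[DAP_lu] / Vlu;
    double C_re = y[DAP_re] / Vre;
    double C3_bl = y[D3G_bl] / Vbl;
    double C3_ki = y[D3G_ki] / Vki;

    double abs_flux = ka * f_absorption * y[DAP_lumen];
    double portal_in = Qha * C_bl + Qgu * C_gu / Kp_DAP + abs_flux;
    double v_met_li = (1 - f_cirrhosis) * Vmax_li * Vli * C_li / (Km + C_li);
    double v_met_ki = Vmax_li * f_ki_Vmax * Vki * C_ki / (Km + C_ki);
    double v_ex_dap = k_DAPEX_ki * f_renal * y[DAP_ki];
    double v_ex_d3g = k_D3GEX_ki * f_renal * y[D3G_ki];

    ydot[DAP_lumen] = -abs_flux;
    ydot[DAP_feces_transit] = -k_feces * y[DAP_feces_transit];
    ydot[DAP_feces] = k_feces * y[DAP_feces_transit];
    ydot[DAP_gu] = Qgu * (C_bl - C_gu / Kp_DAP);
    ydot[DAP_li] = (1 - f_cirrhosis) * portal_in
        - (1 - f_cirrhosis) * Qh * C_li / Kp_DAP - v_met_li;
    ydot[DAP_ki] = Qki * (C_bl - C_ki / Kp_DAP) - v_met_ki - v_ex_dap;
    ydot[DAP_lu] = Qlu * (C_bl - C_lu / Kp_DAP);
    ydot[DAP_re] = PSre * (C_bl - C_re / Kp_re_DAP);
    ydot[DAP_bl] = f_cirrhosis * portal_in
        + (1 - f_cirrhosis) * Qh * C_li / Kp_DAP
        + Qki * C_ki / Kp_DAP + Qlu * C_lu / Kp_DAP
        + PSre * C_re / Kp_re_DAP
        - (Qha + Qgu + Qki + Qlu) * C_bl - PSre * C_bl;
    ydot[DAP_urine] = v_ex_dap;
    ydot[D3G_bl] = v_met_li + Qki * (C3_ki / Kp_D3G - C3_bl);
    ydot[D3G_ki] = Qki * (C3_bl - C3_ki / Kp_D3G) + v_met_ki - v_ex_d3g;
    ydot[D3G_urine] = v_ex_d3g;
}
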