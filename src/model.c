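/* Compiled right-hand side of the GnRH-ERK model, in the deSolve
 * compiled-model convention (initializer + derivative function looked up by
 * name). Must stay in exact agreement with gnrh_rhs() in R/model.R; the
 * test suite checks this.
 *
 * Parameter vector layout: the 37 kinetic parameters in the order of
 * .param_names (R/parameters.R), then the segment-constant GnRH input,
 * the MEK-inhibition flag and the nuclear-feedback flag.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 40

static double parms[N_PARMS];

#define P_R0          parms[0]
#define P_k1          parms[1]
#define P_k_minus1    parms[2]
#define P_k2          parms[3]
#define P_k_minus2    parms[4]
#define P_k3          parms[5]
#define P_k_minus3    parms[6]
#define P_GQ_tot      parms[7]
#define P_k_exp_act   parms[8]
#define P_k_exp       parms[9]
#define P_k_imp_act   parms[10]
#define P_k_imp       parms[11]
#define P_k_mek       parms[12]
#define P_K_MM_MEK    parms[13]
#define P_k_MEK_basal parms[14]
#define P_ERK_tot     parms[15]
#define P_MEK_tot     parms[16]
#define P_kcat_1      parms[17]
#define P_kcat_2      parms[18]
#define P_kcat_3      parms[19]
#define P_kcat_4      parms[20]
#define P_kcat_5      parms[21]
#define P_km_1        parms[22]
#define P_km_2        parms[23]
#define P_km_3        parms[24]
#define P_km_4        parms[25]
#define P_km_5        parms[26]
#define P_kd_ppEn     parms[27]
#define P_MKP_n       parms[28]
#define P_MKP_c       parms[29]
#define P_C_cn        parms[30]
#define P_d_TF1       parms[31]
#define P_k_TF1       parms[32]
#define P_K_MM_TF1    parms[33]
#define P_d_TF1DT     parms[34]
#define P_k_TF1DT     parms[35]
#define P_K_MM_TF1DT  parms[36]
#define P_GNRH        parms[37]
#define P_MEK_INH     parms[38]
#define P_FB_NUCLEAR  parms[39]

void gnrh_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void gnrh_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double HR = y[0], GQ = y[1], E = y[2];
    double E_c = y[3], pE_c = y[4], ppE_c = y[5];
    double E_n = y[6], ppE_n = y[7], TF1 = y[8], TF1DT = y[9];

    /* algebraic MEK activation (quasi-steady state in E) */
    double denom = P_k_MEK_basal + P_k_mek * (P_K_MM_MEK + E);
    double ppMEK = denom > 0.0
        ? P_MEK_tot * (P_k_MEK_basal + P_k_mek * E) / denom
        : 0.0;

    /* distributive dual (de)phosphorylation fluxes */
    double v1 = P_kcat_1 * ppMEK * E_c /
        (P_km_1 * (1.0 + pE_c / P_km_2) + E_c);
    double v2 = P_kcat_2 * ppMEK * pE_c /
        (P_km_2 * (1.0 + E_c / P_km_1) + pE_c);
    double v3 = P_kcat_3 * P_MKP_c * ppE_c /
        (P_km_3 * (1.0 + pE_c / P_km_4 + E_c / P_km_5) + ppE_c);
    double v4 = P_kcat_4 * P_MKP_c * pE_c /
        (P_km_4 * (1.0 + ppE_c / P_km_3 + E_c / P_km_5) + pE_c);
    double v5 = P_kcat_5 * P_MKP_n * ppE_n / (P_kd_ppEn + ppE_n);

    if (P_MEK_INH > 0.5) {
        v1 = 0.0;
        v2 = 0.0;
    }

    double fb = (P_FB_NUCLEAR > 0.5) ? ppE_n : ppE_c;

    ydot[0] = P_k1 * P_GNRH * (P_R0 - HR) - P_k_minus1 * HR;
    ydot[1] = -P_k2 * HR * GQ + P_k_minus2 * (P_GQ_tot - GQ);
    ydot[2] = P_k2 * HR * GQ - P_k_minus3 * E - P_k3 * fb * E;
    ydot[3] = -v1 + v4 - P_k_imp * E_c + P_k_exp / P_C_cn * E_n;
    ydot[4] = v1 - v2 + v3 - v4;
    ydot[5] = v2 - v3 - P_k_imp_act * ppE_c + P_k_exp_act / P_C_cn * ppE_n;
    ydot[6] = P_C_cn * P_k_imp * E_c - P_k_exp * E_n + v5;
    ydot[7] = P_C_cn * P_k_imp_act * ppE_c - P_k_exp_act * ppE_n - v5;
    ydot[8] = P_k_TF1 * ppE_n / (P_K_MM_TF1 + ppE_n) - P_d_TF1 * TF1;
    ydot[9] = P_k_TF1DT * TF1 / (P_K_MM_TF1DT + TF1) - P_d_TF1DT * TF1DT;
}

void R_init_gnrhpulse(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    /* gnrh_init / gnrh_derivs are resolved by name through deSolve */
    R_useDynamicSymbols(dll, TRUE);
}
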