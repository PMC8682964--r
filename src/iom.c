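/* Compiled right-hand side of the Integrated Oscillator Model.
 *
 * Mirrors the reference implementation in R/rhs.R (iom_rhs_r); the two are
 * asserted equal in the test suite.  Parameters arrive in the fixed order
 * defined by .param_order in R/parameters.R, with two runtime controls
 * (clamp_cac, clamp_level) appended.
 */
#include <R.h>
#include <math.h>

#define NPAR 74
static double parms[NPAR];

/* indices must match .param_order in R/parameters.R */
#define P_cm       parms[0]
#define P_gca      parms[1]
#define P_vca      parms[2]
#define P_vm       parms[3]
#define P_sm       parms[4]
#define P_gk       parms[5]
#define P_vk       parms[6]
#define P_vn       parms[7]
#define P_sn       parms[8]
#define P_taun     parms[9]
#define P_gkca     parms[10]
#define P_kkca     parms[11]
#define P_qkca     parms[12]
#define P_gkatp    parms[13]
#define P_ktt      parms[14]
#define P_ktd      parms[15]
#define P_kdd      parms[16]
#define P_fca      parms[17]
#define P_alpha    parms[18]
#define P_kpmca    parms[19]
#define P_kserca   parms[20]
#define P_pleak    parms[21]
#define P_sigmaer  parms[22]
#define P_fer      parms[23]
#define P_deltam   parms[24]
#define P_glucose  parms[25]
#define P_vgk      parms[26]
#define P_kgk      parms[27]
#define P_ngk      parms[28]
#define P_kappa    parms[29]
#define P_vpfk     parms[30]
#define P_k1       parms[31]
#define P_k2       parms[32]
#define P_k3       parms[33]
#define P_k4       parms[34]
#define P_f13      parms[35]
#define P_f23      parms[36]
#define P_f41      parms[37]
#define P_f42      parms[38]
#define P_f43      parms[39]
#define P_lampfk   parms[40]
#define P_kgpdh    parms[41]
#define P_vpdh     parms[42]
#define P_knadhpdh parms[43]
#define P_nadtot   parms[44]
#define P_vo       parms[45]
#define P_ko       parms[46]
#define P_psio     parms[47]
#define P_so       parms[48]
#define P_kres     parms[49]
#define P_vf1f0    parms[50]
#define P_kf1f0    parms[51]
#define P_psif     parms[52]
#define P_sf       parms[53]
#define P_vant     parms[54]
#define P_kant     parms[55]
#define P_kantc    parms[56]
#define P_fant     parms[57]
#define P_p17      parms[58]
#define P_p18      parms[59]
#define P_p21      parms[60]
#define P_p22      parms[61]
#define P_p23      parms[62]
#define P_p24      parms[63]
#define P_fm       parms[64]
#define P_cmito    parms[65]
#define P_gamma    parms[66]
#define P_actot    parms[67]
#define P_amtot    parms[68]
#define P_khyd     parms[69]
#define P_khydca   parms[70]
#define P_deltamv  parms[71]
#define P_clamp    parms[72]
#define P_clamplev parms[73]

void iom_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

static double pfk_rate(double f6p, double fbp, double atp, double amp)
{
    double wa = amp * amp / P_k1;
    double wf = fbp * fbp / P_k2;
    double ws = f6p * f6p / P_k3;
    double wt = atp * atp / P_k4;
    double bottom = 0.0, top = 0.0, wact = 0.0;
    int i, j, k, l;
    for (i = 0; i <= 1; i++)
        for (j = 0; j <= 1; j++)
            for (k = 0; k <= 1; k++)
                for (l = 0; l <= 1; l++) {
                    double w = 1.0;
                    if (i) w *= wa;
                    if (j) w *= wf;
                    if (k) w *= ws;
                    if (l) w *= wt;
                    if (i && k) w /= P_f13;
                    if (j && k) w /= P_f23;
                    if (i && l) w /= P_f41;
                    if (j && l) w /= P_f42;
                    if (k && l) w /= P_f43;
                    bottom += w;
                    if (k) {
                        top += w;
                        if (i && j && !l) wact = w;
                    }
                }
    return P_vpfk * (wact + P_lampfk * (top - wact)) / bottom;
}

void iom_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double v = y[0], n = y[1], cac = y[2], caer = y[3], cam = y[4];
    double f6p = y[5], fbp = y[6], nadhm = y[7], adpm = y[8];
    double psim = y[9], adpc = y[10];

    if (P_clamp != 0.0) cac = P_clamplev;

    double atpc = P_actot - adpc;
    double amp  = adpc * adpc / atpc;

    /* K(ATP) gating */
    double mgadp = 0.165 * adpc, adp3 = 0.135 * adpc, atp4 = 0.05 * atpc;
    double md = mgadp / P_kdd;
    double oinf = (0.08 + 0.89 * md * md + 0.16 * md) /
        ((1.0 + md) * (1.0 + md) *
         (1.0 + atp4 / P_ktt + adp3 / P_ktd));

    /* membrane currents */
    double minf = 1.0 / (1.0 + exp((P_vm - v) / P_sm));
    double ninf = 1.0 / (1.0 + exp((P_vn - v) / P_sn));
    double caq = pow(cac, P_qkca);
    double ica = P_gca * minf * (v - P_vca);
    double ik = P_gk * n * (v - P_vk);
    double ikca = P_gkca * caq / (pow(P_kkca, P_qkca) + caq) * (v - P_vk);
    double ikatp = P_gkatp * oinf * (v - P_vk);

    /* glycolysis */
    double gh = pow(P_glucose, P_ngk);
    double jgk = P_vgk * gh / (pow(P_kgk, P_ngk) + gh);
    double jpfk = pfk_rate(f6p, fbp, atpc, amp);
    double jgpdh = cam * cam / (P_kgpdh + cam * cam) * fbp;

    /* mitochondria */
    double nadm = P_nadtot - nadhm;
    double atpm = P_amtot - adpm;
    double jpdh = P_vpdh / (P_knadhpdh + nadhm / nadm) * jgpdh;
    double jo = P_vo * nadhm / (P_ko + nadhm) /
        (1.0 + exp((psim - P_psio) / P_so));
    double jhres = P_kres * jo;
    double jf1f0 = P_vf1f0 * adpm / (P_kf1f0 + adpm) /
        (1.0 + exp((P_psif - psim) / P_sf));
    double jhatp = 3.0 * jf1f0;
    double rat = atpm / adpm;
    double jant = P_vant * rat / (rat + P_kant) *
        (adpc / (adpc + P_kantc)) * exp(P_fant * psim);
    double jhleak = P_p17 * exp(P_p18 * psim);
    double juni = (P_p21 * psim - P_p22) * cac;
    double jnaca = P_p23 * (cam / cac) * exp(P_p24 * psim);

    /* cytosolic nucleotides */
    double jhyd = (P_khyd + P_khydca * cac) * atpc;

    /* Ca2+ compartments */
    double jmem = -(P_alpha * ica + P_kpmca * cac);
    double jer = P_pleak * (caer - cac) - P_kserca * cac;

    ydot[0] = -(ica + ik + ikca + ikatp) / P_cm;
    ydot[1] = (ninf - n) / P_taun;
    ydot[2] = (P_clamp != 0.0) ? 0.0 :
        P_fca * (jmem + jer + P_deltam * (jnaca - juni));
    ydot[3] = -P_fer * P_sigmaer * jer;
    ydot[4] = P_fm * (juni - jnaca);
    ydot[5] = P_kappa * (jgk - jpfk);
    ydot[6] = jpfk - 0.5 * jgpdh;
    ydot[7] = P_gamma * (jpdh - jo);
    ydot[8] = P_gamma * (jant - jf1f0);
    ydot[9] = (jhres - jhatp - jant - jhleak - jnaca - 2.0 * juni) / P_cmito;
    ydot[10] = jhyd - P_deltamv * jant;
}
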