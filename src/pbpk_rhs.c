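/* Compiled right-hand side of the coupled parent + metabolite whole-body
 * PBPK system.  The layout of the parameter vector and of the state
 * vector mirrors R/engine_parms.R (0-based here); the pure-R reference
 * implementation lives in R/engine_rhs.R and the two are cross-checked
 * in the test suite. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 301

/* scalar parameter slots (R index - 1) */
#define MW_P      p[0]
#define MW_M      p[1]
#define FU_P      p[2]
#define FU_M      p[3]
#define CL_REN    p[4]
#define CL_M1HEP  p[5]
#define K3A4_M1   p[6]
#define K3A4_OTH  p[7]
#define K2C19_M1  p[8]
#define K2C19_OTH p[9]
#define EREF_L3A4  p[10]
#define EREF_L2C19 p[11]
#define EREF_G3A4  p[12]
#define KDEG_L3A4  p[13]
#define KDEG_L2C19 p[14]
#define KDEG_G3A4  p[15]
#define T50_FAST  p[16]
#define B_FAST    p[17]
#define T50_FED   p[18]
#define B_FED     p[19]
#define HAZ_CAP   p[20]
#define EMPTY_MULT  p[21]
#define EMPTY_DECAY p[22]
#define PERP_MODE p[23]
#define PERP_KA   p[24]
#define PERP_V    p[25]
#define PERP_CL   p[26]
#define PERP_FU   p[27]
#define PERP_MECH p[28]
#define PERP_KI     p[29]
#define PERP_KINACT p[30]
#define PERP_EMAX   p[31]
#define PERP_EC50   p[32]
#define N_DOSE    p[33]
#define N_MEAL    p[34]
/* array slots */
#define PV(i)    p[35 + (i)]
#define PQ(i)    p[49 + (i)]
#define KPP(i)   p[63 + (i)]
#define KPM(i)   p[77 + (i)]
#define VLUM(i)  p[91 + (i)]
#define KTRANS(i) p[97 + (i)]
#define KABS(i)  p[103 + (i)]
#define DOSE_T(i)   p[109 + (i)]
#define DOSE_FED(i) p[173 + (i)]
#define MEAL_T(i)   p[237 + (i)]

/* organ positions */
#define O_ADIPOSE 0
#define O_BONE    1
#define O_BRAIN   2
#define O_HEART   3
#define O_KIDNEY  4
#define O_MUSCLE  5
#define O_SKIN    6
#define O_REST    7
#define O_GUT     8
#define O_SPLEEN  9
#define O_LIVER   10
#define O_LUNG    11
#define O_ART     12
#define O_VEN     13

/* state positions */
#define S_UND   0
#define S_DIS   6
#define S_FECAL 12
#define S_P     13
#define S_M     27
#define S_EL3A4  41
#define S_EL2C19 42
#define S_EG3A4  43
#define S_CREN   44
#define S_CM1HEP 45
#define S_CL3A4M1  46
#define S_CL3A4OTH 47
#define S_CL2C19M1  48
#define S_CL2C19OTH 49
#define S_CG3A4M1  50
#define S_CG3A4OTH 51
#define S_PDEPOT 52
#define S_PCENT  53

static double p[N_PARMS];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int i, s;
    double tt = *t;

    /* dissolution hazard from the most recent oral dose */
    double haz = 0.0;
    int nd = (int) (N_DOSE + 0.5);
    if (nd > 0) {
        int last = -1;
        double tlast = -1e30;
        for (i = 0; i < nd; i++) {
            if (DOSE_T(i) <= tt + 1e-12 && DOSE_T(i) > tlast) {
                tlast = DOSE_T(i); last = i;
            }
        }
        if (last >= 0) {
            double age = tt - tlast;
            if (age < 1e-9) age = 1e-9;
            double t50 = (DOSE_FED(last) > 0.5) ? T50_FED : T50_FAST;
            double b   = (DOSE_FED(last) > 0.5) ? B_FED : B_FAST;
            haz = M_LN2 * b / t50 * pow(age / t50, b - 1.0);
            if (haz > HAZ_CAP) haz = HAZ_CAP;
        }
    }

    /* gastric emptying multiplier under meals */
    double empty_mult = 1.0;
    int nm = (int) (N_MEAL + 0.5);
    if (nm > 0) {
        double tmeal = -1e30;
        for (i = 0; i < nm; i++)
            if (MEAL_T(i) <= tt + 1e-12 && MEAL_T(i) > tmeal)
                tmeal = MEAL_T(i);
        if (tmeal > -1e29)
            empty_mult = 1.0 + (EMPTY_MULT - 1.0) *
                exp(-EMPTY_DECAY * (tt - tmeal));
    }

    double ktr[6], dund[6], ddis[6];
    for (s = 0; s < 6; s++) ktr[s] = KTRANS(s);
    ktr[0] *= empty_mult;

    double *und = y + S_UND, *dis = y + S_DIS;
    dund[0] = -haz * und[0] - ktr[0] * und[0];
    ddis[0] =  haz * und[0] - ktr[0] * dis[0];
    double absorbed = 0.0;
    for (s = 1; s < 6; s++) {
        dund[s] = ktr[s-1] * und[s-1] - haz * und[s] - ktr[s] * und[s];
        ddis[s] = ktr[s-1] * dis[s-1] + haz * und[s]
                  - (ktr[s] + KABS(s)) * dis[s];
        absorbed += KABS(s) * dis[s];
    }
    double dfecal = ktr[5] * (und[5] + dis[5]);

    /* tissue and venous-equilibrium (plasma) concentrations */
    double CPv[14], CMv[14];
    double *AP = y + S_P, *AM = y + S_M;
    for (i = 0; i < 14; i++) {
        CPv[i] = AP[i] / PV(i) / KPP(i);
        CMv[i] = AM[i] / PV(i) / KPM(i);
    }
    double CPart = AP[O_ART] / PV(O_ART);
    double CMart = AM[O_ART] / PV(O_ART);
    double CPven = AP[O_VEN] / PV(O_VEN);
    double CMven = AM[O_VEN] / PV(O_VEN);

    /* perpetrator and enzyme turnover */
    double Iu = 0.0, ddep = 0.0, dcen = 0.0;
    int pmode = (int) (PERP_MODE + 0.5);
    if (pmode == 1) {
        double dep = y[S_PDEPOT], cen = y[S_PCENT];
        ddep = -PERP_KA * dep;
        dcen = PERP_KA * dep - PERP_CL / PERP_V * cen;
        Iu = PERP_FU * cen / PERP_V;
    }
    /* pmode == 2 (forcing table) is served by the R right-hand side */

    int mech = (int) (PERP_MECH + 0.5);
    double inact = 0.0, indf = 1.0;
    if (pmode > 0 && mech == 1)
        inact = PERP_KINACT * Iu / (PERP_KI + Iu);
    if (pmode > 0 && mech == 2)
        indf = 1.0 + PERP_EMAX * Iu / (PERP_EC50 + Iu);

    double E_l3 = y[S_EL3A4], E_l2 = y[S_EL2C19], E_g3 = y[S_EG3A4];
    double dE_l3 = EREF_L3A4 * KDEG_L3A4 * indf - (KDEG_L3A4 + inact) * E_l3;
    double dE_g3 = EREF_G3A4 * KDEG_G3A4 * indf - (KDEG_G3A4 + inact) * E_g3;
    double dE_l2 = EREF_L2C19 * KDEG_L2C19 - KDEG_L2C19 * E_l2;

    /* metabolism: clint (uL/min/pmol) * E (umol/L) * V (L) * 60 -> L/h */
    double cu_liv = FU_P * CPv[O_LIVER];
    double cu_gut = FU_P * CPv[O_GUT];
    double scl_liv = 60.0 * PV(O_LIVER), scl_gut = 60.0 * PV(O_GUT);
    double v_l3_m1  = K3A4_M1   * E_l3 * scl_liv * cu_liv;
    double v_l3_oth = K3A4_OTH  * E_l3 * scl_liv * cu_liv;
    double v_l2_m1  = K2C19_M1  * E_l2 * scl_liv * cu_liv;
    double v_l2_oth = K2C19_OTH * E_l2 * scl_liv * cu_liv;
    double v_g3_m1  = K3A4_M1   * E_g3 * scl_gut * cu_gut;
    double v_g3_oth = K3A4_OTH  * E_g3 * scl_gut * cu_gut;
    double v_ren   = CL_REN   * CPart;
    double v_m1hep = CL_M1HEP * CMart;

    double dAP[14], dAM[14];
    static const int simple[8] = {O_ADIPOSE, O_BONE, O_BRAIN, O_HEART,
                                  O_KIDNEY, O_MUSCLE, O_SKIN, O_REST};
    double sumP = 0.0, sumM = 0.0;
    for (i = 0; i < 8; i++) {
        int o = simple[i];
        dAP[o] = PQ(o) * (CPart - CPv[o]);
        dAM[o] = PQ(o) * (CMart - CMv[o]);
        sumP += PQ(o) * CPv[o];
        sumM += PQ(o) * CMv[o];
    }
    dAP[O_GUT] = PQ(O_GUT) * (CPart - CPv[O_GUT]) + absorbed
                 - (v_g3_m1 + v_g3_oth);
    dAM[O_GUT] = PQ(O_GUT) * (CMart - CMv[O_GUT]) + v_g3_m1;
    dAP[O_SPLEEN] = PQ(O_SPLEEN) * (CPart - CPv[O_SPLEEN]);
    dAM[O_SPLEEN] = PQ(O_SPLEEN) * (CMart - CMv[O_SPLEEN]);
    double Qliv = PQ(O_LIVER) + PQ(O_GUT) + PQ(O_SPLEEN);
    dAP[O_LIVER] = PQ(O_LIVER) * CPart + PQ(O_GUT) * CPv[O_GUT]
                   + PQ(O_SPLEEN) * CPv[O_SPLEEN] - Qliv * CPv[O_LIVER]
                   - (v_l3_m1 + v_l3_oth + v_l2_m1 + v_l2_oth);
    dAM[O_LIVER] = PQ(O_LIVER) * CMart + PQ(O_GUT) * CMv[O_GUT]
                   + PQ(O_SPLEEN) * CMv[O_SPLEEN] - Qliv * CMv[O_LIVER]
                   + (v_l3_m1 + v_l2_m1);
    double CO = PQ(O_LUNG);
    dAP[O_LUNG] = CO * (CPven - CPv[O_LUNG]);
    dAM[O_LUNG] = CO * (CMven - CMv[O_LUNG]);
    dAP[O_ART] = CO * (CPv[O_LUNG] - CPart) - v_ren;
    dAM[O_ART] = CO * (CMv[O_LUNG] - CMart) - v_m1hep;
    dAP[O_VEN] = sumP + Qliv * CPv[O_LIVER] - CO * CPven;
    dAM[O_VEN] = sumM + Qliv * CMv[O_LIVER] - CO * CMven;

    for (s = 0; s < 6; s++) { ydot[S_UND + s] = dund[s]; ydot[S_DIS + s] = ddis[s]; }
    ydot[S_FECAL] = dfecal;
    for (i = 0; i < 14; i++) { ydot[S_P + i] = dAP[i]; ydot[S_M + i] = dAM[i]; }
    ydot[S_EL3A4] = dE_l3; ydot[S_EL2C19] = dE_l2; ydot[S_EG3A4] = dE_g3;
    ydot[S_CREN] = v_ren; ydot[S_CM1HEP] = v_m1hep;
    ydot[S_CL3A4M1] = v_l3_m1; ydot[S_CL3A4OTH] = v_l3_oth;
    ydot[S_CL2C19M1] = v_l2_m1; ydot[S_CL2C19OTH] = v_l2_oth;
    ydot[S_CG3A4M1] = v_g3_m1; ydot[S_CG3A4OTH] = v_g3_oth;
    ydot[S_PDEPOT] = ddep; ydot[S_PCENT] = dcen;
}

static const R_CMethodDef CEntries[] = {
    {"pbpk_init",   (DL_FUNC) &pbpk_init,   1},
    {"pbpk_derivs", (DL_FUNC) &pbpk_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_tegopbpk(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
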