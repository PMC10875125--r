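/* Compiled right-hand side of the Ca2+-mitochondria model for deSolve.
 *
 * The 17 rate laws and 18 rate equations mirror the reference R
 * implementation in R/fluxes.R (a unit test asserts agreement to 1e-12).
 * Parameters arrive as a packed numeric vector built by pack_params();
 * the index map below must stay in step with that function.
 *
 * The 17 fluxes are exposed as deSolve auxiliary outputs (nout = 17) so
 * trajectories carry them without recomputation.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define N_PAR 106
static double P[N_PAR];

/* geometry / physical constants */
#define ALPHA    P[0]
#define DELTA    P[1]
#define F_C      P[2]
#define F_ER     P[3]
#define F_M      P[4]
#define C_M      P[5]
#define GAMMA    P[6]
#define RT       P[7]
#define FCONST   P[8]
/* controlled species */
#define PI_C     P[9]
#define PI_M     P[10]
#define NA_C     P[11]
#define NA_M     P[12]
#define MG_M     P[13]
#define H_CY     P[14]
#define H_MI     P[15]
#define O2_M     P[16]
#define ACCOA    P[17]
#define COA      P[18]
#define CO2_M    P[19]
#define COQ      P[20]
#define COQH2    P[21]
#define IP3      P[22]
#define DPH      P[23]
/* leading constants */
#define VSERCA   P[24]
#define VUNI     P[25]
#define VNCX     P[26]
#define VIP3R    P[27]
#define VLEAK    P[28]
#define VANT     P[29]
#define VCS      P[30]
#define VIDH     P[31]
#define VKGDH    P[32]
#define VSDH     P[33]
#define VMDH     P[34]
#define RHORES   P[35]
#define RHOF1    P[36]
#define KFACO    P[37]
#define KFFH     P[38]
#define KFSL     P[39]
#define KHYD     P[40]
#define GH       P[41]
/* saturation constants */
#define KMACCOA  P[42]
#define KMOAACS  P[43]
#define KIACCOA  P[44]
#define KSACCOA  P[45]
#define KMISOC   P[46]
#define KMNADIDH P[47]
#define KAADP    P[48]
#define KACAM    P[49]
#define KINADH   P[50]
#define KH1      P[51]
#define KH2      P[52]
#define KMAKG    P[53]
#define KMNADKG  P[54]
#define KDMG     P[55]
#define KDCA     P[56]
#define KMSUC    P[57]
#define KIOAA    P[58]
#define KIFUM    P[59]
#define KMMAL    P[60]
#define KMNADMDH P[61]
#define KMOAAMDH P[62]
#define KMNADH   P[63]
#define KMNA     P[64]
#define KMCA     P[65]
#define KTRANS   P[66]
#define KACT     P[67]
#define LUNI     P[68]
#define KCA      P[69]
#define KATPC    P[70]
#define KMATPC   P[71]
#define KAIP3    P[72]
#define KACAC    P[73]
#define KICA     P[74]
/* equilibrium constants */
#define KACO     P[75]
#define KFH      P[76]
#define KMDH     P[77]
#define KSL      P[78]
#define KF1      P[79]
#define KRES     P[80]
/* exponents */
#define NI       P[81]
#define NAKG     P[82]
#define NA_UNI   P[83]
#define N_NA     P[84]
#define B_NCX    P[85]
#define F_ANT    P[86]
#define G_OX     P[87]
/* Magnus-Keizer pump constants */
#define PP1      P[88]
#define PP2      P[89]
#define PP3      P[90]
#define PPA      P[91]
#define PPC1     P[92]
#define PPC2     P[93]
#define RR1      P[94]
#define RR2      P[95]
#define RR3      P[96]
#define RRA      P[97]
#define RRC1     P[98]
#define RRC2     P[99]
/* offsets */
#define DPSISTAR P[100]
#define DPSIB    P[101]
/* switches */
#define ARESSQRT P[102]
#define KGDHADD  P[103]
#define OXHALF   P[104]
#define COUPLED  P[105]

static double gexp(double x) { return exp(x > 700.0 ? 700.0 : x); }

/* x / (1 - exp(-x)) through the removable singularity */
static double bern(double x)
{
    if (fabs(x) < 1e-4) return 1.0 + x / 2.0 + x * x / 12.0;
    return x / (1.0 - exp(-x));
}

void camito_init(void (*odeparms)(int *, double *))
{
    int n = N_PAR;
    odeparms(&n, P);
}

static void fluxes(const double *yin, double *J)
{
    double y[18];
    int i;
    for (i = 0; i < 17; i++) y[i] = yin[i] > 0.0 ? yin[i] : 0.0;
    y[17] = yin[17];

    double ADPc = y[0], ADPm = y[1], aKG = y[2], ATPc = y[3], ATPm = y[4];
    double CIT = y[5], FUM = y[6], ISOC = y[7], MAL = y[8], NAD = y[9];
    double NADH = y[10], OAA = y[11], SCoA = y[12], SUC = y[13];
    double Cac = y[14], Cam = y[15], CaER = y[16], DPsi = y[17];
    double FoRT = FCONST / RT;

    /* ER release, SERCA uptake, bulk hydrolysis (cytosolic volume) */
    double ip3g = IP3 * IP3 / (IP3 * IP3 + KAIP3 * KAIP3);
    double ki4 = KICA * KICA * KICA * KICA;
    double ca4 = Cac * Cac * Cac * Cac;
    double J_ERout = (VIP3R * ip3g * Cac * Cac / (Cac * Cac + KACAC * KACAC) *
                          ki4 / (ki4 + ca4) + VLEAK) * (CaER - Cac) / GAMMA;
    double sgate = Cac * Cac / (Cac * Cac + KCA * KCA);
    double J_SERCA = COUPLED > 0.5
        ? VSERCA * sgate * ATPc / (ATPc + KATPC)
        : VSERCA * sgate;
    double J_Hyd = KHYD * ATPc / (ATPc + KMATPC);

    /* mitochondrial Ca2+ transport */
    double xu = 2.0 * (DPsi - DPSISTAR) * FoRT;
    double ctr = Cac / KTRANS;
    double op = 1.0 + ctr;
    double J_UNI = VUNI * bern(xu) * ctr * op * op * op /
        (op * op * op * op + LUNI / pow(1.0 + Cac / KACT, NA_UNI));
    double cac_s = Cac > 1e-12 ? Cac : 1e-12;
    double J_NCX = Cam == 0.0 ? 0.0 :
        VNCX * gexp(B_NCX * (DPsi - DPSISTAR) * FoRT) * (Cam / cac_s) /
        (pow(1.0 + KMNA / NA_C, N_NA) * (1.0 + KMCA / Cam));

    /* oxidative phosphorylation */
    double Ares = ARESSQRT > 0.5 ? KRES * sqrt(NADH / NAD) : KRES * NADH / NAD;
    double eB6 = gexp(6.0 * DPSIB * FoRT);
    double eg6 = gexp(G_OX * 6.0 * DPsi * FoRT);
    double oxpref = OXHALF > 0.5 ? 0.5 : 1.0;
    double J_Ox = oxpref * RHORES *
        ((RRA * pow(10.0, 6.0 * DPH) + RRC1 * eB6) * Ares - RRA * eg6 +
         RRC2 * Ares * eg6) /
        ((1.0 + RR1 * Ares) * eB6 + (RR2 + RR3 * Ares) * eg6);
    double AF1 = KF1 * ATPm / (ADPm * PI_M);
    double eB3 = gexp(3.0 * DPSIB * FoRT);
    double e3 = gexp(3.0 * DPsi * FoRT);
    double J_F1 = -RHOF1 *
        ((PPA * pow(10.0, 3.0 * DPH) + PPC1 * eB3) * AF1 - PPA * e3 +
         PPC2 * AF1 * e3) /
        ((1.0 + PP1 * AF1) * eB3 + (PP2 + PP3 * AF1) * e3);

    /* TCA cycle */
    double J_CS = VCS / (1.0 + KMACCOA / ACCOA +
                         (KMOAACS / OAA) * (1.0 + ACCOA / KIACCOA) +
                         KSACCOA * KMOAACS / (OAA * ACCOA));
    double J_ACO = KFACO * (CIT - ISOC / KACO);
    double act_idh = (1.0 + ADPm / KAADP) * (1.0 + Cam / KACAM);
    double isoc_t = pow(KMISOC / ISOC, NI);
    double nad_t = (KMNADIDH / NAD) * (1.0 + NADH / KINADH);
    double J_IDH = VIDH / (1.0 + H_MI / KH1 + KH2 / H_MI +
                           isoc_t / act_idh + nad_t +
                           isoc_t * nad_t / act_idh);
    double act_kg = (1.0 + MG_M / KDMG) * (1.0 + Cam / KDCA);
    double nad_kg = pow(KMNADKG / NAD, NAKG);
    double J_KGDH = KGDHADD > 0.5
        ? VKGDH / (1.0 + KMAKG / aKG + nad_kg / act_kg)
        : VKGDH / (1.0 + (KMAKG / aKG) * nad_kg / act_kg);
    double J_SL = KFSL * (SCoA * ADPm * PI_M - SUC * ATPm * COA / KSL);
    double J_SDH = VSDH / (1.0 + (KMSUC / SUC) * (1.0 + OAA / KIOAA) *
                           (1.0 + FUM / KIFUM));
    double J_FH = KFFH * (FUM - MAL / KFH);
    double J_MDH = VMDH * (MAL * NAD - OAA * NADH / KMDH) /
        ((1.0 + MAL / KMMAL) * (1.0 + NAD / KMNADMDH) +
         (1.0 + OAA / KMOAAMDH) * (1.0 + NADH / KMNADH) - 1.0);

    /* adenine nucleotide translocator, proton leak */
    double emf = gexp(-F_ANT * DPsi * FoRT);
    double em1 = gexp(-DPsi * FoRT);
    double ATP4c = 0.05 * ATPc, ATP4m = 0.05 * ATPm;
    double ADP3c = 0.45 * ADPc, ADP3m = 0.36 * ADPm;
    double J_ANT = VANT * (ADP3c * ATP4m - ATP4c * ADP3m * em1) /
        ((ADP3c + ATP4c * emf) * (ATP4m + ADP3m));
    double J_Hl = GH * (DPsi - 2.303 * DPH / FoRT);

    J[0] = J_ERout; J[1] = J_SERCA; J[2] = J_NCX; J[3] = J_UNI;
    J[4] = J_Hyd;   J[5] = J_Ox;    J[6] = J_F1;  J[7] = J_CS;
    J[8] = J_ACO;   J[9] = J_IDH;   J[10] = J_KGDH; J[11] = J_SL;
    J[12] = J_SDH;  J[13] = J_FH;   J[14] = J_MDH;  J[15] = J_ANT;
    J[16] = J_Hl;
}

void camito_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double J[17];
    fluxes(y, J);

    double half = COUPLED > 0.5 ? 0.5 : 0.0;
    ydot[0] = -DELTA * J[15] + J[4] + half * J[1];            /* ADPc */
    ydot[1] = J[15] - J[6] - J[11];                           /* ADPm */
    ydot[2] = J[9] - J[10];                                   /* aKG  */
    ydot[3] = DELTA * J[15] - J[4] - half * J[1];             /* ATPc */
    ydot[4] = -J[15] + J[6] + J[11];                          /* ATPm */
    ydot[5] = J[7] - J[8];                                    /* CIT  */
    ydot[6] = J[12] - J[13];                                  /* FUM  */
    ydot[7] = J[8] - J[9];                                    /* ISOC */
    ydot[8] = J[13] - J[14];                                  /* MAL  */
    ydot[9] = J[5] - J[9] - J[10] - J[14];                    /* NAD  */
    ydot[10] = -J[5] + J[9] + J[10] + J[14];                  /* NADH */
    ydot[11] = J[14] - J[7];                                  /* OAA  */
    ydot[12] = J[10] - J[11];                                 /* SCoA */
    ydot[13] = J[11] - J[12];                                 /* SUC  */
    ydot[14] = F_C * GAMMA *
        (-J[1] + J[0] + DELTA * (J[2] - J[3]));               /* Cac  */
    ydot[15] = F_M * GAMMA * (J[3] - J[2]);                   /* Cam  */
    ydot[16] = F_ER * GAMMA / ALPHA * (J[1] - J[0]);          /* CaER */
    ydot[17] = (10.0 * J[5] - 3.0 * J[6] - J[15] - J[16] -
                J[2] - 2.0 * J[3]) / C_M;                     /* DPsi */

    if (ip[0] >= 17) {
        int i;
        for (i = 0; i < 17; i++) yout[i] = J[i];
    }
}

/* flux evaluation for a matrix of states (rows), used in post-processing */
SEXP camito_flux_matrix(SEXP y_mat, SEXP pvec)
{
    if (LENGTH(pvec) != N_PAR) error("parameter vector has wrong length");
    double saved[N_PAR];
    memcpy(saved, P, sizeof(P));
    memcpy(P, REAL(pvec), sizeof(P));

    SEXP dim = getAttrib(y_mat, R_DimSymbol);
    int n = INTEGER(dim)[0], m = INTEGER(dim)[1];
    if (m != 18) { memcpy(P, saved, sizeof(P)); error("state matrix must have 18 columns"); }
    SEXP out = PROTECT(allocMatrix(REALSXP, n, 17));
    double *ym = REAL(y_mat), *om = REAL(out);
    double y[18], J[17];
    int i, k;
    for (i = 0; i < n; i++) {
        for (k = 0; k < 18; k++) y[k] = ym[i + (R_xlen_t) n * k];
        fluxes(y, J);
        for (k = 0; k < 17; k++) om[i + (R_xlen_t) n * k] = J[k];
    }
    memcpy(P, saved, sizeof(P));
    UNPROTECT(1);
    return out;
}
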