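/* CiPAORdv1.0 ventricular action potential model: O'Hara-Rudy (2011)
 * endocardial cell with the Li et al. (2017) IKr Markov model (dynamic drug
 * binding and trapping) and Dutta et al. (2017) conductance scalings.
 *
 * State vector (49):
 *   0  V      membrane potential (mV)
 *   1-8   nai nass ki kss cai cass cansr cajsr (mM)
 *   9-38  ORd gating variables (m hf hs j hsp jp mL hL hLp a iF iS ap iFp
 *         iSp d ff fs fcaf fcas jca nca ffp fcafp xs1 xs2 xk1 Jrelnp Jrelp
 *         CaMKt)
 *   39-47 IKr Markov occupancies (IC1 IC2 C1 C2 O IO IObound Obound Cbound)
 *   48 qNet accumulator (uC/uF): d(qNet)/dt = (IKr+ICaL+INaL+Ito+IKs+IK1)/1000
 *
 * Extra outputs (7): IKr ICaL INaL Ito IKs IK1 Inet (uA/uF).
 *
 * All tunable constants arrive through the deSolve parameter vector; see
 * R/cell-model.R for the packing order (kept in one place on the R side).
 */

#include <R.h>
#include <math.h>

#define NPARMS 84
static double parms[NPARMS];

/* physical constants */
#define nao   parms[0]
#define cao   parms[1]
#define ko    parms[2]
#define Rgas  parms[3]
#define Temp  parms[4]
#define Frdy  parms[5]
/* base conductances */
#define GNa   parms[6]
#define GNaL  parms[7]
#define Gto   parms[8]
#define PCa_  parms[9]
#define GKr   parms[10]
#define GKs   parms[11]
#define GK1   parms[12]
#define Gncx  parms[13]
#define Pnak  parms[14]
#define GKb   parms[15]
#define PNab  parms[16]
#define PCab  parms[17]
#define GpCa  parms[18]
/* Dutta scalings */
#define sNa   parms[19]
#define sNaL  parms[20]
#define sto   parms[21]
#define sCaL  parms[22]
#define sKr   parms[23]
#define sKs   parms[24]
#define sK1   parms[25]
/* static block fractions (Hill pore block), in [0,1] */
#define bNa   parms[26]
#define bNaL  parms[27]
#define bto   parms[28]
#define bCaL  parms[29]
#define bKs   parms[30]
#define bK1   parms[31]
/* applied stimulus (uA/uF) */
#define Istim parms[32]
/* IKr Markov rate constants: 14 triples (A,B,q) starting at 33 */
#define MK(i,j) parms[33 + 3*(i) + (j)]
/* 33+42 = 75 */
#define temp_c parms[75]
#define Kt_    parms[76]
#define trap_k parms[77]
/* drug binding */
#define Kmax   parms[78]
#define EC50n  parms[79]
#define hill_n parms[80]
#define Ku_    parms[81]
#define Vhalf  parms[82]
#define Dconc  parms[83]

void qnetuq_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* .C entry so R can set parameters and evaluate the RHS once (used by
 * derivatives() and its tests without going through an integrator). */
void qnetuq_setparms(double *p, int *np)
{
    int i;
    for (i = 0; i < *np && i < NPARMS; i++) parms[i] = p[i];
}

static double safe_exp_m1(double x)
{   /* exp(x) - 1 with care near 0 */
    return (fabs(x) < 1e-7) ? x * (1.0 + 0.5 * x) : (exp(x) - 1.0);
}

void qnetuq_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    /* --- unpack state --- */
    double v = y[0];
    double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
    double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
    double m = y[9], hf = y[10], hs = y[11], j = y[12], hsp = y[13], jp = y[14];
    double mL = y[15], hL = y[16], hLp = y[17];
    double a = y[18], iF = y[19], iS = y[20], ap = y[21], iFp = y[22], iSp = y[23];
    double d = y[24], ff = y[25], fs = y[26], fcaf = y[27], fcas = y[28];
    double jca = y[29], nca = y[30], ffp = y[31], fcafp = y[32];
    double xs1 = y[33], xs2 = y[34], xk1 = y[35];
    double Jrelnp = y[36], Jrelp = y[37], CaMKt = y[38];
    double IC1 = y[39], IC2 = y[40], C1 = y[41], C2 = y[42];
    double O = y[43], IO = y[44], IObound = y[45], Obound = y[46], Cbound = y[47];

    /* --- cell geometry --- */
    double L = 0.01, rad = 0.0011;
    double vcell = 1000.0 * 3.14 * rad * rad * L;
    double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
    double Acap = 2.0 * Ageo;
    double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
    double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

    /* --- CaMK --- */
    double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
    double CaMKo = 0.05, KmCaM = 0.0015;
    double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
    double CaMKa = CaMKb + CaMKt;
    ydot[38] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;

    /* --- reversal potentials --- */
    double RToF = Rgas * Temp / Frdy;
    double ENa = RToF * log(nao / nai);
    double EK = RToF * log(ko / ki);
    double PKNa = 0.01833;
    double EKs = RToF * log((ko + PKNa * nao) / (ki + PKNa * nai));
    double vfrt = v / RToF;
    double vffrt = v * Frdy / RToF;

    /* --- INa (fast) --- */
    double mss = 1.0 / (1.0 + exp(-(v + 39.57) / 9.871));
    double tm = 1.0 / (6.765 * exp((v + 11.64) / 34.77) +
                       8.552 * exp(-(v + 77.42) / 5.955));
    ydot[9] = (mss - m) / tm;
    double hss = 1.0 / (1.0 + exp((v + 82.90) / 6.086));
    double thf = 1.0 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                        6.149 * exp((v + 0.5096) / 20.27));
    double ths = 1.0 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                        0.3343 * exp((v + 5.730) / 56.66));
    double Ahf = 0.99, Ahs = 1.0 - Ahf;
    ydot[10] = (hss - hf) / thf;
    ydot[11] = (hss - hs) / ths;
    double h = Ahf * hf + Ahs * hs;
    double jss = hss;
    double tj = 2.038 + 1.0 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                               0.3052 * exp((v + 0.9941) / 38.45));
    ydot[12] = (jss - j) / tj;
    double hssp = 1.0 / (1.0 + exp((v + 89.1) / 6.086));
    double thsp = 3.0 * ths;
    ydot[13] = (hssp - hsp) / thsp;
    double hp = Ahf * hf + Ahs * hsp;
    double tjp = 1.46 * tj;
    ydot[14] = (jss - jp) / tjp;
    double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
    double INa = sNa * (1.0 - bNa) * GNa * (v - ENa) * m * m * m *
        ((1.0 - fINap) * h * j + fINap * hp * jp);

    /* --- INaL --- */
    double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
    double tmL = tm;
    ydot[15] = (mLss - mL) / tmL;
    double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
    double thL = 200.0;
    ydot[16] = (hLss - hL) / thL;
    double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
    double thLp = 3.0 * thL;
    ydot[17] = (hLssp - hLp) / thLp;
    double fINaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
    double INaL = sNaL * (1.0 - bNaL) * GNaL * (v - ENa) * mL *
        ((1.0 - fINaLp) * hL + fINaLp * hLp);

    /* --- Ito --- */
    double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                          3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
    ydot[18] = (ass - a) / ta;
    double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
    double delta_epi = 1.0; /* endo */
    double tiF = 4.562 + 1.0 / (0.3933 * exp(-(v + 100.0) / 100.0) +
                                0.08004 * exp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                                1.780e-8 * exp((v + 114.1) / 8.079));
    tiF *= delta_epi; tiS *= delta_epi;
    double AiF = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
    double AiS = 1.0 - AiF;
    ydot[19] = (iss - iF) / tiF;
    ydot[20] = (iss - iS) / tiS;
    double i_gate = AiF * iF + AiS * iS;
    double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
    ydot[21] = (assp - ap) / ta;
    double dti_develop = 1.354 + 1.0e-4 / (exp((v - 167.4) / 15.89) +
                                           exp(-(v - 12.23) / 0.2154));
    double dti_recover = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
    double tiFp = dti_develop * dti_recover * tiF;
    double tiSp = dti_develop * dti_recover * tiS;
    ydot[22] = (iss - iFp) / tiFp;
    ydot[23] = (iss - iSp) / tiSp;
    double ip_gate = AiF * iFp + AiS * iSp;
    double fItop = 1.0 / (1.0 + KmCaMK / CaMKa);
    double Ito = sto * (1.0 - bto) * Gto * (v - EK) *
        ((1.0 - fItop) * a * i_gate + fItop * ap * ip_gate);

    /* --- ICaL / ICaNa / ICaK --- */
    double dss = 1.0 / (1.0 + exp(-(v + 3.940) / 4.230));
    double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
    ydot[24] = (dss - d) / td;
    double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                              0.0045 * exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(v + 5.0) / 4.0) +
                                 0.000035 * exp((v + 5.0) / 6.0));
    double Aff = 0.6, Afs = 1.0 - Aff;
    ydot[25] = (fss - ff) / tff;
    ydot[26] = (fss - fs) / tfs;
    double f = Aff * ff + Afs * fs;
    double fcass = fss;
    double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                                0.04 * exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                  0.00012 * exp(v / 7.0));
    double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
    double Afcas = 1.0 - Afcaf;
    ydot[27] = (fcass - fcaf) / tfcaf;
    ydot[28] = (fcass - fcas) / tfcas;
    double fca = Afcaf * fcaf + Afcas * fcas;
    double tjca = 75.0;
    ydot[29] = (fcass - jca) / tjca;
    double tffp = 2.5 * tff;
    ydot[31] = (fss - ffp) / tffp;
    double fp = Aff * ffp + Afs * fs;
    double tfcafp = 2.5 * tfcaf;
    ydot[32] = (fcass - fcafp) / tfcafp;
    double fcap = Afcaf * fcafp + Afcas * fcas;
    double Kmn = 0.002, k2n = 1000.0;
    double km2n = jca * 1.0;
    double anca = 1.0 / (k2n / km2n + pow(1.0 + Kmn / cass, 4.0));
    ydot[30] = anca * k2n - nca * km2n;
    double PhiCaL = 4.0 * vffrt * (cass * exp(2.0 * vfrt) - 0.341 * cao) /
        safe_exp_m1(2.0 * vfrt);
    double PhiCaNa = 1.0 * vffrt * (0.75 * nass * exp(1.0 * vfrt) - 0.75 * nao) /
        safe_exp_m1(1.0 * vfrt);
    double PhiCaK = 1.0 * vffrt * (0.75 * kss * exp(1.0 * vfrt) - 0.75 * ko) /
        safe_exp_m1(1.0 * vfrt);
    double PCa = sCaL * (1.0 - bCaL) * PCa_;
    double PCap = 1.1 * PCa;
    double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    double fICaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
    double ICaL = (1.0 - fICaLp) * PCa * PhiCaL * d * (f * (1.0 - nca) + jca * fca * nca) +
        fICaLp * PCap * PhiCaL * d * (fp * (1.0 - nca) + jca * fcap * nca);
    double ICaNa = (1.0 - fICaLp) * PCaNa * PhiCaNa * d * (f * (1.0 - nca) + jca * fca * nca) +
        fICaLp * PCaNap * PhiCaNa * d * (fp * (1.0 - nca) + jca * fcap * nca);
    double ICaK = (1.0 - fICaLp) * PCaK * PhiCaK * d * (f * (1.0 - nca) + jca * fca * nca) +
        fICaLp * PCaKp * PhiCaK * d * (fp * (1.0 - nca) + jca * fcap * nca);

    /* --- IKr: Li et al. Markov model with drug binding and trapping --- */
    {
        double qpow = (temp_c - 20.0) / 10.0;
        double r[14];
        int k;
        for (k = 0; k < 14; k++)
            r[k] = MK(k, 0) * exp(MK(k, 1) * v) * pow(MK(k, 2), qpow);
        /* index: 0 A1 C1->C2, 1 A2 C2->C1, 2 A3 IC2->IO, 3 A4 IO->IC2,
         * 4 A11 IC1->IC2, 5 A21 IC2->IC1, 6 A31 C2->O, 7 A41 O->C2,
         * 8 A51 C1->IC1, 9 A61 IC1->C1, 10 A52 C2->IC2, 11 A62 IC2->C2,
         * 12 A53 O->IO, 13 A63 IO->O */
        double Dn = (Dconc > 0.0) ? pow(Dconc, hill_n) : 0.0;
        double kon = (Dn > 0.0) ? Kmax * Ku_ * Dn / (Dn + EC50n) : 0.0;
        double ku_io = Ku_ * r[12] / r[13]; /* microscopic reversibility */
        double trap_open = Kt_ / (1.0 + exp(-(v - Vhalf) / trap_k));

        ydot[39] = -(r[4] * IC1 - r[5] * IC2) + (r[8] * C1 - r[9] * IC1);
        ydot[40] =  (r[4] * IC1 - r[5] * IC2) - (r[2] * IC2 - r[3] * IO)
                  + (r[10] * C2 - r[11] * IC2);
        ydot[41] = -(r[0] * C1 - r[1] * C2) - (r[8] * C1 - r[9] * IC1);
        ydot[42] =  (r[0] * C1 - r[1] * C2) - (r[6] * C2 - r[7] * O)
                  - (r[10] * C2 - r[11] * IC2);
        ydot[43] =  (r[6] * C2 - r[7] * O) - (r[12] * O - r[13] * IO)
                  - (kon * O - Ku_ * Obound);
        ydot[44] =  (r[2] * IC2 - r[3] * IO) + (r[12] * O - r[13] * IO)
                  - (kon * IO - ku_io * IObound);
        ydot[45] =  kon * IO - ku_io * IObound + (trap_open * Cbound - Kt_ * IObound);
        ydot[46] =  kon * O - Ku_ * Obound + (trap_open * Cbound - Kt_ * Obound);
        ydot[47] = -(trap_open * Cbound - Kt_ * Obound)
                   - (trap_open * Cbound - Kt_ * IObound);
    }
    double IKr = sKr * GKr * sqrt(ko / 5.4) * O * (v - EK);

    /* --- IKs --- */
    double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                                 0.001292 * exp(-(v + 210.0) / 230.0));
    ydot[33] = (xs1ss - xs1) / txs1;
    double xs2ss = xs1ss;
    double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                         0.0193 * exp(-(v + 66.54) / 31.0));
    ydot[34] = (xs2ss - xs2) / txs2;
    double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
    double IKs = sKs * (1.0 - bKs) * GKs * KsCa * xs1 * xs2 * (v - EKs);

    /* --- IK1 --- */
    double xk1ss = 1.0 / (1.0 + exp(-(v + 2.5538 * ko + 144.59) /
                                    (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (exp(-(v + 127.2) / 20.36) + exp((v + 236.8) / 69.33));
    ydot[35] = (xk1ss - xk1) / txk1;
    double rk1 = 1.0 / (1.0 + exp((v + 105.8 - 2.6 * ko) / 9.493));
    double IK1 = sK1 * (1.0 - bK1) * GK1 * sqrt(ko) * rk1 * xk1 * (v - EK);

    /* --- INaCa (myoplasmic and subspace) --- */
    double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
    double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
    double kcaon = 1.5e6, kcaoff = 5.0e3, qna = 0.5224, qca = 0.1670;
    double hca = exp(qca * vfrt), hna = exp(qna * vfrt);
    double KmCaAct = 150.0e-6, zna = 1.0;
    double INaCa_i, INaCa_ss;
    {
        double h1 = 1.0 + nai / kna3 * (1.0 + hna);
        double h2 = (nai * hna) / (kna3 * h1);
        double h3 = 1.0 / h1;
        double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
        double h5 = nai * nai / (h4 * kna1 * kna2);
        double h6 = 1.0 / h4;
        double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
        double h8 = nao / (kna3 * hna * h7);
        double h9 = 1.0 / h7;
        double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
        double h11 = nao * nao / (h10 * kna1 * kna2);
        double h12 = 1.0 / h10;
        double k1 = h12 * cao * kcaon, k2 = kcaoff;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k5 = kcaoff, k6 = h6 * cai * kcaon;
        double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + pow(KmCaAct / cai, 2.0));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        INaCa_i = 0.8 * Gncx * allo * (zna * JncxNa + 2.0 * JncxCa);
    }
    {
        double h1 = 1.0 + nass / kna3 * (1.0 + hna);
        double h2 = (nass * hna) / (kna3 * h1);
        double h3 = 1.0 / h1;
        double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
        double h5 = nass * nass / (h4 * kna1 * kna2);
        double h6 = 1.0 / h4;
        double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
        double h8 = nao / (kna3 * hna * h7);
        double h9 = 1.0 / h7;
        double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
        double h11 = nao * nao / (h10 * kna1 * kna2);
        double h12 = 1.0 / h10;
        double k1 = h12 * cao * kcaon, k2 = kcaoff;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k5 = kcaoff, k6 = h6 * cass * kcaon;
        double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + pow(KmCaAct / cass, 2.0));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + 2.0 * JncxCa);
    }

    /* --- INaK --- */
    double INaK;
    {
        double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
        double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
        double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
        double Knai = Knai0 * exp(delta * vfrt / 3.0);
        double Knao = Knao0 * exp((1.0 - delta) * vfrt / 3.0);
        double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
        double Kmgatp = 1.698e-7, H = 1.0e-7, eP = 4.2, Khp = 1.698e-7;
        double Knap = 224.0, Kxkur = 292.0;
        double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
        double a1 = (k1p * pow(nai / Knai, 3.0)) /
            (pow(1.0 + nai / Knai, 3.0) + pow(1.0 + ki / Kki, 2.0) - 1.0);
        double b1 = k1m * MgADP;
        double a2 = k2p;
        double b2 = (k2m * pow(nao / Knao, 3.0)) /
            (pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ko / Kko, 2.0) - 1.0);
        double a3 = (k3p * pow(ko / Kko, 2.0)) /
            (pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ko / Kko, 2.0) - 1.0);
        double b3 = (k3m * P * H) / (1.0 + MgATP / Kmgatp);
        double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
        double b4 = (k4m * pow(ki / Kki, 2.0)) /
            (pow(1.0 + nai / Knai, 3.0) + pow(1.0 + ki / Kki, 2.0) - 1.0);
        double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
        double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
        double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
        double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double zk = 1.0;
        double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
        double JnakK = 2.0 * (E4 * b1 - E3 * a1);
        INaK = Pnak * (zna * JnakNa + zk * JnakK);
    }

    /* --- background and pump currents --- */
    double xkb = 1.0 / (1.0 + exp(-(v - 14.48) / 18.34));
    double IKb = GKb * xkb * (v - EK);
    double INab = PNab * vffrt * (nai * exp(vfrt) - nao) / safe_exp_m1(vfrt);
    double ICab = PCab * 4.0 * vffrt * (cai * exp(2.0 * vfrt) - 0.341 * cao) /
        safe_exp_m1(2.0 * vfrt);
    double IpCa = GpCa * cai / (0.0005 + cai);

    /* --- diffusion fluxes --- */
    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK = (kss - ki) / 2.0;
    double Jdiff = (cass - cai) / 0.2;

    /* --- SR calcium release (RyR) --- */
    double bt = 4.75, a_rel = 0.5 * bt;
    double Jrel_inf = a_rel * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    ydot[36] = (Jrel_inf - Jrelnp) / tau_rel;
    double btp = 1.25 * bt, a_relp = 0.5 * btp;
    double Jrel_infp = a_relp * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    ydot[37] = (Jrel_infp - Jrelp) / tau_relp;
    double fJrelp = 1.0 / (1.0 + KmCaMK / CaMKa);
    double Jrel = (1.0 - fJrelp) * Jrelnp + fJrelp * Jrelp;

    /* --- SR uptake / leak / translocation --- */
    double Jupnp = 0.004375 * cai / (cai + 0.00092);
    double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    double fJupp = 1.0 / (1.0 + KmCaMK / CaMKa);
    double Jleak = 0.0039375 * cansr / 15.0;
    double Jup = (1.0 - fJupp) * Jupnp + fJupp * Jupp - Jleak;
    double Jtr = (cansr - cajsr) / 100.0;

    /* --- ionic concentration ODEs --- */
    double cmdnmax = 0.05, kmcmdn = 0.00238, trpnmax = 0.07, kmtrpn = 0.0005;
    double BSRmax = 0.047, KmBSR = 0.00087, BSLmax = 1.124, KmBSL = 0.0087;
    double csqnmax = 10.0, kmcsqn = 0.8;

    ydot[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
        (Frdy * vmyo) + JdiffNa * vss / vmyo;
    ydot[2] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
    ydot[3] = -(Ito + IKr + IKs + IK1 + IKb + Istim - 2.0 * INaK) * Acap /
        (Frdy * vmyo) + JdiffK * vss / vmyo;
    ydot[4] = -ICaK * Acap / (Frdy * vss) - JdiffK;
    {
        double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / pow(kmcmdn + cai, 2.0) +
                             trpnmax * kmtrpn / pow(kmtrpn + cai, 2.0));
        ydot[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
                          (2.0 * Frdy * vmyo) - Jup * vnsr / vmyo +
                          Jdiff * vss / vmyo);
    }
    {
        double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / pow(KmBSR + cass, 2.0) +
                              BSLmax * KmBSL / pow(KmBSL + cass, 2.0));
        ydot[6] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * Frdy * vss) +
                           Jrel * vjsr / vss - Jdiff);
    }
    ydot[7] = Jup - Jtr * vjsr / vnsr;
    {
        double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / pow(kmcsqn + cajsr, 2.0));
        ydot[8] = Bcajsr * (Jtr - Jrel);
    }

    /* --- membrane potential --- */
    ydot[0] = -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Istim);

    /* --- qNet accumulator: sum of the six currents, integrated in seconds
     * (time is in ms, hence /1000) --- */
    double Inet = IKr + ICaL + INaL + Ito + IKs + IK1;
    ydot[48] = Inet / 1000.0;

    if (ip[0] >= 7) {
        yout[0] = IKr; yout[1] = ICaL; yout[2] = INaL;
        yout[3] = Ito; yout[4] = IKs; yout[5] = IK1; yout[6] = Inet;
    }
}

/* single RHS evaluation for R-side use (parameters set via qnetuq_setparms) */
void qnetuq_derivs_eval(double *t, double *y, double *ydot, double *yout)
{
    int neq = 49, ip = 7;
    qnetuq_derivs(&neq, t, y, ydot, yout, &ip);
}
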