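/* Compiled right-hand sides for the deSolve integrators.
 *
 * Two models are provided:
 *   - "pc"  : the 4-state opsin photocycle alone (voltage clamp runs),
 *             states C1, O1, O2, C2.
 *   - "rgn" : the photocycle coupled to the Fohlmeister-Miller retinal
 *             ganglion neuron membrane model, states
 *             V, m, h, n, c, a, hA, Cai, C1, O1, O2, C2.
 *
 * Time is in ms, voltages in mV, photon flux in photons mm^-2 s^-1,
 * membrane currents in uA cm^-2, Ca in mM.  The photon flux is passed as a
 * parameter: stimuli are piecewise constant and the R driver restarts the
 * integration at every discontinuity.
 */

#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define RGAS    8.314462618   /* J mol^-1 K^-1 */
#define FARADAY 96485.33212   /* C mol^-1 */

/* ---------------- photocycle ----------------
 * parms: 0 Gd1, 1 Gd2, 2 Gr, 3 phim, 4 k1, 5 k2, 6 kf, 7 kb,
 *        8 Gf0, 9 Gb0, 10 p, 11 q, 12 phi
 */
#define NPC 13
static double pcp[NPC];

void pc_initmod(void (*odeparms)(int *, double *))
{
    int n = NPC;
    odeparms(&n, pcp);
}

static void light_rates_c(const double *prm, double phi,
                          double *Ga1, double *Ga2, double *Gf, double *Gb)
{
    double hp = 0.0, hq = 0.0;
    if (phi > 0.0) {
        double fp = pow(phi, prm[10]), mp = pow(prm[3], prm[10]);
        double fq = pow(phi, prm[11]), mq = pow(prm[3], prm[11]);
        hp = fp / (fp + mp);
        hq = fq / (fq + mq);
    }
    *Ga1 = prm[4] * hp;
    *Ga2 = prm[5] * hp;
    *Gf  = prm[8] + prm[6] * hq;
    *Gb  = prm[9] + prm[7] * hq;
}

static void pc_rhs(const double *prm, double phi, const double *y, double *dy)
{
    double Ga1, Ga2, Gf, Gb;
    double C1 = y[0], O1 = y[1], O2 = y[2], C2 = y[3];
    double Gd1 = prm[0], Gd2 = prm[1], Gr = prm[2];

    light_rates_c(prm, phi, &Ga1, &Ga2, &Gf, &Gb);
    dy[0] = Gd1 * O1 - Ga1 * C1 + Gr * C2;
    dy[1] = Ga1 * C1 - (Gd1 + Gf) * O1 + Gb * O2;
    dy[2] = Gf * O1 - (Gd2 + Gb) * O2 + Ga2 * C2;
    dy[3] = Gd2 * O2 - (Ga2 + Gr) * C2;   /* conservation-consistent form */
}

void pc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    pc_rhs(pcp, pcp[12], y, ydot);
}

/* ---------------- RGN membrane model ----------------
 * parms: 0..12 photocycle block as above (12 = phi),
 *        13 gamma, 14 Eopsin (mV), 15 gdens (mS cm^-2),
 *        16 Cm, 17 gNa, 18 gK, 19 gCa, 20 gKA, 21 gKCabar, 22 gL,
 *        23 ENa, 24 EK, 25 EL,
 *        26 Cae, 27 Cares, 28 Cadiss, 29 tauCa, 30 fluxfac, 31 T
 */
#define NRGN 32
static double rgnp[NRGN];

void rgn_initmod(void (*odeparms)(int *, double *))
{
    int n = NRGN;
    odeparms(&n, rgnp);
}

/* a*u/(exp(k*u)-1) with its analytic limit a/k at u = 0 */
static double lin_exp(double a, double k, double u)
{
    double ku = k * u;
    if (fabs(ku) < 1e-7)
        return (a / k) * (1.0 - 0.5 * ku);
    return a * u / expm1(ku);
}

void rgn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *prm = rgnp;
    double V = y[0], m = y[1], h = y[2], n = y[3], c = y[4];
    double a = y[5], hA = y[6], Cai = y[7];
    double O1 = y[9], O2 = y[10];

    double am = lin_exp(-0.6,  -0.1, V + 30.0);
    double bm = 20.0 * exp(-0.055 * (V + 55.0));
    double ah = 0.4 * exp(-0.05 * (V + 50.0));
    double bh = 6.0 / (exp(-0.1 * (V + 20.0)) + 1.0);
    double an = lin_exp(-0.02, -0.1, V + 40.0);
    double bn = 0.4 * exp(-0.0125 * (V + 50.0));
    double ac = lin_exp(-0.3,  -0.1, V + 13.0);
    double bc = 10.0 * exp(-0.055 * (V + 38.0));
    double aa = lin_exp(-0.006, -0.1, V + 90.0);
    double ba = 0.1 * exp(-0.1 * (V + 30.0));
    double ahA = 0.04 * exp(-0.05 * (V + 70.0));
    double bhA = 0.6 / (1.0 + exp(-0.1 * (V + 40.0)));

    double Cai_pos = (Cai > 1e-12) ? Cai : 1e-12;
    double ECa = 1000.0 * RGAS * prm[31] / (2.0 * FARADAY) *
                 log(prm[26] / Cai_pos);
    double rca = Cai_pos / prm[28];
    double gKCa = prm[21] * rca * rca / (1.0 + rca * rca);

    double INa  = prm[17] * m * m * m * h * (V - prm[23]);
    double IK   = prm[18] * n * n * n * n * (V - prm[24]);
    double ICa  = prm[19] * c * c * c * (V - ECa);
    double IKA  = prm[20] * a * a * a * hA * (V - prm[24]);
    double IKCa = gKCa * (V - prm[24]);   /* K+ current, reverses at EK */
    double IL   = prm[22] * (V - prm[25]);
    double IOps = prm[15] * (O1 + prm[13] * O2) * (V - prm[14]);

    ydot[0] = (-(INa + IK + IKA + ICa + IKCa + IL) - IOps) / prm[16];
    ydot[1] = -(am + bm) * m + am;
    ydot[2] = -(ah + bh) * h + ah;
    ydot[3] = -(an + bn) * n + an;
    ydot[4] = -(ac + bc) * c + ac;
    ydot[5] = -(aa + ba) * a + aa;
    ydot[6] = -(ahA + bhA) * hA + ahA;
    ydot[7] = -prm[30] * ICa - (Cai - prm[27]) / prm[29];
    pc_rhs(prm, prm[12], y + 8, ydot + 8);
}

/* ---------------- registration ---------------- */

static const R_CMethodDef CEntries[] = {
    {"pc_derivs",   (DL_FUNC) &pc_derivs,   6},
    {"rgn_derivs",  (DL_FUNC) &rgn_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_optorgn(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
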