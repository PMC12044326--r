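/* Compiled right-hand side for the coupled minimal-PBPK DDI system.
 *
 * State layout (ndrug = 1 or 2):
 *   per drug d (offset 8*d): lumen, enterocyte, liver, central, SAC,
 *   cumulative metabolized, cumulative renally excreted, cumulative fecal;
 *   then n_ind enzyme-activity states (relative activity, baseline 1).
 *
 * Parameter vector layout (padded to P_LEN doubles, packed by the R side):
 *   [0] ndrug, [1] n_ind
 *   per drug: 18 scalars
 *     (ka, kloss, qgut, fugut, vent, vliv, qh, qk, qvil, clr, cladd,
 *      vc, kin, kout, fub, bp, uMfac, eff_cl)
 *   then 3 tissue blocks (liver, gut, kidney), each:
 *     n_enz, N[MAXE], mm[MAXE], c0[MAXE], vmax[MAXE], km[MAXE],
 *     kiu[MAXE], act[MAXE]          (act: 1-based induction state or 0)
 *   then kiu_eff (1 double)
 *   after both drug blocks: n_ind induction entries of 6 doubles:
 *     (src_drug 1/2, tissue 0=liver 1=gut, kdeg, imax, c50, hill)
 */
#include <R.h>
#include <math.h>

#define MAXE 8
#define P_LEN 1024
#define DRUG_BLOCK (18 + 3 * (1 + 7 * MAXE) + 1)

static double P[P_LEN];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = P_LEN;
    odeparms(&n, P);
}

static double clamp0(double x) { return x > 0 ? x : 0; }

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int nd = (int) P[0];
    int n_ind = (int) P[1];
    int nstate = 8 * nd;
    double cp[2], cb[2], cent[2], cbl[2];
    double cu_liv_uM[2], cu_kid_uM[2], gut_uM[2];
    int d, e, j;

    for (d = 0; d < nd; d++) {
        const double *pp = P + 2 + d * DRUG_BLOCK;
        int off = 8 * d;
        double vent = pp[4], vliv = pp[5], qvil = pp[8];
        double vc = pp[11], fub = pp[14], bp = pp[15], uM = pp[16];
        cp[d]   = clamp0(y[off + 3]) / vc;
        cb[d]   = bp * cp[d];
        cent[d] = clamp0(y[off + 1]) / vent;
        cbl[d]  = clamp0(y[off + 2]) / vliv;
        cu_liv_uM[d] = fub * cbl[d] * uM;
        cu_kid_uM[d] = fub * cb[d] * uM;
        gut_uM[d] = pp[3] * pp[2] * cent[d] / qvil * uM;
    }

    for (d = 0; d < nd; d++) {
        const double *pp = P + 2 + d * DRUG_BLOCK;
        int off = 8 * d;
        int o = (nd == 2) ? 1 - d : -1;  /* index of the other drug */
        double ka = pp[0], kloss = pp[1], qgut = pp[2], fugut = pp[3];
        double qh = pp[6], qk = pp[7], clr = pp[9], cladd = pp[10];
        double kin = pp[12], kout = pp[13], fub = pp[14], uM = pp[16];
        double eff_cl = pp[17];
        const double *tis = pp + 18;
        double cu_ent_mgL = fugut * cent[d];
        double cu_ent_uM = cu_ent_mgL * uM;
        double cu_liv_mgL = fub * cbl[d];
        double drv_liv = (o >= 0) ? cu_liv_uM[o] : 0;
        double drv_gut = (o >= 0) ? gut_uM[o] : 0;
        double drv_kid = (o >= 0) ? cu_kid_uM[o] : 0;
        double met[3];
        int ti;

        for (ti = 0; ti < 3; ti++) {
            const double *tb = tis + ti * (1 + 7 * MAXE);
            int ne = (int) tb[0];
            const double *N = tb + 1, *mm = tb + 1 + MAXE,
                         *c0 = tb + 1 + 2 * MAXE, *vmax = tb + 1 + 3 * MAXE,
                         *km = tb + 1 + 4 * MAXE, *kiu = tb + 1 + 5 * MAXE,
                         *act = tb + 1 + 6 * MAXE;
            double cu_uM = (ti == 0) ? cu_liv_uM[d]
                         : (ti == 1) ? cu_ent_uM : cu_kid_uM[d];
            double drv = (ti == 0) ? drv_liv : (ti == 1) ? drv_gut : drv_kid;
            double clu_sum = 0;
            for (e = 0; e < ne; e++) {
                double clu = (mm[e] > 0.5) ? vmax[e] / (km[e] + cu_uM) : c0[e];
                double inh = 1.0 / (1.0 + drv / kiu[e]);
                double a = 1.0;
                if (act[e] > 0.5) a = y[nstate + (int) act[e] - 1];
                clu_sum += clu * inh * a * N[e];
            }
            clu_sum *= 60e-6;  /* uL/min/pmol * pmol -> L/h */
            if (ti == 0) met[0] = clu_sum * cu_liv_mgL;
            else if (ti == 1) met[1] = clu_sum * cu_ent_mgL;
            else {
                double fcl = fub * clu_sum;
                met[2] = qk * fcl / (qk + fcl) * cb[d];
            }
        }

        double effl = 0;
        if (eff_cl > 0) {
            double kiu_e = pp[18 + 3 * (1 + 7 * MAXE)];
            effl = eff_cl * (1.0 / (1.0 + drv_gut / kiu_e)) * cu_ent_mgL;
        }

        double lum = clamp0(y[off + 0]);
        ydot[off + 0] = -(ka + kloss) * lum + effl;
        ydot[off + 1] = ka * lum - qgut * cent[d] - met[1] - effl;
        ydot[off + 2] = qh * cb[d] + qgut * cent[d] - qh * cbl[d] - met[0];
        ydot[off + 3] = qh * cbl[d] - qh * cb[d] - clr * cp[d] - cladd * cp[d]
                        - met[2] - kin * clamp0(y[off + 3]) + kout * clamp0(y[off + 4]);
        ydot[off + 4] = kin * clamp0(y[off + 3]) - kout * clamp0(y[off + 4]);
        ydot[off + 5] = met[0] + met[1] + met[2] + cladd * cp[d];
        ydot[off + 6] = clr * cp[d];
        ydot[off + 7] = kloss * lum;
    }

    for (j = 0; j < n_ind; j++) {
        const double *ib = P + 2 + nd * DRUG_BLOCK + j * 6;
        int src = (int) ib[0] - 1;
        double cu = (ib[1] < 0.5) ? cu_liv_uM[src] : gut_uM[src];
        double h = ib[5];
        double ch = (h == 1.0) ? cu : pow(cu, h);
        double c50h = (h == 1.0) ? ib[4] : pow(ib[4], h);
        double fold = 1.0 + ib[3] * ch / (c50h + ch);
        ydot[8 * nd + j] = ib[2] * (fold - y[8 * nd + j]);
    }
}
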