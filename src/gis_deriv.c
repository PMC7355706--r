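/* Right-hand side of the three-chamber transit/dissolution/precipitation
 * ODE system, compiled for use with deSolve (func = "gis_derivs").
 *
 * States (amounts in ug, volumes in mL):
 *   y[0] V_s      gastric volume
 *   y[1] V_j      jejunal volume
 *   y[2] Xs_s     gastric solid
 *   y[3] Xd_s     gastric dissolved
 *   y[4] Xs_d     duodenal solid
 *   y[5] Xd_d     duodenal dissolved
 *   y[6] Xp_d     duodenal precipitate (inert)
 *   y[7] Xs_j     jejunal solid
 *   y[8] Xd_j     jejunal dissolved
 *   y[9] Xp_j     jejunal precipitate (inert)
 *   y[10..13]     cumulative flux ledgers: gastric-emptied dissolved,
 *                 gastric-emptied solid, duodenum->jejunum dissolved,
 *                 duodenum->jejunum solid
 *
 * Forcings (linearly interpolated by deSolve): solubility (ug/mL) in the
 * stomach, duodenum and jejunum as functions of time, precomputed from the
 * per-chamber pH profiles and the drug's solubility model.
 */

#include <R.h>
#include <math.h>

static double parms[12];
#define kge     parms[0]   /* gastric emptying rate constant, 1/min */
#define ksec_s  parms[1]   /* gastric secretion, mL/min */
#define ksec_d  parms[2]   /* duodenal secretion, mL/min */
#define vfloor  parms[3]   /* gastric residual volume floor, mL */
#define vd      parms[4]   /* constant duodenal volume, mL */
#define frac    parms[5]   /* particle transfer fraction */
#define zs      parms[6]   /* effective Z_s (scale applied), mL/ug/min */
#define zd      parms[7]
#define zj      parms[8]
#define kpre_d  parms[9]   /* 1/min */
#define kpre_j  parms[10]
#define veps    parms[11]  /* volume below which concentration := 0, mL */

static double forc[3];
#define sol_s forc[0]
#define sol_d forc[1]
#define sol_j forc[2]

void gis_initmod(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void gis_initforc(void (*odeforcs)(int *, double *))
{
    int n = 3;
    odeforcs(&n, forc);
}

void gis_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double Vs = y[0], Vj = y[1];
    double Xs_s = y[2], Xd_s = y[3];
    double Xs_d = y[4], Xd_d = y[5];
    double Xs_j = y[7], Xd_j = y[8];

    /* gastric outflow: first-order emptying until the residual floor,
     * then the pump only passes on the secreted fluid.  The switch is
     * blended linearly over a 0.5 mL band above the floor so the
     * right-hand side stays continuous for the solver. */
    double band = 0.5;
    double w = (Vs - vfloor) / band;
    if (w > 1.0) w = 1.0;
    if (w < 0.0) w = 0.0;
    double Qs = w * kge * Vs + (1.0 - w) * ksec_s;

    double conc_s = (Vs > veps) ? Xd_s / Vs : 0.0;
    double diss_s = zs * Xs_s * fmax(0.0, sol_s - conc_s);
    double out_dis_s = (Vs > veps) ? Qs * Xd_s / Vs : 0.0;
    double out_sol_s = (Vs > veps) ? frac * Qs * Xs_s / Vs : 0.0;

    double Qdj = Qs + ksec_d; /* duodenal outflow matches inflow */
    double conc_d = Xd_d / vd;
    double diss_d = zd * Xs_d * fmax(0.0, sol_d - conc_d);
    double pre_d = kpre_d * fmax(0.0, Xd_d - sol_d * vd);
    double out_dis_d = Qdj * Xd_d / vd;
    double out_sol_d = frac * Qdj * Xs_d / vd;

    double conc_j = (Vj > veps) ? Xd_j / Vj : 0.0;
    double diss_j = (Vj > veps) ? zj * Xs_j * fmax(0.0, sol_j - conc_j) : 0.0;
    double pre_j = kpre_j * fmax(0.0, Xd_j - sol_j * Vj);

    ydot[0] = ksec_s - Qs;                          /* V_s  */
    ydot[1] = Qdj;                                  /* V_j  */
    ydot[2] = -diss_s - out_sol_s;                  /* Xs_s */
    ydot[3] = diss_s - out_dis_s;                   /* Xd_s */
    ydot[4] = out_sol_s - diss_d - out_sol_d;       /* Xs_d */
    ydot[5] = out_dis_s + diss_d - pre_d - out_dis_d; /* Xd_d */
    ydot[6] = pre_d;                                /* Xp_d */
    ydot[7] = out_sol_d - diss_j;                   /* Xs_j */
    ydot[8] = out_dis_d + diss_j - pre_j;           /* Xd_j */
    ydot[9] = pre_j;                                /* Xp_j */
    ydot[10] = out_dis_s;
    ydot[11] = out_sol_s;
    ydot[12] = out_dis_d;
    ydot[13] = out_sol_d;
}
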