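/* Compiled right-hand side and root functions for the four-compartment
 * circulation model, in the classic deSolve compiled-model interface
 * (initfunc/derivs/root resolved by name in this package's DLL).
 *
 * State: y[0] = p_e, y[1] = p_a, y[2] = p_v, y[3] = U_LV = p_LV / E_LV(t).
 *
 * Parameter block layout (doubles, kept in step with R/simulate.R):
 *   0 R_e0   1 R_a    2 R_v0   3 R_LV   4 R_eM
 *   5 C_e    6 C_a    7 C_v    8 E_d    9 E_s0
 *  10 c1    11 c2    12 c3    13 c4    14 c5    15 c6
 *  16 omega0 17 phi  18 eps1  19 A1
 *  20 root_mode: 0 await closure (g = p_LV - p_e crossing 0)
 *                1 await reopening (g - hyst)
 *                2 await reopening OR deep closure (g - thr)
 *  21 hyst   22 thr  23 n_events
 *  24..23+NEVMAX          event times t_n
 *  24+NEVMAX..23+2*NEVMAX event closure delays dt_n
 */
#include <R.h>
#include <math.h>

#define NEVMAX 16
#define NPARMS (24 + 2 * NEVMAX)

static double parms[NPARMS];

void cardiowave_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* integrated cardiac phase: omega0 t - (c3 c2/omega0)(cos(omega0 t/c2) - 1) */
static double cw_phase(double t)
{
    double omega0 = parms[16], c2 = parms[11], c3 = parms[12];
    return omega0 * t - (c3 * c2 / omega0) * (cos(omega0 * t / c2) - 1.0);
}

static double cw_elastance(double t)
{
    double E_d = parms[8], E_s0 = parms[9];
    double c1 = parms[10], c2 = parms[11], omega0 = parms[16], phi = parms[17];
    double twopi = 2.0 * M_PI;
    double psi = fmod(cw_phase(t), twopi);
    if (psi < 0) psi += twopi;
    double a = 0.0;
    if (psi < twopi * phi) {
        double s = sin(psi / (2.0 * phi));
        a = s * s;
    }
    double E_s = E_s0 + c1 * sin(omega0 * t / c2);
    return E_d + a * (E_s - E_d);
}

static double cw_notch(double t)
{
    int nev = (int) parms[23];
    double c4 = parms[13], c5 = parms[14], c6 = parms[15];
    double f = 0.0;
    for (int i = 0; i < nev; i++) {
        double tn = parms[24 + i];
        double dt = parms[24 + NEVMAX + i];
        double z = (t - tn - c6 * dt) / dt;
        double ex = -c5 * z * z;
        if (ex > -700.0) f += c4 * exp(ex);
    }
    return f;
}

void cardiowave_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double R_e0 = parms[0], R_a = parms[1], R_v0 = parms[2];
    double R_LV = parms[3], R_eM = parms[4];
    double C_e = parms[5], C_a = parms[6], C_v = parms[7];
    double eps1 = parms[18], A1 = parms[19];

    double E = cw_elastance(*t);
    double p_e = y[0], p_a = y[1], p_v = y[2], U = y[3];
    double p_LV = E * U;

    double ex = -A1 * (p_LV - p_e);
    if (ex > 700.0) ex = 700.0;
    double R_e = R_e0 * (1.0 + eps1 * exp(ex));
    if (R_e > R_eM) R_e = R_eM;

    double R_v = (p_v >= p_LV) ? R_v0 : R_eM;

    double f = cw_notch(*t);
    double Q_LVe = (p_LV - p_e) / R_e;
    double Q_ea  = (p_e - p_a) / R_a;
    double Q_av  = (p_a - p_v) / R_LV;
    double Q_vLV = (p_v - p_LV) / R_v;

    ydot[0] = (Q_LVe - Q_ea + f) / C_e;
    ydot[1] = (Q_ea - Q_av) / C_a;
    ydot[2] = (Q_av - Q_vLV) / C_v;
    ydot[3] = Q_vLV - Q_LVe - f;

    if (ip[0] >= 1) yout[0] = p_LV;
}

void cardiowave_root(int *neq, double *t, double *y, int *ng, double *gout,
                     double *out, int *ip)
{
    double g = cw_elastance(*t) * y[3] - y[0];
    int mode = (int) parms[20];
    if (mode == 0) {
        gout[0] = g;
        gout[1] = 1.0;
    } else if (mode == 1) {
        gout[0] = g - parms[21];
        gout[1] = 1.0;
    } else {
        gout[0] = g - parms[21];
        gout[1] = g - parms[22];
    }
}
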