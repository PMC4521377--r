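/* Compiled right-hand side of the two-compartment sensor shuttling model,
 * in the form expected by deSolve (initfunc + derivs).
 *
 * Parameter vector (set from R):
 *  0 k_phos, 1 k_dephos, 2 k_imp, 3 k_diff, 4 vol_ratio,
 *  5 A0, 6 Amax, 7 t_on, 8 tau_rise, 9 tau_decay (Inf = no decay),
 * 10 form (0 = constant activity, 1 = rise)
 *
 * State: amounts U_n, P_n, U_c, P_c; nucleus volume 1, cytoplasm volume
 * vol_ratio. See the R documentation for the reaction scheme.
 */

#include <R.h>
#include <Rmath.h>

static double parms[11];

#define K_PHOS    parms[0]
#define K_DEPHOS  parms[1]
#define K_IMP     parms[2]
#define K_DIFF    parms[3]
#define VOL_RATIO parms[4]
#define A0        parms[5]
#define AMAX      parms[6]
#define T_ON      parms[7]
#define TAU_RISE  parms[8]
#define TAU_DECAY parms[9]
#define FORM      parms[10]

void skars_initmod(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

static double activity(double t)
{
    double a, dt, decay;
    if (FORM < 0.5) {
        a = A0;
    } else {
        dt = t - T_ON;
        if (dt < 0) {
            a = A0;
        } else {
            decay = R_FINITE(TAU_DECAY) ? exp(-dt / TAU_DECAY) : 1.0;
            a = A0 + (AMAX - A0) * (1.0 - exp(-dt / TAU_RISE)) * decay;
        }
    }
    if (a < 0) a = 0;
    if (a > 1) a = 1;
    return a;
}

void skars_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double a = activity(*t);
    double un = y[0], pn = y[1];
    double uc = y[2] / VOL_RATIO, pc = y[3] / VOL_RATIO;
    double ju = K_DIFF * (uc - un);   /* net passive flux into nucleus */
    double jp = K_DIFF * (pc - pn);
    double imp = K_IMP * uc;
    double kp = K_PHOS * a;

    ydot[0] = -kp * y[0] + K_DEPHOS * y[1] + imp + ju;
    ydot[1] =  kp * y[0] - K_DEPHOS * y[1] + jp;
    ydot[2] = -kp * y[2] + K_DEPHOS * y[3] - imp - ju;
    ydot[3] =  kp * y[2] - K_DEPHOS * y[3] - jp;
}
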