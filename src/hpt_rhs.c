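/* Compiled right-hand side of the 19-compartment HPT-axis model.
 * Parameter order must match .ode_parm_names in R/parameters.R.
 * Amount states; concentration-dependent nonlinearities are evaluated at
 * volume-normalized amounts (x = q * Vref / Vnew) so the feedback senses
 * concentrations; TSH secretion scales with the TSH distribution volume.
 */
#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define NPARMS 56

static double parms[NPARMS];

#define S4        parms[0]
#define k12       parms[1]
#define k13       parms[2]
#define k31free   parms[3]
#define k21free   parms[4]
#define ftp_A     parms[5]
#define ftp_B     parms[6]
#define ftp_C     parms[7]
#define ftp_D     parms[8]
#define k4absorb  parms[9]
#define k02       parms[10]
#define VmaxD1f   parms[11]
#define KmD1f     parms[12]
#define VmaxD1s   parms[13]
#define KmD1s     parms[14]
#define VmaxD2s   parms[15]
#define KmD2s     parms[16]
#define S3        parms[17]
#define k45       parms[18]
#define k46       parms[19]
#define k64free   parms[20]
#define k54free   parms[21]
#define ft3_a     parms[22]
#define ft3_b     parms[23]
#define ft3_c     parms[24]
#define ft3_d     parms[25]
#define k3absorb  parms[26]
#define k05       parms[27]
#define B0        parms[28]
#define A0        parms[29]
#define phi       parms[30]
#define kdegTSH   parms[31]
#define VmaxTSH   parms[32]
#define K50TSH    parms[33]
#define k3        parms[34]
#define T4P_eu    parms[35]
#define T3P_eu    parms[36]
#define kdegT3B   parms[37]
#define KLAGh     parms[38]
#define KLAG      parms[39]
#define k4diss    parms[40]
#define k4excr    parms[41]
#define k3diss    parms[42]
#define k3excr    parms[43]
#define Vp        parms[44]
#define Vtsh      parms[45]
#define Kcirc     parms[46]
#define KSRTSH    parms[47]
#define hill_n    parms[48]
#define hill_m    parms[49]
#define Kf4       parms[50]
#define hill_l    parms[51]
#define rtf       parms[52]
#define infusion  parms[53]
#define circadian parms[54]
#define kdelay    parms[55]

void hpt_initparms(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void hpt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double q[19];
    int i;
    for (i = 0; i < 19; i++)
        q[i] = (y[i] > 0.0) ? y[i] : 0.0; /* clip integrator transients */

    double rp = 3.2 / Vp;
    double rt = 5.2 / Vtsh;
    double x1 = rp * q[0], x4 = rp * q[3], x7 = rt * q[6];

    double q1F = (ftp_A + ftp_B * x1 + ftp_C * x1 * x1 +
                  ftp_D * x1 * x1 * x1) * q[0];
    double q4F = (ft3_a + ft3_b * x1 + ft3_c * x1 * x1 +
                  ft3_d * x1 * x1 * x1) * q[3];
    double SR4 = rtf * S4 * q[18];
    double SR3 = rtf * S3 * q[18];

    double q9n = pow(q[8], hill_n);
    double fCIRC = q9n / (q9n + pow(Kcirc, hill_n));
    double osc = (circadian > 0.0) ? sin(M_PI / 12.0 * (*t) - phi) : 0.0;
    double Km = pow(KSRTSH, hill_m);
    double SRTSH = (B0 + A0 * fCIRC * osc) * Km / (Km + pow(q[8], hill_m));
    double fdegTSH = kdegTSH + VmaxTSH / (K50TSH + x7);
    double q8_11 = pow(q[7], 11.0);
    double fLAG = KLAGh + 2.0 * q8_11 / (q8_11 + pow(KLAG, 11.0));
    double Kl = pow(Kf4, hill_l);
    double f4 = k3 * (1.0 + 5.0 * Kl / (Kl + pow(q[7], hill_l)));
    double NL = VmaxD1f / (KmD1f + q[1]);
    double D1s = VmaxD1s / (KmD1s + q[2]);
    double D2s = VmaxD2s / (KmD2s + q[2]);

    ydot[0] = SR4 + k12 * q[1] + k13 * q[2] - (k31free + k21free) * q1F +
        k4absorb * q[10];
    ydot[1] = k21free * q1F - (k12 + k02 + NL) * q[1];
    ydot[2] = k31free * q1F - (k13 + D1s + D2s) * q[2];
    ydot[3] = SR3 + k45 * q[4] + k46 * q[5] - (k64free + k54free) * q4F +
        k3absorb * q[12] + infusion;
    ydot[4] = k54free * q4F + NL * q[1] - (k45 + k05) * q[4];
    ydot[5] = k64free * q4F + (D1s + D2s) * q[2] - k46 * q[5];
    ydot[6] = SRTSH / rt - fdegTSH * q[6];
    ydot[7] = f4 / T4P_eu * x1 + k3 / T3P_eu * x4 - kdegT3B * q[7];
    ydot[8] = fLAG * (q[7] - q[8]);
    ydot[9] = -k4diss * q[9];
    ydot[10] = k4diss * q[9] - (k4excr + k4absorb) * q[10];
    ydot[11] = -k3diss * q[11];
    ydot[12] = k3diss * q[11] - (k3excr + k3absorb) * q[12];
    ydot[13] = -kdelay * q[13] + q[6];
    ydot[14] = kdelay * (q[13] - q[14]);
    ydot[15] = kdelay * (q[14] - q[15]);
    ydot[16] = kdelay * (q[15] - q[16]);
    ydot[17] = kdelay * (q[16] - q[17]);
    ydot[18] = kdelay * (q[17] - q[18]);
}
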