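/* Right-hand side of the NER pathway ODE model, in the deSolve
 * compiled-code calling convention.
 *
 * State layout (base system, 26 equations):
 *   y[0..4]   D_s   : DNA intermediates I..V (local concentration, uM)
 *   y[5..24]  B_p   : bound factor pools, one per permitted factor x state
 *                     pair, column-major over states (20 pairs)
 *   y[25]     edu   : cumulative repair synthesis, integral of J_gamma
 *
 * The FLIP variant appends 20 labelled bound pools (y[26..45]) that
 * dissociate and are carried over with DNA-state conversions but never
 * rebind (photobleached free pool).
 *
 * Parameter vector (54 doubles, see R/ner-parameters.R):
 *   p[0..19]  kon per pair (uM^-1 min^-1), p[20..39] koff per pair (min^-1),
 *   p[40..44] alpha beta gamma delta epsilon (min^-1),
 *   p[45..51] totals per factor (uM), p[52] phi, p[53] lesions0 (uM).
 */

#include <R.h>

#define N_FACTOR 7
#define N_STATE  5
#define N_PAIR   20

/* factor order: XPC TFIIH XPG XPF XPA RPA PCNA
 * state order:  damaged unwound incised resynthesized rechromatinized */
static const int pair_f[N_PAIR] = {0, 1,
                                   0, 1, 2, 3, 4, 5,
                                   0, 1, 2, 3, 4, 5, 6,
                                   4, 5, 6,
                                   5, 6};
static const int pair_s[N_PAIR] = {0, 0,
                                   1, 1, 1, 1, 1, 1,
                                   2, 2, 2, 2, 2, 2, 2,
                                   3, 3, 3,
                                   4, 4};

static double parms[54];

void ner_init(void (*odeparms)(int *, double *))
{
    int n = 54;
    odeparms(&n, parms);
}

/* transitions: src, dst, flux index into J[] = {Ja, Jb, Jg, Jd, Je} */
static const int tr_src[5] = {0, 1, 2, 3, 1};
static const int tr_dst[5] = {1, 2, 3, 4, 0};

static void derivs_core(double *y, double *ydot, int with_flip)
{
    const double *kon = parms, *koff = parms + 20;
    double alpha = parms[40], beta = parms[41], gamma = parms[42],
           delta = parms[43], eps = parms[44];
    const double *totals = parms + 45;
    double phi = parms[52], lesions0 = parms[53];
    double epsD = 1e-10 * lesions0 + 1e-300;

    double D[N_STATE], th[N_FACTOR][N_STATE] = {{0}};
    double bound[N_FACTOR] = {0};
    int p, s, f, t;

    for (s = 0; s < N_STATE; s++)
        D[s] = y[s];
    for (p = 0; p < N_PAIR; p++) {
        double B = y[5 + p];
        double t = B / (D[pair_s[p]] + epsD);
        /* occupancies are probabilities; clamp integrator drift */
        if (t < 0.0) t = 0.0;
        if (t > 1.0) t = 1.0;
        th[pair_f[p]][pair_s[p]] = t;
        bound[pair_f[p]] += B;
    }

    double J[5]; /* Ja Jb Jg Jd Je */
    J[0] = alpha * D[0] * th[0][0] * th[1][0];
    J[1] = beta * D[1] * th[1][1] * th[2][1] * th[3][1] * th[4][1] * th[5][1];
    J[2] = gamma * D[2] * th[5][2] * th[6][2];
    J[3] = delta * D[3];
    J[4] = eps * D[1] * (1.0 - th[1][1]);

    ydot[0] = -J[0] + J[4];
    ydot[1] = J[0] - J[1] - J[4];
    ydot[2] = J[1] - J[2];
    ydot[3] = J[2] - J[3];
    ydot[4] = J[3];

    double out[N_STATE];
    out[0] = J[0];
    out[1] = J[1] + J[4];
    out[2] = J[2];
    out[3] = J[3];
    out[4] = 0.0;

    for (p = 0; p < N_PAIR; p++) {
        f = pair_f[p];
        s = pair_s[p];
        double B = y[5 + p];
        double freef = totals[f] - phi * bound[f];
        if (freef < 0.0)
            freef = 0.0;
        ydot[5 + p] = kon[p] * freef * (D[s] - B) - koff[p] * B
                      - out[s] * th[f][s];
    }
    for (t = 0; t < 5; t++)
        for (p = 0; p < N_PAIR; p++)
            if (pair_s[p] == tr_dst[t])
                ydot[5 + p] += J[t] * th[pair_f[p]][tr_src[t]];

    ydot[25] = J[2]; /* cumulative EdU incorporation */

    if (with_flip) {
        double lth[N_FACTOR][N_STATE] = {{0}};
        for (p = 0; p < N_PAIR; p++) {
            double t = y[26 + p] / (D[pair_s[p]] + epsD);
            if (t < 0.0) t = 0.0;
            if (t > 1.0) t = 1.0;
            lth[pair_f[p]][pair_s[p]] = t;
        }
        for (p = 0; p < N_PAIR; p++) {
            f = pair_f[p];
            s = pair_s[p];
            ydot[26 + p] = -koff[p] * y[26 + p] - out[s] * lth[f][s];
        }
        for (t = 0; t < 5; t++)
            for (p = 0; p < N_PAIR; p++)
                if (pair_s[p] == tr_dst[t])
                    ydot[26 + p] += J[t] * lth[pair_f[p]][tr_src[t]];
    }
}

void ner_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    derivs_core(y, ydot, 0);
}

void ner_flip_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    derivs_core(y, ydot, 1);
}
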