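/* Compiled right-hand side of the coupled sarcomere-ventricle-circulation-
 * pump system, in the deSolve compiled-model convention. Mirrors the
 * reference implementation in R/circulation.R (.model_core); the packed
 * parameter layout is produced by pack_params() in R/params.R. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 55
static double par[NPAR];

void lvad_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, par);
}

static double softplus_pos(double x, double k)
{
    if (k <= 0.0) return x > 0.0 ? x : 0.0;
    double z = x / k;
    if (z > 30.0) return x;
    return k * log1p(exp(z));
}

void lvad_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    /* calcium */
    const double ca_max = par[0], t1 = par[1], t2 = par[2],
                 base = par[3], period = par[4];
    const int literal = (int) par[5];
    /* sarcomere */
    const double y1 = par[6], z1 = par[7], y2 = par[8], z2 = par[9],
                 y3 = par[10], z3 = par[11], y4 = par[12], yd = par[13],
                 t_total = par[14], b = par[15], h_c = par[16],
                 l0s = par[17], l_a = par[18], r_curv = par[19],
                 a_scale = par[20], k_stiff = par[21];
    /* geometry */
    const double h_wall = par[22], r_0 = par[23], l0g = par[24],
                 conv = par[25];
    /* circulation */
    const double c_ao = par[26], c_art = par[27], c_vc = par[28],
                 c_pa = par[29], c_pv = par[30],
                 r_mv = par[31], r_av = par[32], r_tc = par[33],
                 r_pval = par[34], r_sys = par[35], r_pul = par[36],
                 r_conduit = par[37],
                 e_max_rv = par[38], e_min_rv = par[39], v0_rv = par[40],
                 t_sys_rv = par[41];
    /* pump + control */
    const int attach = (int) par[42];
    const double qc = par[43], lc = par[44], off = par[45],
                 fc1 = par[46], fc2 = par[47], lp = par[48];
    const int mode = (int) par[49];
    const double omega_mean = par[50], mod_frac = par[51], phase = par[52];
    const double pulse_width = par[53];
    const double smoothing = par[54];

    const double tca = y[0], tca_star = y[1], t_star = y[2], x = y[3];
    double v_lv = y[4];
    if (v_lv < 1e-9) v_lv = 1e-9;
    const double v_rv = y[5];
    const double p_ao = y[6] / c_ao, p_art = y[7] / c_art,
                 p_vc = y[8] / c_vc, p_pa = y[9] / c_pa,
                 p_pv = y[10] / c_pv, q_po = y[11];

    /* calcium transient (continuous or literal variant) */
    double tc = fmod(*t, period);
    if (tc < 0.0) tc += period;
    double ca;
    if (tc <= t1)
        ca = ca_max / 2.0 * (1.0 - cos(M_PI * tc / t1)) + base;
    else if (tc <= t2)
        ca = ca_max / 2.0 * (1.0 + cos(M_PI * (tc - t1) / (t2 - t1))) + base;
    else
        ca = literal ? 0.0 : base;

    /* left ventricle: volume -> radius -> length -> force -> pressure */
    const double r_lv = cbrt(3.0 * v_lv / (2.0 * M_PI));
    const double l = l0g * r_lv / r_0;

    const double t_free = t_total - tca - tca_star - t_star;
    const double dlm = l - l_a;
    const double eff = exp(-r_curv * dlm * dlm);
    const double d_x = b * (l - x - h_c);
    const double det = yd * d_x * d_x;
    const double d_tca = y1 * t_free * ca + z2 * tca_star
                         - (y2 * eff + z1) * tca;
    const double d_tca_star = y2 * eff * tca + z3 * t_star * ca
                              - (z2 + det + y3) * tca_star;
    const double d_t_star = y3 * tca_star - (z3 * ca + y4 + det) * t_star;

    const double fa = a_scale * (tca_star + t_star) * (l - x);
    const double fp = -k_stiff * (1.0 - l / l0s);
    const double p_lv = conv * 2.0 * (fa + fp) * h_wall / r_lv;

    /* right ventricle: time-varying elastance */
    double act = 0.0;
    if (tc < t_sys_rv)
        act = 0.5 * (1.0 - cos(2.0 * M_PI * tc / t_sys_rv));
    const double p_rv = (e_min_rv + (e_max_rv - e_min_rv) * act)
                        * (v_rv - v0_rv);

    /* valves and vascular flows (mL/s) */
    const double q_mv = softplus_pos(p_pv - p_lv, smoothing) / r_mv;
    const double q_av = softplus_pos(p_lv - p_ao, smoothing) / r_av;
    const double q_tc = softplus_pos(p_vc - p_rv, smoothing) / r_tc;
    const double q_pval = softplus_pos(p_rv - p_pa, smoothing) / r_pval;
    const double q_sys = (p_art - p_vc) / r_sys;
    const double q_pul = (p_pa - p_pv) / r_pul;

    /* pump speed program */
    double omega = omega_mean;
    if (mode != 0 && mod_frac > 0.0) {
        double shift = phase + (mode == 2 ? period / 2.0 : 0.0);
        double tw = fmod(*t - shift, period);
        if (tw < 0.0) tw += period;
        const double width = pulse_width > 0.0 ? pulse_width : t2;
        double w = (tw < width)
                   ? 0.5 * (1.0 - cos(2.0 * M_PI * tw / width)) : 0.0;
        omega = omega_mean * (1.0 + mod_frac * (w - 0.5 * width / period));
    }

    const double head = qc * omega * omega + lc * omega + off
                        - (fc1 * omega - fc2) * q_po;
    const double q_po_mls = q_po * 1000.0 / 60.0;
    double q_out, dq_po, q_bypass;
    if (attach == 1) {          /* series: aorta -> pump -> artery */
        q_out = q_po_mls;
        dq_po = (head - (p_art - p_ao)) / lp;
        q_bypass = 0.0;
    } else if (attach == 2) {   /* parallel: LV -> pump -> aorta */
        q_out = (p_ao - p_art) / r_conduit;
        dq_po = (head - (p_ao - p_lv)) / lp;
        q_bypass = q_po_mls;
    } else {                    /* unassisted */
        q_out = (p_ao - p_art) / r_conduit;
        dq_po = 0.0;
        q_bypass = 0.0;
    }

    ydot[0] = d_tca;
    ydot[1] = d_tca_star;
    ydot[2] = d_t_star;
    ydot[3] = d_x;
    ydot[4] = q_mv - q_av - q_bypass;
    ydot[5] = q_tc - q_pval;
    ydot[6] = q_av + q_bypass - q_out;
    ydot[7] = q_out - q_sys;
    ydot[8] = q_sys - q_tc;
    ydot[9] = q_pval - q_pul;
    ydot[10] = q_pul - q_mv;
    ydot[11] = dq_po;

    if (ip[0] >= 1) yout[0] = ca;
}

void R_init_lvadsim(DllInfo *info)
{
    /* deSolve resolves lvad_init / lvad_derivs by name at run time */
    R_registerRoutines(info, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
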