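# Tabulated state-variable constants of the calcium-transient and
# troponin/cross-bridge kinetics, reproduced verbatim with provenance notes.
# Units follow the table; y1 and z3 are printed as "uM s^-1" but multiply a
# calcium concentration in the kinetic equations, so they are bimolecular
# rates (uM^-1 s^-1) -- implemented as such for dimensional consistency with
# the Negroni--Lascano source model.
t1: {value: 40.6, unit: ms, note: time of peak calcium concentration}
t2: {value: 130.2, unit: ms, note: time calcium has fallen back to 0.1 uM}
ca_max: {value: 1.47, unit: uM, note: healthy peak amplitude above baseline}
y1: {value: 39, unit: uM^-1 s^-1, note: printed "uM s^-1"; bimolecular in Ca}
z1: {value: 30, unit: s^-1}
y2: {value: 1.3, unit: s^-1}
z2: {value: 1.3, unit: s^-1}
y3: {value: 30, unit: s^-1}
z3: {value: 1560, unit: uM^-1 s^-1, note: printed "uM s^-1"; bimolecular in Ca}
y4: {value: 40, unit: s^-1}
yd: {value: 8, unit: s um^-2}
t_total: {value: 70, unit: uM}
b: {value: 800, unit: s^-1}
h_c: {value: 0.005, unit: um}
l_0: {value: 1.17, unit: um}
# Constants the kinetic/force equations require but the table omits
# (optimal-overlap length l_a, overlap curvature r_curv, force scale a_scale,
# passive stiffness k_stiff): shipped in default_params.yaml, exposed for
# calibration.
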