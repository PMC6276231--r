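# Default parameter set for the multi-scale heart--LVAD model.
#
# Sarcomere kinetic constants and the calcium-transient timing are the
# tabulated Negroni--Lascano-type set (see table1_sarcomere.yaml for the
# per-constant provenance). Constants marked CALIBRATED below were produced
# by calibrate_baseline() against the healthy unassisted waveform targets
# (peak LVP 110 mmHg, aortic systolic/diastolic 95/70 mmHg) and are
# versioned data: edit via recalibration, not by hand.
calcium:
  ca_max: 1.47        # uM, healthy peak amplitude (HF 0.54, HF+beta-blocker 0.8)
  t1: 40.6            # ms, time of peak
  t2: 130.2           # ms, return to diastolic level
  baseline: 0.1       # uM, diastolic floor
  period: 0.8         # s, cardiac cycle
  literal: yes        # zero after t2 (printed piecewise form)
sarcomere:
  y1: 39.0            # uM^-1 s^-1, T + Ca binding
  z1: 30.0            # s^-1
  y2: 1.3             # s^-1, attachment (x overlap factor)
  z2: 1.3             # s^-1
  y3: 30.0            # s^-1
  z3: 1560.0          # uM^-1 s^-1, T* + Ca -> TCa*
  y4: 40.0            # s^-1
  yd: 8.0             # s um^-2, velocity-dependent detachment
  t_total: 70.0       # uM, total troponin
  b: 800.0            # s^-1, cross-bridge length relaxation
  h_c: 0.005          # um, equilibrium bridge elongation
  l_0: 1.17           # um, unstressed half-sarcomere length
  l_a: 1.17           # um, optimal-overlap length (literature default)
  r_curv: 2.6         # um^-2, overlap curvature (literature default)
  a_scale: 4954.8     # kPa/(uM um)  CALIBRATED
  k_stiff: 35.0       # kPa, passive stiffness
geometry:
  wall_thickness: 1.1 # cm
  r_0: 3.6            # cm, unstressed chamber radius
  l_0: 1.17           # um
  stress_to_pressure: 7.5006  # mmHg per kPa
circulation:          # compliances mL/mmHg, resistances mmHg s/mL
  c_ao: 0.6
  c_art: 1.0
  c_vc: 60.0
  c_pa: 2.0
  c_pv: 12.0
  r_mv: 0.016
  r_av: 0.05065       # CALIBRATED (sets the LVP - aortic systolic gap)
  r_tc: 0.024
  r_pval: 0.0055
  r_sys: 1.3352       # CALIBRATED
  r_pul: 0.08
  r_conduit: 0.02
  e_max_rv: 1.2       # mmHg/mL, RV end-systolic elastance
  e_min_rv: 0.04      # mmHg/mL
  v0_rv: 0.0          # mL
  t_sys_rv: 0.3       # s, RV activation duration
  total_blood_volume: 687.0  # mL stressed  CALIBRATED
pump:                 # pressure-head characteristic, speed in R/s, flow L/min
  quad_coeff: 0.0115
  lin_coeff: 0.079
  offset: -15.5
  flow_coeff_slope: 0.086
  flow_coeff_intercept: 0.58
  inertance: 0.05     # mmHg/((L/min)/s)
  omega_limit: 200.0  # R/s, carried but not applied
  attach: none        # unassisted baseline; series = intra-aortic pump
control:
  mode: constant
  omega_mean: 0.0     # R/s
  modulation_fraction: 0.3
  phase: 0.0          # s
  pulse_width: 0.25   # s, speed-pulse duration (mechanical systole)
valve_smoothing: 0.0  # mmHg; 0 = exact diode valves
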