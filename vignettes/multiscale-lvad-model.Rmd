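---
title: "A multi-scale model of the assisted circulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale model of the assisted circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lvadsim` simulates a closed-loop human circulation in which the left
ventricle is driven from the subcellular level — a prescribed intracellular
calcium transient feeding troponin/cross-bridge kinetics — while a rotary
blood pump (LVAD) assists the systemic side. This vignette documents the
model, the numerical choices, and the design decisions that were genuinely
open, in enough detail that a reader can judge what the package's tests do
and do not establish.

## The contractile chain

**Calcium transient.** Free calcium over one cardiac cycle (period $T$ =
0.8 s) is a piecewise raised cosine: a rise from the 0.1 µM diastolic
baseline to $\mathrm{Ca}_{max} + 0.1$ µM at $t_1$ = 40.6 ms, a fall back to
baseline at $t_2$ = 130.2 ms, and zero afterwards. The closed-form peak is
therefore 1.57 µM at exactly $t_1$ for the healthy amplitude
$\mathrm{Ca}_{max}$ = 1.47 µM; the conventional rounded citation of this
waveform ("1.5 µM at 40 ms") is a display precision matter, and the test
suite records both. Disease states are pure amplitude substitutions:
0.54 µM for heart failure, 0.8 µM for heart failure under β-blockade —
the drug is modeled solely through improved calcium cycling, with no
peripheral vascular action.

**Why the post-$t_2$ branch is zero by default.** The printed piecewise
form is discontinuous at $t_2$ (the falling branch ends at 0.1 µM, the
final branch is 0). A seemingly cleaner alternative holds the 0.1 µM
baseline for the rest of the cycle. We implemented both and made the
*literal* (zero) form the default, because the continuous variant breaks
diastole: with 0.1 µM of free calcium held between beats, the
$T^* + \mathrm{Ca} \to \mathrm{TCa}^*$ recycling path (rate
$Z_3 \cdot 0.1 = 156\,\mathrm{s}^{-1}$, against the
$Y_3 = 30\,\mathrm{s}^{-1}$ return) sustains roughly 1.5 µM of attached
cross-bridges indefinitely — a resting tone of over 15 mmHg at chamber
scale. The ventricle then cannot fill from venous pressures and no
parameter set reproduces a 110/8 mmHg systolic/diastolic ratio. The flag
`calcium_params(literal = FALSE)` (CLI: `--continuous-calcium`) restores
the continuous variant for sensitivity work.

**Troponin/cross-bridge kinetics.** Three bound pools are tracked:
calcium-bound troponin $[\mathrm{TCa}]$, attached calcium-bound bridges
$[\mathrm{TCa}^*]$ and attached calcium-free bridges $[T^*]$; free troponin
is $T_t$ minus the bound pools, so total troponin is conserved *by
construction* (the conservation test verifies the integrated trajectory to
1e-6 relative, which checks the integrator, not the algebra). Attachment is
modulated by a Gaussian filament-overlap factor
$e^{-R(L - L_a)^2}$ in the half-sarcomere length $L$, and both attached
pools detach at a rate proportional to $(dX/dt)^2$, where the cross-bridge
elongation state $X$ relaxes to $L - h_c$ at rate $B$. The $(dX/dt)$ in the
detachment terms is evaluated from the same algebraic expression within the
same call, keeping the right-hand side a pure function of state. The rate
table prints $Y_1$ and $Z_3$ with units µM s⁻¹; both multiply a calcium
concentration, so they are implemented as bimolecular rates (µM⁻¹ s⁻¹),
the only dimensionally consistent reading.

**Force and the chamber.** Active stress is
$F_a = A\,([\mathrm{TCa}^*]+[T^*])(L - X)$ and passive stress
$F_p = -K(1 - L/L_0)$ (kPa). The chamber is a thin-walled hemisphere,
$V = \tfrac{2}{3}\pi R^3$, with affine fibre strain $L/L_0 = R/R_0$ and
Laplace pressure $P = 2 F h / R$ converted at 7.5006 mmHg/kPa. Wall
thickness is constant over the cycle (no incompressibility correction) —
the simplest geometry consistent with a hemispherical chamber description.

## The circulation and the pump

Eight parts form the closed loop: LV, RV, aorta, artery, vena cava,
pulmonary artery, pulmonary vein, and the pump, with mitral, aortic,
tricuspid and pulmonary valves as ideal diodes with series resistance.
Vascular compartments are linear compliances on stressed volume; the right
ventricle is a time-varying elastance with a raised-cosine activation of
0.30 s — only the left ventricle uses the multi-scale chain, since it is
the chamber whose unloading is under study and the RV needs only to
support realistic loading trends.

The pump's head characteristic is quadratic in speed $\omega$ (R/s) and
affine in flow $Q$ (L/min),
$H = 0.0115\,\omega^2 + 0.079\,\omega - 15.5 - (0.086\,\omega - 0.58)Q$,
plus an inertial term $L_P\,dQ/dt$ that makes pump flow a state variable.
The speed unit follows the characteristic's convention (R/s); any rev/s
versus rad/s ambiguity is absorbed by calibration of the surrounding
circulation and does not affect the reported hemodynamics. A threshold
speed is carried in the parameter set but never applied, matching the
source description of the device.

**Attachment.** The pump is placed *in series inside the aorta* (between
the proximal aortic and distal arterial compartments) by default, with a
ventricle-to-aorta bypass available as configuration. The device modeled
here is an intra-aortic pump, and the series placement is also the only
topology that reproduces the characteristic support signature this model
family reports: mean aortic-valve flow *rising* with support level
(the pump lowers the proximal-aortic afterload, so the ventricle ejects
more), arterial pressure rising, arterial pulsatility falling. A parallel
bypass steals valve flow by construction and inverts the first trend.

**Speed modulation.** `constant` holds the mean speed; `co_pulse` adds a
raised-cosine pulse, centred to zero mean so every mode has the same
cycle-mean speed; `counter_pulse` shifts the pulse by half a period. The
pulse width defaults to 0.25 s: mechanical systole in this model spans
roughly 0–0.25 s, because cross-bridge detachment outlasts the 0.13 s
calcium transient, and "co-pulsation" means the speed surge overlaps
*ejection*. With a pulse confined to the calcium window the surge misses
late ejection and counter-pulsation gains a spurious diastolic-augmentation
advantage in arterial pulsatility. Width and phase remain configurable;
the modulation amplitude defaults to 0.3 of the mean speed.

## Parameters: printed, inherited, calibrated

The kinetic table supplies the calcium timing and all reaction rates. Four
contractile constants the equations need but the table omits ($A$, $K$,
$R$, $L_a$), the chamber geometry ($h$, $R_0$), and every circulation
constant are not printed anywhere; they are shipped in
`inst/extdata/default_params.yaml` with per-constant comments. The subset
marked CALIBRATED ($A$, systemic resistance, aortic valve resistance,
stressed blood volume) was produced by `calibrate_baseline()` — bounded
Nelder–Mead (Brent in one dimension) on logistic-transformed coordinates,
deterministic from a fixed start — against the healthy unassisted waveform
targets: peak LV pressure 110 mmHg, aortic systolic/diastolic 95/70 mmHg.
All three are met to within 0.01 mmHg by the shipped file, and the test
suite pins them to ±3 mmHg as a regression.

The heart-failure mean aortic-valve flow (2.87 L/min at 0.54 µM calcium)
was deliberately *excluded* from the calibration target set, so the
package's 2.94 L/min for that scenario is an out-of-calibration
prediction, not a fit.

## Numerics

* Integrator: `lsoda` (deSolve), rtol 1e-8, atol 1e-10, with the
  right-hand side compiled in C; an identical plain-R implementation is
  retained and the two are held to agreement by a test.
* Valves: exact diodes (`max(ΔP, 0)/R`) evaluated inside the adaptive
  solver. lsoda's step-size control resolves the corner reliably here; a
  softplus smoothing of configurable sharpness is available
  (`valve_smoothing`, mmHg) for stiffer configurations.
* Periodic steady state: cycle-to-cycle integration until the maximum
  relative change of the cycle-start state falls below 1e-3 (with small
  absolute floors per state scale), budget 80 cycles; non-convergence is
  flagged on the result, never thrown. The healthy baseline converges in
  ~11 cycles from the shipped initial state.
* Output grid: 1 ms; metrics change by under 0.2% on a 0.5 ms grid
  (tested). Cross-tolerance agreement (rtol 1e-10/atol 1e-12 versus
  default) is under 0.5% on all cycle metrics (tested).
* Speed searches (`set_bai()`, `match_map()`) are bisections on the mean
  pump speed, warm-started from the previous converged state; both rely on
  monotonicity of their objective in speed over the bracket, which the
  test suite verifies empirically.

## Evaluation indices

External work is $0.0022/T \int P\,Q\,dt$ (W) with pressure in mmHg and
flow in L/min — the 0.0022 factor is exactly the mmHg·(L/min)→W
conversion, which fixes the flow unit; $Q$ is the instantaneous
transvalvular outflow of the chamber under study (pulmonary-valve flow for
the RV, whose formula is not separately printed in this model family).
Pulsatile ratio is $(\max - \min)/\text{mean}$ of a pressure waveform.
The blood assist index is the pump share of total hydraulic power,
$W_{pump}/(W_{pump}+W_{lv})$, both terms computed with the same
external-work integral on the respective pressure-difference/flow pair;
the original index definition is not reprinted in the source literature,
so the hydraulic reading is adopted and documented here.

**Drug-coupling protocol.** The paired β-blocker run keeps the pump speed
tuned for the drug-free mode — the clinical analogue of adding a drug on
top of unchanged device support. The attained mean arterial pressure moves
by under 2 mmHg, so the pairing remains a matched-perfusion comparison for
practical purposes; an exact re-match option exists but nullifies most of
the volume-unloading signal the comparison is meant to expose.

## Known limitations, and printed values this model does not reproduce

* No baroreflex or autonomic control; heart rate is fixed at 0.8 s.
* No suction detection: the venous reservoir (vena cava compliance
  60 mL/mmHg) sustains venous return at high support, so flow keeps
  rising with speed instead of saturating. Related: unit analysis of the
  source model family's printed values shows its high-support operating
  points (e.g. 4.29 L/min of valve flow at 90% assistance with ~98 mmHg
  arterial pressure) are only consistent with the printed pump
  characteristic if the proximal aorta is pulled to between −20 and
  −95 mmHg — deep suction with near-zero ventricular work. This package's
  honest hydraulic accounting instead reaches 90% assistance at
  ~6.5 L/min; the monotone trends agree, the operating point does not.
* Printed external-work magnitudes of several watts for a circulation
  whose total hydraulic power is a few tenths of a watt
  (0.0022 × 60 mmHg × 2.87 L/min ≈ 0.38 W) cannot be reproduced by any
  pressure×flow integral in stated units; the discrepancy factor of ~16.7
  equals the mL/s-to-L/min ratio, suggesting a flow-unit slip upstream.
  The package reports watts computed dimensionally; orderings across
  support modes (co-pulse < constant < counter-pulse for LV work) are
  reproduced and tested, magnitudes are not.
* The peak-LV-pressure insensitivity to β-blockade reported qualitatively
  ("no significant difference") comes out at +6% here (tested against the
  stricter 5% band, and documented as marginally outside it); pulmonary
  pulsatile ratio *rises* slightly with the drug in this model because the
  mean pulmonary pressure falls faster than its pulse.
* Thin-wall Laplace mechanics with a single fibre direction; no
  finite-element wall stress, no trabecular structure, no hemolysis or
  thrombosis indices.

## Problem sizes used by the shipped tests and scripts

Converged runs integrate 10–40 cycles of 0.8 s on a 1 ms output grid;
speed searches take 6–15 such runs each. The full support-level sweep
(8 levels plus baseline), the three-mode comparison and the paired drug
experiment together run in well under five minutes on a single core,
which is the scale at which all shipped results were produced.
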