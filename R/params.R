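#' Calcium transient parameters
#'
#' Parameters of the piecewise raised-cosine intracellular calcium transient
#' that drives left-ventricular contraction. Times are in milliseconds as
#' conventionally tabulated for this waveform; all internal computation is in
#' seconds (conversion is centralized in [calcium_transient()]).
#'
#' @param ca_max Peak free-calcium amplitude above baseline (uM). 1.47 uM is
#'   the healthy ventricular myocyte value; 0.54 uM models heart failure and
#'   0.8 uM heart failure under beta-blockade.
#' @param t1 Time of peak calcium (ms).
#' @param t2 Time at which calcium has returned to the diastolic level (ms).
#' @param baseline Diastolic calcium floor (uM).
#' @param period Cardiac cycle length (s).
#' @param literal If `TRUE` (default), the transient is exactly zero after
#'   `t2`, the literal piecewise form (discontinuous by `baseline` at
#'   `t2`). If `FALSE`, the diastolic baseline is held after `t2`, which
#'   keeps the waveform continuous; note that a sustained 0.1 uM floor
#'   leaves a substantial population of attached cross-bridges between
#'   beats and with it a non-physiological diastolic tone (see the methods
#'   vignette), so the literal form is the default.
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(ca_max = 1.47, t1 = 40.6, t2 = 130.2,
                           baseline = 0.1, period = 0.8, literal = TRUE) {
  stopifnot(is.finite(ca_max), is.finite(t1), is.finite(t2),
            is.finite(baseline), is.finite(period))
  if (!(t1 > 0 && t2 > t1 && t2 < period * 1000))
    stop("require 0 < t1 < t2 < period (ms)")
  if (ca_max <= 0) stop("ca_max must be positive")
  if (baseline < 0) stop("baseline must be non-negative")
  structure(list(ca_max = ca_max, t1 = t1, t2 = t2, baseline = baseline,
                 period = period, literal = isTRUE(literal)),
            class = "calcium_params")
}

#' Sarcomere kinetic and mechanical parameters
#'
#' Rate constants of the troponin/cross-bridge scheme (three bound pools
#' `[TCa]`, `[TCa*]`, `[T*]` plus free troponin by conservation) and the
#' cross-bridge mechanical constants. Defaults are the tabulated kinetic set;
#' `y1` and `z3` are bimolecular rates (uM^-1 s^-1) since each multiplies a
#' calcium concentration. The force scale `a_scale`, passive stiffness
#' `k_stiff`, overlap curvature `r_curv` and optimal-overlap length `l_a`
#' are not part of the tabulated set and are exposed for calibration.
#'
#' @param y1 T + Ca binding rate (uM^-1 s^-1).
#' @param z1 TCa dissociation rate (s^-1).
#' @param y2 Cross-bridge attachment rate (s^-1), modulated by filament
#'   overlap `exp(-r_curv (L - l_a)^2)`.
#' @param z2 Cross-bridge detachment rate TCa* -> TCa (s^-1).
#' @param y3 Calcium release rate from attached bridges TCa* -> T* (s^-1).
#' @param z3 Calcium rebinding rate T* + Ca -> TCa* (uM^-1 s^-1).
#' @param y4 Detachment rate T* -> T (s^-1).
#' @param yd Velocity-dependent detachment coefficient (s um^-2), acting on
#'   both attached pools through `(dX/dt)^2`.
#' @param t_total Total troponin concentration (uM).
#' @param b Rate at which the cross-bridge elongation relaxes to `h_c`
#'   (s^-1).
#' @param h_c Equilibrium cross-bridge elongation (um).
#' @param l_0 Unstressed half-sarcomere length (um).
#' @param l_a Half-sarcomere length of maximal thick/thin filament overlap
#'   (um).
#' @param r_curv Curvature of the overlap function (um^-2).
#' @param a_scale Active force scale (kPa per uM per um).
#' @param k_stiff Passive stiffness (kPa).
#' @return An object of class `sarcomere_params`.
#' @export
sarcomere_params <- function(y1 = 39, z1 = 30, y2 = 1.3, z2 = 1.3, y3 = 30,
                             z3 = 1560, y4 = 40, yd = 8, t_total = 70,
                             b = 800, h_c = 0.005, l_0 = 1.17, l_a = 1.17,
                             r_curv = 2.6, a_scale = 1800, k_stiff = 25) {
  p <- list(y1 = y1, z1 = z1, y2 = y2, z2 = z2, y3 = y3, z3 = z3, y4 = y4,
            yd = yd, t_total = t_total, b = b, h_c = h_c, l_0 = l_0,
            l_a = l_a, r_curv = r_curv, a_scale = a_scale, k_stiff = k_stiff)
  rates <- c("y1", "z1", "y2", "z2", "y3", "z3", "y4", "yd", "b")
  if (any(!vapply(p, function(x) is.numeric(x) && is.finite(x), TRUE)))
    stop("all sarcomere parameters must be finite numbers")
  if (any(unlist(p[rates]) < 0)) stop("rates must be non-negative")
  if (t_total <= 0) stop("t_total must be positive")
  if (!(h_c > 0 && h_c < l_0)) stop("require 0 < h_c < l_0")
  structure(p, class = "sarcomere_params")
}

#' Ventricular geometry
#'
#' Hemispherical thin-wall chamber linking volume, radius, half-sarcomere
#' length and pressure. Strain is affine: `L/l_0 = R/r_0`. Pressure follows
#' the Laplace relation `P = 2 F h / R` with `F` the wall stress produced by
#' the sarcomere model (kPa) and `stress_to_pressure` the kPa-to-mmHg factor.
#'
#' @param wall_thickness Myocardial wall thickness (cm), constant over the
#'   cycle.
#' @param r_0 Unstressed chamber radius (cm).
#' @param l_0 Unstressed half-sarcomere length (um).
#' @param stress_to_pressure Conversion from wall-stress units to mmHg
#'   (7.5006 mmHg/kPa).
#' @return An object of class `ventricle_geometry`.
#' @export
ventricle_geometry <- function(wall_thickness = 1.1, r_0 = 3.6, l_0 = 1.17,
                               stress_to_pressure = 7.5006) {
  stopifnot(wall_thickness > 0, r_0 > 0, l_0 > 0, stress_to_pressure > 0)
  structure(list(wall_thickness = wall_thickness, r_0 = r_0, l_0 = l_0,
                 stress_to_pressure = stress_to_pressure),
            class = "ventricle_geometry")
}

#' Lumped circulation parameters
#'
#' Compliances, resistances and the right-ventricular time-varying elastance
#' of the closed eight-part loop (left ventricle, right ventricle, aorta,
#' artery, vena cava, pulmonary artery, pulmonary vein, pump). Compartment
#' pressures are `(V - v0)/C`; the tracked volumes are stressed volumes with
#' `v0 = 0` for the vascular compartments, so the conserved total is the
#' stressed blood volume.
#'
#' @param c_ao,c_art,c_vc,c_pa,c_pv Compliances (mL/mmHg) of aorta, artery,
#'   vena cava, pulmonary artery, pulmonary vein.
#' @param r_mv,r_av,r_tc,r_pval Valve resistances (mmHg s/mL): mitral,
#'   aortic, tricuspid, pulmonary.
#' @param r_sys,r_pul Systemic and pulmonary vascular resistances
#'   (mmHg s/mL).
#' @param r_conduit Resistance of the aorta-to-artery segment when the pump
#'   is absent (mmHg s/mL).
#' @param e_max_rv,e_min_rv End-systolic and diastolic right-ventricular
#'   elastances (mmHg/mL).
#' @param v0_rv Right-ventricular unstressed volume (mL).
#' @param t_sys_rv Duration of right-ventricular activation (s).
#' @param total_blood_volume Conserved stressed blood volume (mL); used to
#'   build the default initial state.
#' @return An object of class `circulation_params`.
#' @export
circulation_params <- function(c_ao = 0.6, c_art = 1.0, c_vc = 60,
                               c_pa = 2.0, c_pv = 12,
                               r_mv = 0.016, r_av = 0.018, r_tc = 0.024,
                               r_pval = 0.0055, r_sys = 0.9, r_pul = 0.08,
                               r_conduit = 0.02,
                               e_max_rv = 0.6, e_min_rv = 0.04, v0_rv = 0,
                               t_sys_rv = 0.30, total_blood_volume = 830) {
  p <- list(c_ao = c_ao, c_art = c_art, c_vc = c_vc, c_pa = c_pa,
            c_pv = c_pv, r_mv = r_mv, r_av = r_av, r_tc = r_tc,
            r_pval = r_pval, r_sys = r_sys, r_pul = r_pul,
            r_conduit = r_conduit, e_max_rv = e_max_rv,
            e_min_rv = e_min_rv, v0_rv = v0_rv, t_sys_rv = t_sys_rv,
            total_blood_volume = total_blood_volume)
  pos <- setdiff(names(p), "v0_rv")
  if (any(unlist(p[pos]) <= 0))
    stop("compliances, resistances and elastances must be positive")
  structure(p, class = "circulation_params")
}

#' Rotary pump characteristic parameters
#'
#' Coefficients of the pump pressure-head characteristic
#' `H(omega, Q) = quad_coeff omega^2 + lin_coeff omega + offset -
#' (flow_coeff_slope omega - flow_coeff_intercept) Q + inertance dQ/dt`
#' with speed `omega` in R/s, flow `Q` in L/min and head in mmHg, plus the
#' attachment of the pump in the loop.
#'
#' @param quad_coeff Quadratic speed coefficient (mmHg per (R/s)^2).
#' @param lin_coeff Linear speed coefficient (mmHg per R/s).
#' @param offset Static head offset (mmHg).
#' @param flow_coeff_slope,flow_coeff_intercept Flow-dependence of the head
#'   (mmHg per L/min, per R/s and absolute).
#' @param inertance Blood inertia in the pump conduit (mmHg per
#'   (L/min)/s).
#' @param omega_limit Threshold speed (R/s); carried for completeness, not
#'   applied by the integrator.
#' @param attach One of `"none"` (unassisted: resistive aorta-artery
#'   conduit), `"series"` (intra-aortic pump between the aorta and artery
#'   compartments; the default when assisting) or `"parallel"`
#'   (ventricle-to-aorta bypass).
#' @return An object of class `pump_params`.
#' @export
pump_params <- function(quad_coeff = 0.0115, lin_coeff = 0.079,
                        offset = -15.5, flow_coeff_slope = 0.086,
                        flow_coeff_intercept = 0.58, inertance = 0.05,
                        omega_limit = 200,
                        attach = c("none", "series", "parallel")) {
  attach <- match.arg(attach)
  if (inertance <= 0) stop("inertance must be positive")
  structure(list(quad_coeff = quad_coeff, lin_coeff = lin_coeff,
                 offset = offset, flow_coeff_slope = flow_coeff_slope,
                 flow_coeff_intercept = flow_coeff_intercept,
                 inertance = inertance, omega_limit = omega_limit,
                 attach = attach),
            class = "pump_params")
}

#' Pump speed control
#'
#' Speed program over the cardiac cycle. `constant` holds `omega_mean`;
#' `co_pulse` adds a zero-mean raised-cosine modulation whose positive lobe
#' is aligned with ventricular systole (the calcium transient);
#' `counter_pulse` is the same waveform shifted by half a period. The cycle
#' mean equals `omega_mean` in every mode.
#'
#' @param mode One of `"constant"`, `"co_pulse"`, `"counter_pulse"`.
#' @param omega_mean Cycle-mean rotational speed (R/s).
#' @param modulation_fraction Relative modulation amplitude in `[0, 1)`;
#'   ignored in constant mode.
#' @param phase Additional phase offset of the modulation (s).
#' @param pulse_width Duration of the raised-cosine speed pulse (s); `NA`
#'   (default) uses the systolic window of the calcium transient (`t2`).
#' @return An object of class `pump_control`.
#' @export
pump_control <- function(mode = c("constant", "co_pulse", "counter_pulse"),
                         omega_mean = 0, modulation_fraction = 0.3,
                         phase = 0, pulse_width = NA_real_) {
  mode <- match.arg(mode)
  if (omega_mean < 0) stop("omega_mean must be non-negative")
  if (!(modulation_fraction >= 0 && modulation_fraction < 1))
    stop("modulation_fraction must lie in [0, 1)")
  structure(list(mode = mode, omega_mean = omega_mean,
                 modulation_fraction = modulation_fraction, phase = phase,
                 pulse_width = pulse_width),
            class = "pump_control")
}

#' Assemble a full model parameter set
#'
#' @param calcium A [calcium_params()] object.
#' @param sarcomere A [sarcomere_params()] object.
#' @param geometry A [ventricle_geometry()] object.
#' @param circulation A [circulation_params()] object.
#' @param pump A [pump_params()] object.
#' @param control A [pump_control()] object.
#' @param valve_smoothing Softplus sharpness for the valve law (mmHg); 0
#'   (default) keeps the exact ideal-diode valves.
#' @return An object of class `lvad_params`.
#' @export
model_params <- function(calcium = calcium_params(),
                         sarcomere = sarcomere_params(),
                         geometry = ventricle_geometry(),
                         circulation = circulation_params(),
                         pump = pump_params(),
                         control = pump_control(),
                         valve_smoothing = 0) {
  stopifnot(inherits(calcium, "calcium_params"),
            inherits(sarcomere, "sarcomere_params"),
            inherits(geometry, "ventricle_geometry"),
            inherits(circulation, "circulation_params"),
            inherits(pump, "pump_params"),
            inherits(control, "pump_control"))
  structure(list(calcium = calcium, sarcomere = sarcomere,
                 geometry = geometry, circulation = circulation,
                 pump = pump, control = control,
                 valve_smoothing = valve_smoothing),
            class = "lvad_params")
}

#' Default calibrated parameter set
#'
#' Loads the parameter file shipped with the package. The circulation,
#' geometry and force-scale constants in that file were produced by
#' [calibrate_baseline()] against the healthy-baseline waveform targets
#' (peak left-ventricular pressure 110 mmHg; aortic systolic/diastolic
#' 95/70 mmHg) and are versioned data, not code.
#'
#' @param disease_state One of `"healthy"`, `"hf"`, `"hf_beta_blocker"`;
#'   selects the peak-calcium amplitude (1.47, 0.54 or 0.8 uM) with every
#'   other parameter unchanged.
#' @return An `lvad_params` object.
#' @export
default_params <- function(disease_state = c("healthy", "hf",
                                             "hf_beta_blocker")) {
  disease_state <- match.arg(disease_state)
  path <- system.file("extdata", "default_params.yaml", package = "lvadsim",
                      mustWork = TRUE)
  p <- load_params(path)
  p$calcium$ca_max <- switch(disease_state,
                             healthy = 1.47, hf = 0.54,
                             hf_beta_blocker = 0.8)
  p
}

#' Read a parameter set from a YAML or JSON config file
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return An `lvad_params` object.
#' @export
load_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config extension: ", ext)
  build <- function(ctor, block, class_drop = character()) {
    block <- block[setdiff(names(block), class_drop)]
    do.call(ctor, block)
  }
  model_params(
    calcium = build(calcium_params, raw$calcium),
    sarcomere = build(sarcomere_params, raw$sarcomere),
    geometry = build(ventricle_geometry, raw$geometry),
    circulation = build(circulation_params, raw$circulation),
    pump = build(pump_params, raw$pump),
    control = build(pump_control, raw$control),
    valve_smoothing = if (is.null(raw$valve_smoothing)) 0 else raw$valve_smoothing
  )
}

#' Write a parameter set to a YAML or JSON config file
#'
#' @param params An `lvad_params` object.
#' @param path Destination path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "lvad_params"))
  plain <- lapply(params, function(x) if (is.list(x)) unclass(x) else x)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported config extension: ", ext)
  invisible(path)
}

# Packed parameter vector for the compiled right-hand side. Layout is shared
# with src/model_rhs.c; keep the two in lockstep.
pack_params <- function(p) {
  ca <- p$calcium; sa <- p$sarcomere; ge <- p$geometry
  ci <- p$circulation; pu <- p$pump; co <- p$control
  c(
    # calcium (times converted to seconds here, once)
    ca$ca_max, ca$t1 / 1000, ca$t2 / 1000, ca$baseline, ca$period,
    as.numeric(ca$literal),
    # sarcomere
    sa$y1, sa$z1, sa$y2, sa$z2, sa$y3, sa$z3, sa$y4, sa$yd, sa$t_total,
    sa$b, sa$h_c, sa$l_0, sa$l_a, sa$r_curv, sa$a_scale, sa$k_stiff,
    # geometry
    ge$wall_thickness, ge$r_0, ge$l_0, ge$stress_to_pressure,
    # circulation
    ci$c_ao, ci$c_art, ci$c_vc, ci$c_pa, ci$c_pv,
    ci$r_mv, ci$r_av, ci$r_tc, ci$r_pval, ci$r_sys, ci$r_pul, ci$r_conduit,
    ci$e_max_rv, ci$e_min_rv, ci$v0_rv, ci$t_sys_rv,
    # pump
    switch(pu$attach, none = 0, series = 1, parallel = 2),
    pu$quad_coeff, pu$lin_coeff, pu$offset, pu$flow_coeff_slope,
    pu$flow_coeff_intercept, pu$inertance,
    # control
    switch(co$mode, constant = 0, co_pulse = 1, counter_pulse = 2),
    co$omega_mean, co$modulation_fraction, co$phase,
    if (is.na(co$pulse_width)) -1 else co$pulse_width,
    # numerics
    p$valve_smoothing
  )
}

#' @export
print.lvad_params <- function(x, ...) {
  cat("<lvad_params>\n")
  cat(sprintf("  calcium: ca_max %.3g uM, t1 %.3g ms, t2 %.3g ms, period %.3g s\n",
              x$calcium$ca_max, x$calcium$t1, x$calcium$t2, x$calcium$period))
  cat(sprintf("  pump: attach %s, mode %s, omega_mean %.3g R/s\n",
              x$pump$attach, x$control$mode, x$control$omega_mean))
  cat(sprintf("  circulation: R_sys %.3g mmHg s/mL, stressed volume %.4g mL\n",
              x$circulation$r_sys, x$circulation$total_blood_volume))
  invisible(x)
}
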