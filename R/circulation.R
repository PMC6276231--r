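# State vector layout (shared with src/model_rhs.c):
#   1 tca, 2 tca_star, 3 t_star (uM), 4 x (um),
#   5 v_lv, 6 v_rv, 7 v_ao, 8 v_art, 9 v_vc, 10 v_pa, 11 v_pv (mL),
#   12 q_po (L/min)
.state_names <- c("tca", "tca_star", "t_star", "x", "v_lv", "v_rv", "v_ao",
                  "v_art", "v_vc", "v_pa", "v_pv", "q_po")

#' Valve flow (ideal diode)
#'
#' Forward flow through a valve of resistance `r_valve` under a pressure
#' difference `delta_p`; reverse flow is blocked. With `smoothing > 0` the
#' positive-part is replaced by a softplus of that sharpness (mmHg), a
#' smooth approximation useful for stiff integrators.
#'
#' @param delta_p Pressure difference upstream minus downstream (mmHg);
#'   vectorized.
#' @param r_valve Valve resistance (mmHg s/mL), positive.
#' @param smoothing Softplus scale in mmHg; 0 for the exact diode.
#' @return Flow (mL/s), never negative.
#' @export
valve_flow <- function(delta_p, r_valve, smoothing = 0) {
  if (r_valve <= 0) stop("valve resistance must be positive")
  if (smoothing > 0) {
    # numerically safe softplus: k log(1 + exp(x/k))
    z <- delta_p / smoothing
    sp <- smoothing * ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
    sp / r_valve
  } else {
    pmax(delta_p, 0) / r_valve
  }
}

#' Pump pressure head
#'
#' Static plus inertial head of the rotary pump:
#' `H = quad_coeff w^2 + lin_coeff w + offset - (flow_coeff_slope w -
#' flow_coeff_intercept) q + inertance dq_dt`.
#'
#' @param omega Rotational speed (R/s), non-negative.
#' @param q Pump flow (L/min).
#' @param dq_dt Rate of change of pump flow (L/min per s).
#' @param p A [pump_params()] object.
#' @return Pressure head (mmHg).
#' @export
pump_pressure_head <- function(omega, q, dq_dt = 0, p = pump_params()) {
  if (any(omega < 0)) stop("omega must be non-negative")
  p$quad_coeff * omega^2 + p$lin_coeff * omega + p$offset -
    (p$flow_coeff_slope * omega - p$flow_coeff_intercept) * q +
    p$inertance * dq_dt
}

#' Pump speed waveform
#'
#' Speed program over the cycle. The modulation waveform is a raised-cosine
#' pulse spanning the systolic interval `[0, t2]` of the calcium transient,
#' centred to zero mean so the cycle-mean speed equals `omega_mean` in
#' every mode; counter-pulse shifts the pulse by half a period.
#'
#' @param t Time (s), vectorized; interpreted modulo the period.
#' @param control A [pump_control()] object.
#' @param calcium A [calcium_params()] object supplying the period and the
#'   systolic window.
#' @return Speed (R/s).
#' @export
speed_waveform <- function(t, control, calcium = calcium_params()) {
  stopifnot(inherits(control, "pump_control"),
            inherits(calcium, "calcium_params"))
  if (control$mode == "constant" || control$modulation_fraction == 0)
    return(rep(control$omega_mean, length(t)))
  period <- calcium$period
  shift <- control$phase + if (control$mode == "counter_pulse") period / 2 else 0
  tc <- (t - shift) %% period
  width <- if (is.null(control$pulse_width) || is.na(control$pulse_width))
    calcium$t2 / 1000 else control$pulse_width  # systolic window (s)
  w <- ifelse(tc < width, 0.5 * (1 - cos(2 * pi * tc / width)), 0)
  w_mean <- 0.5 * width / period      # cycle mean of the pulse
  control$omega_mean * (1 + control$modulation_fraction * (w - w_mean))
}

# Core model algebra: pressures, flows and state derivatives at one instant.
# Returns list(deriv, aux). Used by the reference R right-hand side and by
# the waveform post-processor; the compiled C right-hand side mirrors it.
.model_core <- function(t, y, p) {
  ci <- p$circulation; ge <- p$geometry; sa <- p$sarcomere
  sm <- p$valve_smoothing
  y <- unname(y)

  tca <- y[1]; tca_star <- y[2]; t_star <- y[3]; x <- y[4]
  v_lv <- max(y[5], 1e-9); v_rv <- y[6]
  p_ao <- y[7] / ci$c_ao; p_art <- y[8] / ci$c_art; p_vc <- y[9] / ci$c_vc
  p_pa <- y[10] / ci$c_pa; p_pv <- y[11] / ci$c_pv
  q_po <- y[12]

  # left ventricle: volume -> radius -> length -> force -> pressure
  r_lv <- (3 * v_lv / (2 * pi))^(1 / 3)
  l <- ge$l_0 * r_lv / ge$r_0
  ca <- calcium_transient(t, p$calcium)
  ds <- sarcomere_rhs(list(tca = tca, tca_star = tca_star, t_star = t_star,
                           x = x), ca, l, sa)
  f <- sarcomere_force(list(tca_star = tca_star, t_star = t_star, x = x),
                       l, sa)
  p_lv <- pressure_from_force(f[["total"]], r_lv, ge)

  # right ventricle: time-varying elastance
  tc <- t %% p$calcium$period
  act <- if (tc < ci$t_sys_rv) 0.5 * (1 - cos(2 * pi * tc / ci$t_sys_rv)) else 0
  e_rv <- ci$e_min_rv + (ci$e_max_rv - ci$e_min_rv) * act
  p_rv <- e_rv * (v_rv - ci$v0_rv)

  # valves
  q_mv <- valve_flow(p_pv - p_lv, ci$r_mv, sm)
  q_av <- valve_flow(p_lv - p_ao, ci$r_av, sm)
  q_tc <- valve_flow(p_vc - p_rv, ci$r_tc, sm)
  q_pval <- valve_flow(p_rv - p_pa, ci$r_pval, sm)
  q_sys <- (p_art - p_vc) / ci$r_sys
  q_pul <- (p_pa - p_pv) / ci$r_pul

  omega <- speed_waveform(t, p$control, p$calcium)
  attach <- p$pump$attach
  q_po_mls <- q_po * 1000 / 60
  head_static <- pump_pressure_head(omega, q_po, 0, p$pump)

  if (attach == "series") {
    q_out <- q_po_mls                       # aorta -> artery through pump
    dq_po <- (head_static - (p_art - p_ao)) / p$pump$inertance
    q_bypass <- 0
  } else if (attach == "parallel") {
    q_out <- (p_ao - p_art) / ci$r_conduit
    dq_po <- (head_static - (p_ao - p_lv)) / p$pump$inertance
    q_bypass <- q_po_mls                    # LV -> aorta through pump
  } else {
    q_out <- (p_ao - p_art) / ci$r_conduit
    dq_po <- 0
    q_bypass <- 0
  }

  dv_lv <- q_mv - q_av - q_bypass
  deriv <- c(ds[["d_tca"]], ds[["d_tca_star"]], ds[["d_t_star"]],
             ds[["d_x"]],
             dv_lv,
             q_tc - q_pval,
             q_av + q_bypass - q_out,
             q_out - q_sys,
             q_sys - q_tc,
             q_pval - q_pul,
             q_pul - q_mv,
             dq_po)

  aux <- c(p_lv = p_lv, p_rv = p_rv, p_ao = p_ao, p_art = p_art,
           p_vc = p_vc, p_pa = p_pa, p_pv = p_pv,
           q_mv = q_mv, q_av = q_av, q_tc = q_tc, q_pval = q_pval,
           q_sys = q_sys, q_pul = q_pul, q_pump = q_po,
           omega = omega, ca = ca, l = l,
           f_active = f[["active"]], f_passive = f[["passive"]],
           f_total = f[["total"]],
           pump_dp = if (attach == "series") p_art - p_ao
                     else if (attach == "parallel") p_ao - p_lv else 0)
  list(deriv = deriv, aux = aux)
}

#' Full system right-hand side
#'
#' Assembles the state derivatives of the coupled sarcomere-ventricle-
#' circulation-pump system at one instant: left-ventricular pressure from
#' the multi-scale chain, right-ventricular pressure from a time-varying
#' elastance, compartment pressures from compliances, valve and vascular
#' flows, and the pump-flow equation rearranged for `dq/dt`. The sum of all
#' volume derivatives is identically zero (closed loop).
#'
#' @param t Time (s).
#' @param y State vector (see [initial_state()] for the layout).
#' @param params An `lvad_params` object.
#' @return List with the derivative vector and named auxiliary outputs
#'   (pressures mmHg, flows mL/s, pump flow L/min, speed, calcium, length,
#'   forces), in the deSolve convention.
#' @export
system_rhs <- function(t, y, params) {
  if (any(!is.finite(y))) stop("non-finite state passed to system_rhs")
  core <- .model_core(t, y, params)
  list(core$deriv, core$aux)
}

#' Default initial state
#'
#' A physiologically ordered distribution of the stressed blood volume over
#' the compartments, with the sarcomere at rest. Any initial state with the
#' same total volume converges to the same periodic orbit.
#'
#' @param params An `lvad_params` object.
#' @return Named state vector.
#' @export
initial_state <- function(params) {
  ci <- params$circulation
  vt <- ci$total_blood_volume
  # fractions of stressed volume; remainder to the vena cava
  v_lv <- 120; v_rv <- 110
  v_ao <- 45 * ci$c_ao / 0.6; v_art <- 85 * ci$c_art
  v_pa <- 15 * ci$c_pa; v_pv <- 8 * ci$c_pv
  v_vc <- vt - (v_lv + v_rv + v_ao + v_art + v_pa + v_pv)
  if (v_vc <= 0) stop("total_blood_volume too small for the default split")
  r_lv <- radius_from_volume(v_lv, params$geometry)
  l <- length_from_radius(r_lv, params$geometry)
  y <- c(0.02, 0.01, 0.01, l - params$sarcomere$h_c,
         v_lv, v_rv, v_ao, v_art, v_vc, v_pa, v_pv, 0)
  names(y) <- .state_names
  y
}

# Integrate exactly one cardiac cycle from state y0 starting at phase t0.
.integrate_cycle <- function(y0, t0, params, dt_out, rtol, atol,
                             use_compiled = TRUE) {
  period <- params$calcium$period
  times <- seq(t0, t0 + period, by = dt_out)
  if (use_compiled) {
    deSolve::ode(y = y0, times = times, func = "lvad_derivs",
                 parms = pack_params(params), dllname = "lvadsim",
                 initfunc = "lvad_init", nout = 1, outnames = "ca_out",
                 method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 50000)
  } else {
    deSolve::ode(y = y0, times = times,
                 func = function(t, y, parms) list(.model_core(t, y, parms)$deriv),
                 parms = params, method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 50000)
  }
}

#' Integrate the closed loop to periodic steady state
#'
#' Runs the model cycle by cycle from `init` until the cycle-start state
#' repeats to within `tol` (maximum relative change, with a small absolute
#' floor per state scale), or `max_cycles` is reached. The final cycle is
#' returned densely sampled together with all derived waveforms.
#'
#' @param params An `lvad_params` object.
#' @param init Initial state; defaults to [initial_state()].
#' @param max_cycles Cycle budget before giving up (non-convergence is
#'   flagged, not an error).
#' @param tol Relative cycle-to-cycle change below which the orbit is
#'   declared periodic.
#' @param dt_out Output grid spacing (s) for the final cycle.
#' @param rtol,atol Integrator tolerances (lsoda).
#' @param use_compiled Use the compiled right-hand side (default); the
#'   plain-R right-hand side is retained as a reference implementation.
#' @return An object of class `lvad_sim`: list with `series` (data.frame of
#'   time, states and derived waveforms over the final cycle), `state0`
#'   (converged cycle-start state), `converged`, `cycles`, `residual`,
#'   `params`.
#' @export
run_to_steady_state <- function(params, init = NULL, max_cycles = 80,
                                tol = 1e-3, dt_out = 0.001,
                                rtol = 1e-8, atol = 1e-10,
                                use_compiled = TRUE) {
  stopifnot(inherits(params, "lvad_params"))
  y <- if (is.null(init)) initial_state(params) else init
  if (length(y) != length(.state_names)) stop("bad initial state length")
  names(y) <- .state_names
  period <- params$calcium$period
  resid <- Inf
  cycles <- 0
  scale_floor <- c(rep(1e-3, 3), 1e-3, rep(0.5, 7), 0.05)
  repeat {
    out <- .integrate_cycle(y, 0, params, dt_out, rtol, atol, use_compiled)
    y_new <- out[nrow(out), 1 + seq_along(.state_names)]
    y_new <- stats::setNames(as.numeric(y_new), .state_names)
    cycles <- cycles + 1
    resid <- max(abs(y_new - y) / pmax(abs(y), scale_floor))
    y <- y_new
    if (resid < tol || cycles >= max_cycles) break
  }
  converged <- resid < tol
  # dense final cycle with derived waveforms
  final <- .integrate_cycle(y, 0, params, dt_out, rtol, atol, use_compiled)
  series <- derive_waveforms(final, params)
  structure(list(series = series, state0 = y, converged = converged,
                 cycles = cycles, residual = resid, params = params),
            class = "lvad_sim")
}

#' Derived waveforms from an integrated state trajectory
#'
#' Recomputes every pressure, flow and force from the states on the output
#' grid (pure algebra; identical for the compiled and reference
#' right-hand sides).
#'
#' @param out A deSolve matrix whose first column is time followed by the
#'   twelve states.
#' @param params An `lvad_params` object.
#' @return data.frame of time, states and auxiliaries.
#' @export
derive_waveforms <- function(out, params) {
  times <- out[, 1]
  states <- out[, 2:(1 + length(.state_names)), drop = FALSE]
  aux <- t(vapply(seq_along(times),
                  function(i) .model_core(times[i], states[i, ], params)$aux,
                  .model_core(times[1], states[1, ], params)$aux))
  df <- data.frame(time = times, states, aux)
  names(df) <- c("time", .state_names, colnames(aux))
  df
}

#' @export
print.lvad_sim <- function(x, ...) {
  cat(sprintf("<lvad_sim> %s after %d cycles (residual %.2e)\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$cycles, x$residual))
  m <- cycle_metrics(x)
  cat(sprintf("  peak LVP %.1f mmHg, AoP %.1f/%.1f, MAP %.1f, AV flow %.2f L/min\n",
              m$peak_lvp, m$systolic_ap, m$diastolic_ap, m$map, m$mean_av_flow))
  invisible(x)
}
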