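#' Ventricular external work
#'
#' Cycle-averaged hydraulic power `0.0022/T * integral(P(t) Q(t) dt)` with
#' pressure in mmHg and flow in L/min; the 0.0022 factor converts
#' mmHg x L/min to watts. Integration is trapezoidal on the supplied grid.
#'
#' @param pressure_series Pressure over one cycle (mmHg).
#' @param flow_series Flow over one cycle (L/min), same length and grid.
#' @param period Cycle length (s).
#' @param times Optional time grid (s); defaults to a uniform grid spanning
#'   the period.
#' @return Power (W).
#' @export
external_work <- function(pressure_series, flow_series, period,
                          times = NULL) {
  n <- length(pressure_series)
  if (length(flow_series) != n) stop("series lengths differ")
  if (n < 2) stop("need at least two samples")
  if (is.null(times)) times <- seq(0, period, length.out = n)
  prod <- pressure_series * flow_series
  integral <- sum(diff(times) * (utils::head(prod, -1) + utils::tail(prod, -1)) / 2)
  0.0022 / period * integral
}

#' Pulsatile ratio of a pressure waveform
#'
#' `(max - min) / mean` over one cycle.
#'
#' @param pressure_series Pressure over one cycle (mmHg), non-empty with a
#'   non-zero mean.
#' @return Dimensionless pulsatile ratio.
#' @export
pulsatile_ratio <- function(pressure_series) {
  if (length(pressure_series) == 0) stop("empty series")
  m <- mean(pressure_series)
  if (abs(m) < .Machine$double.eps * 100)
    stop("mean pressure is zero; pulsatile ratio undefined")
  (max(pressure_series) - min(pressure_series)) / m
}

#' Blood assist index
#'
#' Fraction of the total hydraulic power delivered by the pump,
#' `W_pump / (W_pump + W_lv)`, each power computed with [external_work()]
#' from the respective pressure/flow pair.
#'
#' @param pump_pressure Pump pressure rise over the cycle (mmHg).
#' @param pump_flow Pump flow (L/min).
#' @param lv_pressure Left-ventricular pressure (mmHg).
#' @param cardiac_output Left-ventricular outflow (L/min).
#' @param period Cycle length (s).
#' @return Fraction in `[0, 1]` (NA with a warning when both powers are
#'   zero).
#' @export
blood_assist_index <- function(pump_pressure, pump_flow, lv_pressure,
                               cardiac_output, period) {
  w_pump <- external_work(pump_pressure, pump_flow, period)
  w_lv <- external_work(lv_pressure, cardiac_output, period)
  if (w_pump == 0 && w_lv == 0) {
    warning("both pump and ventricular power are zero; BAI undefined")
    return(NA_real_)
  }
  w_pump / (w_pump + w_lv)
}

#' Signed area of a pressure-volume loop
#'
#' Shoelace area of the closed (volume, pressure) trajectory, in mmHg mL.
#' For a counter-clockwise physiological loop the value is positive and
#' approximates the ventricular stroke work.
#'
#' @param volume Volume samples over one cycle (mL).
#' @param pressure Pressure samples over one cycle (mmHg).
#' @return Area (mmHg mL).
#' @export
pv_loop_area <- function(volume, pressure) {
  n <- length(volume)
  if (length(pressure) != n || n < 3) stop("need matched series, n >= 3")
  j <- c(n, seq_len(n - 1))
  abs(sum(volume[j] * pressure - volume * pressure[j]) / 2)
}

#' Evaluation indices of a converged cycle
#'
#' Aggregates the standard read-outs from a simulated cycle: left and right
#' ventricular external work, arterial and pulmonary pulsatile ratios,
#' blood assist index, mean aortic-valve flow, pressure extrema, peak
#' myocardial stress and the PV loops.
#'
#' @param sim An `lvad_sim` object from [run_to_steady_state()], or a
#'   waveform data.frame as produced by [derive_waveforms()].
#' @param period Cycle length (s); taken from the simulation when omitted.
#' @return An object of class `cycle_metrics` (a list; see fields in the
#'   source). Carries `converged = FALSE` when the underlying simulation
#'   did not reach periodic steady state, in which case the values are
#'   flagged unreliable rather than withheld.
#' @export
cycle_metrics <- function(sim, period = NULL) {
  if (inherits(sim, "lvad_sim")) {
    s <- sim$series
    if (is.null(period)) period <- sim$params$calcium$period
    converged <- sim$converged
  } else {
    s <- sim
    if (is.null(period)) period <- max(s$time) - min(s$time)
    converged <- TRUE
  }
  to_lmin <- 60 / 1000
  q_av_lmin <- s$q_av * to_lmin
  q_pval_lmin <- s$q_pval * to_lmin
  lv_ew <- external_work(s$p_lv, q_av_lmin, period, s$time)
  rv_ew <- external_work(s$p_rv, q_pval_lmin, period, s$time)
  bai <- if (all(s$q_pump == 0)) 0 else
    blood_assist_index(s$pump_dp, s$q_pump, s$p_lv, q_av_lmin, period)
  res <- list(
    lv_ew = lv_ew, rv_ew = rv_ew,
    pr_arterial = pulsatile_ratio(s$p_art),
    pr_pulmonary = pulsatile_ratio(s$p_pa),
    bai = bai,
    mean_av_flow = mean(q_av_lmin),
    mean_pump_flow = mean(s$q_pump),
    peak_lvp = max(s$p_lv),
    systolic_ap = max(s$p_ao),
    diastolic_ap = min(s$p_ao),
    map = mean(s$p_art),
    peak_force = max(s$f_total),
    edv = max(s$v_lv), esv = min(s$v_lv),
    pv_loop = data.frame(volume = s$v_lv, pressure = s$p_lv),
    pv_loop_rv = data.frame(volume = s$v_rv, pressure = s$p_rv),
    converged = converged
  )
  structure(res, class = "cycle_metrics")
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat("<cycle_metrics>", if (!x$converged) "(UNRELIABLE: not converged)", "\n")
  cat(sprintf("  LV EW %.3f W  RV EW %.3f W  BAI %.3f\n", x$lv_ew, x$rv_ew,
              if (is.na(x$bai)) NA else x$bai))
  cat(sprintf("  AV flow %.2f L/min  peak LVP %.1f  AoP %.1f/%.1f  MAP %.1f mmHg\n",
              x$mean_av_flow, x$peak_lvp, x$systolic_ap, x$diastolic_ap,
              x$map))
  cat(sprintf("  PR arterial %.3f  PR pulmonary %.3f  EDV %.1f  ESV %.1f mL\n",
              x$pr_arterial, x$pr_pulmonary, x$edv, x$esv))
  invisible(x)
}

# Flatten a cycle_metrics object to a one-row data.frame (loops dropped).
metrics_row <- function(m, ...) {
  scal <- m[!vapply(m, is.data.frame, TRUE)]
  scal$converged <- as.logical(scal$converged)
  cbind(data.frame(...), as.data.frame(scal))
}
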