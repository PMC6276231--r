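# Run a simulation at a given mean speed, warm-starting from a previous
# converged state when available.
.run_at_omega <- function(omega, params, init = NULL, ...) {
  params$control$omega_mean <- omega
  if (params$pump$attach == "none") params$pump$attach <- "series"
  run_to_steady_state(params, init = init, ...)
}

# Generic monotone root bracketing + bisection on omega_mean.
# fval(sim) must be increasing in omega over the bracket.
.bisect_omega <- function(params, fval, target, tol_f, bracket,
                          max_iter = 40, quiet = TRUE, ...) {
  lo <- bracket[1]; hi <- bracket[2]
  sim_lo <- .run_at_omega(lo, params, ...)
  f_lo <- fval(sim_lo)
  sim_hi <- .run_at_omega(hi, params, init = sim_lo$state0, ...)
  f_hi <- fval(sim_hi)
  if (target < f_lo || target > f_hi)
    stop(sprintf(
      "target %.4g outside achievable range [%.4g, %.4g] for speeds [%g, %g]",
      target, f_lo, f_hi, lo, hi))
  sim <- sim_hi
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    sim <- .run_at_omega(mid, params, init = sim$state0, ...)
    f_mid <- fval(sim)
    if (!quiet)
      message(sprintf("  bisect omega=%.3f -> %.4g (target %.4g)", mid,
                      f_mid, target))
    if (abs(f_mid - target) < tol_f) {
      return(list(omega = mid, sim = sim, achieved = f_mid, iter = i))
    }
    if (f_mid < target) lo <- mid else hi <- mid
  }
  list(omega = (lo + hi) / 2, sim = sim, achieved = fval(sim),
       iter = max_iter)
}

#' Find the pump speed achieving a target blood assist index
#'
#' Bisects the cycle-mean pump speed until the converged-cycle BAI is
#' within `tol` of `target_bai`. Relies on BAI increasing monotonically
#' with speed over the bracket (verified empirically by the test suite).
#'
#' @param target_bai Target support fraction in (0, 1).
#' @param params An `lvad_params` object; the pump is attached in series if
#'   currently absent.
#' @param tol Acceptable |BAI - target| (0.005 by default).
#' @param bracket Speed search interval (R/s).
#' @param quiet Suppress per-iteration messages.
#' @param ... Passed to [run_to_steady_state()].
#' @return List with `omega` (R/s), the converged `sim`, the `achieved`
#'   BAI and the iteration count. An unreachable target raises an error
#'   reporting the achievable range.
#' @export
set_bai <- function(target_bai, params, tol = 0.005,
                    bracket = c(40, 220), quiet = TRUE, ...) {
  if (!(target_bai > 0 && target_bai < 1))
    stop("target_bai must lie in (0, 1)")
  .bisect_omega(params, function(sim) cycle_metrics(sim)$bai,
                target_bai, tol, bracket, quiet = quiet, ...)
}

#' Find the pump speed matching a target mean arterial pressure
#'
#' Bisects the cycle-mean pump speed until the converged-cycle mean
#' arterial (distal-compartment) pressure is within `tol` of
#' `target_map`. Used to equalize perfusion pressure across support modes
#' before comparing them.
#'
#' @param target_map Target mean arterial pressure (mmHg).
#' @param params An `lvad_params` object (the control block selects the
#'   support mode).
#' @param tol Acceptable |MAP - target| (0.5 mmHg by default).
#' @inheritParams set_bai
#' @return As [set_bai()], with `achieved` the attained MAP.
#' @export
match_map <- function(target_map, params, tol = 0.5,
                      bracket = c(40, 220), quiet = TRUE, ...) {
  .bisect_omega(params, function(sim) cycle_metrics(sim)$map,
                target_map, tol, bracket, quiet = quiet, ...)
}
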