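#' Intracellular calcium transient
#'
#' Piecewise raised-cosine free-calcium waveform over the cardiac cycle:
#' a half-cosine rise from the diastolic baseline to `ca_max + baseline`
#' over `[0, t1]`, a half-cosine fall back to baseline over `[t1, t2]`, and
#' the diastolic level thereafter. With the `literal` flag of
#' [calcium_params()] the after-`t2` branch is exactly zero instead, which
#' reproduces the printed piecewise form at the cost of a `baseline`-sized
#' discontinuity at `t2`.
#'
#' @param t Time (s), vectorized; values beyond one period are wrapped
#'   (the transient is periodic). Negative times are an error.
#' @param p A [calcium_params()] object.
#' @return Free calcium concentration (uM).
#' @export
#' @examples
#' p <- calcium_params()
#' calcium_transient(0, p)            # diastolic baseline
#' calcium_transient(0.0406, p)       # peak, ca_max + baseline
calcium_transient <- function(t, p) {
  stopifnot(inherits(p, "calcium_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  tm <- (t %% p$period) * 1000  # ms within cycle
  ca <- rep(if (p$literal) 0 else p$baseline, length(tm))
  up <- tm <= p$t1
  dn <- tm > p$t1 & tm <= p$t2
  ca[up] <- p$ca_max / 2 * (1 - cos(pi * tm[up] / p$t1)) + p$baseline
  ca[dn] <- p$ca_max / 2 *
    (1 + cos(pi * (tm[dn] - p$t1) / (p$t2 - p$t1))) + p$baseline
  ca
}

#' Time derivatives of the sarcomere state
#'
#' Right-hand side of the troponin/cross-bridge kinetic scheme. The three
#' bound pools are calcium-bound troponin `tca`, attached calcium-bound
#' bridges `tca_star` and attached calcium-free bridges `t_star`; free
#' troponin is `t_total` minus the bound pools, so total troponin is
#' conserved identically. The cross-bridge elongation state `x` relaxes to
#' `l - h_c` at rate `b`, and the velocity-dependent detachment terms use
#' that same `dx/dt` algebraically (the right-hand side is a pure function
#' of state).
#'
#' @param s Named list or vector with `tca`, `tca_star`, `t_star` (uM) and
#'   `x` (um).
#' @param ca Free calcium concentration (uM).
#' @param l Half-sarcomere length (um), positive.
#' @param p A [sarcomere_params()] object.
#' @return Named numeric vector `d_tca`, `d_tca_star`, `d_t_star` (uM/s)
#'   and `d_x` (um/s).
#' @export
sarcomere_rhs <- function(s, ca, l, p) {
  stopifnot(inherits(p, "sarcomere_params"))
  s <- lapply(as.list(s), unname)
  if (l <= 0) stop("half-sarcomere length must be positive")
  if (any(!is.finite(c(s$tca, s$tca_star, s$t_star, s$x, ca))))
    stop("non-finite state or calcium input")
  t_free <- p$t_total - s$tca - s$tca_star - s$t_star
  eff <- exp(-p$r_curv * (l - p$l_a)^2)
  d_x <- p$b * (l - s$x - p$h_c)
  det <- p$yd * d_x^2
  d_tca <- p$y1 * t_free * ca + p$z2 * s$tca_star -
    (p$y2 * eff + p$z1) * s$tca
  d_tca_star <- p$y2 * eff * s$tca + p$z3 * s$t_star * ca -
    (p$z2 + det + p$y3) * s$tca_star
  d_t_star <- p$y3 * s$tca_star - (p$z3 * ca + p$y4 + det) * s$t_star
  c(d_tca = d_tca, d_tca_star = d_tca_star, d_t_star = d_t_star, d_x = d_x)
}

#' Sarcomere force
#'
#' Active force is proportional to the attached cross-bridge concentration
#' and the bridge elongation `l - x`; passive force is linear in the strain
#' relative to the unstressed length `l_0`. Units follow `a_scale` and
#' `k_stiff` (kPa in the shipped parameter set).
#'
#' @inheritParams sarcomere_rhs
#' @return Named numeric vector `active`, `passive`, `total`.
#' @export
sarcomere_force <- function(s, l, p) {
  stopifnot(inherits(p, "sarcomere_params"))
  s <- lapply(as.list(s), unname)
  if (l <= 0) stop("half-sarcomere length must be positive")
  fa <- p$a_scale * (s$tca_star + s$t_star) * (l - s$x)
  fp <- -p$k_stiff * (1 - l / p$l_0)
  c(active = fa, passive = fp, total = fa + fp)
}
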