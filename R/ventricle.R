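#' Chamber radius from volume
#'
#' The chamber is a hemisphere, `V = (2/3) pi R^3`; this inverts that
#' relation. Wall volume is not included (thin-wall assumption).
#'
#' @param v Chamber volume (mL), non-negative; vectorized.
#' @param g A [ventricle_geometry()] object (unused by the inversion itself
#'   but kept for interface symmetry).
#' @return Radius (cm).
#' @export
radius_from_volume <- function(v, g = ventricle_geometry()) {
  if (any(!is.finite(v)) || any(v < 0)) stop("volume must be finite and >= 0")
  (3 * v / (2 * pi))^(1 / 3)
}

#' Chamber volume from radius
#' @param r Radius (cm), non-negative; vectorized.
#' @inheritParams radius_from_volume
#' @return Volume (mL).
#' @export
volume_from_radius <- function(r, g = ventricle_geometry()) {
  if (any(!is.finite(r)) || any(r < 0)) stop("radius must be finite and >= 0")
  (2 / 3) * pi * r^3
}

#' Half-sarcomere length from chamber radius
#'
#' Affine fibre strain: `L/l_0 = R/r_0`. Optionally returns the chain-rule
#' length rate for a given volume rate, `dL/dt = (l_0/r_0) dR/dV dV/dt`
#' with `dR/dV = 1/(2 pi R^2)`.
#'
#' @param r Radius (cm), positive.
#' @param g A [ventricle_geometry()] object.
#' @param dv_dt Optional volume rate (mL/s).
#' @return Length (um), or a list `list(l, dl_dt)` when `dv_dt` is given.
#' @export
length_from_radius <- function(r, g = ventricle_geometry(), dv_dt = NULL) {
  if (any(r <= 0)) stop("radius must be positive")
  l <- g$l_0 * r / g$r_0
  if (is.null(dv_dt)) return(l)
  list(l = l, dl_dt = (g$l_0 / g$r_0) * dv_dt / (2 * pi * r^2))
}

#' Chamber pressure from wall force
#'
#' Laplace law for the thin-walled hemisphere: `P = 2 F h / R`, converted
#' to mmHg by `stress_to_pressure`.
#'
#' @param f Total wall stress (kPa, or whatever unit `stress_to_pressure`
#'   converts from).
#' @param r Chamber radius (cm), positive.
#' @param g A [ventricle_geometry()] object.
#' @return Pressure (mmHg).
#' @export
pressure_from_force <- function(f, r, g = ventricle_geometry()) {
  if (any(r <= 0)) stop("radius must be positive")
  g$stress_to_pressure * 2 * f * g$wall_thickness / r
}
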