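#' Write simulation outputs to a directory
#'
#' Writes the dense final-cycle time series as CSV (time, pressures,
#' volumes, valve and pump flows, speed), the PV loop as a two-column CSV,
#' a machine-readable convergence report (JSON) and a reproducibility
#' manifest (package version, parameter hash, solver settings).
#'
#' @param sim An `lvad_sim` object.
#' @param dir Output directory (created if missing).
#' @param name Scenario name used as the file stem.
#' @return Invisibly, the paths written.
#' @export
write_sim_outputs <- function(sim, dir, name = "scenario") {
  stopifnot(inherits(sim, "lvad_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- sim$series
  cols <- c("time", "p_lv", "p_rv", "p_ao", "p_art", "p_vc", "p_pa", "p_pv",
            "v_lv", "v_rv", "q_mv", "q_av", "q_tc", "q_pval", "q_sys",
            "q_pul", "q_pump", "omega", "ca", "l", "f_total")
  series_path <- file.path(dir, paste0(name, "_series.csv"))
  write.csv(s[, cols], series_path, row.names = FALSE)
  pv_path <- file.path(dir, paste0(name, "_pvloop.csv"))
  write.csv(data.frame(volume = s$v_lv, pressure = s$p_lv), pv_path,
            row.names = FALSE)
  conv_path <- file.path(dir, paste0(name, "_convergence.json"))
  jsonlite::write_json(list(converged = sim$converged, cycles = sim$cycles,
                            residual = sim$residual),
                       conv_path, auto_unbox = TRUE, digits = NA)
  manifest_path <- file.path(dir, paste0(name, "_manifest.json"))
  packed <- pack_params(sim$params)
  jsonlite::write_json(
    list(package = "lvadsim",
         version = as.character(utils::packageVersion("lvadsim")),
         param_hash = sum(packed * seq_along(packed)) %% 1e9,
         params = lapply(sim$params, function(x)
           if (is.list(x)) unclass(x) else x),
         solver = list(method = "lsoda", rtol = 1e-8, atol = 1e-10,
                       dt_out = diff(s$time[1:2]))),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(c(series_path, pv_path, conv_path, manifest_path))
}

#' Plot a simulated cycle
#'
#' Base-graphics panels of the ventricular/aortic pressures, the PV loop,
#' the calcium transient and the valve/pump flows of a converged cycle.
#'
#' @param x An `lvad_sim` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.lvad_sim <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(s$time, cbind(s$p_lv, s$p_ao, s$p_art), type = "l",
                    lty = 1, col = c("black", "red", "blue"),
                    xlab = "time (s)", ylab = "pressure (mmHg)",
                    main = "LV / aortic / arterial pressure")
  graphics::plot(s$v_lv, s$p_lv, type = "l", xlab = "LV volume (mL)",
                 ylab = "LV pressure (mmHg)", main = "PV loop")
  graphics::plot(s$time, s$ca, type = "l", xlab = "time (s)",
                 ylab = "calcium (uM)", main = "calcium transient")
  graphics::matplot(s$time, cbind(s$q_av * 0.06, s$q_mv * 0.06, s$q_pump),
                    type = "l", lty = 1,
                    col = c("red", "blue", "darkgreen"),
                    xlab = "time (s)", ylab = "flow (L/min)",
                    main = "AV / mitral / pump flow")
  invisible(x)
}
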