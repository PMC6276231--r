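#' Scenario specification
#'
#' A named experiment: a disease state (which fixes the peak-calcium
#' amplitude), a support prescription (none, a target blood assist index,
#' or a support mode matched to a mean-arterial-pressure target) and
#' optional parameter overrides.
#'
#' @param name Scenario label.
#' @param disease_state `"healthy"` (ca_max 1.47 uM), `"hf"` (0.54 uM) or
#'   `"hf_beta_blocker"` (0.8 uM).
#' @param support Either `NULL` (unassisted), `list(bai = fraction)` or
#'   `list(mode = "...", map_target = mmHg)`.
#' @param overrides Named list of parameter patches,
#'   `"block.field" = value` (e.g. `"circulation.r_sys" = 1.2`).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, disease_state = c("healthy", "hf",
                                                  "hf_beta_blocker"),
                          support = NULL, overrides = list()) {
  disease_state <- match.arg(disease_state)
  if (!is.null(support)) {
    has_bai <- !is.null(support$bai)
    has_mode <- !is.null(support$mode) && !is.null(support$map_target)
    if (has_bai == has_mode)
      stop("support must be exactly one of {bai} or {mode, map_target}")
  }
  structure(list(name = name, disease_state = disease_state,
                 support = support, overrides = overrides),
            class = "scenario_spec")
}

# Apply "block.field" overrides to an lvad_params object.
apply_overrides <- function(params, overrides) {
  for (nm in names(overrides)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(path) == 1 && path == "valve_smoothing") {
      params$valve_smoothing <- overrides[[nm]]
    } else if (length(path) == 2 && path[1] %in% names(params) &&
               path[2] %in% names(params[[path[1]]])) {
      params[[path[1]]][[path[2]]] <- overrides[[nm]]
    } else stop("unknown parameter override: ", nm)
  }
  params
}

#' Run a single scenario to periodic steady state
#'
#' @param spec A [scenario_spec()] object.
#' @param params Base parameter set; defaults to the shipped calibrated
#'   set for the scenario's disease state.
#' @param ... Passed to [run_to_steady_state()] / the speed search.
#' @return List with the converged `sim`, its `metrics`, the scenario
#'   `spec` and (when supported) the tuned pump speed `omega`.
#' @export
run_scenario <- function(spec, params = NULL, ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(params)) params <- default_params(spec$disease_state)
  else params$calcium$ca_max <- switch(spec$disease_state,
                                       healthy = 1.47, hf = 0.54,
                                       hf_beta_blocker = 0.8)
  params <- apply_overrides(params, spec$overrides)
  if (is.null(spec$support)) {
    params$pump$attach <- "none"
    params$control$omega_mean <- 0
    sim <- run_to_steady_state(params, ...)
    omega <- 0
  } else if (!is.null(spec$support$bai)) {
    params$pump$attach <- "series"
    res <- set_bai(spec$support$bai, params, ...)
    sim <- res$sim; omega <- res$omega
  } else {
    params$pump$attach <- "series"
    params$control$mode <- spec$support$mode
    res <- match_map(spec$support$map_target, params, ...)
    sim <- res$sim; omega <- res$omega
  }
  list(sim = sim, metrics = cycle_metrics(sim), spec = spec, omega = omega)
}

#' Support-level sweep
#'
#' Runs the unassisted baseline plus one constant-speed simulation per
#' blood-assist-index level, each tuned by [set_bai()], and tabulates the
#' cycle metrics.
#'
#' @param levels BAI targets in (0, 1) (the canonical experiment uses
#'   `seq(0.2, 0.9, by = 0.1)`).
#' @param disease_state Disease state for every row (default `"hf"`).
#' @param params Optional base parameter set.
#' @param quiet Suppress progress messages.
#' @param ... Passed to the runners.
#' @return data.frame, one row per level (plus the baseline), ordered by
#'   level; non-converged levels are flagged in the `converged` column
#'   and the sweep continues.
#' @export
run_bai_sweep <- function(levels = seq(0.2, 0.9, by = 0.1),
                          disease_state = "hf", params = NULL,
                          quiet = TRUE, ...) {
  if (length(levels) && any(levels <= 0 | levels >= 1))
    stop("levels must lie in (0, 1)")
  base <- run_scenario(scenario_spec("baseline", disease_state), params, ...)
  rows <- list(metrics_row(base$metrics, scenario = "baseline",
                           bai_target = 0, omega = 0))
  for (lv in sort(levels)) {
    if (!quiet) message(sprintf("BAI level %.0f%%", 100 * lv))
    row <- tryCatch({
      res <- run_scenario(scenario_spec(sprintf("bai_%02.0f", 100 * lv),
                                        disease_state,
                                        support = list(bai = lv)),
                          params, ...)
      metrics_row(res$metrics, scenario = res$spec$name, bai_target = lv,
                  omega = res$omega)
    }, error = function(e) {
      warning(sprintf("level %.2f failed: %s", lv, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

#' Support-mode comparison at matched perfusion pressure
#'
#' Tunes the mean pump speed of each support mode (constant, co-pulse,
#' counter-pulse) to the same mean arterial pressure and tabulates the
#' metrics; optionally repeats every mode under beta-blockade.
#'
#' @param map_target Mean arterial pressure to match (mmHg); the canonical
#'   experiment uses 98.
#' @param disease_state Disease state without the drug (default `"hf"`).
#' @param with_drug Also run each mode with the beta-blocker calcium
#'   amplitude.
#' @param modes Support modes to compare.
#' @param params Optional base parameter set.
#' @param ... Passed to the runners.
#' @return data.frame, one row per (mode, drug) combination. A mode whose
#'   MAP target cannot be reached raises an error naming that mode.
#' @export
run_mode_comparison <- function(map_target = 98, disease_state = "hf",
                                with_drug = FALSE,
                                modes = c("constant", "co_pulse",
                                          "counter_pulse"),
                                params = NULL, ...) {
  states <- if (with_drug) c(disease_state, "hf_beta_blocker")
            else disease_state
  rows <- list()
  for (st in states) for (md in modes) {
    res <- tryCatch(
      run_scenario(scenario_spec(paste(md, st, sep = "_"), st,
                                 support = list(mode = md,
                                                map_target = map_target)),
                   params, ...),
      error = function(e) stop(sprintf("mode '%s' (%s): %s", md, st,
                                       conditionMessage(e)), call. = FALSE))
    rows[[length(rows) + 1]] <-
      metrics_row(res$metrics, scenario = res$spec$name, mode = md,
                  disease_state = st, omega = res$omega)
  }
  do.call(rbind, rows)
}

#' Drug-coupling experiment
#'
#' Paired comparison, per support mode, of LVAD support with and without
#' beta-blockade at the same mean-arterial-pressure target. The drug is
#' modeled purely as the change of peak intracellular calcium from 0.54 to
#' 0.8 uM (no peripheral vascular effect).
#'
#' @inheritParams run_mode_comparison
#' @param rematch If `FALSE` (default) the beta-blocker run keeps the pump
#'   speed tuned for the drug-free mode, mimicking a drug added on top of
#'   unchanged device support (the attained MAP moves by under 2 mmHg); if
#'   `TRUE` the drug rows are re-matched to `map_target`.
#' @return data.frame with paired rows and per-mode deltas (`d_edv`,
#'   `d_peak_lvp_rel`, `d_pr_pulmonary`) attached as attribute `"deltas"`.
#' @export
run_drug_coupling <- function(modes = c("constant", "co_pulse",
                                        "counter_pulse"),
                              map_target = 98, params = NULL,
                              rematch = FALSE, ...) {
  if (rematch) {
    tab <- run_mode_comparison(map_target = map_target,
                               disease_state = "hf", with_drug = TRUE,
                               modes = modes, params = params, ...)
  } else {
    rows <- list()
    for (md in modes) {
      res <- run_scenario(scenario_spec(paste(md, "hf", sep = "_"), "hf",
                                        support = list(mode = md,
                                                       map_target =
                                                         map_target)),
                          params, ...)
      rows[[length(rows) + 1]] <-
        metrics_row(res$metrics, scenario = res$spec$name, mode = md,
                    disease_state = "hf", omega = res$omega)
      pd <- if (is.null(params)) default_params("hf_beta_blocker")
            else apply_overrides(params,
                                 list("calcium.ca_max" = 0.8))
      pd$pump$attach <- "series"
      pd$control$mode <- md
      pd$control$omega_mean <- res$omega
      simd <- run_to_steady_state(pd, init = res$sim$state0, ...)
      rows[[length(rows) + 1]] <-
        metrics_row(cycle_metrics(simd),
                    scenario = paste(md, "hf_beta_blocker", sep = "_"),
                    mode = md, disease_state = "hf_beta_blocker",
                    omega = res$omega)
    }
    tab <- do.call(rbind, rows)
  }
  off <- tab[tab$disease_state == "hf", ]
  on <- tab[tab$disease_state == "hf_beta_blocker", ]
  deltas <- data.frame(
    mode = off$mode,
    d_edv = on$edv - off$edv,
    d_esv = on$esv - off$esv,
    d_peak_lvp_rel = (on$peak_lvp - off$peak_lvp) / off$peak_lvp,
    d_pr_pulmonary = on$pr_pulmonary - off$pr_pulmonary,
    d_pr_arterial = on$pr_arterial - off$pr_arterial,
    d_lv_ew = on$lv_ew - off$lv_ew)
  attr(tab, "deltas") <- deltas
  tab
}

#' Calibrate the unassisted baseline against waveform targets
#'
#' Bounded Nelder-Mead minimization of weighted squared relative residuals
#' between converged-cycle metrics and their targets. Free parameters are
#' addressed as `"block.field"` strings; the search works in log space
#' inside the given bounds (logistic transform), so every iterate is
#' admissible. Deterministic for a fixed starting point.
#'
#' @param params Starting parameter set.
#' @param targets data.frame with columns `metric` (a scalar field of
#'   [cycle_metrics()]), `value`, `weight`, and optionally `disease_state`
#'   (default `"healthy"`).
#' @param free Character vector of free parameter names, e.g.
#'   `c("sarcomere.a_scale", "circulation.r_sys")`. Empty: the input set
#'   is returned unchanged (identity).
#' @param bounds Named list of `c(lower, upper)` per free parameter.
#' @param maxit Nelder-Mead iteration budget.
#' @param resid_tol Root-mean-square weighted relative residual above
#'   which the report is marked failed (parameters are still returned).
#' @param quiet Suppress progress output.
#' @param ... Passed to [run_to_steady_state()].
#' @return List with `params` (calibrated), `report` (data.frame of
#'   target vs achieved), `value` (objective), `converged` (optimizer
#'   status), `ok` (residual below `resid_tol`).
#' @export
calibrate_baseline <- function(params, targets, free, bounds,
                               maxit = 200, resid_tol = 0.05,
                               quiet = TRUE, ...) {
  stopifnot(inherits(params, "lvad_params"),
            all(c("metric", "value", "weight") %in% names(targets)))
  if (is.null(targets$disease_state)) targets$disease_state <- "healthy"
  eval_metrics <- function(p) {
    out <- list()
    for (st in unique(targets$disease_state)) {
      q <- p
      q$calcium$ca_max <- switch(st, healthy = 1.47, hf = 0.54,
                                 hf_beta_blocker = 0.8)
      q$pump$attach <- "none"
      sim <- run_to_steady_state(q, ...)
      out[[st]] <- cycle_metrics(sim)
    }
    out
  }
  objective_of <- function(p) {
    mets <- eval_metrics(p)
    r <- mapply(function(metric, value, weight, st) {
      got <- mets[[st]][[metric]]
      weight * ((got - value) / value)^2
    }, targets$metric, targets$value, targets$weight,
       targets$disease_state)
    sum(r)
  }
  report_of <- function(p) {
    mets <- eval_metrics(p)
    targets$achieved <- mapply(function(metric, st) mets[[st]][[metric]],
                               targets$metric, targets$disease_state)
    targets
  }
  if (length(free) == 0) {
    rep0 <- report_of(params)
    return(list(params = params, report = rep0,
                value = objective_of(params), converged = TRUE, ok = TRUE))
  }
  stopifnot(all(free %in% names(bounds)))
  lo <- vapply(bounds[free], `[`, 0, 1)
  hi <- vapply(bounds[free], `[`, 0, 2)
  get_free <- function(p) vapply(free, function(nm) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    p[[path[1]]][[path[2]]]
  }, 0)
  set_free <- function(p, vals) {
    names(vals) <- free
    apply_overrides(p, as.list(vals))
  }
  # logistic transform keeps iterates strictly inside the bounds
  to_z <- function(x) stats::qlogis(pmin(pmax((x - lo) / (hi - lo), 1e-6),
                                         1 - 1e-6))
  to_x <- function(z) lo + (hi - lo) * stats::plogis(z)
  fn <- function(z) {
    val <- objective_of(set_free(params, to_x(z)))
    if (!quiet) message(sprintf("  obj %.5g at %s", val,
                                paste(signif(to_x(z), 4), collapse = ", ")))
    val
  }
  opt <- if (length(free) == 1) {
    # Brent for one free parameter (Nelder-Mead is unreliable in 1-D)
    stats::optim(to_z(get_free(params)), fn, method = "Brent",
                 lower = -12, upper = 12,
                 control = list(maxit = maxit))
  } else {
    stats::optim(to_z(get_free(params)), fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-6))
  }
  params_out <- set_free(params, to_x(opt$par))
  rep_out <- report_of(params_out)
  rms <- sqrt(mean(((rep_out$achieved - rep_out$value) / rep_out$value)^2))
  list(params = params_out, report = rep_out, value = opt$value,
       converged = opt$convergence == 0, ok = rms <= resid_tol)
}
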