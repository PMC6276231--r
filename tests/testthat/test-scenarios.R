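test_that("scenario specification validates its support forms", {
  s <- scenario_spec("x", "hf", support = list(bai = 0.5))
  expect_s3_class(s, "scenario_spec")
  expect_error(scenario_spec("x", "hf", support = list()), "exactly one")
  expect_error(scenario_spec("x", "hf",
                             support = list(bai = 0.5, mode = "constant",
                                            map_target = 98)),
               "exactly one")
  expect_error(scenario_spec("x", "sick"), "arg")
})

test_that("parameter overrides patch nested fields and reject unknown ones", {
  p <- default_params("healthy")
  q <- apply_overrides(p, list("circulation.r_sys" = 2,
                               "sarcomere.b" = 500,
                               "valve_smoothing" = 0.1))
  expect_equal(q$circulation$r_sys, 2)
  expect_equal(q$sarcomere$b, 500)
  expect_equal(q$valve_smoothing, 0.1)
  expect_error(apply_overrides(p, list("circulation.bogus" = 1)),
               "unknown")
})

test_that("an empty level list yields the baseline-only table", {
  tab <- run_bai_sweep(levels = numeric(0), disease_state = "hf")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$scenario, "baseline")
  expect_equal(tab$bai, 0)
  expect_equal(tab$omega, 0)
  expect_gt(tab$mean_av_flow, 0)
})

test_that("calibration with no free parameters is the identity", {
  p <- default_params("healthy")
  targets <- data.frame(metric = c("peak_lvp", "systolic_ap",
                                   "diastolic_ap"),
                        value = c(110, 95, 70), weight = 1)
  cal <- calibrate_baseline(p, targets, free = character(0),
                            bounds = list())
  expect_equal(cal$params, p)
  expect_true(cal$ok)
  # the shipped default set already sits on the calibration targets
  expect_equal(cal$report$achieved, cal$report$value, tolerance = 0.02)
})

test_that("a short calibration descends from a perturbed start", {
  p <- default_params("healthy")
  p$sarcomere$a_scale <- p$sarcomere$a_scale * 0.9   # knock it off target
  targets <- data.frame(metric = "peak_lvp", value = 110, weight = 1)
  bounds <- list("sarcomere.a_scale" = c(2000, 12000))
  bad <- calibrate_baseline(p, targets, free = character(0),
                            bounds = list())
  cal <- calibrate_baseline(p, targets, free = "sarcomere.a_scale",
                            bounds = bounds, maxit = 40)
  expect_lt(cal$value, bad$value)
  expect_lt(abs(cal$report$achieved - 110), 2)
})

test_that("simulation outputs and manifest are written and re-readable", {
  dir <- tempfile()
  paths <- write_sim_outputs(healthy_sim(), dir, "healthy")
  expect_true(all(file.exists(paths)))
  s <- read.csv(file.path(dir, "healthy_series.csv"))
  expect_true(all(c("time", "p_lv", "p_ao", "q_av", "omega") %in% names(s)))
  conv <- jsonlite::read_json(file.path(dir, "healthy_convergence.json"))
  expect_true(conv$converged)
  man <- jsonlite::read_json(file.path(dir, "healthy_manifest.json"))
  expect_equal(man$solver$method, "lsoda")
})
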