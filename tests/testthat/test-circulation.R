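test_that("valve law is an ideal diode with resistance", {
  expect_equal(valve_flow(-20, 0.05), 0)
  expect_equal(valve_flow(10, 0.05), 200)
  dp <- seq(-5, 5, by = 0.01)
  q <- valve_flow(dp, 0.1)
  expect_true(all(q >= 0))
  expect_true(all(diff(q) >= 0))                 # non-decreasing
  expect_lt(max(abs(diff(q))), 0.2)              # continuous at the corner
  # softplus variant approaches the diode as sharpness -> 0
  qs <- valve_flow(dp, 0.1, smoothing = 1e-4)
  expect_equal(qs, q, tolerance = 1e-2)
  expect_error(valve_flow(1, 0), "positive")
})

test_that("pump head characteristic evaluates exactly", {
  pp <- pump_params()
  expect_equal(pump_pressure_head(0, 0, 0, pp), -15.5)
  expect_equal(pump_pressure_head(100, 0, 0, pp),
               0.0115 * 1e4 + 0.079 * 100 - 15.5)
  expect_equal(pump_pressure_head(100, 0, 0, pp), 107.4)
  # inertial term adds linearly
  expect_equal(pump_pressure_head(100, 2, 10, pp) -
               pump_pressure_head(100, 2, 0, pp), pp$inertance * 10)
  # above omega = 0.58/0.086 the steady head decreases with flow
  w <- 10
  h <- vapply(0:6, function(q) pump_pressure_head(w, q, 0, pp), 0)
  expect_true(all(diff(h) < 0))
})

test_that("speed waveforms have the right means, limits and phase relation", {
  cap <- calcium_params()
  tt <- seq(0, 0.8, length.out = 4001)[-4001]
  ctl <- pump_control("constant", omega_mean = 120)
  expect_equal(speed_waveform(tt, ctl, cap), rep(120, length(tt)))
  # zero modulation collapses co-pulse to constant
  ctl0 <- pump_control("co_pulse", 120, modulation_fraction = 0)
  expect_equal(speed_waveform(tt, ctl0, cap), rep(120, length(tt)))
  # cycle mean equals omega_mean in every mode
  for (md in c("co_pulse", "counter_pulse")) {
    ctl <- pump_control(md, 120, modulation_fraction = 0.3,
                        pulse_width = 0.25)
    expect_equal(mean(speed_waveform(tt, ctl, cap)), 120,
                 tolerance = 1e-6)
  }
  # counter-pulse is co-pulse delayed by half a period
  co <- pump_control("co_pulse", 120, 0.3, pulse_width = 0.25)
  ct <- pump_control("counter_pulse", 120, 0.3, pulse_width = 0.25)
  expect_equal(speed_waveform(tt, ct, cap),
               speed_waveform(tt - 0.4, co, cap))
})

test_that("assembled right-hand side conserves volume and respects the diodes", {
  p <- default_params("healthy")
  set.seed(11)
  for (i in 1:20) {
    y <- initial_state(p)
    y[1:3] <- runif(3, 0, 10)
    y[5:11] <- y[5:11] * runif(7, 0.6, 1.4)
    r <- system_rhs(runif(1, 0, 0.8), y, p)
    # closed loop: volume derivatives cancel to rounding of O(1e3) flows
    expect_lt(abs(sum(r[[1]][5:11])), 1e-8)
    aux <- r[[2]]
    expect_true(all(aux[c("q_mv", "q_av", "q_tc", "q_pval")] >= 0))
    if (aux[["p_lv"]] < aux[["p_ao"]]) expect_equal(aux[["q_av"]], 0)
  }
})

test_that("zero-speed series pump with blocked branch reduces to the baseline loop", {
  p <- default_params("hf")                      # attach "none"
  y <- initial_state(p)
  r_none <- system_rhs(0.1, y, p)
  # same state, pump attached in series but q = 0 and the conduit closed:
  # inter-compartment flows must match the resistive baseline except for
  # the aorta-artery segment carried by the pump state
  p2 <- p; p2$pump$attach <- "series"
  r_series <- system_rhs(0.1, y, p2)
  keep <- c(1:6, 9:11)  # all but the aorta/artery pair and pump flow
  expect_equal(r_series[[1]][keep], r_none[[1]][keep], tolerance = 1e-12)
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- default_params("hf")
  p$pump$attach <- "series"; p$control$omega_mean <- 90
  p$control$mode <- "co_pulse"
  y0 <- initial_state(p)
  a <- run_to_steady_state(p, init = y0, max_cycles = 2, tol = 0,
                           use_compiled = TRUE)
  b <- run_to_steady_state(p, init = y0, max_cycles = 2, tol = 0,
                           use_compiled = FALSE)
  expect_equal(a$state0, b$state0, tolerance = 1e-6)
})

test_that("healthy baseline reaches a conserved periodic orbit quickly", {
  sim <- healthy_sim()
  expect_true(sim$converged)
  expect_lte(sim$cycles, 50)
  # blood volume conserved over the final cycle
  vt <- rowSums(sim$series[, c("v_lv", "v_rv", "v_ao", "v_art", "v_vc",
                               "v_pa", "v_pv")])
  expect_lt(diff(range(vt)) / mean(vt), 1e-6)
  # a converged run re-integrated one more cycle barely moves the metrics
  again <- run_to_steady_state(sim$params, init = sim$state0,
                               max_cycles = 1)
  m1 <- cycle_metrics(sim); m2 <- cycle_metrics(again)
  for (f in c("lv_ew", "mean_av_flow", "peak_lvp", "map"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-3)
  # mitral and aortic valves never conduct simultaneously
  expect_equal(sum(sim$series$q_mv > 1e-9 & sim$series$q_av > 1e-9), 0)
})

test_that("parameter round trip through config files is lossless", {
  p <- default_params("healthy")
  tmp <- tempfile(fileext = ".yaml")
  save_params(p, tmp)
  q <- load_params(tmp)
  expect_equal(q, p)
  tmp2 <- tempfile(fileext = ".json")
  save_params(p, tmp2)
  expect_equal(load_params(tmp2), p)
})
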