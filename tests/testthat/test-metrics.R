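test_that("external work integrates pressure-flow power with the 0.0022 factor", {
  n <- 801; period <- 0.8
  expect_equal(external_work(rep(100, n), rep(0, n), period), 0)
  expect_equal(external_work(rep(100, n), rep(5, n), period), 1.1)
  # normalization by the period: same sampled product, half the period
  expect_equal(external_work(rep(100, n), rep(5, n), period / 2), 1.1)
  # bilinear in the two scales
  pserie <- 80 + 30 * sin(seq(0, 2 * pi, length.out = n))
  qserie <- pmax(10 * sin(seq(0, 2 * pi, length.out = n)), 0)
  w <- external_work(pserie, qserie, period)
  expect_equal(external_work(3 * pserie, 2 * qserie, period), 6 * w)
  expect_error(external_work(1:5, 1:4, period), "lengths")
})

test_that("pulsatile ratio is (max - min)/mean and scale invariant", {
  expect_equal(pulsatile_ratio(rep(90, 100)), 0)
  s <- c(80, 100, 120, 100)  # max 120, min 80, mean 100
  expect_equal(pulsatile_ratio(s), 0.4)
  expect_equal(pulsatile_ratio(7 * s), pulsatile_ratio(s))
  expect_error(pulsatile_ratio(numeric(0)), "empty")
  expect_error(pulsatile_ratio(c(-1, 1)), "zero")
})

test_that("blood assist index is the pump share of total hydraulic power", {
  n <- 401; period <- 0.8
  lvp <- 60 + 40 * pmax(sin(seq(0, 2 * pi, length.out = n)), 0)
  co <- pmax(8 * sin(seq(0, 2 * pi, length.out = n)), 0)
  expect_equal(blood_assist_index(rep(80, n), rep(0, n), lvp, co, period), 0)
  # symmetric powers give one half
  expect_equal(blood_assist_index(lvp, co, lvp, co, period), 0.5)
  expect_warning(
    b <- blood_assist_index(rep(0, n), rep(0, n), rep(0, n), rep(0, n),
                            period), "undefined")
  expect_true(is.na(b))
})

test_that("PV-loop area matches the ventricular stroke work cross-oracle", {
  # rectangle loop: area is exact
  vol <- c(120, 120, 60, 60); prs <- c(10, 110, 110, 10)
  expect_equal(pv_loop_area(vol, prs), 60 * 100)
  expect_equal(pv_loop_area(rep(80, 10), rep(50, 10)), 0)  # degenerate
  # on a converged healthy cycle the shoelace area approximates the
  # external-work integral of the same chamber (PdV vs P*Q accounting)
  sim <- healthy_sim()
  m <- cycle_metrics(sim)
  area_w <- pv_loop_area(m$pv_loop$volume, m$pv_loop$pressure) *
    133.322e-6 / sim$params$calcium$period  # mmHg mL -> J, per cycle time
  expect_equal(area_w, m$lv_ew, tolerance = 0.30)
})

test_that("cycle metrics fill every field coherently", {
  m <- cycle_metrics(healthy_sim())
  expect_true(m$converged)
  expect_true(m$systolic_ap >= m$map && m$map >= m$diastolic_ap)
  expect_true(m$pr_arterial >= 0 && m$pr_pulmonary >= 0)
  expect_true(m$bai == 0)                      # unassisted
  expect_true(m$edv > m$esv)
  expect_true(all(c("volume", "pressure") %in% names(m$pv_loop)))
})

test_that("metrics are stable under output-grid refinement", {
  sim <- healthy_sim()
  fine <- run_to_steady_state(sim$params, init = sim$state0,
                              max_cycles = 1, dt_out = 5e-4)
  m1 <- cycle_metrics(sim); m2 <- cycle_metrics(fine)
  for (f in c("lv_ew", "rv_ew", "mean_av_flow", "peak_lvp", "map",
              "systolic_ap", "diastolic_ap"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 2e-3)
})
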