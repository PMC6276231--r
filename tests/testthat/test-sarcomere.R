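test_that("calcium transient matches its closed form at the landmarks", {
  p <- calcium_params()  # 1.47 uM, 40.6/130.2 ms, literal zero tail
  expect_equal(calcium_transient(0, p), 0.1)
  # analytic maximum at t1: ca_max + baseline
  expect_equal(calcium_transient(0.0406, p), 1.57)
  expect_equal(calcium_transient(0.5, p), 0)            # beyond t2
  pc <- calcium_params(literal = FALSE)
  expect_equal(calcium_transient(0.5, pc), 0.1)         # continuous tail
  # the falling branch reaches the baseline as t approaches t2
  expect_equal(calcium_transient(0.13019, p), 0.1, tolerance = 1e-4)
  # periodicity
  tt <- c(0.01, 0.07, 0.4)
  expect_equal(calcium_transient(tt + p$period, p),
               calcium_transient(tt, p))
  # the grid argmax sits at t1 with value ca_max + baseline
  tg <- seq(0, p$period, by = 1e-5)
  ca <- calcium_transient(tg, p)
  expect_equal(tg[which.max(ca)] * 1000, p$t1, tolerance = 1e-3)
  expect_equal(max(ca), p$ca_max + 0.1, tolerance = 1e-6)
  expect_error(calcium_transient(-0.1, p), "finite")
  expect_error(calcium_params(t1 = 200, t2 = 100), "t1")
})

test_that("kinetic right-hand side matches hand arithmetic and conserves troponin", {
  p <- sarcomere_params()
  # fully unbound rest state with no calcium is a fixed point
  l <- 1.0
  rest <- list(tca = 0, tca_star = 0, t_star = 0, x = l - p$h_c)
  d <- sarcomere_rhs(rest, ca = 0, l = l, p = p)
  expect_equal(unname(d), c(0, 0, 0, 0))
  # hand-evaluated derivative: [T] = 70 - 17 = 53 uM, ca = 1 uM, overlap 1
  s <- list(tca = 10, tca_star = 5, t_star = 2, x = p$l_a - p$h_c)
  d <- sarcomere_rhs(s, ca = 1, l = p$l_a, p = p)
  expect_equal(d[["d_tca"]], 39 * 53 * 1 + 1.3 * 5 - (1.3 + 30) * 10)
  expect_equal(d[["d_tca"]], 1760.5)
  # bound-pool derivatives sum to -d[T]/dt for random admissible states
  set.seed(42)
  for (i in 1:25) {
    tot <- runif(3, 0, 20)
    s <- list(tca = tot[1], tca_star = tot[2], t_star = tot[3],
              x = runif(1, 0.8, 1.3))
    ca <- runif(1, 0, 2); l <- runif(1, 0.8, 1.3)
    d <- sarcomere_rhs(s, ca, l, p)
    eps <- 1e-7
    t_of <- function(s) p$t_total - s$tca - s$tca_star - s$t_star
    s2 <- s
    s2$tca <- s$tca + d[["d_tca"]] * eps
    s2$tca_star <- s$tca_star + d[["d_tca_star"]] * eps
    s2$t_star <- s$t_star + d[["d_t_star"]] * eps
    d_t <- (t_of(s2) - t_of(s)) / eps
    expect_equal(d[["d_tca"]] + d[["d_tca_star"]] + d[["d_t_star"]], -d_t,
                 tolerance = 1e-9)
  }
})

test_that("force law reproduces its defining products", {
  p <- sarcomere_params()
  # no attached bridges, no active force
  f <- sarcomere_force(list(tca_star = 0, t_star = 0, x = 1), l = 1.1, p)
  expect_equal(f[["active"]], 0)
  # unstressed length, no passive force
  f <- sarcomere_force(list(tca_star = 1, t_star = 1, x = 1.1), l = p$l_0, p)
  expect_equal(f[["passive"]], 0)
  # direct evaluation with unit force scale
  p1 <- sarcomere_params(a_scale = 1)
  f <- sarcomere_force(list(tca_star = 4, t_star = 3, x = 1.0), l = 1.005, p1)
  expect_equal(f[["active"]], 0.035)
  expect_equal(f[["total"]], f[["active"]] + f[["passive"]])
})

# isometric twitch: integrate the sarcomere alone at fixed length
isometric_twitch <- function(ca_max, l = 1.05, p = sarcomere_params(),
                             cap = calcium_params()) {
  cap$ca_max <- ca_max
  rhs <- function(t, y, parms) {
    s <- list(tca = y[1], tca_star = y[2], t_star = y[3], x = y[4])
    list(unname(sarcomere_rhs(s, calcium_transient(t, cap), l, p)))
  }
  out <- deSolve::ode(c(0, 0, 0, l - p$h_c), seq(0, 0.8, 1e-3), rhs, NULL,
                      rtol = 1e-8, atol = 1e-10)
  apply(out[, 2:4], 1, function(r)
    sarcomere_force(list(tca_star = r[2], t_star = r[3],
                         x = l - p$h_c), l, p)[["active"]])
}

test_that("isometric relaxation decays to rest and peak force grows with calcium", {
  p <- sarcomere_params()
  l <- 1.05
  # start from a bound state with ca = 0: all species decay, x -> l - h_c
  rhs0 <- function(t, y, parms) {
    s <- list(tca = y[1], tca_star = y[2], t_star = y[3], x = y[4])
    list(unname(sarcomere_rhs(s, 0, l, p)))
  }
  out <- deSolve::ode(c(5, 3, 1, l - 0.002), seq(0, 1, 5e-3), rhs0, NULL,
                      rtol = 1e-10, atol = 1e-12)
  # the total bound pool decays monotonically (individual pools may
  # transiently exchange occupancy on the way down)
  bound <- rowSums(out[, 2:4])
  expect_true(all(diff(bound) < 1e-8))
  expect_equal(unname(out[nrow(out), 2:4]), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(unname(out[nrow(out), 5]), l - p$h_c, tolerance = 1e-6)
  # peak twitch force is monotone over the three disease amplitudes
  peaks <- vapply(c(0.54, 0.8, 1.47), function(cm)
    max(isometric_twitch(cm)), 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("concentrations remain non-negative under admissible calcium input", {
  p <- sarcomere_params()
  cap <- calcium_params()
  set.seed(7)
  for (i in 1:5) {
    l <- runif(1, 0.9, 1.3)
    cap$ca_max <- runif(1, 0.3, 2)
    rhs <- function(t, y, parms) {
      s <- list(tca = y[1], tca_star = y[2], t_star = y[3], x = y[4])
      list(unname(sarcomere_rhs(s, calcium_transient(t, cap), l, p)))
    }
    out <- deSolve::ode(c(0, 0, 0, l - p$h_c), seq(0, 1.6, 1e-3), rhs,
                        NULL, rtol = 1e-8, atol = 1e-10)
    expect_true(all(out[, 2:4] > -1e-8))
    # bound pools never exceed total troponin
    expect_true(all(rowSums(out[, 2:4]) <= p$t_total + 1e-8))
  }
})
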