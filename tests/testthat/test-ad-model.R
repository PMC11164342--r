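test_that("rate curves interpolate the sensitive and resistant extremes", {
  p <- ad_params(gamma_R = 0.01, gamma_S = 0.03, delta_R = -0.005,
                 delta_S = 0.05, A_gamma = 0.4, A_delta = -0.7,
                 B_gamma = 2, B_delta = 1.5)
  expect_equal(gamma_of_x(1e6, p), 0.01, tolerance = 1e-12)
  expect_equal(gamma_of_x(-1e6, p), 0.03, tolerance = 1e-12)
  expect_equal(delta_of_x(1e6, p), -0.005, tolerance = 1e-12)
  expect_equal(delta_of_x(-1e6, p), 0.05, tolerance = 1e-12)
  # logistic midpoints
  expect_equal(gamma_of_x(-p$A_gamma / p$B_gamma, p), (0.01 + 0.03) / 2)
  expect_equal(delta_of_x(-p$A_delta / p$B_delta, p), (-0.005 + 0.05) / 2)
  # overflow-safe at extreme arguments
  expect_true(is.finite(gamma_of_x(1e4, p)) && is.finite(gamma_of_x(-1e4, p)))
  # constant when the extremes coincide
  pc <- ad_params(delta_R = 0.02, delta_S = 0.02)
  expect_equal(delta_of_x(c(-3, 0, 5), pc), rep(0.02, 3))
  # bounded between the extremes on random draws
  set.seed(5)
  xs <- rnorm(100, 0, 5)
  expect_true(all(gamma_of_x(xs, p) >= 0.01 & gamma_of_x(xs, p) <= 0.03))
  expect_true(all(delta_of_x(xs, p) >= -0.005 & delta_of_x(xs, p) <= 0.05))
})

test_that("fitness gradient matches central finite differences and signs", {
  set.seed(7)
  for (rep in 1:30) {
    p <- ad_params(gamma_R = runif(1, 0, 0.03), gamma_S = runif(1, 0, 0.05),
                   delta_R = runif(1, -0.02, 0.03),
                   delta_S = runif(1, 0, 0.09),
                   A_gamma = rnorm(1), A_delta = rnorm(1),
                   B_gamma = runif(1, 0.1, 3), B_delta = runif(1, 0.1, 3))
    x <- rnorm(1, 0, 3)
    a <- sample(0:1, 1)
    W <- function(x) (1 - a) * gamma_of_x(x, p) - a * delta_of_x(x, p)
    h <- 1e-5
    fd <- (W(x + h) - W(x - h)) / (2 * h)
    expect_lt(abs(fitness_gradient(x, a, p) - fd), 1e-8)
  }
  # treatment selects for resistance, treatment-free intervals against it
  p <- ad_params(delta_S = 0.05, delta_R = -0.001, gamma_S = 0.02,
                 gamma_R = 0.005, B_gamma = 1, B_delta = 1)
  xs <- seq(-8, 8, by = 0.5)
  expect_true(all(fitness_gradient(xs, 1, p) > 0))
  expect_true(all(fitness_gradient(xs, 0, p) < 0))
})

test_that("B = 0 freezes x and reduces to the single-cell exponential", {
  p <- ad_params(gamma_S = 0.02, gamma_R = 0.01, delta_S = 0.05,
                 delta_R = 0.001, A_gamma = 0, A_delta = 0,
                 B_gamma = 0, B_delta = 0)
  sched <- make_schedule()
  days <- seq(0, 600, by = 20)
  tr <- simulate_ad(p, sched, 250, days)
  expect_equal(tr$x, rep(0, length(days)), tolerance = 1e-12)
  # rates pinned at the x = 0 midpoint values
  g0 <- gamma_of_x(0, p); d0 <- delta_of_x(0, p)
  ref <- simulate_single(g0, d0, sched, 250, days)
  expect_equal(tr$C, ref$C, tolerance = 1e-7)
})

test_that("resistance level x is monotone within regimes", {
  set.seed(21)
  for (rep in 1:10) {
    p <- ad_params(gamma_R = runif(1, 0, 0.02), gamma_S = runif(1, 0.02, 0.05),
                   delta_R = runif(1, -0.01, 0.01),
                   delta_S = runif(1, 0.02, 0.09),
                   A_gamma = rnorm(1), A_delta = rnorm(1),
                   B_gamma = runif(1, 0.2, 2), B_delta = runif(1, 0.2, 2))
    on <- make_schedule(starts = 0, n_cycles = 20, spacing = 21)
    tr_on <- simulate_ad(p, on, 100, seq(0, 350, by = 7))
    expect_true(all(diff(tr_on$x) >= -1e-10))
    expect_true(all(tr_on$N > 0))
    none <- ca125_schedule(data.frame(line_number = integer(),
                                      cycle_day = numeric()))
    tr_off <- simulate_ad(p, none, 100, seq(0, 350, by = 7))
    expect_true(all(diff(tr_off$x) <= 1e-10))
  }
})

test_that("integration matches a fixed-step RK4 oracle", {
  p <- ad_params(gamma_R = 0.012, gamma_S = 0.028, delta_R = -0.003,
                 delta_S = 0.06, A_gamma = 0.3, A_delta = -0.2,
                 B_gamma = 1.2, B_delta = 0.8)
  sched <- make_schedule()
  days <- seq(0, 550, by = 25)
  tr <- simulate_ad(p, sched, 300, days)
  # independent fixed-step RK4 on (logN, x), 0.05-day steps, split at regimes
  rk4 <- function(h) {
    f <- function(y, a) {
      W <- (1 - a) * gamma_of_x(y[2], p) - a * delta_of_x(y[2], p)
      c(W, p$K * fitness_gradient(y[2], a, p))
    }
    y <- c(log(300), 0)
    out <- matrix(NA_real_, length(days), 2)
    out[days == 0, ] <- y
    bounds <- sort(unique(c(0, as.vector(sched$intervals), days,
                            max(days))))
    bounds <- bounds[bounds <= max(days)]
    for (i in seq_len(length(bounds) - 1)) {
      a <- alpha(sched, (bounds[i] + bounds[i + 1]) / 2)
      span <- bounds[i + 1] - bounds[i]
      nstep <- max(1L, ceiling(span / h))
      hh <- span / nstep
      for (s in seq_len(nstep)) {
        k1 <- f(y, a); k2 <- f(y + hh / 2 * k1, a)
        k3 <- f(y + hh / 2 * k2, a); k4 <- f(y + hh * k3, a)
        y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      out[abs(days - bounds[i + 1]) < 1e-9, ] <- rep(y, each = sum(abs(days - bounds[i + 1]) < 1e-9))
    }
    out
  }
  ref <- rk4(0.05)
  expect_lt(max(abs(exp(ref[, 1]) - tr$N) / tr$N), 1e-5)
  expect_lt(max(abs(ref[, 2] - tr$x)), 1e-6)
})

test_that("K -> 0 converges to the fixed-x single-cell limit", {
  sched <- make_schedule()
  days <- seq(0, 500, by = 25)
  base <- ad_params(gamma_S = 0.02, gamma_R = 0.008, delta_S = 0.05,
                    delta_R = 0, B_gamma = 1, B_delta = 1)
  fixed <- simulate_single(gamma_of_x(0, base), delta_of_x(0, base),
                           sched, 200, days)
  dev <- sapply(c(0.01, 1e-4, 1e-6), function(K) {
    p <- ad_params(gamma_S = 0.02, gamma_R = 0.008, delta_S = 0.05,
                   delta_R = 0, B_gamma = 1, B_delta = 1, K = K)
    max(abs(simulate_ad(p, sched, 200, days)$C - fixed$C) / fixed$C)
  })
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-4)
})
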