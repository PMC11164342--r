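test_that("objective is zero at the generating parameters and penalises infeasibility", {
  p <- make_single_cell_patient(0.02, 0.05)
  th <- c(gamma_S = 0.02, delta_S = 0.05)
  expect_lt(objective(th, p, "single"), 1e-18)
  # one measurement off by a factor e gives squared-log-error 1
  sched <- make_schedule(starts = 0, n_cycles = 2)
  m <- data.frame(day = c(0, 10), ca125 = c(100, 100 * exp(-0.5) * exp(1)))
  pat <- ca125_patient("E1", m, sched, last_followup_day = 50)
  expect_equal(objective(c(gamma_S = 0.01, delta_S = 0.05), pat, "single"),
               1, tolerance = 1e-10)
  # hand-computed residual sum on five points
  p5 <- make_single_cell_patient(0.02, 0.05)
  th_off <- c(gamma_S = 0.03, delta_S = 0.04)
  m5 <- p5$measurements[1:5, ]
  pred <- simulate_single(0.03, 0.04, p5$schedule, m5$ca125[1], m5$day)$C
  manual <- sum((log(m5$ca125) - log(pred))^2)
  pat5 <- ca125_patient("M5", m5, p5$schedule, last_followup_day = 900)
  expect_equal(objective(th_off, pat5, "single"), manual, tolerance = 1e-12)
})

test_that("reparameterisation is a bijection on random draws", {
  set.seed(13)
  for (v in c("single", "SR_R0", "SR_mu", "AD")) {
    spec <- ca125dyn:::.variant_spec(v)
    for (rep in 1:20) {
      psi <- rnorm(length(spec$names), 0, 2)
      theta <- ca125dyn:::.from_unconstrained(psi, spec)
      back <- ca125dyn:::.to_unconstrained(theta, spec)
      expect_equal(unname(back), unname(psi), tolerance = 1e-12)
    }
  }
})

test_that("fitting windows cut at the start of the following line", {
  p <- make_single_cell_patient()
  lines <- p$schedule$lines
  w2 <- fitting_window(p, "two")
  expect_equal(w2$cutoff_day, lines$start_day[3])
  expect_equal(fitting_window(p, "all")$cutoff_day, Inf)
  # degenerates to all data when the patient has at most k lines
  expect_equal(fitting_window(p, "four")$cutoff_day, Inf)
})

test_that("noiseless single-cell data are recovered exactly and reproducibly", {
  p <- make_single_cell_patient(0.0142, 0.04421)
  ctl <- fit_control(n_restarts = 3, seed = 42)
  f1 <- ca125_fit(p, "single", control = ctl)
  expect_true(f1$converged)
  expect_lt(f1$rss, 1e-12)
  expect_equal(coef(f1)[["gamma_S"]], 0.0142, tolerance = 1e-4)
  expect_equal(coef(f1)[["delta_S"]], 0.04421, tolerance = 1e-4)
  # bit-for-bit reproducibility under the same control
  f2 <- ca125_fit(p, "single", control = ctl)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
})

test_that("two-compartment variants collapse gracefully on single-cell data", {
  p <- make_single_cell_patient(0.02, 0.05)
  ctl <- fit_control(n_restarts = 6, seed = 7)
  f_single <- ca125_fit(p, "single", control = ctl)
  f_sr <- ca125_fit(p, "SR_R0", control = ctl)
  expect_lt(f_single$rss, 1e-10)
  # nesting: the richer model cannot do materially better than zero
  expect_lt(f_sr$rss, 1e-6)
})

test_that("insufficient data inside the window is refused", {
  sched <- make_schedule(starts = 0, n_cycles = 3)
  m <- data.frame(day = c(0, 21, 42), ca125 = c(100, 80, 60))
  pat <- ca125_patient("S1", m, sched, last_followup_day = 100)
  expect_error(ca125_fit(pat, "SR_R0"), "insufficient data")
  tab <- fit_cohort(ca125_cohort(list(pat)), variants = "SR_R0")
  expect_false(tab$table$converged[1])
  expect_match(tab$table$reason[1], "insufficient")
})

test_that("fit_cohort enumerates the patient x variant x window grid", {
  cfg <- generator_config(n_patients = 2, seed = 5, noise_sd = 0.1)
  coh <- generate_cohort(cfg)$cohort
  tab <- fit_cohort(coh, variants = c("single", "SR_R0"), windows = "all",
                    control = fit_control(n_restarts = 2, maxit = 500))
  expect_equal(nrow(tab$table), 4)
  expect_setequal(unique(tab$table$variant), c("single", "SR_R0"))
})

test_that("SR_R0 recovery on a noiseless two-compartment patient", {
  cfg <- generator_config(n_patients = 6, seed = 88, noise_sd = 0,
                          n_lines_range = c(4L, 4L))
  g <- generate_cohort(cfg)
  npts <- vapply(g$cohort, function(p) nrow(p$measurements), 0L)
  i <- which(npts >= 25)[1]
  f <- ca125_fit(g$cohort[[i]], "SR_R0",
                 control = fit_control(n_restarts = 25, seed = 9,
                                       jitter_sd = 1.5, maxit = 5000,
                                       n_polish = 4))
  truth <- canonical_sr_truth(g$truth[i, ])
  expect_lt(max(abs(coef(f) - truth) / abs(truth)), 0.01)
  expect_lt(f$rss, 1e-10)
})

test_that("predictions beyond the window are exact on self-generated data", {
  cfg <- generator_config(n_patients = 4, seed = 123, noise_sd = 0,
                          n_lines_range = c(4L, 4L))
  g <- generate_cohort(cfg)
  npts <- vapply(g$cohort, function(p) nrow(p$measurements), 0L)
  i <- which(npts >= 25)[1]
  p <- g$cohort[[i]]
  f <- ca125_fit(p, "SR_R0", window = "two",
                 control = fit_control(n_restarts = 25, seed = 9,
                                       jitter_sd = 1.5, maxit = 5000,
                                       n_polish = 4))
  pr <- predict_future(f)
  expect_true(any(!pr$in_window))
  if (f$rss < 1e-12)
    expect_lt(max(abs(log(pr$observed) - log(pr$C))), 1e-3)
  # all-line window: prediction days equal fitting days
  f_all <- ca125_fit(p, "single", control = fit_control(n_restarts = 2))
  pr_all <- predict_future(f_all)
  expect_true(all(pr_all$in_window))
  expect_equal(pr_all$day, p$measurements$day)
})

test_that("AD fitting drives the objective to the noiseless floor", {
  cfg <- generator_config(n_patients = 1, seed = 77, noise_sd = 0,
                          model = "AD", n_lines_range = c(3L, 3L))
  g <- generate_cohort(cfg)
  f <- ca125_fit(g$cohort[[1]], "AD",
                 control = fit_control(n_restarts = 3, seed = 5,
                                       maxit = 3000))
  expect_true(f$converged)
  expect_lt(f$rss, 1e-6)
})
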