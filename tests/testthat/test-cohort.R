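test_that("schedules expose closed on-treatment intervals and alpha", {
  sched <- make_schedule(starts = c(100), n_cycles = 5, spacing = 25)
  expect_equal(sched$lines$start_day, 100)
  expect_equal(sched$lines$end_day, 200)
  expect_identical(alpha(sched, 150), 1L)
  expect_identical(alpha(sched, 250), 0L)
  # boundary days are on-treatment (closed-interval convention)
  expect_identical(alpha(sched, c(100, 200)), c(1L, 1L))
  expect_identical(alpha(sched, c(99.999, 200.001)), c(0L, 0L))
})

test_that("alpha is piecewise constant and additive over intervals", {
  set.seed(11)
  for (rep in 1:20) {
    sched <- random_schedule()
    t <- runif(1, 0, max(sched$lines$end_day) + 200)
    ends <- c(sched$intervals)
    if (min(abs(t - ends)) > 1e-6) {
      eps <- min(abs(t - ends)) / 2
      expect_identical(alpha(sched, t - eps), alpha(sched, t + eps))
    }
    # total on-treatment time = sum of interval lengths via fine grid
    grid <- seq(0, max(sched$lines$end_day) + 100, by = 0.25)
    on_time <- sum(alpha(sched, grid)) * 0.25
    expect_equal(on_time,
                 sum(sched$intervals[, 2] - sched$intervals[, 1]),
                 tolerance = 0.05)
  }
})

test_that("read_cohort assembles, normalises day origin, and round-trips", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(patient_id = c("A", "B", "A", "B", "A"),
                       day = c(50, 10, 60, 30, 80),
                       ca125 = c(100, 200, 90, 150, 120)),
            file.path(dir, "m.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = c("A", "A", "B"),
                       line_number = c(1, 1, 1),
                       cycle_day = c(55, 76, 15),
                       drug = "carboplatin"),
            file.path(dir, "t.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = c("A", "B"), age_at_diagnosis = c(60, 55),
                       first_line_type = "PDS", residual_disease = "<=1cm",
                       pretreatment_ca125 = c(100, 200), uln = 35,
                       diagnosis_day = c(40, 0), progression_day = c(70, NA),
                       death_day = c(NA, 90), last_followup_day = c(300, NA)),
            file.path(dir, "o.csv"), row.names = FALSE)
  coh <- read_cohort(file.path(dir, "m.csv"), file.path(dir, "t.csv"),
                     file.path(dir, "o.csv"))
  expect_length(coh, 2)
  # interleaved rows partitioned correctly; day origin = first measurement
  expect_equal(coh[["A"]]$measurements$day, c(0, 10, 30))
  expect_equal(coh[["B"]]$measurements$day, c(0, 20))
  expect_equal(coh[["A"]]$schedule$lines$start_day, 5)
  expect_equal(coh[["A"]]$progression_day, 20)
  expect_equal(coh[["B"]]$death_day, 80)
  # round-trip on the normalised representation
  out <- withr::local_tempdir()
  write_cohort(coh, out)
  coh2 <- read_cohort(file.path(out, "measurements.csv"),
                      file.path(out, "treatments.csv"),
                      file.path(out, "outcomes.csv"))
  expect_equal(coh2[["A"]]$measurements, coh[["A"]]$measurements)
  expect_equal(coh2[["B"]]$schedule$lines, coh[["B"]]$schedule$lines)
  expect_equal(coh2[["A"]]$progression_day, coh[["A"]]$progression_day)
})

test_that("validation rejects malformed inputs", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(patient_id = "A", day = 0, value = 5),
            file.path(dir, "m.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = character(), line_number = integer(),
                       cycle_day = numeric(), drug = character()),
            file.path(dir, "t.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = "A", age_at_diagnosis = 60,
                       first_line_type = "PDS", residual_disease = "",
                       pretreatment_ca125 = 10, uln = 35, diagnosis_day = 0,
                       progression_day = NA, death_day = NA,
                       last_followup_day = 100),
            file.path(dir, "o.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "m.csv"), file.path(dir, "t.csv"),
                           file.path(dir, "o.csv")), "ca125")
  expect_error(ca125_patient("X", data.frame(day = c(0, 5), ca125 = c(10, -5)),
                             ca125_schedule(data.frame(line_number = integer(),
                                                       cycle_day = numeric())),
                             last_followup_day = 10),
               "positive")
  expect_error(ca125_patient("X", data.frame(day = c(0, 0), ca125 = c(10, 12)),
                             ca125_schedule(data.frame(line_number = integer(),
                                                       cycle_day = numeric())),
                             last_followup_day = 10),
               "duplicate")
})

test_that("eligibility filtering retains exactly the qualifying patients", {
  base <- function(id, n_meas = 10, n_lines = 3, platinum = TRUE,
                   progressed = TRUE) {
    sched <- make_schedule(starts = 100 + 150 * (seq_len(n_lines) - 1L),
                           n_cycles = 3,
                           drugs = if (platinum) "carboplatin" else
                             "topotecan")
    days <- seq(0, 700, length.out = n_meas)
    ca125_patient(id, data.frame(day = days, ca125 = 50 + days / 10), sched,
                  progression_day = if (progressed) 120 else NA_real_,
                  last_followup_day = 900)
  }
  coh <- ca125_cohort(list(
    base("ok1"), base("ok2"), base("ok3"),
    base("few_points", n_meas = 6),        # exactly 6 is too few
    base("one_line", n_lines = 1),
    base("no_platinum", platinum = FALSE),
    base("no_progression", progressed = FALSE),
    base("ok4"), base("ok5"), base("ok6")))
  kept <- filter_eligible(coh)
  expect_setequal(names(kept), c("ok1", "ok2", "ok3", "ok4", "ok5", "ok6"))
  # strictly more than six points required: 7 passes
  coh7 <- ca125_cohort(list(base("seven", n_meas = 7)))
  expect_length(filter_eligible(coh7), 1)
  # idempotent
  expect_identical(names(filter_eligible(kept)), names(kept))
})
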