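# Shared fixtures: small deterministic schedules and patients built in code.

make_schedule <- function(starts = c(10, 200, 420), n_cycles = 4,
                          spacing = 21, drugs = "carboplatin") {
  cyc <- do.call(rbind, lapply(seq_along(starts), function(k)
    data.frame(line_number = k,
               cycle_day = starts[k] + spacing * (seq_len(n_cycles) - 1L),
               drug = drugs[min(k, length(drugs))])))
  ca125_schedule(cyc)
}

# Patient whose measurements lie exactly on a single-cell trajectory.
make_single_cell_patient <- function(gamma_S = 0.0142, delta_S = 0.04421,
                                     C0 = 300, id = "SC1",
                                     schedule = make_schedule()) {
  days <- sort(unique(c(0, schedule$cycles$cycle_day,
                        as.vector(vapply(seq_len(nrow(schedule$lines) - 1L),
                          function(i) {
                            a <- schedule$lines$end_day[i]
                            b <- schedule$lines$start_day[i + 1L]
                            a + (b - a) * c(1, 2) / 3
                          }, numeric(2))),
                        max(schedule$lines$end_day) + c(40, 90, 140))))
  C <- simulate_single(gamma_S, delta_S, schedule, C0, days)$C
  ca125_patient(id, data.frame(day = days, ca125 = C), schedule,
                progression_day = schedule$lines$start_day[2L] - 5,
                last_followup_day = max(days) + 500)
}

# Canonical labelling of a ground-truth SR_R0 parameter vector (resistant
# compartment = smaller on-treatment death rate), mirroring the fit output.
canonical_sr_truth <- function(truth_row) {
  th <- c(gamma_R = truth_row$gamma_R, gamma_S = truth_row$gamma_S,
          delta_R = truth_row$delta_R, delta_S = truth_row$delta_S,
          R0_frac = truth_row$R0_frac)
  if (th[["delta_R"]] > th[["delta_S"]] && th[["delta_R"]] >= 0) {
    th[c("gamma_R", "gamma_S", "delta_R", "delta_S")] <-
      th[c("gamma_S", "gamma_R", "delta_S", "delta_R")]
    th[["R0_frac"]] <- 1 - th[["R0_frac"]]
  }
  th
}

random_sr_params <- function() {
  sr_params(gamma_R = runif(1, 0, 0.05), gamma_S = runif(1, 0, 0.05),
            delta_R = runif(1, -0.03, 0.04), delta_S = runif(1, 0, 0.09),
            mu = if (runif(1) < 0.5) 0 else 10^runif(1, -5, -3),
            R0 = runif(1, 0, 100))
}

random_schedule <- function() {
  n_lines <- sample(1:5, 1)
  n_cycles <- sample(2:8, 1)
  span <- (n_cycles - 1) * 21
  starts <- cumsum(c(runif(1, 0, 30), rep(span, n_lines - 1) +
                       runif(max(0, n_lines - 1), 30, 300)))
  make_schedule(starts = starts, n_cycles = n_cycles)
}
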