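# Truncated normal draw by rejection (clamped after max_tries).
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        max_tries = 1000L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- stats::rnorm(1, mean, sd)
    tries <- 1L
    while ((v < lower || v > upper) && tries < max_tries) {
      v <- stats::rnorm(1, mean, sd)
      tries <- tries + 1L
    }
    out[i] <- min(max(v, lower), upper)
  }
  out
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the structure of a multi-line chemotherapy cohort:
#' dosing cycles 21 days apart, line durations with median 106 days and
#' between-line gaps with median 165 days (log-normal, right-skewed),
#' parameter priors centred on the across-patient summary of the
#' sensitive/resistant model (delta_R -0.00018, delta_S 0.04421, gamma_S
#' 0.0142, gamma_R 0.01024, ln R0 0.1208 with prior sd widened to 1 because
#' the source summary's sd is inconsistent with its range), multiplicative
#' log-normal measurement noise (sd 0.2 on log CA-125), and exponential
#' survival whose log-hazard increases in gamma_S and gamma_R and decreases
#' in delta_R.
#'
#' Three qualitative response patterns are generated: \code{fluctuating}
#' (CA-125 falls on each line and regrows between lines),
#' \code{primary_resistant} (negative delta_R and a large initial resistant
#' fraction, so CA-125 rises through treatment after an initial dip) and
#' \code{durable} (large delta_S, slow regrowth, CA-125 stays low).
#'
#' @param n_patients cohort size.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param model generating model: \code{"SR_R0"}, \code{"SR_mu"},
#'   \code{"single"} or \code{"AD"}.
#' @param priors named list of \code{c(mean, sd)} for \code{gamma_R},
#'   \code{gamma_S}, \code{delta_R}, \code{delta_S} and \code{ln_R0}.
#' @param noise_sd sd of additive noise on log CA-125.
#' @param cycle_interval days between dosing cycles.
#' @param line_duration_median,gap_median,duration_sdlog log-normal schedule
#'   parameters (days).
#' @param n_lines_range integer pair, inclusive range of treatment lines.
#' @param pattern_weights probabilities of the three response patterns (must
#'   sum to 1).
#' @param survival_link named coefficients mapping \code{(gamma_S, gamma_R,
#'   delta_R)} to the log-hazard.
#' @param baseline_loghazard intercept of the log-hazard (per day).
#' @param censor_horizon administrative censoring, days after end of line 2.
#' @param drift optional \code{list(after_line =, growth =)}: after the end
#'   of the given line the true trajectory switches to treatment-insensitive
#'   exponential growth at the given rate, emulating a resistant relapse that
#'   the fitted window cannot anticipate.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_patients = 100L, seed = 1L, model = "SR_R0",
                             priors = list(
                               gamma_R = c(0.01024, 0.0127),
                               gamma_S = c(0.0142, 0.0167),
                               delta_R = c(-0.00018, 0.0127),
                               delta_S = c(0.04421, 0.0241),
                               ln_R0 = c(0.1208, 1.0)),
                             noise_sd = 0.2, cycle_interval = 21,
                             line_duration_median = 106, gap_median = 165,
                             duration_sdlog = 0.4,
                             n_lines_range = c(2L, 6L),
                             pattern_weights = c(fluctuating = 0.6,
                                                 primary_resistant = 0.25,
                                                 durable = 0.15),
                             survival_link = c(gamma_S = 25, gamma_R = 25,
                                               delta_R = -25),
                             baseline_loghazard = -7.1,
                             censor_horizon = 2500,
                             drift = NULL) {
  stopifnot(abs(sum(pattern_weights) - 1) < 1e-8, noise_sd >= 0,
            length(n_lines_range) == 2L,
            n_lines_range[1L] >= 1L,
            n_lines_range[1L] <= n_lines_range[2L])
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 model = model, priors = priors, noise_sd = noise_sd,
                 cycle_interval = cycle_interval,
                 line_duration_median = line_duration_median,
                 gap_median = gap_median, duration_sdlog = duration_sdlog,
                 n_lines_range = as.integer(n_lines_range),
                 pattern_weights = pattern_weights,
                 survival_link = survival_link,
                 baseline_loghazard = baseline_loghazard,
                 censor_horizon = censor_horizon, drift = drift),
            class = "generator_config")
}

#' Draw a treatment schedule
#'
#' Number of lines uniform over \code{n_lines_range}; each line consists of
#' cycles \code{cycle_interval} days apart whose total span is drawn
#' log-normal with the configured median; between-line gaps are log-normal
#' with the configured median (floored at 30 days). The first line starts 7
#' days after the baseline measurement (day 0) and always contains a
#' platinum agent.
#'
#' @param config a \code{\link{generator_config}}.
#' @return a \code{\link{ca125_schedule}}. Uses the current RNG stream.
#' @export
generate_schedule <- function(config) {
  choices <- seq(config$n_lines_range[1L], config$n_lines_range[2L])
  n_lines <- choices[sample.int(length(choices), 1L)]
  other_drugs <- c("carboplatin", "paclitaxel", "gemcitabine",
                   "liposomal doxorubicin", "topotecan")
  start <- 7
  cyc <- list()
  for (k in seq_len(n_lines)) {
    span <- stats::rlnorm(1, log(config$line_duration_median),
                          config$duration_sdlog)
    n_cycles <- max(2L, as.integer(round(span / config$cycle_interval)) + 1L)
    days <- start + config$cycle_interval * (seq_len(n_cycles) - 1L)
    drug <- if (k == 1L) "carboplatin+paclitaxel" else
      sample(other_drugs, 1L)
    cyc[[k]] <- data.frame(line_number = k, cycle_day = days, drug = drug)
    gap <- max(30, stats::rlnorm(1, log(config$gap_median),
                                 config$duration_sdlog))
    start <- max(days) + gap
  }
  ca125_schedule(do.call(rbind, cyc))
}

# Draw model parameters for one patient given its response pattern.
.draw_theta <- function(config, pattern) {
  pr <- config$priors
  gamma_R <- .rtruncnorm(1, pr$gamma_R[1L], pr$gamma_R[2L], lower = 0)
  gamma_S <- .rtruncnorm(1, pr$gamma_S[1L], pr$gamma_S[2L], lower = 0)
  delta_R <- stats::rnorm(1, pr$delta_R[1L], pr$delta_R[2L])
  delta_S <- .rtruncnorm(1, pr$delta_S[1L], pr$delta_S[2L], lower = 0)
  R0 <- exp(stats::rnorm(1, pr$ln_R0[1L], pr$ln_R0[2L]))
  if (pattern == "fluctuating") {
    delta_S <- .rtruncnorm(1, pr$delta_S[1L], pr$delta_S[2L], lower = 0.02)
    gamma_S <- .rtruncnorm(1, pr$gamma_S[1L], pr$gamma_S[2L], lower = 0.005)
  } else if (pattern == "primary_resistant") {
    delta_R <- -abs(stats::rnorm(1, pr$delta_R[1L], pr$delta_R[2L])) - 0.001
  } else if (pattern == "durable") {
    delta_S <- .rtruncnorm(1, pr$delta_S[1L] + 0.02, pr$delta_S[2L],
                           lower = 0.04)
    gamma_S <- 0.25 * gamma_S
    gamma_R <- 0.25 * gamma_R
  }
  mu <- if (config$model == "SR_mu") exp(stats::rnorm(1, log(1e-4), 1)) else 0
  list(gamma_R = gamma_R, gamma_S = gamma_S, delta_R = delta_R,
       delta_S = delta_S, mu = mu, R0 = R0,
       A_gamma = stats::rnorm(1, 0, 1), A_delta = stats::rnorm(1, 0, 1),
       B_gamma = exp(stats::rnorm(1, 0, 0.3)),
       B_delta = exp(stats::rnorm(1, 0, 0.3)))
}

# Measurement days: baseline day 0, every cycle day, two points inside each
# between-line gap, and three follow-up points after the last line.
.measurement_days <- function(schedule) {
  lines <- schedule$lines
  days <- c(0, schedule$cycles$cycle_day)
  if (nrow(lines) > 1L) {
    for (i in seq_len(nrow(lines) - 1L)) {
      a <- lines$end_day[i]; b <- lines$start_day[i + 1L]
      days <- c(days, a + (b - a) * c(1, 2) / 3)
    }
  }
  last <- lines$end_day[nrow(lines)]
  days <- c(days, last + c(30, 90, 150))
  sort(unique(round(days, 6)))
}

#' Generate one synthetic patient
#'
#' Draws a response pattern and model parameters, simulates the chosen model
#' along a drawn schedule, observes CA-125 with multiplicative log-normal
#' noise at baseline, cycle days, gap points and follow-up days, and draws a
#' survival time from an exponential model whose log-hazard is
#' \code{baseline_loghazard + survival_link . (gamma_S, gamma_R, delta_R)},
#' censored \code{censor_horizon} days after the end of line 2 (or of the
#' last line for single-line schedules).
#'
#' @param config a \code{\link{generator_config}}.
#' @param patient_id id string.
#' @return list with \code{patient} (a \code{\link{ca125_patient}}) and
#'   \code{truth} (one-row data.frame of generating parameters, pattern and
#'   survival ground truth). Uses the current RNG stream.
#' @export
generate_patient <- function(config, patient_id = "P001") {
  pattern <- sample(names(config$pattern_weights), 1L,
                    prob = config$pattern_weights)
  schedule <- generate_schedule(config)
  theta <- .draw_theta(config, pattern)
  C0 <- stats::rlnorm(1, log(300), 0.8)
  R0 <- switch(pattern,
               fluctuating = min(theta$R0, 0.2 * C0),
               primary_resistant = stats::runif(1, 0.3, 0.8) * C0,
               durable = min(theta$R0, 0.05 * C0))
  if (config$model %in% c("SR_mu", "single")) R0 <- 0
  theta$R0 <- R0
  days <- .measurement_days(schedule)
  true_C <- switch(config$model,
    SR_R0 = ,
    SR_mu = ,
    single = {
      p <- sr_params(gamma_R = theta$gamma_R, gamma_S = theta$gamma_S,
                     delta_R = theta$delta_R, delta_S = theta$delta_S,
                     mu = theta$mu, R0 = min(theta$R0, C0))
      if (config$model == "single")
        p <- sr_params(gamma_R = 0, gamma_S = theta$gamma_S, delta_R = 0,
                       delta_S = theta$delta_S)
      simulate_sr(p, schedule, C0, days)$C
    },
    AD = simulate_ad(ad_params(gamma_R = theta$gamma_R,
                               gamma_S = theta$gamma_S,
                               delta_R = theta$delta_R,
                               delta_S = theta$delta_S,
                               A_gamma = theta$A_gamma,
                               A_delta = theta$A_delta,
                               B_gamma = theta$B_gamma,
                               B_delta = theta$B_delta),
                     schedule, C0, days)$C,
    stop("unknown generating model: ", config$model))
  if (!is.null(config$drift)) {
    lines <- schedule$lines
    kd <- min(config$drift$after_line, nrow(lines))
    t_d <- lines$end_day[kd]
    C_d <- true_C[which.min(abs(days - t_d))]
    post <- days > t_d
    true_C[post] <- C_d * exp(config$drift$growth * (days[post] - t_d))
  }
  # standard normals scaled afterwards, so the RNG stream (and hence every
  # other draw) is identical across noise settings
  obs <- true_C * exp(config$noise_sd * stats::rnorm(length(days)))
  lines <- schedule$lines
  anchor <- lines$end_day[min(2L, nrow(lines))]
  loghaz <- config$baseline_loghazard +
    sum(config$survival_link * unlist(theta[names(config$survival_link)]))
  surv_time <- stats::rexp(1, exp(loghaz))
  event <- surv_time <= config$censor_horizon
  death_day <- if (event) anchor + surv_time else NA_real_
  followup_day <- max(anchor + config$censor_horizon, max(days))
  progression_day <- if (nrow(lines) >= 2L) lines$start_day[2L] - 10 else
    NA_real_
  patient <- ca125_patient(
    patient_id = patient_id,
    measurements = data.frame(day = days, ca125 = obs),
    schedule = schedule,
    age_at_diagnosis = round(stats::rnorm(1, 60, 10), 1),
    first_line_type = sample(c("PDS", "NACT"), 1L, prob = c(0.8, 0.2)),
    residual_disease = sample(c("<=1cm", ">1cm", NA), 1L,
                              prob = c(0.3, 0.6, 0.1)),
    pretreatment_ca125 = obs[1L],
    uln = 35,
    diagnosis_day = -30,
    progression_day = progression_day,
    death_day = death_day,
    last_followup_day = followup_day)
  truth <- data.frame(patient_id = patient_id, pattern = pattern,
                      model = config$model,
                      gamma_R = theta$gamma_R, gamma_S = theta$gamma_S,
                      delta_R = theta$delta_R, delta_S = theta$delta_S,
                      mu = theta$mu, R0 = theta$R0,
                      R0_frac = theta$R0 / C0, C0 = C0,
                      A_gamma = theta$A_gamma, A_delta = theta$A_delta,
                      B_gamma = theta$B_gamma, B_delta = theta$B_delta,
                      survival_time = surv_time, event = as.integer(event))
  list(patient = patient, truth = truth)
}

#' Generate a synthetic cohort
#'
#' \code{config$n_patients} independent draws of
#' \code{\link{generate_patient}} under a fixed seed; fully reproducible.
#'
#' @param config a \code{\link{generator_config}}.
#' @param out_dir optional directory: if given, writes
#'   \code{measurements.csv}, \code{treatments.csv}, \code{outcomes.csv} and
#'   \code{ground_truth.csv} there.
#' @return list with \code{cohort} (a \code{\link{ca125_cohort}}) and
#'   \code{truth} (data.frame of generating parameters).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  draws <- lapply(seq_len(config$n_patients), function(i)
    generate_patient(config, sprintf("P%04d", i)))
  cohort <- ca125_cohort(lapply(draws, `[[`, "patient"))
  truth <- if (length(draws)) do.call(rbind, lapply(draws, `[[`, "truth")) else
    data.frame(patient_id = character())
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir)
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE, na = "")
  }
  list(cohort = cohort, truth = truth)
}
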