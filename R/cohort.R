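#' Construct a treatment schedule from dosing cycles
#'
#' A schedule is an ordered set of treatment lines, each a group of dosing
#' cycles. The on-treatment interval of a line is the closed interval from its
#' first to its last cycle day, including intra-line gaps between cycles. The
#' treatment indicator \code{\link{alpha}} is 1 on these intervals and 0
#' elsewhere.
#'
#' @param cycles data.frame with columns \code{line_number} (positive
#'   integers), \code{cycle_day} (dosing days), and optionally \code{drug}
#'   (free-text label per cycle).
#' @return An object of class \code{ca125_schedule} with elements
#'   \code{cycles} (the input, sorted), \code{lines} (one row per line:
#'   \code{line_number}, \code{start_day}, \code{end_day}, \code{n_cycles}),
#'   and \code{intervals} (two-column matrix of on-treatment intervals).
#' @export
#' @examples
#' sched <- ca125_schedule(data.frame(
#'   line_number = c(1, 1, 1, 2, 2),
#'   cycle_day = c(0, 21, 42, 200, 221)
#' ))
#' sched$lines
ca125_schedule <- function(cycles) {
  if (nrow(cycles) == 0L) {
    lines <- data.frame(line_number = integer(), start_day = numeric(),
                        end_day = numeric(), n_cycles = integer())
    out <- list(cycles = cycles, lines = lines,
                intervals = matrix(numeric(), ncol = 2L,
                                   dimnames = list(NULL, c("start_day", "end_day"))))
    class(out) <- "ca125_schedule"
    return(out)
  }
  stopifnot(all(c("line_number", "cycle_day") %in% names(cycles)))
  if (is.null(cycles$drug)) cycles$drug <- NA_character_
  if (any(!is.finite(cycles$cycle_day)))
    stop("non-finite cycle_day in schedule")
  cycles <- cycles[order(cycles$line_number, cycles$cycle_day), , drop = FALSE]
  rownames(cycles) <- NULL
  ln <- sort(unique(cycles$line_number))
  if (any(ln <= 0) || any(ln != as.integer(ln)))
    stop("line_number must be a positive integer")
  start_day <- vapply(ln, function(k) min(cycles$cycle_day[cycles$line_number == k]), 0)
  end_day   <- vapply(ln, function(k) max(cycles$cycle_day[cycles$line_number == k]), 0)
  n_cycles  <- vapply(ln, function(k) sum(cycles$line_number == k), 0L)
  ord <- order(start_day)
  lines <- data.frame(line_number = ln[ord], start_day = start_day[ord],
                      end_day = end_day[ord], n_cycles = n_cycles[ord])
  if (nrow(lines) > 1L &&
      any(lines$start_day[-1L] <= lines$end_day[-nrow(lines)]))
    stop("on-treatment intervals of distinct lines overlap")
  out <- list(cycles = cycles, lines = lines,
              intervals = cbind(start_day = lines$start_day,
                                end_day = lines$end_day))
  class(out) <- "ca125_schedule"
  out
}

#' @export
print.ca125_schedule <- function(x, ...) {
  cat("Treatment schedule:", nrow(x$lines), "line(s)\n")
  if (nrow(x$lines)) print(x$lines, row.names = FALSE)
  invisible(x)
}

#' Treatment indicator
#'
#' Returns 1 when \code{t} lies inside a closed on-treatment interval
#' \code{[start_day, end_day]} of some line, otherwise 0. Days exactly on an
#' interval boundary count as on-treatment.
#'
#' @param schedule a \code{\link{ca125_schedule}}.
#' @param t numeric vector of days.
#' @return integer vector of 0/1, same length as \code{t}.
#' @export
alpha <- function(schedule, t) {
  stopifnot(inherits(schedule, "ca125_schedule"))
  iv <- schedule$intervals
  if (nrow(iv) == 0L) return(integer(length(t)))
  out <- integer(length(t))
  for (i in seq_len(nrow(iv)))
    out <- out | (t >= iv[i, 1L] & t <= iv[i, 2L])
  as.integer(out)
}

#' Construct a patient record
#'
#' Bundles one patient's CA-125 series, treatment schedule, clinical
#' covariates and outcome times. Days are offsets from the patient's first
#' CA-125 measurement (day 0), the time origin used throughout; use
#' \code{\link{read_cohort}} to build records from raw files with arbitrary
#' day origins.
#'
#' @param patient_id character scalar.
#' @param measurements data.frame with columns \code{day} and \code{ca125}
#'   (U/mL, positive); sorted by day internally.
#' @param schedule a \code{\link{ca125_schedule}}.
#' @param age_at_diagnosis,first_line_type,residual_disease,pretreatment_ca125,uln
#'   clinical covariates; \code{first_line_type} one of \code{"PDS"},
#'   \code{"NACT"}; \code{residual_disease} one of \code{"<=1cm"},
#'   \code{">1cm"}; missing values allowed (\code{NA}).
#' @param diagnosis_day,progression_day,death_day,last_followup_day outcome
#'   days (may be \code{NA}; a patient without \code{death_day} must have
#'   \code{last_followup_day}).
#' @return An object of class \code{ca125_patient}.
#' @export
ca125_patient <- function(patient_id, measurements, schedule,
                          age_at_diagnosis = NA_real_,
                          first_line_type = NA_character_,
                          residual_disease = NA_character_,
                          pretreatment_ca125 = NA_real_,
                          uln = 35,
                          diagnosis_day = NA_real_,
                          progression_day = NA_real_,
                          death_day = NA_real_,
                          last_followup_day = NA_real_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            is.data.frame(measurements),
            all(c("day", "ca125") %in% names(measurements)),
            inherits(schedule, "ca125_schedule"))
  if (any(!is.finite(measurements$day)))
    stop("measurement days must be finite")
  if (any(!is.finite(measurements$ca125)) || any(measurements$ca125 <= 0))
    stop("CA-125 values must be positive: patient ", patient_id)
  if (anyDuplicated(measurements$day))
    stop("duplicate measurement day for patient ", patient_id)
  measurements <- measurements[order(measurements$day),
                               c("day", "ca125"), drop = FALSE]
  rownames(measurements) <- NULL
  if (is.na(death_day) && is.na(last_followup_day))
    stop("patient ", patient_id,
         ": last_followup_day required when death_day is absent")
  if (!is.na(progression_day) && !is.na(diagnosis_day) &&
      progression_day < diagnosis_day)
    stop("patient ", patient_id, ": progression before diagnosis")
  structure(list(
    patient_id = patient_id,
    measurements = measurements,
    schedule = schedule,
    age_at_diagnosis = age_at_diagnosis,
    first_line_type = first_line_type,
    residual_disease = residual_disease,
    pretreatment_ca125 = pretreatment_ca125,
    uln = uln,
    diagnosis_day = diagnosis_day,
    progression_day = progression_day,
    death_day = death_day,
    last_followup_day = last_followup_day
  ), class = "ca125_patient")
}

#' @export
print.ca125_patient <- function(x, ...) {
  cat("CA-125 patient record:", x$patient_id, "\n",
      nrow(x$measurements), "measurements over",
      diff(range(x$measurements$day)), "days;",
      nrow(x$schedule$lines), "treatment line(s)\n")
  invisible(x)
}

#' Construct a cohort
#'
#' @param patients list of \code{\link{ca125_patient}} records (ids must be
#'   unique).
#' @return An object of class \code{ca125_cohort}: a named list of patient
#'   records.
#' @export
ca125_cohort <- function(patients) {
  stopifnot(all(vapply(patients, inherits, TRUE, "ca125_patient")))
  ids <- vapply(patients, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  names(patients) <- ids
  structure(patients, class = "ca125_cohort")
}

#' @export
print.ca125_cohort <- function(x, ...) {
  cat("CA-125 cohort:", length(x), "patient(s)\n")
  invisible(x)
}

#' @export
`[.ca125_cohort` <- function(x, i) {
  structure(unclass(x)[i], class = "ca125_cohort")
}

#' Read a cohort from tabular files
#'
#' Assembles patient records from three CSV files: measurements
#' (\code{patient_id, day, ca125}), treatments
#' (\code{patient_id, line_number, cycle_day, drug}) and outcomes
#' (\code{patient_id, age_at_diagnosis, first_line_type, residual_disease,
#' pretreatment_ca125, uln, diagnosis_day, progression_day, death_day,
#' last_followup_day}; empty cell = absent). All days of each patient are
#' re-expressed as offsets from that patient's first CA-125 measurement,
#' which becomes day 0.
#'
#' @param measurements_path,treatments_path,outcomes_path file paths.
#' @return A \code{\link{ca125_cohort}}.
#' @export
read_cohort <- function(measurements_path, treatments_path, outcomes_path) {
  meas <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  trt  <- utils::read.csv(treatments_path, stringsAsFactors = FALSE)
  outc <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)
  .require_cols(meas, c("patient_id", "day", "ca125"), "measurements")
  .require_cols(trt, c("patient_id", "line_number", "cycle_day", "drug"),
                "treatments")
  .require_cols(outc, c("patient_id", "age_at_diagnosis", "first_line_type",
                        "residual_disease", "pretreatment_ca125", "uln",
                        "diagnosis_day", "progression_day", "death_day",
                        "last_followup_day"), "outcomes")
  if (any(!is.finite(meas$ca125)) || any(meas$ca125 <= 0))
    stop("non-positive CA-125 value in measurements file")
  if (anyDuplicated(meas[c("patient_id", "day")]))
    stop("duplicate (patient_id, day) measurement")
  outc$patient_id <- as.character(outc$patient_id)
  meas$patient_id <- as.character(meas$patient_id)
  trt$patient_id <- as.character(trt$patient_id)
  patients <- lapply(unique(meas$patient_id), function(id) {
    m <- meas[meas$patient_id == id, , drop = FALSE]
    origin <- min(m$day)
    cyc <- trt[trt$patient_id == id, c("line_number", "cycle_day", "drug"),
               drop = FALSE]
    cyc$cycle_day <- cyc$cycle_day - origin
    o <- outc[outc$patient_id == id, , drop = FALSE]
    if (nrow(o) == 0L)
      o <- data.frame(age_at_diagnosis = NA_real_,
                      first_line_type = NA_character_,
                      residual_disease = NA_character_,
                      pretreatment_ca125 = NA_real_, uln = 35,
                      diagnosis_day = NA_real_, progression_day = NA_real_,
                      death_day = NA_real_, last_followup_day = max(m$day))
    shift <- function(v) {
      v <- suppressWarnings(as.numeric(v))
      ifelse(is.na(v), NA_real_, v - origin)
    }
    chr_or_na <- function(v) {
      v <- as.character(v)
      if (length(v) == 0L || is.na(v) || !nzchar(v)) NA_character_ else v
    }
    ca125_patient(
      patient_id = id,
      measurements = data.frame(day = m$day - origin, ca125 = m$ca125),
      schedule = ca125_schedule(cyc),
      age_at_diagnosis = suppressWarnings(as.numeric(o$age_at_diagnosis[1L])),
      first_line_type = chr_or_na(o$first_line_type[1L]),
      residual_disease = chr_or_na(o$residual_disease[1L]),
      pretreatment_ca125 = suppressWarnings(as.numeric(o$pretreatment_ca125[1L])),
      uln = suppressWarnings(as.numeric(o$uln[1L])),
      diagnosis_day = shift(o$diagnosis_day[1L]),
      progression_day = shift(o$progression_day[1L]),
      death_day = shift(o$death_day[1L]),
      last_followup_day = shift(o$last_followup_day[1L])
    )
  })
  ca125_cohort(patients)
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("format error: ", what, " file lacks column(s) ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Write a cohort to tabular files
#'
#' Inverse of \code{\link{read_cohort}} on already day-0-normalised cohorts:
#' writes \code{measurements.csv}, \code{treatments.csv} and
#' \code{outcomes.csv} into \code{dir}.
#'
#' @param cohort a \code{\link{ca125_cohort}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meas <- do.call(rbind, lapply(cohort, function(p)
    data.frame(patient_id = p$patient_id, p$measurements)))
  if (is.null(meas))
    meas <- data.frame(patient_id = character(), day = numeric(),
                       ca125 = numeric())
  trt <- do.call(rbind, lapply(cohort, function(p) {
    cyc <- p$schedule$cycles
    if (nrow(cyc) == 0L) return(NULL)
    data.frame(patient_id = p$patient_id, line_number = cyc$line_number,
               cycle_day = cyc$cycle_day, drug = cyc$drug)
  }))
  if (is.null(trt))
    trt <- data.frame(patient_id = character(), line_number = integer(),
                      cycle_day = numeric(), drug = character())
  outc <- do.call(rbind, lapply(cohort, function(p)
    data.frame(patient_id = p$patient_id,
               age_at_diagnosis = p$age_at_diagnosis,
               first_line_type = p$first_line_type,
               residual_disease = p$residual_disease,
               pretreatment_ca125 = p$pretreatment_ca125,
               uln = p$uln, diagnosis_day = p$diagnosis_day,
               progression_day = p$progression_day, death_day = p$death_day,
               last_followup_day = p$last_followup_day)))
  if (is.null(outc))
    outc <- data.frame(patient_id = character(), age_at_diagnosis = numeric(),
                       first_line_type = character(),
                       residual_disease = character(),
                       pretreatment_ca125 = numeric(), uln = numeric(),
                       diagnosis_day = numeric(), progression_day = numeric(),
                       death_day = numeric(), last_followup_day = numeric())
  paths <- file.path(dir, c("measurements.csv", "treatments.csv",
                            "outcomes.csv"))
  utils::write.csv(meas, paths[1L], row.names = FALSE, na = "")
  utils::write.csv(trt, paths[2L], row.names = FALSE, na = "")
  utils::write.csv(outc, paths[3L], row.names = FALSE, na = "")
  invisible(paths)
}

#' Per-patient eligibility report
#'
#' Evaluates the study inclusion criteria for each patient: more than six
#' CA-125 measurements (i.e. at least 7), completion of second-line treatment
#' (at least two lines and the last recorded day not before the end of line
#' 2), a platinum-based first-line regimen, and recorded disease progression.
#'
#' @param cohort a \code{\link{ca125_cohort}}.
#' @param platinum_drugs character vector of platinum agent names matched
#'   case-insensitively as substrings of first-line drug labels.
#' @return data.frame with one row per patient and logical columns for each
#'   criterion plus \code{eligible}.
#' @export
eligibility <- function(cohort,
                        platinum_drugs = c("carboplatin", "cisplatin")) {
  rows <- lapply(cohort, function(p) {
    lines <- p$schedule$lines
    n_lines <- nrow(lines)
    # completion is judged from observation (measurements, follow-up, death),
    # not from the dosing calendar itself
    last_day <- max(c(p$measurements$day, p$death_day, p$last_followup_day),
                    na.rm = TRUE)
    second_line_done <- n_lines >= 2L && last_day >= lines$end_day[2L]
    first_drugs <- p$schedule$cycles$drug[p$schedule$cycles$line_number ==
                                            lines$line_number[1L]]
    platinum <- n_lines >= 1L && any(vapply(
      platinum_drugs,
      function(d) any(grepl(d, first_drugs, ignore.case = TRUE)),
      TRUE))
    data.frame(patient_id = p$patient_id,
               n_measurements = nrow(p$measurements),
               enough_points = nrow(p$measurements) >= 7L,
               second_line_completed = second_line_done,
               platinum_first_line = platinum,
               progression_recorded = !is.na(p$progression_day))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$eligible <- out$enough_points & out$second_line_completed &
    out$platinum_first_line & out$progression_recorded
  out
}

#' Filter a cohort to eligible patients
#'
#' Retains patients satisfying all criteria of \code{\link{eligibility}}.
#' Idempotent; the input cohort is not modified.
#'
#' @inheritParams eligibility
#' @return A \code{\link{ca125_cohort}} containing only eligible patients.
#' @export
filter_eligible <- function(cohort,
                            platinum_drugs = c("carboplatin", "cisplatin")) {
  rep <- eligibility(cohort, platinum_drugs)
  cohort[rep$patient_id[rep$eligible]]
}
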