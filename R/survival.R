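#' Assemble survival-analysis inputs from a cohort
#'
#' Overall survival time is measured from the end of second-line treatment to
#' death or last follow-up (avoiding the survivorship bias of timing from
#' diagnosis, since eligibility requires surviving through line 2). Clinical
#' covariates are resolved from the patient records; model- or data-derived
#' covariates are resolved from an optional per-patient table. Only complete
#' cases on the requested covariates are returned.
#'
#' Covariates resolvable from the cohort itself: \code{age_at_diagnosis},
#' \code{first_line_type}, \code{residual_disease},
#' \code{log_pretreatment_ca125}, \code{pfi} (end of first line to
#' progression, days).
#'
#' @param cohort a \code{\link{ca125_cohort}}.
#' @param covariates character vector of covariate names to include.
#' @param extra optional data.frame with a \code{patient_id} column supplying
#'   additional covariates (e.g. fitted model parameters or data-based
#'   traits).
#' @return data.frame with \code{patient_id}, \code{time} (days),
#'   \code{event} (1 = death) and one column per covariate; attribute
#'   \code{n_excluded} records how many patients were dropped.
#' @export
build_survival_inputs <- function(cohort, covariates = character(),
                                  extra = NULL) {
  rows <- lapply(cohort, function(p) {
    lines <- p$schedule$lines
    if (nrow(lines) < 2L) return(NULL)
    anchor <- lines$end_day[2L]
    end <- if (!is.na(p$death_day)) p$death_day else p$last_followup_day
    if (is.na(end) || end < anchor) return(NULL)
    base <- data.frame(patient_id = p$patient_id, time = end - anchor,
                       event = as.integer(!is.na(p$death_day)))
    base$age_at_diagnosis <- p$age_at_diagnosis
    base$first_line_type <- p$first_line_type
    base$residual_disease <- p$residual_disease
    base$log_pretreatment_ca125 <-
      if (!is.na(p$pretreatment_ca125) && p$pretreatment_ca125 > 0)
        log(p$pretreatment_ca125) else NA_real_
    base$pfi <- if (!is.na(p$progression_day))
      p$progression_day - lines$end_day[1L] else NA_real_
    base
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(structure(data.frame(patient_id = character(), time = numeric(),
                                event = integer()), n_excluded = length(cohort)))
  rownames(out) <- NULL
  if (!is.null(extra)) {
    stopifnot("patient_id" %in% names(extra))
    out <- merge(out, extra, by = "patient_id", all.x = TRUE, sort = FALSE)
  }
  unresolved <- setdiff(covariates, names(out))
  if (length(unresolved))
    stop("covariate(s) not resolvable: ", paste(unresolved, collapse = ", "))
  out <- out[c("patient_id", "time", "event", covariates)]
  n0 <- length(cohort)
  keep <- stats::complete.cases(out)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n0 - nrow(out)
  out
}

#' Median-split Kaplan-Meier comparison
#'
#' Splits patients at the median of a continuous covariate (values exactly at
#' the median join the lower group), estimates Kaplan-Meier curves per group
#' and tests their difference with the log-rank test (or the
#' Peto-Peto/Wilcoxon-type test).
#'
#' @param inputs as returned by \code{\link{build_survival_inputs}}.
#' @param covariate name of a continuous covariate in \code{inputs}.
#' @param test \code{"logrank"} (default) or \code{"wilcoxon"}.
#' @return list of class \code{median_split_km}: \code{survfit} object
#'   (\code{fit}), per-group median survival (\code{medians}), test
#'   statistic, p-value, group sizes, and the split value.
#' @export
median_split_km <- function(inputs, covariate,
                            test = c("logrank", "wilcoxon")) {
  test <- match.arg(test)
  v <- inputs[[covariate]]
  if (is.null(v)) stop("covariate not found: ", covariate)
  med <- stats::median(v)
  if (all(v == med)) stop("degenerate split: all values equal the median")
  group <- factor(ifelse(v <= med, "low", "high"), levels = c("low", "high"))
  if (min(table(group)) < 2L) stop("fewer than 2 patients in a group")
  dat <- data.frame(time = inputs$time, event = inputs$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat,
                           rho = if (test == "logrank") 0 else 1)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  med_tab <- summary(fit)$table
  medians <- if (is.matrix(med_tab)) med_tab[, "median"] else
    med_tab[["median"]]
  structure(list(fit = fit, medians = medians, statistic = sd$chisq,
                 p_value = p, n = table(group), split_value = med,
                 covariate = covariate, test = test),
            class = "median_split_km")
}

#' @export
print.median_split_km <- function(x, ...) {
  cat("Median split on", x$covariate, "at", format(x$split_value, digits = 4),
      "\n  groups (low/high):", x$n[["low"]], "/", x$n[["high"]],
      "\n  median survival:", paste(format(x$medians, digits = 5),
                                    collapse = " / "),
      "\n ", x$test, "chi-square =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.median_split_km <- function(x, ...) {
  graphics::plot(x$fit, col = c("steelblue", "firebrick"),
                 xlab = "days from end of second-line treatment",
                 ylab = "survival probability", ...)
  graphics::legend("topright", legend = c("low", "high"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Multivariate Cox proportional-hazards regression
#'
#' Partial-likelihood estimation (Efron tie handling) of adjusted hazard
#' ratios for a set of covariates. Categorical covariates contribute one
#' hazard ratio per non-reference level.
#'
#' @param inputs as returned by \code{\link{build_survival_inputs}}.
#' @param covariate_names covariates to include (must exist in
#'   \code{inputs}).
#' @param min_cases_per_covariate guardrail: required complete cases per
#'   covariate (default 10).
#' @return data.frame with one row per estimated coefficient:
#'   \code{covariate}, \code{hazard_ratio}, \code{ci_low}, \code{ci_high},
#'   \code{p_value}, \code{n_used}; the fitted \code{coxph} object is
#'   attached as attribute \code{model}.
#' @export
cox_multivariate <- function(inputs, covariate_names,
                             min_cases_per_covariate = 10) {
  missing_cov <- setdiff(covariate_names, names(inputs))
  if (length(missing_cov))
    stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "))
  dat <- inputs[c("time", "event", covariate_names)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < min_cases_per_covariate * length(covariate_names))
    stop("too few complete cases (", nrow(dat), ") for ",
         length(covariate_names), " covariates")
  for (cn in covariate_names)
    if (is.character(dat[[cn]])) dat[[cn]] <- factor(dat[[cn]])
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariate_names, collapse = " + ")))
  model <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w)))
        stop("Cox model failed (possible separation): ", conditionMessage(w))
      suppressWarnings(survival::coxph(fml, data = dat, ties = "efron"))
    })
  s <- summary(model)
  out <- data.frame(covariate = rownames(s$coefficients),
                    hazard_ratio = s$coefficients[, "exp(coef)"],
                    ci_low = s$conf.int[, "lower .95"],
                    ci_high = s$conf.int[, "upper .95"],
                    p_value = s$coefficients[, "Pr(>|z|)"],
                    n_used = nrow(dat))
  rownames(out) <- NULL
  attr(out, "model") <- model
  out
}
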