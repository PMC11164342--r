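#' Control settings for model fitting
#'
#' @param n_restarts number of multistart local optimisations (the first
#'   start is the trait-derived initial estimate, the rest are jittered
#'   copies on the unconstrained scale).
#' @param seed integer seed making the jitter (and hence the fit)
#'   reproducible.
#' @param maxit maximum Nelder-Mead iterations per start.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param n_polish extra Nelder-Mead runs restarted from the best point, to
#'   tighten convergence of the simplex.
#' @param jitter_sd standard deviation of the Gaussian jitter applied to the
#'   unconstrained parameters for restarts 2..n_restarts.
#' @param penalty finite objective value returned when a parameter set yields
#'   a non-positive or non-finite trajectory, so the simplex can contract
#'   away from infeasible regions.
#' @param ad_rtol integrator relative tolerance used when the adaptive
#'   dynamics model is evaluated inside the objective.
#' @param init optional named vector of initial natural-scale parameter
#'   values overriding the trait-derived start.
#' @return list of class \code{fit_control}.
#' @export
fit_control <- function(n_restarts = 20L, seed = 1L, maxit = 2000L,
                        reltol = 1e-12, n_polish = 2L, jitter_sd = 0.5,
                        penalty = 1e12, ad_rtol = 1e-6, init = NULL) {
  structure(list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 maxit = as.integer(maxit), reltol = reltol,
                 n_polish = as.integer(n_polish), jitter_sd = jitter_sd,
                 penalty = penalty, ad_rtol = ad_rtol, init = init),
            class = "fit_control")
}

# Variant descriptions: free parameter names and their transforms to the
# unconstrained optimisation scale. R0 is parameterised as a fraction of
# C(0) in (0, 1) so S(0) >= 0 by construction.
.variant_spec <- function(variant) {
  switch(variant,
    single = list(names = c("gamma_S", "delta_S"),
                  transform = c("log", "log")),
    SR_R0 = list(names = c("gamma_R", "gamma_S", "delta_R", "delta_S",
                           "R0_frac"),
                 transform = c("log", "log", "id", "log", "logit")),
    SR_mu = list(names = c("gamma_R", "gamma_S", "delta_R", "delta_S", "mu"),
                 transform = c("log", "log", "id", "log", "log")),
    AD = list(names = c("gamma_R", "gamma_S", "delta_R", "delta_S",
                        "A_gamma", "A_delta", "B_gamma", "B_delta"),
              transform = c("log", "log", "id", "log", "id", "id", "log",
                            "log")),
    stop("unknown model variant: ", variant)
  )
}

.to_unconstrained <- function(theta, spec) {
  psi <- theta
  for (i in seq_along(spec$names)) {
    psi[i] <- switch(spec$transform[i],
                     log = log(theta[i]),
                     logit = stats::qlogis(theta[i]),
                     id = theta[i])
  }
  psi
}

.from_unconstrained <- function(psi, spec) {
  theta <- psi
  for (i in seq_along(spec$names)) {
    theta[i] <- switch(spec$transform[i],
                       log = exp(psi[i]),
                       logit = stats::plogis(psi[i]),
                       id = psi[i])
  }
  names(theta) <- spec$names
  theta
}

#' Resolve a fitting window to its cutoff day
#'
#' A k-line window includes all measurements up to (and including) the start
#' day of line k+1, i.e. the fitted lines plus the gaps following them; an
#' all-line window includes every measurement. If the patient has at most k
#' lines the k-line window degenerates to all data.
#'
#' @param patient a \code{\link{ca125_patient}}.
#' @param window one of \code{"all"}, \code{"two"}, \code{"three"},
#'   \code{"four"} or a positive integer number of fitted lines.
#' @return list with \code{kind} and \code{cutoff_day}.
#' @export
fitting_window <- function(patient, window = "all") {
  k <- if (is.numeric(window)) as.integer(window) else
    switch(window, all = Inf, two = 2L, three = 3L, four = 4L,
           stop("unknown window kind: ", window))
  lines <- patient$schedule$lines
  cutoff <- if (is.infinite(k) || nrow(lines) <= k) Inf else
    lines$start_day[k + 1L]
  list(kind = if (is.numeric(window)) paste0(window, "_line") else window,
       k = k, cutoff_day = cutoff)
}

# Simulate the named variant; returns model C at days (vector) or NULL on
# failure. theta is the natural-scale named vector.
.simulate_variant <- function(variant, theta, schedule, C0, days, ad_rtol = 1e-8) {
  tryCatch({
    C <- switch(variant,
      single = simulate_single(theta[["gamma_S"]], theta[["delta_S"]],
                               schedule, C0, days)$C,
      SR_R0 = simulate_sr(sr_params(gamma_R = theta[["gamma_R"]],
                                    gamma_S = theta[["gamma_S"]],
                                    delta_R = theta[["delta_R"]],
                                    delta_S = theta[["delta_S"]],
                                    mu = 0, R0 = theta[["R0_frac"]] * C0),
                          schedule, C0, days)$C,
      SR_mu = simulate_sr(sr_params(gamma_R = theta[["gamma_R"]],
                                    gamma_S = theta[["gamma_S"]],
                                    delta_R = theta[["delta_R"]],
                                    delta_S = theta[["delta_S"]],
                                    mu = theta[["mu"]], R0 = 0),
                          schedule, C0, days)$C,
      AD = simulate_ad(ad_params(gamma_R = theta[["gamma_R"]],
                                 gamma_S = theta[["gamma_S"]],
                                 delta_R = theta[["delta_R"]],
                                 delta_S = theta[["delta_S"]],
                                 A_gamma = theta[["A_gamma"]],
                                 A_delta = theta[["A_delta"]],
                                 B_gamma = theta[["B_gamma"]],
                                 B_delta = theta[["B_delta"]]),
                       schedule, C0, days, rtol = ad_rtol)$C
    )
    C
  }, error = function(e) NULL)
}

#' Least-squares objective on log CA-125
#'
#' Sum of squared deviations between log-transformed observed CA-125 and the
#' model prediction over the measurements inside the fitting window, with
#' C(0) fixed to the first observed value. Parameter sets producing
#' non-positive or non-finite trajectories return a large finite penalty
#' rather than an error, so optimisers can recover.
#'
#' @param theta named natural-scale parameter vector (see
#'   \code{\link{fit_control}} and the variant's free parameters).
#' @param patient a \code{\link{ca125_patient}}.
#' @param variant one of \code{"single"}, \code{"SR_R0"}, \code{"SR_mu"},
#'   \code{"AD"}.
#' @param window as in \code{\link{fitting_window}}.
#' @param penalty value returned for infeasible simulations.
#' @param ad_rtol integrator tolerance for the AD variant.
#' @return The residual sum of squares on the log scale.
#' @export
objective <- function(theta, patient, variant, window = "all",
                      penalty = 1e12, ad_rtol = 1e-6) {
  win <- fitting_window(patient, window)
  m <- patient$measurements
  m <- m[m$day <= win$cutoff_day, , drop = FALSE]
  if (nrow(m) < 1L) stop("no measurements inside the fitting window")
  C0 <- m$ca125[1L]
  C <- .simulate_variant(variant, theta, patient$schedule, C0, m$day, ad_rtol)
  if (is.null(C) || any(!is.finite(C)) || any(C <= 0)) return(penalty)
  sum((log(m$ca125) - log(C))^2)
}

# Fast objective for the SR family: precomputes the regime segmentation and
# the evaluation-day layout once, so each objective call is a short loop of
# closed-form updates. Equivalent to objective() on the same inputs.
.make_sr_objective <- function(patient, variant, window, penalty) {
  win <- fitting_window(patient, window)
  m <- patient$measurements[patient$measurements$day <= win$cutoff_day, ,
                            drop = FALSE]
  logY <- log(m$ca125)
  C0 <- m$ca125[1L]
  tmax <- max(m$day)
  seg <- .regime_segments(patient$schedule, tmax)
  nseg <- length(seg$start)
  idx <- lapply(seq_len(nseg), function(i)
    which(m$day > seg$start[i] & m$day <= seg$end[i]))
  dts <- lapply(seq_len(nseg), function(i) m$day[idx[[i]]] - seg$start[i])
  seglen <- seg$end - seg$start
  at0 <- which(m$day == 0)

  function(theta) {
    mu <- if (variant == "SR_mu") theta[["mu"]] else 0
    R <- if (variant == "SR_R0") theta[["R0_frac"]] * C0 else 0
    S <- C0 - R
    gR <- if (variant == "single") 0 else theta[["gamma_R"]]
    dR <- if (variant == "single") 0 else theta[["delta_R"]]
    gS <- theta[["gamma_S"]]; dS <- theta[["delta_S"]]
    pred <- numeric(length(logY))
    if (length(at0)) pred[at0] <- C0
    for (i in seq_len(nseg)) {
      a <- seg$a[i]
      ra <- (1 - a) * gR - a * dR
      rb <- (1 - a) * gS - a * dS - mu
      ii <- idx[[i]]
      if (length(ii)) {
        dt <- dts[[i]]
        ea <- exp(ra * dt); eb <- exp(rb * dt)
        Sv <- S * eb
        Rv <- if (mu == 0) R * ea else if (abs(rb - ra) < 1e-12)
          R * ea + mu * S * dt * ea else
          R * ea + mu * S * (eb - ea) / (rb - ra)
        pred[ii] <- Rv + Sv
      }
      dt <- seglen[i]
      ea <- exp(ra * dt); eb <- exp(rb * dt)
      Rnew <- if (mu == 0) R * ea else if (abs(rb - ra) < 1e-12)
        R * ea + mu * S * dt * ea else
        R * ea + mu * S * (eb - ea) / (rb - ra)
      S <- S * eb
      R <- Rnew
    }
    if (any(!is.finite(pred)) || any(pred <= 0)) return(penalty)
    sum((logY - log(pred))^2)
  }
}

# With mu = 0 the two compartments of the SR_R0 variant are exchangeable
# (C = R + S and each evolves independently), so the objective has two
# symmetric global minima. Canonical labelling: the resistant compartment is
# the one with the smaller on-treatment death rate. The swap is only taken
# when it keeps delta_S >= 0.
.canonicalize_sr_r0 <- function(theta) {
  if (theta[["delta_R"]] > theta[["delta_S"]] && theta[["delta_R"]] >= 0) {
    theta[c("gamma_R", "gamma_S", "delta_R", "delta_S")] <-
      theta[c("gamma_S", "gamma_R", "delta_S", "delta_R")]
    theta[["R0_frac"]] <- 1 - theta[["R0_frac"]]
  }
  theta
}

# Trait-derived initial estimates on the natural scale.
.initial_theta <- function(patient, variant) {
  tr <- estimate_traits(patient)$traits
  first_res <- tr$resistance[1L]
  first_agg <- tr$aggressiveness[1L]
  later_res <- rev(tr$resistance[-1L][!is.na(tr$resistance[-1L])])[1L]
  later_agg <- rev(tr$aggressiveness[-1L][!is.na(tr$aggressiveness[-1L])])[1L]
  pos <- function(v, fallback) {
    if (length(v) == 0L || is.na(v) || v <= 1e-5) fallback else v
  }
  delta_S <- pos(-first_res, 0.04)
  gamma_S <- pos(first_agg, 0.014)
  delta_R <- if (length(later_res) && !is.na(later_res)) -later_res else
    0.25 * delta_S
  gamma_R <- if (length(later_agg) && !is.na(later_agg) && later_agg > 1e-5)
    later_agg else 0.75 * gamma_S
  switch(variant,
    single = c(gamma_S = gamma_S, delta_S = delta_S),
    SR_R0 = c(gamma_R = gamma_R, gamma_S = gamma_S, delta_R = delta_R,
              delta_S = delta_S, R0_frac = 0.1),
    SR_mu = c(gamma_R = gamma_R, gamma_S = gamma_S, delta_R = delta_R,
              delta_S = delta_S, mu = 1e-4),
    AD = c(gamma_R = gamma_R, gamma_S = gamma_S, delta_R = delta_R,
           delta_S = delta_S, A_gamma = 0, A_delta = 0, B_gamma = 1,
           B_delta = 1)
  )
}

#' Fit a CA-125 dynamic model to one patient
#'
#' Constrained least squares on log CA-125 by multistart Nelder-Mead on a
#' smooth reparameterisation: non-negative rates via a log map, \code{R0} as
#' a logit-mapped fraction of C(0), \code{delta_R} and the AD offsets
#' unconstrained. The first start is derived from the patient's data-based
#' resistance and aggressiveness; further starts are jittered copies. The
#' best solution is polished by re-running the simplex from the incumbent.
#'
#' @param patient a \code{\link{ca125_patient}}.
#' @param variant \code{"single"}, \code{"SR_R0"}, \code{"SR_mu"} or
#'   \code{"AD"}.
#' @param window fitting window, see \code{\link{fitting_window}}.
#' @param control a \code{\link{fit_control}}.
#' @return An object of class \code{ca125_fit}: the estimates (\code{theta},
#'   natural scale), \code{rss}, \code{n_obs}, convergence information, the
#'   window actually used and the patient the model was fitted to.
#' @export
#' @examples
#' cfg <- generator_config(n_patients = 1, seed = 7, noise_sd = 0.1)
#' pat <- generate_cohort(cfg)$cohort[[1]]
#' fit <- ca125_fit(pat, "SR_R0", control = fit_control(n_restarts = 3))
#' coef(fit)
ca125_fit <- function(patient, variant = c("SR_R0", "SR_mu", "single", "AD"),
                      window = "all", control = fit_control()) {
  variant <- match.arg(variant)
  spec <- .variant_spec(variant)
  win <- fitting_window(patient, window)
  m <- patient$measurements[patient$measurements$day <= win$cutoff_day, ,
                            drop = FALSE]
  p <- length(spec$names)
  if (nrow(m) < p + 1L)
    stop("insufficient data: ", nrow(m), " measurements in window but ",
         p + 1L, " required for variant ", variant)

  obj_theta <- if (variant %in% c("single", "SR_R0", "SR_mu"))
    .make_sr_objective(patient, variant, window, control$penalty) else
    function(theta) objective(theta, patient, variant, window,
                              penalty = control$penalty,
                              ad_rtol = control$ad_rtol)
  obj_psi <- function(psi) obj_theta(.from_unconstrained(psi, spec))

  theta0 <- if (!is.null(control$init)) control$init[spec$names] else
    .initial_theta(patient, variant)
  psi0 <- .to_unconstrained(theta0, spec)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(control$seed)

  # Structured second start for the two-compartment variants: a large initial
  # resistant fraction with the compartment roles reversed, covering the
  # primary-resistance regime that trait-derived starts miss.
  psi_alts <- list()
  if (variant == "SR_R0") {
    alt <- theta0
    alt[c("gamma_R", "gamma_S", "delta_R", "delta_S")] <-
      theta0[c("gamma_S", "gamma_R", "delta_S", "delta_R")]
    alt[["delta_S"]] <- max(alt[["delta_S"]], 1e-4)
    alt[["R0_frac"]] <- 0.75
    # and a minor-resistant-clone start: R takes over only late
    alt2 <- theta0
    alt2[["R0_frac"]] <- 0.002
    alt2[["delta_R"]] <- -0.001
    psi_alts <- list(.to_unconstrained(alt, spec),
                     .to_unconstrained(alt2, spec))
  }
  # wider exploration on the bounded (logit) coordinates, whose natural scale
  # is compressed relative to the log-rate coordinates; the jitter magnitude
  # cycles through several scales so restarts probe both the neighbourhood of
  # the trait-derived start and distant basins
  jit_scale <- ifelse(spec$transform == "logit", 3, 1) * control$jitter_sd
  jit_cycle <- c(0.4, 1, 2)

  best <- NULL
  n_used <- 0L
  for (r in seq_len(max(1L, control$n_restarts))) {
    start <- if (r == 1L) psi0 else if (r - 1L <= length(psi_alts))
      psi_alts[[r - 1L]] else
      psi0 + stats::rnorm(length(psi0), 0,
                          jit_scale * jit_cycle[1L + (r %% 3L)])
    fit <- tryCatch(
      stats::optim(start, obj_psi, method = "Nelder-Mead",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e) NULL)
    n_used <- n_used + 1L
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || best$value >= control$penalty) {
    out <- structure(list(patient_id = patient$patient_id, variant = variant,
                          window = win, theta = theta0, rss = NA_real_,
                          n_obs = nrow(m), converged = FALSE,
                          n_restarts_used = n_used, patient = patient,
                          C0 = m$ca125[1L], control = control),
                     class = "ca125_fit")
    return(out)
  }
  # Polish: alternate quasi-Newton (finite-difference gradients) and simplex
  # restarts from the incumbent until no further improvement.
  for (i in seq_len(control$n_polish)) {
    improved <- FALSE
    for (method in c("BFGS", "Nelder-Mead")) {
      pol <- tryCatch(
        suppressWarnings(
          stats::optim(best$par, obj_psi, method = method,
                       control = list(maxit = control$maxit,
                                      reltol = control$reltol))),
        error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value) {
        improved <- TRUE
        best <- pol
      }
    }
    if (!improved) break
  }
  theta <- .from_unconstrained(best$par, spec)
  if (variant == "SR_R0") theta <- .canonicalize_sr_r0(theta)
  structure(list(patient_id = patient$patient_id, variant = variant,
                 window = win, theta = theta, rss = best$value,
                 n_obs = nrow(m), converged = TRUE,
                 n_restarts_used = n_used, patient = patient,
                 C0 = m$ca125[1L], control = control),
            class = "ca125_fit")
}

#' @export
coef.ca125_fit <- function(object, ...) object$theta

#' @export
print.ca125_fit <- function(x, ...) {
  cat("CA-125 model fit (", x$variant, ", window ", x$window$kind,
      ") for patient ", x$patient_id, "\n", sep = "")
  cat("  RSS(log):", format(x$rss, digits = 6), " n_obs:", x$n_obs,
      " converged:", x$converged, "\n")
  print(signif(x$theta, 5))
  invisible(x)
}

#' @export
summary.ca125_fit <- function(object, ...) {
  k <- length(object$theta) + 1L
  out <- list(fit = object,
              aic = if (is.na(object$rss)) NA_real_ else
                model_aic(object$rss, object$n_obs, k),
              sigma = if (is.na(object$rss)) NA_real_ else
                sqrt(object$rss / object$n_obs))
  class(out) <- "summary.ca125_fit"
  out
}

#' @export
print.summary.ca125_fit <- function(x, ...) {
  print(x$fit)
  cat("  AIC:", format(x$aic, digits = 6),
      " residual sd (log scale):", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

#' Predict CA-125 from a fitted model
#'
#' Simulates the fitted variant over the patient's full treatment schedule,
#' including lines beyond the fitting window, so out-of-window values are
#' genuine forecasts.
#'
#' @param object a \code{\link{ca125_fit}}.
#' @param days evaluation days; defaults to all of the patient's measurement
#'   days.
#' @param ... unused.
#' @return data.frame with columns \code{day} and \code{C} (predicted CA-125,
#'   U/mL).
#' @export
predict.ca125_fit <- function(object, days = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  if (is.null(days)) days <- object$patient$measurements$day
  C <- .simulate_variant(object$variant, object$theta,
                         object$patient$schedule, object$C0, sort(days),
                         ad_rtol = 1e-8)
  if (is.null(C)) stop("simulation failed at the fitted parameters")
  data.frame(day = sort(days), C = C)
}

#' Predict beyond the fitting window
#'
#' Convenience wrapper around \code{\link{predict.ca125_fit}} evaluating the
#' fitted model at every measurement day of the patient over the full
#' schedule.
#'
#' @param fit a converged \code{\link{ca125_fit}}.
#' @return data.frame with columns \code{day}, \code{C}, \code{observed} and
#'   \code{in_window}.
#' @export
predict_future <- function(fit) {
  m <- fit$patient$measurements
  pr <- predict(fit, days = m$day)
  pr$observed <- m$ca125[match(pr$day, m$day)]
  pr$in_window <- pr$day <= fit$window$cutoff_day
  pr
}

#' @export
residuals.ca125_fit <- function(object, ...) {
  m <- object$patient$measurements
  m <- m[m$day <= object$window$cutoff_day, , drop = FALSE]
  pr <- predict(object, days = m$day)
  log(m$ca125) - log(pr$C)
}

#' @export
logLik.ca125_fit <- function(object, ...) {
  n <- object$n_obs
  val <- -(n / 2) * (log(2 * pi * object$rss / n) + 1)
  attr(val, "df") <- length(object$theta) + 1L
  attr(val, "nobs") <- n
  class(val) <- "logLik"
  val
}

#' @export
plot.ca125_fit <- function(x, ...) {
  m <- x$patient$measurements
  pr <- predict(x, days = seq(0, max(m$day), length.out = 200))
  graphics::plot(m$day, m$ca125, log = "y", xlab = "day",
                 ylab = "CA-125 (U/mL)", pch = 16, ...)
  graphics::lines(pr$day, pr$C, col = "firebrick")
  if (is.finite(x$window$cutoff_day))
    graphics::abline(v = x$window$cutoff_day, lty = 2)
  invisible(x)
}

#' @export
simulate.ca125_fit <- function(object, nsim = 1, seed = NULL, sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sd)) sd <- sqrt(object$rss / object$n_obs)
  pr <- predict(object)
  out <- as.data.frame(replicate(nsim,
    pr$C * exp(stats::rnorm(nrow(pr), 0, sd))))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(day = pr$day, out)
}

#' Fit models across a cohort
#'
#' Runs \code{\link{ca125_fit}} for the Cartesian product of patients, model
#' variants and fitting windows. Failures (too few points, non-convergence)
#' are recorded as rows with \code{converged = FALSE}, never raised.
#'
#' @param cohort a \code{\link{ca125_cohort}} (normally eligibility-filtered).
#' @param variants character vector of variant names.
#' @param windows character vector of window kinds.
#' @param control a \code{\link{fit_control}}.
#' @return list of class \code{ca125_fit_table} with \code{fits} (nested
#'   list keyed by patient/variant/window) and \code{table} (one row per fit:
#'   estimates, rss, n_obs, converged, reason).
#' @export
fit_cohort <- function(cohort, variants = "SR_R0", windows = "all",
                       control = fit_control()) {
  fits <- list()
  rows <- list()
  for (id in names(cohort)) {
    for (v in variants) {
      for (w in windows) {
        key <- paste(id, v, w, sep = ".")
        f <- tryCatch(ca125_fit(cohort[[id]], v, w, control),
                      error = function(e) e)
        if (inherits(f, "error")) {
          rows[[key]] <- data.frame(patient_id = id, variant = v, window = w,
                                    rss = NA_real_, n_obs = NA_integer_,
                                    converged = FALSE,
                                    reason = conditionMessage(f))
        } else {
          fits[[key]] <- f
          th <- as.list(f$theta)
          names(th) <- names(f$theta)
          rows[[key]] <- cbind(
            data.frame(patient_id = id, variant = v, window = w,
                       rss = f$rss, n_obs = f$n_obs,
                       converged = f$converged, reason = ""),
            as.data.frame(th))
        }
      }
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    all_cols <- c("patient_id", "variant", "window", "rss", "n_obs",
                  "converged", "reason", "gamma_R", "gamma_S", "delta_R",
                  "delta_S", "R0_frac", "mu", "A_gamma", "A_delta",
                  "B_gamma", "B_delta")
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA_real_
    r[all_cols]
  }))
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab), class = "ca125_fit_table")
}

#' @export
print.ca125_fit_table <- function(x, ...) {
  cat("Cohort fit table:", nrow(x$table), "fits (",
      sum(x$table$converged), "converged )\n")
  invisible(x)
}
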