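# Local linear fit at target index using the k nearest neighbours by time
# (symmetric window clipped at the boundaries). Optionally leave the target
# point out of the fit.
.local_linear_at <- function(x, y, i, k, loo = FALSE) {
  n <- length(x)
  k <- max(2L, min(k, n))
  half <- k %/% 2L
  lo <- max(1L, i - half); hi <- min(n, lo + k - 1L); lo <- max(1L, hi - k + 1L)
  sel <- lo:hi
  if (loo) sel <- sel[sel != i]
  if (length(sel) < 2L) sel <- setdiff(seq_len(n), if (loo) i else integer())
  xs <- x[sel]; ys <- y[sel]
  xm <- mean(xs); ym <- mean(ys)
  sxx <- sum((xs - xm)^2)
  b <- if (sxx < .Machine$double.eps * max(1, sum(xs^2))) 0 else
    sum((xs - xm) * (ys - ym)) / sxx
  ym + b * (x[i] - xm)
}

#' Variable-span local linear smoother
#'
#' A smoothing reference in the style of Friedman's variable-span smoother:
#' candidate spans 0.05, 0.2 and 0.5 of the data are compared per point by
#' leave-one-out cross-validated residuals, the selected spans are themselves
#' smoothed at the mid span, and the final fit is a local linear fit with the
#' per-point span. With fewer than 10 points the fit falls back to a single
#' local linear fit at span 0.5. Used as the model-free baseline in the RSS
#' ratio.
#'
#' @param days strictly increasing numeric vector (ties must be collapsed
#'   beforehand).
#' @param log_values numeric response (conventionally log CA-125).
#' @return Fitted values at \code{days}.
#' @export
supersmoother <- function(days, log_values) {
  n <- length(days)
  if (n != length(log_values)) stop("days and values differ in length")
  if (n < 5L) stop("insufficient data: smoother needs at least 5 points")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  spans <- c(0.05, 0.2, 0.5)
  ks <- pmax(2L, ceiling(spans * n))
  fit_k <- function(kvec) vapply(seq_len(n), function(i)
    .local_linear_at(days, log_values, i, kvec[min(i, length(kvec))]), 0)
  if (n < 10L)
    return(vapply(seq_len(n), function(i)
      .local_linear_at(days, log_values, i, ks[3L]), 0))
  cv <- sapply(ks, function(k) vapply(seq_len(n), function(i)
    abs(log_values[i] - .local_linear_at(days, log_values, i, k, loo = TRUE)),
    0))
  pick <- spans[max.col(-cv, ties.method = "first")]
  # smooth the selected spans at the mid span, then refit with them
  k_mid <- pmax(2L, ceiling(0.2 * n))
  span_smooth <- vapply(seq_len(n), function(i)
    .local_linear_at(days, pick, i, k_mid), 0)
  span_smooth <- pmin(pmax(span_smooth, min(spans)), max(spans))
  k_final <- pmax(2L, ceiling(span_smooth * n))
  vapply(seq_len(n), function(i)
    .local_linear_at(days, log_values, i, k_final[i]), 0)
}

#' Goodness-of-fit ratio against the smoother baseline
#'
#' Ratio of the smoother's residual sum of squares to the model's. Values
#' near 1 mean the mechanistic model tracks the data about as closely as a
#' flexible model-free smoother; values near 0 mean it fits far worse.
#'
#' @param rss_sup RSS of the smoother on log CA-125.
#' @param rss_model RSS of the model on the same points.
#' @return \code{rss_sup / rss_model}; \code{Inf} (with a warning) when
#'   \code{rss_model} is zero.
#' @export
rss_ratio <- function(rss_sup, rss_model) {
  stopifnot(rss_sup >= 0, rss_model >= 0)
  if (rss_model == 0) {
    warning("rss_model is zero: ratio undefined, returning Inf")
    return(Inf)
  }
  rss_sup / rss_model
}

#' Akaike information criterion from a log-scale RSS
#'
#' Gaussian likelihood with the variance profiled out:
#' ln L = -(n/2) (ln(2 pi rss / n) + 1), AIC = 2k - 2 ln L. The parameter
#' count \code{k} should include the profiled variance (+1), applied
#' uniformly across variants so rankings are unaffected by the convention.
#'
#' @param rss residual sum of squares (log CA-125 scale).
#' @param n_obs number of observations.
#' @param k number of parameters (free model parameters + 1 for the
#'   variance).
#' @return AIC; \code{-Inf} when \code{rss} is zero (degenerate perfect fit).
#' @export
model_aic <- function(rss, n_obs, k) {
  stopifnot(n_obs > 0, rss >= 0, k >= 1)
  if (rss == 0) return(-Inf)
  lnL <- -(n_obs / 2) * (log(2 * pi * rss / n_obs) + 1)
  2 * k - 2 * lnL
}

#' In-sample and out-of-sample R-squared of a fit
#'
#' Three coefficients of determination on log CA-125: over the fitting-window
#' points (\code{r2_fitted}), over the points from just after the window
#' through the end of the gap following the next line (\code{r2_next},
#' short-term forecast), and over all points after the window
#' (\code{r2_later}, long-term forecast). Each uses total sum of squares
#' centred on that point set's own mean, so a forecast worse than the
#' evaluation points' mean yields a negative value. Entries are \code{NA}
#' when the point set has fewer than 2 points.
#'
#' @param fit a converged \code{\link{ca125_fit}}.
#' @return Named numeric vector \code{c(r2_fitted, r2_next, r2_later)}.
#' @export
r_squared_triplet <- function(fit) {
  if (!fit$converged) stop("fit did not converge")
  patient <- fit$patient
  pr <- predict_future(fit)
  logY <- log(pr$observed); logC <- log(pr$C)
  cutoff <- fit$window$cutoff_day
  lines <- patient$schedule$lines
  k <- fit$window$k
  next_end <- if (is.finite(k) && nrow(lines) > k + 1L)
    lines$start_day[k + 2L] else Inf
  r2 <- function(sel) {
    if (sum(sel) < 2L) return(NA_real_)
    y <- logY[sel]; f <- logC[sel]
    # a numerically diverged forecast carries no usable prediction
    if (any(!is.finite(f))) return(NA_real_)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(NA_real_)
    1 - sum((y - f)^2) / tss
  }
  c(r2_fitted = r2(pr$day <= cutoff),
    r2_next = r2(pr$day > cutoff & pr$day <= next_end),
    r2_later = r2(pr$day > cutoff))
}

#' Evaluate one fit: ratio, AIC and the R-squared triplet
#'
#' @param fit a \code{\link{ca125_fit}}.
#' @return One-row data.frame with \code{patient_id}, \code{variant},
#'   \code{window}, \code{ratio}, \code{aic}, \code{r2_fitted},
#'   \code{r2_next}, \code{r2_later}.
#' @export
evaluate_fit <- function(fit) {
  base <- data.frame(patient_id = fit$patient_id, variant = fit$variant,
                     window = fit$window$kind, ratio = NA_real_,
                     aic = NA_real_, r2_fitted = NA_real_,
                     r2_next = NA_real_, r2_later = NA_real_)
  if (!fit$converged) return(base)
  m <- fit$patient$measurements
  m <- m[m$day <= fit$window$cutoff_day, , drop = FALSE]
  base$ratio <- if (nrow(m) >= 5L) {
    smoothed <- supersmoother(m$day, log(m$ca125))
    rss_sup <- sum((log(m$ca125) - smoothed)^2)
    rss_ratio(rss_sup, fit$rss)
  } else NA_real_
  base$aic <- model_aic(fit$rss, fit$n_obs, length(fit$theta) + 1L)
  r2 <- r_squared_triplet(fit)
  base$r2_fitted <- r2[["r2_fitted"]]
  base$r2_next <- r2[["r2_next"]]
  base$r2_later <- r2[["r2_later"]]
  base
}

#' Evaluate every fit in a cohort fit table
#'
#' @param fit_table a \code{\link{fit_cohort}} result.
#' @return data.frame, one row per fit (non-converged fits keep \code{NA}
#'   metrics).
#' @export
evaluate_cohort <- function(fit_table) {
  stopifnot(inherits(fit_table, "ca125_fit_table"))
  rows <- lapply(fit_table$fits, evaluate_fit)
  failed <- fit_table$table[!fit_table$table$converged, , drop = FALSE]
  if (nrow(failed)) {
    rows <- c(rows, lapply(seq_len(nrow(failed)), function(i)
      data.frame(patient_id = failed$patient_id[i],
                 variant = failed$variant[i], window = failed$window[i],
                 ratio = NA_real_, aic = NA_real_, r2_fitted = NA_real_,
                 r2_next = NA_real_, r2_later = NA_real_)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
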