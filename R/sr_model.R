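#' Parameters of the sensitive/resistant two-cell-type model
#'
#' The model tracks treatment-sensitive cells S and treatment-resistant cells
#' R. Off treatment the populations grow at rates \code{gamma_S} and
#' \code{gamma_R}; during a treatment line they die at rates \code{delta_S}
#' and \code{delta_R}; sensitive cells convert to resistant ones at rate
#' \code{mu}. Observed CA-125 is C = R + S. \code{delta_R} may be negative
#' (net growth of resistant cells under treatment); all other rates are
#' non-negative.
#'
#' @param gamma_R,gamma_S growth rates off treatment, per day (>= 0).
#' @param delta_R death rate of resistant cells on treatment, per day
#'   (unconstrained sign).
#' @param delta_S death rate of sensitive cells on treatment, per day (>= 0).
#' @param mu sensitive-to-resistant transition rate, per day (>= 0); acts
#'   both on and off treatment.
#' @param R0 initial resistant population, same units as CA-125 (>= 0).
#' @param delta_C optional CA-125 turnover rate per day for the extended
#'   marker-kinetics variant (\code{NA} = instantaneous marker, C = R + S).
#' @return An object of class \code{sr_params}.
#' @export
sr_params <- function(gamma_R = 0.01024, gamma_S = 0.0142,
                      delta_R = -0.00018, delta_S = 0.04421,
                      mu = 0, R0 = 0, delta_C = NA_real_) {
  stopifnot(gamma_R >= 0, gamma_S >= 0, delta_S >= 0, mu >= 0, R0 >= 0)
  structure(list(gamma_R = gamma_R, gamma_S = gamma_S, delta_R = delta_R,
                 delta_S = delta_S, mu = mu, R0 = R0, delta_C = delta_C),
            class = "sr_params")
}

#' @export
print.sr_params <- function(x, ...) {
  cat("SR model parameters (per day):\n")
  print(unlist(x[c("gamma_R", "gamma_S", "delta_R", "delta_S", "mu", "R0")]))
  invisible(x)
}

# Net per-capita rates of the linear system under indicator a:
#   dR/dt = rate_R * R + mu * S,  dS/dt = rate_S * S
.sr_rates <- function(params, a) {
  list(r = (1 - a) * params$gamma_R - a * params$delta_R,
       s = (1 - a) * params$gamma_S - a * params$delta_S - params$mu)
}

#' Exact propagation of the SR system over one treatment regime
#'
#' Advances the state (R, S) by \code{dt} days under a constant treatment
#' indicator using the closed-form solution of the triangular linear system.
#' With per-capita rates a (resistant) and b (sensitive, including the -mu
#' drain), S(dt) = S e^(b dt) and
#' R(dt) = R e^(a dt) + mu S (e^(b dt) - e^(a dt)) / (b - a), replaced by the
#' analytic limit R e^(a dt) + mu S dt e^(a dt) when |b - a| < 1e-12.
#'
#' @param state named numeric vector or list with elements \code{R}, \code{S}.
#' @param params an \code{\link{sr_params}}.
#' @param a treatment indicator, 0 or 1.
#' @param dt non-negative duration in days.
#' @return Named numeric vector \code{c(R, S, C)} with C = R + S.
#' @export
propagate_interval <- function(state, params, a, dt) {
  if (dt < 0) stop("dt must be non-negative")
  R <- state[["R"]]; S <- state[["S"]]
  rt <- .sr_rates(params, a)
  ea <- exp(rt$r * dt); eb <- exp(rt$s * dt)
  Snew <- S * eb
  if (params$mu == 0) {
    Rnew <- R * ea
  } else if (abs(rt$s - rt$r) < 1e-12) {
    Rnew <- R * ea + params$mu * S * dt * ea
  } else {
    Rnew <- R * ea + params$mu * S * (eb - ea) / (rt$s - rt$r)
  }
  c(R = Rnew, S = Snew, C = Rnew + Snew)
}

# Breakpoint grid for piecewise propagation: segment boundaries at every line
# start/end clipped to [0, tmax], with the indicator on each open segment.
.regime_segments <- function(schedule, tmax) {
  iv <- schedule$intervals
  bp <- sort(unique(c(0, tmax, iv[iv[, 1L] <= tmax, 1L],
                      iv[iv[, 2L] <= tmax, 2L])))
  bp <- bp[bp >= 0 & bp <= tmax]
  if (length(bp) < 2L) bp <- c(0, tmax)
  mid <- (bp[-length(bp)] + bp[-1L]) / 2
  list(start = bp[-length(bp)], end = bp[-1L],
       a = alpha(schedule, mid))
}

#' Simulate the SR model along a treatment schedule
#'
#' Propagates the two-compartment system exactly across every regime boundary
#' (line starts and ends) and evaluates CA-125 C = R + S at \code{eval_days}.
#' Initial state: R(0) = \code{params$R0}, S(0) = \code{C0 - params$R0}.
#'
#' @param params an \code{\link{sr_params}} with \code{R0 <= C0}.
#' @param schedule a \code{\link{ca125_schedule}}.
#' @param C0 initial CA-125 (> 0), conventionally the first observed value.
#' @param eval_days non-negative days at which to report the state.
#' @return data.frame of class \code{ca125_trajectory} with columns
#'   \code{day}, \code{R}, \code{S}, \code{C}.
#' @export
simulate_sr <- function(params, schedule, C0, eval_days) {
  stopifnot(C0 > 0, all(eval_days >= 0))
  if (params$R0 > C0)
    stop("infeasible initial condition: R0 exceeds C(0)")
  eval_days <- sort(eval_days)
  tmax <- max(eval_days, 0)
  seg <- .regime_segments(schedule, tmax)
  out <- matrix(NA_real_, nrow = length(eval_days), ncol = 3L,
                dimnames = list(NULL, c("R", "S", "C")))
  state <- c(R = params$R0, S = C0 - params$R0)
  t0 <- 0
  if (any(eval_days == 0))
    out[eval_days == 0, ] <- c(state, sum(state))
  for (i in seq_along(seg$start)) {
    rt <- .sr_rates(params, seg$a[i])
    sel <- which(eval_days > seg$start[i] & eval_days <= seg$end[i])
    if (length(sel)) {
      dt <- eval_days[sel] - seg$start[i]
      ea <- exp(rt$r * dt); eb <- exp(rt$s * dt)
      Sv <- state[["S"]] * eb
      if (params$mu == 0) {
        Rv <- state[["R"]] * ea
      } else if (abs(rt$s - rt$r) < 1e-12) {
        Rv <- state[["R"]] * ea + params$mu * state[["S"]] * dt * ea
      } else {
        Rv <- state[["R"]] * ea +
          params$mu * state[["S"]] * (eb - ea) / (rt$s - rt$r)
      }
      out[sel, "R"] <- Rv; out[sel, "S"] <- Sv; out[sel, "C"] <- Rv + Sv
    }
    state <- propagate_interval(state, params, seg$a[i],
                                seg$end[i] - seg$start[i])[c("R", "S")]
  }
  traj <- data.frame(day = eval_days, R = out[, "R"], S = out[, "S"],
                     C = out[, "C"])
  class(traj) <- c("ca125_trajectory", "data.frame")
  traj
}

#' Simulate the single cell-type special case
#'
#' The single-compartment model is the SR system with \code{mu = 0} and
#' \code{R0 = 0}: log CA-125 is piecewise linear with slope \code{-delta_S}
#' on treatment and \code{gamma_S} off treatment.
#'
#' @param gamma_S,delta_S growth and death rates per day.
#' @inheritParams simulate_sr
#' @return As \code{\link{simulate_sr}}.
#' @export
simulate_single <- function(gamma_S, delta_S, schedule, C0, eval_days) {
  simulate_sr(sr_params(gamma_R = 0, gamma_S = gamma_S, delta_R = 0,
                        delta_S = delta_S, mu = 0, R0 = 0),
              schedule, C0, eval_days)
}

#' Simulate the extended marker-kinetics variant
#'
#' Couples CA-125 turnover dC/dt = delta_C (R + S - C) to the two-compartment
#' dynamics, so the observed marker tracks the tumour burden with lag
#' 1/delta_C. Integrated numerically (lsoda) with restarts at every regime
#' boundary.
#'
#' @param params an \code{\link{sr_params}} with positive \code{delta_C}.
#' @inheritParams simulate_sr
#' @return data.frame with columns \code{day}, \code{R}, \code{S}, \code{C}.
#' @export
simulate_sr_extended <- function(params, schedule, C0, eval_days) {
  if (is.na(params$delta_C) || params$delta_C <= 0)
    stop("delta_C must be positive for the extended variant")
  stopifnot(C0 > 0, all(eval_days >= 0))
  if (params$R0 > C0) stop("infeasible initial condition: R0 exceeds C(0)")
  deriv <- function(t, y, parms) {
    a <- parms$a
    rt <- .sr_rates(params, a)
    list(c(rt$r * y[1L] + params$mu * y[2L],
           rt$s * y[2L],
           params$delta_C * (y[1L] + y[2L] - y[3L])))
  }
  .piecewise_ode(y0 = c(R = params$R0, S = C0 - params$R0, C = C0),
                 deriv = deriv, schedule = schedule, eval_days = eval_days,
                 rtol = 1e-8, atol = 1e-10)
}

# Shared piecewise integration: restart lsoda at every regime boundary so no
# step crosses an alpha switch. deriv(t, y, parms) sees parms$a.
.piecewise_ode <- function(y0, deriv, schedule, eval_days, rtol, atol) {
  eval_days <- sort(eval_days)
  tmax <- max(eval_days, 0)
  seg <- .regime_segments(schedule, tmax)
  res <- matrix(NA_real_, nrow = length(eval_days), ncol = length(y0),
                dimnames = list(NULL, names(y0)))
  if (any(eval_days == 0)) res[eval_days == 0, ] <- y0
  state <- y0
  for (i in seq_along(seg$start)) {
    sel <- which(eval_days > seg$start[i] & eval_days <= seg$end[i])
    times <- sort(unique(c(seg$start[i], eval_days[sel], seg$end[i])))
    if (length(times) < 2L) next
    sol <- deSolve::lsoda(y = state, times = times, func = deriv,
                          parms = list(a = seg$a[i]),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("integrator failure on segment [", seg$start[i], ", ",
           seg$end[i], "]")
    if (length(sel))
      res[sel, ] <- sol[match(eval_days[sel], sol[, 1L]), -1L, drop = FALSE]
    state <- sol[nrow(sol), -1L]
  }
  out <- data.frame(day = eval_days, as.data.frame(res))
  class(out) <- c("ca125_trajectory", "data.frame")
  out
}

# Reference integrator for the plain SR system (test oracle; the closed-form
# propagation is the production path).
.simulate_sr_ode <- function(params, schedule, C0, eval_days,
                             rtol = 1e-10, atol = 1e-12) {
  deriv <- function(t, y, parms) {
    rt <- .sr_rates(params, parms$a)
    list(c(rt$r * y[1L] + params$mu * y[2L], rt$s * y[2L]))
  }
  out <- .piecewise_ode(y0 = c(R = params$R0, S = C0 - params$R0),
                        deriv = deriv, schedule = schedule,
                        eval_days = eval_days, rtol = rtol, atol = atol)
  out$C <- out$R + out$S
  out
}

#' @export
plot.ca125_trajectory <- function(x, log = "y", ...) {
  graphics::plot(x$day, x$C, type = "l", log = log, xlab = "day",
                 ylab = "CA-125 (U/mL)", ...)
  invisible(x)
}
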