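#' Parameters of the adaptive-dynamics model
#'
#' A single cancer cell population N carries a continuous chemoresistance
#' level x shared by all cells. Growth and death rates interpolate between
#' the sensitive and resistant extremes through logistic functions of x:
#' gamma(x) = gamma_R + (gamma_S - gamma_R) / (1 + exp(B_gamma x + A_gamma)),
#' and analogously delta(x). x climbs the gradient of the net growth
#' W(x) = (1 - alpha) gamma(x) - alpha delta(x) at rate K, so treatment
#' pushes x up (towards resistance) and treatment-free intervals pull it
#' down (towards faster growth).
#'
#' @param gamma_R,gamma_S,delta_R,delta_S rates per day, as in
#'   \code{\link{sr_params}}.
#' @param A_gamma,A_delta dimensionless offsets placing the half-maximum of
#'   the growth and death curves.
#' @param B_gamma,B_delta dimensionless non-negative shape (steepness)
#'   parameters.
#' @param K selection-response rate (per day), fixed at 0.01 in the standard
#'   analysis.
#' @param x0 initial resistance level (dimensionless; not an estimated
#'   parameter - the offsets A absorb the choice of origin).
#' @return An object of class \code{ad_params}.
#' @export
ad_params <- function(gamma_R = 0.01024, gamma_S = 0.0142,
                      delta_R = -0.00018, delta_S = 0.04421,
                      A_gamma = 0, A_delta = 0, B_gamma = 1, B_delta = 1,
                      K = 0.01, x0 = 0) {
  stopifnot(gamma_R >= 0, gamma_S >= 0, delta_S >= 0,
            B_gamma >= 0, B_delta >= 0, K > 0)
  structure(list(gamma_R = gamma_R, gamma_S = gamma_S, delta_R = delta_R,
                 delta_S = delta_S, A_gamma = A_gamma, A_delta = A_delta,
                 B_gamma = B_gamma, B_delta = B_delta, K = K, x0 = x0),
            class = "ad_params")
}

#' @export
print.ad_params <- function(x, ...) {
  cat("Adaptive-dynamics model parameters:\n")
  print(unlist(x))
  invisible(x)
}

# Overflow-safe logistic 1 / (1 + e^u)
.inv_logistic <- function(u) {
  out <- numeric(length(u))
  pos <- u >= 0
  out[pos] <- exp(-u[pos]) / (1 + exp(-u[pos]))
  out[!pos] <- 1 / (1 + exp(u[!pos]))
  out
}

# Derivative of 1 / (1 + e^u) wrt u: -e^u / (1 + e^u)^2, overflow-safe
.inv_logistic_deriv <- function(u) {
  s <- .inv_logistic(abs(u))          # = 1/(1+e^|u|)
  -(s * (1 - s))                      # symmetric in u
}

#' Growth rate as a function of resistance level
#'
#' @param x resistance level (vectorised).
#' @param params an \code{\link{ad_params}}.
#' @return gamma(x): tends to \code{gamma_R} as x grows large and to
#'   \code{gamma_S} as x becomes very negative (for \code{B_gamma > 0}).
#' @export
gamma_of_x <- function(x, params) {
  params$gamma_R + (params$gamma_S - params$gamma_R) *
    .inv_logistic(params$B_gamma * x + params$A_gamma)
}

#' Death rate as a function of resistance level
#'
#' @inheritParams gamma_of_x
#' @return delta(x), interpolating \code{delta_S} (x very negative) to
#'   \code{delta_R} (x very positive).
#' @export
delta_of_x <- function(x, params) {
  params$delta_R + (params$delta_S - params$delta_R) *
    .inv_logistic(params$B_delta * x + params$A_delta)
}

#' Fitness gradient of the resistance level
#'
#' Analytic derivative of the net growth W(x) = (1 - alpha) gamma(x) -
#' alpha delta(x) with respect to x. On treatment (alpha = 1) with
#' \code{delta_S > delta_R} the gradient is positive everywhere (selection
#' for resistance); off treatment with \code{gamma_S > gamma_R} it is
#' negative (selection for growth).
#'
#' @param x resistance level (vectorised).
#' @param a treatment indicator, 0 or 1.
#' @param params an \code{\link{ad_params}}.
#' @return dW/dx at x.
#' @export
fitness_gradient <- function(x, a, params) {
  dgamma <- (params$gamma_S - params$gamma_R) * params$B_gamma *
    .inv_logistic_deriv(params$B_gamma * x + params$A_gamma)
  ddelta <- (params$delta_S - params$delta_R) * params$B_delta *
    .inv_logistic_deriv(params$B_delta * x + params$A_delta)
  (1 - a) * dgamma - a * ddelta
}

#' Simulate the adaptive-dynamics model along a treatment schedule
#'
#' Integrates dN/dt = W(x) N and dx/dt = K dW/dx with N(0) = C0 and
#' x(0) = \code{params$x0}, restarting the integrator at every regime
#' boundary. log N is integrated for positivity; CA-125 output is N.
#'
#' @param params an \code{\link{ad_params}}.
#' @param schedule a \code{\link{ca125_schedule}}.
#' @param C0 initial CA-125 (> 0).
#' @param eval_days non-negative evaluation days.
#' @param rtol,atol integrator tolerances.
#' @return data.frame of class \code{ca125_trajectory} with columns
#'   \code{day}, \code{N}, \code{x}, \code{C} (= N).
#' @export
simulate_ad <- function(params, schedule, C0, eval_days,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ad_params"), C0 > 0, all(eval_days >= 0))
  deriv <- function(t, y, parms) {
    a <- parms$a
    x <- y[2L]
    W <- (1 - a) * gamma_of_x(x, params) - a * delta_of_x(x, params)
    list(c(W, params$K * fitness_gradient(x, a, params)))
  }
  out <- .piecewise_ode(y0 = c(logN = log(C0), x = params$x0), deriv = deriv,
                        schedule = schedule, eval_days = eval_days,
                        rtol = rtol, atol = atol)
  traj <- data.frame(day = out$day, N = exp(out$logN), x = out$x,
                     C = exp(out$logN))
  class(traj) <- c("ca125_trajectory", "data.frame")
  traj
}
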